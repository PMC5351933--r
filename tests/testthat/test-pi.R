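# Haplotype overlap proportion and conditional variants.

# Panel with 4 engineered blocks; patterns chosen so cross-block r2 stays
# well below 0.8 (0 or 1/3).
pi_panel <- function() {
  fixture_panel(list(
    list(ids = c("g1", "a1"), pattern = c(1, 1, 1, 1, 0, 0, 0, 0)),
    list(ids = c("g2", "a2"), pattern = c(1, 1, 0, 0, 1, 1, 0, 0)),
    list(ids = c("g3", "a3"), pattern = c(1, 0, 1, 0, 1, 0, 1, 0)),
    list(ids = c("g4", "a4"), pattern = c(1, 1, 1, 0, 0, 0, 1, 0))
  ))
}

member_interval <- function(panel, id) {
  pos <- panel$variants$pos[panel$variants$id == id]
  interval_set("chr1", pos - 1, pos)
}

test_that("pi_statistic counts blocks with any member inside the annotation", {
  panel <- pi_panel()
  blocks <- expand_blocks(panel, c("g1", "g2", "g3", "g4"), min_r2 = 0.8)
  # members are exactly the within-block pairs
  expect_equal(nrow(blocks$members), 8)

  expect_equal(pi_statistic(blocks, interval_set(), panel), 0)

  # annotation covering the members of g1 and g3 only -> 0.5
  ann <- rbind(member_interval(panel, "a1"), member_interval(panel, "a3"))
  expect_equal(pi_statistic(blocks, ann, panel), 0.5)

  # every sentinel inside the annotation -> 1
  all_s <- do.call(rbind, lapply(c("g1", "g2", "g3", "g4"), function(id) {
    member_interval(panel, id)
  }))
  expect_equal(pi_statistic(blocks, all_s, panel), 1)

  empty <- structure(list(members = blocks$members[0, ], sentinels = character(0),
                          r2_threshold = 0.8, window_bp = 1e7),
                     class = "haplotype_blocks")
  expect_warning(out <- pi_statistic(empty, ann, panel), "zero")
  expect_true(is.na(out))
})

test_that("pi against a union of annotations is at least the max of the parts", {
  panel <- pi_panel()
  blocks <- expand_blocks(panel, c("g1", "g2", "g3", "g4"), min_r2 = 0.8)
  a <- member_interval(panel, "a1")
  b <- rbind(member_interval(panel, "a2"), member_interval(panel, "a3"))
  pu <- pi_statistic(blocks, rbind(a, b), panel)
  expect_gte(pu, max(pi_statistic(blocks, a, panel),
                     pi_statistic(blocks, b, panel)))
})

test_that("pi_curve is non-increasing in r2 and respects declared nesting", {
  ds <- generate_dataset(small_config(n_sentinels = 200, planted_fold = 2,
                                      seed = 21))
  layers <- list(
    dhs = ds$dhs,
    footprints = ds$footprints,
    footprint_motif = intersect_intervals(ds$footprints, ds$motif_occurrences)
  )
  pc <- pi_curve(ds$sentinels$id, ds$panel, layers, r2_grid = c(0.5, 0.7, 0.9))
  for (layer in names(layers)) {
    v <- pc$pi[pc$layer == layer]
    expect_true(all(diff(v) <= 1e-12), info = layer)
  }
  for (thr in unique(pc$r2_threshold)) {
    v <- pc$pi[pc$r2_threshold == thr]
    names(v) <- pc$layer[pc$r2_threshold == thr]
    expect_gte(v[["dhs"]], v[["footprints"]])
    expect_gte(v[["footprints"]], v[["footprint_motif"]])
  }
  expect_true(all(pc$n_blocks == 200))
  expect_true(all(pc$pi >= 0 & pc$pi <= 1))
})

test_that("degenerate grid at r2 = 1 reduces to sentinel-only overlap", {
  withr::with_seed(31, {
    # panel of mutually-uncorrelated-ish random columns: no perfect proxies
    cols <- replicate(12, random_binary_col(30))
    variants <- data.frame(id = sprintf("v%02d", 1:12), chrom = "c1",
                           pos = 100 * (1:12), ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
    panel <- phased_panel(variants, cols)
    ann <- interval_set(chrom = rep("c1", 2), start = c(99, 399),
                        end = c(100, 400))  # covers v01 and v04 only
    pc <- pi_curve(c("v01", "v02", "v04"), panel, list(ann = ann),
                   r2_grid = 1.0)
    expect_equal(pc$pi, 2 / 3)
  })
})

test_that("conditional pi restricts to blocks sharing member variants", {
  panel <- fixture_panel(list(
    list(ids = c("gs1", "es1", "m1"), pattern = c(1, 1, 1, 1, 0, 0, 0, 0)),
    list(ids = c("gs2", "es2", "m2"), pattern = c(1, 1, 0, 0, 1, 1, 0, 0)),
    list(ids = c("gs3", "es3", "m3"), pattern = c(1, 0, 1, 0, 1, 0, 1, 0)),
    list(ids = "gs4", pattern = c(1, 1, 0, 0, 0, 0, 1, 1)),
    list(ids = "gs5", pattern = c(1, 0, 0, 1, 1, 0, 0, 1))
  ))
  ga <- expand_blocks(panel, paste0("gs", 1:5), min_r2 = 0.8)
  eb <- expand_blocks(panel, paste0("es", 1:3), min_r2 = 0.8)
  # annotation hits m1 only: 3 of 5 GWAS blocks share an eQTL SNV, 1 of
  # those 3 hits the annotation -> 1/3
  ann <- member_interval(panel, "m1")
  out <- conditional_pi(ga, eb, ann, panel)
  expect_equal(as.numeric(out), 1 / 3)
  expect_equal(attr(out, "n_conditional"), 3)

  # identity: conditioning a block set on itself is the unconditional value
  out2 <- conditional_pi(ga, ga, ann, panel)
  expect_equal(as.numeric(out2), pi_statistic(ga, ann, panel))

  # disjoint block sets: undefined with a zero count
  solo <- expand_blocks(panel, "gs4", min_r2 = 0.8)
  other <- expand_blocks(panel, "gs5", min_r2 = 0.8)
  expect_warning(out3 <- conditional_pi(solo, other, ann, panel), "share")
  expect_true(is.na(out3))
  expect_equal(attr(out3, "n_conditional"), 0)
})

test_that("down-sampling blocks leaves the expected proportion unchanged", {
  ds <- generate_dataset(small_config(n_sentinels = 300, planted_fold = 2,
                                      seed = 33))
  blocks <- expand_blocks(ds$panel, ds$sentinels$id, min_r2 = 0.5)
  hits <- block_hits(blocks, ds$footprints, ds$panel)
  full <- mean(hits)
  withr::with_seed(7, {
    sub_means <- vapply(1:1000, function(i) mean(sample(hits, 100)), 1)
  })
  se <- stats::sd(sub_means) / sqrt(1000)
  expect_lt(abs(mean(sub_means) - full), max(2 * se, 1e-3))
})
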