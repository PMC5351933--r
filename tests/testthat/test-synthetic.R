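# Synthetic dataset generator: determinism, invariants, planted effects,
# round-trip I/O.

test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(n_dhs = -1), "n_dhs")
  expect_error(synthetic_config(footprint_per_dhs_prob = 1.5),
               "footprint_per_dhs_prob")
  expect_error(synthetic_config(dhs_length_bp = c(500, 200)), "dhs_length_bp")
  expect_error(synthetic_config(motif_length = 15,
                                footprint_length_bp = c(11, 22)),
               "motif_length")
  expect_error(synthetic_config(planted_fold = -2), "planted_fold")
  expect_error(synthetic_config(n_haplotypes_in_panel = 99),
               "n_haplotypes_in_panel")
  # infeasible fold is caught at generation with the field named
  expect_error(generate_dataset(small_config(planted_fold = 500)),
               "planted_fold")
})

test_that("the same seed gives a bit-identical dataset, different seeds differ", {
  cfg <- small_config(seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(small_config(seed = 6))
  expect_false(identical(d1$panel$variants$pos, d3$panel$variants$pos))
})

test_that("containment invariants hold for every generated record", {
  ds <- generate_dataset(small_config(seed = 8, n_chromosomes = 2,
                                      chrom_length_bp = 3e5))
  # footprint subset DHS: subtracting DHS territory leaves nothing
  expect_equal(nrow(subtract_intervals(ds$footprints, ds$dhs)), 0)
  expect_equal(nrow(subtract_intervals(ds$dhs, ds$workspace)), 0)
  # each footprint is inside exactly one DHS
  ov <- GenomicRanges::countOverlaps(
    haplofoot:::as_granges(ds$footprints), haplofoot:::as_granges(ds$dhs))
  expect_true(all(ov == 1))
  # DHS do not overlap each other
  expect_equal(interval_bp(ds$dhs), interval_bp(ds$dhs, merge = FALSE))
  # footprint widths respect the configured range
  w <- ds$footprints$end - ds$footprints$start
  expect_true(all(w >= 11 & w <= 22))
  # sentinels all lie within DHS
  v <- ds$panel$variants
  sent <- v[v$id %in% ds$sentinels$id, ]
  iv <- interval_set(sent$chrom, sent$pos - 1, sent$pos)
  expect_true(all(intersect_any(iv, ds$dhs)))
})

test_that("perfect within-block LD when the target r2 is 1", {
  ds <- generate_dataset(small_config(within_block_r2 = 1, n_snvs = 100,
                                      seed = 9))
  v <- ds$panel$variants
  key <- paste0(v$chrom, ":", floor((v$pos - 1) / 10000))
  blocks <- split(seq_len(nrow(v)), key)
  blocks <- Filter(function(ix) length(ix) >= 2, blocks)
  expect_gt(length(blocks), 0)
  for (ix in blocks[1:min(5, length(blocks))]) {
    r <- compute_r2(ds$panel$haplotypes[, ix[1]], ds$panel$haplotypes[, ix[2]])
    expect_equal(r, 1)
  }
})

test_that("mean within-block r2 approaches the target for a 200-haplotype panel", {
  ds <- generate_dataset(small_config(n_haplotypes_in_panel = 200,
                                      n_snvs = 400, n_sentinels = 0,
                                      within_block_r2 = 0.8, seed = 10))
  v <- ds$panel$variants
  key <- paste0(v$chrom, ":", floor((v$pos - 1) / 10000))
  r2s <- unlist(lapply(split(seq_len(nrow(v)), key), function(ix) {
    if (length(ix) < 2) return(NULL)
    pairs <- utils::combn(ix[seq_len(min(6, length(ix)))], 2)
    apply(pairs, 2, function(p) {
      compute_r2(ds$panel$haplotypes[, p[1]], ds$panel$haplotypes[, p[2]])
    })
  }))
  r2s <- r2s[!is.na(r2s)]
  expect_gt(length(r2s), 50)
  expect_lt(abs(mean(r2s) - 0.8), 0.1)
})

test_that("a unit planted fold leaves sentinel overlap at the baseline rate", {
  ds <- generate_dataset(small_config(n_sentinels = 10000, planted_fold = 1,
                                      n_snvs = 200, seed = 1))
  q <- ds$truth$baseline_rate
  rate <- mean(ds$truth$sentinels$in_footprint)
  expect_lt(abs(rate - q), 3 * sqrt(q * (1 - q) / 10000))
  expect_false(any(ds$truth$sentinels$forced))
})

test_that("the realized fold tracks the planted fold", {
  ds <- generate_dataset(small_config(n_sentinels = 10000, planted_fold = 1.65,
                                      n_snvs = 200, seed = 2))
  expect_gt(ds$truth$realized_fold, 1.45)
  expect_lt(ds$truth$realized_fold, 1.85)
})

test_that("planted artefacts are exactly the footprints the filter removes", {
  ds <- generate_dataset(small_config(seed = 12, artefact_spike_prob = 0.1))
  parts <- filter_artefacts(ds$footprints, ds$cut_track)
  planted <- ds$truth$footprints$name[ds$truth$footprints$artefact]
  expect_setequal(parts$removed$name, planted)
})

test_that("datasets round-trip through the on-disk format", {
  ds <- generate_dataset(small_config(seed = 13, n_snvs = 60,
                                      n_sentinels = 40, n_motifs = 30,
                                      n_dhs = 40, chrom_length_bp = 5e4,
                                      n_haplotypes_in_panel = 20))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(!is.na(manifest$md5)))
  # footprint BED line count equals the generated footprint count
  expect_equal(length(readLines(file.path(dir, "footprints.bed"))),
               nrow(ds$footprints))

  back <- read_dataset(dir)
  for (f in c("workspace", "dhs", "footprints", "blacklist")) {
    expect_equal(back[[f]][c("chrom", "start", "end", "name", "score")],
                 ds[[f]][c("chrom", "start", "end", "name", "score")],
                 info = f)
  }
  expect_equal(back$motif_occurrences$tf_id, ds$motif_occurrences$tf_id)
  expect_equal(back$panel$variants, ds$panel$variants)
  expect_equal(unname(back$panel$haplotypes), unname(ds$panel$haplotypes))
  expect_identical(back$cut_track, ds$cut_track)
  expect_identical(back$conservation_track, ds$conservation_track)
  expect_equal(back$sentinels, ds$sentinels)
  expect_equal(back$expression, ds$expression)
  expect_equal(back$hits, ds$hits)
  expect_equal(back$pwms$TF01$prob, ds$pwms$TF01$prob)
  expect_equal(unclass(back$config), unclass(ds$config))
  expect_equal(back$truth$footprints, ds$truth$footprints)
  expect_equal(back$truth$sentinels, ds$truth$sentinels)
  expect_equal(back$truth$baseline_rate, ds$truth$baseline_rate,
               tolerance = 1e-6)
})

test_that("an empty dataset still writes valid files and a manifest", {
  cfg <- small_config(n_dhs = 0, n_sentinels = 0, n_motifs = 0, n_snvs = 10)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$dhs), 0)
  expect_equal(nrow(ds$footprints), 0)
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_equal(nrow(read_bed(file.path(dir, "dhs.bed"))), 0)
  expect_equal(nrow(read_bed(file.path(dir, "footprints.bed"))), 0)
})
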