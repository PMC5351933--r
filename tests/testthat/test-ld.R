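# LD r-squared and haplotype block expansion.

test_that("compute_r2 reproduces the haplotype-frequency formula", {
  expect_equal(compute_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_r2(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.0)
  # 2x2 haplotype-count table oracle: pA = 3/8, pB = 2/8, pAB = 2/8
  # -> (2/8 - 6/64)^2 / ((3/8)(5/8)(2/8)(6/8)) = 5/9
  expect_equal(compute_r2(c(1, 1, 1, 0, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0, 0, 0)),
               5 / 9, tolerance = 1e-12)
})

test_that("compute_r2 is symmetric, allele-label invariant, and NA when monomorphic", {
  withr::with_seed(3, {
    for (i in 1:25) {
      n <- sample(c(10, 50, 200), 1)
      a <- random_binary_col(n)
      b <- random_binary_col(n)
      r <- compute_r2(a, b)
      expect_equal(r, compute_r2(b, a))
      expect_equal(r, compute_r2(1 - a, b))
      expect_equal(r, compute_r2(a, 1 - b))
      expect_equal(r, suppressWarnings(stats::cor(a, b))^2, tolerance = 1e-12)
      expect_gte(r, 0)
      expect_lte(r, 1 + 1e-12)
    }
  })
  expect_true(is.na(compute_r2(c(0, 0, 0, 0), c(1, 0, 1, 0))))
  expect_true(is.na(compute_r2(c(1, 0, 1, 0), c(1, 1, 1, 1))))
})

test_that("expand_haplotype collects exactly the linked variants", {
  # groups in perfect LD; cross-group r2 is 0 or 1/3, below any threshold used
  pA <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pB <- c(1, 1, 0, 0, 1, 1, 0, 0)
  panel <- fixture_panel(list(
    list(ids = c("s1", "m1", "m2", "m3", "m4"), pattern = pA),
    list(ids = c("s2", "x1"), pattern = pB)
  ))
  b <- expand_haplotype(panel, "s1", min_r2 = 0.8)
  expect_setequal(b$members$id, c("s1", "m1", "m2", "m3", "m4"))
  expect_true(all(b$members$r2 == 1))

  # no variant reaches the threshold -> singleton block
  panel2 <- fixture_panel(list(
    list(ids = "s1", pattern = pA),
    list(ids = "x1", pattern = pB)
  ))
  b2 <- expand_haplotype(panel2, "s1", min_r2 = 0.5)
  expect_equal(b2$members$id, "s1")

  expect_error(expand_haplotype(panel, "s99"), "nearest")
})

test_that("bulk expansion equals per-sentinel brute force on a random panel", {
  withr::with_seed(17, {
    n_hap <- 60
    n_var <- 50
    cols <- replicate(n_var, random_binary_col(n_hap))
    variants <- data.frame(
      id = sprintf("v%02d", 1:n_var), chrom = rep(c("c1", "c2"), each = 25),
      pos = rep(seq(1000, by = 500, length.out = 25), 2),
      ref = "A", alt = "C", stringsAsFactors = FALSE
    )
    panel <- fixture_with <- phased_panel(variants, cols)
    sent <- sample(variants$id, 10)
    bulk <- expand_blocks(panel, sent, min_r2 = 0.2, window_bp = 4000)
    for (s in sent) {
      one <- expand_haplotype(panel, s, min_r2 = 0.2, window_bp = 4000)
      got <- bulk$members[bulk$members$sentinel == s, ]
      expect_setequal(got$id, one$members$id)
      expect_equal(sort(got$r2), sort(one$members$r2), tolerance = 1e-9)
      # brute-force all-pairs oracle
      si <- match(s, panel$variants$id)
      oracle <- panel$variants$id[vapply(seq_len(n_var), function(j) {
        if (j == si) return(TRUE)
        v <- panel$variants
        if (v$chrom[j] != v$chrom[si]) return(FALSE)
        if (abs(v$pos[j] - v$pos[si]) > 4000) return(FALSE)
        r <- compute_r2(panel$haplotypes[, si], panel$haplotypes[, j])
        !is.na(r) && r >= 0.2
      }, TRUE)]
      expect_setequal(one$members$id, oracle)
    }
  })
})

test_that("raising the r2 threshold never adds members", {
  withr::with_seed(23, {
    cols <- replicate(40, random_binary_col(80))
    variants <- data.frame(id = sprintf("v%02d", 1:40), chrom = "c1",
                           pos = seq(100, by = 200, length.out = 40),
                           ref = "A", alt = "C", stringsAsFactors = FALSE)
    panel <- phased_panel(variants, cols)
    lo <- expand_haplotype(panel, "v05", min_r2 = 0.1)
    hi <- expand_haplotype(panel, "v05", min_r2 = 0.5)
    expect_true(all(hi$members$id %in% lo$members$id))
  })
})

test_that("blocks_to_intervals converts 1-based positions to 1-bp intervals", {
  panel <- fixture_panel(list(list(ids = c("s1", "m1"),
                                   pattern = c(1, 1, 0, 0))))
  b <- expand_haplotype(panel, "s1", min_r2 = 0.5)
  iv <- blocks_to_intervals(b, panel)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$start, panel$variants$pos[match(iv$name, panel$variants$id)] - 1)
  expect_equal(iv$end - iv$start, rep(1, 2))
  expect_true(all(iv$sentinel == "s1"))
  # round trip: interval -> position recovers the panel's 1-based positions
  expect_setequal(iv$end, panel$variants$pos)
})

test_that("panel VCF-like format round-trips", {
  withr::with_seed(9, {
    cols <- replicate(10, random_binary_col(20))
    variants <- data.frame(id = sprintf("v%02d", 1:10), chrom = "c1",
                           pos = sort(sample(1:5000, 10)),
                           ref = sample(c("A", "C"), 10, TRUE),
                           alt = sample(c("G", "T"), 10, TRUE),
                           stringsAsFactors = FALSE)
    panel <- phased_panel(variants, cols)
    f <- withr::local_tempfile()
    write_panel(panel, f)
    back <- read_panel(f)
    expect_equal(back$variants, panel$variants)
    expect_equal(unname(back$haplotypes), unname(panel$haplotypes))
  })
})
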