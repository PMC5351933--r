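# PWM construction, exact p-value thresholds, scanning, disruption.

test_that("pwm constructor validates rows and background", {
  prob <- matrix(0.25, 4, 4)
  expect_s3_class(pwm("t", prob), "pwm")
  bad <- prob; bad[1, 1] <- 0.5
  expect_error(pwm("t", bad), "sum to 1")
  expect_error(pwm("t", prob, background = c(0, 1, 1, 1)), "positive")
  # pseudocount rescues zero entries
  z <- matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE)
  expect_error(pwm("t", z))
  expect_s3_class(pwm("t", z, pseudocount = 0.01), "pwm")
})

test_that("score distribution sums to one and threshold is monotone in p", {
  withr::with_seed(2, {
    x <- fixture_pwm(k = 6)
    d <- haplofoot:::pwm_score_distribution(x)
    expect_equal(sum(d$prob), 1, tolerance = 1e-6)
    ps <- c(0.5, 0.1, 0.01, 1e-3)
    thr <- vapply(ps, function(p) suppressWarnings(pvalue_score_threshold(x, p)), 1)
    expect_true(all(diff(thr) >= 0))
  })
})

test_that("threshold edge cases: p = 1 and a background-equal PWM", {
  withr::with_seed(4, {
    x <- fixture_pwm(k = 5)
    d <- haplofoot:::pwm_score_distribution(x)
    min_score <- min(d$scores[d$prob > 0]) * 1e-3
    expect_equal(pvalue_score_threshold(x, 1), min_score)
  })
  # PWM equal to background: log-odds identically 0, so the whole mass sits
  # at score 0; p = 1 admits it, smaller p admits no k-mer at all
  flat <- pwm("flat", matrix(0.25, 6, 4))
  expect_equal(pvalue_score_threshold(flat, 1), 0)
  expect_warning(none <- pvalue_score_threshold(flat, 0.5), "achievable")
  expect_equal(none, 1e-3)
})

test_that("DP threshold equals exhaustive enumeration for short motifs", {
  withr::with_seed(6, {
    for (k in 4:6) {
      x <- fixture_pwm(k = k)
      for (p in c(0.05, 1e-2, 1e-3, 1e-4)) {
        expect_equal(suppressWarnings(pvalue_score_threshold(x, p)),
                     enumerate_threshold(x, p),
                     info = sprintf("k=%d p=%g", k, p))
      }
    }
    # non-uniform background
    y <- pwm("y", fixture_pwm(k = 4)$prob, background = c(0.4, 0.1, 0.1, 0.4))
    expect_equal(suppressWarnings(pvalue_score_threshold(y, 0.01)),
                 enumerate_threshold(y, 0.01))
  })
})

test_that("scan finds a near-deterministic motif exactly once and skips masks", {
  x <- fixture_pwm(k = 8, seed = 31)
  cons <- pwm_consensus(x)
  seq <- paste0(strrep("A", 50), cons, strrep("C", 50))
  hits <- scan_pwm(seq, x, p = 1e-4)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 50)
  expect_equal(fwd$end, 58)
  expect_equal(fwd$seq, cons)

  # fully masked sequence yields nothing
  expect_equal(nrow(scan_pwm(tolower(seq), x, p = 1e-4)), 0)
  # masking just the motif removes the hit
  masked <- paste0(strrep("A", 50), tolower(cons), strrep("C", 50))
  expect_equal(nrow(scan_pwm(masked, x, p = 1e-4)[
    scan_pwm(masked, x, p = 1e-4)$strand == "+", ]), 0)
  # sequence shorter than the motif
  expect_equal(nrow(scan_pwm("ACGT", x)), 0)
})

test_that("scan equals per-window brute-force rescoring on random sequence", {
  withr::with_seed(41, {
    x <- fixture_pwm(k = 6, dom = 0.7)
    seqs <- random_sequence(3000)
    p <- 1e-2
    hits <- scan_pwm(seqs, x, p = p)
    # independent oracle: rescore every window with scalar arithmetic
    bin <- 1e-3
    thr <- round(enumerate_threshold(x, p) / bin)
    base <- strsplit(seqs, "")[[1]]
    code <- match(base, c("A", "C", "G", "T"))
    S_f <- round(log2(sweep(x$prob, 2, x$background, "/")) / bin)
    rc <- haplofoot:::pwm_revcomp(x)
    S_r <- round(log2(sweep(rc$prob, 2, rc$background, "/")) / bin)
    oracle <- list()
    for (i in 1:(3000 - 5)) {
      w <- code[i:(i + 5)]
      for (strand in c("+", "-")) {
        S <- if (strand == "+") S_f else S_r
        sc <- sum(S[cbind(1:6, w)])
        if (sc >= thr) {
          oracle[[length(oracle) + 1]] <- data.frame(start = i - 1,
                                                     strand = strand,
                                                     score = sc * bin)
        }
      }
    }
    oracle <- do.call(rbind, oracle)
    oracle <- oracle[order(oracle$start, oracle$strand), ]
    expect_equal(nrow(hits), nrow(oracle))
    expect_equal(hits$start, oracle$start)
    expect_equal(hits$strand, oracle$strand)
    expect_equal(hits$score, oracle$score, tolerance = 1e-9)
  })
})

test_that("scan output mirrors under reverse complement", {
  withr::with_seed(43, {
    x <- fixture_pwm(k = 6, dom = 0.75)
    seqs <- random_sequence(1500)
    revcomp <- function(s) {
      paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
    }
    h1 <- scan_pwm(seqs, x, p = 1e-2)
    h2 <- scan_pwm(revcomp(seqs), x, p = 1e-2)
    expect_equal(nrow(h1), nrow(h2))
    m1 <- sort(1500 - h1$end)
    m2 <- sort(h2$start)
    expect_equal(m1, m2)
  })
})

test_that("disruption calls match full rescoring and guard ref mismatches", {
  x <- fixture_pwm(k = 8, seed = 51)
  cons <- pwm_consensus(x)
  seqs <- paste0("AAAA", cons, "TTTT")
  hit <- scan_pwm(seqs, x, p = 1e-4)
  hit <- hit[hit$strand == "+", ][1, ]
  dom <- substr(cons, 3, 3)
  worst <- setdiff(c("A", "C", "G", "T"), dom)[1]
  # losing a dominant base collapses the score below threshold
  expect_true(is_disruptive(hit, x, dom, worst, 3))
  # identity substitution never disrupts
  expect_false(is_disruptive(hit, x, dom, dom, 3))
  expect_error(is_disruptive(hit, x, worst, dom, 3), "does not match")

  # enumerated oracle over all positions and alternates
  bin <- 1e-3
  S <- round(log2(sweep(x$prob, 2, x$background, "/")) / bin)
  thr <- round(enumerate_threshold(x, 1e-4) / bin)
  old <- sum(S[cbind(1:8, match(strsplit(cons, "")[[1]], c("A", "C", "G", "T")))])
  for (off in 1:8) {
    ref <- substr(cons, off, off)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      new <- old - S[off, ref] + S[off, alt]
      expect_equal(is_disruptive(hit, x, ref, alt, off),
                   (old >= thr) != (new >= thr),
                   info = sprintf("off=%d alt=%s", off, alt))
    }
  }
})

test_that("disruption test handles the no-disruption degenerate case", {
  # two footprints in two DHS, one SNV in a footprint, no motif hits at all
  dhs <- interval_set(chrom = c("c", "c"), start = c(0, 500), end = c(200, 700))
  fp <- interval_set(chrom = c("c", "c"), start = c(50, 550), end = c(70, 570))
  snv <- interval_set("c", 60, 61, name = "v1", ref = "A", alt = "G")
  out <- disruption_proportion_test(snv, fp, dhs, haplofoot:::motif_hits_frame(),
                                    list(), n_shuffles = 50, seed = 1)
  expect_equal(out$observed, 0)
  expect_equal(out$p_value, 1)
  expect_error(
    disruption_proportion_test(
      interval_set("c", 400, 401, name = "v", ref = "A", alt = "G"),
      fp, dhs, haplofoot:::motif_hits_frame(), list(), n_shuffles = 10),
    "undefined")
})

test_that("MEME minimal format round-trips PWMs exactly", {
  withr::with_seed(61, {
    ps <- list(a = fixture_pwm("a", k = 5), b = fixture_pwm("b", k = 9))
    f <- withr::local_tempfile()
    write_meme(ps, f)
    back <- read_meme(f)
    expect_equal(names(back), c("a", "b"))
    expect_equal(back$a$prob, ps$a$prob)
    expect_equal(back$b$prob, ps$b$prob)
    expect_equal(unname(back$a$background), rep(0.25, 4))
  })
})
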