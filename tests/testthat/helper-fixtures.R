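# Shared fixtures, all built in code.

# Small phased panel with engineered perfect-LD groups. Each entry of
# `patterns` is a binary haplotype column shared (identically) by all the
# ids listed for it, giving within-group r2 = 1 and controlled cross-group
# r2. Positions are consecutive 100 bp apart on chr1.
fixture_panel <- function(groups) {
  ids <- unlist(lapply(groups, `[[`, "ids"))
  cols <- do.call(cbind, lapply(groups, function(g) {
    matrix(rep(g$pattern, length(g$ids)), ncol = length(g$ids))
  }))
  variants <- data.frame(
    id = ids, chrom = "chr1", pos = 100 * seq_along(ids),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  phased_panel(variants, cols)
}

# Uniform-ish random binary column with both alleles present.
random_binary_col <- function(n) {
  repeat {
    p <- stats::runif(1, 0.05, 0.95)
    x <- stats::rbinom(n, 1, p)
    if (any(x == 1) && any(x == 0)) return(x)
  }
}

# A sharply informative PWM: one dominant base (prob `dom`) per position.
fixture_pwm <- function(tf_id = "TFX", k = 8, dom = 0.85, seed = NULL) {
  make <- function() {
    d <- sample(1:4, k, replace = TRUE)
    prob <- matrix((1 - dom) / 3, nrow = k, ncol = 4)
    prob[cbind(seq_len(k), d)] <- dom
    pwm(tf_id, prob)
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$prob, 1, which.max)], collapse = "")
}

# Independent enumeration oracle for the PWM score threshold: enumerate all
# 4^k k-mers, bin each position's log2-odds to the 1e-3 grid, and find the
# smallest achievable score with tail probability <= p (or max + 1 bin).
enumerate_threshold <- function(x, p, bin = 1e-3) {
  k <- nrow(x$prob)
  S <- round(log2(sweep(x$prob, 2, x$background, "/")) / bin)
  km <- as.matrix(expand.grid(rep(list(1:4), k)))
  score <- numeric(nrow(km))
  prob <- rep(1, nrow(km))
  for (j in seq_len(k)) {
    score <- score + S[j, km[, j]]
    prob <- prob * x$background[km[, j]]
  }
  agg <- tapply(prob, score, sum)
  sc <- as.numeric(names(agg))
  o <- order(sc)
  sc <- sc[o]
  tail <- rev(cumsum(rev(agg[o])))
  ok <- which(tail <= p)
  if (length(ok) == 0) (max(sc) + 1) * bin else sc[min(ok)] * bin
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small synthetic config used by several suites.
small_config <- function(...) {
  args <- list(
    n_chromosomes = 1, chrom_length_bp = 2e5, n_dhs = 150,
    dhs_length_bp = c(200, 400), footprint_per_dhs_prob = 0.5,
    n_snvs = 300, n_haplotypes_in_panel = 50, ld_block_length_bp = 10000,
    within_block_r2 = 0.8, n_sentinels = 400, planted_fold = 1,
    n_motifs = 100, motif_length = 8, expressed_tf_fraction = 0.5,
    conservation_signal = 0.5, artefact_spike_prob = 0.05, seed = 1
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}
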