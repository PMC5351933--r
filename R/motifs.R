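#' Construct a position weight matrix
#'
#' @param tf_id TF identifier.
#' @param prob Matrix of per-position nucleotide probabilities, one row per
#'   motif position, columns `A, C, G, T`; each row sums to 1.
#' @param background Background nucleotide frequencies (default uniform);
#'   strictly positive.
#' @param pseudocount Added to every probability before renormalising, so
#'   zero entries get a finite log-odds (default 0, i.e. the matrix is used
#'   as supplied).
#' @return An object of class `pwm`.
#' @export
pwm <- function(tf_id, prob, background = rep(0.25, 4), pseudocount = 0) {
  stopifnot(is.matrix(prob), ncol(prob) == 4, nrow(prob) >= 4,
            length(background) == 4)
  if (any(background <= 0)) stop("background frequencies must be positive")
  if (pseudocount > 0) {
    prob <- prob + pseudocount
    prob <- prob / rowSums(prob)
  }
  if (any(abs(rowSums(prob) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (any(prob <= 0)) {
    stop("PWM probabilities must be positive (use a pseudocount)")
  }
  colnames(prob) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  names(background) <- c("A", "C", "G", "T")
  structure(list(tf_id = tf_id, prob = prob, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions\n", x$tf_id, nrow(x$prob)))
  invisible(x)
}

pwm_length <- function(x) nrow(x$prob)

# Log-odds score bin width: scores are discretised to integer multiples of
# this for the exact p-value dynamic programme and all scanning.
.SCORE_BIN <- 1e-3

# Integer-binned log2-odds matrix (positions x 4).
pwm_score_int <- function(x) {
  s <- log2(sweep(x$prob, 2, x$background, "/"))
  matrix(as.integer(round(s / .SCORE_BIN)), nrow = nrow(s),
         dimnames = dimnames(s))
}

pwm_revcomp <- function(x) {
  pr <- x$prob[rev(seq_len(nrow(x$prob))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(pr) <- c("A", "C", "G", "T")
  pwm(x$tf_id, pr, background = unname(x$background[c("T", "G", "C", "A")]))
}

# Exact distribution of the binned score of a background-drawn k-mer.
# Returns list(scores = integer grid, prob, tail = P(score >= s)).
pwm_score_distribution <- function(x) {
  S <- pwm_score_int(x)
  bg <- x$background
  lo <- 0L; hi <- 0L
  v <- 1
  for (i in seq_len(nrow(S))) {
    lo2 <- lo + min(S[i, ]); hi2 <- hi + max(S[i, ])
    nv <- numeric(hi2 - lo2 + 1)
    for (b in 1:4) {
      at <- (lo + S[i, b] - lo2 + 1):(hi + S[i, b] - lo2 + 1)
      nv[at] <- nv[at] + v * bg[b]
    }
    v <- nv; lo <- lo2; hi <- hi2
  }
  list(scores = lo:hi, prob = v, tail = rev(cumsum(rev(v))))
}

#' Score threshold for an exact match p-value
#'
#' The p-value of a score `s` is the probability that a k-mer drawn from
#' the 0-order background scores at least `s`. The threshold is the
#' smallest achievable (binned) score whose p-value is at most `p`,
#' computed by exact dynamic programming over the discretised log-odds
#' distribution. If even the maximal score has p-value above `p`, one bin
#' above the maximum is returned with a warning (no window can match).
#' At `p = 1` the whole distribution qualifies, so the minimum achievable
#' score is returned.
#'
#' @param pwm A [pwm()].
#' @param p Match p-value in `(0, 1]`.
#' @return Threshold score (log2-odds, on the 1e-3 bin grid).
#' @export
pvalue_score_threshold <- function(pwm, p) {
  stopifnot(inherits(pwm, "pwm"), p > 0, p <= 1)
  d <- pwm_score_distribution(pwm)
  ok <- which(d$tail <= p + 1e-12 & d$prob > 0)
  if (length(ok) == 0) {
    warning(sprintf("p = %g below the smallest achievable tail; no k-mer matches",
                    p))
    return((max(d$scores[d$prob > 0]) + 1) * .SCORE_BIN)
  }
  d$scores[min(ok)] * .SCORE_BIN
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

seq_codes <- function(sequence) {
  unname(DNA_CODE[strsplit(sequence, "", fixed = TRUE)[[1]]])
}

# Binned window scores along coded sequence; NA where the window touches a
# masked/ambiguous base.
window_scores_int <- function(codes, S) {
  k <- nrow(S)
  n <- length(codes) - k + 1
  if (n <= 0) return(numeric(0))
  total <- numeric(n)
  for (j in seq_len(k)) {
    total <- total + S[j, ][codes[j:(j + n - 1)]]
  }
  total
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; windows containing `N` or masked (lowercase)
#' bases are skipped. A window is a hit when its binned log2-odds score
#' reaches [pvalue_score_threshold()] at `p`.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (lowercase = masked).
#' @param pwm A [pwm()].
#' @param p Match p-value threshold (default 1e-4).
#' @param chrom Chromosome name recorded in the hits (default "seq").
#' @param offset0 0-based coordinate of the first sequence base (default 0).
#' @return A `data.frame` of motif hits: `tf_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `p_value` and `seq` (the
#'   forward-strand window sequence).
#' @export
scan_pwm <- function(sequence, pwm, p = 1e-4, chrom = "seq", offset0 = 0) {
  stopifnot(inherits(pwm, "pwm"))
  k <- pwm_length(pwm)
  empty <- motif_hits_frame()
  if (nchar(sequence) < k) return(empty)
  codes <- seq_codes(sequence)
  d <- pwm_score_distribution(pwm)
  thr_int <- as.integer(round(
    suppressWarnings(pvalue_score_threshold(pwm, p)) / .SCORE_BIN
  ))
  hits <- list(empty)
  for (strand in c("+", "-")) {
    S <- if (strand == "+") pwm_score_int(pwm) else pwm_score_int(pwm_revcomp(pwm))
    sc <- window_scores_int(codes, S)
    at <- which(!is.na(sc) & sc >= thr_int)
    if (length(at) == 0) next
    tail_at <- function(s_int) {
      i <- findInterval(s_int, d$scores)
      ifelse(i < 1, 1, d$tail[pmax(i, 1)])
    }
    hits[[length(hits) + 1]] <- data.frame(
      tf_id = pwm$tf_id,
      chrom = chrom,
      start = offset0 + at - 1,
      end = offset0 + at - 1 + k,
      strand = strand,
      score = sc[at] * .SCORE_BIN,
      p_value = tail_at(sc[at]),
      seq = substring(sequence, at, at + k - 1),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

motif_hits_frame <- function() {
  data.frame(tf_id = character(0), chrom = character(0), start = numeric(0),
             end = numeric(0), strand = character(0), score = numeric(0),
             p_value = numeric(0), seq = character(0), stringsAsFactors = FALSE)
}

#' Does an allele substitution disrupt a motif match?
#'
#' Rescores the hit window with the alternate base substituted at
#' `offset_in_motif` (1-based, in forward-genome window coordinates) and
#' reports whether match status at the p-value threshold changes in either
#' direction (loss of a match or gain of one).
#'
#' @param hit One row of a [scan_pwm()] hit frame.
#' @param pwm The [pwm()] the hit was scanned with.
#' @param ref_base,alt_base Reference and alternate bases (forward strand).
#' @param offset_in_motif 1-based offset of the variant within the window.
#' @param p Match p-value threshold (default 1e-4).
#' @return Logical.
#' @export
is_disruptive <- function(hit, pwm, ref_base, alt_base, offset_in_motif,
                          p = 1e-4) {
  k <- pwm_length(pwm)
  stopifnot(offset_in_motif >= 1, offset_in_motif <= k)
  window_seq <- hit$seq
  have <- substr(window_seq, offset_in_motif, offset_in_motif)
  if (have != ref_base) {
    stop(sprintf("ref base '%s' does not match hit sequence base '%s' at offset %d",
                 ref_base, have, offset_in_motif))
  }
  if (ref_base == alt_base) return(FALSE)
  S <- if (identical(hit$strand, "-")) pwm_score_int(pwm_revcomp(pwm)) else pwm_score_int(pwm)
  thr_int <- as.integer(round(
    suppressWarnings(pvalue_score_threshold(pwm, p)) / .SCORE_BIN
  ))
  old_int <- as.integer(round(hit$score / .SCORE_BIN))
  new_int <- old_int - S[offset_in_motif, ref_base] + S[offset_in_motif, alt_base]
  (old_int >= thr_int) != (new_int >= thr_int)
}

# Precompute, for every SNV, whether it disrupts >= 1 overlapping hit.
# snvs: interval_set of 1-bp variants with ref/alt columns; hits: scan_pwm
# frame; pwms: named list of pwm objects keyed by tf_id.
snv_disruption_flags <- function(snvs, hits, pwms, p = 1e-4) {
  n <- nrow(snvs)
  flags <- rep(FALSE, n)
  if (n == 0 || nrow(hits) == 0) return(flags)
  offsets <- chrom_offsets(unique(c(snvs$chrom, hits$chrom)))
  sp <- globalize(snvs$chrom, snvs$start, offsets)
  hs <- globalize(hits$chrom, hits$start, offsets)
  he <- globalize(hits$chrom, hits$end, offsets)
  o <- order(hs)
  # hits are short; scan candidates by position window
  for (i in seq_len(n)) {
    cand <- which(hs <= sp[i] & he > sp[i])
    for (j in cand) {
      off <- sp[i] - hs[j] + 1
      flag <- tryCatch(
        is_disruptive(hits[j, , drop = FALSE], pwms[[hits$tf_id[j]]],
                      snvs$ref[i], snvs$alt[i], off, p = p),
        error = function(e) NA
      )
      if (isTRUE(flag)) {
        flags[i] <- TRUE
        break
      }
    }
  }
  flags
}

#' Motif-disruption proportion test for footprint variants
#'
#' Observed statistic: the fraction of footprint-contained SNVs that
#' disrupt at least one overlapping motif hit. The null re-places every
#' footprint uniformly within a containing-capable DHS (the motif hits and
#' the per-SNV disruption status stay fixed; only which SNVs fall inside
#' footprints changes) `n_shuffles` times; the empirical p-value uses the
#' add-one rule.
#'
#' @param snvs 1-bp variant [interval_set()] with `ref` and `alt` columns.
#' @param footprints Footprint [interval_set()].
#' @param dhs DHS [interval_set()] used as the shuffling workspace.
#' @param hits Motif hit frame from [scan_pwm()] (or the generator).
#' @param pwms Named list of [pwm()] objects keyed by `tf_id`.
#' @param n_shuffles Number of footprint shuffles (default 1000).
#' @param seed Optional RNG seed.
#' @param p Match p-value threshold used for disruption calls.
#' @return List with `observed`, `null_mean`, `null_sd`, `p_value`,
#'   `n_snvs_in_footprints` and the per-shuffle `null` statistics.
#' @export
disruption_proportion_test <- function(snvs, footprints, dhs, hits, pwms,
                                       n_shuffles = 1000, seed = NULL,
                                       p = 1e-4) {
  snvs <- as_interval_set(snvs)
  footprints <- as_interval_set(footprints)
  dhs <- as_interval_set(dhs)
  if (is.null(snvs$ref) || is.null(snvs$alt)) {
    stop("snvs must carry 'ref' and 'alt' columns")
  }
  flags <- snv_disruption_flags(snvs, hits, pwms, p = p)
  offsets <- chrom_offsets(unique(c(snvs$chrom, dhs$chrom, footprints$chrom)))
  sp <- globalize(snvs$chrom, snvs$start, offsets)
  fp_m <- merge_global(footprints, offsets)
  inside <- any_overlap_global(sp, sp + 1, fp_m)
  if (sum(inside) == 0) stop("no SNVs inside footprints: statistic undefined")
  observed <- mean(flags[inside])

  seg <- merge_global(dhs, offsets)
  seg_len <- seg$end - seg$start
  widths <- footprints$end - footprints$start
  null <- numeric(n_shuffles)
  with_seed(seed, {
    for (it in seq_len(n_shuffles)) {
      qs <- place_randomly(widths, seg$start, seg_len)
      m <- sort_merged(qs, qs + widths)
      ins <- any_overlap_global(sp, sp + 1, m)
      null[it] <- if (any(ins)) mean(flags[ins]) else NA_real_
    }
  })
  ok <- !is.na(null)
  p_emp <- (sum(null[ok] >= observed) + 1) / (sum(ok) + 1)
  list(observed = observed, null_mean = mean(null[ok]),
       null_sd = stats::sd(null[ok]), p_value = p_emp,
       n_snvs_in_footprints = sum(inside), null = null)
}

# Draw one uniform placement per item width within capacity-weighted
# segments (global coordinates). Shared by shuffling and the null above.
place_randomly <- function(widths, seg_start, seg_len) {
  n <- length(widths)
  out <- numeric(n)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    cap <- seg_len - w + 1
    ok <- which(cap > 0)
    if (length(ok) == 0) {
      stop(sprintf("item of width %d longer than every workspace segment", w))
    }
    pick <- ok[sample.int(length(ok), length(idx), replace = TRUE,
                          prob = cap[ok])]
    out[idx] <- seg_start[pick] + floor(stats::runif(length(idx)) * cap[pick])
  }
  out
}

# Merge possibly-overlapping global [s, e) pairs into disjoint sorted form.
sort_merged <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  keep <- c(TRUE, s[-1] > cummax(e[-length(e)]))
  grp <- cumsum(keep)
  list(start = s[keep], end = as.numeric(tapply(e, grp, max)))
}

#' Read PWMs from a MEME minimal motif file
#'
#' Supports the minimal format: a `MEME version` line, optional `ALPHABET`
#' and `Background letter frequencies` sections, and `MOTIF` blocks with
#' `letter-probability matrix` entries.
#'
#' @param path Input path.
#' @return Named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    toks <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    if (length(vals) == 4 && !anyNA(vals)) bg <- vals
  }
  motif_at <- grep("^MOTIF", lines)
  out <- list()
  for (m in motif_at) {
    id <- strsplit(trimws(lines[m]), "\\s+")[[1]][2]
    hdr <- m + grep("^letter-probability matrix", lines[(m + 1):length(lines)])[1]
    k <- as.numeric(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + k)]
    prob <- do.call(rbind, lapply(rows, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    out[[id]] <- pwm(id, prob, background = bg)
  }
  out
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms Named list of [pwm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    sprintf("A %.17g C %.17g G %.17g T %.17g", bg[1], bg[2], bg[3], bg[4]),
    ""
  )
  for (x in pwms) {
    k <- pwm_length(x)
    lines <- c(lines,
               sprintf("MOTIF %s", x$tf_id),
               sprintf("letter-probability matrix: alength= 4 w= %d", k),
               vapply(seq_len(k), function(i) {
                 paste(sprintf("%.17g", x$prob[i, ]), collapse = " ")
               }, ""),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
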