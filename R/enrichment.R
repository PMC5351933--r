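#' Shuffle intervals within a workspace
#'
#' Each item is independently re-placed: a workspace segment able to
#' contain it is chosen with probability proportional to
#' `segment_length - item_length + 1`, then a uniform offset within the
#' segment. Lengths are preserved and overlaps among shuffled items are
#' permitted. This is the randomisation scheme behind the permutation
#' enrichment test: annotations are shuffled only where they could fall
#' (e.g. footprints within DHS).
#'
#' @param items [interval_set()] to re-place.
#' @param workspace [interval_set()] defining allowed territory (merged
#'   internally).
#' @param seed Optional RNG seed.
#' @return An [interval_set()] of shuffled items (names preserved).
#' @export
shuffle_within_workspace <- function(items, workspace, seed = NULL) {
  items <- as_interval_set(items)
  workspace <- as_interval_set(workspace)
  if (nrow(items) == 0) return(items)
  offsets <- chrom_offsets(workspace$chrom)
  seg <- merge_global(workspace, offsets)
  seg_len <- seg$end - seg$start
  widths <- items$end - items$start
  too_big <- widths > max(seg_len)
  if (any(too_big)) {
    stop(sprintf("item '%s' is longer than every workspace segment",
                 items$name[which(too_big)[1]]))
  }
  qs <- with_seed(seed, place_randomly(widths, seg$start, seg_len))
  chrom_names <- names(offsets)
  ci <- floor(qs / .CHROM_STRIDE) + 1
  interval_set(
    chrom = chrom_names[ci],
    start = qs - (ci - 1) * .CHROM_STRIDE,
    end = qs - (ci - 1) * .CHROM_STRIDE + widths,
    name = items$name
  )
}

#' Workspace-constrained randomisation enrichment
#'
#' Observed statistic: the number of query segments overlapping the
#' annotation by at least one base pair (`mode = "segment"`), or total
#' overlap base pairs (`mode = "bp"`). The null distribution comes from
#' `n` independent shuffles of the query within the workspace; the
#' empirical p-value uses the add-one rule
#' `(#\{null >= observed\} + 1) / (n + 1)` for enrichment (the two-sided
#' option doubles the smaller tail). Fold is observed over null mean.
#'
#' With `strata`, a label per workspace segment, each query segment is
#' shuffled only among the workspace segments sharing the label of the
#' segment it originates from (the generalisation of GC-isochore
#' correction to arbitrary strata).
#'
#' @param query Query [interval_set()] (every segment must lie in the
#'   workspace).
#' @param annotation Annotation [interval_set()].
#' @param workspace Workspace [interval_set()].
#' @param n Number of randomisations (default 10000; below 100 a warning
#'   about unstable p-values is emitted).
#' @param seed Optional RNG seed; for a fixed seed, runs with larger `n`
#'   extend the null of smaller `n` (prefix-consistent).
#' @param mode `"segment"` (default) or `"bp"`.
#' @param strata Optional vector of labels, one per `workspace` row.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `enrichment_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `fold`, `p_empirical`, `q` (`NA` until
#'   adjusted), `n_randomisations`, `mode`.
#' @export
fold_enrichment <- function(query, annotation, workspace, n = 10000,
                            seed = NULL, mode = c("segment", "bp"),
                            strata = NULL, alternative = c("greater", "two.sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  query <- as_interval_set(query)
  annotation <- as_interval_set(annotation)
  workspace <- as_interval_set(workspace)
  if (n < 100) warning("fewer than 100 randomisations: empirical p is unstable")
  if (nrow(annotation) == 0) warning("empty annotation: fold undefined")
  offsets <- chrom_offsets(workspace$chrom)
  ann <- merge_global(annotation, offsets)
  qs <- globalize(query$chrom, query$start, offsets)
  qe <- globalize(query$chrom, query$end, offsets)
  widths <- query$end - query$start

  stat <- function(s, e) {
    ov <- overlap_bp_global(s, e, ann)
    if (mode == "segment") sum(ov > 0) else sum(ov)
  }
  observed <- stat(qs, qe)

  if (is.null(strata)) {
    groups <- list(seq_len(nrow(query)))
    segs <- list(merge_global(workspace, offsets))
  } else {
    stopifnot(length(strata) == nrow(workspace))
    ws <- globalize(workspace$chrom, workspace$start, offsets)
    we <- globalize(workspace$chrom, workspace$end, offsets)
    seg_of <- vapply(qs, function(x) {
      i <- which(ws <= x & we > x)
      if (length(i) == 0) NA_integer_ else i[1]
    }, 1L)
    if (anyNA(seg_of)) stop("every query segment must start inside the workspace")
    labs <- as.character(strata)
    groups <- split(seq_len(nrow(query)), labs[seg_of])
    segs <- lapply(names(groups), function(l) {
      sel <- workspace[labs == l, , drop = FALSE]
      merge_global(sel, offsets)
    })
  }

  null <- numeric(n)
  with_seed(seed, {
    s <- numeric(nrow(query))
    for (it in seq_len(n)) {
      for (g in seq_along(groups)) {
        idx <- groups[[g]]
        seg <- segs[[g]]
        s[idx] <- place_randomly(widths[idx], seg$start, seg$end - seg$start)
      }
      null[it] <- stat(s, s + widths)
    }
  })
  null_mean <- mean(null)
  p_ge <- (sum(null >= observed) + 1) / (n + 1)
  p_le <- (sum(null <= observed) + 1) / (n + 1)
  p_emp <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
  structure(list(
    observed = observed,
    null_mean = null_mean,
    null_sd = stats::sd(null),
    fold = if (null_mean > 0) observed / null_mean else NA_real_,
    p_empirical = p_emp,
    q = NA_real_,
    n_randomisations = n,
    mode = mode
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed %g, null %0.2f +/- %0.2f, fold %0.3f, p = %0.4g (n = %d, %s mode)\n",
    x$observed, x$null_mean, x$null_sd, x$fold, x$p_empirical,
    x$n_randomisations, x$mode))
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin, order-preserving wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_qvalues <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Assign quintile strata from a per-base track over fixed-size bins
#'
#' Helper generalising 1-Mb GC-isochore correction: workspace segments are
#' binned by their midpoint into `bin_bp` windows, the mean track value of
#' each window is ranked, and quintile labels are returned per segment.
#'
#' @param workspace [interval_set()] of workspace segments.
#' @param track A [scored_track()] (e.g. GC fraction).
#' @param bin_bp Bin size (default 1e6).
#' @return Character vector of `"Q1"`..`"Q5"` labels, one per segment.
#' @export
gc_quintile_strata <- function(workspace, track, bin_bp = 1e6) {
  workspace <- as_interval_set(workspace)
  mid <- floor((workspace$start + workspace$end) / 2)
  bin <- paste0(workspace$chrom, ":", floor(mid / bin_bp))
  bin_mean <- vapply(unique(bin), function(b) {
    sel <- which(bin == b)
    mean(unlist(lapply(sel, function(i) {
      track_values(track, workspace$chrom[i], workspace$start[i], workspace$end[i])
    })))
  }, 1)
  q <- stats::quantile(bin_mean, probs = seq(0.2, 0.8, 0.2), names = FALSE)
  lab <- paste0("Q", findInterval(bin_mean, q) + 1)
  lab[match(bin, names(bin_mean))]
}
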