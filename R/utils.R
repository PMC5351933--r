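# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.numeric(x))
}

check_prob <- function(x, field) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single probability in [0, 1]")
  invisible(as.numeric(x))
}

check_range <- function(x, field, min = 1) {
  if (length(x) != 2 || !is.numeric(x) || anyNA(x) || x[1] > x[2] || x[1] < min)
    stop_field(field, "must be a numeric (min, max) pair with min <= max")
  invisible(as.numeric(x))
}

# Chromosome -> large disjoint offset so per-chromosome coordinates can be
# pooled into one sorted axis. Offsets are exact in doubles for any
# chromosome shorter than .CHROM_STRIDE.
.CHROM_STRIDE <- 1e10

chrom_offsets <- function(chroms) {
  chroms <- sort(unique(as.character(chroms)))
  stats::setNames((seq_along(chroms) - 1) * .CHROM_STRIDE, chroms)
}

globalize <- function(chrom, pos, offsets) {
  off <- offsets[as.character(chrom)]
  if (anyNA(off)) stop("interval on a chromosome absent from the workspace")
  unname(off) + pos
}

# Merge an interval set into disjoint sorted global [start, end) pairs.
merge_global <- function(x, offsets) {
  if (nrow(x) == 0) return(list(start = numeric(0), end = numeric(0)))
  gs <- globalize(x$chrom, x$start, offsets)
  ge <- globalize(x$chrom, x$end, offsets)
  o <- order(gs)
  gs <- gs[o]; ge <- ge[o]
  # union of sorted intervals
  keep_start <- c(TRUE, gs[-1] > cummax(ge[-length(ge)]))
  grp <- cumsum(keep_start)
  list(start = gs[keep_start],
       end = as.numeric(tapply(ge, grp, max)))
}

# Covered base pairs of merged annotation `ann` strictly below global
# coordinate x (vectorised over x).
cum_coverage <- function(x, ann) {
  if (length(ann$start) == 0) return(numeric(length(x)))
  cw <- cumsum(ann$end - ann$start)
  i <- findInterval(x, ann$start)
  out <- numeric(length(x))
  pos <- i >= 1
  ii <- i[pos]
  out[pos] <- c(0, cw)[ii] + pmax(0, pmin(x[pos], ann$end[ii]) - ann$start[ii])
  out
}

# Overlap (>= 1 bp) of query [qs, qe) against merged annotation, vectorised.
overlap_bp_global <- function(qs, qe, ann) {
  cum_coverage(qe, ann) - cum_coverage(qs, ann)
}

any_overlap_global <- function(qs, qe, ann) {
  overlap_bp_global(qs, qe, ann) > 0
}

log_line <- function(log, stage, msg) {
  c(log, sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}
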