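#' Construct a genomic interval set
#'
#' Interval sets are the package's universal currency: DNase hypersensitivity
#' sites (DHS), footprints, motif occurrences, blacklist regions, workspaces
#' and single-base variant positions are all represented as 0-based half-open
#' intervals `[start, end)` in a plain `data.frame` with class
#' `"interval_set"`. Optional columns beyond the BED6 set carry annotations
#' such as `tf_id` or the sentinel a variant belongs to.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors; 0-based half-open coordinates with
#'   `end > start`.
#' @param name Optional labels (defaults to `"."`).
#' @param score Optional numeric scores (defaults to `NA`).
#' @param strand Optional strand (stored but ignored by all analyses).
#' @param ... Further equal-length annotation columns.
#'
#' @return A `data.frame` of class `interval_set`, sorted by chromosome and
#'   start.
#' @export
interval_set <- function(chrom = character(0), start = numeric(0),
                         end = numeric(0), name = NULL, score = NULL,
                         strand = NULL, ...) {
  n <- max(length(chrom), length(start), length(end))
  recycle <- function(x) if (length(x) == 1 && n > 1) rep(x, n) else x
  chrom <- recycle(chrom)
  start <- recycle(start)
  end <- recycle(end)
  if (!is.null(name)) name <- recycle(name)
  if (!is.null(score)) score <- recycle(score)
  if (!is.null(strand)) strand <- recycle(strand)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom must be non-empty")
    if (anyNA(start) || anyNA(end)) stop("start/end must be non-missing")
    if (any(start < 0)) stop("start must be >= 0")
    if (any(end <= start)) stop("end must be greater than start")
  }
  x <- data.frame(
    chrom = chrom, start = start, end = end,
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(NA_real_, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interval_set", "data.frame")
  x
}

as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  do.call(interval_set, c(
    list(chrom = x$chrom, start = x$start, end = x$end),
    x[setdiff(names(x), c("chrom", "start", "end"))]
  ))
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

from_granges <- function(gr) {
  interval_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Read a BED3/BED6 file
#'
#' Coordinates are kept verbatim as 0-based half-open. Column 4 is parsed as
#' the name, column 5 as a numeric score when numeric (`"."` becomes `NA`),
#' column 6 as strand. Reading is gzip-transparent.
#'
#' @param path Path to a tab-separated BED file (optionally gzipped).
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(interval_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                 which(nf < 3)[1], path))
  }
  col <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  start <- suppressWarnings(as.numeric(col(2, NA)))
  end <- suppressWarnings(as.numeric(col(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 bad[1], path))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid interval on line %d in %s: end <= start", bad[1], path))
  }
  interval_set(
    chrom = col(1, NA),
    start = start,
    end = end,
    name = col(4, "."),
    score = suppressWarnings(as.numeric(col(5, "."))),
    strand = col(6, ".")
  )
}

#' Write an interval set as BED6
#'
#' @param x An [interval_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_interval_set(x)
  out <- data.frame(
    x$chrom, format_bp(x$start), format_bp(x$end),
    ifelse(is.na(x$name), ".", x$name),
    ifelse(is.na(x$score), ".", as.character(x$score)),
    ifelse(is.na(x$strand), ".", x$strand)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Which query intervals overlap an annotation?
#'
#' Half-open semantics: touching intervals `[0,10)` and `[10,20)` do not
#' overlap; any shared base pair counts.
#'
#' @param query,annotation [interval_set()] objects.
#' @return Logical vector, one entry per `query` row.
#' @export
intersect_any <- function(query, annotation) {
  query <- as_interval_set(query)
  annotation <- as_interval_set(annotation)
  if (nrow(query) == 0) return(logical(0))
  if (nrow(annotation) == 0) return(rep(FALSE, nrow(query)))
  suppressWarnings(
    IRanges::overlapsAny(as_granges(query), as_granges(annotation))
  )
}

#' Subtract one interval territory from another
#'
#' Returns the maximal sub-intervals of the territory of `a` not covered by
#' `b` (names and scores are territory-level and therefore dropped). The
#' total base pairs of the result equal `bp(a) - bp(a intersect b)` on merged
#' territories.
#'
#' @param a,b [interval_set()] objects.
#' @return An [interval_set()].
#' @export
subtract_intervals <- function(a, b) {
  a <- as_interval_set(a)
  b <- as_interval_set(b)
  if (nrow(a) == 0) return(interval_set())
  if (nrow(b) == 0) return(from_granges(GenomicRanges::reduce(as_granges(a))))
  ga <- as_granges(a)
  gb <- as_granges(b)
  from_granges(suppressWarnings(
    GenomicRanges::setdiff(ga, gb, ignore.strand = TRUE)
  ))
}

#' Intersect two interval territories
#'
#' @param a,b [interval_set()] objects.
#' @return An [interval_set()] of the shared territory.
#' @export
intersect_intervals <- function(a, b) {
  a <- as_interval_set(a)
  b <- as_interval_set(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(interval_set())
  from_granges(suppressWarnings(
    GenomicRanges::intersect(as_granges(a), as_granges(b), ignore.strand = TRUE)
  ))
}

#' Total covered base pairs of an interval set
#'
#' @param x An [interval_set()].
#' @param merge Merge overlapping intervals first (default `TRUE`).
#' @return Numeric scalar.
#' @export
interval_bp <- function(x, merge = TRUE) {
  x <- as_interval_set(x)
  if (nrow(x) == 0) return(0)
  if (!merge) return(sum(x$end - x$start))
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(as_granges(x)))))
}
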