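#' Per-base scored track
#'
#' A scored track holds one numeric value per base over named chromosomes
#' (0-based positions). It carries conservation scores and DNase cut counts.
#' Positions never written to are 0, matching the convention that missing
#' positions read as 0.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @return An object of class `scored_track`: a list of per-chromosome
#'   numeric vectors.
#' @export
scored_track <- function(chrom_lengths) {
  stopifnot(length(chrom_lengths) > 0, !is.null(names(chrom_lengths)))
  x <- lapply(chrom_lengths, function(l) numeric(l))
  class(x) <- "scored_track"
  x
}

track_chrom_lengths <- function(track) {
  vapply(unclass(track), length, numeric(1))
}

#' Read values from a scored track
#'
#' @param track A [scored_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open range; clipped to the chromosome.
#' @return Numeric vector of per-base values (length `end - start` after
#'   clipping).
#' @export
track_values <- function(track, chrom, start, end) {
  v <- track[[chrom]]
  if (is.null(v)) stop(sprintf("track has no chromosome '%s'", chrom))
  start <- max(0, start)
  end <- min(length(v), end)
  if (end <= start) return(numeric(0))
  v[(start + 1):end]
}

#' Add values to a range of a scored track
#'
#' @inheritParams track_values
#' @param values Numeric vector (length 1 or `end - start`) added in place.
#' @return The modified track.
#' @export
track_add <- function(track, chrom, start, end, values) {
  v <- track[[chrom]]
  if (is.null(v)) stop(sprintf("track has no chromosome '%s'", chrom))
  stopifnot(start >= 0, end <= length(v), end > start)
  idx <- (start + 1):end
  track[[chrom]][idx] <- v[idx] + values
  track
}

track_set <- function(track, chrom, pos0, value) {
  track[[chrom]][pos0 + 1] <- value
  track
}

#' Write a scored track as a 3-column table
#'
#' Emits `chrom`, 0-based position and value for every non-zero position;
#' zero positions are implicit.
#'
#' @param track A [scored_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track), function(ch) {
    v <- track[[ch]]
    nz <- which(v != 0)
    if (length(nz) == 0) return(NULL)
    data.frame(chrom = ch, pos0 = nz - 1, value = v[nz])
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) rows <- data.frame(chrom = character(0), pos0 = numeric(0),
                                        value = numeric(0))
  rows$value <- sprintf("%.17g", rows$value)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a scored track written by [write_track()]
#'
#' @param path Input path.
#' @param chrom_lengths Named numeric vector giving the track domain.
#' @return A [scored_track()].
#' @export
read_track <- function(path, chrom_lengths) {
  track <- scored_track(chrom_lengths)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", colClasses = c("character", "numeric", "numeric")),
    error = function(e) NULL
  )
  if (is.null(tab) || nrow(tab) == 0) return(track)
  for (ch in unique(tab[[1]])) {
    sel <- tab[[1]] == ch
    track <- track_set(track, ch, tab[[2]][sel], tab[[3]][sel])
  }
  track
}
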