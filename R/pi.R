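#' Per-block annotation hits
#'
#' A haplotype block counts as a hit when at least one member variant's
#' 1-bp interval overlaps the annotation (binary, unweighted).
#'
#' @param blocks A `haplotype_block`, list of them, or `haplotype_blocks`.
#' @param annotation [interval_set()].
#' @param panel The [phased_panel()] the blocks were expanded from.
#' @return Named logical vector, one entry per block (per sentinel, in
#'   block order; duplicate sentinels remain distinct entries).
#' @export
block_hits <- function(blocks, annotation, panel) {
  blocks <- blocks_members(blocks)
  m <- blocks$members
  annotation <- as_interval_set(annotation)
  hits <- stats::setNames(rep(FALSE, length(blocks$sentinels)), blocks$sentinels)
  if (nrow(m) == 0 || nrow(annotation) == 0) return(hits)
  idx <- match(m$id, panel$variants$id)
  if (anyNA(idx)) stop("block member absent from panel")
  offsets <- chrom_offsets(unique(c(panel$variants$chrom, annotation$chrom)))
  pos <- globalize(panel$variants$chrom[idx], panel$variants$pos[idx] - 1, offsets)
  ann <- merge_global(annotation, offsets)
  member_hit <- any_overlap_global(pos, pos + 1, ann)
  agg <- tapply(member_hit, m$sentinel, any)
  found <- match(blocks$sentinels, names(agg))
  hits[!is.na(found)] <- as.logical(agg[found[!is.na(found)]])
  hits
}

#' The haplotype overlap proportion
#'
#' The headline statistic: the proportion of haplotype blocks with at
#' least one member SNV whose 1-bp interval overlaps the annotation.
#'
#' @inheritParams block_hits
#' @return Proportion in `[0, 1]`; `NA` with a warning for zero blocks.
#' @export
pi_statistic <- function(blocks, annotation, panel) {
  blocks <- blocks_members(blocks)
  if (length(blocks$sentinels) == 0) {
    warning("zero haplotype blocks: proportion undefined")
    return(NA_real_)
  }
  mean(block_hits(blocks, annotation, panel))
}

#' Haplotype overlap proportion across r-squared thresholds and layers
#'
#' Expands every sentinel once at the smallest threshold of the grid, then
#' evaluates the overlap proportion for each (threshold, layer) pair by
#' nesting (members at a higher threshold are a subset of those at a lower
#' one, so the proportion is non-increasing along the grid).
#'
#' @param sentinels Character vector of sentinel variant ids.
#' @param panel A [phased_panel()].
#' @param annotations Named list of annotation [interval_set()]s (the
#'   layers, e.g. DHS, footprints, footprint-motif intersection).
#' @param r2_grid Ascending r-squared thresholds (default
#'   `c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)`).
#' @param window_bp LD window (default 10 Mb).
#' @return An object of class `pi_curve`: `data.frame` with columns
#'   `r2_threshold`, `layer`, `pi`, `n_blocks` (the denominator).
#' @export
pi_curve <- function(sentinels, panel, annotations,
                     r2_grid = seq(0.5, 1.0, 0.1), window_bp = 1e7) {
  stopifnot(!is.unsorted(r2_grid), length(annotations) > 0,
            !is.null(names(annotations)))
  blocks <- expand_blocks(panel, sentinels, min_r2 = min(r2_grid),
                          window_bp = window_bp)
  rows <- list()
  for (thr in r2_grid) {
    b <- filter_blocks(blocks, thr)
    for (layer in names(annotations)) {
      rows[[length(rows) + 1]] <- data.frame(
        r2_threshold = thr,
        layer = layer,
        pi = pi_statistic(b, annotations[[layer]], panel),
        n_blocks = length(b$sentinels),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pi_curve", "data.frame")
  out
}

#' Conditional haplotype overlap proportion
#'
#' Restricts the first block set to blocks sharing at least one member
#' variant with some block of the second set (e.g. GWAS haplotypes that
#' contain an eQTL SNV), then evaluates the overlap proportion of that
#' subset.
#'
#' @param blocks_a,blocks_b Block sets over the same panel.
#' @param annotation [interval_set()].
#' @param panel The shared [phased_panel()].
#' @return Proportion over the conditional subset; `NA` with attribute
#'   `n_conditional = 0` and a warning when no blocks share members.
#' @export
conditional_pi <- function(blocks_a, blocks_b, annotation, panel) {
  a <- blocks_members(blocks_a)
  b <- blocks_members(blocks_b)
  shared <- unique(a$members$sentinel[a$members$id %in% b$members$id])
  if (length(shared) == 0) {
    warning("no blocks share member variants: conditional proportion undefined")
    return(structure(NA_real_, n_conditional = 0))
  }
  keep <- a$members$sentinel %in% shared
  sub <- structure(list(members = a$members[keep, , drop = FALSE],
                        sentinels = a$sentinels[a$sentinels %in% shared],
                        r2_threshold = a$r2_threshold,
                        window_bp = a$window_bp),
                   class = "haplotype_blocks")
  structure(pi_statistic(sub, annotation, panel),
            n_conditional = length(sub$sentinels))
}
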