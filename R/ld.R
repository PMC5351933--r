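#' Construct a phased haplotype panel
#'
#' The panel is the source of pairwise linkage disequilibrium: a binary
#' haplotype-by-variant matrix (1 = ALT allele) over biallelic SNVs with
#' 1-based positions, as in a phased reference panel.
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; positions sorted within chromosome.
#' @param haplotypes Binary matrix, one row per haplotype, one column per
#'   variant (columns in `variants` order).
#' @return An object of class `phased_panel`.
#' @export
phased_panel <- function(variants, haplotypes) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            is.matrix(haplotypes),
            ncol(haplotypes) == nrow(variants),
            nrow(haplotypes) >= 2)
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (!all(haplotypes %in% c(0, 1))) stop("haplotype matrix must be binary")
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  haplotypes <- haplotypes[, o, drop = FALSE]
  colnames(haplotypes) <- variants$id
  structure(list(variants = variants, haplotypes = haplotypes),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d haplotypes x %d variants on %d chromosome(s)\n",
              nrow(x$haplotypes), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Computes \deqn{r^2 = \frac{(p_{AB} - p_A p_B)^2}{p_A(1-p_A)\,p_B(1-p_B)}}
#' from two phased haplotype columns, where \eqn{p_A} and \eqn{p_B} are ALT
#' frequencies and \eqn{p_{AB}} the joint ALT-ALT frequency. This equals the
#' squared Pearson correlation of the binary columns.
#'
#' @param col_a,col_b Binary vectors of equal length (>= 2), one entry per
#'   phased haplotype.
#' @return r-squared in `[0, 1]`, or `NA` if either column is monomorphic
#'   (undefined LD, deliberately distinct from r-squared 0).
#' @export
compute_r2 <- function(col_a, col_b) {
  stopifnot(length(col_a) == length(col_b), length(col_a) >= 2)
  p_a <- mean(col_a)
  p_b <- mean(col_b)
  if (p_a == 0 || p_a == 1 || p_b == 0 || p_b == 1) return(NA_real_)
  p_ab <- mean(col_a * col_b)
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# r2 of one column against every column of a matrix; NA for monomorphic.
r2_against <- function(col_s, mat) {
  n <- length(col_s)
  p_a <- mean(col_s)
  p_b <- colMeans(mat)
  p_ab <- as.numeric(crossprod(col_s, mat)) / n
  out <- (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  out[p_b == 0 | p_b == 1] <- NA_real_
  if (p_a == 0 || p_a == 1) out[] <- NA_real_
  out
}

#' Expand a sentinel variant into its haplotype block
#'
#' Collects every panel variant on the sentinel's chromosome within
#' `window_bp` whose r-squared with the sentinel reaches `min_r2`
#' (inclusive). Monomorphic variants have undefined LD and are skipped. The
#' sentinel is always a member at r-squared 1.
#'
#' @param panel A [phased_panel()].
#' @param sentinel Variant id present in the panel.
#' @param min_r2 Minimum r-squared (default 0.5).
#' @param window_bp Maximum distance from the sentinel (default 10 Mb).
#' @return An object of class `haplotype_block`: list with `sentinel`,
#'   `members` (`data.frame` of `id`, `r2`), `r2_threshold`, `window_bp`.
#' @export
expand_haplotype <- function(panel, sentinel, min_r2 = 0.5, window_bp = 1e7) {
  stopifnot(inherits(panel, "phased_panel"))
  idx <- match(sentinel, panel$variants$id)
  if (is.na(idx)) {
    d <- utils::adist(sentinel, panel$variants$id)
    nearest <- panel$variants$id[order(d)][seq_len(min(3, nrow(panel$variants)))]
    stop(sprintf("sentinel '%s' not in panel; nearest ids: %s",
                 sentinel, paste(nearest, collapse = ", ")))
  }
  v <- panel$variants
  cand <- which(v$chrom == v$chrom[idx] &
                  abs(v$pos - v$pos[idx]) <= window_bp & seq_len(nrow(v)) != idx)
  r2 <- r2_against(panel$haplotypes[, idx], panel$haplotypes[, cand, drop = FALSE])
  keep <- !is.na(r2) & r2 >= min_r2
  members <- data.frame(
    id = c(sentinel, v$id[cand][keep]),
    r2 = c(1, r2[keep]),
    stringsAsFactors = FALSE
  )
  structure(list(sentinel = sentinel, members = members,
                 r2_threshold = min_r2, window_bp = window_bp),
            class = "haplotype_block")
}

#' Expand many sentinels at once
#'
#' Bulk equivalent of [expand_haplotype()], using per-chromosome matrix
#' cross-products so thousands of sentinels stay fast.
#'
#' @inheritParams expand_haplotype
#' @param sentinels Character vector of variant ids.
#' @param chunk Number of sentinels per cross-product block.
#' @return An object of class `haplotype_blocks`: list with a long-format
#'   `members` `data.frame` (`sentinel`, `id`, `r2`), `sentinels`,
#'   `r2_threshold`, `window_bp`.
#' @export
expand_blocks <- function(panel, sentinels, min_r2 = 0.5, window_bp = 1e7,
                          chunk = 500) {
  stopifnot(inherits(panel, "phased_panel"))
  miss <- setdiff(sentinels, panel$variants$id)
  if (length(miss) > 0) {
    stop(sprintf("sentinel(s) not in panel: %s",
                 paste(utils::head(miss, 3), collapse = ", ")))
  }
  v <- panel$variants
  H <- panel$haplotypes
  n <- nrow(H)
  parts <- list()
  for (ch in unique(v$chrom[match(sentinels, v$id)])) {
    cols <- which(v$chrom == ch)
    X <- H[, cols, drop = FALSE]
    mu <- colMeans(X)
    sdv <- sqrt(mu * (1 - mu))
    poly <- sdv > 0
    Z <- sweep(X, 2, mu, "-")
    Z[, poly] <- sweep(Z[, poly, drop = FALSE], 2, sdv[poly] * sqrt(n), "/")
    sent_ch <- sentinels[v$chrom[match(sentinels, v$id)] == ch]
    sent_local <- match(sent_ch, v$id[cols])
    pos <- v$pos[cols]
    for (i in seq(1, length(sent_ch), by = chunk)) {
      j <- i:min(i + chunk - 1, length(sent_ch))
      sl <- sent_local[j]
      R2 <- crossprod(Z[, sl, drop = FALSE], Z)^2
      R2[, !poly] <- NA_real_
      R2[!poly[sl], ] <- NA_real_
      win_ok <- abs(outer(pos[sl], pos, "-")) <= window_bp
      hit <- which(!is.na(R2) & R2 >= min_r2 & win_ok, arr.ind = TRUE)
      self <- cbind(row = seq_along(sl), col = sl)
      hit <- hit[!(hit[, 2] == sl[hit[, 1]]), , drop = FALSE]
      parts[[length(parts) + 1]] <- data.frame(
        sentinel = c(sent_ch[j][self[, 1]], sent_ch[j][hit[, 1]]),
        id = c(v$id[cols][self[, 2]], v$id[cols][hit[, 2]]),
        r2 = c(rep(1, length(sl)), R2[hit]),
        stringsAsFactors = FALSE
      )
    }
  }
  members <- do.call(rbind, parts)
  rownames(members) <- NULL
  structure(list(members = members, sentinels = sentinels,
                 r2_threshold = min_r2, window_bp = window_bp),
            class = "haplotype_blocks")
}

# Canonical long format for any block representation.
blocks_members <- function(blocks) {
  if (inherits(blocks, "haplotype_blocks")) return(blocks)
  if (inherits(blocks, "haplotype_block")) blocks <- list(blocks)
  stopifnot(all(vapply(blocks, inherits, TRUE, "haplotype_block")))
  members <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(sentinel = b$sentinel, id = b$members$id, r2 = b$members$r2,
               stringsAsFactors = FALSE)
  }))
  structure(list(members = members,
                 sentinels = vapply(blocks, function(b) b$sentinel, ""),
                 r2_threshold = min(vapply(blocks, function(b) b$r2_threshold, 1)),
                 window_bp = max(vapply(blocks, function(b) b$window_bp, 0))),
            class = "haplotype_blocks")
}

# Restrict blocks to a higher r2 threshold (members are nested by design).
filter_blocks <- function(blocks, min_r2) {
  blocks <- blocks_members(blocks)
  if (min_r2 < blocks$r2_threshold) {
    stop("cannot lower the r2 threshold without re-expanding")
  }
  keep <- blocks$members$r2 >= min_r2 |
    blocks$members$id == blocks$members$sentinel
  blocks$members <- blocks$members[keep, , drop = FALSE]
  blocks$r2_threshold <- min_r2
  blocks
}

#' Convert haplotype block members to 1-bp intervals
#'
#' Variant positions are 1-based in the panel; each member becomes the
#' 0-based half-open interval `[pos - 1, pos)`, tagged with its sentinel and
#' r-squared.
#'
#' @param block A `haplotype_block`, `haplotype_blocks`, or list of blocks.
#' @param panel The [phased_panel()] the blocks were expanded from.
#' @return An [interval_set()] with columns `sentinel` and `r2`.
#' @export
blocks_to_intervals <- function(block, panel) {
  blocks <- blocks_members(block)
  m <- blocks$members
  idx <- match(m$id, panel$variants$id)
  if (anyNA(idx)) stop("block member absent from panel")
  interval_set(
    chrom = panel$variants$chrom[idx],
    start = panel$variants$pos[idx] - 1,
    end = panel$variants$pos[idx],
    name = m$id,
    sentinel = m$sentinel,
    r2 = m$r2
  )
}

#' Read a phased panel from a minimal VCF-like file
#'
#' Format: tab-separated columns `CHROM POS ID REF ALT`, then one phased
#' column per individual written `a|b` with `a,b` in `{0,1}` (two haplotypes
#' per individual). A leading `#` header line is permitted.
#'
#' @param path Input path (optionally gzipped).
#' @return A [phased_panel()].
#' @export
read_panel <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("panel file has no variant records")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6) || length(unique(nf)) != 1) {
    stop("panel file must have CHROM POS ID REF ALT plus phased columns")
  }
  m <- do.call(rbind, fields)
  variants <- data.frame(
    id = m[, 3], chrom = m[, 1], pos = as.numeric(m[, 2]),
    ref = m[, 4], alt = m[, 5], stringsAsFactors = FALSE
  )
  gt <- m[, 6:ncol(m), drop = FALSE]
  a <- substr(gt, 1, 1)
  b <- substr(gt, 3, 3)
  if (!all(c(a, b) %in% c("0", "1")) || !all(substr(gt, 2, 2) == "|")) {
    stop("panel genotype columns must be phased 'a|b' with a,b in {0,1}")
  }
  n_var <- nrow(variants)
  haps <- matrix(0, nrow = 2 * ncol(gt), ncol = n_var)
  haps[seq(1, nrow(haps), by = 2), ] <- t(matrix(as.numeric(a), nrow = n_var))
  haps[seq(2, nrow(haps), by = 2), ] <- t(matrix(as.numeric(b), nrow = n_var))
  phased_panel(variants, haps)
}

#' Write a phased panel in the minimal VCF-like format
#'
#' @param panel A [phased_panel()] with an even number of haplotypes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  H <- panel$haplotypes
  if (nrow(H) %% 2 != 0) {
    stop("panel must have an even haplotype count to write individual columns")
  }
  a <- H[seq(1, nrow(H), by = 2), , drop = FALSE]
  b <- H[seq(2, nrow(H), by = 2), , drop = FALSE]
  gt <- matrix(paste0(a, "|", b), nrow = nrow(a))
  v <- panel$variants
  lines <- c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT",
            paste0("ind", seq_len(nrow(a)))), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], format_bp(v$pos[i]), v$id[i], v$ref[i], v$alt[i],
              gt[, i]), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
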