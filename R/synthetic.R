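#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' DHS containing short TF footprints, block-structured LD among panel
#' SNVs, sentinel variants with a configurable planted fold-enrichment
#' inside footprints, motif occurrences with elevated central conservation
#' for expressed TFs, and per-base DNase cut profiles with occasional
#' single-position artefact spikes.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome.
#' @param n_dhs Total DHS count (placed without overlap).
#' @param dhs_length_bp `(min, max)` DHS length.
#' @param footprint_per_dhs_prob Probability a DHS contains a footprint.
#' @param footprint_length_bp `(min, max)` footprint length (default the
#'   narrow 11-22 bp setting).
#' @param n_snvs Panel SNV count (uniform positions).
#' @param n_haplotypes_in_panel Haplotypes in the phased panel (even, so
#'   the panel can be written as phased individuals).
#' @param ld_block_length_bp LD block length; SNVs in the same block share
#'   an ancestral haplotype.
#' @param within_block_r2 Target pairwise r-squared within a block.
#' @param n_sentinels Number of sentinel variants.
#' @param planted_fold Fold-enrichment of sentinels inside footprints
#'   relative to uniform placement over DHS base pairs.
#' @param n_motifs Total motif occurrences.
#' @param motif_length PWM length (must fit the narrowest footprint).
#' @param expressed_tf_fraction Fraction of TFs highly expressed.
#' @param conservation_signal Log-conservation added across expressed-TF
#'   motif occurrences.
#' @param artefact_spike_prob Probability a footprint is a planted
#'   cut-profile artefact.
#' @param seed RNG seed; the same seed yields a bit-identical dataset.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 2,
                             chrom_length_bp = 1e6,
                             n_dhs = 500,
                             dhs_length_bp = c(200, 500),
                             footprint_per_dhs_prob = 0.25,
                             footprint_length_bp = c(11, 22),
                             n_snvs = 2000,
                             n_haplotypes_in_panel = 200,
                             ld_block_length_bp = 20000,
                             within_block_r2 = 0.8,
                             n_sentinels = 500,
                             planted_fold = 1.65,
                             n_motifs = 400,
                             motif_length = 8,
                             expressed_tf_fraction = 0.5,
                             conservation_signal = 0.5,
                             artefact_spike_prob = 0.05,
                             seed = 1) {
  cfg <- list(
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    chrom_length_bp = check_count(chrom_length_bp, "chrom_length_bp", min = 1000),
    n_dhs = check_count(n_dhs, "n_dhs", min = 0),
    dhs_length_bp = check_range(dhs_length_bp, "dhs_length_bp"),
    footprint_per_dhs_prob = check_prob(footprint_per_dhs_prob, "footprint_per_dhs_prob"),
    footprint_length_bp = check_range(footprint_length_bp, "footprint_length_bp"),
    n_snvs = check_count(n_snvs, "n_snvs", min = 0),
    n_haplotypes_in_panel = check_count(n_haplotypes_in_panel, "n_haplotypes_in_panel", min = 2),
    ld_block_length_bp = check_count(ld_block_length_bp, "ld_block_length_bp"),
    within_block_r2 = check_prob(within_block_r2, "within_block_r2"),
    n_sentinels = check_count(n_sentinels, "n_sentinels", min = 0),
    planted_fold = planted_fold,
    n_motifs = check_count(n_motifs, "n_motifs", min = 0),
    motif_length = check_count(motif_length, "motif_length", min = 4),
    expressed_tf_fraction = check_prob(expressed_tf_fraction, "expressed_tf_fraction"),
    conservation_signal = conservation_signal,
    artefact_spike_prob = check_prob(artefact_spike_prob, "artefact_spike_prob"),
    seed = check_count(seed, "seed", min = 0)
  )
  if (!is.numeric(planted_fold) || length(planted_fold) != 1 || planted_fold < 0)
    stop_field("planted_fold", "must be a single non-negative number")
  if (!is.numeric(conservation_signal) || conservation_signal < 0)
    stop_field("conservation_signal", "must be non-negative")
  if (cfg$footprint_length_bp[2] > cfg$dhs_length_bp[1])
    stop_field("footprint_length_bp", "maximum footprint must fit the smallest DHS")
  if (cfg$motif_length > cfg$footprint_length_bp[1])
    stop_field("motif_length", "motif must fit the narrowest footprint")
  if (cfg$n_haplotypes_in_panel %% 2 != 0)
    stop_field("n_haplotypes_in_panel", "must be even (phased individuals)")
  class(cfg) <- "synthetic_config"
  cfg
}

# Place k non-overlapping intervals of given lengths uniformly in [0, L).
place_nonoverlapping <- function(lens, L) {
  k <- length(lens)
  free <- L - sum(lens)
  if (free < 0) stop_field("n_dhs", "intervals do not fit the chromosome")
  u <- sort(stats::runif(k, 0, free))
  starts <- floor(u) + cumsum(c(0, lens[-k]))
  starts
}

# Flip probability giving expected pairwise r2 = target under the shared
# ancestral-column scheme: corr(X, Y) = (1 - 2 eps)^2, r2 = (1 - 2 eps)^4.
flip_eps <- function(target_r2) (1 - target_r2^0.25) / 2

# LD-block key, safe for zero-length input (paste0 would recycle the
# scalar separator to length 1).
block_key_of <- function(chrom, pos, block_len) {
  if (length(chrom) == 0) return(character(0))
  paste0(chrom, ":", floor((pos - 1) / block_len))
}

#' Generate a complete synthetic dataset
#'
#' Deterministic for a fixed seed. Every footprint lies inside exactly one
#' DHS, every DHS inside the workspace; sentinel positions are uniform
#' over DHS base pairs with the planted fold-enrichment applied by
#' rejection; the truth record is sufficient to score recovery of the
#' planted effects.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `workspace`,
#'   `dhs`, `footprints`, `blacklist`, `cut_track`, `conservation_track`,
#'   `panel`, `sentinels`, `motif_occurrences`, `pwms`, `hits`,
#'   `expression`, `chrom_lengths`, `config` and `truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  L <- cfg$chrom_length_bp
  chrom_lengths <- stats::setNames(rep(L, cfg$n_chromosomes), chroms)
  workspace <- interval_set(chrom = chroms, start = rep(0, length(chroms)),
                            end = rep(L, length(chroms)))

  # blacklist: a couple of anomalous regions per chromosome
  bl_start <- unlist(lapply(chroms, function(ch) floor(stats::runif(2, 0, L - 500))))
  blacklist <- interval_set(chrom = rep(chroms, each = 2), start = bl_start,
                            end = bl_start + 500,
                            name = sprintf("bl_%03d", seq_along(bl_start)))

  # DHS, non-overlapping within each chromosome
  n_per <- rep(floor(cfg$n_dhs / cfg$n_chromosomes), cfg$n_chromosomes)
  extra <- cfg$n_dhs - sum(n_per)
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1
  dhs_parts <- lapply(seq_along(chroms), function(i) {
    k <- n_per[i]
    if (k == 0) return(NULL)
    lens <- sample(seq(cfg$dhs_length_bp[1], cfg$dhs_length_bp[2]), k, replace = TRUE)
    data.frame(chrom = chroms[i], start = place_nonoverlapping(lens, L),
               len = lens)
  })
  dhs_df <- do.call(rbind, dhs_parts)
  if (is.null(dhs_df)) {
    dhs_df <- data.frame(chrom = character(0), start = numeric(0),
                         len = numeric(0))
  }
  dhs <- interval_set(chrom = dhs_df$chrom, start = dhs_df$start,
                      end = dhs_df$start + dhs_df$len,
                      name = sprintf("dhs_%05d", seq_len(nrow(dhs_df))))

  # footprints: at most one per DHS; latent true/false label drives scores
  has_fp <- stats::runif(nrow(dhs)) < cfg$footprint_per_dhs_prob
  fp_dhs <- which(has_fp)
  n_fp <- length(fp_dhs)
  fp_len <- sample(seq(cfg$footprint_length_bp[1], cfg$footprint_length_bp[2]),
                   n_fp, replace = TRUE)
  dlen <- dhs$end[fp_dhs] - dhs$start[fp_dhs]
  fp_start <- dhs$start[fp_dhs] + floor(stats::runif(n_fp) * (dlen - fp_len + 1))
  fp_true <- stats::runif(n_fp) < 0.5
  score_boundary <- 50
  fp_score <- ifelse(fp_true, stats::runif(n_fp, score_boundary, 100),
                     stats::runif(n_fp, 0, score_boundary))
  fp_artefact <- stats::runif(n_fp) < cfg$artefact_spike_prob
  fp_name <- sprintf("fp_%05d", seq_len(n_fp))
  footprints <- interval_set(chrom = dhs$chrom[fp_dhs], start = fp_start,
                             end = fp_start + fp_len, name = fp_name,
                             score = fp_score)
  # interval_set re-sorts; recover per-row metadata by name
  ord <- match(footprints$name, fp_name)
  fp_true <- fp_true[ord]; fp_artefact <- fp_artefact[ord]

  # transcription factors, expression classes, PWMs
  n_tf <- max(2, min(24, ceiling(cfg$n_motifs / 25)))
  n_hi <- min(n_tf - 1, max(1, round(cfg$expressed_tf_fraction * n_tf)))
  tf_ids <- sprintf("TF%02d", seq_len(n_tf))
  hi_tfs <- tf_ids[seq_len(n_hi)]
  und_tfs <- setdiff(tf_ids, hi_tfs)
  k <- cfg$motif_length
  pwms <- lapply(tf_ids, function(id) {
    dom <- sample(1:4, k, replace = TRUE)
    prob <- matrix(0.05, nrow = k, ncol = 4)
    prob[cbind(seq_len(k), dom)] <- 0.85
    pwm(id, prob)
  })
  names(pwms) <- tf_ids

  # motif occurrences: expressed-TF motifs inside true footprints,
  # undetectable-TF motifs in half of the false footprints, surplus
  # expressed-TF occurrences in DHS territory clear of footprints
  occ <- list()
  add_occ <- function(chrom, start, tf, origin) {
    occ[[length(occ) + 1]] <<- data.frame(
      chrom = chrom, start = start, tf_id = tf, origin = origin,
      stringsAsFactors = FALSE)
  }
  true_idx <- which(fp_true)
  if (length(true_idx) > 0) {
    room <- (footprints$end - footprints$start)[true_idx] - k + 1
    add_occ(footprints$chrom[true_idx],
            footprints$start[true_idx] + floor(stats::runif(length(true_idx)) * room),
            sample(hi_tfs, length(true_idx), replace = TRUE), "true_fp")
  }
  false_idx <- which(!fp_true)
  false_idx <- false_idx[stats::runif(length(false_idx)) < 0.5]
  if (length(false_idx) > 0) {
    room <- (footprints$end - footprints$start)[false_idx] - k + 1
    add_occ(footprints$chrom[false_idx],
            footprints$start[false_idx] + floor(stats::runif(length(false_idx)) * room),
            sample(und_tfs, length(false_idx), replace = TRUE), "false_fp")
  }
  n_extra <- cfg$n_motifs - length(true_idx) - length(false_idx)
  if (n_extra > 0 && nrow(dhs) > 0) {
    pad <- interval_set(chrom = footprints$chrom,
                        start = pmax(0, footprints$start - (k - 1)),
                        end = pmin(L, footprints$end + (k - 1)))
    allowed <- if (nrow(footprints) > 0) subtract_intervals(dhs, pad) else dhs
    allowed <- allowed[(allowed$end - allowed$start) >= k, , drop = FALSE]
    offs <- chrom_offsets(chroms)
    seg <- merge_global(allowed, offs)
    gpos <- place_randomly(rep(k, n_extra), seg$start, seg$end - seg$start)
    ci <- floor(gpos / .CHROM_STRIDE) + 1
    add_occ(names(offs)[ci], gpos - (ci - 1) * .CHROM_STRIDE,
            sample(hi_tfs, n_extra, replace = TRUE), "extra")
  }
  occ <- if (length(occ) > 0) do.call(rbind, occ) else {
    data.frame(chrom = character(0), start = numeric(0),
               tf_id = character(0), origin = character(0),
               stringsAsFactors = FALSE)
  }
  motif_occurrences <- interval_set(chrom = occ$chrom, start = occ$start,
                                    end = occ$start + k, name = occ$tf_id,
                                    tf_id = occ$tf_id, origin = occ$origin)

  # realized motif hits: consensus sequence of the occurrence's PWM
  consensus <- vapply(pwms, function(x) {
    paste(c("A", "C", "G", "T")[apply(x$prob, 1, which.max)], collapse = "")
  }, "")
  cons_score <- vapply(pwms, function(x) {
    S <- pwm_score_int(x)
    sum(S[cbind(seq_len(k), apply(x$prob, 1, which.max))]) * .SCORE_BIN
  }, 1)
  cons_p <- vapply(pwms, function(x) {
    d <- pwm_score_distribution(x)
    smax <- max(d$scores[d$prob > 0])
    d$tail[match(smax, d$scores)]
  }, 1)
  hits <- data.frame(
    tf_id = motif_occurrences$tf_id,
    chrom = motif_occurrences$chrom,
    start = motif_occurrences$start,
    end = motif_occurrences$end,
    strand = rep("+", nrow(motif_occurrences)),
    score = unname(cons_score[motif_occurrences$tf_id]),
    p_value = unname(cons_p[motif_occurrences$tf_id]),
    seq = unname(consensus[motif_occurrences$tf_id]),
    stringsAsFactors = FALSE
  )

  # conservation track: Gaussian noise over DHS neighbourhoods, planted
  # signal across expressed-TF motif occurrences
  noise_region <- from_granges(GenomicRanges::reduce(as_granges(
    interval_set(chrom = dhs$chrom, start = pmax(0, dhs$start - 60),
                 end = pmin(L, dhs$end + 60)))))
  hi_occ <- motif_occurrences[motif_occurrences$tf_id %in% hi_tfs, , drop = FALSE]
  conservation <- scored_track(chrom_lengths)
  for (ch in chroms) {
    v <- numeric(L)
    nr <- noise_region[noise_region$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(nr))) {
      idx <- (nr$start[i] + 1):nr$end[i]
      v[idx] <- stats::rnorm(length(idx), 0, 0.3)
    }
    ho <- hi_occ[hi_occ$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ho))) {
      idx <- (ho$start[i] + 1):ho$end[i]
      v[idx] <- v[idx] + cfg$conservation_signal
    }
    conservation[[ch]] <- v
  }

  # cut-count track: Poisson background over DHS neighbourhoods; planted
  # artefacts dominate their 100-bp window by construction
  cut_region <- from_granges(GenomicRanges::reduce(as_granges(
    interval_set(chrom = dhs$chrom, start = pmax(0, dhs$start - 110),
                 end = pmin(L, dhs$end + 110)))))
  cuts <- scored_track(chrom_lengths)
  for (ch in chroms) {
    v <- numeric(L)
    cr <- cut_region[cut_region$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(cr))) {
      idx <- (cr$start[i] + 1):cr$end[i]
      v[idx] <- stats::rpois(length(idx), 1)
    }
    for (i in which(fp_artefact & footprints$chrom == ch)) {
      len <- footprints$end[i] - footprints$start[i]
      centre <- footprints$start[i] + floor(len / 2)
      spike_at <- min(max(centre + sample(-100:100, 1), 0), L - 1)
      win <- v[max(1, centre - 100 + 1):min(L, centre + 101)]
      v[spike_at + 1] <- 10 * max(1, sum(win))
    }
    cuts[[ch]] <- v
  }

  # phased panel: block-structured LD via shared ancestral columns
  n_hap <- cfg$n_haplotypes_in_panel
  eps <- flip_eps(cfg$within_block_r2)
  snv_per <- rep(floor(cfg$n_snvs / cfg$n_chromosomes), cfg$n_chromosomes)
  extra <- cfg$n_snvs - sum(snv_per)
  if (extra > 0) snv_per[seq_len(extra)] <- snv_per[seq_len(extra)] + 1
  snv_chrom <- rep(chroms, snv_per)
  snv_pos <- unlist(lapply(seq_along(chroms), function(i) {
    sort(sample.int(L, snv_per[i]))
  }))
  block_key <- block_key_of(snv_chrom, snv_pos, cfg$ld_block_length_bp)
  ancestors <- new.env(parent = emptyenv())
  anc_of <- function(key) {
    a <- ancestors[[key]]
    if (is.null(a)) {
      a <- stats::rbinom(n_hap, 1, 0.5)
      ancestors[[key]] <- a
    }
    a
  }
  flip_col <- function(anc) {
    if (eps == 0) return(anc)
    (anc + stats::rbinom(n_hap, 1, eps)) %% 2
  }
  snv_mat <- vapply(block_key, function(key) flip_col(anc_of(key)),
                    numeric(n_hap))

  # sentinel positions: uniform over DHS base pairs with the planted fold
  # applied by rejection toward (or away from) footprints
  offs <- chrom_offsets(chroms)
  dhs_m <- merge_global(dhs, offs)
  fp_m <- merge_global(footprints, offs)
  dhs_bp <- sum(dhs_m$end - dhs_m$start)
  fp_bp <- sum(fp_m$end - fp_m$start)
  baseline <- if (dhs_bp > 0) fp_bp / dhs_bp else 0
  phi <- cfg$planted_fold
  if (cfg$n_sentinels > 0 && dhs_bp == 0) {
    stop_field("n_sentinels", "sentinels require at least one DHS")
  }
  if (phi * baseline > 1) {
    stop_field("planted_fold",
               sprintf("fold %g infeasible at footprint density %.4f", phi, baseline))
  }
  n_s <- cfg$n_sentinels
  if (phi >= 1) {
    alpha <- if (baseline < 1) baseline * (phi - 1) / (1 - baseline) else 0
    forced_in <- stats::runif(n_s) < alpha
    forced_out <- rep(FALSE, n_s)
  } else {
    forced_in <- rep(FALSE, n_s)
    forced_out <- stats::runif(n_s) < (1 - phi)
  }
  outside_m <- merge_global(subtract_intervals(dhs, footprints), offs)
  # map each footprint to its motif occurrence (if any) for motif-aware
  # forced placement
  fp_has_hit <- rep(NA_integer_, nrow(footprints))
  if (nrow(footprints) > 0 && nrow(hits) > 0) {
    for (r in which(occ$origin %in% c("true_fp", "false_fp"))) {
      j <- which(footprints$chrom == occ$chrom[r] &
                   footprints$start <= occ$start[r] &
                   footprints$end >= occ$start[r] + k)
      if (length(j) == 1) fp_has_hit[j] <- r
    }
  }
  draw_positions <- function(idx_forced_in, idx_forced_out, idx_plain) {
    pos <- numeric(n_s)
    planted_hit <- rep(NA_integer_, n_s)
    if (length(idx_plain) > 0) {
      pos[idx_plain] <- place_randomly(rep(1, length(idx_plain)),
                                       dhs_m$start, dhs_m$end - dhs_m$start)
    }
    if (length(idx_forced_out) > 0) {
      pos[idx_forced_out] <- place_randomly(rep(1, length(idx_forced_out)),
                                            outside_m$start,
                                            outside_m$end - outside_m$start)
    }
    if (length(idx_forced_in) > 0) {
      fl <- footprints$end - footprints$start
      pick <- sample.int(nrow(footprints), length(idx_forced_in),
                         replace = TRUE, prob = fl)
      for (t in seq_along(idx_forced_in)) {
        j <- pick[t]
        r <- fp_has_hit[j]
        gstart <- globalize(footprints$chrom[j], footprints$start[j], offs)
        if (!is.na(r)) {
          mstart <- globalize(occ$chrom[r], occ$start[r], offs)
          pos[idx_forced_in[t]] <- mstart + sample.int(k, 1) - 1
          planted_hit[idx_forced_in[t]] <- r
        } else {
          pos[idx_forced_in[t]] <- gstart + sample.int(fl[j], 1) - 1
        }
      }
    }
    list(pos = pos, planted_hit = planted_hit)
  }
  dp <- draw_positions(which(forced_in), which(forced_out),
                       which(!forced_in & !forced_out))
  sent_gpos <- dp$pos
  planted_hit <- dp$planted_hit
  # resolve position collisions (panel positions must be unique)
  snv_gpos <- globalize(snv_chrom, snv_pos - 1, offs)
  repeat {
    dup <- duplicated(sent_gpos) | sent_gpos %in% snv_gpos
    if (!any(dup)) break
    rd <- draw_positions(which(dup & forced_in), which(dup & forced_out),
                         which(dup & !forced_in & !forced_out))
    sent_gpos[dup] <- rd$pos[dup]
    planted_hit[dup] <- rd$planted_hit[dup]
  }
  ci <- floor(sent_gpos / .CHROM_STRIDE) + 1
  sent_chrom <- names(offs)[ci]
  sent_pos <- sent_gpos - (ci - 1) * .CHROM_STRIDE + 1  # 1-based
  sent_ids <- sprintf("sent_%05d", seq_len(n_s))
  sent_in_fp <- any_overlap_global(sent_gpos, sent_gpos + 1, fp_m)

  sent_block <- block_key_of(sent_chrom, sent_pos, cfg$ld_block_length_bp)
  sent_mat <- vapply(sent_block, function(key) flip_col(anc_of(key)),
                     numeric(n_hap))

  # ref/alt alleles, consistent with any overlapping motif hit
  bases <- c("A", "C", "G", "T")
  rand_base <- function(n) bases[sample.int(4, n, replace = TRUE)]
  rand_other <- function(ref) {
    vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  }
  assign_alleles <- function(chrom, gpos) {
    n <- length(gpos)
    ref <- rand_base(n)
    hs <- globalize(hits$chrom, hits$start, offs)
    he <- globalize(hits$chrom, hits$end, offs)
    for (i in seq_len(n)) {
      j <- which(hs <= gpos[i] & he > gpos[i])
      if (length(j) > 0) {
        off_in <- gpos[i] - hs[j[1]] + 1
        ref[i] <- substr(hits$seq[j[1]], off_in, off_in)
      }
    }
    list(ref = ref, alt = rand_other(ref))
  }
  snv_al <- assign_alleles(snv_chrom, snv_gpos)
  sent_al <- assign_alleles(sent_chrom, sent_gpos)
  # planted disruption: forced-in sentinels landing in a motif get the
  # least-probable base as their alternate allele
  disruptive_planted <- rep(FALSE, n_s)
  for (i in which(!is.na(planted_hit))) {
    r <- planted_hit[i]
    off_in <- (sent_gpos[i] - globalize(occ$chrom[r], occ$start[r], offs)) + 1
    pw <- pwms[[occ$tf_id[r]]]
    ref_b <- substr(hits$seq[r], off_in, off_in)
    worst <- bases[which.min(pw$prob[off_in, ])]
    if (worst == ref_b) worst <- bases[order(pw$prob[off_in, ])[2]]
    sent_al$ref[i] <- ref_b
    sent_al$alt[i] <- worst
    disruptive_planted[i] <- TRUE
  }

  variants <- data.frame(
    id = c(paste0("snv_", sprintf("%05d", seq_along(snv_pos))), sent_ids),
    chrom = c(snv_chrom, sent_chrom),
    pos = c(snv_pos, sent_pos),
    ref = c(snv_al$ref, sent_al$ref),
    alt = c(snv_al$alt, sent_al$alt),
    stringsAsFactors = FALSE
  )
  panel <- phased_panel(variants, cbind(snv_mat, sent_mat))

  sentinels <- data.frame(
    id = sent_ids,
    trait = sprintf("trait_%02d", sample.int(10, n_s, replace = TRUE)),
    p_value = 10^-stats::runif(n_s, 5, 20),
    stringsAsFactors = FALSE
  )

  samples <- paste0("S", 1:5)
  expression <- matrix(0, nrow = n_tf, ncol = length(samples),
                       dimnames = list(tf_ids, samples))
  expression[hi_tfs, ] <- stats::runif(n_hi * length(samples), 15, 60)

  truth <- list(
    planted_fold = phi,
    baseline_rate = baseline,
    realized_fold = mean(sent_in_fp) / baseline,
    score_boundary = score_boundary,
    boundary_centile = 100 * mean(footprints$score < score_boundary),
    epsilon = eps,
    hi_tfs = hi_tfs,
    und_tfs = und_tfs,
    footprints = data.frame(name = footprints$name, true = fp_true,
                            artefact = fp_artefact, stringsAsFactors = FALSE),
    sentinels = data.frame(id = sent_ids, in_footprint = sent_in_fp,
                           forced = forced_in | forced_out,
                           disruptive_planted = disruptive_planted,
                           stringsAsFactors = FALSE)
  )

  structure(list(
    workspace = workspace, dhs = dhs, footprints = footprints,
    blacklist = blacklist, cut_track = cuts,
    conservation_track = conservation, panel = panel,
    sentinels = sentinels, motif_occurrences = motif_occurrences,
    pwms = pwms, hits = hits, expression = expression,
    chrom_lengths = chrom_lengths, config = cfg, truth = truth
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_dataset: %d chromosome(s), %d DHS, %d footprints, ",
    "%d panel variants (%d sentinels), %d motif occurrences\n"),
    length(x$chrom_lengths), nrow(x$dhs), nrow(x$footprints),
    nrow(x$panel$variants), nrow(x$sentinels), nrow(x$motif_occurrences)))
  invisible(x)
}
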