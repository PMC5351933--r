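#' Pipeline configuration
#'
#' Defaults follow the published analysis parameters: r-squared grid 0.5 to
#' 1.0, a 10-Mb LD window, a genome-wide-significance sentinel filter at
#' P < 5e-8, footprint widths 11-22 bp, the >50% cut-profile skew filter
#' within 100 bp, calibration at a TP:FP target of 2, 10,000 enrichment
#' randomisations, FIMO-style motif matching at P < 1e-4, and 1,000
#' footprint shuffles for the disruption test.
#'
#' @param synthetic A [synthetic_config()] to generate data from, or `NULL`.
#' @param data_dir Dataset directory from [write_dataset()] (used when
#'   `synthetic` is `NULL`).
#' @param r2_grid Ascending r-squared thresholds.
#' @param window_bp LD window.
#' @param gwas_p_threshold Sentinel inclusion p-value.
#' @param qc List of footprint QC settings (`min_width`, `max_width`,
#'   `artefact_window`, `artefact_skew`, and optionally `autosomes`).
#' @param calibration List with `enabled`, `target_ratio`, `centile_grid`,
#'   `delta_threshold`, `flank_bp`.
#' @param enrichment List with `n` (randomisations) and `mode`.
#' @param motif List with `p` and `n_shuffles`.
#' @param seed Top-level seed for every randomised stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, data_dir = NULL,
                            r2_grid = seq(0.5, 1.0, 0.1), window_bp = 1e7,
                            gwas_p_threshold = 5e-8,
                            qc = list(), calibration = list(),
                            enrichment = list(), motif = list(), seed = 1) {
  if (is.null(synthetic) && is.null(data_dir)) {
    stop("supply either a synthetic generation block or a data directory")
  }
  merge_defaults <- function(given, defaults) {
    defaults[names(given)] <- given
    defaults
  }
  structure(list(
    synthetic = synthetic,
    data_dir = data_dir,
    r2_grid = r2_grid,
    window_bp = window_bp,
    gwas_p_threshold = gwas_p_threshold,
    qc = merge_defaults(qc, list(min_width = 11, max_width = 22,
                                 artefact_window = 100, artefact_skew = 0.5,
                                 autosomes = NULL)),
    calibration = merge_defaults(calibration, list(
      enabled = TRUE, target_ratio = 2, centile_grid = seq(0, 95, 5),
      delta_threshold = 0.1, flank_bp = 50)),
    enrichment = merge_defaults(enrichment, list(n = 10000, mode = "segment")),
    motif = merge_defaults(motif, list(p = 1e-4, n_shuffles = 1000)),
    seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments
#'   (with `synthetic` holding [synthetic_config()] fields).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$enrichment)) {
    nm <- names(raw$enrichment)
    nm[nm == "FALSE"] <- "n"  # YAML 1.1 reads a bare `n:` key as a boolean
    nm[nm == "n_randomisations"] <- "n"
    names(raw$enrichment) <- nm
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_config, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: generate or load the dataset; drop sentinels failing
#' the genome-wide-significance filter; footprint QC (blacklist, width,
#' artefact filter); optional conservation-based score calibration;
#' haplotype expansion across the r-squared grid and overlap-proportion
#' curves for the DHS, footprint and footprint-motif layers;
#' workspace-constrained enrichment of sentinel variants in footprints
#' (DHS workspace) and in DHS (chromosome workspace minus blacklist);
#' the motif-disruption test; Benjamini-Hochberg correction across the
#' enrichment rows.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `haplofoot_report` with elements `counts`,
#'   `qc`, `calibration`, `pi`, `enrichment`, `disruption`, `seed` and
#'   `log`. All tables are plain `data.frame`s.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  stage <- function(name, msg) log <<- log_line(log, name, msg)

  ds <- if (!is.null(config$synthetic)) {
    generate_dataset(config$synthetic)
  } else {
    read_dataset(config$data_dir)
  }
  stage("data", sprintf("%d DHS, %d footprints, %d sentinels",
                        nrow(ds$dhs), nrow(ds$footprints), nrow(ds$sentinels)))

  sent <- ds$sentinels[ds$sentinels$p_value < config$gwas_p_threshold, ,
                       drop = FALSE]
  stage("sentinel_filter", sprintf("%d of %d sentinels pass P < %g",
                                   nrow(sent), nrow(ds$sentinels),
                                   config$gwas_p_threshold))
  if (nrow(sent) == 0) stop("pipeline stage sentinel_filter: no sentinels pass")

  qc <- footprint_qc(
    ds$footprints, blacklist = ds$blacklist,
    autosomes = config$qc$autosomes, cuts = ds$cut_track,
    min_bp = config$qc$min_width, max_bp = config$qc$max_width,
    half_window_bp = config$qc$artefact_window,
    skew_threshold = config$qc$artefact_skew
  )
  fp <- qc$kept
  stage("footprint_qc", sprintf("%d of %d footprints kept", nrow(fp),
                                nrow(ds$footprints)))
  if (nrow(fp) == 0) stop("pipeline stage footprint_qc: no footprints survive")

  calibration <- NULL
  if (isTRUE(config$calibration$enabled)) {
    classes <- classify_tfs(ds$expression)
    calibration <- calibrate_threshold(
      fp, ds$motif_occurrences, classes$highly_expressed,
      classes$undetectable, ds$conservation_track,
      target_ratio = config$calibration$target_ratio,
      centile_grid = config$calibration$centile_grid,
      delta_threshold = config$calibration$delta_threshold,
      flank_bp = config$calibration$flank_bp
    )
    stage("calibration", sprintf("chosen score centile: %s",
                                 format(calibration$chosen_centile)))
  }

  layers <- list(
    dhs = ds$dhs,
    footprints = fp,
    footprint_motif = intersect_intervals(fp, ds$motif_occurrences)
  )
  pi_tab <- pi_curve(sent$id, ds$panel, layers, r2_grid = config$r2_grid,
                     window_bp = config$window_bp)
  stage("pi_curves", sprintf("%d (threshold, layer) cells over %d blocks",
                             nrow(pi_tab), nrow(sent)))

  all_iv <- panel_variant_intervals(ds$panel)
  sent_iv <- all_iv[all_iv$name %in% sent$id, , drop = FALSE]
  arms <- subtract_intervals(ds$workspace, ds$blacklist)
  enr <- list(
    footprints_vs_dhs_workspace = fold_enrichment(
      sent_iv, fp, ds$dhs, n = config$enrichment$n,
      seed = config$seed, mode = config$enrichment$mode),
    dhs_vs_chromosome_workspace = fold_enrichment(
      sent_iv, ds$dhs, arms, n = config$enrichment$n,
      seed = config$seed + 1, mode = config$enrichment$mode)
  )
  stage("enrichment", sprintf("%d tests at n = %d", length(enr),
                              config$enrichment$n))

  disruption <- disruption_proportion_test(
    all_iv, fp, ds$dhs, ds$hits, ds$pwms,
    n_shuffles = config$motif$n_shuffles, seed = config$seed + 2,
    p = config$motif$p
  )
  stage("disruption", sprintf("observed %.3f vs null %.3f, p = %.4g",
                              disruption$observed, disruption$null_mean,
                              disruption$p_value))

  q <- bh_qvalues(vapply(enr, function(e) e$p_empirical, 1))
  enr_tab <- data.frame(
    test = names(enr),
    observed = vapply(enr, function(e) e$observed, 1),
    null_mean = vapply(enr, function(e) e$null_mean, 1),
    null_sd = vapply(enr, function(e) e$null_sd, 1),
    fold = vapply(enr, function(e) e$fold, 1),
    p_empirical = vapply(enr, function(e) e$p_empirical, 1),
    q = q,
    n_randomisations = vapply(enr, function(e) e$n_randomisations, 1),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    counts = data.frame(
      stage = c("dhs", "footprints_in", "footprints_kept", "sentinels_in",
                "sentinels_kept"),
      n = c(nrow(ds$dhs), nrow(ds$footprints), nrow(fp),
            nrow(ds$sentinels), nrow(sent))),
    qc = qc$counts,
    calibration = calibration,
    pi = pi_tab,
    enrichment = enr_tab,
    disruption = disruption[c("observed", "null_mean", "null_sd", "p_value",
                              "n_snvs_in_footprints")],
    seed = config$seed,
    log = log
  ), class = "haplofoot_report")
}

# 1-bp intervals for every panel variant, carrying ref/alt.
panel_variant_intervals <- function(panel) {
  v <- panel$variants
  interval_set(chrom = v$chrom, start = v$pos - 1, end = v$pos, name = v$id,
               ref = v$ref, alt = v$alt)
}

#' Write the report tables of a pipeline run
#'
#' @param report A [run_pipeline()] result.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "haplofoot_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.table(
    x, file.path(directory, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$counts, "counts.tsv")
  w(report$qc, "qc.tsv")
  if (!is.null(report$calibration)) w(report$calibration$curve, "calibration.tsv")
  w(report$pi, "pi_curve.tsv")
  w(report$enrichment, "enrichment.tsv")
  w(data.frame(report$disruption), "disruption.tsv")
  writeLines(report$log, file.path(directory, "run.log"))
  invisible(directory)
}

#' @export
print.haplofoot_report <- function(x, ...) {
  cat("haplofoot pipeline report\n")
  cat("enrichment:\n")
  print(x$enrichment, row.names = FALSE)
  cat(sprintf("disruption: observed %.3f vs null %.3f (p = %.4g)\n",
              x$disruption$observed, x$disruption$null_mean,
              x$disruption$p_value))
  invisible(x)
}
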