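#' Write a synthetic dataset to a directory
#'
#' Emits BED6 files (workspace, DHS, footprints, blacklist, motifs),
#' 3-column per-base track tables, a minimal VCF-like phased panel,
#' sentinel and expression tables, PWMs in MEME minimal format, realized
#' motif hits, the truth record, and a manifest listing every file with
#' its MD5 checksum. Everything round-trips through [read_dataset()].
#'
#' @param ds A [generate_dataset()] result.
#' @param directory Output directory (created if absent).
#' @return The manifest `data.frame` (file, md5), invisibly.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(directory, f)

  utils::write.table(
    data.frame(chrom = names(ds$chrom_lengths),
               length = format_bp(unname(ds$chrom_lengths))),
    path("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bed(ds$workspace, path("workspace.bed"))
  write_bed(ds$dhs, path("dhs.bed"))
  write_bed(ds$footprints, path("footprints.bed"))
  write_bed(ds$blacklist, path("blacklist.bed"))
  write_bed(ds$motif_occurrences, path("motifs.bed"))
  write_track(ds$cut_track, path("cut_track.tsv"))
  write_track(ds$conservation_track, path("conservation_track.tsv"))
  write_panel(ds$panel, path("panel.vcf"))
  utils::write.table(ds$sentinels, path("sentinels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- data.frame(tf_id = rownames(ds$expression), ds$expression,
                     check.names = FALSE)
  utils::write.table(expr, path("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_meme(ds$pwms, path("pwms.meme"))
  utils::write.table(ds$hits, path("hits.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(ds$config), path("config.yaml"), precision = 15)
  truth_scalars <- ds$truth[!vapply(ds$truth, is.data.frame, TRUE)]
  yaml::write_yaml(truth_scalars, path("truth.yaml"), precision = 15)
  utils::write.table(ds$truth$footprints, path("footprint_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$sentinels, path("sentinel_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c("chrom_sizes.tsv", "workspace.bed", "dhs.bed", "footprints.bed",
             "blacklist.bed", "motifs.bed", "cut_track.tsv",
             "conservation_track.tsv", "panel.vcf", "sentinels.tsv",
             "expression.tsv", "pwms.meme", "hits.tsv", "config.yaml",
             "truth.yaml", "footprint_truth.tsv", "sentinel_truth.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(vapply(files, path, ""))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

read_tsv_df <- function(path, logical_cols = character(0)) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in intersect(logical_cols, names(out))) {
    out[[cl]] <- as.logical(out[[cl]])
  }
  out
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param directory Dataset directory.
#' @return A list of class `synthetic_dataset`.
#' @export
read_dataset <- function(directory) {
  path <- function(f) file.path(directory, f)
  sizes <- utils::read.table(path("chrom_sizes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  chrom_lengths <- stats::setNames(as.numeric(sizes[[2]]), sizes[[1]])
  motifs <- read_bed(path("motifs.bed"))
  motifs$tf_id <- motifs$name
  expr_df <- read_tsv_df(path("expression.tsv"))
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$tf_id
  cfg_raw <- yaml::read_yaml(path("config.yaml"))
  config <- do.call(synthetic_config, cfg_raw)
  truth <- yaml::read_yaml(path("truth.yaml"))
  truth$footprints <- read_tsv_df(path("footprint_truth.tsv"),
                                  c("true", "artefact"))
  truth$sentinels <- read_tsv_df(path("sentinel_truth.tsv"),
                                 c("in_footprint", "forced",
                                   "disruptive_planted"))
  structure(list(
    workspace = read_bed(path("workspace.bed")),
    dhs = read_bed(path("dhs.bed")),
    footprints = read_bed(path("footprints.bed")),
    blacklist = read_bed(path("blacklist.bed")),
    cut_track = read_track(path("cut_track.tsv"), chrom_lengths),
    conservation_track = read_track(path("conservation_track.tsv"), chrom_lengths),
    panel = read_panel(path("panel.vcf")),
    sentinels = read_tsv_df(path("sentinels.tsv")),
    motif_occurrences = motifs,
    pwms = read_meme(path("pwms.meme")),
    hits = read_tsv_df(path("hits.tsv")),
    expression = expression,
    chrom_lengths = chrom_lengths,
    config = config,
    truth = truth
  ), class = "synthetic_dataset")
}
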