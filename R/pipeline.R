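# ---- end-to-end orchestration ----------------------------------------------

#' Run the full scan / density / profile analysis from one config
#'
#' The config is a named list (or the path of a YAML file holding one)
#' with fields:
#' \describe{
#'   \item{fasta}{genome FASTA path (required).}
#'   \item{out_dir}{output directory (required).}
#'   \item{params}{optional list of [scan_params()] arguments.}
#'   \item{tracks}{optional named list of BED paths; each gets a density /
#'     fold-enrichment row.}
#'   \item{gff}{optional GFF3 path; adds TSS and TES profiles.}
#'   \item{peaks}{optional list(path=, q_col=, q_max=); adds a
#'     peak-centered profile.}
#'   \item{n_bins}{chromosome bins for the ideogram profile (default 2000).}
#'   \item{half_window}{profile half-window in bp (default 3000).}
#'   \item{bootstrap}{bootstrap replicates for profile bands (default 0).}
#'   \item{seed}{seed; required when bootstrap > 0.}
#' }
#'
#' Outputs written under `out_dir`: `hdna_motifs.bed`, `hdna_regions.bed`,
#' per-chromosome `bins_<chrom>.tsv`, `density.tsv` (one row per track),
#' profile TSVs, and `summary.tsv` with the headline numbers (mirror and
#' H-DNA motif counts, merged-region count, per-Mb densities). The run is
#' deterministic given config plus seed.
#'
#' @param config named list or YAML file path.
#' @return (invisibly) a list with summary, densities, motifs, regions and
#'   profiles.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$fasta)) stop("config error: 'fasta' is required")
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  for (p in c(config$fasta, config$gff, config$peaks$path,
              unlist(config$tracks)))
    if (!file.exists(p)) stop("config error: missing input file ", p)
  bootstrap <- config$bootstrap %||% 0
  if (bootstrap > 0 && is.null(config$seed))
    stop("config error: bootstrap requested without a seed")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(scan_params, as.list(config$params))
  n_bins <- config$n_bins %||% 2000
  half_window <- config$half_window %||% 3000

  genome <- read_fasta(config$fasta)
  chrom_sizes <- nchar(genome)
  genome_bp <- sum(as.numeric(chrom_sizes))

  mirror <- do.call(rbind, c(lapply(names(genome), function(id)
    scan_mirror_repeats(genome[[id]], chrom = id, params = params)),
    list(make.row.names = FALSE)))
  mirror <- classify_hdna(mirror, params)
  hdna <- mirror[mirror$is_hdna, , drop = FALSE]
  regions <- merge_intervals(as_track(hdna))
  write_bed(hdna, file.path(config$out_dir, "hdna_motifs.bed"))
  write_bed(regions, file.path(config$out_dir, "hdna_regions.bed"))

  summary <- data.frame(
    metric = c("genome_bp", "mirror_repeat_count", "hdna_motif_count",
               "hdna_region_count", "hdna_regions_per_mb",
               "hdna_bp_per_mb"),
    value = c(genome_bp, nrow(mirror), nrow(hdna), nrow(regions),
              1e6 * nrow(regions) / genome_bp,
              1e6 * track_bp(regions) / genome_bp))

  for (id in names(genome)) {
    bp <- assign_bins(hdna[hdna$chrom == id, , drop = FALSE],
                      chrom_sizes[[id]], n_bins = n_bins)
    utils::write.table(
      data.frame(chrom = id, bin = seq_len(bp$n_bins), count = bp$counts,
                 enrichment = bp$enrichment),
      file.path(config$out_dir, paste0("bins_", id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  densities <- NULL
  if (!is.null(config$tracks)) {
    densities <- do.call(rbind, lapply(names(config$tracks), function(nm) {
      tr <- read_bed(config$tracks[[nm]], name = nm)
      d <- region_density(hdna, tr, genome_bp = genome_bp)
      data.frame(track = nm, region_bp = d$region_bp, motif_bp = d$motif_bp,
                 motif_count = d$motif_count, bp_density = d$bp_density,
                 fold_vs_genome = d$fold_vs_genome,
                 fold_vs_background = d$fold_vs_background)
    }))
    utils::write.table(densities, file.path(config$out_dir, "density.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  profiles <- list()
  if (!is.null(config$gff)) {
    anchors <- read_gff_genes(config$gff)
    if (nrow(anchors) > 0) {
      for (site in c("tss", "tes")) {
        prof <- site_profile(
          data.frame(chrom = anchors$chrom, pos = anchors[[site]],
                     strand = anchors$strand),
          hdna, half_window = half_window, chrom_sizes = chrom_sizes,
          bootstrap = bootstrap, seed = config$seed)
        utils::write.table(prof, file.path(config$out_dir,
                                           paste0("profile_", site, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        profiles[[site]] <- prof
      }
    }
  }
  if (!is.null(config$peaks)) {
    pk <- read_bed(config$peaks$path, name = "peaks")
    q_col <- config$peaks$q_col %||% "q_value"
    kept <- if (!is.null(pk[[q_col]]))
      filter_and_merge_peaks(pk, q_max = config$peaks$q_max %||% 0.005,
                             q_col = q_col)
    else merge_intervals(pk)
    centers <- (kept$start + kept$end) %/% 2L
    prof <- site_profile(
      data.frame(chrom = kept$chrom, pos = centers, strand = "+"),
      hdna, half_window = half_window, chrom_sizes = chrom_sizes,
      bootstrap = bootstrap, seed = config$seed)
    utils::write.table(prof, file.path(config$out_dir, "profile_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    profiles$peaks <- prof
  }

  utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(summary = summary, densities = densities, motifs = hdna,
                 regions = regions, profiles = profiles))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
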