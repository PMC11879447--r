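# ---- genomic binning and density / enrichment statistics -------------------

#' Assign motifs to equal-width chromosome bins
#'
#' Bin index of a coordinate x is `1 + floor(n_bins * x / chrom_size)`,
#' clamped to `[1, n_bins]` (the clamp makes `x = chrom_size`, legal for a
#' half-open end coordinate, land in the last bin). A motif whose start and
#' end fall in different bins is counted in every intermediate bin.
#'
#' @param motifs data.frame with start/end columns, single chromosome.
#' @param chrom_size chromosome length in bp.
#' @param n_bins number of bins (default 2000).
#' @return object of class `bin_profile`: list with n_bins, counts,
#'   bp_counts (bp of merged motif coverage per bin) and enrichment
#'   (counts over their mean).
#' @export
assign_bins <- function(motifs, chrom_size, n_bins = 2000) {
  stopifnot(chrom_size > 0, n_bins >= 1)
  if (nrow(motifs) > 0) {
    bad <- motifs$start < 0 | motifs$end > chrom_size
    if (any(bad))
      stop("motif outside chromosome: row ", which(bad)[1], " (",
           motifs$start[which(bad)[1]], "-", motifs$end[which(bad)[1]], ")")
  }
  bin_of <- function(x) pmin(pmax(1 + floor(n_bins * x / chrom_size), 1), n_bins)
  counts <- integer(n_bins)
  if (nrow(motifs) > 0) {
    b1 <- bin_of(motifs$start); b2 <- bin_of(motifs$end)
    idx <- sequence(b2 - b1 + 1, from = b1)
    counts <- tabulate(idx, nbins = n_bins)
  }
  # bp of merged motif coverage per bin (bin i spans
  # [floor((i-1)*size/n), floor(i*size/n)) )
  bp_counts <- numeric(n_bins)
  if (nrow(motifs) > 0) {
    merged <- merge_intervals(data.frame(chrom = "x", start = motifs$start,
                                         end = motifs$end))
    bb <- floor((0:n_bins) * chrom_size / n_bins)
    bins_ir <- IRanges::IRanges(bb[-length(bb)] + 1L, bb[-1])
    mot_ir <- IRanges::IRanges(merged$start + 1L, merged$end)
    ov <- IRanges::findOverlaps(bins_ir, mot_ir)
    if (length(ov) > 0) {
      w <- IRanges::width(IRanges::pintersect(
        bins_ir[S4Vectors::queryHits(ov)], mot_ir[S4Vectors::subjectHits(ov)]))
      bp_counts <- as.numeric(tapply(w, factor(S4Vectors::queryHits(ov),
                                               levels = seq_len(n_bins)), sum))
      bp_counts[is.na(bp_counts)] <- 0
    }
  }
  enr <- if (mean(counts) > 0) counts / mean(counts) else rep(NA_real_, n_bins)
  structure(list(n_bins = n_bins, counts = counts, bp_counts = bp_counts,
                 enrichment = enr),
            class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("bin_profile: %d bins, %d motif assignments, max enrichment %.2f\n",
              x$n_bins, sum(x$counts),
              if (all(is.na(x$enrichment))) NA else max(x$enrichment, na.rm = TRUE)))
  invisible(x)
}

#' Motif density of a genomic region set
#'
#' Density is measured in merged-motif base pairs per region base pair
#' (reported per kB) and in merged motif regions per Mb. When `genome_bp`
#' is supplied two fold enrichments are added: `fold_vs_genome`, the
#' region's bp density over the genome-wide bp density (the region's share
#' of motifs over its share of the genome), and `fold_vs_background`, the
#' region's density over the density of the rest of the genome.
#'
#' @param motifs motif data.frame or track (chrom/start/end).
#' @param track region track (consolidated internally if needed).
#' @param genome_bp optional total genome size in bp.
#' @return list of class `density_result`.
#' @export
region_density <- function(motifs, track, genome_bp = NULL) {
  region <- merge_intervals(as_track(track))
  region_bp <- track_bp(region)
  name <- attr(track, "track_name")
  if (is.null(name)) name <- "region"
  if (region_bp == 0) {
    warning("region covers 0 bp; density undefined")
    return(structure(list(region_name = name, region_bp = 0,
                          motif_bp = 0, motif_count = 0,
                          bp_density = NA_real_, count_density = NA_real_,
                          fold_vs_genome = NA_real_,
                          fold_vs_background = NA_real_),
                     class = "density_result"))
  }
  merged <- merge_intervals(as_track(motifs))
  motif_bp <- intersect_bp(merged, region)$bp
  hits <- GenomicRanges::findOverlaps(track_to_gr(merged), track_to_gr(region))
  motif_count <- length(unique(S4Vectors::queryHits(hits)))
  res <- list(region_name = name, region_bp = region_bp,
              motif_bp = motif_bp, motif_count = motif_count,
              bp_density = 1000 * motif_bp / region_bp,
              count_density = 1e6 * motif_count / region_bp,
              fold_vs_genome = NA_real_, fold_vs_background = NA_real_)
  if (!is.null(genome_bp)) {
    total_bp <- track_bp(merged)
    dens_region <- motif_bp / region_bp
    dens_genome <- total_bp / genome_bp
    if (dens_genome > 0) res$fold_vs_genome <- dens_region / dens_genome
    out_bp <- genome_bp - region_bp
    dens_bg <- (total_bp - motif_bp) / out_bp
    if (out_bp > 0 && dens_bg > 0)
      res$fold_vs_background <- dens_region / dens_bg
  }
  structure(res, class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "density_result '%s': %s bp region, %d motif regions, %.2f bp/kB%s\n",
    x$region_name, format(x$region_bp, big.mark = ","), x$motif_count,
    x$bp_density,
    if (!is.na(x$fold_vs_genome))
      sprintf(", %.2f-fold vs genome", x$fold_vs_genome) else ""))
  invisible(x)
}

#' Fold enrichment of a motif share over a genome share
#'
#' E.g. a region holding 12.69% of all motifs while spanning 0.31% of the
#' genome is 40.94-fold enriched. Inputs may be fractions or percentages,
#' as long as both use the same scale.
#' @param fraction_in_region share of motifs in the region.
#' @param fraction_of_genome share of the genome the region occupies.
#' @export
fold_enrichment <- function(fraction_in_region, fraction_of_genome) {
  if (any(fraction_of_genome == 0)) {
    warning("fold enrichment undefined for a zero genome fraction")
    return(ifelse(fraction_of_genome == 0, NA_real_,
                  fraction_in_region / fraction_of_genome))
  }
  fraction_in_region / fraction_of_genome
}

#' Fisher's exact test on a 2x2 overlap table
#'
#' Standard construction: rows are site categories (e.g. sites inside vs
#' outside an annotation), columns are overlap outcomes (>= 1 motif overlap
#' vs none). The odds ratio reported is the sample cross-product ratio,
#' with 0/Inf returned as flagged extremes; the p-value is the exact
#' two-sided hypergeometric probability.
#'
#' @param n11,n12,n21,n22 the four cell counts.
#' @return list with odds_ratio, p_value, table.
#' @export
fisher_overlap_test <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  tab <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) {
    warning("all-zero table; test undefined")
    return(list(odds_ratio = NA_real_, p_value = NA_real_, table = tab))
  }
  or <- if (n12 == 0 || n21 == 0) {
    if (n11 == 0 || n22 == 0) NaN else Inf
  } else (n11 * n22) / (n12 * n21)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Bootstrap quantile bands for a positional statistic
#'
#' Resamples the sampling units (rows of a matrix, or elements of a
#' list/vector) with replacement `N` times, recomputes the statistic, and
#' returns the empirical per-position quantiles. The seed is mandatory so
#' that bands are reproducible; the caller's RNG state is restored on exit.
#'
#' @param units numeric matrix (rows = units, e.g. per-anchor offset
#'   counts), or a vector/list of units.
#' @param statistic function mapping a resampled `units` object to a
#'   numeric vector (one value per position). Default: column means for a
#'   matrix, plain mean otherwise.
#' @param N number of bootstrap replicates (default 1000).
#' @param q_lo,q_hi quantiles of the band (default 0.025 / 0.975).
#' @param seed integer RNG seed (required).
#' @return list with `lo` and `hi` numeric vectors.
#' @export
bootstrap_quantiles <- function(units, statistic = NULL, N = 1000,
                                q_lo = 0.025, q_hi = 0.975, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible bootstrap bands")
  n <- if (is.matrix(units)) nrow(units) else length(units)
  if (n < 1) stop("need at least one unit to resample")
  if (is.null(statistic))
    statistic <- if (is.matrix(units)) colMeans else mean
  take <- if (is.matrix(units)) {
    function(i) units[i, , drop = FALSE]
  } else {
    function(i) units[i]
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats_mat <- vapply(seq_len(N), function(r) {
    as.numeric(statistic(take(sample.int(n, n, replace = TRUE))))
  }, numeric(length(as.numeric(statistic(take(seq_len(n)))))))
  stats_mat <- matrix(stats_mat, ncol = N)   # positions x replicates
  list(lo = apply(stats_mat, 1, stats::quantile, probs = q_lo, na.rm = TRUE,
                  names = FALSE),
       hi = apply(stats_mat, 1, stats::quantile, probs = q_hi, na.rm = TRUE,
                  names = FALSE))
}
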