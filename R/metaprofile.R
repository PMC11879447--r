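# ---- position-anchored motif density profiles ------------------------------

#' Motif density profile around anchored sites
#'
#' Counts motif base pairs at each signed offset in `-half_window ..
#' +half_window` around a set of anchors (TSS, TES, peak centers, ...),
#' sums over anchors, and normalizes by the window mean to give a local
#' enrichment. Minus-strand anchors contribute with the offset sign
#' flipped, so "downstream" is always positive. Motifs are consolidated
#' first, so each genomic base counts once per anchor. Anchors closer than
#' `half_window` to a chromosome edge contribute only their in-bounds
#' offsets.
#'
#' @param anchors data.frame with columns chrom, pos (0-based bp) and
#'   optionally strand ("+"/"-"; missing strand treated as "+").
#' @param motifs motif data.frame or track.
#' @param half_window window half-width in bp (default 3000).
#' @param chrom_sizes optional named vector of chromosome lengths used for
#'   edge truncation on the right; the left edge (position 0) is always
#'   respected.
#' @param bootstrap number of bootstrap replicates for a 95% band over
#'   anchors (0 = none).
#' @param seed RNG seed, required when `bootstrap > 0`.
#' @return data.frame of class `positional_profile` with columns offset,
#'   count, enrichment and (with bootstrap) ci_lo, ci_hi; attributes
#'   n_anchors and half_window.
#' @export
site_profile <- function(anchors, motifs, half_window = 3000,
                         chrom_sizes = NULL, bootstrap = 0, seed = NULL) {
  stopifnot(nrow(anchors) >= 1, half_window >= 1)
  if (bootstrap > 0 && is.null(seed))
    stop("bootstrap bands require a seed")
  if (is.null(anchors$strand)) anchors$strand <- "+"
  W <- as.integer(half_window)
  L <- 2L * W + 1L
  merged <- merge_intervals(as_track(motifs))
  n_anc <- nrow(anchors)

  # per-anchor counts only materialized when bootstrapping
  acc <- if (bootstrap > 0) matrix(0, n_anc, L) else numeric(L)

  win <- annotation_track(anchors$chrom,
                          pmax(anchors$pos - W, 0L),
                          anchors$pos + W + 1L)
  hits <- GenomicRanges::findOverlaps(track_to_gr(win), track_to_gr(merged))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qh)) {
    ai <- qh[h]
    mi <- sh[h]
    pos <- anchors$pos[ai]
    lo_g <- max(merged$start[mi], pos - W, 0)
    hi_g <- min(merged$end[mi] - 1, pos + W)
    if (!is.null(chrom_sizes)) {
      cs <- chrom_sizes[[anchors$chrom[ai]]]
      if (!is.null(cs)) hi_g <- min(hi_g, cs - 1)
    }
    if (hi_g < lo_g) next
    o1 <- lo_g - pos; o2 <- hi_g - pos
    if (anchors$strand[ai] == "-") { tmp <- o1; o1 <- -o2; o2 <- -tmp }
    idx <- (o1 + W + 1L):(o2 + W + 1L)
    if (bootstrap > 0) acc[ai, idx] <- acc[ai, idx] + 1
    else acc[idx] <- acc[idx] + 1
  }
  counts <- if (bootstrap > 0) colSums(acc) else acc
  wmean <- mean(counts)
  enr <- if (wmean > 0) counts / wmean else rep(NA_real_, L)
  df <- data.frame(offset = -W:W, count = counts, enrichment = enr)
  if (bootstrap > 0) {
    band <- bootstrap_quantiles(
      acc,
      statistic = function(m) {
        cs <- colSums(m); mu <- mean(cs)
        if (mu > 0) cs / mu else rep(NA_real_, ncol(m))
      },
      N = bootstrap, seed = seed)
    df$ci_lo <- band$lo; df$ci_hi <- band$hi
  }
  structure(df, class = c("positional_profile", "data.frame"),
            n_anchors = n_anc, half_window = W)
}

#' Binned motif profile along tandem array spans
#'
#' Each array interval is partitioned into `n_bins` equal bins; motifs
#' overlapping the array are clipped to it, mapped to array-relative
#' coordinates and counted with the intermediate-bin rule of
#' [assign_bins()]. `fraction` gives each bin's share of the total motif
#' occurrences across the array (the per-array normalization used for
#' array-positional plots); `enrichment` the count over the bin mean.
#' Genic overlay intervals (e.g. 18S/5.8S/28S placeholders) are reported
#' as bin ranges.
#'
#' @param arrays array track (one profile per interval).
#' @param motifs motif data.frame or track.
#' @param n_bins bins per array (default 3500).
#' @param genic optional track with a `name` column giving genic intervals
#'   to overlay.
#' @return list of per-array results, each holding `profile` (a
#'   `bin_profile` plus `fraction`), `overlays`, and the array interval;
#'   plus a `combined` element with summed counts when all arrays share
#'   `n_bins`.
#' @export
rdna_bin_profile <- function(arrays, motifs, n_bins = 3500, genic = NULL) {
  arrays <- as_track(arrays)
  if (nrow(arrays) == 0) stop("empty array track")
  motifs <- as_track(motifs)
  out <- vector("list", nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    a_chr <- arrays$chrom[i]; a_s <- arrays$start[i]; a_e <- arrays$end[i]
    len <- a_e - a_s
    sel <- motifs$chrom == a_chr & motifs$end > a_s & motifs$start < a_e
    m <- motifs[sel, , drop = FALSE]
    rel <- data.frame(start = pmax(m$start, a_s) - a_s,
                      end = pmin(m$end, a_e) - a_s)
    prof <- assign_bins(rel, chrom_size = len, n_bins = n_bins)
    total <- sum(prof$counts)
    prof$fraction <- if (total > 0) prof$counts / total else rep(NA_real_, n_bins)
    overlays <- NULL
    if (!is.null(genic)) {
      gsel <- genic$chrom == a_chr & genic$end > a_s & genic$start < a_e
      g <- genic[gsel, , drop = FALSE]
      if (nrow(g) > 0) {
        bin_of <- function(x) pmin(pmax(1 + floor(n_bins * x / len), 1), n_bins)
        overlays <- data.frame(
          name = if (!is.null(g$name)) g$name else "genic",
          bin_start = bin_of(pmax(g$start, a_s) - a_s),
          bin_end = bin_of(pmin(g$end, a_e) - a_s),
          stringsAsFactors = FALSE)
      }
    }
    out[[i]] <- list(chrom = a_chr, start = a_s, end = a_e,
                     profile = prof, overlays = overlays)
  }
  combined <- Reduce(`+`, lapply(out, function(x) x$profile$counts))
  list(arrays = out, combined_counts = combined)
}

#' Filter a peak set by q-value and merge
#'
#' Keeps peaks with q-value strictly below `q_max` (a peak at exactly
#' `q_max` is dropped), then consolidates overlapping and bookended
#' survivors into superset intervals.
#'
#' @param peaks track with a q-value column.
#' @param q_max strict upper bound on the q-value (default 0.005).
#' @param q_col name of the q-value column (default "q_value").
#' @return consolidated `annotation_track`.
#' @export
filter_and_merge_peaks <- function(peaks, q_max = 0.005, q_col = "q_value") {
  if (is.null(peaks[[q_col]]))
    stop("no '", q_col, "' column in the peak set; to skip FDR filtering, ",
         "call merge_intervals() directly")
  keep <- peaks[[q_col]] < q_max
  merge_intervals(peaks[keep, , drop = FALSE])
}

#' Position frequency matrix of motif arms near anchors
#'
#' Collects the first-arm sequences of motifs whose span intersects any
#' anchor window (`pos +/- half_window`), keeps arms of the modal arm
#' length, aligns them at the arm start and reports per-position base
#' frequencies.
#'
#' @param motifs motif data.frame with seq and arm_len columns.
#' @param anchors data.frame with chrom and pos columns.
#' @param half_window window half-width in bp (default 3000).
#' @return 4 x L numeric matrix (rows A, C, G, T) with attribute `n_arms`;
#'   a 4 x 0 matrix (with a warning) when no motif lies in any window.
#' @export
arm_pwm <- function(motifs, anchors, half_window = 3000) {
  base_rows <- c("A", "C", "G", "T")
  empty <- matrix(numeric(0), nrow = 4, ncol = 0, dimnames = list(base_rows))
  if (nrow(motifs) == 0 || nrow(anchors) == 0) {
    warning("no motifs in the anchor vicinity; empty PWM")
    return(structure(empty, n_arms = 0L))
  }
  win <- annotation_track(anchors$chrom,
                          pmax(anchors$pos - half_window, 0L),
                          anchors$pos + half_window + 1L)
  hits <- GenomicRanges::findOverlaps(track_to_gr(as_track(motifs)),
                                      track_to_gr(win))
  sel <- unique(S4Vectors::queryHits(hits))
  if (length(sel) == 0) {
    warning("no motifs in the anchor vicinity; empty PWM")
    return(structure(empty, n_arms = 0L))
  }
  arms <- toupper(substr(motifs$seq[sel], 1, motifs$arm_len[sel]))
  lens <- nchar(arms)
  tab <- table(lens)
  modal <- as.integer(names(tab)[which.max(tab)])   # ties: smallest length
  arms <- arms[lens == modal]
  mat <- do.call(rbind, strsplit(arms, "", fixed = TRUE))
  pwm <- vapply(seq_len(modal), function(j) {
    col <- factor(mat[, j], levels = base_rows)
    as.numeric(table(col)) / length(arms)
  }, numeric(4))
  dimnames(pwm) <- list(base_rows, NULL)
  structure(pwm, n_arms = length(arms))
}

#' Classify a profile by where its maximum enrichment falls
#'
#' @param profile a `positional_profile` from [site_profile()].
#' @param radius classification radius around the anchor in bp
#'   (default 250).
#' @return list with max_enrichment, offset (argmax, ties resolved toward
#'   the smallest |offset|) and within_radius.
#' @export
max_enrichment_class <- function(profile, radius = 250) {
  enr <- profile$enrichment
  if (all(is.na(enr))) stop("profile enrichment is undefined")
  best <- max(enr, na.rm = TRUE)
  cand <- which(enr == best)
  off <- profile$offset[cand]
  off <- off[order(abs(off), off)][1]
  list(max_enrichment = best, offset = off,
       within_radius = abs(off) <= radius)
}
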