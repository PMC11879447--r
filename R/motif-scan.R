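# ---- mirror repeat / H-DNA scanning ---------------------------------------
#
# A mirror repeat is a sequence repeated with a center of symmetry on the
# same strand: the second arm is the character reversal (not the complement)
# of the first, separated by a short unconstrained spacer. The H-DNA subset
# — mirror repeats able to fold into an intramolecular triplex via Hoogsteen
# pairing — is the AG- or CT-rich fraction: purity max(frac_AG, frac_CT)
# at or above `min_purity`, with motifs of `max_at` or more total AT
# content excluded (poly-A/T tracts mirror trivially but do not form
# stable triplexes).

#' Scan parameters for mirror-repeat / H-DNA detection
#'
#' @param min_arm minimum arm length in bp (default 10).
#' @param max_spacer maximum spacer length in bp (default 7, i.e. spacers
#'   shorter than 8 bp).
#' @param min_purity minimum AG-or-CT fraction over the whole motif for the
#'   H-DNA call (default 0.90, inclusive).
#' @param max_at AT-content exclusion threshold (default 0.80; motifs with
#'   frac_at >= max_at are rejected).
#' @param max_arm optional cap on arm extension (default `Inf`).
#' @return a validated list of class `scan_params`.
#' @export
scan_params <- function(min_arm = 10, max_spacer = 7, min_purity = 0.90,
                        max_at = 0.80, max_arm = Inf) {
  stopifnot(min_arm >= 1, max_spacer >= 0,
            min_purity > 0, min_purity <= 1,
            max_at > 0, max_at <= 1, max_arm >= min_arm)
  structure(list(min_arm = as.integer(min_arm),
                 max_spacer = as.integer(max_spacer),
                 min_purity = min_purity, max_at = max_at,
                 max_arm = max_arm),
            class = "scan_params")
}

empty_repeats <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             arm_len = integer(0), spacer_len = integer(0),
             seq = character(0), stringsAsFactors = FALSE)
}

#' Detect maximal mirror repeats in a sequence
#'
#' For every center boundary p and every spacer length s in
#' `0..max_spacer`, arms are extended maximally (case-insensitive exact
#' match; extension stops at non-ACGT characters and sequence edges). One
#' repeat is reported per (p, s) with arm length >= `min_arm`; spans
#' containing any non-ACGT character are discarded. Overlapping repeats
#' from distinct centers/spacers are all reported, so the motif count
#' exceeds the merged-region count in repetitive sequence.
#'
#' @param seq a single sequence string.
#' @param chrom chromosome name attached to the output (default the name
#'   of `seq`, else "seq").
#' @param params a [scan_params()] object.
#' @return data.frame with chrom, start, end (0-based half-open), arm_len,
#'   spacer_len, seq (verbatim motif sequence), sorted by (start, end).
#' @export
scan_mirror_repeats <- function(seq, chrom = NULL, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"), length(seq) == 1)
  if (is.null(chrom)) chrom <- if (!is.null(names(seq))) names(seq) else "seq"
  seq <- unname(seq)
  if (nchar(seq) == 0) return(empty_repeats())
  max_arm <- if (is.finite(params$max_arm)) as.integer(params$max_arm)
             else .Machine$integer.max
  hits <- .scan_mirror_cpp(seq, params$min_arm, params$max_spacer, max_arm)
  if (length(hits$start) == 0) return(empty_repeats())
  df <- data.frame(chrom = chrom, start = hits$start,
                   end = hits$start + 2L * hits$arm_len + hits$spacer_len,
                   arm_len = hits$arm_len, spacer_len = hits$spacer_len,
                   stringsAsFactors = FALSE)
  df$seq <- substring(seq, df$start + 1L, df$end)
  df <- df[order(df$start, df$end, df$spacer_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compositional classification of mirror repeats as H-DNA
#'
#' Adds AG/CT/AT fractions (computed case-insensitively over the whole
#' motif, arms plus spacer) and the H-DNA flag: purity = max(frac_ag,
#' frac_ct) >= `min_purity` and frac_at < `max_at`.
#'
#' @param reps data.frame from [scan_mirror_repeats()] (needs a `seq`
#'   column).
#' @param params a [scan_params()] object.
#' @return `reps` with columns frac_ag, frac_ct, frac_at, is_hdna added.
#' @export
classify_hdna <- function(reps, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"))
  if (nrow(reps) == 0) {
    reps$frac_ag <- numeric(0); reps$frac_ct <- numeric(0)
    reps$frac_at <- numeric(0); reps$is_hdna <- logical(0)
    return(reps)
  }
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(reps$seq)), c("A", "C", "G", "T"))
  len <- rowSums(counts)
  reps$frac_ag <- (counts[, "A"] + counts[, "G"]) / len
  reps$frac_ct <- (counts[, "C"] + counts[, "T"]) / len
  reps$frac_at <- (counts[, "A"] + counts[, "T"]) / len
  purity <- pmax(reps$frac_ag, reps$frac_ct)
  reps$is_hdna <- purity >= params$min_purity & reps$frac_at < params$max_at
  reps
}

#' Scan a sequence for H-DNA motifs
#'
#' Composition of [scan_mirror_repeats()] and [classify_hdna()], keeping
#' only motifs with `is_hdna == TRUE`.
#' @inheritParams scan_mirror_repeats
#' @export
scan_hdna <- function(seq, chrom = NULL, params = scan_params()) {
  reps <- classify_hdna(scan_mirror_repeats(seq, chrom, params), params)
  reps <- reps[reps$is_hdna, , drop = FALSE]
  rownames(reps) <- NULL
  reps
}

#' Scan every record of a genome for H-DNA motifs
#' @param genome named character vector of sequences (see [read_fasta()]).
#' @param params a [scan_params()] object.
#' @export
scan_genome_hdna <- function(genome, params = scan_params()) {
  out <- lapply(names(genome), function(id)
    scan_hdna(genome[[id]], chrom = id, params = params))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Brute-force mirror-repeat oracle
#'
#' Independent reference implementation for testing: for every (center,
#' spacer) pair each candidate arm length is re-tested from scratch by
#' direct character comparison, and the maximal passing arm is kept. Must
#' agree exactly with [scan_mirror_repeats()]. Refuses sequences longer
#' than 5 kb (quadratic cost).
#'
#' @inheritParams scan_mirror_repeats
#' @export
oracle_scan <- function(seq, chrom = NULL, params = scan_params()) {
  stopifnot(inherits(params, "scan_params"), length(seq) == 1)
  if (is.null(chrom)) chrom <- if (!is.null(names(seq))) names(seq) else "seq"
  n <- nchar(seq)
  if (n > 5000) stop("oracle_scan is quadratic; refuse sequences > 5 kb")
  if (n == 0) return(empty_repeats())
  x <- strsplit(toupper(unname(seq)), "", fixed = TRUE)[[1]]
  acgt <- x %in% c("A", "C", "G", "T")
  max_arm <- if (is.finite(params$max_arm)) params$max_arm else n
  rows <- list()
  for (p in seq_len(n - 1)) {            # boundary after 1-based position p
    for (s in 0:params$max_spacer) {
      best <- 0L
      for (k in seq_len(max_arm)) {
        li <- p - k + 1L; ri <- p + s + k
        if (li < 1L || ri > n) break
        i1 <- p:li                       # arm1, read outward from center
        i2 <- (p + s + 1L):ri            # arm2, read outward from center
        if (!all(acgt[i1]) || !all(acgt[i2]) || !all(x[i1] == x[i2])) break
        best <- k
      }
      if (best < params$min_arm) next
      span <- (p - best + 1L):(p + s + best)
      if (!all(acgt[span])) next         # spacer may carry non-ACGT
      rows[[length(rows) + 1L]] <-
        c(start = p - best, arm = best, spacer = s)
    }
  }
  if (length(rows) == 0) return(empty_repeats())
  m <- do.call(rbind, rows)
  df <- data.frame(chrom = chrom, start = as.integer(m[, "start"]),
                   end = as.integer(m[, "start"] + 2 * m[, "arm"] + m[, "spacer"]),
                   arm_len = as.integer(m[, "arm"]),
                   spacer_len = as.integer(m[, "spacer"]),
                   stringsAsFactors = FALSE)
  df$seq <- substring(unname(seq), df$start + 1L, df$end)
  df <- df[order(df$start, df$end, df$spacer_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Spacer- and arm-length histograms of a motif set
#'
#' @param motifs data.frame with arm_len and spacer_len columns.
#' @param normalize if TRUE, add a `density` column summing to 1.
#' @return list with data.frames `spacer` and `arm` (value, count).
#' @export
motif_summary <- function(motifs, normalize = FALSE) {
  hist_of <- function(v) {
    if (length(v) == 0)
      return(data.frame(value = integer(0), count = integer(0)))
    tab <- table(v)
    df <- data.frame(value = as.integer(names(tab)),
                     count = as.integer(tab))
    if (normalize) df$density <- df$count / sum(df$count)
    df
  }
  list(spacer = hist_of(motifs$spacer_len), arm = hist_of(motifs$arm_len))
}
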