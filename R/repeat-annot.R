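# ---- short tandem repeats --------------------------------------------------

#' Detect exact short tandem repeats
#'
#' Reports all maximal exact tandem runs with primitive unit length
#' `1..max_unit` and at least `min_copies` full copies (the trailing copy
#' may be partial and is included in the span). Runs are maximal — not
#' extendable by one period on either side — and each run is reported once,
#' under its primitive unit. No mismatches are tolerated; runs containing
#' non-ACGT characters are not reported.
#'
#' @param seq a single sequence string.
#' @param chrom chromosome name for the output.
#' @param max_unit largest unit length considered (default 9 bp).
#' @param min_copies minimum number of full copies (default 2).
#' @return data.frame with chrom, start, end, unit, unit_len, copies.
#' @export
scan_strs <- function(seq, chrom = NULL, max_unit = 9, min_copies = 2) {
  stopifnot(length(seq) == 1, max_unit >= 1, min_copies >= 2)
  if (is.null(chrom)) chrom <- if (!is.null(names(seq))) names(seq) else "seq"
  seq <- unname(seq)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      unit_len = integer(0), copies = numeric(0),
                      stringsAsFactors = FALSE)
  if (nchar(seq) == 0) return(empty)
  hits <- .scan_str_cpp(seq, as.integer(max_unit), as.integer(min_copies))
  if (length(hits$start) == 0) return(empty)
  df <- data.frame(chrom = chrom, start = hits$start, end = hits$end,
                   unit = toupper(substring(seq, hits$start + 1L,
                                            hits$start + hits$unit_len)),
                   unit_len = hits$unit_len, copies = hits$copies,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Brute-force tandem-repeat coverage oracle
#'
#' Per-base coverage bitmap computed by direct periodicity checks, for
#' validating [scan_strs()] on short inputs: a base is covered when it lies
#' in some exact tandem run (unit `1..max_unit`, >= `min_copies` full
#' copies). Primitivity is irrelevant for coverage, since a run with a
#' non-primitive unit is covered by the run of its smaller period.
#'
#' @inheritParams scan_strs
#' @return logical vector of length `nchar(seq)`.
#' @export
oracle_str_coverage <- function(seq, max_unit = 9, min_copies = 2) {
  n <- nchar(seq)
  if (n > 2000) stop("oracle_str_coverage is quadratic; keep inputs <= 2 kb")
  x <- strsplit(toupper(unname(seq)), "", fixed = TRUE)[[1]]
  acgt <- x %in% c("A", "C", "G", "T")
  covered <- logical(n)
  for (u in seq_len(max_unit)) {
    for (i in seq_len(n)) {
      # extend a period-u match rightwards from i by direct comparison
      j <- i
      while (j + u <= n && acgt[j] && acgt[j + u] && x[j] == x[j + u])
        j <- j + 1
      L <- j - i
      if (L >= (min_copies - 1) * u) covered[i:(i + u + L - 1)] <- TRUE
    }
  }
  covered
}

#' Fraction of the base pairs of one track covered by another
#'
#' Both tracks are consolidated before measuring, so the result is
#' invariant under pre-merging. Returns `NA` (with a warning) when `a`
#' covers zero base pairs.
#' @param a,b tracks; the fraction is relative to `a`.
#' @export
bp_overlap_fraction <- function(a, b) {
  ma <- merge_intervals(as_track(a))
  bp_a <- track_bp(ma)
  if (bp_a == 0) {
    warning("bp_overlap_fraction undefined: first track covers 0 bp")
    return(NA_real_)
  }
  intersect_bp(ma, as_track(b))$bp / bp_a
}

# ---- G-quadruplex scoring --------------------------------------------------

#' Per-base G4 propensity scores
#'
#' Run-based scoring: every base inside a G-run of length L scores
#' `+min(L, 4)`, every base inside a C-run `-min(L, 4)`, all other bases 0.
#' The score array of the complementary strand is the negation of the
#' forward array.
#' @param seq a single sequence string.
#' @return numeric vector of per-base signed scores.
#' @export
g4hunter_scores <- function(seq) {
  if (nchar(seq) == 0) return(numeric(0))
  x <- strsplit(toupper(unname(seq)), "", fixed = TRUE)[[1]]
  r <- rle(x)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4),
         ifelse(r$values == "C", -pmin(r$lengths, 4), 0))
  rep(val, r$lengths)
}

# maximal sub-span of `sc` whose mean is >= threshold (leftmost on ties);
# returns c(start, end) 1-based inclusive, or NULL
g4_trim <- function(sc, threshold) {
  m <- length(sc)
  cs <- c(0, cumsum(sc))
  for (L in m:1) {
    means <- (cs[(L + 1):(m + 1)] - cs[1:(m - L + 1)]) / L
    hit <- which(means >= threshold)
    if (length(hit) > 0) return(c(hit[1], hit[1] + L - 1))
  }
  NULL
}

#' Call G-quadruplex-prone regions from windowed G4 scores
#'
#' Slides a window of `window` bp over the per-base score array; windows
#' whose mean absolute score reaches `threshold` are kept (sign gives the
#' G-rich `+` or C-rich `-` strand), overlapping same-sign windows are
#' merged, and each merged region is trimmed to the maximal sub-span whose
#' mean still meets the threshold.
#'
#' @inheritParams scan_strs
#' @param window sliding window width in bp (default 25).
#' @param threshold minimum mean |score| (default 1.5).
#' @return data.frame with chrom, start, end, strand, mean_score.
#' @export
detect_g4 <- function(seq, chrom = NULL, window = 25, threshold = 1.5) {
  stopifnot(window >= 1)
  if (is.null(chrom)) chrom <- if (!is.null(names(seq))) names(seq) else "seq"
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mean_score = numeric(0), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < window) return(empty)
  sc <- g4hunter_scores(seq)
  cs <- c(0, cumsum(sc))
  wmean <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  out <- list()
  for (side in c(1, -1)) {
    qual <- which(side * wmean >= threshold)   # window start indices
    if (length(qual) == 0) next
    # merge overlapping/adjacent qualifying windows into candidate regions
    brk <- c(0, which(diff(qual) > window), length(qual))
    for (g in seq_len(length(brk) - 1)) {
      idx <- qual[(brk[g] + 1):brk[g + 1]]
      lo <- min(idx); hi <- max(idx) + window - 1
      tr <- g4_trim(side * sc[lo:hi], threshold)
      if (is.null(tr)) next
      s1 <- lo + tr[1] - 1; s2 <- lo + tr[2] - 1
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s1 - 1L, end = s2,
        strand = if (side > 0) "+" else "-",
        mean_score = mean(sc[s1:s2]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
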