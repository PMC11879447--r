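#' @useDynLib hdnascan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import IRanges
#' @import GenomicRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
#' @importFrom stats fisher.test runif
#' @importFrom utils read.delim write.table
NULL

# ---- annotation tracks -----------------------------------------------------
#
# All coordinates in this package are 0-based half-open [start, end), the
# BED convention. GFF (1-based inclusive) is converted at the boundary.
# A track is a plain data.frame with columns chrom/start/end (extra columns
# allowed) carrying a name and a consolidated flag as attributes.

#' Construct an annotation track
#'
#' @param chrom character vector of chromosome names (or a data.frame with
#'   columns `chrom`, `start`, `end`, in which case the remaining arguments
#'   are ignored and extra columns are retained).
#' @param start,end integer vectors, 0-based half-open.
#' @param name track label.
#' @param consolidated logical; TRUE only when intervals are known to be
#'   sorted and per-chromosome non-overlapping.
#' @return a data.frame of class `annotation_track`.
#' @export
annotation_track <- function(chrom, start = NULL, end = NULL, name = "track",
                             consolidated = FALSE) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- data.frame(chrom = as.character(chrom),
                     start = as.integer(start), end = as.integer(end),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0) {
    if (any(is.na(df$start) | is.na(df$end)))
      stop("track has NA coordinates")
    if (any(df$start < 0) || any(df$start >= df$end))
      stop("track intervals must satisfy 0 <= start < end")
    if (any(is.na(df$chrom) | df$chrom == ""))
      stop("track chromosome names must be non-empty")
  }
  structure(df, class = c("annotation_track", "data.frame"),
            track_name = name, consolidated = consolidated)
}

#' @export
print.annotation_track <- function(x, ...) {
  nm <- attr(x, "track_name")
  if (is.null(nm)) nm <- "track"
  cat(sprintf("annotation_track '%s': %d intervals, %s bp%s\n",
              nm, nrow(x),
              format(track_bp(x), big.mark = ","),
              if (isTRUE(attr(x, "consolidated"))) " (consolidated)" else ""))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Total base pairs of a track (intervals as given, no merging)
#' @param track an annotation track or chrom/start/end data.frame.
#' @export
track_bp <- function(track) {
  if (nrow(track) == 0) return(0)
  sum(as.numeric(track$end) - as.numeric(track$start))
}

# internal: 0-based half-open data.frame <-> GRanges (1-based closed)
track_to_gr <- function(track) {
  if (nrow(track) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(track$start + 1L, track$end))
}

gr_to_track <- function(gr, name = "track", consolidated = FALSE) {
  annotation_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  ), name = name, consolidated = consolidated)
}

# coerce any chrom/start/end data.frame to a track without copying extras
as_track <- function(x, name = "track") {
  if (inherits(x, "annotation_track")) return(x)
  annotation_track(x[, c("chrom", "start", "end"), drop = FALSE], name = name)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file (plain or gzipped)
#'
#' Sequence letters are preserved verbatim (case included); record ids are
#' the header up to the first whitespace. Order follows the file.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "r")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0) return(stats::setNames(character(0), character(0)))
  if (!startsWith(first, ">"))
    stop("malformed FASTA header at line 1 of ", path,
         ": expected '>' , got '", substr(first, 1, 20), "'")
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path (".gz" suffix triggers compression).
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# ---- BED -------------------------------------------------------------------

#' Read a BED-like file into an annotation track
#'
#' Accepts any tab-separated file with at least chrom/start/end columns
#' (0-based half-open). Columns 4-6 are named name/score/strand when
#' present; further columns are retained verbatim as `extra7`, `extra8`, ...
#' so that e.g. broadPeak q-value columns survive for downstream filters.
#'
#' @param path file path.
#' @param name track label (defaults to the file name).
#' @return an `annotation_track`.
#' @export
read_bed <- function(path, name = NULL) {
  if (is.null(name)) name <- basename(path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  if (!any(keep))
    return(annotation_track(character(0), integer(0), integer(0), name = name))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", lineno[which(nf < 3)[1]], " has fewer than 3 columns")
  ncol_use <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(ncol_use)], character(ncol_use)))
  if (ncol_use == 1) m <- t(m)
  bad <- !grepl("^[0-9]+$", m[, 2]) | !grepl("^[0-9]+$", m[, 3])
  if (any(bad))
    stop("non-integer coordinates on BED line ", lineno[which(bad)[1]])
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- start >= end
  if (any(bad))
    stop("start >= end on BED line ", lineno[which(bad)[1]])
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  std <- c("name", "score", "strand")
  for (j in seq_len(ncol_use)[-(1:3)]) {
    cn <- if (j <= 6) std[j - 3] else paste0("extra", j)
    df[[cn]] <- utils::type.convert(m[, j], as.is = TRUE)
  }
  annotation_track(df, name = name, consolidated = FALSE)
}

#' Write a track as BED
#'
#' Coordinates round-trip exactly through [read_bed()]. Columns beyond
#' chrom/start/end are written in their stored order.
#' @param track an annotation track or compatible data.frame.
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  df <- as.data.frame(track)
  if (nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- GFF3 genes ------------------------------------------------------------

#' Extract gene anchors (TSS/TES) from a GFF3 file
#'
#' GFF3 coordinates (1-based inclusive) are converted to the package's
#' 0-based convention; the TSS is the 5' end by strand, the TES the 3' end.
#'
#' @param path GFF3 file path.
#' @param feature_types GFF `type` values to keep (default `"gene"`;
#'   use e.g. `"rRNA"` for ribosomal gene records).
#' @return data.frame with gene_id, chrom, start, end (0-based half-open),
#'   strand, tss, tes.
#' @export
read_gff_genes <- function(path, feature_types = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  strand <- as.character(GenomicRanges::strand(gr))
  unstranded <- !strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand skipped")
    gr <- gr[!unstranded]
    strand <- strand[!unstranded]
  }
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
        else if ("Name" %in% names(md)) as.character(md$Name)
        else paste0("feature", seq_along(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    tes = ifelse(strand == "+", end0 - 1L, start0),
    stringsAsFactors = FALSE
  )
}

# ---- interval algebra ------------------------------------------------------

#' Consolidate a track: merge overlapping and bookended intervals
#'
#' Touching intervals (`[1,5)`, `[5,9)`) merge into one region, matching the
#' default of the common BED merge utility. Idempotent.
#' @param track an annotation track or compatible data.frame.
#' @return consolidated `annotation_track` (extra columns dropped).
#' @export
merge_intervals <- function(track) {
  track <- as_track(track)
  if (nrow(track) == 0)
    return(annotation_track(character(0), integer(0), integer(0),
                            name = attr(track, "track_name"),
                            consolidated = TRUE))
  gr <- GenomicRanges::reduce(track_to_gr(track))
  gr <- GenomicRanges::sort(gr)
  gr_to_track(gr, name = attr(track, "track_name"), consolidated = TRUE)
}

#' Base-pair intersection of two tracks
#'
#' Both inputs are consolidated first, so multiply-covered bases count once.
#' @param a,b tracks.
#' @return list with `overlaps` (an annotation track of the shared spans)
#'   and `bp` (total shared base pairs).
#' @export
intersect_bp <- function(a, b) {
  ga <- GenomicRanges::reduce(track_to_gr(as_track(a)))
  gb <- GenomicRanges::reduce(track_to_gr(as_track(b)))
  ov <- suppressWarnings(GenomicRanges::intersect(ga, gb))
  list(overlaps = gr_to_track(ov, name = "overlap", consolidated = TRUE),
       bp = sum(as.numeric(GenomicRanges::width(ov))))
}

#' Filter intervals by reciprocal overlap
#'
#' Keeps intervals of `a` for which some interval of `b` shares at least
#' `frac` of the length of *both* intervals.
#' @param a,b tracks (used as given; not merged).
#' @param frac required fraction in (0, 1].
#' @export
reciprocal_overlap_filter <- function(a, b, frac) {
  if (!is.numeric(frac) || length(frac) != 1 || frac <= 0 || frac > 1)
    stop("frac must be a single number in (0, 1]")
  a <- as_track(a); b <- as_track(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(a[integer(0), , drop = FALSE])
  ga <- track_to_gr(a); gb <- track_to_gr(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (length(hits) == 0) return(a[integer(0), , drop = FALSE])
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(ga)[qh], GenomicRanges::ranges(gb)[sh]))
  keep <- ow >= frac * GenomicRanges::width(ga)[qh] &
          ow >= frac * GenomicRanges::width(gb)[sh]
  a[sort(unique(qh[keep])), , drop = FALSE]
}
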