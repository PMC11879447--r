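# ---- synthetic genomes with planted motifs ---------------------------------
#
# The generator emulates the genomic structure the analysis assumes: an
# i.i.d. background of stated GC content carrying sparse planted H-DNA
# motifs, plus tandem rDNA-like arrays (exact copies of a unit holding
# 18S/5.8S/28S placeholders) whose intergenic spacers carry CT-rich mirror
# repeats at fixed unit offsets, gene annotations with strand, and
# (separately) peak sets overlapping a stated fraction of planted motifs.
# Every planted element is listed in a truth ledger so recovery can be
# scored exactly.

reverse_chars <- function(s)
  vapply(strsplit(s, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))

rand_bases <- function(n, gc) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Specification of a synthetic genome
#'
#' Defaults describe the standard study conditions of the package: a 10 Mb
#' genome at human-like GC, five rDNA-like arrays of twenty 5 kb units
#' (0.5% of the genome), four CT-rich H-DNA motifs planted per intergenic
#' spacer at fixed unit offsets, and a uniform background of 20 planted
#' H-DNA motifs per Mb — i.e. an array-to-background H-DNA bp density
#' ratio of 40.
#'
#' @param genome_len genome length in bp.
#' @param gc background GC fraction.
#' @param n_arrays number of tandem arrays.
#' @param unit_len array unit length in bp.
#' @param units_per_array exact tandem copies per array.
#' @param genic_layout data.frame (name/start/end, unit-relative 0-based)
#'   of the rRNA gene placeholders within a unit.
#' @param igs_offsets unit-relative start offsets of planted motifs (all
#'   must lie in the intergenic spacer, after the last genic interval).
#' @param igs_motif list(arm=, spacer=): planted motif template; the motif
#'   is arm + spacer + reverse(arm). Default is the modal CT-rich rDNA
#'   motif family (arm 10, spacer 1).
#' @param background_motif_rate planted H-DNA motifs per Mb of non-array
#'   sequence.
#' @param n_mirror_only,n_decoys background plantings of the two negative
#'   classes: mirror repeats failing the compositional filter, and
#'   sequences failing the mirror definition altogether.
#' @param gene_count number of protein-coding gene annotations.
#' @param gene_len_range min/max gene length in bp.
#' @param tes_motif_offset if > 0, additionally plant one H-DNA motif this
#'   many bp downstream of each gene's TES (strand-aware); 0 disables.
#' @param seed integer seed (mandatory; the generator is deterministic
#'   given the spec).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_len = 10e6, gc = 0.41,
                           n_arrays = 5, unit_len = 5000,
                           units_per_array = 20,
                           genic_layout = data.frame(
                             name = c("18S", "5.8S", "28S"),
                             start = c(200L, 860L, 1010L),
                             end = c(760L, 910L, 2510L)),
                           igs_offsets = c(2600L, 3200L, 3800L, 4400L),
                           igs_motif = list(arm = "ctctctctgt", spacer = "c"),
                           background_motif_rate = 20,
                           n_mirror_only = 30, n_decoys = 30,
                           gene_count = 40, gene_len_range = c(2000, 8000),
                           tes_motif_offset = 0,
                           seed) {
  if (missing(seed)) stop("synthetic_spec requires a seed")
  motif_len <- 2L * nchar(igs_motif$arm) + nchar(igs_motif$spacer)
  stopifnot(genome_len > 0, gc > 0, gc < 1,
            n_arrays >= 1, units_per_array >= 2,
            all(genic_layout$start < genic_layout$end),
            all(genic_layout$end <= unit_len),
            background_motif_rate >= 0, gene_count >= 0)
  genic_max <- max(genic_layout$end)
  if (any(igs_offsets <= genic_max) ||
      any(igs_offsets + motif_len + 1L >= unit_len))
    stop("igs_offsets must place motifs (plus 1 bp breakers) strictly ",
         "inside the intergenic spacer")
  if (n_arrays * units_per_array * unit_len >= genome_len)
    stop("arrays do not fit in the genome")
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 n_arrays = as.integer(n_arrays),
                 unit_len = as.integer(unit_len),
                 units_per_array = as.integer(units_per_array),
                 genic_layout = genic_layout,
                 igs_offsets = as.integer(igs_offsets),
                 igs_motif = igs_motif, motif_len = motif_len,
                 background_motif_rate = background_motif_rate,
                 n_mirror_only = as.integer(n_mirror_only),
                 n_decoys = as.integer(n_decoys),
                 gene_count = as.integer(gene_count),
                 gene_len_range = as.integer(gene_len_range),
                 tes_motif_offset = as.integer(tes_motif_offset),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# fixed negative-class templates; both verified at generation time
mirror_only_template <- function() {
  arm <- "agctagctag"                     # 50/50 AG vs CT: fails purity
  paste0(arm, "t", reverse_chars(arm))
}
decoy_template <- function() "gactacgtgcacgatcagtca"  # no mirror arm >= 10

plant_seq <- function(template) strsplit(template, "", fixed = TRUE)[[1]]

#' Generate a synthetic genome with a planted-motif truth ledger
#'
#' Deterministic given the spec (the caller's RNG state is restored).
#' Background is i.i.d. at the stated GC; each planted motif is flanked by
#' fixed breaker bases so its arms cannot extend into the background, and
#' the genome is rescanned after assembly with any accidental background
#' H-DNA redrawn locally, so the truth ledger is exhaustive for the H-DNA
#' class. Arrays are exact tandem copies of a single unit.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, writes genome.fa,
#'   truth.tsv, arrays.bed, genic.bed and genes.gff3.
#' @return list with genome (named character vector, one chromosome
#'   "chr1"), truth (data.frame: class, chrom, start, end, arm_len,
#'   spacer_len, seq, origin), arrays/genic tracks, genes (anchor
#'   data.frame) and the spec.
#' @export
generate_genome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  params <- scan_params()
  tmpl <- paste0(spec$igs_motif$arm, spec$igs_motif$spacer,
                 reverse_chars(spec$igs_motif$arm))
  mlen <- spec$motif_len

  # the templates must themselves scan as claimed
  tchk <- classify_hdna(oracle_scan(tmpl, params = params), params)
  stopifnot(nrow(tchk) == 1, tchk$is_hdna,
            tchk$start == 0, tchk$end == nchar(tmpl))
  mo_tmpl <- mirror_only_template()
  mchk <- classify_hdna(oracle_scan(mo_tmpl, params = params), params)
  stopifnot(nrow(mchk) == 1, !mchk$is_hdna)
  stopifnot(nrow(oracle_scan(decoy_template(), params = params)) == 0)

  # ---- unit template with IGS plantings, verified in tandem context ----
  unit <- NULL
  for (try in 1:100) {
    u <- rand_bases(spec$unit_len, spec$gc)
    for (o in spec$igs_offsets) {
      u[(o + 1):(o + mlen)] <- plant_seq(tmpl)
      u[o] <- "A"; u[o + mlen + 1] <- "G"     # arm-extension breakers
    }
    doubled <- paste(rep(paste(u, collapse = ""), 2), collapse = "")
    found <- scan_hdna(doubled, params = params)
    expect_starts <- sort(c(spec$igs_offsets,
                            spec$unit_len + spec$igs_offsets))
    ok <- nrow(found) == length(expect_starts) &&
      all(sort(found$start) == expect_starts) &&
      all(found$arm_len == nchar(spec$igs_motif$arm)) &&
      all(found$spacer_len == nchar(spec$igs_motif$spacer))
    if (ok) { unit <- u; break }
  }
  if (is.null(unit))
    stop("could not draw a clean array unit after 100 attempts")

  # ---- layout: arrays in evenly spaced blocks -------------------------
  array_len <- spec$unit_len * spec$units_per_array
  block <- spec$genome_len %/% spec$n_arrays
  margin <- min(50000L, max(1000L, (block - array_len) %/% 4))
  array_starts <- vapply(seq_len(spec$n_arrays), function(i) {
    lo <- (i - 1L) * block + margin
    hi <- i * block - array_len - margin
    as.integer(lo + sample.int(max(hi - lo, 1L), 1L) - 1L)
  }, integer(1))
  arrays <- annotation_track(rep("chr1", spec$n_arrays), array_starts,
                             array_starts + array_len, name = "rDNA_array",
                             consolidated = TRUE)

  g <- rand_bases(spec$genome_len, spec$gc)
  for (s in array_starts)
    g[(s + 1):(s + array_len)] <- rep(unit, spec$units_per_array)

  # genic placeholder annotations, one triplet per unit copy
  genic <- do.call(rbind, lapply(seq_len(spec$n_arrays), function(i) {
    do.call(rbind, lapply(seq_len(spec$units_per_array), function(k) {
      off <- array_starts[i] + (k - 1L) * spec$unit_len
      data.frame(chrom = "chr1",
                 start = off + spec$genic_layout$start,
                 end = off + spec$genic_layout$end,
                 name = spec$genic_layout$name,
                 array_id = i, unit_index = k,
                 stringsAsFactors = FALSE)
    }))
  }))

  # truth rows for the array plantings
  truth_arr <- do.call(rbind, lapply(seq_len(spec$n_arrays), function(i) {
    do.call(rbind, lapply(seq_len(spec$units_per_array), function(k) {
      off <- array_starts[i] + (k - 1L) * spec$unit_len
      data.frame(class = "hdna", chrom = "chr1",
                 start = off + spec$igs_offsets,
                 end = off + spec$igs_offsets + mlen,
                 arm_len = nchar(spec$igs_motif$arm),
                 spacer_len = nchar(spec$igs_motif$spacer),
                 seq = tmpl, origin = "array",
                 stringsAsFactors = FALSE)
    }))
  }))

  # ---- background placements ------------------------------------------
  occupied <- cbind(array_starts - 200L, array_starts + array_len + 200L)
  place <- function(len, n, min_gap = 100L) {
    # n non-overlapping [start, start+len) spans clear of `occupied`
    out <- integer(0)
    tries <- 0L
    while (length(out) < n && tries < n * 1000L) {
      tries <- tries + 1L
      s <- sample.int(spec$genome_len - len - 2L, 1L)
      cand_lo <- s - min_gap; cand_hi <- s + len + min_gap
      if (any(cand_lo < occupied[, 2] & cand_hi > occupied[, 1])) next
      occupied <<- rbind(occupied, c(s, s + len))
      out <- c(out, s)
    }
    if (length(out) < n) stop("could not place ", n, " elements")
    sort(out)
  }

  # genes first (annotations only; sequence untouched)
  genes <- NULL
  truth_tes <- NULL
  if (spec$gene_count > 0) {
    glens <- sample(spec$gene_len_range[1]:spec$gene_len_range[2],
                    spec$gene_count, replace = TRUE)
    reserve <- max(spec$tes_motif_offset + mlen + 200L, 200L)
    gstarts <- vapply(glens, function(l) place(l + 2L * reserve, 1L), integer(1)) +
      reserve
    gstrand <- sample(c("+", "-"), spec$gene_count, replace = TRUE)
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(spec$gene_count)),
                        chrom = "chr1", start = gstarts,
                        end = gstarts + glens, strand = gstrand,
                        stringsAsFactors = FALSE)
    genes$tss <- ifelse(gstrand == "+", genes$start, genes$end - 1L)
    genes$tes <- ifelse(gstrand == "+", genes$end - 1L, genes$start)
    if (spec$tes_motif_offset > 0) {
      mstart <- ifelse(gstrand == "+", genes$tes + spec$tes_motif_offset,
                       genes$tes - spec$tes_motif_offset - mlen + 1L)
      truth_tes <- data.frame(class = "hdna", chrom = "chr1",
                              start = mstart, end = mstart + mlen,
                              arm_len = nchar(spec$igs_motif$arm),
                              spacer_len = nchar(spec$igs_motif$spacer),
                              seq = tmpl, origin = "tes",
                              stringsAsFactors = FALSE)
    }
  }

  background_bp <- spec$genome_len - spec$n_arrays * array_len
  n_back <- round(spec$background_motif_rate * background_bp / 1e6)
  back_starts <- if (n_back > 0) place(mlen, n_back) else integer(0)
  mo_tmpl_len <- nchar(mo_tmpl)
  mo_starts <- if (spec$n_mirror_only > 0)
    place(mo_tmpl_len, spec$n_mirror_only) else integer(0)
  dc_tmpl <- decoy_template()
  dc_starts <- if (spec$n_decoys > 0)
    place(nchar(dc_tmpl), spec$n_decoys) else integer(0)

  plant_at <- function(starts, template, breakers = TRUE) {
    v <- plant_seq(template)
    for (s in starts) {
      g[(s + 1):(s + length(v))] <<- v
      if (breakers) { g[s] <<- "A"; g[s + length(v) + 1] <<- "G" }
    }
  }
  plant_at(back_starts, tmpl)
  if (!is.null(truth_tes)) plant_at(truth_tes$start, tmpl)
  plant_at(mo_starts, mo_tmpl)
  plant_at(dc_starts, dc_tmpl, breakers = FALSE)

  truth <- rbind(
    truth_arr,
    if (length(back_starts) > 0)
      data.frame(class = "hdna", chrom = "chr1", start = back_starts,
                 end = back_starts + mlen,
                 arm_len = nchar(spec$igs_motif$arm),
                 spacer_len = nchar(spec$igs_motif$spacer),
                 seq = tmpl, origin = "background",
                 stringsAsFactors = FALSE),
    truth_tes,
    if (length(mo_starts) > 0)
      data.frame(class = "mirror_only", chrom = "chr1", start = mo_starts,
                 end = mo_starts + mo_tmpl_len, arm_len = 10L,
                 spacer_len = 1L, seq = mo_tmpl, origin = "background",
                 stringsAsFactors = FALSE),
    if (length(dc_starts) > 0)
      data.frame(class = "decoy", chrom = "chr1", start = dc_starts,
                 end = dc_starts + nchar(dc_tmpl), arm_len = NA_integer_,
                 spacer_len = NA_integer_, seq = dc_tmpl,
                 origin = "background", stringsAsFactors = FALSE))

  # ---- rescan and locally redraw accidental background H-DNA ----------
  planted_key <- paste(truth$start[truth$class == "hdna"],
                       truth$end[truth$class == "hdna"])
  in_protected <- function(pos) {   # planted spans and arrays stay intact
    hd <- truth[truth$class != "decoy", ]
    any(pos >= hd$start & pos < hd$end) ||
      any(pos >= arrays$start & pos < arrays$end)
  }
  for (iter in 1:20) {
    gs <- paste(g, collapse = "")
    found <- scan_hdna(gs, chrom = "chr1", params = params)
    extra <- found[!(paste(found$start, found$end) %in% planted_key), ,
                   drop = FALSE]
    if (nrow(extra) == 0) break
    if (iter == 20)
      stop("could not clear accidental background H-DNA after 20 redraws")
    for (r in seq_len(nrow(extra))) {
      pos <- extra$start[r]:(extra$end[r] - 1L)
      pos <- pos[!vapply(pos, in_protected, logical(1))]
      if (length(pos) > 0) g[pos + 1L] <- rand_bases(length(pos), spec$gc)
    }
  }

  genome <- c(chr1 = gs)
  out <- list(genome = genome, truth = truth, arrays = arrays,
              genic = annotation_track(genic, name = "rRNA_genic"),
              genes = genes, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fa"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed(arrays, file.path(out_dir, "arrays.bed"))
    write_bed(out$genic[, c("chrom", "start", "end", "name")],
              file.path(out_dir, "genic.bed"))
    write_genes_gff3(genes, genic, file.path(out_dir, "genes.gff3"))
    out$out_dir <- out_dir
  }
  out
}

# GFF3 writer for the generator's annotations (1-based inclusive on disk)
write_genes_gff3 <- function(genes, genic, path) {
  lines <- "##gff-version 3"
  if (!is.null(genes) && nrow(genes) > 0)
    lines <- c(lines, sprintf(
      "%s\thdnascan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_biotype=protein_coding",
      genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id))
  if (!is.null(genic) && nrow(genic) > 0)
    lines <- c(lines, sprintf(
      "%s\thdnascan\trRNA\t%d\t%d\t.\t+\t.\tID=rrna_%d_%d_%s;Name=%s",
      genic$chrom, genic$start + 1L, genic$end,
      genic$array_id, genic$unit_index, genic$name, genic$name))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic peak set over planted motifs
#'
#' A fraction of peaks is centered on planted H-DNA motifs (with a small
#' uniform jitter); the rest are uniform on the genome. Synthetic q-values
#' are drawn so that a stated fraction of peaks pass the strict `q < 0.005`
#' filter of [filter_and_merge_peaks()].
#'
#' @param truth truth ledger from [generate_genome()].
#' @param genome_len genome length in bp.
#' @param frac_on_motif fraction of peaks centered on planted H-DNA.
#' @param n_peaks number of peaks.
#' @param peak_len peak width in bp.
#' @param q_pass_frac fraction of peaks with q-value below 0.005.
#' @param jitter maximum |offset| of a motif-centered peak from the motif
#'   midpoint, in bp.
#' @param seed integer seed (required).
#' @return annotation track with name, score, strand and q_value columns.
#' @export
generate_peaks <- function(truth, genome_len, frac_on_motif = 0.5,
                           n_peaks = 200, peak_len = 400,
                           q_pass_frac = 0.8, jitter = 10, seed) {
  stopifnot(frac_on_motif >= 0, frac_on_motif <= 1, n_peaks >= 1,
            peak_len >= 1)
  if (missing(seed)) stop("generate_peaks requires a seed")
  if (n_peaks * peak_len > genome_len)
    stop("peak set exceeds genome capacity")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  hd <- truth[truth$class == "hdna", , drop = FALSE]
  n_on <- round(frac_on_motif * n_peaks)
  if (n_on > 0 && nrow(hd) == 0) stop("no planted H-DNA to center peaks on")
  centers <- integer(0)
  if (n_on > 0) {
    pick <- sample.int(nrow(hd), n_on, replace = n_on > nrow(hd))
    mid <- (hd$start[pick] + hd$end[pick]) %/% 2L
    centers <- mid + sample(-jitter:jitter, n_on, replace = TRUE)
  }
  if (n_peaks - n_on > 0)
    centers <- c(centers,
                 sample.int(genome_len - peak_len, n_peaks - n_on) +
                   peak_len %/% 2L)
  start <- pmax(centers - peak_len %/% 2L, 0L)
  end <- pmin(start + peak_len, genome_len)
  n_pass <- round(q_pass_frac * n_peaks)
  q <- numeric(n_peaks)
  pass_idx <- sample.int(n_peaks, n_pass)
  q[pass_idx] <- stats::runif(n_pass, 0, 0.005)
  q[setdiff(seq_len(n_peaks), pass_idx)] <-
    stats::runif(n_peaks - n_pass, 0.0051, 1)
  df <- data.frame(chrom = rep(truth$chrom[1], n_peaks),
                   start = as.integer(start), end = as.integer(end),
                   name = sprintf("peak%04d", seq_len(n_peaks)),
                   score = 0L, strand = ".",
                   q_value = q, stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  annotation_track(df, name = "synthetic_peaks")
}
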