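# shared fixtures: generated in code, cached for the duration of the run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# the package's standard study conditions: default spec, fixed seed
default_sim <- function() {
  fixture("default_sim", function() generate_genome(synthetic_spec(seed = 101)))
}

default_sim_hdna <- function() {
  fixture("default_sim_hdna", function() {
    sim <- default_sim()
    scan_hdna(sim$genome[["chr1"]], chrom = "chr1")
  })
}

# same conditions plus a motif planted 1 kb downstream of every TES
tes_sim <- function() {
  fixture("tes_sim", function()
    generate_genome(synthetic_spec(tes_motif_offset = 1000, seed = 202)))
}

small_sim <- function() {
  fixture("small_sim", function()
    generate_genome(synthetic_spec(genome_len = 1e6, n_arrays = 2,
                                   units_per_array = 5, gene_count = 10,
                                   n_mirror_only = 8, n_decoys = 8,
                                   seed = 11)))
}

random_seq <- function(n, gc = 0.5, n_frac = 0) {
  alphabet <- c("A", "C", "G", "T", "N")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2) * (1 - n_frac)
  paste(sample(alphabet, n, replace = TRUE, prob = c(p, n_frac)),
        collapse = "")
}

random_track <- function(n, chrom = "chr1", span = 10000, max_len = 200) {
  s <- sample.int(span - max_len, n, replace = TRUE)
  annotation_track(rep(chrom, n), s, s + sample.int(max_len, n, replace = TRUE))
}

# per-base coverage bitmap oracle for interval algebra
bitmap_cover <- function(track, n) {
  v <- logical(n)
  for (i in seq_len(nrow(track)))
    v[(track$start[i] + 1):track$end[i]] <- TRUE
  v
}

revcomp <- function(s)
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
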