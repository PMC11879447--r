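test_that("truth ledger counts follow the spec layout", {
  spec <- synthetic_spec(genome_len = 3e5, n_arrays = 1, units_per_array = 10,
                         igs_offsets = 2600L, gene_count = 0,
                         background_motif_rate = 0, n_mirror_only = 0,
                         n_decoys = 0, seed = 5)
  sim <- generate_genome(spec)
  expect_equal(sum(sim$truth$class == "hdna"), 10)
  expect_equal(unique(sim$truth$origin), "array")
  expect_equal(nchar(sim$genome[["chr1"]]), 3e5)
})

test_that("generation is byte-identical under one seed, different under another", {
  spec <- synthetic_spec(genome_len = 2e5, n_arrays = 1, units_per_array = 3,
                         gene_count = 2, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_genome(spec, out_dir = d1)
  s2 <- generate_genome(spec, out_dir = d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_genome(synthetic_spec(genome_len = 2e5, n_arrays = 1,
                                       units_per_array = 3, gene_count = 2,
                                       seed = 43))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("every truth row verifies against its claimed class", {
  sim <- small_sim()
  params <- scan_params()
  for (cls in c("hdna", "mirror_only", "decoy")) {
    rows <- sim$truth[sim$truth$class == cls, ]
    expect_gt(nrow(rows), 0)
    chk <- classify_hdna(oracle_scan(rows$seq[1], params = params), params)
    if (cls == "hdna") expect_true(nrow(chk) == 1 && chk$is_hdna)
    if (cls == "mirror_only") expect_true(nrow(chk) == 1 && !chk$is_hdna)
    if (cls == "decoy") expect_equal(nrow(chk), 0)
  }
})

test_that("planted motifs are recovered exactly; decoys are never called", {
  sim <- small_sim()
  hd <- scan_hdna(sim$genome[["chr1"]], chrom = "chr1")
  truth_hd <- sim$truth[sim$truth$class == "hdna", ]
  found <- paste(hd$start, hd$end, hd$arm_len, hd$spacer_len)
  planted <- paste(truth_hd$start, truth_hd$end,
                   truth_hd$arm_len, truth_hd$spacer_len)
  expect_true(all(planted %in% found))
  # ledger exhaustiveness: nothing called outside the planted spans
  expect_equal(sum(!(paste(hd$start, hd$end) %in%
                       paste(truth_hd$start, truth_hd$end))), 0)
  decoys <- sim$truth[sim$truth$class == "decoy", ]
  expect_equal(sum(paste(hd$start, hd$end) %in%
                     paste(decoys$start, decoys$end)), 0)
})

test_that("infeasible specs are rejected at construction", {
  expect_error(synthetic_spec(seed = 1, igs_offsets = 100L), "intergenic")
  expect_error(synthetic_spec(seed = 1, genome_len = 1e5), "fit")
  expect_error(synthetic_spec(), "seed")
})

test_that("synthetic peaks hit planted motifs at the requested rate", {
  sim <- small_sim()
  pk <- generate_peaks(sim$truth, sim$spec$genome_len, frac_on_motif = 1,
                       n_peaks = 50, peak_len = 200, q_pass_frac = 0.8,
                       seed = 6)
  expect_equal(nrow(pk), 50)
  expect_equal(mean(pk$q_value < 0.005), 0.8)
  hd_track <- sim$truth[sim$truth$class == "hdna", ]
  # every peak is centered on a planted motif (jitter << peak half-width)
  centers <- (pk$start + pk$end) %/% 2
  mids <- (hd_track$start + hd_track$end) %/% 2
  near <- vapply(centers, function(x) min(abs(x - mids)), numeric(1))
  expect_true(all(near <= 10))

  pk0 <- generate_peaks(sim$truth, sim$spec$genome_len, frac_on_motif = 0,
                        n_peaks = 50, peak_len = 200, seed = 6)
  near0 <- vapply((pk0$start + pk0$end) %/% 2,
                  function(x) min(abs(x - mids)), numeric(1))
  expect_gt(median(near0), 100)
  expect_error(generate_peaks(sim$truth, 1e4, n_peaks = 100,
                              peak_len = 200, seed = 1), "capacity")
})

test_that("peak/H-DNA association at arrays is detectable by Fisher's test", {
  sim <- small_sim()
  pk <- generate_peaks(sim$truth, sim$spec$genome_len, frac_on_motif = 0.5,
                       n_peaks = 200, peak_len = 300, seed = 8)
  hd <- sim$truth[sim$truth$class == "hdna", c("chrom", "start", "end")]
  has_hdna <- GenomicRanges::countOverlaps(
    hdnascan:::track_to_gr(pk), hdnascan:::track_to_gr(hd)) > 0
  in_arr <- GenomicRanges::countOverlaps(
    hdnascan:::track_to_gr(pk), hdnascan:::track_to_gr(sim$arrays)) > 0
  r <- fisher_overlap_test(sum(in_arr & has_hdna), sum(in_arr & !has_hdna),
                           sum(!in_arr & has_hdna), sum(!in_arr & !has_hdna))
  expect_lt(r$p_value, 0.01)
})
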