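test_that("site profiles place motif bp at signed, strand-aware offsets", {
  anchors <- data.frame(chrom = "c", pos = 5000, strand = "+")
  motifs <- data.frame(chrom = "c", start = 5100, end = 5101)
  p <- site_profile(anchors, motifs, half_window = 300)
  expect_equal(p$count[p$offset == 100], 1)
  expect_equal(sum(p$count), 1)

  # minus-strand anchor: a motif physically left of it is downstream (+)
  anchors$strand <- "-"
  motifs <- data.frame(chrom = "c", start = 4900, end = 4902)
  p <- site_profile(anchors, motifs, half_window = 300)
  expect_equal(p$count[p$offset %in% c(99, 100)], c(1, 1))
  expect_equal(sum(p$count), 2)
})

test_that("profile counts are conserved and mean enrichment is one", {
  set.seed(17)
  anchors <- data.frame(chrom = "c", pos = c(2000, 9000, 16000), strand = "+")
  motifs <- data.frame(chrom = "c",
                       start = sort(sample.int(18000, 60)))
  motifs$end <- motifs$start + sample.int(30, 60, replace = TRUE)
  p <- site_profile(anchors, motifs, half_window = 500)
  windows <- annotation_track(anchors$chrom, anchors$pos - 500,
                              anchors$pos + 501)
  expect_equal(sum(p$count),
               intersect_bp(merge_intervals(cbind(motifs, chrom = "c")),
                            windows)$bp)
  expect_equal(mean(p$enrichment), 1)

  # flipping every strand reverses the profile
  rev_anchors <- transform(anchors, strand = "-")
  pr <- site_profile(rev_anchors, motifs, half_window = 500)
  expect_equal(pr$count, rev(p$count))
})

test_that("anchors near the chromosome edge contribute in-bounds offsets only", {
  anchors <- data.frame(chrom = "c", pos = 100, strand = "+")
  motifs <- data.frame(chrom = "c", start = 0, end = 400)
  p <- site_profile(anchors, motifs, half_window = 300,
                    chrom_sizes = c(c = 400))
  expect_equal(sum(p$count), 400)                       # [0,400) only
  expect_equal(p$count[p$offset == -150], 0)            # before position 0
  expect_equal(p$count[p$offset == 250], 1)
  expect_equal(p$count[p$offset == 300], 0)             # past the chrom end
})

test_that("peak FDR filtering is strict at the threshold and merges survivors", {
  peaks <- annotation_track(data.frame(
    chrom = "c", start = c(0, 50, 120, 300), end = c(100, 150, 200, 400),
    q_value = c(0.004, 0.0049, 0.005, 1e-6)))
  kept <- filter_and_merge_peaks(peaks)
  # q = 0.005 exactly is dropped; the two overlapping survivors merge
  expect_equal(kept$start, c(0, 300))
  expect_equal(kept$end, c(150, 400))
  expect_error(filter_and_merge_peaks(annotation_track("c", 1, 2)),
               "q_value")
})

test_that("arm PWMs align first arms of the modal length", {
  motifs <- data.frame(chrom = "c",
                       start = c(1000, 1200, 1400),
                       end = c(1021, 1221, 1421),
                       arm_len = 10, spacer_len = 1,
                       seq = c("ctctctctgtctgtctctctc",
                               "ctctctctgtctgtctctctc",
                               "gagagagagatagagagagag"))
  anchors <- data.frame(chrom = "c", pos = 1500)
  pwm <- arm_pwm(motifs, anchors, half_window = 3000)
  expect_equal(dim(pwm), c(4, 10))
  expect_equal(colSums(pwm), rep(1, 10))
  expect_equal(unname(pwm["C", 1]), 2 / 3)
  expect_equal(unname(pwm["G", 1]), 1 / 3)
  expect_equal(attr(pwm, "n_arms"), 3)

  # all arms identical: indicator columns
  pwm1 <- arm_pwm(motifs[1:2, ], anchors)
  expect_true(all(pwm1 %in% c(0, 1)))

  expect_warning(e <- arm_pwm(motifs, data.frame(chrom = "c", pos = 9e6)),
                 "vicinity")
  expect_equal(ncol(e), 0)
})

test_that("maximum-enrichment classification uses the radius and centric ties", {
  prof <- structure(data.frame(offset = -500:500,
                               count = 0, enrichment = 1),
                    class = c("positional_profile", "data.frame"))
  prof$enrichment[prof$offset == 0] <- 5
  r <- max_enrichment_class(prof, radius = 250)
  expect_true(r$within_radius)
  expect_equal(r$offset, 0)
  expect_equal(r$max_enrichment, 5)

  prof$enrichment[] <- 1
  prof$enrichment[prof$offset == 500] <- 4
  r <- max_enrichment_class(prof, radius = 250)
  expect_false(r$within_radius)
  expect_equal(r$offset, 500)

  # exact tie resolved toward the smallest |offset|
  prof$enrichment[] <- 1
  prof$enrichment[prof$offset %in% c(-300, 10)] <- 2
  expect_equal(max_enrichment_class(prof)$offset, 10)

  prof$enrichment <- NA_real_
  expect_error(max_enrichment_class(prof), "undefined")
})

test_that("array bin profiles localize planted IGS motifs periodically", {
  sim <- small_sim()
  hd <- scan_hdna(sim$genome[["chr1"]], chrom = "chr1")
  prof <- rdna_bin_profile(sim$arrays, hd, n_bins = 3500, genic = sim$genic)
  spec <- sim$spec
  arr <- prof$arrays[[1]]
  expect_equal(sum(arr$profile$counts > 0) > 0, TRUE)
  expect_equal(sum(arr$profile$fraction), 1)

  # motifs fall outside every genic overlay bin range (IGS-only planting)
  occupied <- which(arr$profile$counts > 0)
  for (r in seq_len(nrow(arr$overlays))) {
    ov <- arr$overlays[r, ]
    expect_equal(sum(occupied >= ov$bin_start & occupied <= ov$bin_end), 0)
  }

  # periodic planting: identical per-unit bin phase in every unit copy
  bins_per_unit <- 3500 / spec$units_per_array
  unit_sets <- split((occupied - 1) %% bins_per_unit,
                     (occupied - 1) %/% bins_per_unit)
  unit_sets <- lapply(unit_sets, function(x) sort(unique(x)))
  expect_equal(length(unique(unit_sets)), 1)
  expect_error(rdna_bin_profile(sim$arrays[0, ], hd), "empty")
})

test_that("bootstrap bands attach to site profiles and cover the point estimate", {
  set.seed(23)
  anchors <- data.frame(chrom = "c", pos = sample(5000:95000, 40),
                        strand = "+")
  motifs <- data.frame(chrom = "c", start = sort(sample.int(99000, 500)))
  motifs$end <- motifs$start + 21
  p <- site_profile(anchors, motifs, half_window = 200, bootstrap = 100,
                    seed = 4)
  expect_true(all(c("ci_lo", "ci_hi") %in% names(p)))
  expect_true(all(p$ci_lo <= p$ci_hi))
  expect_error(site_profile(anchors, motifs, bootstrap = 10), "seed")
})
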