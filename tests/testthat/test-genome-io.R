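test_that("FASTA round-trips verbatim, ids from the header first word", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 assembled", "ACGTacgtNn", ">chr2", "gggTTT"), path)
  seqs <- read_fasta(path)
  expect_identical(seqs, c(chr1 = "ACGTacgtNn", chr2 = "gggTTT"))

  set.seed(3)
  rt <- c(a = random_seq(500), b = tolower(random_seq(333)))
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rt, p2)
  expect_identical(read_fasta(p2), rt)

  gz <- withr::local_tempfile(fileext = ".fa.gz")
  write_fasta(rt, gz)
  expect_identical(read_fasta(gz), rt)
})

test_that("malformed FASTA headers are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">chr1"), path)
  expect_error(read_fasta(path), "line 1")
})

test_that("BED parsing keeps extra columns and reports bad lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr2\t0\t5\tpk1\t17\t+\t0.003"), path)
  tr <- read_bed(path)
  expect_equal(tr$start, c(10, 0))
  expect_equal(tr$end, c(20, 5))
  # shortest line bounds the parsed column count; re-read richer file alone
  writeLines("chr2\t0\t5\tpk1\t17\t+\t0.003", path)
  rich <- read_bed(path)
  expect_equal(rich$name, "pk1")
  expect_equal(rich$score, 17)
  expect_equal(rich$extra7, 0.003)

  writeLines("chr1\t30\t20", path)
  expect_error(read_bed(path), "start >= end on BED line 1")
  writeLines(c("chr1\t1\t2", "chr1\tx\t2"), path)
  expect_error(read_bed(path), "line 2")

  file.create(path2 <- withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(read_bed(path2)), 0)
})

test_that("BED output round-trips coordinates through read_bed", {
  set.seed(9)
  for (i in 1:3) {
    tr <- random_track(50)
    path <- withr::local_tempfile(fileext = ".bed")
    write_bed(tr, path)
    back <- read_bed(path)
    expect_equal(back$start, tr$start)
    expect_equal(back$end, tr$end)
  }
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(annotation_track("c", 10, 20), path)
  expect_identical(readLines(path), "c\t10\t20")
})

test_that("GFF gene anchors convert to 0-based strand-aware TSS/TES", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t101\t200\t.\t+\t.\tID=gp",
               "chr1\tx\tgene\t101\t200\t.\t-\t.\tID=gm"), path)
  g <- read_gff_genes(path)
  expect_equal(g$start, c(100, 100))
  expect_equal(g$end, c(200, 200))
  expect_equal(g$tss[g$gene_id == "gp"], 100)
  expect_equal(g$tes[g$gene_id == "gp"], 199)
  expect_equal(g$tss[g$gene_id == "gm"], 199)
  expect_equal(g$tes[g$gene_id == "gm"], 100)
})

test_that("generator GFF reproduces the truth gene anchors", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  hdnascan:::write_genes_gff3(sim$genes, NULL, file.path(dir, "g.gff3"))
  g <- read_gff_genes(file.path(dir, "g.gff3"))
  g <- g[match(sim$genes$gene_id, g$gene_id), ]
  expect_equal(g$tss, sim$genes$tss)
  expect_equal(g$tes, sim$genes$tes)
  expect_equal(g$strand, sim$genes$strand)
})

test_that("merge consolidates, merges bookended intervals, is idempotent", {
  expect_equal(nrow(merge_intervals(annotation_track(character(0),
                                                     integer(0), integer(0)))), 0)
  m <- merge_intervals(annotation_track(c("c", "c"), c(1, 3), c(5, 8)))
  expect_equal(m$start, 1)
  expect_equal(m$end, 8)
  bk <- merge_intervals(annotation_track(c("c", "c"), c(1, 5), c(5, 9)))
  expect_equal(nrow(bk), 1)
  expect_equal(bk$end, 9)

  set.seed(21)
  tr <- random_track(1000)
  m <- merge_intervals(tr)
  expect_identical(as.data.frame(merge_intervals(m)), as.data.frame(m))
  expect_equal(track_bp(m), sum(bitmap_cover(tr, 10000)))
  expect_lte(track_bp(m), track_bp(tr))
})

test_that("intersect_bp equals the per-base bitmap AND and is symmetric", {
  a <- annotation_track("c", 0, 10); b <- annotation_track("c", 5, 15)
  expect_equal(intersect_bp(a, b)$bp, 5)
  expect_equal(intersect_bp(a, annotation_track("c", 50, 60))$bp, 0)

  set.seed(33)
  for (i in 1:5) {
    x <- random_track(200); y <- random_track(150)
    bp <- intersect_bp(x, y)$bp
    expect_equal(bp, sum(bitmap_cover(x, 10000) & bitmap_cover(y, 10000)))
    expect_equal(intersect_bp(y, x)$bp, bp)
  }
})

test_that("reciprocal overlap requires the fraction on both sides", {
  a <- annotation_track("c", 0, 100); b <- annotation_track("c", 50, 150)
  expect_equal(nrow(reciprocal_overlap_filter(a, b, 0.2)), 1)
  a2 <- annotation_track("c", 0, 1000); b2 <- annotation_track("c", 900, 1000)
  expect_equal(nrow(reciprocal_overlap_filter(a2, b2, 0.2)), 0)
  expect_equal(nrow(reciprocal_overlap_filter(a2, b2, 0.1)), 1)
  expect_equal(nrow(reciprocal_overlap_filter(
    a, annotation_track("c", 500, 600), 0.2)), 0)
  expect_error(reciprocal_overlap_filter(a, b, 0), "frac")
  expect_error(reciprocal_overlap_filter(a, b, 1.5), "frac")
})
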