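test_that("chrom.sizes parsing preserves order and rejects bad input", {
  p <- tempfile()
  writeLines("chr1\t100\nchr2\t50", p)
  lay <- read_chrom_sizes(p)
  expect_s3_class(lay, "genome_layout")
  expect_equal(lay$chrom, c("chr1", "chr2"))
  expect_equal(lay$length, c(100, 50))

  writeLines("chr1\t100\nchr1\t50", p)
  expect_error(read_chrom_sizes(p), "duplicate")

  writeLines(c("chr1\t100", "chr2"), p)
  expect_error(read_chrom_sizes(p), "line 2")

  writeLines("chr1\t0", p)
  expect_error(read_chrom_sizes(p), "positive")

  # chromosome-level genome: 29 chromosomes, file order preserved exactly
  set.seed(42)
  nm <- sprintf("ssa%02d", sample(29))
  ln <- sample(1e5:2e5, 29)
  writeLines(sprintf("%s\t%d", nm, ln), p)
  lay <- read_chrom_sizes(p)
  expect_equal(lay$chrom, nm)
  expect_equal(lay$length, as.numeric(ln))
})

test_that("bedGraph reading densifies, zero-fills, and validates", {
  lay <- genome_layout("chr1", 6)
  p <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t4\t7.0", p)
  tr <- read_bedgraph(p, lay)
  expect_equal(tr$depth$chr1, c(7, 7, 7, 7, 0, 0))

  writeLines(character(0), p)
  expect_equal(read_bedgraph(p, lay)$depth$chr1, numeric(6))

  writeLines(c("chr1\t0\t4\t7", "chr1\t3\t5\t2"), p)
  expect_error(read_bedgraph(p, lay), "overlap")

  writeLines("chr1\t2\t9\t1", p)
  expect_error(read_bedgraph(p, lay), "bounds")

  writeLines(c("chr1\t0\t2\t5", "chrX\t0\t2\t5", "chrX\t3\t4\t1"), p)
  expect_warning(tr <- read_bedgraph(p, lay), "2 bedGraph record")
  expect_equal(tr$depth$chr1, c(5, 5, 0, 0, 0, 0))
})

test_that("random non-overlapping bedGraph records equal a per-base fill", {
  set.seed(7)
  for (rep in 1:10) {
    lay <- random_layout(2)
    p <- tempfile(fileext = ".bedgraph")
    lines <- character(0)
    expected <- lapply(setNames(lay$length, lay$chrom), numeric)
    for (ch in lay$chrom) {
      L <- lay$length[lay$chrom == ch]
      pos <- 0
      while (pos < L - 2) {
        s <- pos + sample(0:3, 1)
        e <- min(L, s + sample(1:8, 1))
        if (s >= e) break
        v <- sample(0:50, 1)
        lines <- c(lines, sprintf("%s\t%d\t%d\t%d", ch, s, e, v))
        expected[[ch]][(s + 1):e] <- v  # brute-force per-base fill
        pos <- e + sample(0:4, 1)
      }
    }
    writeLines(sample(lines), p)  # order must not matter
    tr <- read_bedgraph(p, lay)
    expect_equal(tr$depth, expected, ignore_attr = TRUE)
  }
})

test_that("bedGraph write-then-read is identity on dense tracks", {
  set.seed(11)
  lay <- random_layout(3)
  tr <- random_track(lay, max_depth = 5)
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  expect_equal(read_bedgraph(p, lay)$depth, tr$depth,
               ignore_attr = TRUE)
})

test_that("alignment depth counts M/=/X/D spans of retained primary reads", {
  lay <- genome_layout("chr1", 50)
  p <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:50")
  read10 <- "r1\t0\tchr1\t1\t60\t10M\t*\t0\t0\tAAAAAAAAAA\t*"
  writeLines(c(hdr, read10), p)
  tr <- depth_from_alignments(p, lay)
  expect_equal(tr$depth$chr1, c(rep(1, 10), rep(0, 40)))

  writeLines(c(hdr, read10, sub("r1", "r2", read10)), p)
  expect_equal(depth_from_alignments(p, lay)$depth$chr1,
               c(rep(2, 10), rep(0, 40)))

  # MAPQ filter drops the second read
  low <- "r2\t0\tchr1\t1\t5\t10M\t*\t0\t0\tAAAAAAAAAA\t*"
  writeLines(c(hdr, read10, low), p)
  expect_equal(max(depth_from_alignments(p, lay, min_mapq = 10)$depth$chr1),
               1)

  # deletions covered, introns not
  gap <- "r3\t0\tchr1\t1\t60\t4M2D2M2N2M\t*\t0\t0\tAAAAAAAA\t*"
  writeLines(c(hdr, gap), p)
  d <- depth_from_alignments(p, lay)$depth$chr1
  expect_equal(d[1:12], c(1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1))
})

test_that("alignment depth equals an independent pileup recount", {
  set.seed(13)
  lay <- genome_layout(c("chrA", "chrB"), c(400, 300))
  sam <- write_sam_fixture(lay, 200)
  for (mq in c(0, 30)) {
    got <- depth_from_alignments(sam, lay, min_mapq = mq)
    want <- oracle_pileup(sam, lay, min_mapq = mq)
    expect_equal(got$depth, want$depth, ignore_attr = TRUE)
  }
})

test_that("alignment header must match the layout", {
  lay <- genome_layout(c("chr1", "chrZ"), c(50, 70))
  p <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:50",
               "r1\t0\tchr1\t1\t60\t5M\t*\t0\t0\tAAAAA\t*"), p)
  expect_error(depth_from_alignments(p, lay), "chrZ")
})

test_that("flank extraction clips at bounds and matches substrings", {
  lay <- genome_layout("chr1", 100000)
  fa <- random_fasta(lay)
  reg <- genomic_regions("chr1", 20000, 21000)
  fl <- extract_flanks(fa, reg, flank_bp = 10000)
  expect_equal(fl$start, 10000)
  expect_equal(fl$end, 31000)
  expect_equal(nchar(fl$seq), 21000)
  expect_false(fl$clipped)
  expect_equal(fl$id, "chr1:10000-31000")

  edge <- extract_flanks(fa, genomic_regions("chr1", 100, 200),
                         flank_bp = 10000)
  expect_equal(edge$start, 0)
  expect_true(edge$clipped)

  # substring oracle over 50 random regions on a smaller genome
  set.seed(19)
  lay2 <- genome_layout(c("c1", "c2"), c(500, 400))
  fa2 <- random_fasta(lay2)
  genome <- Biostrings::readDNAStringSet(fa2)
  for (i in 1:50) {
    ch <- sample(lay2$chrom, 1)
    L <- lay2$length[lay2$chrom == ch]
    s <- sample(0:(L - 10), 1)
    e <- s + sample(1:10, 1)
    fb <- sample(0:60, 1)
    fl <- extract_flanks(fa2, genomic_regions(ch, s, e), flank_bp = fb)
    rs <- max(0, s - fb); re <- min(L, e + fb)
    expect_identical(fl$seq,
                     as.character(Biostrings::subseq(genome[[ch]],
                                                     rs + 1, re)))
    # length bounds invariant
    expect_lte(nchar(fl$seq), 2 * fb + (e - s))
    expect_gte(nchar(fl$seq), e - s)
  }
  expect_error(extract_flanks(fa2, genomic_regions("nope", 0, 5)), "nope")
})

test_that("BED write/read round trip preserves coordinates and scores", {
  reg <- genomic_regions(c("chr1", "chr2"), c(5, 0), c(10, 7),
                         label = c("a", NA))
  reg$mean_coverage <- c(12.5, 3)
  p <- tempfile(fileext = ".bed")
  write_bed(reg, p)
  expect_match(readLines(p)[1], "^chr1\t5\t10\ta\t12\\.5$")
  back <- read_bed(p)
  expect_equal(back$chrom, reg$chrom)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$score, reg$mean_coverage)

  write_bed(genomic_regions(character(0), numeric(0), numeric(0)), p)
  expect_length(readLines(p), 0)
  expect_equal(nrow(read_bed(p)), 0)
})
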