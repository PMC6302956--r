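test_that("split-read records follow the CIGAR walk", {
  seqs <- test_genome_seqs()
  reads <- data.frame(
    qname = c("r1", "r2", "r3"),
    flag = 67L, rname = "chr1",
    pos = c(1001L, 101L, 501L), mapq = 60L,
    cigar = c("30M100N40M", "50M", "20M50N30M60N25M"),
    seq = NA, nh = 1L, nm = 0L)
  for (i in 1:3) {
    reads$seq[i] <- spliced_seq(seqs, "chr1", reads$pos[i], reads$cigar[i])
  }
  sr <- extract_from_sam(seqs, reads)

  r1 <- sr[sr$read_id == "r1", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$left_start, 1000L)
  expect_equal(r1$intron_start, 1030L)
  expect_equal(r1$intron_end, 1130L)
  expect_equal(r1$right_end, 1170L)
  expect_equal(r1$introns_in_read, 1L)

  expect_equal(nrow(sr[sr$read_id == "r2", ]), 0L)

  r3 <- sr[sr$read_id == "r3", ]
  expect_equal(nrow(r3), 2L)
  expect_true(all(r3$introns_in_read == 2L))
  # 20M50N30M60N25M at 0-based 500
  expect_equal(r3$intron_start, c(520L, 600L))
  expect_equal(r3$intron_end, c(570L, 660L))
  expect_equal(r3$left_len, c(20L, 30L))
  expect_equal(r3$right_len, c(30L, 25L))
})

test_that("soft clips and intron bounds are honoured", {
  seqs <- test_genome_seqs()
  reads <- data.frame(
    qname = c("clip", "small", "big"),
    flag = 67L, rname = "chr1",
    pos = c(1001L, 101L, 201L), mapq = 60L,
    cigar = c("5S30M100N40M", "30M3N40M", "30M100N40M"),
    seq = NA, nh = 1L, nm = NA)
  reads$seq[1] <- paste0("AAAAA",
                         spliced_seq(seqs, "chr1", 1001L, "30M100N40M"))
  reads$seq[2] <- spliced_seq(seqs, "chr1", 101L, "30M3N40M")
  reads$seq[3] <- spliced_seq(seqs, "chr1", 201L, "30M100N40M")
  sr <- extract_from_sam(seqs, reads, min_intron = 4L, max_intron = 50L)

  # the 3N skip is under min_intron and both 100N skips are above
  # max_intron: all three dropped and tallied
  diag <- attr(sr, "diagnostics", exact = TRUE)
  expect_equal(diag$skips_out_of_bounds, 3L)
  clip <- sr[sr$read_id == "clip", ]
  expect_equal(nrow(clip), 0L)

  sr2 <- extract_from_sam(seqs, reads, min_intron = 4L, max_intron = 500L)
  clip <- sr2[sr2$read_id == "clip", ]
  expect_equal(clip$left_start, 1000L)
  expect_equal(clip$left_clip, 5L)
  expect_equal(clip$read_length, 75L)
})

test_that("mismatch truncation shortens the match run, not the anchor", {
  seqs <- test_genome_seqs()
  base <- spliced_seq(seqs, "chr1", 1001L, "30M100N40M")
  # plant a mismatch 5 bases left of the junction (read position 26)
  mut <- base
  orig <- substr(mut, 26, 26)
  substr(mut, 26, 26) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  reads <- data.frame(qname = c("clean", "mut"), flag = 67L, rname = "chr1",
                      pos = 1001L, mapq = 60L, cigar = "30M100N40M",
                      seq = c(base, mut), nh = 1L, nm = c(0L, 1L))
  sr <- extract_from_sam(seqs, reads)
  clean <- sr[sr$read_id == "clean", ]
  mutr <- sr[sr$read_id == "mut", ]
  expect_equal(clean$lmmes, 30L)
  expect_equal(clean$rmmes, 40L)
  expect_equal(mutr$lmmes, 4L)   # matches at distances 1..4, mismatch at 5
  expect_equal(mutr$rmmes, 40L)
  expect_equal(mutr$left_len, 30L)  # anchor length unaffected
})

test_that("edit distance falls back to genome comparison when NM is absent", {
  seqs <- test_genome_seqs()
  base <- spliced_seq(seqs, "chr1", 1001L, "30M100N40M")
  mut <- base
  for (p in c(3, 40)) {
    orig <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  }
  reads <- data.frame(qname = "x", flag = 67L, rname = "chr1", pos = 1001L,
                      mapq = 60L, cigar = "30M100N40M", seq = mut,
                      nh = NA, nm = NA)
  sr <- extract_from_sam(seqs, reads)
  expect_equal(sr$mismatches, 2L)
  expect_true(sr$uniquely_mapped)  # mapq fallback at default cutoff 30
})

test_that("prepare merges inputs, conserves records and sorts", {
  seqs <- test_genome_seqs(len = 5000L)
  mk_reads <- function(n, offset) {
    pos <- sample(seq(101L, 3000L), n, replace = TRUE)
    data.frame(qname = paste0("m", offset + seq_len(n)), flag = 67L,
               rname = "chr1", pos = pos, mapq = 60L, cigar = "10M20N10M",
               seq = vapply(pos, function(p)
                 spliced_seq(seqs, "chr1", p, "10M20N10M"), character(1)),
               nh = 1L, nm = 0L)
  }
  set.seed(42)
  g <- write_test_genome(seqs)
  s1 <- write_test_sam(seqs, mk_reads(100L, 0L))
  s2 <- write_test_sam(seqs, mk_reads(150L, 100L))
  prep <- prepare(c(s1, s2), g)
  expect_equal(prep$read_count, 250)
  expect_equal(prep$source_count, 2L)
  pos <- Rsamtools::scanBam(prep$alignment_path,
                            param = Rsamtools::ScanBamParam(what = "pos"))[[1]]$pos
  expect_true(all(diff(pos) >= 0L))

  # idempotence: preparing the prepared output returns it unchanged
  prep2 <- prepare(prep$alignment_path, g)
  expect_equal(prep2$alignment_path, prep$alignment_path)
  expect_equal(prep2$read_count, 250)
})

test_that("prepare rejects alignments over contigs missing from the genome", {
  seqs <- test_genome_seqs()
  bad <- c(seqs, chrZ = substr(seqs[[1]], 1, 500))
  names(bad) <- c("chr1", "chrZ")
  reads <- data.frame(qname = "r", flag = 67L, rname = "chrZ", pos = 10L,
                      mapq = 60L, cigar = "10M20N10M",
                      seq = spliced_seq(bad, "chrZ", 10L, "10M20N10M"),
                      nh = 1L, nm = 0L)
  g <- write_test_genome(seqs)  # genome lacks chrZ
  s <- write_test_sam(bad, reads)
  expect_error(prepare(s, g), "consistency error")
})

test_that("extraction matches an independent junction scan on a fixture", {
  skip_if_not_installed("GenomicAlignments")
  fx <- small_fixture()
  g <- fx$paths$genome
  prep <- prepare(fx$paths$sam, g)
  sr <- iterate_split_reads(prep)

  ga <- GenomicAlignments::readGAlignments(prep$alignment_path)
  jx <- GenomicAlignments::junctions(ga)
  flat <- unlist(jx)
  ref <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(flat))
  ref_counts <- ref[, .N, by = .(contig, start, end)]
  mine <- sr[, .N, by = .(contig, start = intron_start, end = intron_end)]
  data.table::setkeyv(ref_counts, c("contig", "start", "end"))
  data.table::setkeyv(mine, c("contig", "start", "end"))
  expect_equal(as.data.frame(mine), as.data.frame(ref_counts))
})

test_that("fetch_sequence respects bounds and strand", {
  seqs <- c(chrT = "ACGTAAGG")
  g <- write_test_genome(seqs)
  expect_equal(fetch_sequence(g, "chrT", 0, 8), "ACGTAAGG")
  expect_equal(fetch_sequence(g, "chrT", 0, 4, "-"), "ACGT")  # palindrome
  expect_equal(fetch_sequence(g, "chrT", 4, 8, "-"), "CCTT")
  expect_error(fetch_sequence(g, "chrT", 4, 9), "out of bounds")
})
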