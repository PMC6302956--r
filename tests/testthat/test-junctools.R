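demo_junctions <- function() {
  jm <- data.table::data.table(
    id = c("JUNC00000001", "JUNC00000002"),
    contig = c("ctg1", "ctg1"),
    start = c(1030L, 5000L), end = c(1130L, 5200L),
    strand = c("+", "-"),
    donor = c("GT", "GT"), acceptor = c("AG", "AG"),
    site_category = c("canonical", "canonical"),
    nb_raw = c(10L, 3L), nb_unique_split = c(10L, 3L),
    nb_unique_mapped = c(10L, 2L), nb_reliable = c(9L, 1L),
    reliable_ratio = c(0.9, 1 / 3), entropy = c(2.25, 0.9182958340544896),
    max_overhang = c(35L, 20L), maxmmes = c(30L, 12L),
    mean_mismatches = c(0.1, 2 / 3),
    left_hamming = c(7L, 6L), right_hamming = c(8L, 9L),
    min_hamming = c(7L, 6L),
    intron_score = c(0, 0.5849625007211562),
    pwm_score = c(12.5, -3.25), splicing_signal = c(8.125, -1.0625),
    left_anchor_start = c(1000L, 4980L), right_anchor_end = c(1170L, 5230L),
    max_read_length = c(76L, 76L), nb_samples = c(1L, 1L),
    in_reference = c(TRUE, FALSE),
    probability = c(0.97, 0.4123456789012345),
    genuine = c(TRUE, FALSE))
  for (i in 1:20) jm[, (paste0("dev", i)) := c(0.25 * i, 1 / 3)]
  jm
}

test_that("tab round trip is lossless and byte-identical", {
  jm <- demo_junctions()
  f1 <- tempfile(fileext = ".tab")
  f2 <- tempfile(fileext = ".tab")
  write_junctions(jm, f1, "tab", seed = 77L)
  back <- read_junctions(f1, "tab")
  expect_equal(attr(back, "seed", exact = TRUE), 77L)
  for (col in names(jm)) {
    expect_equal(back[[col]], jm[[col]], info = col)
  }
  write_junctions(back, f2, "tab", seed = 77L)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("records missing metrics still round trip as NA", {
  minimal <- data.table::data.table(contig = "c", start = 5L, end = 55L)
  f <- tempfile(fileext = ".tab")
  write_junctions(minimal, f, "tab")
  back <- read_junctions(f, "tab")
  expect_equal(back$start, 5L)
  expect_true(is.na(back$entropy))
  expect_true(is.na(back$genuine))
})

test_that("BED12 blocks encode the anchors and thick interval the intron", {
  jm <- demo_junctions()[1]
  f <- tempfile(fileext = ".bed")
  write_junctions(jm, f, "bed_exon")
  line <- strsplit(readLines(f)[2], "\t")[[1]]
  expect_equal(line[2], "1000")
  expect_equal(line[3], "1170")
  expect_equal(line[5], "970")        # round(1000 * 0.97)
  expect_equal(line[7], "1030")
  expect_equal(line[8], "1130")
  expect_equal(line[10], "2")
  expect_equal(line[11], "30,40")
  expect_equal(line[12], "0,130")

  back <- read_junctions(f, "bed_exon")
  expect_equal(back$start, 1030L)
  expect_equal(back$end, 1130L)
  expect_equal(back$left_anchor_start, 1000L)
  expect_equal(back$right_anchor_end, 1170L)
  expect_equal(back$probability, 0.97)

  f2 <- tempfile(fileext = ".bed")
  write_junctions(back, f2, "bed_exon")
  expect_identical(readLines(f), readLines(f2))

  bad <- line
  bad[10] <- "3"; bad[11] <- "30,40,5"; bad[12] <- "0,130,160"
  fbad <- tempfile(fileext = ".bed")
  writeLines(c(readLines(f)[1], paste(bad, collapse = "\t")), fbad)
  expect_error(read_junctions(fbad, "bed_exon"), "2 blocks")
})

test_that("empty junction sets write header-only files", {
  empty <- demo_junctions()[0]
  f <- tempfile(fileext = ".tab")
  write_junctions(empty, f, "tab")
  lines <- readLines(f)
  expect_equal(length(lines), 4L)  # 3 comment lines + column header
  expect_equal(nrow(read_junctions(f, "tab")), 0L)
})

test_that("hint and mapper exports use the documented coordinates", {
  jm <- demo_junctions()
  fg <- tempfile(fileext = ".gff3")
  write_junctions(jm, fg, "hint_gff")
  g <- strsplit(readLines(fg)[2], "\t")[[1]]
  expect_equal(g[3], "intron")
  expect_equal(g[4], "1031")  # 1-based inclusive start
  expect_equal(g[5], "1130")
  fm <- tempfile(fileext = ".txt")
  write_junctions(jm, fm, "mapper_sj")
  m <- strsplit(readLines(fm)[1], "\t")[[1]]
  expect_equal(m[2], "1029")  # last exonic base before the intron, 0-based
  expect_equal(m[3], "1130")  # first exonic base after it, 0-based
  expect_equal(m[4], "+")
})

test_that("set algebra keys on the intron locus and counts samples", {
  base <- demo_junctions()
  s1 <- base
  s2 <- base[1]
  s3 <- data.table::copy(base)[, start := start + 1L]  # disjoint loci
  u <- set_operate(list(s1, s2), "union")
  expect_equal(nrow(u), 2L)
  expect_equal(u[start == 1030L]$nb_samples, 2L)
  expect_equal(u[start == 5000L]$nb_samples, 1L)

  u6 <- set_operate(rep(list(s2), 6), "union")
  expect_equal(u6$nb_samples, 6L)

  expect_equal(nrow(set_operate(list(s1, s3), "union")), 4L)

  i <- set_operate(list(s1, s2), "intersection")
  expect_equal(nrow(i), 1L)
  expect_equal(i$start, 1030L)

  expect_equal(nrow(set_operate(list(s1, s1), "subtract")), 0L)
  d <- set_operate(list(s1, s2), "subtract")
  expect_equal(d$start, 5000L)

  # union is order-insensitive on the locus level
  u_ab <- set_operate(list(s1, s3), "union")
  u_ba <- set_operate(list(s3, s1), "union")
  expect_equal(u_ab[, .(contig, start, end, nb_samples)],
               u_ba[, .(contig, start, end, nb_samples)])
})

write_two_intron_gtf <- function(path) {
  # txA: exons [1,100], [200,300], [400,500] (introns [100,199), [300,399))
  # txB shares the first intron
  lines <- c(
    "ctg1\ttest\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"txA\";",
    "ctg1\ttest\texon\t200\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"txA\";",
    "ctg1\ttest\texon\t400\t500\t.\t+\t.\tgene_id \"g1\"; transcript_id \"txA\";",
    "ctg1\ttest\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"txB\";",
    "ctg1\ttest\texon\t200\t260\t.\t+\t.\tgene_id \"g1\"; transcript_id \"txB\";",
    "ctg1\ttest\texon\t700\t800\t.\t+\t.\tgene_id \"g2\"; transcript_id \"txC\";")
  writeLines(lines, path)
  path
}

test_that("GTF exon pairs convert to deduplicated 0-based introns", {
  f <- write_two_intron_gtf(tempfile(fileext = ".gtf"))
  ref <- load_reference(f)
  expect_equal(nrow(ref$introns), 2L)  # shared intron deduplicated,
                                       # single-exon txC contributes nothing
  expect_true(all(ref$introns$start %in% c(100L, 300L)))
  expect_equal(sort(ref$introns$end), c(199L, 399L))
})

test_that("reference comparison partitions junctions into the four classes", {
  f <- write_two_intron_gtf(tempfile(fileext = ".gtf"))
  ref <- load_reference(f)
  probe <- data.table::data.table(
    contig = "ctg1",
    start = c(100L,  # class 1: matches intron [100,199)
              100L,  # class 2: donor of intron A, acceptor of intron B
              100L,  # class 3: annotated donor, novel acceptor
              910L), # class 4: both novel
    end = c(199L, 399L, 950L, 980L),
    strand = "+")
  cmp <- compare_to_reference(probe, ref)
  expect_equal(cmp$labels, 1:4)
  expect_equal(unname(cmp$breakdown), c(1L, 1L, 1L, 1L))
  expect_equal(sum(cmp$breakdown), nrow(probe))
})

test_that("evaluation computes recall, precision and their harmonic mean", {
  truth <- data.frame(contig = "c", start = c(10, 20, 30, 40), end = c(15, 25, 35, 45))
  expect_equal(evaluate_junctions(truth, truth),
               list(recall = 1, precision = 1, f1 = 1))
  half <- truth[1:2, ]
  ev <- evaluate_junctions(half, truth)
  expect_equal(ev$recall, 0.5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$f1, 2 / 3)
  none <- truth[0, ]
  expect_equal(evaluate_junctions(none, truth),
               list(recall = 0, precision = 0, f1 = 0))
  expect_error(evaluate_junctions(truth, none), "parameter error")
  # swapping arguments swaps recall and precision
  extra <- rbind(truth, data.frame(contig = "c", start = 99, end = 120))
  a <- evaluate_junctions(extra, truth)
  b <- evaluate_junctions(truth, extra)
  expect_equal(a$recall, b$precision)
  expect_equal(a$precision, b$recall)
})
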