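make_intron_genome <- function(donor, acceptor, flank = 30L, intron = 80L,
                               seed = 9L) {
  set.seed(seed)
  pre <- paste0(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
  mid <- paste0(sample(c("A", "C", "G", "T"), intron - 4L, replace = TRUE),
                collapse = "")
  post <- paste0(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                 collapse = "")
  list(seqs = c(chrM = paste0(pre, donor, mid, acceptor, post)),
       start = flank, end = flank + intron)
}

test_that("splice sites classify and resolve strand by dinucleotide pair", {
  cases <- list(
    list(d = "GT", a = "AG", cat = "canonical", strand = "+"),
    list(d = "CT", a = "AC", cat = "canonical", strand = "-"),
    list(d = "GC", a = "AG", cat = "semi_canonical", strand = "+"),
    list(d = "GT", a = "AT", cat = "semi_canonical", strand = "-"),  # AT-AC rc
    list(d = "AA", a = "TT", cat = "novel", strand = "?"),
    list(d = "NT", a = "AG", cat = "novel", strand = "?"))
  for (cs in cases) {
    g <- make_intron_genome(cs$d, cs$a)
    call <- classify_splice_sites(g$seqs, "chrM", g$start, g$end)
    expect_equal(call$site_category, cs$cat, info = paste(cs$d, cs$a))
    expect_equal(call$strand, cs$strand, info = paste(cs$d, cs$a))
  }
})

test_that("strand resolution is involution-consistent under revcomp", {
  g <- make_intron_genome("GT", "AG", flank = 25L, intron = 60L)
  fwd <- classify_splice_sites(g$seqs, "chrM", g$start, g$end)
  expect_equal(fwd$strand, "+")
  # reverse-complement the contig; the intron moves to the mirrored interval
  L <- nchar(g$seqs[["chrM"]])
  rc <- c(chrM = fetch_sequence(g$seqs, "chrM", 0, L, "-"))
  rev_call <- classify_splice_sites(rc, "chrM", L - g$end, L - g$start)
  expect_equal(rev_call$site_category, "canonical")
  expect_equal(rev_call$strand, "-")
  expect_equal(rev_call$donor, fwd$donor)
  expect_equal(rev_call$acceptor, fwd$acceptor)
})

test_that("hamming scores flag repeat-like junction boundaries", {
  set.seed(10)
  flank <- paste0(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
  anchor10 <- substr(flank, 31, 40)
  intronbody <- paste0(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                       collapse = "")
  # intron whose last 10 bases copy the left anchor's last 10: left score 0
  seqs <- c(chrH = paste0(flank, intronbody, anchor10, flank))
  start <- 40L; end <- 40L + 60L
  h <- hamming_scores(seqs, "chrH", start, end, window = 10L)
  expect_equal(h$left_hamming, 0L)
  expect_equal(h$min_hamming, 0L)

  # complementary alphabet windows differ everywhere
  seqs2 <- c(chrH = paste0(strrep("A", 20), strrep("C", 20), strrep("A", 20)))
  h2 <- hamming_scores(seqs2, "chrH", 20L, 40L, window = 10L)
  expect_equal(h2$left_hamming, 10L)
  expect_equal(h2$right_hamming, 10L)

  expect_error(hamming_scores(seqs2, "chrH", 20L, 40L, window = 0L),
               "parameter error")

  # random pairs agree with a brute-force character comparison
  set.seed(11)
  for (i in 1:50) {
    s <- paste0(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
    seqs3 <- c(chrR = s)
    st <- sample(20:40, 1); en <- st + sample(25:60, 1)
    h3 <- hamming_scores(seqs3, "chrR", st, en, window = 10L)
    expect_equal(h3$left_hamming,
                 oracle_hamming(substr(s, st - 9, st), substr(s, en - 9, en)))
    expect_equal(h3$right_hamming,
                 oracle_hamming(substr(s, st + 1, st + 10),
                                substr(s, en + 1, en + 10)))
    expect_equal(h3$min_hamming, min(h3$left_hamming, h3$right_hamming))
  }
})

test_that("hamming scores are symmetric under joint reverse-complement", {
  set.seed(12)
  s <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  seqs <- c(chrS = s)
  st <- 60L; en <- 140L
  fwd <- hamming_scores(seqs, "chrS", st, en, window = 10L)
  rc <- c(chrS = oracle_revcomp(s))
  L <- nchar(s)
  rev <- hamming_scores(rc, "chrS", L - en, L - st, window = 10L)
  # reverse-complement swaps the left and right windows
  expect_equal(rev$left_hamming, fwd$right_hamming)
  expect_equal(rev$right_hamming, fwd$left_hamming)
  expect_equal(rev$min_hamming, fwd$min_hamming)
})

test_that("intron-size model uses the nearest-rank 95th percentile", {
  m <- fit_intron_size(1:100)
  expect_equal(m$l95, 95)
  m2 <- fit_intron_size(rep(77L, 30))
  expect_equal(m2$l95, 77)
  expect_error(fit_intron_size(1:19), "training error")

  expect_equal(intron_size_score(50, m), 0)
  expect_equal(intron_size_score(95, m), 0)    # boundary inclusive
  expect_equal(intron_size_score(190, m), 1)   # doubling adds one bit
  # monotone non-decreasing, and zero on >= 95% of the training lengths
  lens <- sort(sample(30:5000, 200, replace = TRUE))
  m3 <- fit_intron_size(lens)
  sc <- intron_size_score(lens, m3)
  expect_true(all(diff(sc) >= 0))
  expect_gte(mean(sc == 0), 0.95)
})

test_that("PWM probabilities follow the pseudocount formula", {
  # 30 identical canonical training loci on one genome
  g <- make_intron_genome("GT", "AG", flank = 40L, intron = 100L)
  loci <- data.frame(contig = "chrM", start = rep(g$start, 30),
                     end = g$end, strand = "+")
  tiny <- train_pwm(g$seqs, loci, pseudocount = 1e-9)
  # with a vanishing pseudocount every observed base has probability ~1
  expect_equal(max(tiny$donor_matrix[, 4]), 1, tolerance = 1e-6)
  expect_equal(unname(tiny$donor_matrix["G", 4]), 1,
               tolerance = 1e-6)  # the G of GT

  # a position split between two bases: (n/2 + c) / (n + 4c)
  g2 <- make_intron_genome("GT", "AG", flank = 40L, intron = 100L, seed = 21L)
  both <- rbind(
    data.frame(contig = "chrM", start = g$start, end = g$end, strand = "+"),
    data.frame(contig = "chrM2", start = g2$start, end = g2$end,
               strand = "+"))
  seqs2 <- c(g$seqs, chrM2 = g2$seqs[["chrM"]])
  names(seqs2) <- c("chrM", "chrM2")
  pc <- 0.5
  m <- train_pwm(seqs2, both[rep(1:2, each = 10), ], pseudocount = pc)
  n <- 20
  b1 <- substr(g$seqs[["chrM"]], g$start - 2, g$start - 2)    # donor pos 1
  b2 <- substr(seqs2[["chrM2"]], g2$start - 2, g2$start - 2)
  if (b1 != b2) {
    expect_equal(unname(m$donor_matrix[b1, 1]), (n / 2 + pc) / (n + 4 * pc))
  }
  # huge pseudocount washes out to uniform
  flat <- train_pwm(seqs2, both[rep(1:2, each = 10), ], pseudocount = 1e7)
  expect_equal(as.numeric(flat$donor_matrix), rep(0.25, length(flat$donor_matrix)),
               tolerance = 1e-5)
  # per-position probabilities always sum to one
  expect_equal(colSums(m$donor_matrix), rep(1, ncol(m$donor_matrix)))
  expect_equal(colSums(m$acceptor_matrix), rep(1, ncol(m$acceptor_matrix)))
})

test_that("uniform model over uniform background scores zero", {
  g <- make_intron_genome("GT", "AG")
  model <- structure(list(
    donor_matrix = matrix(0.25, 4, 11,
                          dimnames = list(c("A", "C", "G", "T"), NULL)),
    acceptor_matrix = matrix(0.25, 4, 23,
                             dimnames = list(c("A", "C", "G", "T"), NULL)),
    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    pseudocount = 0.5, donor_window = c(-3L, 8L),
    acceptor_window = c(-20L, 3L), n_train = 20L), class = "jf_pwm")
  sc <- pwm_score(model, g$seqs,
                  data.frame(contig = "chrM", start = g$start, end = g$end,
                             strand = "+"))
  expect_equal(sc, 0)
  # a single enriched position contributes its log-odds exactly
  lift <- model
  donor_base <- substr(g$seqs[["chrM"]], g$start - 2, g$start - 2)
  lift$donor_matrix[, 1] <- 0.5 / 3
  lift$donor_matrix[donor_base, 1] <- 0.5
  sc2 <- pwm_score(lift, g$seqs,
                   data.frame(contig = "chrM", start = g$start, end = g$end,
                              strand = "+"))
  expect_equal(sc2, log2(0.5 / 0.25))
})

test_that("splicing signal is a positive-vs-negative likelihood contrast", {
  g <- make_intron_genome("GT", "AG")
  loci <- data.frame(contig = "chrM", start = rep(g$start, 25), end = g$end,
                     strand = "+")
  m <- train_pwm(g$seqs, loci)
  sc <- splicing_signal_score(m, m, g$seqs, loci[1, ])
  expect_equal(sc, 0)  # identical models cancel exactly
  # definitional decomposition: with both models trained on the same genome
  # (hence the same background), the signal equals the PWM-score difference
  g2 <- make_intron_genome("AA", "TT", seed = 33L)
  seqs_all <- c(g$seqs[["chrM"]], g2$seqs[["chrM"]])
  names(seqs_all) <- c("chrM", "chrN")
  pos_loci <- data.frame(contig = "chrM", start = rep(g$start, 25),
                         end = g$end, strand = "+")
  neg_loci <- data.frame(contig = "chrN", start = rep(g2$start, 25),
                         end = g2$end, strand = "+")
  pos <- train_pwm(seqs_all, pos_loci)
  neg <- train_pwm(seqs_all, neg_loci)
  probe <- pos_loci[1, ]
  s_pos <- pwm_score(pos, seqs_all, probe)
  s_neg <- pwm_score(neg, seqs_all, probe)
  sig <- splicing_signal_score(pos, neg, seqs_all, probe)
  expect_equal(sig, s_pos - s_neg, tolerance = 1e-9)
})

test_that("PWM models serialize to inspectable plain text", {
  g <- make_intron_genome("GT", "AG")
  loci <- data.frame(contig = "chrM", start = rep(g$start, 25), end = g$end,
                     strand = "+")
  m <- train_pwm(g$seqs, loci)
  f <- tempfile(fileext = ".pwm")
  write_pwm(m, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# donor_matrix$", lines)))
  expect_true(any(grepl("^# acceptor_matrix$", lines)))
  # 4 base rows per matrix, values parse back to the trained probabilities
  donor_a <- strsplit(grep("^A\t", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.numeric(donor_a[-1]), unname(m$donor_matrix["A", ]))
})

test_that("PWM training demands strand-resolved loci", {
  g <- make_intron_genome("AA", "TT")
  loci <- data.frame(contig = "chrM", start = rep(g$start, 25), end = g$end,
                     strand = "?")
  expect_error(train_pwm(g$seqs, loci), "training error")
  expect_error(train_pwm(g$seqs, loci[1:5, ]), "training error")
})
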