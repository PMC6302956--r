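# Genome-derived junction features: donor/acceptor dinucleotide composition
# with strand resolution, repeat hamming scores (windows anchored at the
# junction boundaries), the positive-set intron-size score, and position
# weight matrix / splicing-signal scores trained from the self-labelled sets.

CANONICAL_PAIRS <- c("GT-AG")
SEMI_CANONICAL_PAIRS <- c("GC-AG", "AT-AC")

pair_category <- function(donor, acceptor) {
  p <- paste0(donor, "-", acceptor)
  if (p %in% CANONICAL_PAIRS) return("canonical")
  if (p %in% SEMI_CANONICAL_PAIRS) return("semi_canonical")
  "novel"
}

#' Classify donor/acceptor splice sites and resolve strand
#'
#' Reads the first and last two intronic bases and tests the dinucleotide pair
#' both as-is (plus strand) and reverse-complemented (minus strand). The
#' strand resolving to a canonical pair (GT-AG) is preferred, then
#' semi-canonical (GC-AG, AT-AC); when neither strand matches, the category is
#' novel and the strand unknown. Ambiguous bases yield novel/unknown.
#'
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param contig,start,end Vectors describing intron loci (0-based half-open).
#' @return `data.table` with columns `donor`, `acceptor` (on the resolved
#'   strand; plus orientation when unknown), `site_category` and `strand`
#'   (`"+"`, `"-"`, `"?"`).
#' @export
classify_splice_sites <- function(genome, contig, start, end) {
  seqs <- load_genome(genome)
  n <- length(contig)
  stopifnot(length(start) == n, length(end) == n, all(end - start >= 4L))
  donor <- acceptor <- category <- strand <- character(n)
  for (i in seq_len(n)) {
    d_plus <- seq0(seqs, contig[i], start[i], start[i] + 2L)
    a_plus <- seq0(seqs, contig[i], end[i] - 2L, end[i])
    if (grepl("[^ACGT]", d_plus) || grepl("[^ACGT]", a_plus)) {
      donor[i] <- d_plus; acceptor[i] <- a_plus
      category[i] <- "novel"; strand[i] <- "?"
      next
    }
    d_minus <- revcomp(a_plus)
    a_minus <- revcomp(d_plus)
    cat_plus <- pair_category(d_plus, a_plus)
    cat_minus <- pair_category(d_minus, a_minus)
    rank <- c(canonical = 1L, semi_canonical = 2L, novel = 3L)
    if (rank[cat_plus] <= rank[cat_minus] && cat_plus != "novel") {
      donor[i] <- d_plus; acceptor[i] <- a_plus
      category[i] <- cat_plus; strand[i] <- "+"
    } else if (cat_minus != "novel") {
      donor[i] <- d_minus; acceptor[i] <- a_minus
      category[i] <- cat_minus; strand[i] <- "-"
    } else {
      donor[i] <- d_plus; acceptor[i] <- a_plus
      category[i] <- "novel"; strand[i] <- "?"
    }
  }
  data.table::data.table(donor = donor, acceptor = acceptor,
                         site_category = category, strand = strand)
}

#' Repeat hamming scores at the junction boundaries
#'
#' Compares the last `window` bases of the left anchor with the last `window`
#' bases of the intron (left score), and the first `window` bases of the
#' intron with the first `window` bases of the right anchor (right score). A
#' low score means the junction boundary sits in a repeat and the skip may be
#' repeat-triggered rather than a genuine intron. Windows are truncated
#' symmetrically where the contig or the intron is shorter than `window`.
#'
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param contig,start,end Vectors of intron loci (0-based half-open).
#' @param window Window width in bases (default 10).
#' @return `data.table` with `left_hamming`, `right_hamming`, `min_hamming`
#'   and the effective `hamming_window` used per locus.
#' @export
hamming_scores <- function(genome, contig, start, end, window = 10L) {
  if (window < 1L) stop("parameter error: hamming window must be >= 1")
  seqs <- load_genome(genome)
  n <- length(contig)
  left <- right <- win <- integer(n)
  for (i in seq_len(n)) {
    clen <- nchar(seqs[[contig[i]]])
    w <- min(window, end[i] - start[i], start[i], clen - end[i])
    win[i] <- w
    if (w <= 0L) {
      left[i] <- 0L; right[i] <- 0L
      next
    }
    left[i] <- hamming_string(
      seq0(seqs, contig[i], start[i] - w, start[i]),
      seq0(seqs, contig[i], end[i] - w, end[i]))
    right[i] <- hamming_string(
      seq0(seqs, contig[i], start[i], start[i] + w),
      seq0(seqs, contig[i], end[i], end[i] + w))
  }
  data.table::data.table(left_hamming = left, right_hamming = right,
                         min_hamming = pmin(left, right),
                         hamming_window = win)
}

#' Fit the positive-set intron-size model
#'
#' @param positive_lengths Intron lengths (bases) of the rule-derived positive
#'   set; at least 20 values are required.
#' @return Object of class `jf_intron_model` with field `l95`, the
#'   nearest-rank 95th percentile of the positive lengths.
#' @export
fit_intron_size <- function(positive_lengths) {
  lens <- as.numeric(positive_lengths)
  lens <- lens[!is.na(lens)]
  if (length(lens) < 20L) {
    stop("training error: need at least 20 positive intron lengths to fit ",
         "the intron-size model (have ", length(lens),
         "); consider relaxing the positive rules")
  }
  sorted <- sort(lens)
  l95 <- sorted[ceiling(0.95 * length(sorted))]
  structure(list(l95 = l95), class = "jf_intron_model")
}

#' Intron-size score
#'
#' Junctions whose intron is no longer than the positive set's 95th-percentile
#' length score 0; longer introns score `log2(length / l95)`, growing with
#' excess length.
#'
#' @param length Intron length(s) in bases.
#' @param model `jf_intron_model` from [fit_intron_size()].
#' @return Non-negative score(s).
#' @export
intron_size_score <- function(length, model) {
  stopifnot(inherits(model, "jf_intron_model"), all(length >= 1))
  ifelse(length <= model$l95, 0, log2(length / model$l95))
}

# transcript-oriented PWM window sequences for a set of loci; returns NA for
# loci with unknown strand or out-of-bounds windows
pwm_window_seqs <- function(seqs, contig, start, end, strand,
                            donor_window, acceptor_window) {
  n <- length(contig)
  donor <- acceptor <- rep(NA_character_, n)
  dw <- donor_window; aw <- acceptor_window
  for (i in seq_len(n)) {
    if (!strand[i] %in% c("+", "-")) next
    clen <- nchar(seqs[[contig[i]]])
    if (strand[i] == "+") {
      ds <- start[i] + dw[1L]; de <- start[i] + dw[2L]
      as_ <- end[i] + aw[1L]; ae <- end[i] + aw[2L]
      if (ds < 0L || de > clen || as_ < 0L || ae > clen) next
      donor[i] <- seq0(seqs, contig[i], ds, de)
      acceptor[i] <- seq0(seqs, contig[i], as_, ae)
    } else {
      # donor sits at the intron's right genomic edge on the minus strand
      ds <- end[i] - dw[2L]; de <- end[i] - dw[1L]
      as_ <- start[i] - aw[2L]; ae <- start[i] - aw[1L]
      if (ds < 0L || de > clen || as_ < 0L || ae > clen) next
      donor[i] <- revcomp(seq0(seqs, contig[i], ds, de))
      acceptor[i] <- revcomp(seq0(seqs, contig[i], as_, ae))
    }
  }
  list(donor = donor, acceptor = acceptor)
}

count_matrix <- function(sequences, width, pseudocount) {
  m <- matrix(0, nrow = 4L, ncol = width, dimnames = list(BASES, NULL))
  for (s in sequences) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (j in seq_len(width)) {
      b <- chars[j]
      if (b %in% BASES) m[b, j] <- m[b, j] + 1
    }
  }
  n <- length(sequences)
  (m + pseudocount) / (n + 4 * pseudocount)
}

#' Train donor/acceptor position weight matrices
#'
#' Builds per-position nucleotide probability matrices over windows around the
#' donor and acceptor sites of the supplied loci, in transcript orientation
#' (negative window offsets are exonic). Probabilities are
#' `(count + pseudocount) / (n + 4 pseudocount)`; the background is the
#' genome-wide mononucleotide frequency.
#'
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param loci data.frame with columns `contig`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`; unknown-strand loci are skipped).
#' @param donor_window,acceptor_window `c(upstream, downstream)` offsets
#'   around the splice site (defaults `c(-3, 8)` and `c(-20, 3)`).
#' @param pseudocount Pseudocount per nucleotide (default 0.5).
#' @return Object of class `jf_pwm` with fields `donor_matrix`,
#'   `acceptor_matrix`, `background`, `pseudocount`, `n_train`, and the
#'   windows.
#' @export
train_pwm <- function(genome, loci, donor_window = c(-3L, 8L),
                      acceptor_window = c(-20L, 3L), pseudocount = 0.5) {
  stopifnot(pseudocount > 0)
  seqs <- load_genome(genome)
  loci <- as.data.frame(loci)
  if (nrow(loci) < 20L) {
    stop("training error: need at least 20 loci to train a PWM (have ",
         nrow(loci), ")")
  }
  win <- pwm_window_seqs(seqs, loci$contig, loci$start, loci$end, loci$strand,
                         donor_window, acceptor_window)
  ok <- !is.na(win$donor) & !is.na(win$acceptor) &
    !grepl("[^ACGT]", win$donor) & !grepl("[^ACGT]", win$acceptor)
  if (!any(ok)) {
    stop("training error: no stranded loci with extractable windows; ",
         "all training loci were skipped")
  }
  dwidth <- donor_window[2L] - donor_window[1L]
  awidth <- acceptor_window[2L] - acceptor_window[1L]
  donor_m <- count_matrix(win$donor[ok], dwidth, pseudocount)
  acceptor_m <- count_matrix(win$acceptor[ok], awidth, pseudocount)

  all_bases <- table(factor(strsplit(paste0(seqs, collapse = ""), "",
                                     fixed = TRUE)[[1L]], levels = BASES))
  bg <- as.numeric(all_bases) / sum(all_bases)
  names(bg) <- BASES
  bg[bg <= 0] <- 1e-9
  bg <- bg / sum(bg)

  structure(list(donor_matrix = donor_m, acceptor_matrix = acceptor_m,
                 background = bg, pseudocount = pseudocount,
                 donor_window = donor_window,
                 acceptor_window = acceptor_window,
                 n_train = sum(ok)),
            class = "jf_pwm")
}

#' @export
print.jf_pwm <- function(x, ...) {
  cat("splice-site PWM (", x$n_train, " training loci)\n", sep = "")
  cat("donor window [", x$donor_window[1L], ",", x$donor_window[2L],
      "), acceptor window [", x$acceptor_window[1L], ",",
      x$acceptor_window[2L], ")\n", sep = "")
  invisible(x)
}

#' Write a PWM to a plain-text matrix file
#'
#' @param model `jf_pwm` object.
#' @param path Output path.
#' @export
write_pwm <- function(model, path) {
  stopifnot(inherits(model, "jf_pwm"))
  lines <- c(
    paste0("## junctionfilter pwm v", JF_FORMAT_VERSION),
    paste0("## donor_window\t", model$donor_window[1L], "\t",
           model$donor_window[2L]),
    paste0("## acceptor_window\t", model$acceptor_window[1L], "\t",
           model$acceptor_window[2L]),
    paste0("## pseudocount\t", num2str(model$pseudocount)),
    paste0("## background\t", paste(num2str(model$background), collapse = "\t")))
  for (part in c("donor_matrix", "acceptor_matrix")) {
    m <- model[[part]]
    lines <- c(lines, paste0("# ", part))
    for (b in BASES) {
      lines <- c(lines, paste(c(b, num2str(m[b, ])), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# log2 likelihood of windows under a PWM model (sum over donor + acceptor)
pwm_loglik <- function(model, donor_seq, acceptor_seq) {
  ll <- 0
  for (part in list(list(m = model$donor_matrix, s = donor_seq),
                    list(m = model$acceptor_matrix, s = acceptor_seq))) {
    chars <- strsplit(part$s, "", fixed = TRUE)[[1L]]
    for (j in seq_along(chars)) {
      b <- chars[j]
      if (b %in% BASES) ll <- ll + log2(part$m[b, j])
    }
  }
  ll
}

pwm_bg_loglik <- function(model, donor_seq, acceptor_seq) {
  ll <- 0
  for (s in c(donor_seq, acceptor_seq)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (b in chars) if (b %in% BASES) ll <- ll + log2(model$background[[b]])
  }
  ll
}

#' Position-weight-matrix score of junctions
#'
#' Sum over the donor and acceptor window positions of
#' `log2(p_model(base) / p_background(base))`. Loci with unknown strand are
#' scored on both strands and the maximum is taken; windows that fall outside
#' the contig contribute 0.
#'
#' @param model `jf_pwm` from [train_pwm()].
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param loci data.frame with `contig`, `start`, `end`, `strand`.
#' @return Numeric score per locus (bits).
#' @export
pwm_score <- function(model, genome, loci) {
  stopifnot(inherits(model, "jf_pwm"))
  seqs <- load_genome(genome)
  loci <- as.data.frame(loci)
  score_one <- function(contig, start, end, strand) {
    win <- pwm_window_seqs(seqs, contig, start, end, strand,
                           model$donor_window, model$acceptor_window)
    if (is.na(win$donor[1L]) || is.na(win$acceptor[1L])) return(NA_real_)
    pwm_loglik(model, win$donor[1L], win$acceptor[1L]) -
      pwm_bg_loglik(model, win$donor[1L], win$acceptor[1L])
  }
  n <- nrow(loci)
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- loci$strand[i]
    if (st %in% c("+", "-")) {
      v <- score_one(loci$contig[i], loci$start[i], loci$end[i], st)
    } else {
      v <- max(score_one(loci$contig[i], loci$start[i], loci$end[i], "+"),
               score_one(loci$contig[i], loci$start[i], loci$end[i], "-"),
               na.rm = TRUE)
      if (!is.finite(v)) v <- NA_real_
    }
    out[i] <- if (is.na(v)) 0 else v
  }
  out
}

#' Splicing-signal score of junctions
#'
#' Log-likelihood of the donor/acceptor windows under the positive-set PWM
#' minus that under the negative-set PWM — the strength of the splicing signal
#' relative to the background of rule-rejected junctions. Unknown-strand loci
#' take the maximum over both strands.
#'
#' @param pos_model,neg_model `jf_pwm` models trained on the positive and
#'   negative self-labelled sets (same windows).
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param loci data.frame with `contig`, `start`, `end`, `strand`.
#' @return Numeric score per locus (bits).
#' @export
splicing_signal_score <- function(pos_model, neg_model, genome, loci) {
  stopifnot(inherits(pos_model, "jf_pwm"), inherits(neg_model, "jf_pwm"),
            identical(pos_model$donor_window, neg_model$donor_window),
            identical(pos_model$acceptor_window, neg_model$acceptor_window))
  seqs <- load_genome(genome)
  loci <- as.data.frame(loci)
  score_one <- function(contig, start, end, strand) {
    win <- pwm_window_seqs(seqs, contig, start, end, strand,
                           pos_model$donor_window, pos_model$acceptor_window)
    if (is.na(win$donor[1L]) || is.na(win$acceptor[1L])) return(NA_real_)
    pwm_loglik(pos_model, win$donor[1L], win$acceptor[1L]) -
      pwm_loglik(neg_model, win$donor[1L], win$acceptor[1L])
  }
  n <- nrow(loci)
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- loci$strand[i]
    if (st %in% c("+", "-")) {
      v <- score_one(loci$contig[i], loci$start[i], loci$end[i], st)
    } else {
      v <- max(score_one(loci$contig[i], loci$start[i], loci$end[i], "+"),
               score_one(loci$contig[i], loci$start[i], loci$end[i], "-"),
               na.rm = TRUE)
      if (!is.finite(v)) v <- NA_real_
    }
    out[i] <- if (is.na(v)) 0 else v
  }
  out
}

#' Annotate a junction table with splice-site and hamming metrics
#'
#' Convenience driver used by the pipeline: adds `donor`, `acceptor`,
#' `site_category`, resolved `strand`, and the hamming repeat scores to an
#' [analyze_junctions()] table.
#'
#' @param junctions Junction metric table.
#' @param genome Genome (path, named character vector, or `DNAStringSet`).
#' @param hamming_window Window width for [hamming_scores()].
#' @return The table with added columns (modified by reference and returned).
#' @export
add_site_metrics <- function(junctions, genome, hamming_window = 10L) {
  seqs <- load_genome(genome)
  sites <- classify_splice_sites(seqs, junctions$contig, junctions$start,
                                 junctions$end)
  ham <- hamming_scores(seqs, junctions$contig, junctions$start,
                        junctions$end, window = hamming_window)
  junctions[, `:=`(donor = sites$donor, acceptor = sites$acceptor,
                   site_category = sites$site_category,
                   strand = sites$strand,
                   left_hamming = ham$left_hamming,
                   right_hamming = ham$right_hamming,
                   min_hamming = ham$min_hamming)]
  junctions[]
}
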