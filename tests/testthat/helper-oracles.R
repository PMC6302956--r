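# Independent brute-force oracles. These deliberately re-derive each metric
# by naive looping / direct formula evaluation, sharing no code with the
# package implementations.

oracle_entropy <- function(counts) {
  total <- 0
  for (c in counts) total <- total + c
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / total
      h <- h - p * log(p) / log(2)
    }
  }
  h
}

oracle_deviations <- function(offsets, n_offsets, positions = 20) {
  n <- length(offsets)
  a <- min(n_offsets, positions)
  e <- n / a
  out <- numeric(positions)
  for (i in seq_len(positions)) {
    if (i <= a) {
      o <- 0
      for (x in offsets) if (x == i) o <- o + 1
      out[i] <- abs(o - e) / sqrt(e)
    }
  }
  out
}

oracle_max_overhang <- function(left, right) {
  best <- -Inf
  for (i in seq_along(left)) {
    m <- if (left[i] < right[i]) left[i] else right[i]
    if (m > best) best <- m
  }
  best
}

oracle_maxmmes <- oracle_max_overhang

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- 0
  for (i in seq_along(ca)) if (ca[i] != cb[i]) d <- d + 1
  d
}

oracle_intron_score <- function(len, l95) {
  if (len <= l95) 0 else log(len / l95) / log(2)
}

oracle_nearest_rank_p95 <- function(lengths) {
  s <- sort(lengths)
  s[ceiling(0.95 * length(s))]
}

# independent reverse complement
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# independent PWM window extraction + log-odds scoring; negative window
# offsets are upstream of the splice site in transcript orientation
oracle_pwm_windows <- function(genome_str, start, end, strand, dw, aw) {
  if (strand == "+") {
    donor <- substr(genome_str, start + dw[1] + 1, start + dw[2])
    acceptor <- substr(genome_str, end + aw[1] + 1, end + aw[2])
  } else {
    donor <- oracle_revcomp(substr(genome_str, end - dw[2] + 1, end - dw[1]))
    acceptor <- oracle_revcomp(substr(genome_str, start - aw[2] + 1,
                                      start - aw[1]))
  }
  list(donor = donor, acceptor = acceptor)
}

oracle_pwm_score <- function(model, genome_str, start, end, strand) {
  win <- oracle_pwm_windows(genome_str, start, end, strand,
                            model$donor_window, model$acceptor_window)
  total <- 0
  for (part in list(c("donor_matrix", win$donor),
                    c("acceptor_matrix", win$acceptor))) {
    m <- model[[part[1]]]
    chars <- strsplit(part[2], "")[[1]]
    for (j in seq_along(chars)) {
      b <- chars[j]
      total <- total + log(m[b, j] / model$background[[b]]) / log(2)
    }
  }
  total
}
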