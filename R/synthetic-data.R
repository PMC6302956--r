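# Synthetic fixture generation: a small multi-contig genome with planted
# canonical introns, spliced reads over genuine junctions with near-uniform
# anchor offsets, and spurious junctions reproducing the characteristic
# false-positive signatures (stacked low-entropy support, non-canonical
# dinucleotides, repeat-induced misalignment, single-read support with a
# mismatch hard against the junction). Everything is written as plain-text
# standard formats (FASTA, GFF3, BED, SAM) and is byte-reproducible under a
# fixed seed.

SPURIOUS_ARCHETYPES <- c("low_entropy", "non_canonical", "repeat_induced",
                         "single_read")

#' Specification of a synthetic junction fixture
#'
#' Defaults describe the standard study conditions: 2 contigs of 100 kb, 300
#' genuine junctions at 30x split-read coverage with 76-base reads and a 0.5%
#' per-base mismatch rate, plus 75 spurious junctions of each archetype.
#' Intron lengths are log-normal (median ~100 bases) clamped to
#' `[intron_min, intron_max]`.
#'
#' @param seed Integer seed; the whole fixture is a deterministic function of
#'   the spec.
#' @param n_contigs,contig_length Genome shape.
#' @param n_genuine Number of genuine junctions.
#' @param n_spurious Named integer vector of spurious counts per archetype
#'   (`low_entropy`, `non_canonical`, `repeat_induced`, `single_read`).
#' @param read_length Read length in bases.
#' @param coverage Split reads per genuine junction.
#' @param mismatch_rate Per-base substitution rate in `[0, 1)`.
#' @param intron_meanlog,intron_sdlog,intron_min,intron_max Intron length
#'   distribution (log-normal, clamped).
#' @param min_anchor Minimum anchor length of generated reads.
#' @return Object of class `jf_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, contig_length = 100000L,
                         n_genuine = 300L,
                         n_spurious = c(low_entropy = 75L,
                                        non_canonical = 75L,
                                        repeat_induced = 75L,
                                        single_read = 75L),
                         read_length = 76L, coverage = 30L,
                         mismatch_rate = 0.005,
                         intron_meanlog = log(100), intron_sdlog = 0.5,
                         intron_min = 61L, intron_max = 1500L,
                         min_anchor = 8L) {
  if (mismatch_rate < 0 || mismatch_rate >= 1) {
    stop("parameter error: mismatch_rate must be in [0, 1)")
  }
  if (read_length < 2L * min_anchor) {
    stop("parameter error: reads shorter than twice the minimum anchor (",
         read_length, " < 2*", min_anchor, ")")
  }
  ns <- n_spurious
  if (is.null(names(ns)) || !all(names(ns) %in% SPURIOUS_ARCHETYPES)) {
    stop("n_spurious must be named with archetypes: ",
         paste(SPURIOUS_ARCHETYPES, collapse = ", "))
  }
  full <- stats::setNames(integer(length(SPURIOUS_ARCHETYPES)),
                          SPURIOUS_ARCHETYPES)
  full[names(ns)] <- as.integer(ns)
  stopifnot(all(full >= 0L), n_genuine >= 0L, coverage >= 1L)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genuine = as.integer(n_genuine), n_spurious = full,
                 read_length = as.integer(read_length),
                 coverage = as.integer(coverage),
                 mismatch_rate = mismatch_rate,
                 intron_meanlog = intron_meanlog,
                 intron_sdlog = intron_sdlog,
                 intron_min = as.integer(intron_min),
                 intron_max = as.integer(intron_max),
                 min_anchor = as.integer(min_anchor)),
            class = "jf_fixture_spec")
}

random_seq <- function(n) {
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

replace_bases <- function(seqstr, start0, replacement) {
  # overwrite bases at 0-based position start0
  paste0(substr(seqstr, 1L, start0),
         replacement,
         substr(seqstr, start0 + nchar(replacement) + 1L, nchar(seqstr)))
}

# place loci greedily along contigs; errors when the genome cannot hold them
place_loci <- function(spec, intron_lengths) {
  n <- length(intron_lengths)
  flank <- spec$read_length + 10L
  gap <- 20L
  contig <- character(n); start <- integer(n); end <- integer(n)
  ci <- 1L
  cursor <- flank + 50L
  for (i in seq_len(n)) {
    len <- intron_lengths[i]
    while (cursor + len + flank + gap > spec$contig_length) {
      ci <- ci + 1L
      cursor <- flank + 50L
      if (ci > spec$n_contigs) {
        stop("parameter error: fixture spec is infeasible - the genome is ",
             "too small for the requested junctions")
      }
    }
    contig[i] <- paste0("ctg", ci)
    start[i] <- cursor
    end[i] <- cursor + len
    cursor <- cursor + len + flank + gap
  }
  data.table::data.table(contig = contig, start = start, end = end)
}

# preallocated read collector; avoids per-read table construction
read_accumulator <- function(capacity, qname_prefix = "read") {
  k <- 0L
  qname <- character(capacity); flag <- integer(capacity)
  rname <- character(capacity); pos1 <- integer(capacity)
  mapq <- integer(capacity); cigar <- character(capacity)
  seqv <- character(capacity); nh <- integer(capacity)
  add <- function(genome, contig, s, e, a, read_length, reliable, nh_val,
                  mapq_val, seqstr = NULL) {
    r <- make_read(genome, contig, s, e, a, read_length)
    k <<- k + 1L
    qname[k] <<- sprintf("%s%06d", qname_prefix, k)
    flag[k] <<- if (reliable) 67L else 65L  # paired+first, +proper if reliable
    rname[k] <<- contig
    pos1[k] <<- r$pos1
    mapq[k] <<- mapq_val
    cigar[k] <<- r$cigar
    seqv[k] <<- if (is.null(seqstr)) r$seq else seqstr
    nh[k] <<- nh_val
  }
  table <- function() {
    idx <- seq_len(k)
    data.table::data.table(qname = qname[idx], flag = flag[idx],
                           rname = rname[idx], pos1 = pos1[idx],
                           mapq = mapq[idx], cigar = cigar[idx],
                           seq = seqv[idx], nh = nh[idx])
  }
  list(add = function(genome, contig, s, e, a, read_length, reliable, nh,
                      mapq, seqstr = NULL)
         add(genome, contig, s, e, a, read_length, reliable, nh, mapq,
             seqstr),
       table = table)
}

make_read <- function(genome, contig, s, e, a, read_length) {
  left <- substr(genome[[contig]], s - a + 1L, s)
  right <- substr(genome[[contig]], e + 1L, e + read_length - a)
  list(seq = paste0(left, right),
       pos1 = s - a + 1L,
       cigar = paste0(a, "M", e - s, "N", read_length - a, "M"))
}

#' Generate a complete synthetic fixture
#'
#' Builds a genome with planted introns, generates split reads over every
#' planted junction, applies the per-base mismatch rate, and writes the
#' genome FASTA, a GFF3 annotation of the genuine genes, a truth intron BED,
#' a table of planted spurious junctions with their archetypes, and a
#' coordinate-sorted SAM file.
#'
#' Genuine junctions carry GT-AG sites (half on each strand), near-uniform
#' anchor-start offsets and coverage-proportional reliable support. Each
#' spurious archetype violates exactly its designated signature:
#' `low_entropy` junctions stack a few reads on one offset; `non_canonical`
#' junctions have novel boundary dinucleotides and minimal support;
#' `repeat_induced` junctions sit in a planted 12-base repeat so their
#' minimum hamming score is 0; `single_read` junctions are supported by one
#' non-unique read with a mismatch three bases from the junction.
#'
#' @param spec `jf_fixture_spec`.
#' @param output_dir Directory the files are written to.
#' @return Object of class `jf_fixture`: file paths (`genome`, `annotation`,
#'   `truth_bed`, `spurious_tab`, `sam`), the in-memory `truth` and
#'   `spurious` tables, and the genome as a named character vector.
#' @export
generate_fixture <- function(spec, output_dir = tempfile("jf_fixture_")) {
  stopifnot(inherits(spec, "jf_fixture_spec"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  set.seed(spec$seed)

  n_spur <- sum(spec$n_spurious)
  n_total <- spec$n_genuine + n_spur

  genome <- stats::setNames(
    vapply(seq_len(spec$n_contigs), function(i) random_seq(spec$contig_length),
           character(1L)),
    paste0("ctg", seq_len(spec$n_contigs)))

  lens <- pmin(pmax(round(stats::rlnorm(n_total, spec$intron_meanlog,
                                        spec$intron_sdlog)),
                    spec$intron_min), spec$intron_max)
  loci <- place_loci(spec, lens)
  type <- c(rep("genuine", spec$n_genuine),
            rep(names(spec$n_spurious), spec$n_spurious))
  loci[, type := sample(type)]
  loci[, strand := "+"]
  loci[type == "genuine", strand := sample(c("+", "-"), .N, replace = TRUE)]

  # plant splice-site dinucleotides and repeat signatures
  for (i in seq_len(nrow(loci))) {
    ct <- loci$contig[i]; s <- loci$start[i]; e <- loci$end[i]
    tp <- loci$type[i]
    if (tp %in% c("genuine", "low_entropy", "single_read")) {
      if (loci$strand[i] == "+") {
        genome[[ct]] <- replace_bases(genome[[ct]], s, "GT")
        genome[[ct]] <- replace_bases(genome[[ct]], e - 2L, "AG")
      } else {
        genome[[ct]] <- replace_bases(genome[[ct]], s, "CT")
        genome[[ct]] <- replace_bases(genome[[ct]], e - 2L, "AC")
      }
    } else if (tp == "non_canonical") {
      # AA..TT is novel on both strands (its reverse complement is AA..TT)
      genome[[ct]] <- replace_bases(genome[[ct]], s, "AA")
      genome[[ct]] <- replace_bases(genome[[ct]], e - 2L, "TT")
    } else if (tp == "repeat_induced") {
      # copy the 12 bases left of the junction over the intron's last 12:
      # the left-anchor and intron-edge hamming windows become identical
      block <- substr(genome[[ct]], s - 11L, s)
      genome[[ct]] <- replace_bases(genome[[ct]], e - 12L, block)
    }
  }

  # reads
  L <- spec$read_length
  qual <- strrep("I", L)
  acc <- read_accumulator(spec$n_genuine * spec$coverage + 4L * n_spur + 8L)
  for (i in seq_len(nrow(loci))) {
    ct <- loci$contig[i]; s <- loci$start[i]; e <- loci$end[i]
    tp <- loci$type[i]
    if (tp == "genuine") {
      offs <- sample(seq.int(spec$min_anchor, L - spec$min_anchor),
                     spec$coverage, replace = TRUE)
      for (a in offs) acc$add(genome, ct, s, e, a, L, reliable = TRUE,
                              nh = 1L, mapq = 60L)
    } else if (tp == "low_entropy") {
      a <- as.integer(L / 2L)
      for (k in 1:4) acc$add(genome, ct, s, e, a, L, reliable = FALSE,
                             nh = 4L, mapq = 3L)
    } else if (tp == "non_canonical") {
      n_r <- sample(1:2, 1L)
      offs <- sample(seq.int(spec$min_anchor, L - spec$min_anchor), n_r)
      for (a in offs) acc$add(genome, ct, s, e, a, L, reliable = FALSE,
                              nh = 3L, mapq = 2L)
    } else if (tp == "repeat_induced") {
      offs <- sample(seq.int(spec$min_anchor, L - spec$min_anchor), 3L)
      for (a in offs) acc$add(genome, ct, s, e, a, L, reliable = FALSE,
                              nh = 5L, mapq = 1L)
    } else if (tp == "single_read") {
      a <- sample(seq.int(spec$min_anchor + 4L, L - spec$min_anchor), 1L)
      r <- make_read(genome, ct, s, e, a, L)
      # plant a substitution three bases upstream of the junction, so the
      # left-side mismatch-truncated match is 2
      p <- a - 2L
      orig <- substr(r$seq, p, p)
      substr(r$seq, p, p) <- sample(setdiff(BASES, orig), 1L)
      acc$add(genome, ct, s, e, a, L, reliable = FALSE, nh = 3L, mapq = 2L,
              seqstr = r$seq)
    }
  }
  reads <- acc$table()

  # sequencing errors
  if (spec$mismatch_rate > 0) {
    reads <- corrupt_read_table(reads, genome, spec$mismatch_rate)
  }
  reads[, nm := nm_against_genome(seq, rname, pos1, cigar, genome)]

  data.table::setorderv(reads, c("rname", "pos1", "qname"))

  paths <- list(
    genome = file.path(output_dir, "genome.fa"),
    annotation = file.path(output_dir, "annotation.gff3"),
    truth_bed = file.path(output_dir, "truth_introns.bed"),
    spurious_tab = file.path(output_dir, "truth_spurious.tsv"),
    sam = file.path(output_dir, "reads.sam"))

  # FASTA (60-column wrap)
  fa <- unlist(lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    c(paste0(">", nm),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
  }))
  writeLines(fa, paths$genome)

  truth <- loci[type == "genuine", .(contig, start, end, strand)]
  truth[, id := sprintf("TRUE%05d", seq_len(.N))]
  spurious <- loci[type != "genuine",
                   .(contig, start, end, strand = "?", archetype = type)]
  spurious[, id := sprintf("FALSE%05d", seq_len(.N))]

  # annotation: one two-exon gene per genuine intron
  gff <- c("##gff-version 3")
  flank <- 60L
  for (i in seq_len(nrow(truth))) {
    ct <- truth$contig[i]; s <- truth$start[i]; e <- truth$end[i]
    st <- truth$strand[i]
    gid <- paste0("gene", i); tid <- paste0("tx", i)
    gff <- c(gff,
      paste(ct, "synthetic", "gene", s - flank + 1L, e + flank, ".", st, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(ct, "synthetic", "mRNA", s - flank + 1L, e + flank, ".", st, ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"),
      paste(ct, "synthetic", "exon", s - flank + 1L, s, ".", st, ".",
            paste0("ID=", tid, ".e1;Parent=", tid), sep = "\t"),
      paste(ct, "synthetic", "exon", e + 1L, e + flank, ".", st, ".",
            paste0("ID=", tid, ".e2;Parent=", tid), sep = "\t"))
  }
  writeLines(gff, paths$annotation)

  writeLines(paste(truth$contig, truth$start, truth$end, truth$id, 0,
                   truth$strand, sep = "\t"), paths$truth_bed)
  writeLines(c(paste("contig", "start", "end", "strand", "archetype", "id",
                     sep = "\t"),
               paste(spurious$contig, spurious$start, spurious$end,
                     spurious$strand, spurious$archetype, spurious$id,
                     sep = "\t")), paths$spurious_tab)

  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  nchar(genome)),
           paste(reads$qname, reads$flag, reads$rname, reads$pos1,
                 reads$mapq, reads$cigar, "=", reads$pos1, 0, reads$seq,
                 qual, paste0("NM:i:", reads$nm), paste0("NH:i:", reads$nh),
                 sep = "\t"))
  writeLines(sam, paths$sam)

  structure(list(spec = spec, paths = paths, truth = truth[],
                 spurious = spurious[], genome = genome,
                 n_reads = nrow(reads)),
            class = "jf_fixture")
}

#' @export
print.jf_fixture <- function(x, ...) {
  cat("synthetic junction fixture: ", nrow(x$truth), " genuine + ",
      nrow(x$spurious), " spurious junctions, ", x$n_reads, " reads\n",
      sep = "")
  invisible(x)
}

# vectorized NM recomputation: per-read mismatch count against the genome
nm_against_genome <- function(seq, rname, pos1, cigar, genome) {
  n <- length(seq)
  nm <- integer(n)
  ops_all <- parse_cigar(cigar)
  for (i in seq_len(n)) {
    ops <- ops_all[[i]]
    rpos <- pos1[i] - 1L
    qpos <- 0L
    mm <- 0L
    cseq <- genome[[rname[i]]]
    for (k in seq_along(ops$len)) {
      l <- ops$len[k]; o <- ops$op[k]
      if (o %in% c("M", "=", "X")) {
        g <- charToRaw(substr(cseq, rpos + 1L, rpos + l))
        r <- charToRaw(substr(seq[i], qpos + 1L, qpos + l))
        mm <- mm + sum(g != r)
        rpos <- rpos + l; qpos <- qpos + l
      } else if (o == "I") { mm <- mm + l; qpos <- qpos + l }
      else if (o == "D") { mm <- mm + l; rpos <- rpos + l }
      else if (o == "N") rpos <- rpos + l
      else if (o == "S") qpos <- qpos + l
    }
    nm[i] <- mm
  }
  nm
}

# substitution noise on an in-memory read table (RNG state of the caller)
corrupt_read_table <- function(reads, genome, rate) {
  L <- nchar(reads$seq)
  for (i in seq_len(nrow(reads))) {
    hits <- which(stats::runif(L[i]) < rate)
    if (length(hits) == 0L) next
    s <- reads$seq[i]
    for (p in hits) {
      orig <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(BASES, orig), 1L)
    }
    reads$seq[i] <- s
  }
  reads
}

#' Apply substitution noise to a SAM file
#'
#' Substitutes bases of every aligned read at the given per-base rate and
#' rewrites the edit-distance (`NM`) tags consistently with the mutated
#' sequences versus the genome. A rate of 0 returns the input unchanged
#' (modulo tag recomputation).
#'
#' @param sam_path Input SAM path.
#' @param genome Genome (path or named character vector).
#' @param mismatch_rate Per-base substitution rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param out_path Output SAM path (default: overwrite input).
#' @return `out_path`, invisibly.
#' @export
corrupt_reads <- function(sam_path, genome, mismatch_rate, seed = 1L,
                          out_path = sam_path) {
  if (mismatch_rate < 0 || mismatch_rate >= 1) {
    stop("parameter error: mismatch_rate must be in [0, 1)")
  }
  genome <- load_genome(genome)
  lines <- readLines(sam_path)
  hdr <- grepl("^@", lines)
  body <- lines[!hdr]
  if (length(body) == 0L) {
    writeLines(lines, out_path)
    return(invisible(out_path))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  set.seed(seed)
  out_body <- character(length(body))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    seqstr <- f[10L]
    if (mismatch_rate > 0 && seqstr != "*") {
      hits <- which(stats::runif(nchar(seqstr)) < mismatch_rate)
      for (p in hits) {
        orig <- substr(seqstr, p, p)
        substr(seqstr, p, p) <- sample(setdiff(BASES, orig), 1L)
      }
      f[10L] <- seqstr
    }
    if (seqstr != "*" && f[3L] != "*") {
      nm <- nm_against_genome(f[10L], f[3L], as.integer(f[4L]), f[6L], genome)
      nm_idx <- grep("^NM:i:", f)
      if (length(nm_idx) > 0L) f[nm_idx[1L]] <- paste0("NM:i:", nm)
      else f <- c(f, paste0("NM:i:", nm))
    }
    out_body[i] <- paste(f, collapse = "\t")
  }
  writeLines(c(lines[hdr], out_body), out_path)
  invisible(out_path)
}

#' Generate related fixtures for several samples
#'
#' Builds one genome and one planted truth, then emits per-sample SAM files in
#' which a core fraction of the genuine junctions is expressed in every
#' sample and the remainder is distributed round-robin across samples;
#' spurious junctions are likewise split so each sample carries its own
#' artifacts. Used to study merged-alignment versus per-sample-union
#' filtering.
#'
#' @param spec `jf_fixture_spec` (its `seed` drives everything).
#' @param n_samples Number of samples.
#' @param shared_fraction Fraction of genuine junctions present in all
#'   samples (default 0.7).
#' @return List of class `jf_multi_fixture`: the base `fixture` (whose SAM
#'   covers all planted junctions and serves as the merged-equivalent input),
#'   `sample_sams` (paths), and per-sample truth tables.
#' @export
generate_multi_sample_fixture <- function(spec, n_samples = 3L,
                                          shared_fraction = 0.7) {
  stopifnot(inherits(spec, "jf_fixture_spec"), n_samples >= 2L,
            shared_fraction > 0, shared_fraction <= 1)
  base_dir <- tempfile("jf_multi_")
  fx <- generate_fixture(spec, base_dir)

  set.seed(spec$seed + 1000L)
  n_g <- nrow(fx$truth)
  core <- sort(sample.int(n_g, round(shared_fraction * n_g)))
  rest <- setdiff(seq_len(n_g), core)
  rest_owner <- rep_len(seq_len(n_samples), length(rest))

  n_s <- nrow(fx$spurious)
  spur_owner <- rep_len(seq_len(n_samples), n_s)

  sample_sams <- character(n_samples)
  sample_truth <- vector("list", n_samples)
  for (si in seq_len(n_samples)) {
    genuine_idx <- sort(c(core, rest[rest_owner == si]))
    spur_idx <- which(spur_owner == si)
    truth_si <- fx$truth[genuine_idx]
    spur_si <- fx$spurious[spur_idx]
    sub_spec <- spec
    sub_spec$seed <- spec$seed + si
    sam <- write_sample_sam(fx, truth_si, spur_si, sub_spec,
                            file.path(base_dir,
                                      sprintf("sample%02d.sam", si)))
    sample_sams[si] <- sam
    sample_truth[[si]] <- truth_si
  }
  structure(list(fixture = fx, sample_sams = sample_sams,
                 sample_truth = sample_truth,
                 core_truth = fx$truth[core]),
            class = "jf_multi_fixture")
}

# regenerate reads for a subset of planted junctions (shared genome)
write_sample_sam <- function(fx, truth_si, spur_si, spec, sam_path) {
  set.seed(spec$seed)
  genome <- fx$genome
  L <- spec$read_length
  qual <- strrep("I", L)
  acc <- read_accumulator(nrow(truth_si) * spec$coverage +
                            4L * nrow(spur_si) + 8L,
                          qname_prefix = sprintf("s%dread", spec$seed))
  for (i in seq_len(nrow(truth_si))) {
    offs <- sample(seq.int(spec$min_anchor, L - spec$min_anchor),
                   spec$coverage, replace = TRUE)
    for (a in offs) acc$add(genome, truth_si$contig[i], truth_si$start[i],
                            truth_si$end[i], a, L, TRUE, 1L, 60L)
  }
  for (i in seq_len(nrow(spur_si))) {
    ct <- spur_si$contig[i]; s <- spur_si$start[i]; e <- spur_si$end[i]
    tp <- spur_si$archetype[i]
    if (tp == "low_entropy") {
      a <- as.integer(L / 2L)
      for (k in 1:4) acc$add(genome, ct, s, e, a, L, FALSE, 4L, 3L)
    } else if (tp == "non_canonical") {
      for (a in sample(seq.int(spec$min_anchor, L - spec$min_anchor),
                       sample(1:2, 1L)))
        acc$add(genome, ct, s, e, a, L, FALSE, 3L, 2L)
    } else if (tp == "repeat_induced") {
      for (a in sample(seq.int(spec$min_anchor, L - spec$min_anchor), 3L))
        acc$add(genome, ct, s, e, a, L, FALSE, 5L, 1L)
    } else {
      a <- sample(seq.int(spec$min_anchor + 4L, L - spec$min_anchor), 1L)
      r <- make_read(genome, ct, s, e, a, L)
      p <- a - 2L
      orig <- substr(r$seq, p, p)
      substr(r$seq, p, p) <- sample(setdiff(BASES, orig), 1L)
      acc$add(genome, ct, s, e, a, L, FALSE, 3L, 2L, seqstr = r$seq)
    }
  }
  reads <- acc$table()
  if (spec$mismatch_rate > 0) {
    reads <- corrupt_read_table(reads, genome, spec$mismatch_rate)
  }
  reads[, nm := nm_against_genome(seq, rname, pos1, cigar, genome)]
  data.table::setorderv(reads, c("rname", "pos1", "qname"))
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:", nchar(genome)),
           paste(reads$qname, reads$flag, reads$rname, reads$pos1,
                 reads$mapq, reads$cigar, "=", reads$pos1, 0, reads$seq,
                 qual, paste0("NM:i:", reads$nm), paste0("NH:i:", reads$nh),
                 sep = "\t"))
  writeLines(sam, sam_path)
  sam_path
}
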