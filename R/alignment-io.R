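# Alignment input: the prepare stage (merge / coordinate-sort / index) and
# split-read extraction from reference-skip ("N") CIGAR operations.

# BAM files start with a gzip magic number; plain SAM is text
is_bam_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

bam_is_coord_sorted <- function(path) {
  hd <- Rsamtools::scanBamHeader(path)[[1L]]$text
  if (is.null(hd[["@HD"]])) return(FALSE)
  any(grepl("^SO:coordinate$", hd[["@HD"]]))
}

#' Prepare alignments and genome for junction extraction
#'
#' Merges one or more SAM/BAM files into a single coordinate-sorted, indexed
#' BAM and ensures the genome FASTA is indexed. A single input that is already
#' coordinate-sorted and indexed is returned unchanged, so the operation is
#' idempotent. Every contig named in the alignment headers must exist in the
#' genome.
#'
#' @param alignment_paths Character vector of SAM or BAM paths.
#' @param genome_path Path to the genome FASTA.
#' @param output_dir Directory for the merged/sorted BAM and indices
#'   (default: a fresh temporary directory).
#'
#' @return An object of class `jf_prepared` with fields `alignment_path`,
#'   `genome_path`, `read_count` (total records across inputs) and
#'   `source_count`.
#' @export
prepare <- function(alignment_paths, genome_path,
                    output_dir = tempfile("jf_prepare_")) {
  stopifnot(length(alignment_paths) >= 1L)
  for (p in c(alignment_paths, genome_path)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  fai <- paste0(genome_path, ".fai")
  if (!file.exists(fai)) {
    tryCatch(Rsamtools::indexFa(genome_path),
             error = function(e) stop("format error: cannot index genome '",
                                      genome_path, "': ", conditionMessage(e)))
  }
  genome_contigs <- Rsamtools::scanFaIndex(genome_path)
  genome_names <- as.character(GenomicRanges::seqnames(genome_contigs))

  # convert any SAM inputs to BAM
  bams <- character(length(alignment_paths))
  for (i in seq_along(alignment_paths)) {
    p <- alignment_paths[i]
    if (is_bam_file(p)) {
      bams[i] <- p
    } else {
      dest <- file.path(output_dir, paste0("input_", i))
      bams[i] <- tryCatch(
        Rsamtools::asBam(p, destination = dest, overwrite = TRUE,
                         indexDestination = FALSE),
        error = function(e) stop("format error: cannot parse '", p, "' as ",
                                 "SAM/BAM: ", conditionMessage(e)))
    }
  }

  # header consistency against the genome
  for (b in bams) {
    hdr <- tryCatch(Rsamtools::scanBamHeader(b)[[1L]],
                    error = function(e) stop("format error: cannot read ",
                                             "header of '", b, "': ",
                                             conditionMessage(e)))
    missing <- setdiff(names(hdr$targets), genome_names)
    if (length(missing) > 0L) {
      stop("consistency error: contig '", missing[1L],
           "' in alignments is absent from the genome")
    }
  }

  read_count <- sum(vapply(
    bams, function(b) Rsamtools::countBam(b)$records, numeric(1L)))

  # idempotent fast path: one input, already sorted and indexed
  if (length(bams) == 1L && bam_is_coord_sorted(bams[1L]) &&
      file.exists(paste0(bams[1L], ".bai"))) {
    out <- bams[1L]
  } else {
    if (length(bams) > 1L) {
      sorted <- character(length(bams))
      for (i in seq_along(bams)) {
        sorted[i] <- Rsamtools::sortBam(
          bams[i], file.path(output_dir, paste0("sorted_", i)))
      }
      merged <- file.path(output_dir, "merged.bam")
      out <- Rsamtools::mergeBam(sorted, merged, overwrite = TRUE)
    } else {
      out <- Rsamtools::sortBam(bams[1L], file.path(output_dir, "prepared"))
    }
    Rsamtools::indexBam(out)
  }

  structure(list(alignment_path = out,
                 genome_path = genome_path,
                 read_count = read_count,
                 source_count = length(alignment_paths)),
            class = "jf_prepared")
}

#' @export
print.jf_prepared <- function(x, ...) {
  cat("prepared alignment input\n",
      "  alignment: ", x$alignment_path, "\n",
      "  genome:    ", x$genome_path, "\n",
      "  records:   ", x$read_count, " from ", x$source_count, " file(s)\n",
      sep = "")
  invisible(x)
}

# parse a CIGAR string into integer lengths and single-char ops
parse_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  lapply(toks, function(tk) {
    list(len = as.integer(sub("[A-Z=]$", "", tk)),
         op = substr(tk, nchar(tk), nchar(tk)))
  })
}

#' Extract split-read records from a prepared alignment
#'
#' Scans the alignment for reference-skip ("N") CIGAR operations and emits one
#' record per skip whose length lies within `[min_intron, max_intron]`. Each
#' record carries the skip's flanking anchor intervals, the supporting read's
#' uniqueness and pairing flags, its edit distance, and the per-side
#' mismatch-truncated contiguous match lengths (`lmmes`, `rmmes`) obtained by
#' comparing the read sequence against the genome walking away from the
#' junction. Unmapped reads are skipped; secondary and supplementary records
#' are excluded unless `include_secondary`.
#'
#' A read is called uniquely mapped when its hit-count tag (`NH`) equals one;
#' when the tag is absent, when its mapping quality is at least `min_mapq`.
#' Edit distances come from the `NM` tag, or are recomputed against the genome
#' when the tag is missing.
#'
#' @param prepared A `jf_prepared` object from [prepare()].
#' @param min_intron,max_intron Intron length bounds in bases.
#' @param min_mapq Mapping-quality fallback cutoff for unique mapping.
#' @param include_secondary Keep secondary/supplementary records?
#'
#' @return A `data.table` with one row per in-bounds skip operation: columns
#'   `read_id`, `contig`, `left_start`, `intron_start`, `intron_end`,
#'   `right_end`, `offset` (upstream-anchor length), `left_len`, `right_len`,
#'   `lmmes`, `rmmes`, `uniquely_mapped`, `properly_paired`, `introns_in_read`,
#'   `mismatches`, `read_length`, `left_clip`, `right_clip`. All coordinates
#'   0-based half-open. A `diagnostics` attribute tallies records read and
#'   skipped by reason.
#' @export
iterate_split_reads <- function(prepared, min_intron = 4L,
                                max_intron = 500000L, min_mapq = 30L,
                                include_secondary = FALSE) {
  stopifnot(inherits(prepared, "jf_prepared"),
            min_intron > 0L, min_intron <= max_intron)
  genome <- load_genome(prepared$genome_path)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("NM", "NH"))
  bam <- Rsamtools::scanBam(prepared$alignment_path, param = param)[[1L]]

  n_records <- length(bam$flag)
  flag <- bam$flag
  mapped <- !is.na(bam$pos) & bitwAnd(flag, 4L) == 0L
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  keep <- mapped & (include_secondary | primary)
  has_skip <- grepl("N", bam$cigar, fixed = TRUE)
  sel <- which(keep & has_skip)

  diag <- list(records_read = n_records,
               records_unmapped = sum(!mapped),
               records_secondary = sum(mapped & !primary & !include_secondary),
               split_reads = length(sel),
               skips_out_of_bounds = 0L,
               skips_zero_anchor = 0L)

  seqs_chr <- as.character(bam$seq[sel])
  cig_ops <- parse_cigar(bam$cigar[sel])
  rname <- as.character(bam$rname)[sel]
  pos0 <- bam$pos[sel] - 1L  # to 0-based
  qname <- bam$qname[sel]
  mapq <- bam$mapq[sel]
  nm_tag <- if (!is.null(bam$tag$NM)) bam$tag$NM[sel] else rep(NA_integer_, length(sel))
  nh_tag <- if (!is.null(bam$tag$NH)) bam$tag$NH[sel] else rep(NA_integer_, length(sel))
  flag_sel <- flag[sel]

  n_skips_total <- sum(vapply(cig_ops, function(o) sum(o$op == "N"),
                              integer(1L)))
  # preallocated accumulators, one slot per potential record
  A <- new.env(parent = emptyenv())
  A$k <- 0L
  for (nm in c("left_start", "intron_start", "intron_end", "right_end",
               "lmmes", "rmmes", "introns_in_read", "mismatches",
               "read_length", "left_clip", "right_clip", "read_idx"))
    assign(nm, integer(n_skips_total), envir = A)
  A$uniquely_mapped <- logical(n_skips_total)
  A$properly_paired <- logical(n_skips_total)
  oob <- 0L
  zero_anchor <- 0L

  for (ri in seq_along(sel)) {
    ops <- cig_ops[[ri]]
    lens <- ops$len
    opch <- ops$op
    contig <- rname[ri]
    cseq <- genome[[contig]]
    rseq <- seqs_chr[ri]
    seq_known <- !is.na(rseq) && rseq != "*"

    # walk the CIGAR, collecting aligned (ref, query) blocks and skip bounds
    rpos <- pos0[ri]
    qpos <- 0L
    n_ops <- length(lens)
    blk_ref <- integer(0L); blk_q <- integer(0L); blk_len <- integer(0L)
    skips <- list()
    n_ins <- 0L; n_del <- 0L
    left_clip <- 0L; right_clip <- 0L
    for (k in seq_len(n_ops)) {
      l <- lens[k]; o <- opch[k]
      if (o %in% c("M", "=", "X")) {
        blk_ref <- c(blk_ref, rpos); blk_q <- c(blk_q, qpos)
        blk_len <- c(blk_len, l)
        rpos <- rpos + l; qpos <- qpos + l
      } else if (o == "I") {
        n_ins <- n_ins + l; qpos <- qpos + l
      } else if (o == "D") {
        n_del <- n_del + l; rpos <- rpos + l
      } else if (o == "N") {
        skips[[length(skips) + 1L]] <- c(rpos, rpos + l)
        rpos <- rpos + l
      } else if (o == "S") {
        if (k == 1L) left_clip <- l else right_clip <- l
        qpos <- qpos + l
      }
      # H and P consume nothing we track
    }
    if (length(skips) == 0L) next
    introns_in_read <- length(skips)
    read_length <- if (seq_known) nchar(rseq) else qpos

    # per-aligned-base match vector against the genome
    apos <- integer(0L); amatch <- logical(0L)
    if (length(blk_ref) > 0L) {
      apos <- unlist(lapply(seq_along(blk_ref), function(b) {
        seq.int(blk_ref[b], length.out = blk_len[b])
      }), use.names = FALSE)
      if (seq_known) {
        amatch <- unlist(lapply(seq_along(blk_ref), function(b) {
          g <- charToRaw(substr(cseq, blk_ref[b] + 1L, blk_ref[b] + blk_len[b]))
          r <- charToRaw(substr(rseq, blk_q[b] + 1L, blk_q[b] + blk_len[b]))
          g == r
        }), use.names = FALSE)
      } else {
        amatch <- rep(TRUE, length(apos))
      }
    }

    mm <- nm_tag[ri]
    if (is.na(mm)) mm <- sum(!amatch) + n_ins + n_del
    uniq <- if (!is.na(nh_tag[ri])) nh_tag[ri] == 1L else
      (!is.na(mapq[ri]) && mapq[ri] >= min_mapq)
    paired_ok <- bitwAnd(flag_sel[ri], 1L) == 1L &&
      bitwAnd(flag_sel[ri], 2L) == 2L

    # anchor boundaries: any skip delimits the anchors of its neighbours
    skip_s <- vapply(skips, `[`, numeric(1L), 1L)
    skip_e <- vapply(skips, `[`, numeric(1L), 2L)
    first_ref <- if (length(blk_ref) > 0L) min(blk_ref) else pos0[ri]
    last_ref <- rpos
    for (j in seq_len(introns_in_read)) {
      s <- skip_s[j]; e <- skip_e[j]
      ilen <- e - s
      if (ilen < min_intron || ilen > max_intron) {
        oob <- oob + 1L
        next
      }
      la <- if (j == 1L) first_ref else skip_e[j - 1L]
      ra <- if (j == introns_in_read) last_ref else skip_s[j + 1L]
      if (la >= s || e >= ra) {
        zero_anchor <- zero_anchor + 1L
        next
      }
      # mismatch-truncated contiguous match lengths, walking away from the
      # junction on each side (deleted reference bases break the run)
      lm <- 0L
      repeat {
        p <- s - lm - 1L
        if (p < la) break
        idx <- match(p, apos)
        if (is.na(idx) || !amatch[idx]) break
        lm <- lm + 1L
      }
      rm_ <- 0L
      repeat {
        p <- e + rm_
        if (p >= ra) break
        idx <- match(p, apos)
        if (is.na(idx) || !amatch[idx]) break
        rm_ <- rm_ + 1L
      }
      k <- A$k + 1L
      A$k <- k
      A$read_idx[k] <- ri
      A$left_start[k] <- as.integer(la)
      A$intron_start[k] <- as.integer(s)
      A$intron_end[k] <- as.integer(e)
      A$right_end[k] <- as.integer(ra)
      A$lmmes[k] <- lm
      A$rmmes[k] <- rm_
      A$introns_in_read[k] <- introns_in_read
      A$mismatches[k] <- as.integer(mm)
      A$read_length[k] <- as.integer(read_length)
      A$left_clip[k] <- left_clip
      A$right_clip[k] <- right_clip
      A$uniquely_mapped[k] <- uniq
      A$properly_paired[k] <- paired_ok
    }
  }

  n_out <- A$k
  idx <- seq_len(n_out)
  ridx <- A$read_idx[idx]
  out <- data.table::data.table(
    read_id = qname[ridx],
    contig = rname[ridx],
    left_start = A$left_start[idx],
    intron_start = A$intron_start[idx],
    intron_end = A$intron_end[idx],
    right_end = A$right_end[idx],
    offset = A$intron_start[idx] - A$left_start[idx],
    left_len = A$intron_start[idx] - A$left_start[idx],
    right_len = A$right_end[idx] - A$intron_end[idx],
    lmmes = A$lmmes[idx],
    rmmes = A$rmmes[idx],
    uniquely_mapped = A$uniquely_mapped[idx],
    properly_paired = A$properly_paired[idx],
    introns_in_read = A$introns_in_read[idx],
    mismatches = A$mismatches[idx],
    read_length = A$read_length[idx],
    left_clip = A$left_clip[idx],
    right_clip = A$right_clip[idx])
  diag$skips_out_of_bounds <- oob
  diag$skips_zero_anchor <- zero_anchor
  data.table::setattr(out, "diagnostics", diag)
  out[]
}

#' Fetch a genomic subsequence
#'
#' @param genome Genome FASTA path, named character vector, or `DNAStringSet`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#'
#' @return Uppercase nucleotide string.
#' @export
fetch_sequence <- function(genome, contig, start, end, strand = "+") {
  seqs <- load_genome(genome)
  s <- seq0(seqs, contig, start, end)
  if (strand == "-") s <- revcomp(s)
  s
}
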