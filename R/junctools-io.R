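# Junction file formats and set utilities: the descriptive tab format, exon
# BED12 and intron BED6, GFF3 intron hints and mapper splice-site hints;
# union/intersection/subtraction with per-sample markup; comparison against a
# reference annotation into four support classes; recall/precision/F1.

jf_tab_header <- function(seed = NA) {
  c(paste0("## junctionfilter tab v", JF_FORMAT_VERSION),
    "## coordinates: 0-based half-open intron intervals",
    paste0("## seed: ", ifelse(is.na(seed), "NA", as.character(seed))))
}

# normalize a junction table to the full tab column set (missing -> NA)
jf_normalize_columns <- function(records) {
  dt <- data.table::as.data.table(records)
  if (!"id" %in% names(dt)) {
    dt[, id := sprintf("JUNC%08d", seq_len(.N))]
  }
  for (col in JF_TAB_COLUMNS) {
    if (!col %in% names(dt)) {
      if (col %in% JF_TAB_CHARACTER) dt[, (col) := NA_character_]
      else if (col %in% JF_TAB_LOGICAL) dt[, (col) := NA]
      else dt[, (col) := NA_real_]
    }
  }
  dt[, JF_TAB_COLUMNS, with = FALSE]
}

format_tab_field <- function(x) {
  if (is.character(x)) {
    out <- x
    out[is.na(out)] <- "NA"
    out
  } else if (is.logical(x)) {
    out <- ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
    out
  } else {
    num2str(as.numeric(x))
  }
}

#' Write junctions to disk
#'
#' Supported formats:
#' \describe{
#'   \item{tab}{Descriptive tabular format: three `##` header lines (format
#'     version, coordinate convention, seed) followed by a header row and one
#'     row per junction with every metric, the classifier probability and the
#'     verdict. Positions are 0-based half-open. Lossless.}
#'   \item{bed_exon}{BED12 with two blocks (the maximal anchors), thick
#'     interval = the intron, score = `round(1000 * probability)`, name = the
#'     junction id. Lossy but round-trips the locus, anchors and score.}
#'   \item{intron_bed}{BED6 over the intron interval.}
#'   \item{hint_gff}{GFF3 `intron` features (1-based inclusive), usable as
#'     two-pass alignment or gene-prediction hints. One-way.}
#'   \item{mapper_sj}{Splice-site hint text for spliced aligners: contig, the
#'     0-based position of the last exonic base before the intron, the 0-based
#'     position of the first exonic base after it, and the strand. This is the
#'     dialect HISAT2-style `--known-splicesite-infile` lists use. One-way.}
#' }
#'
#' @param records Junction table (any subset of the tab columns; missing
#'   metrics are written as NA).
#' @param path Output path.
#' @param format One of `"tab"`, `"bed_exon"`, `"intron_bed"`, `"hint_gff"`,
#'   `"mapper_sj"`.
#' @param seed Seed recorded in the tab header (default taken from the
#'   table's `seed` attribute).
#' @return `path`, invisibly.
#' @export
write_junctions <- function(records, path,
                            format = c("tab", "bed_exon", "intron_bed",
                                       "hint_gff", "mapper_sj"),
                            seed = attr(records, "seed", exact = TRUE)) {
  format <- match.arg(format)
  dt <- jf_normalize_columns(records)
  if (is.null(seed)) seed <- NA
  strand_out <- ifelse(dt$strand %in% c("+", "-"), dt$strand, ".")
  lines <- switch(format,
    tab = {
      body <- do.call(paste, c(lapply(dt, format_tab_field), sep = "\t"))
      c(jf_tab_header(seed), paste(JF_TAB_COLUMNS, collapse = "\t"), body)
    },
    bed_exon = {
      la <- ifelse(is.na(dt$left_anchor_start), dt$start - 1, dt$left_anchor_start)
      ra <- ifelse(is.na(dt$right_anchor_end), dt$end + 1, dt$right_anchor_end)
      score <- ifelse(is.na(dt$probability), 0, round(1000 * dt$probability))
      left_size <- dt$start - la
      right_size <- ra - dt$end
      c("track name=\"junctions\" description=\"splice junctions\" useScore=1",
        paste(dt$contig, num2str(la), num2str(ra), dt$id, num2str(score),
              strand_out, num2str(dt$start), num2str(dt$end), "255,0,0", "2",
              paste0(num2str(left_size), ",", num2str(right_size)),
              paste0("0,", num2str(dt$end - la)),
              sep = "\t"))
    },
    intron_bed = {
      score <- ifelse(is.na(dt$probability), 0, round(1000 * dt$probability))
      paste(dt$contig, num2str(dt$start), num2str(dt$end), dt$id,
            num2str(score), strand_out, sep = "\t")
    },
    hint_gff = {
      c("##gff-version 3",
        paste(dt$contig, "junctionfilter", "intron",
              num2str(dt$start + 1), num2str(dt$end),
              ifelse(is.na(dt$probability), ".", num2str(dt$probability)),
              strand_out, ".",
              paste0("ID=", dt$id, ";mult=",
                     ifelse(is.na(dt$nb_raw), 0, dt$nb_raw)),
              sep = "\t"))
    },
    mapper_sj = {
      paste(dt$contig, num2str(dt$start - 1), num2str(dt$end), strand_out,
            sep = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read junctions from disk
#'
#' Inverse of [write_junctions()] for the lossless `tab` format and the
#' `bed_exon`/`intron_bed` dialects; `hint_gff` and `mapper_sj` are one-way
#' exports. BED12 records must carry exactly two blocks whose arithmetic is
#' consistent with the thick (intron) interval.
#'
#' @param path Input path.
#' @param format One of `"tab"`, `"bed_exon"`, `"intron_bed"`.
#' @return Junction `data.table`; for `tab`, field-for-field identical to the
#'   written table, with the recorded seed in the `seed` attribute.
#' @export
read_junctions <- function(path, format = c("tab", "bed_exon", "intron_bed")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "tab") {
    hdr <- grep("^##", lines)
    seed <- NA_integer_
    seed_line <- grep("^## seed: ", lines, value = TRUE)
    if (length(seed_line) > 0L) {
      s <- sub("^## seed: ", "", seed_line[1L])
      seed <- if (s == "NA") NA_integer_ else as.integer(s)
    }
    body <- lines[setdiff(seq_along(lines), hdr)]
    if (length(body) < 1L) stop("parse error: tab file has no header row")
    cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(cols, JF_TAB_COLUMNS)) {
      stop("parse error at line ", max(hdr, 0) + 1L,
           ": unexpected tab column layout")
    }
    rows <- body[-1L]
    dt <- if (length(rows) == 0L) jf_normalize_columns(
      data.table::data.table(contig = character(), start = integer(),
                             end = integer())[0L]) else {
      parts <- data.table::tstrsplit(rows, "\t", fixed = TRUE)
      if (length(parts) != length(JF_TAB_COLUMNS)) {
        bad <- which(lengths(strsplit(rows, "\t", fixed = TRUE)) !=
                       length(JF_TAB_COLUMNS))[1L]
        stop("parse error at line ", length(hdr) + 1L + bad,
             ": wrong field count")
      }
      names(parts) <- JF_TAB_COLUMNS
      d <- data.table::as.data.table(parts)
      for (col in JF_TAB_COLUMNS) {
        if (col %in% JF_TAB_CHARACTER) {
          d[get(col) == "NA", (col) := NA_character_]
        } else if (col %in% JF_TAB_LOGICAL) {
          d[, (col) := c("TRUE" = TRUE, "FALSE" = FALSE)[get(col)]]
        } else {
          v <- d[[col]]
          v[v == "NA"] <- NA_character_
          d[, (col) := as.numeric(v)]
        }
      }
      int_cols <- c("start", "end", "nb_raw", "nb_unique_split",
                    "nb_unique_mapped", "nb_reliable", "max_overhang",
                    "maxmmes", "left_hamming", "right_hamming", "min_hamming",
                    "left_anchor_start", "right_anchor_end",
                    "max_read_length", "nb_samples")
      for (col in int_cols) {
        v <- d[[col]]
        if (all(is.na(v) | v == round(v))) d[, (col) := as.integer(get(col))]
      }
      d
    }
    data.table::setattr(dt, "seed", seed)
    return(dt[])
  }
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "bed_exon") {
    out <- vector("list", length(parts))
    for (i in seq_along(parts)) {
      f <- parts[[i]]
      if (length(f) < 12L) stop("parse error at line ", i, ": BED12 needs ",
                                "12 fields")
      block_count <- as.integer(f[10L])
      if (is.na(block_count) || block_count != 2L) {
        stop("parse error at line ", i, ": junction BED12 requires exactly ",
             "2 blocks, found ", f[10L])
      }
      sizes <- as.integer(strsplit(f[11L], ",")[[1L]])
      starts <- as.integer(strsplit(f[12L], ",")[[1L]])
      chrom_start <- as.integer(f[2L])
      chrom_end <- as.integer(f[3L])
      thick_start <- as.integer(f[7L])
      thick_end <- as.integer(f[8L])
      if (starts[1L] != 0L ||
          chrom_start + sizes[1L] != thick_start ||
          chrom_start + starts[2L] != thick_end ||
          chrom_start + starts[2L] + sizes[2L] != chrom_end) {
        stop("parse error at line ", i, ": BED12 block arithmetic is ",
             "inconsistent with the thick interval")
      }
      out[[i]] <- data.table::data.table(
        id = f[4L], contig = f[1L], start = thick_start, end = thick_end,
        strand = ifelse(f[6L] %in% c("+", "-"), f[6L], "?"),
        left_anchor_start = chrom_start, right_anchor_end = chrom_end,
        probability = as.numeric(f[5L]) / 1000)
    }
    return(data.table::rbindlist(out))
  }
  # intron_bed
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    f <- parts[[i]]
    if (length(f) < 6L) stop("parse error at line ", i, ": BED6 needs 6 fields")
    out[[i]] <- data.table::data.table(
      id = f[4L], contig = f[1L], start = as.integer(f[2L]),
      end = as.integer(f[3L]),
      strand = ifelse(f[6L] %in% c("+", "-"), f[6L], "?"),
      probability = as.numeric(f[5L]) / 1000)
  }
  data.table::rbindlist(out)
}

#' Set algebra over junction sets with per-sample markup
#'
#' Junctions are keyed on their intron locus `(contig, start, end)`. The
#' union records, per junction, the number of contributing sets it occurs in
#' (`nb_samples`); intersection keeps loci present in every set; subtraction
#' keeps loci of the first set absent from all others. Metric columns are
#' taken from the first set containing each locus.
#'
#' @param sets List of junction tables.
#' @param op `"union"`, `"intersection"` or `"subtract"`.
#' @return Marked junction `data.table` with an `nb_samples` column.
#' @export
set_operate <- function(sets, op = c("union", "intersection", "subtract")) {
  op <- match.arg(op)
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (length(sets) < 2L && op != "union") {
    stop("'", op, "' needs at least 2 sets")
  }
  tabs <- lapply(seq_along(sets), function(i) {
    d <- data.table::as.data.table(sets[[i]])
    d[, .jf_set := i]
    d
  })
  all_rows <- data.table::rbindlist(tabs, fill = TRUE)
  counts <- all_rows[, .(nb_samples = data.table::uniqueN(.jf_set)),
                     by = .(contig, start, end)]
  first <- all_rows[!duplicated(all_rows[, .(contig, start, end)])]
  first[, .jf_set := NULL]
  merged <- merge(first,
                  counts, by = c("contig", "start", "end"), sort = TRUE,
                  suffixes = c(".old", ""))
  if ("nb_samples.old" %in% names(merged)) merged[, nb_samples.old := NULL]
  out <- switch(op,
    union = merged,
    intersection = merged[nb_samples == length(sets)],
    subtract = {
      k1 <- tabs[[1L]][, .(contig, start, end)]
      others <- data.table::rbindlist(
        lapply(tabs[-1L], function(d) d[, .(contig, start, end)]))
      keep <- k1[!others, on = c("contig", "start", "end")]
      merged[keep, on = c("contig", "start", "end"), nomatch = NULL]
    })
  data.table::setcolorder(out, intersect(JF_TAB_COLUMNS, names(out)))
  out[]
}

#' Mark junctions found in a reference
#'
#' Union of the input sets with per-sample occurrence counts plus an
#' `in_reference` flag — the markup used to stratify junctions by how many
#' samples support them and whether the annotation already knows them.
#'
#' @param sets List of junction tables (one per sample).
#' @param reference `jf_reference` from [load_reference()].
#' @return Marked junction `data.table`.
#' @export
junction_markup <- function(sets, reference) {
  u <- set_operate(sets, "union")
  stopifnot(inherits(reference, "jf_reference"))
  ref_keys <- locus_key(reference$introns$contig, reference$introns$start,
                        reference$introns$end)
  u[, in_reference := locus_key(contig, start, end) %in% ref_keys]
  u[]
}

#' Load a reference annotation into an intron index
#'
#' GTF/GFF3 exons are grouped by transcript and converted to introns (the
#' gaps between consecutive exons); single-exon transcripts contribute
#' nothing. Intron BED input is taken as-is. All coordinates are converted to
#' 0-based half-open intervals and deduplicated.
#'
#' @param path Annotation path.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed"`.
#' @return Object of class `jf_reference`: `introns` table plus donor/acceptor
#'   boundary site sets.
#' @export
load_reference <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed",
                     stop("cannot infer annotation format from '", path, "'"))
  }
  if (format == "bed") {
    dt <- read_junctions(path, "intron_bed")
    introns <- unique(dt[, .(contig, start, end, strand)])
  } else {
    gr <- rtracklayer::import(path, format = ifelse(format == "gtf", "gtf",
                                                    "gff3"))
    exons <- gr[gr$type == "exon"]
    if (length(exons) == 0L) stop("annotation contains no exon features")
    tx <- if (!is.null(exons$transcript_id)) as.character(exons$transcript_id)
      else if (!is.null(exons$Parent)) vapply(exons$Parent, function(p)
        as.character(p)[1L], character(1L))
      else stop("exons carry neither transcript_id nor Parent")
    d <- data.table::data.table(
      contig = as.character(GenomicRanges::seqnames(exons)),
      start1 = GenomicRanges::start(exons),
      end1 = GenomicRanges::end(exons),
      strand = as.character(GenomicRanges::strand(exons)),
      tx = tx)
    data.table::setorderv(d, c("tx", "start1"))
    introns <- d[, {
      if (.N < 2L) NULL
      else .(contig = contig[-.N],
             # intron between consecutive exons, converted to 0-based
             # half-open: [prev exon 1-based end, next exon 1-based start - 1)
             start = end1[-.N], end = start1[-1L] - 1L,
             strand = strand[-.N])
    }, by = tx][, tx := NULL]
    introns <- unique(introns[end > start])
  }
  introns[!strand %in% c("+", "-"), strand := "?"]
  structure(list(
    introns = introns[],
    donor_sites = unique(introns[, .(contig, pos = start, strand)]),
    acceptor_sites = unique(introns[, .(contig, pos = end, strand)])),
    class = "jf_reference")
}

#' @export
print.jf_reference <- function(x, ...) {
  cat("reference intron index: ", nrow(x$introns), " introns\n", sep = "")
  invisible(x)
}

#' Classify junctions by reference support
#'
#' Partitions junctions into four classes of decreasing annotation support:
#' class 1 — both splice sites match the same reference intron; class 2 —
#' both boundary positions are annotated splice sites but never of the same
#' intron; class 3 — exactly one boundary is annotated; class 4 — both
#' boundaries are novel. Matching is strand-aware when both the junction and
#' the reference record a strand, and positional otherwise.
#'
#' @param junctions Junction table (`contig`, `start`, `end`, optional
#'   `strand`).
#' @param reference `jf_reference` from [load_reference()].
#' @return List with `breakdown` (named counts class1..class4, summing to the
#'   number of junctions) and `labels` (integer class per junction).
#' @export
compare_to_reference <- function(junctions, reference) {
  stopifnot(inherits(reference, "jf_reference"))
  j <- data.table::as.data.table(junctions)
  if (!"strand" %in% names(j)) j[, strand := "?"]
  ri <- reference$introns
  ref_strandless <- locus_key(ri$contig, ri$start, ri$end)
  ref_stranded <- paste0(ref_strandless, ":", ri$strand)
  donor_pos <- paste(reference$donor_sites$contig,
                     reference$donor_sites$pos)
  acceptor_pos <- paste(reference$acceptor_sites$contig,
                        reference$acceptor_sites$pos)
  donor_stranded <- paste(donor_pos, reference$donor_sites$strand)
  acceptor_stranded <- paste(acceptor_pos, reference$acceptor_sites$strand)

  n <- nrow(j)
  labels <- integer(n)
  for (i in seq_len(n)) {
    key <- locus_key(j$contig[i], j$start[i], j$end[i])
    st <- j$strand[i]
    stranded <- st %in% c("+", "-")
    intron_hit <- if (stranded) {
      paste0(key, ":", st) %in% ref_stranded || key %in%
        ref_strandless[ri$strand == "?"]
    } else key %in% ref_strandless
    if (intron_hit) {
      labels[i] <- 1L
      next
    }
    dkey <- paste(j$contig[i], j$start[i])
    akey <- paste(j$contig[i], j$end[i])
    left_hit <- if (stranded) {
      paste(dkey, st) %in% donor_stranded || dkey %in%
        donor_pos[reference$donor_sites$strand == "?"]
    } else dkey %in% donor_pos
    right_hit <- if (stranded) {
      paste(akey, st) %in% acceptor_stranded || akey %in%
        acceptor_pos[reference$acceptor_sites$strand == "?"]
    } else akey %in% acceptor_pos
    labels[i] <- if (left_hit && right_hit) 2L
      else if (left_hit || right_hit) 3L else 4L
  }
  breakdown <- vapply(1:4, function(k) sum(labels == k), integer(1L))
  names(breakdown) <- paste0("class", 1:4)
  list(breakdown = breakdown, labels = labels)
}

#' Recall, precision and F1 of a predicted junction set
#'
#' @param predicted,truth Junction tables or key data.frames (`contig`,
#'   `start`, `end`); `truth` must be non-empty.
#' @return Named list `recall`, `precision`, `f1`. An empty prediction scores
#'   0 everywhere.
#' @export
evaluate_junctions <- function(predicted, truth) {
  pk <- unique(locus_key(predicted$contig, predicted$start, predicted$end))
  tk <- unique(locus_key(truth$contig, truth$start, truth$end))
  if (length(tk) == 0L) stop("parameter error: truth set is empty")
  tp <- length(intersect(pk, tk))
  recall <- tp / length(tk)
  precision <- if (length(pk) == 0L) 0 else tp / length(pk)
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(recall = recall, precision = precision, f1 = f1)
}
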