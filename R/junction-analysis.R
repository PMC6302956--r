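# Junction analysis: collapse split reads into distinct intron loci and
# compute the alignment-derived metrics (support classes, Shannon entropy of
# anchor-start offsets, anchor-position coverage deviations, maximal overhang,
# mismatch-truncated MaxMMES, mean mismatches).

#' Collapse split reads into distinct junctions
#'
#' Groups split-read records by their intron interval, yielding one support
#' profile per distinct junction. Each supporting read contributes exactly one
#' support entry per locus it spans.
#'
#' @param split_reads `data.table` from [iterate_split_reads()].
#' @return The same table keyed by `(contig, intron_start, intron_end)`, with
#'   a `junction_id` column identifying each distinct locus; class
#'   `jf_profiles`. Use [analyze_junctions()] to reduce profiles to metrics.
#' @export
collapse_junctions <- function(split_reads) {
  sr <- data.table::as.data.table(split_reads)
  data.table::setkeyv(sr, c("contig", "intron_start", "intron_end"))
  sr[, junction_id := .GRP, by = .(contig, intron_start, intron_end)]
  data.table::setattr(sr, "class", c("jf_profiles", class(sr)))
  sr[]
}

#' Count split-read support classes for one junction
#'
#' @param profile Support rows for a single junction (columns
#'   `uniquely_mapped`, `properly_paired`, `introns_in_read`).
#' @return List with `nb_raw` (all supporting split reads), `nb_unique_split`
#'   (reads containing a single intron), `nb_unique_mapped`, `nb_reliable`
#'   (uniquely mapped and properly paired) and `reliable_ratio`.
#' @export
count_support_classes <- function(profile) {
  profile <- as.data.frame(profile)
  if (nrow(profile) == 0L) stop("undefined metric: empty support profile")
  nb_raw <- nrow(profile)
  nb_unique_split <- sum(profile$introns_in_read == 1L)
  nb_unique_mapped <- sum(profile$uniquely_mapped)
  nb_reliable <- sum(profile$uniquely_mapped & profile$properly_paired)
  list(nb_raw = nb_raw,
       nb_unique_split = nb_unique_split,
       nb_unique_mapped = nb_unique_mapped,
       nb_reliable = nb_reliable,
       reliable_ratio = nb_reliable / nb_raw)
}

#' Shannon entropy of anchor-start offsets
#'
#' Under random read sampling, split-read start sites are expected to be
#' uniformly distributed across the upstream anchor; entropy near zero flags
#' stacked, suspicious support.
#'
#' @param offset_counts Numeric vector of read counts per distinct offset
#'   (names optional).
#' @return Entropy in bits: \eqn{-\sum_i p_i \log_2 p_i} with
#'   \eqn{p_i = c_i / \sum c}; 0 when a single offset carries all reads.
#' @export
shannon_entropy <- function(offset_counts) {
  counts <- as.numeric(offset_counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("undefined metric: no positive offset counts")
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Deviation of observed from expected read counts at anchor positions
#'
#' With `n` supporting reads spread over `n_offsets` possible anchor start
#' offsets (capped at `positions`), the expected per-position count is
#' `E = n / min(n_offsets, positions)`. The deviation at anchor position
#' `i` is the standardized residual `|O_i - E| / sqrt(E)`; positions beyond
#' the anchor are exactly 0.
#'
#' @param offsets Integer vector of per-read anchor-start offsets (1-based
#'   distance from the read's upstream-anchor start to the junction).
#' @param n_offsets Number of possible offset values (typically the maximum
#'   read length minus one).
#' @param positions Number of anchor positions reported (default 20).
#' @return Numeric vector of length `positions`.
#' @export
anchor_deviations <- function(offsets, n_offsets, positions = 20L) {
  offsets <- as.integer(offsets)
  n <- length(offsets)
  if (n == 0L) stop("undefined metric: no supporting reads")
  a <- min(as.integer(n_offsets), positions)
  if (a < 1L) stop("n_offsets must be >= 1")
  e <- n / a
  dev <- numeric(positions)
  obs <- tabulate(offsets[offsets >= 1L & offsets <= a], nbins = a)
  dev[seq_len(a)] <- abs(obs - e) / sqrt(e)
  dev
}

#' Maximal split-read overhang of a junction
#'
#' @param profile Support rows for one junction (columns `left_len`,
#'   `right_len`), or two numeric vectors via `left`/`right`.
#' @param left,right Optional per-read anchor lengths, used instead of
#'   `profile`.
#' @return Maximum over supporting reads of the smaller anchor length; its
#'   best attainable value is half the maximum read length.
#' @export
max_overhang <- function(profile = NULL, left = NULL, right = NULL) {
  if (is.null(left)) {
    profile <- as.data.frame(profile)
    if (nrow(profile) == 0L) stop("undefined metric: empty support profile")
    left <- profile$left_len
    right <- profile$right_len
  }
  if (length(left) == 0L) stop("undefined metric: empty support profile")
  max(pmin(left, right))
}

#' MaxMMES: maximum of minimal mismatch-truncated matches
#'
#' Per supporting read, each side's contiguous match run is truncated at the
#' first mismatch walking away from the junction; the read's MMES is the
#' smaller side, and the junction's MaxMMES the maximum over reads. The
#' truncated run lengths are computed against the genome during split-read
#' extraction (`lmmes`, `rmmes`).
#'
#' @param profile Support rows for one junction (columns `lmmes`, `rmmes`),
#'   or two numeric vectors via `lmmes`/`rmmes`.
#' @param lmmes,rmmes Optional per-read truncated match lengths.
#' @return Integer MaxMMES; never exceeds [max_overhang()].
#' @export
maxmmes <- function(profile = NULL, lmmes = NULL, rmmes = NULL) {
  if (is.null(lmmes)) {
    profile <- as.data.frame(profile)
    if (nrow(profile) == 0L) stop("undefined metric: empty support profile")
    lmmes <- profile$lmmes
    rmmes <- profile$rmmes
  }
  if (length(lmmes) == 0L) stop("undefined metric: empty support profile")
  max(pmin(lmmes, rmmes))
}

#' Mean mismatches per supporting read
#'
#' @param mismatches Numeric vector of per-read edit distances, or a profile
#'   with a `mismatches` column.
#' @return Arithmetic mean.
#' @export
mean_mismatches <- function(mismatches) {
  if (is.data.frame(mismatches)) mismatches <- mismatches$mismatches
  if (length(mismatches) == 0L) stop("undefined metric: empty support profile")
  mean(as.numeric(mismatches))
}

#' Reduce split-read support to per-junction metrics
#'
#' Collapses split reads by intron locus and computes every alignment-derived
#' metric per junction, plus the anchor extents needed by the exon-BED writer.
#'
#' @param split_reads `data.table` from [iterate_split_reads()] (or an already
#'   collapsed `jf_profiles` table).
#' @param positions Number of anchor-deviation positions (default 20).
#' @return `data.table` with one row per junction: locus columns (`contig`,
#'   `start`, `end`, strand set later from splice sites), support-class
#'   counts, `entropy`, `max_overhang`, `maxmmes`, `mean_mismatches`,
#'   `dev1..dev20`, `left_anchor_start`, `right_anchor_end`,
#'   `max_read_length`, and a stable `id`.
#' @export
analyze_junctions <- function(split_reads, positions = 20L) {
  sr <- data.table::as.data.table(split_reads)
  if (nrow(sr) == 0L) {
    empty <- data.table::data.table(
      id = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), nb_raw = integer(),
      nb_unique_split = integer(), nb_unique_mapped = integer(),
      nb_reliable = integer(), reliable_ratio = numeric(),
      entropy = numeric(), max_overhang = integer(), maxmmes = integer(),
      mean_mismatches = numeric())
    for (i in seq_len(positions)) empty[, (paste0("dev", i)) := numeric()]
    empty[, `:=`(left_anchor_start = integer(), right_anchor_end = integer(),
                 max_read_length = integer())]
    return(empty)
  }
  dev_cols <- paste0("dev", seq_len(positions))
  per_junction <- function(d) {
    sup <- count_support_classes(d)
    devs <- anchor_deviations(d$offset, n_offsets = max(d$read_length) - 1L,
                              positions = positions)
    out <- c(sup,
             list(entropy = shannon_entropy(table(d$offset)),
                  max_overhang = max(pmin(d$left_len, d$right_len)),
                  maxmmes = max(pmin(d$lmmes, d$rmmes)),
                  mean_mismatches = mean(as.numeric(d$mismatches))),
             as.list(devs),
             list(left_anchor_start = min(d$left_start),
                  right_anchor_end = max(d$right_end),
                  max_read_length = max(d$read_length)))
    names(out)[10:(9 + positions)] <- dev_cols
    out
  }
  res <- sr[, per_junction(.SD), by = .(contig, intron_start, intron_end)]
  data.table::setnames(res, c("intron_start", "intron_end"), c("start", "end"))
  data.table::setorderv(res, c("contig", "start", "end"))
  res[, strand := "?"]
  res[, id := sprintf("JUNC%08d", .I)]
  data.table::setcolorder(res, c("id", "contig", "start", "end", "strand"))
  res[]
}
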