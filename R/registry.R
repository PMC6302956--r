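# Central schema: canonical feature ordering, tab-file column layout, and the
# pipeline configuration object shared by every stage. The ordering of
# `jf_feature_names()` is versioned: serialized models remain applicable only
# while it is stable.

JF_FORMAT_VERSION <- "1"

JF_FEATURE_NAMES <- c(
  "nb_reliable", "reliable_ratio", "maxmmes", "mean_mismatches",
  "intron_score", "min_hamming", "pwm_score", "splicing_signal",
  paste0("dev", 1:20)
)

JF_TAB_COLUMNS <- c(
  "id", "contig", "start", "end", "strand",
  "donor", "acceptor", "site_category",
  "nb_raw", "nb_unique_split", "nb_unique_mapped", "nb_reliable",
  "reliable_ratio", "entropy", "max_overhang", "maxmmes", "mean_mismatches",
  "left_hamming", "right_hamming", "min_hamming",
  "intron_score", "pwm_score", "splicing_signal",
  paste0("dev", 1:20),
  "left_anchor_start", "right_anchor_end", "max_read_length",
  "nb_samples", "in_reference", "probability", "genuine"
)

JF_TAB_CHARACTER <- c("id", "contig", "strand", "donor", "acceptor",
                      "site_category")
JF_TAB_LOGICAL <- c("in_reference", "genuine")

#' Canonical classifier feature names
#'
#' The 28 features used by the junction classifier, in their canonical order:
#' reliable read count, reliable-to-raw ratio, MaxMMES, mean mismatches per
#' read, intron-size score, minimum hamming repeat score, position weight
#' matrix score, splicing-signal score, and the 20 anchor-position coverage
#' deviations. The order is stable across releases so that serialized models
#' stay applicable.
#'
#' @return Character vector of length 28.
#' @export
jf_feature_names <- function() JF_FEATURE_NAMES

#' Extract the canonical feature vector from a junction record
#'
#' @param record A single junction record: a one-row data.frame (or a named
#'   list) carrying at least the 28 canonical metric fields named by
#'   [jf_feature_names()]. Missing trailing deviation entries are padded with
#'   zero; any other missing metric is an error naming the field.
#'
#' @return Named numeric vector of length 28 in canonical order.
#' @export
to_feature_vector <- function(record) {
  record <- as.list(record)
  wanted <- JF_FEATURE_NAMES
  vals <- numeric(length(wanted))
  names(vals) <- wanted
  for (i in seq_along(wanted)) {
    nm <- wanted[i]
    v <- record[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      if (grepl("^dev[0-9]+$", nm)) {
        vals[i] <- 0
        next
      }
      stop("incomplete junction record: missing metric '", nm, "'")
    }
    vals[i] <- as.numeric(v)
  }
  if (any(!is.finite(vals))) {
    stop("incomplete junction record: non-finite metric '",
         wanted[which(!is.finite(vals))[1L]], "'")
  }
  vals
}

#' Build the feature matrix for a junction table
#'
#' @param junctions Junction table as produced by the analysis and genome-metric
#'   stages (one row per junction, canonical metric columns present).
#' @return Numeric matrix, one row per junction, 28 canonical feature columns.
#' @export
feature_matrix <- function(junctions) {
  junctions <- as.data.frame(junctions)
  missing <- setdiff(JF_FEATURE_NAMES, names(junctions))
  if (length(missing) > 0L) {
    stop("incomplete junction table: missing metric '", missing[1L], "'")
  }
  m <- as.matrix(junctions[, JF_FEATURE_NAMES, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    bad <- JF_FEATURE_NAMES[which(colSums(!is.finite(m)) > 0L)[1L]]
    stop("incomplete junction table: non-finite metric '", bad, "'")
  }
  rownames(m) <- junctions$id
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the junction filtering pipeline with its default.
#' All thresholds are exposed; the single `seed` drives every stochastic stage
#' (SMOTE oversampling and random-forest training) and is recorded in output
#' headers and reports.
#'
#' @param min_intron,max_intron Intron length bounds (bases) for reference-skip
#'   operations to be treated as candidate introns.
#' @param min_mapq Mapping-quality cutoff used to call a read uniquely mapped
#'   when the aligner emits no hit-count tag.
#' @param include_secondary Whether secondary/supplementary records contribute
#'   to junction support (default `FALSE`: a read counts once).
#' @param hamming_window Window width (bases) for the repeat hamming scores.
#' @param donor_window,acceptor_window PWM windows around the donor and
#'   acceptor sites, as `c(upstream, downstream)` offsets relative to the
#'   splice site in transcript orientation; negative values are exonic.
#' @param pseudocount PWM pseudocount added per nucleotide.
#' @param rules Rule thresholds for the self-training sets; see
#'   [junction_rules()].
#' @param min_training Minimum size of each rule-derived training set.
#' @param smote_k Number of nearest neighbours used by SMOTE.
#' @param n_trees Number of trees in the random forest.
#' @param threshold Probability at or above which a junction is called genuine.
#' @param seed Integer seed for all stochastic stages.
#' @param threads Worker threads for table operations; results are independent
#'   of this value.
#'
#' @return A list of class `jf_config`.
#' @export
pipeline_config <- function(min_intron = 4L,
                            max_intron = 500000L,
                            min_mapq = 30L,
                            include_secondary = FALSE,
                            hamming_window = 10L,
                            donor_window = c(-3L, 8L),
                            acceptor_window = c(-20L, 3L),
                            pseudocount = 0.5,
                            rules = junction_rules(),
                            min_training = 20L,
                            smote_k = 5L,
                            n_trees = 100L,
                            threshold = 0.5,
                            seed = 1L,
                            threads = 1L) {
  stopifnot(min_intron > 0L, min_intron <= max_intron,
            hamming_window > 0L, pseudocount > 0,
            threshold >= 0, threshold <= 1,
            n_trees >= 1L, smote_k >= 1L, threads >= 1L)
  cfg <- list(
    min_intron = as.integer(min_intron),
    max_intron = as.integer(max_intron),
    min_mapq = as.integer(min_mapq),
    include_secondary = isTRUE(include_secondary),
    hamming_window = as.integer(hamming_window),
    donor_window = as.integer(donor_window),
    acceptor_window = as.integer(acceptor_window),
    pseudocount = pseudocount,
    rules = rules,
    min_training = as.integer(min_training),
    smote_k = as.integer(smote_k),
    n_trees = as.integer(n_trees),
    threshold = threshold,
    seed = as.integer(seed),
    threads = as.integer(threads)
  )
  class(cfg) <- "jf_config"
  cfg
}

#' @export
print.jf_config <- function(x, ...) {
  cat("junction filtering configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- paste0("<", length(v), " rule thresholds>")
    cat(sprintf("  %-18s %s\n", nm, paste(v, collapse = ",")))
  }
  invisible(x)
}
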