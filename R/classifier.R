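# Self-training classifier: rule-based positive/negative set construction,
# SMOTE class balancing, random-forest training (100 trees), and probability
# scoring/filtering of the full junction set.

#' Default rule thresholds for the self-training sets
#'
#' The positive set contains junctions that pass all positive rules; the
#' negative set contains junctions failing in characteristic false-positive
#' ways (any negative rule). Junctions matching neither remain unlabelled and
#' are only scored, never trained on. The rules deliberately label only
#' extreme cases: the sets need to be precise, not complete.
#'
#' @param pos_min_reliable Minimum reliable read count (positive rule).
#' @param pos_min_entropy Minimum offset entropy in bits (positive rule).
#' @param pos_min_maxmmes Minimum MaxMMES (positive rule).
#' @param pos_max_mean_mismatches Maximum mean mismatches (positive rule).
#' @param pos_min_hamming Minimum hamming repeat score (positive rule).
#' @param neg_novel_max_raw Raw-count ceiling for novel-dinucleotide negatives.
#' @param neg_zero_entropy_max_raw Raw-count ceiling for zero-entropy
#'   negatives.
#' @param neg_max_hamming Hamming score at or below which a junction is a
#'   repeat-induced negative.
#' @param neg_max_maxmmes MaxMMES ceiling for unreliable negatives (paired
#'   with zero reliable reads).
#' @return Named list of thresholds.
#' @export
junction_rules <- function(pos_min_reliable = 5L,
                           pos_min_entropy = 1.0,
                           pos_min_maxmmes = 12L,
                           pos_max_mean_mismatches = 1.0,
                           pos_min_hamming = 5L,
                           neg_novel_max_raw = 2L,
                           neg_zero_entropy_max_raw = 5L,
                           neg_max_hamming = 2L,
                           neg_max_maxmmes = 6L) {
  list(pos_min_reliable = pos_min_reliable,
       pos_min_entropy = pos_min_entropy,
       pos_min_maxmmes = pos_min_maxmmes,
       pos_max_mean_mismatches = pos_max_mean_mismatches,
       pos_min_hamming = pos_min_hamming,
       neg_novel_max_raw = neg_novel_max_raw,
       neg_zero_entropy_max_raw = neg_zero_entropy_max_raw,
       neg_max_hamming = neg_max_hamming,
       neg_max_maxmmes = neg_max_maxmmes)
}

#' Build the rule-derived training sets
#'
#' Applies aggressive rule-based filtering to label a precise positive subset
#' (canonical or semi-canonical sites, strong, clean, well-distributed
#' support) and a precise negative subset (novel sites with minimal support,
#' stacked zero-entropy support, repeat-like boundaries, or short unreliable
#' matches). The two rule families are mutually exclusive by construction.
#'
#' @param junctions Junction table with splice-site and hamming metrics
#'   (see [add_site_metrics()]).
#' @param rules Thresholds from [junction_rules()].
#' @param min_training Minimum acceptable size of each set.
#' @return Object of class `jf_training`: a list with `label` (character
#'   vector aligned to `junctions`: `"positive"`, `"negative"` or
#'   `"unlabelled"`), `positive_keys` and `negative_keys` (junction ids).
#' @export
build_training_sets <- function(junctions, rules = junction_rules(),
                                min_training = 20L) {
  j <- as.data.frame(junctions)
  needed <- c("site_category", "nb_reliable", "entropy", "maxmmes",
              "mean_mismatches", "min_hamming", "nb_raw")
  missing <- setdiff(needed, names(j))
  if (length(missing) > 0L) {
    stop("junction table lacks rule metric '", missing[1L], "'")
  }
  pos <- j$site_category %in% c("canonical", "semi_canonical") &
    j$nb_reliable >= rules$pos_min_reliable &
    j$entropy >= rules$pos_min_entropy &
    j$maxmmes >= rules$pos_min_maxmmes &
    j$mean_mismatches <= rules$pos_max_mean_mismatches &
    j$min_hamming >= rules$pos_min_hamming
  neg <- (j$site_category == "novel" & j$nb_raw <= rules$neg_novel_max_raw) |
    (j$entropy == 0 & j$nb_raw <= rules$neg_zero_entropy_max_raw) |
    (j$min_hamming <= rules$neg_max_hamming) |
    (j$maxmmes <= rules$neg_max_maxmmes & j$nb_reliable == 0L)
  label <- rep("unlabelled", nrow(j))
  label[pos & !neg] <- "positive"
  label[neg & !pos] <- "negative"
  n_pos <- sum(label == "positive")
  n_neg <- sum(label == "negative")
  if (n_pos < min_training || n_neg < min_training) {
    stop("training error: rule-derived sets too small (", n_pos,
         " positive, ", n_neg, " negative; need ", min_training,
         " each); consider relaxing the rule thresholds")
  }
  structure(list(label = label,
                 positive_keys = j$id[label == "positive"],
                 negative_keys = j$id[label == "negative"]),
            class = "jf_training")
}

#' @export
print.jf_training <- function(x, ...) {
  cat("self-training junction sets: ", length(x$positive_keys), " positive, ",
      length(x$negative_keys), " negative, ",
      sum(x$label == "unlabelled"), " unlabelled\n", sep = "")
  invisible(x)
}

#' Balance two classes with synthetic minority oversampling (SMOTE)
#'
#' Grows the minority class to the majority size by placing synthetic points
#' on segments between each sampled minority point and one of its `k` nearest
#' minority neighbours (Euclidean distance in feature space). Deterministic
#' under a fixed seed. When the minority holds a single point it is
#' duplicated; `k` is lowered to `size - 1` when the minority is smaller than
#' `k + 1`.
#'
#' @param minority,majority Numeric feature matrices (rows = samples).
#' @param k Number of nearest neighbours (default 5).
#' @param seed Integer seed.
#' @return List with `minority` (grown to `nrow(majority)`) and `majority`
#'   (unchanged).
#' @export
smote_balance <- function(minority, majority, k = 5L, seed = 1L) {
  minority <- as.matrix(minority)
  majority <- as.matrix(majority)
  if (nrow(minority) == 0L) stop("minority class is empty")
  if (nrow(minority) >= nrow(majority)) {
    return(list(minority = minority, majority = majority))
  }
  n_needed <- nrow(majority) - nrow(minority)
  set.seed(seed)
  if (nrow(minority) == 1L) {
    synth <- minority[rep(1L, n_needed), , drop = FALSE]
    return(list(minority = rbind(minority, synth), majority = majority))
  }
  k <- min(k, nrow(minority) - 1L)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  # k nearest minority neighbours per point (ties broken by row order)
  nn <- do.call(rbind, lapply(seq_len(nrow(minority)),
                              function(i) order(d[i, ])[seq_len(k)]))
  base_idx <- sample.int(nrow(minority), n_needed, replace = TRUE)
  nb_pick <- sample.int(k, n_needed, replace = TRUE)
  gap <- stats::runif(n_needed)
  synth <- matrix(0, nrow = n_needed, ncol = ncol(minority),
                  dimnames = list(NULL, colnames(minority)))
  for (i in seq_len(n_needed)) {
    a <- minority[base_idx[i], ]
    b <- minority[nn[base_idx[i], nb_pick[i]], ]
    synth[i, ] <- a + gap[i] * (b - a)
  }
  list(minority = rbind(minority, synth), majority = majority)
}

#' Train the junction random forest
#'
#' An ensemble of `n_trees` decision trees over the 28 canonical features,
#' trained on the SMOTE-balanced rule-derived sets. Reproducible under a
#' fixed seed; feature importances are retained.
#'
#' @param features Numeric matrix with the canonical feature columns.
#' @param labels Logical or character vector (`TRUE`/`"genuine"` vs
#'   `FALSE`/`"invalid"`), one per row.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @return Object of class `jf_model` wrapping the forest; its `importance`
#'   field holds mean-decrease-in-accuracy importances.
#' @export
train_forest <- function(features, labels, n_trees = 100L, seed = 1L) {
  features <- as.matrix(features)
  if (is.logical(labels)) labels <- ifelse(labels, "genuine", "invalid")
  y <- factor(labels, levels = c("invalid", "genuine"))
  if (length(unique(y)) < 2L) {
    stop("training error: labels contain a single class")
  }
  stopifnot(nrow(features) == length(y), n_trees >= 1L)
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = y, ntree = n_trees,
                                   importance = TRUE)
  structure(list(forest = rf,
                 feature_names = colnames(features),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 importance = randomForest::importance(
                   rf, type = 1L)[, 1L]),
            class = "jf_model")
}

#' @export
print.jf_model <- function(x, ...) {
  cat("junction random forest: ", x$n_trees, " trees, ",
      length(x$feature_names), " features (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Score junctions and call verdicts
#'
#' Applies the trained forest to every junction: the probability is the
#' fraction of trees voting genuine, and the verdict is genuine when the
#' probability is at or above `threshold` (default 0.5; raise it to
#' prioritize precision, lower it for recall).
#'
#' @param model `jf_model` from [train_forest()].
#' @param features Numeric matrix with the model's feature columns (row names
#'   used as junction ids).
#' @param threshold Probability threshold in \\[0, 1].
#' @return `data.table` with `id`, `probability`, `genuine`.
#' @export
score_and_filter <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "jf_model"), threshold >= 0, threshold <= 1)
  features <- as.matrix(features)
  if (!identical(colnames(features), model$feature_names)) {
    stop("contract error: feature columns do not match the trained model (",
         "expected ", length(model$feature_names), " canonical features)")
  }
  prob <- stats::predict(model$forest, newdata = features,
                         type = "prob")[, "genuine"]
  data.table::data.table(
    id = if (!is.null(rownames(features))) rownames(features) else
      as.character(seq_len(nrow(features))),
    probability = as.numeric(prob),
    genuine = as.numeric(prob) >= threshold)
}
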