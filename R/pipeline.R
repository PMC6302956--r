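# Pipeline orchestration: prepare -> junction analysis -> filter, runnable in
# one go or stage by stage; staged runs compose to exactly the full run.

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the junction-analysis stage
#'
#' Extracts split reads from a prepared alignment, collapses them into
#' distinct junctions, computes all alignment-derived metrics, and annotates
#' splice sites and hamming scores from the genome. Writes the full junction
#' set in tab and exon-BED formats.
#'
#' @param prepared `jf_prepared` from [prepare()].
#' @param config `jf_config` from [pipeline_config()].
#' @param output_dir Output directory.
#' @return List with `junctions` (the analyzed table), `files` and
#'   `diagnostics`.
#' @export
run_junction_analysis <- function(prepared, config = pipeline_config(),
                                  output_dir = tempfile("jf_junc_")) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  old_threads <- data.table::getDTthreads()
  data.table::setDTthreads(config$threads)
  on.exit(data.table::setDTthreads(old_threads))

  sr <- iterate_split_reads(prepared,
                            min_intron = config$min_intron,
                            max_intron = config$max_intron,
                            min_mapq = config$min_mapq,
                            include_secondary = config$include_secondary)
  junc <- analyze_junctions(sr)
  genome <- load_genome(prepared$genome_path)
  add_site_metrics(junc, genome, hamming_window = config$hamming_window)
  data.table::setattr(junc, "seed", config$seed)

  files <- list(all_tab = file.path(output_dir, "all_junctions.tab"),
                all_bed = file.path(output_dir, "all_junctions.bed"))
  write_junctions(junc, files$all_tab, "tab", seed = config$seed)
  write_junctions(junc, files$all_bed, "bed_exon")
  list(junctions = junc, files = files,
       diagnostics = attr(sr, "diagnostics", exact = TRUE))
}

#' Run the filtering stage
#'
#' Self-trains the classifier on an analyzed junction table: builds the
#' rule-derived positive and negative sets, fits the intron-size and PWM
#' models on them, adds the model-derived features to every junction,
#' balances the sets with SMOTE, trains the random forest, scores every
#' junction and writes both the scored full set and the filtered subset.
#'
#' @param junctions Analyzed junction table (from [run_junction_analysis()]
#'   or [read_junctions()] on a tab file).
#' @param genome Genome (path or named character vector).
#' @param config `jf_config`.
#' @param output_dir Output directory.
#' @return List with `junctions` (scored full set), `filtered`, `model`,
#'   `training`, `report`, `files`.
#' @export
run_filter <- function(junctions, genome, config = pipeline_config(),
                       output_dir = tempfile("jf_filter_")) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  old_threads <- data.table::getDTthreads()
  data.table::setDTthreads(config$threads)
  on.exit(data.table::setDTthreads(old_threads))

  junc <- data.table::as.data.table(junctions)
  genome <- load_genome(genome)

  training <- build_training_sets(junc, rules = config$rules,
                                  min_training = config$min_training)
  pos <- junc[training$label == "positive"]
  neg <- junc[training$label == "negative"]

  # model-derived features, fitted on the self-labelled sets
  size_model <- fit_intron_size(pos$end - pos$start)
  junc$intron_score <- intron_size_score(junc$end - junc$start, size_model)
  pos_pwm <- train_pwm(genome, pos, donor_window = config$donor_window,
                       acceptor_window = config$acceptor_window,
                       pseudocount = config$pseudocount)
  # negative loci mostly lack a resolvable strand; train the negative model
  # on their plus orientation (arbitrary but deterministic)
  neg_loci <- data.table::copy(neg)
  neg_loci[!strand %in% c("+", "-"), strand := "+"]
  neg_pwm <- train_pwm(genome, neg_loci, donor_window = config$donor_window,
                       acceptor_window = config$acceptor_window,
                       pseudocount = config$pseudocount)
  loci <- junc[, c("contig", "start", "end", "strand"), with = FALSE]
  junc$pwm_score <- pwm_score(pos_pwm, genome, loci)
  junc$splicing_signal <- splicing_signal_score(pos_pwm, neg_pwm, genome,
                                                loci)

  fm <- feature_matrix(junc)
  pos_m <- fm[training$label == "positive", , drop = FALSE]
  neg_m <- fm[training$label == "negative", , drop = FALSE]
  if (nrow(pos_m) <= nrow(neg_m)) {
    bal <- smote_balance(pos_m, neg_m, k = config$smote_k, seed = config$seed)
    feats <- rbind(bal$minority, bal$majority)
    labels <- c(rep(TRUE, nrow(bal$minority)), rep(FALSE, nrow(bal$majority)))
  } else {
    bal <- smote_balance(neg_m, pos_m, k = config$smote_k, seed = config$seed)
    feats <- rbind(bal$majority, bal$minority)
    labels <- c(rep(TRUE, nrow(bal$majority)), rep(FALSE, nrow(bal$minority)))
  }
  model <- train_forest(feats, labels, n_trees = config$n_trees,
                        seed = config$seed)
  verdicts <- score_and_filter(model, fm, threshold = config$threshold)
  junc[, probability := verdicts$probability]
  junc[, genuine := verdicts$genuine]
  filtered <- junc[genuine == TRUE]

  data.table::setattr(junc, "seed", config$seed)
  data.table::setattr(filtered, "seed", config$seed)

  files <- list(
    scored_tab = file.path(output_dir, "all_junctions.scored.tab"),
    scored_bed = file.path(output_dir, "all_junctions.scored.bed"),
    filtered_tab = file.path(output_dir, "filtered_junctions.tab"),
    filtered_bed = file.path(output_dir, "filtered_junctions.bed"),
    report = file.path(output_dir, "report.json"))
  write_junctions(junc, files$scored_tab, "tab", seed = config$seed)
  write_junctions(junc, files$scored_bed, "bed_exon")
  write_junctions(filtered, files$filtered_tab, "tab", seed = config$seed)
  write_junctions(filtered, files$filtered_bed, "bed_exon")

  report <- list(
    seed = config$seed,
    n_junctions = nrow(junc),
    n_filtered = nrow(filtered),
    n_positive_training = length(training$positive_keys),
    n_negative_training = length(training$negative_keys),
    intron_l95 = size_model$l95,
    threshold = config$threshold,
    n_trees = config$n_trees,
    feature_importance = as.list(model$importance))
  write_report(report, files$report)

  list(junctions = junc, filtered = filtered, model = model,
       training = training, report = report, files = files)
}

#' Run the full pipeline
#'
#' Prepare, analyze, filter — exactly the composition of the three stages
#' under one configuration, writing both the full analyzed junction set and
#' the filtered subset in tab and exon-BED formats, plus a JSON report with
#' counts, training-set sizes, feature importances and the seed.
#'
#' @param alignments Character vector of SAM/BAM paths.
#' @param genome Genome FASTA path.
#' @param config `jf_config`.
#' @param output_dir Output directory.
#' @return List with `prepared`, `junctions`, `filtered`, `model`,
#'   `training`, `report`, `files` (all stage outputs).
#' @export
run_full <- function(alignments, genome, config = pipeline_config(),
                     output_dir = tempfile("jf_run_")) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  prepared <- stage_wrap("prep",
    prepare(alignments, genome, file.path(output_dir, "prepared")))
  junc_out <- stage_wrap("junc",
    run_junction_analysis(prepared, config, output_dir))
  # the filter stage consumes the junc stage's tab file, so staged and full
  # runs are the same computation
  reread <- read_junctions(junc_out$files$all_tab, "tab")
  filt_out <- stage_wrap("filter",
    run_filter(reread, prepared$genome_path, config, output_dir))
  c(list(prepared = prepared, diagnostics = junc_out$diagnostics),
    filt_out,
    list(files = c(junc_out$files, filt_out$files)))
}

#' Run one pipeline stage
#'
#' @param stage `"prep"`, `"junc"` or `"filter"`.
#' @param ... Stage inputs: `prep` takes `alignments` and `genome`; `junc`
#'   takes a `jf_prepared` object (or `alignments` + `genome`); `filter`
#'   takes `junctions` (a table or a tab-file path) and `genome`.
#' @param config `jf_config`.
#' @param output_dir Output directory.
#' @return The stage's output list.
#' @export
run_stage <- function(stage = c("prep", "junc", "filter"), ...,
                      config = pipeline_config(),
                      output_dir = tempfile("jf_stage_")) {
  stage <- match.arg(stage)
  args <- list(...)
  if (stage == "prep") {
    return(prepare(args$alignments, args$genome, output_dir))
  }
  if (stage == "junc") {
    prepared <- args$prepared
    if (is.null(prepared)) {
      if (is.null(args$alignments) || is.null(args$genome)) {
        stop("usage error: stage 'junc' needs a prepared input (or ",
             "alignments + genome); run stage 'prep' first")
      }
      prepared <- prepare(args$alignments, args$genome,
                          file.path(output_dir, "prepared"))
    }
    return(run_junction_analysis(prepared, config, output_dir))
  }
  junctions <- args$junctions
  if (is.null(junctions)) {
    stop("usage error: stage 'filter' needs the junc stage's junction table ",
         "or tab file; run stage 'junc' first")
  }
  if (is.character(junctions) && length(junctions) == 1L) {
    junctions <- read_junctions(junctions, "tab")
  }
  if (is.null(args$genome)) stop("usage error: stage 'filter' needs a genome")
  run_filter(junctions, args$genome, config, output_dir)
}
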