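#' Run the editing-analysis pipeline end to end
#'
#' Executes filter, pileup, edit calling, annotation, tissue merge, RPKM
#' and summary, writing all tables as TSV plus a machine-readable run log.
#' The input is either a [sim_config()] (a self-contained demonstration
#' run: the synthetic dataset is generated first and a recovery report
#' against the truth table is emitted) or a list with elements `genome`
#' (FASTA path), `features` (GFF3 path) and `sam` (named character vector
#' of per-tissue SAM/BAM paths).
#'
#' @param config A [sim_config()] or an input-path list (see above).
#' @param outdir Output directory, created if needed.
#' @param filter_params An [alignment_filter_params()].
#' @param params A [call_params()].
#' @param diff_threshold Differential-editing threshold.
#' @param known_positions Optional integer vector of previously reported
#'   edit positions (adds a newly-discovered count to the summary).
#' @return Invisibly, a list with all intermediate objects (`genome`,
#'   `features`, `pileups`, `calls`, `annotated`, `differential`,
#'   `expression`, `summary`, `truth` when simulated) and `paths`.
#' @export
run_pipeline <- function(config, outdir,
                         filter_params = alignment_filter_params(),
                         params = call_params(), diff_threshold = 0.20,
                         known_positions = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simulated <- inherits(config, "sim_config")
  truth <- NULL
  if (simulated) {
    sim <- simulate_dataset(config, file.path(outdir, "sim"))
    genome <- sim$genome
    features <- sim$features
    truth <- sim$truth
    aln_raw <- sim$alignments
    tissues <- config$tissue_labels
  } else {
    for (field in c("genome", "features", "sam")) {
      if (is.null(config[[field]]))
        stop("configuration error: missing field '", field, "'")
    }
    if (is.null(names(config$sam)) || any(!nzchar(names(config$sam))))
      stop("configuration error: 'sam' must be a named vector of per-tissue paths")
    genome <- read_genome(config$genome)
    features <- read_features(config$features)
    tissues <- names(config$sam)
    aln_raw <- lapply(config$sam, read_alignments, genome = genome)
  }

  aln <- lapply(aln_raw, filter_alignments, params = filter_params)
  pileups <- lapply(aln, build_pileup, genome = genome)
  calls <- lapply(pileups, call_edits, genome = genome, features = features,
                  params = params)
  annotated <- lapply(calls, annotate_edits, features = features,
                      genome = genome)
  differential <- merge_tissues(calls, pileups, genome, params = params,
                                diff_threshold = diff_threshold)
  expression <- compute_rpkm(aln, features)
  summary <- summarize_edits(annotated, genome, differential = differential,
                             known_positions = known_positions,
                             diff_threshold = diff_threshold)
  context <- neighbor_context(do.call(rbind, lapply(tissues, function(t) {
    x <- annotated[[t]]
    x[!x$homopolymer_flag, , drop = FALSE]
  })), genome)

  paths <- list()
  for (t in tissues) {
    paths[[paste0("calls_", t)]] <- file.path(outdir, paste0("calls_", t, ".tsv"))
    write_calls(annotated[[t]], paths[[paste0("calls_", t)]])
  }
  paths$differential <- file.path(outdir, "differential.tsv")
  write.table(format_efficiencies(differential), paths$differential,
              sep = "\t", quote = FALSE, row.names = FALSE)
  paths$expression <- file.path(outdir, "expression.tsv")
  write.table(expression, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$context <- file.path(outdir, "context.tsv")
  write.table(context, paths$context, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$summary <- file.path(outdir, "summary.txt")
  con <- file(paths$summary, open = "wb")
  writeLines(utils::capture.output(print(summary)), con, sep = "\n")
  close(con)

  if (simulated) {
    paths$recovery <- file.path(outdir, "recovery.tsv")
    rec <- recovery_report(truth, calls, config)
    write.table(rec, paths$recovery, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  paths$run_log <- file.path(outdir, "run_log.json")
  log <- list(
    package = "plastedit",
    version = as.character(utils::packageVersion("plastedit")),
    simulated = simulated,
    tissues = tissues,
    filter_params = unclass(filter_params),
    call_params = unclass(params),
    diff_threshold = diff_threshold,
    seed = if (simulated) config$seed else NULL
  )
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(genome = genome, features = features, truth = truth,
                 alignments = aln, pileups = pileups, calls = calls,
                 annotated = annotated, differential = differential,
                 expression = expression, summary = summary,
                 context = context, paths = paths))
}

format_efficiencies <- function(df) {
  for (nm in grep("^(eff_|delta$)", names(df), value = TRUE))
    df[[nm]] <- ifelse(is.na(df[[nm]]), "NA", sprintf("%.4f", df[[nm]]))
  df
}

#' Recovery of planted edits by the caller
#'
#' Compares called sites against a simulation truth table, per tissue:
#' whether each planted site was called, its called efficiency, the
#' absolute error, and whether the estimate lies within three binomial
#' standard errors of the truth at the observed depth.
#'
#' @param truth Truth table from [plant_edits()].
#' @param calls_per_tissue Named list of call data frames.
#' @param config The [sim_config()] used for simulation.
#' @return Long data frame, one row per planted site per tissue.
#' @export
recovery_report <- function(truth, calls_per_tissue, config) {
  rows <- list()
  for (t in config$tissue_labels) {
    ct <- calls_per_tissue[[t]]
    m <- match(truth$position, ct$position)
    true_eff <- truth[[paste0("eff_", t)]]
    called_eff <- ct$efficiency[m]
    depth <- ct$depth[m]
    se <- sqrt(true_eff * (1 - true_eff) / pmax(depth, 1L))
    rows[[t]] <- data.frame(
      tissue = t, position = truth$position, strand = truth$strand,
      edit_type = truth$edit_type, feature_class = truth$feature_class,
      in_homopolymer = truth$in_homopolymer,
      true_efficiency = true_eff,
      called = !is.na(m),
      flagged = ifelse(is.na(m), NA, ct$homopolymer_flag[m]),
      called_efficiency = called_eff,
      depth = depth,
      abs_error = abs(called_eff - true_eff),
      within_3se = !is.na(called_eff) & abs(called_eff - true_eff) <= 3 * se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
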