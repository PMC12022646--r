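#' Pipeline configuration
#'
#' Bundles stage toggles, thresholds and either a simulation config or
#' input paths for a full run of the analysis chain: simulate (or load)
#' -> isotope-correct -> quantify -> batch-correct -> CV filter ->
#' variability / individuality -> sex model.
#'
#' @param simulation a [cohort_config()] (with a seed), or NULL when
#'   loading data from files.
#' @param areas_csv,manifest_tsv,registry_tsv input paths, used when
#'   `simulation` is NULL.
#' @param correct_isotopes run type-II isotopic overlap correction
#'   (default TRUE).
#' @param batch_scale scale for batch correction, `"linear"` or `"log2"`.
#' @param cv_threshold retention CV threshold in percent (default 30).
#' @param rescue_rate study detection rate for rescuing high-CV lipids.
#' @param q_threshold significance threshold on BH q-values (default 0.05).
#' @param n_distance_participants participants sampled for the
#'   individuality analysis.
#' @param run_variability,run_sex_model stage toggles.
#' @param out_dir optional output directory; stage outputs are written as
#'   TSV/CSV/JSON when given.
#' @param seed seed for the non-simulation stochastic steps (participant
#'   sampling); defaults to the simulation seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL,
                            areas_csv = NULL, manifest_tsv = NULL,
                            registry_tsv = NULL,
                            correct_isotopes = TRUE,
                            batch_scale = c("linear", "log2"),
                            cv_threshold = 30,
                            rescue_rate = 0.8,
                            q_threshold = 0.05,
                            n_distance_participants = 20,
                            run_variability = TRUE,
                            run_sex_model = TRUE,
                            out_dir = NULL,
                            seed = NULL) {
  batch_scale <- match.arg(batch_scale)
  if (is.null(simulation)) {
    if (is.null(areas_csv) || is.null(manifest_tsv) || is.null(registry_tsv)) {
      stop("either `simulation` or all of areas_csv/manifest_tsv/registry_tsv must be given")
    }
  } else {
    stopifnot(inherits(simulation, "cohort_config"))
    if (is.null(simulation$seed)) stop("a seed is mandatory when simulating")
    if (is.null(seed)) seed <- simulation$seed
  }
  if (cv_threshold < 0) stop("cv_threshold must be >= 0")
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must be in (0, 1]")
  if (rescue_rate < 0 || rescue_rate > 1) stop("rescue_rate must be in [0, 1]")
  structure(list(simulation = simulation, areas_csv = areas_csv,
                 manifest_tsv = manifest_tsv, registry_tsv = registry_tsv,
                 correct_isotopes = correct_isotopes,
                 batch_scale = batch_scale, cv_threshold = cv_threshold,
                 rescue_rate = rescue_rate, q_threshold = q_threshold,
                 n_distance_participants = n_distance_participants,
                 run_variability = run_variability,
                 run_sex_model = run_sex_model,
                 out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the chain with per-stage logging (timings and record
#' accounting: injections, lipids retained/dropped with reasons). Every
#' stage output is a pure function of (inputs, config, seed); identical
#' config and seed reproduce identical numbers.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result` with elements `manifest`,
#'   `registry`, `truth` (when simulated), `areas`, `concentrations`,
#'   `corrected`, `batch_model`, `qc_cv`, `retention`, `variability`
#'   (subject CVs + ICC + distances + PCA), `sex_results`, and a `funnel`
#'   accounting data frame.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  ## --- acquire ------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_cohort(config$simulation))
    manifest <- sim$manifest; registry <- sim$registry
    areas <- sim$areas; truth <- sim$truth
  } else {
    sim <- NULL; truth <- NULL
    manifest <- stage("load", read.delim(config$manifest_tsv))
    registry <- read_registry(config$registry_tsv)
    areas <- read_abundance_csv(config$areas_csv)
  }
  say("injections: %d study, %d QC, %d blank; %d lipid transitions",
      sum(manifest$role == "study"), sum(manifest$role == "QC"),
      sum(manifest$role == "blank"), nrow(registry))

  ## --- isotope correction on the area scale -------------------------
  if (config$correct_isotopes) {
    graph <- interference_graph(registry)
    areas_c <- stage("deisotope", correct_isotopic_overlap(areas, graph))
    say("isotope correction: %d interference edges, %d cells clipped at 0",
        nrow(graph), attr(areas_c, "n_clipped"))
  } else {
    areas_c <- areas
  }

  ## --- quantification -----------------------------------------------
  conc <- stage("quantify", quantify(areas_c, registry))

  ## --- batch correction (QC-anchored) -------------------------------
  nonblank <- manifest$role != "blank"
  qc_rows <- manifest$role == "QC"
  model <- stage("fit_batch_model",
                 fit_batch_model(conc[manifest$injection_id[qc_rows], ,
                                      drop = FALSE],
                                 manifest$batch[qc_rows],
                                 scale = config$batch_scale))
  corrected <- stage("apply_batch_correction", {
    keep <- manifest$injection_id[nonblank]
    apply_batch_correction(conc[keep, , drop = FALSE], model,
                           manifest$batch[nonblank])
  })

  ## --- QC CVs + retention filter ------------------------------------
  cv_post <- qc_cv(corrected[manifest$injection_id[qc_rows], , drop = FALSE])
  study_ids <- manifest$injection_id[manifest$role == "study"]
  det <- colMeans(!is.na(corrected[study_ids, , drop = FALSE]) &
                    corrected[study_ids, , drop = FALSE] > 0)
  retention <- retention_filter(cv_post, threshold = config$cv_threshold,
                                study_detection_rate = det,
                                rescue_rate = config$rescue_rate)
  say("retention: %d/%d lipids kept (%d rescued); median between-batch CV %.1f%%",
      sum(retention$retained), nrow(retention), sum(retention$rescue_flag),
      median(cv_post, na.rm = TRUE))
  kept <- retention$lipid[retention$retained]
  analysed <- corrected[, kept, drop = FALSE]

  ## --- variability / individuality ----------------------------------
  variability <- NULL
  if (config$run_variability) {
    variability <- stage("variability", {
      cvs <- subject_cvs(analysed, manifest)
      icc_df <- icc(analysed, manifest)
      dists <- individuality_distances(
        analysed, manifest,
        n_sampled_participants = config$n_distance_participants,
        seed = config$seed)
      pca <- pca_overview(analysed[study_ids[study_ids %in% rownames(analysed)], ,
                                   drop = FALSE])
      report <- merge(cvs, icc_df[, c("lipid", "icc", "sigma2_b", "sigma2_w",
                                      "converged")], by = "lipid", sort = FALSE)
      report$qc_cv <- cv_post[report$lipid]
      list(report = report, distances = dists, pca = pca)
    })
    say("ICC median %.2f; within/between distance %.2f/%.2f (p=%.2g)",
        median(variability$report$icc, na.rm = TRUE),
        variability$distances$within_mean, variability$distances$between_mean,
        variability$distances$p)
  }

  ## --- sex model ----------------------------------------------------
  sex_results <- NULL
  if (config$run_sex_model) {
    sex_results <- stage("sex_model",
                         fit_sex_model(analysed, manifest, registry = registry))
    say("sex model: %d/%d lipids with q < %.2f",
        sum(sex_results$q < config$q_threshold, na.rm = TRUE),
        nrow(sex_results), config$q_threshold)
  }

  funnel <- data.frame(
    stage = c("quantified", "retained", "rescued", "sex_significant"),
    n = c(nrow(retention), sum(retention$retained),
          sum(retention$rescue_flag),
          if (is.null(sex_results)) NA_integer_ else
            sum(sex_results$q < config$q_threshold, na.rm = TRUE)))

  result <- structure(list(manifest = manifest, registry = registry,
                           truth = truth, areas = areas,
                           concentrations = conc, corrected = corrected,
                           batch_model = model, qc_cv = cv_post,
                           retention = retention, variability = variability,
                           sex_results = sex_results, funnel = funnel,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

## Writes the stage outputs as plain-text tables under `dir`.
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(result$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_registry(result$registry, file.path(dir, "registry.tsv"))
  write_abundance_csv(result$corrected, file.path(dir, "concentrations_corrected.csv"))
  qc <- data.frame(lipid = names(result$qc_cv),
                   between_batch_cv = unname(result$qc_cv))
  write.table(merge(qc, result$retention[, c("lipid", "retained",
                                             "rescue_flag", "reason")],
                    by = "lipid"),
              file.path(dir, "qc_retention.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(result$variability)) {
    write.table(result$variability$report,
                file.path(dir, "variability.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_dendrogram(result$variability$distances,
                     file.path(dir, "individuality_dendrogram.nwk"))
  }
  if (!is.null(result$sex_results)) {
    write.table(result$sex_results, file.path(dir, "sex_differences.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  lipids quantified: %d, retained: %d\n",
              nrow(x$retention), sum(x$retention$retained)))
  if (!is.null(x$variability)) {
    cat(sprintf("  median ICC: %.2f\n",
                median(x$variability$report$icc, na.rm = TRUE)))
  }
  if (!is.null(x$sex_results)) {
    cat(sprintf("  sex-different lipids (q < %.2f): %d\n",
                x$config$q_threshold,
                sum(x$sex_results$q < x$config$q_threshold, na.rm = TRUE)))
  }
  invisible(x)
}
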