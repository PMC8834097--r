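#' Default end-to-end pipeline configuration
#'
#' Parameters for [run_pipeline()]: two synthetic cohorts sharing a planted
#' signature, preprocessing (imputation + outlier screen), discriminant
#' fits, LKOCV stability profiling, univariate screens, coincident
#' signature selection, a reduced refit, and cross-dataset signature
#' transfer. Every stochastic stage has an explicit seed.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @return A named list (class `run_config`), YAML-serializable.
#' @export
default_run_config <- function(out_dir = tempfile("cytosig_run_"), seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir,
    seed = seed,
    n_shared_signature = 7,
    impute = "half_min",
    outlier_confidence = 0.995,
    outlier_components = 2,
    stability = list(K_a = 5, K_b = 1, n_iterations = 100),
    signature = list(mean_threshold = 0.2, cv_threshold = 1.0,
                     require_direction_match = TRUE),
    cohort_a = list(preset = "human41", seed = seed * 101L + 1L),
    cohort_b = list(preset = "mouse_brain", seed = seed * 101L + 2L),
    lkocv_seed_a = seed * 101L + 3L,
    lkocv_seed_b = seed * 101L + 4L
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [default_run_config()]; absent
#'   fields fall back to the defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = if (is.null(usr$seed)) 1L else usr$seed)
  for (nm in names(usr)) {
    if (is.list(usr[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(usr[[nm]])] <- usr[[nm]]
    } else cfg[[nm]] <- usr[[nm]]
  }
  cfg
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates the study replica end to end on two synthetic cohorts that
#' share a planted signature: generate (`gen_paired_datasets`), preprocess
#' (imputation, iterative Mahalanobis outlier screen), fit rotated
#' discriminant PLS models, profile LV1 loading stability by LKOCV, run
#' univariate rank screens, select the coincident cross-dataset signature,
#' refit on the reduced signature panel, and transfer the cohort-A
#' signature model onto cohort B. All stage outputs are written under
#' `config$out_dir` (TSV/JSON) along with a machine-readable
#' `summary.json`; reruns with the same config are bit-identical.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()], or a path to a YAML config.
#' @return Invisibly, a list with the fitted objects and the summary list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cfg_a <- stage("simulate", do.call(synthetic_preset, config$cohort_a))
  cfg_b <- do.call(synthetic_preset, config$cohort_b)
  shared <- intersect(cfg_a$analyte_names, cfg_b$analyte_names)
  shared <- shared[seq_len(min(config$n_shared_signature, length(shared)))]
  pair <- stage("simulate", gen_paired_datasets(cfg_a, cfg_b, shared))
  write_panel(pair$a$panel, out("panel_a.tsv"), out("meta_a.tsv"))
  write_panel(pair$b$panel, out("panel_b.tsv"), out("meta_b.tsv"))

  pre <- stage("preprocess", lapply(list(a = pair$a$panel, b = pair$b$panel),
    function(p) remove_outliers(impute_missing(p, config$impute),
                                confidence = config$outlier_confidence,
                                n_components = config$outlier_components)))
  jsonlite::write_json(list(removed_a = pre$a$removed_ids,
                            removed_b = pre$b$removed_ids),
                       out("removed.json"), auto_unbox = FALSE)

  case_a <- cfg_a$group_labels[["case"]]; case_b <- cfg_b$group_labels[["case"]]
  fit_a <- stage("fit", cyto_pls(pre$a$panel, "group", case = case_a))
  fit_b <- stage("fit", cyto_pls(pre$b$panel, "group", case = case_b))
  write_model(fit_a, out("model_a.json"))
  write_model(fit_b, out("model_b.json"))

  prof_a <- stage("stability",
    lkocv_profile(pre$a$panel, "group", case = case_a, K = config$stability$K_a,
                  n_iterations = config$stability$n_iterations,
                  seed = config$lkocv_seed_a))
  prof_b <- stage("stability",
    lkocv_profile(pre$b$panel, "group", case = case_b, K = config$stability$K_b,
                  n_iterations = config$stability$n_iterations,
                  seed = config$lkocv_seed_b))
  write_profile(prof_a, out("profile_a.tsv"))
  write_profile(prof_b, out("profile_b.tsv"))

  uni_a <- stage("univariate", univariate_screen(pre$a$panel, "subgroup"))
  uni_b <- stage("univariate", univariate_screen(pre$b$panel, "group"))
  utils::write.table(uni_a, out("univariate_a.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(uni_b, out("univariate_b.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  sig <- stage("coincident", withCallingHandlers(
    select_coincident(prof_a, prof_b,
                      mean_threshold = config$signature$mean_threshold,
                      cv_threshold = config$signature$cv_threshold,
                      require_direction_match = config$signature$require_direction_match),
    warning = function(w) invokeRestart("muffleWarning")))
  jsonlite::write_json(as.data.frame(sig), out("signature.json"), digits = NA)

  reduced <- transfer <- NULL
  if (nrow(sig)) {
    reduced <- stage("reduced_fit",
                     reduced_fit(pre$a$panel, sig, "group", case = case_a))
    write_model(reduced, out("model_reduced_a.json"))
    transfer <- stage("transfer",
                      transfer_signature(reduced, pre$b$panel, case = case_b))
    jsonlite::write_json(list(auc = transfer$auc, p = transfer$p,
                              lv1 = as.list(transfer$lv1)),
                         out("transfer.json"), digits = NA, auto_unbox = TRUE)
  }

  summary <- list(
    seed = config$seed,
    n_samples = c(a = nrow(pre$a$panel$x), b = nrow(pre$b$panel$x)),
    removed_outliers = list(a = pre$a$removed_ids, b = pre$b$removed_ids),
    planted_shared = shared,
    lv1_loadings_a = as.list(stats::setNames(fit_a$weights[, 1], fit_a$analytes)),
    lv1_loadings_b = as.list(stats::setNames(fit_b$weights[, 1], fit_b$analytes)),
    signature = sig$analyte,
    signature_recovered_shared = intersect(sig$analyte, shared),
    transfer_auc = if (is.null(transfer)) NA else transfer$auc,
    transfer_p = if (is.null(transfer)) NA else transfer$p,
    n_significant_univariate_b = sum(uni_b$p_adjusted < 0.05, na.rm = TRUE)
  )
  jsonlite::write_json(summary, out("summary.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pair = pair, fits = list(a = fit_a, b = fit_b),
                 profiles = list(a = prof_a, b = prof_b),
                 univariate = list(a = uni_a, b = uni_b),
                 signature = sig, reduced = reduced, transfer = transfer,
                 summary = summary, out_dir = config$out_dir))
}
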