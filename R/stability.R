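#' Leave-K-out stability profile of LV1 loadings
#'
#' Quantifies how much each analyte's LV1 loading depends on individual
#' samples. The model is refitted `n_iterations` times, each time after
#' removing a uniformly random subset of K samples (drawn without
#' replacement within an iteration; independent draws across iterations).
#' Each replicate's full pipeline is re-run from scratch (z-scoring, NIPALS
#' fit, rotation), its LV1 weight vector is sign-aligned to the full-model
#' reference (flipped when the dot product is negative — PLS weights are
#' sign-indeterminate across refits), and per-analyte mean, SD and
#' coefficient of variation (SD/|mean|) are accumulated. A low CV marks a
#' loading that is stable against which samples happened to be measured.
#'
#' Draws that would leave a group with fewer than 2 samples are redrawn (the
#' count is reported), so every replicate model is a valid two-group fit.
#'
#' @param panel A [cytokine_panel()].
#' @param target,case As in [cyto_pls()].
#' @param K Number of samples to leave out per iteration (0 <= K < n - 2).
#' @param n_iterations Number of replicate models (default 100).
#' @param seed Integer seed; the profile is bit-reproducible given the seed.
#' @param impute Missing-cell policy.
#' @return Object of class `stability_profile`: a data frame with columns
#'   `analyte`, `mean`, `sd`, `cv` plus attributes `K`, `n_iterations`,
#'   `seed`, `reference` (full-model LV1 loadings), `n_redraws` and
#'   `case_label`.
#' @examples
#' cohort <- gen_cohort(synthetic_config(n_control = 10, n_case = 10,
#'                                       n_analytes = 10, seed = 3))
#' prof <- lkocv_profile(cohort$panel, "group", case = "MLIV", K = 2,
#'                       n_iterations = 25, seed = 11)
#' head(prof[order(-abs(prof$mean)), ])
#' @export
lkocv_profile <- function(panel, target, case = NULL, K, n_iterations = 100,
                          seed = NULL, impute = "half_min") {
  stopifnot(inherits(panel, "cytokine_panel"))
  panel <- impute_missing(panel, impute)
  n <- nrow(panel$x)
  if (K < 0 || K >= n - 2) stop("K must satisfy 0 <= K < n - 2")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  full <- cyto_pls(panel, target, case = case)
  ref <- full$weights[, 1]
  if (!is.null(seed)) set.seed(seed)
  p <- length(ref)
  acc <- matrix(NA_real_, n_iterations, p, dimnames = list(NULL, names(ref)))
  grp <- if (full$y_type == "discriminant") full$y else NULL
  n_redraws <- 0L
  for (it in seq_len(n_iterations)) {
    repeat {
      keep <- if (K == 0) seq_len(n) else setdiff(seq_len(n), sample.int(n, K))
      if (is.null(grp) || (sum(grp[keep] > 0) >= 2 && sum(grp[keep] <= 0) >= 2)) break
      n_redraws <- n_redraws + 1L
    }
    sub <- subset_panel(panel, samples = keep)
    tv <- if (is.character(target) && length(target) == 1 &&
              target %in% names(panel$meta)) target else target[keep]
    rep_fit <- cyto_pls(sub, tv, case = case)
    w <- rep_fit$weights[, 1]
    if (sum(w * ref) < 0) w <- -w
    acc[it, ] <- w
  }
  mu <- colMeans(acc)
  sdv <- apply(acc, 2, stats::sd)
  if (n_iterations == 1) sdv[] <- 0
  cv <- ifelse(mu == 0, Inf, sdv / abs(mu))
  out <- data.frame(analyte = names(ref), mean = unname(mu), sd = unname(sdv),
                    cv = unname(cv), stringsAsFactors = FALSE)
  structure(out,
            class = c("stability_profile", "data.frame"),
            K = K, n_iterations = n_iterations, seed = seed,
            reference = ref, n_redraws = n_redraws,
            case_label = full$case_label, y_type = full$y_type)
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("<stability_profile> %d analytes, K = %d, %d iterations (%d redraws)\n",
              nrow(x), attr(x, "K"), attr(x, "n_iterations"), attr(x, "n_redraws")))
  ord <- order(-abs(x$mean))
  print.data.frame(utils::head(x[ord, ], 10), row.names = FALSE, digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more analytes\n")
  invisible(x)
}

#' Write / read a stability profile as TSV
#'
#' @param profile A `stability_profile`.
#' @param path Output path.
#' @return `path` invisibly (writer); a plain data frame (reader).
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
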