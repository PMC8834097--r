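#' Impute missing concentrations
#'
#' Multiplexed immunoassays routinely report out-of-range values as missing;
#' before scaling these must be filled (or the samples dropped).
#'
#' @param panel A [cytokine_panel()].
#' @param policy One of:
#'   * `"half_min"` (default): replace missing cells with half the column's
#'     minimum observed value — the usual below-detection-limit convention;
#'   * `"column_min"`: replace with the column minimum;
#'   * `"drop_sample"`: remove every sample with any missing value.
#' @return A `cytokine_panel` with no missing cells.
#' @export
impute_missing <- function(panel, policy = c("half_min", "column_min", "drop_sample")) {
  stopifnot(inherits(panel, "cytokine_panel"))
  policy <- match.arg(policy)
  x <- panel$x
  if (!anyNA(x)) return(panel)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("analyte(s) with no observed values: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  if (policy == "drop_sample") {
    keep <- rowSums(is.na(x)) == 0
    if (!any(keep)) stop("drop_sample would remove every sample")
    return(subset_panel(panel, samples = keep))
  }
  fill <- apply(x, 2, min, na.rm = TRUE)
  if (policy == "half_min") fill <- fill / 2
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- fill[idx[, 2]]
  cytokine_panel(x, panel$meta)
}

#' Column z-scoring
#'
#' Centers and scales each analyte to mean 0, SD 1 (sample SD, divisor
#' n - 1). All model fitting in this package operates on z-scored data, so
#' analytes contribute on a common scale regardless of their raw abundance.
#' Missing cells are imputed first (see [impute_missing()]).
#'
#' @param panel A [cytokine_panel()] or a plain numeric matrix.
#' @param impute Imputation policy passed to [impute_missing()] when `panel`
#'   has missing cells.
#' @return An object of class `zscaled`: list with `z` (n x p matrix),
#'   `center` and `scale` (per-analyte mean and sample SD, pg/mL), and
#'   `analytes`. The stored parameters let [predict.zscaled()] apply the
#'   identical transform to new data.
#' @examples
#' zs <- zscore(matrix(c(1, 3, 2, 8), 2, 2,
#'                     dimnames = list(c("a", "b"), c("x", "y"))))
#' zs$z  # each column has mean 0, SD 1
#' @export
zscore <- function(panel, impute = "half_min") {
  if (inherits(panel, "cytokine_panel")) {
    panel <- impute_missing(panel, impute)
    x <- panel$x
  } else {
    x <- as.matrix(panel)
    if (anyNA(x)) stop("matrix input to zscore() must be complete")
  }
  if (nrow(x) < 2) stop("need at least 2 samples to z-score")
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad))
    stop("constant analyte column(s), cannot scale: ",
         paste(colnames(x)[bad], collapse = ", "))
  z <- sweep(sweep(x, 2, ctr), 2, sdv, "/")
  structure(list(z = z, center = ctr, scale = sdv, analytes = colnames(x)),
            class = "zscaled")
}

#' Apply a stored z-scoring transform to new data
#'
#' @param object A `zscaled` object from [zscore()].
#' @param newdata A `cytokine_panel` or matrix containing at least the
#'   analytes of `object` (matched by name).
#' @param ... Unused.
#' @return Matrix of z-scores under the training transform.
#' @export
predict.zscaled <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cytokine_panel")) newdata$x else as.matrix(newdata)
  miss <- setdiff(object$analytes, colnames(x))
  if (length(miss)) stop("analyte(s) missing from new data: ", paste(miss, collapse = ", "))
  x <- x[, object$analytes, drop = FALSE]
  sweep(sweep(x, 2, object$center), 2, object$scale, "/")
}

#' @export
print.zscaled <- function(x, ...) {
  cat(sprintf("<zscaled> %d samples x %d analytes (column mean 0, sample SD 1)\n",
              nrow(x$z), length(x$analytes)))
  invisible(x)
}

#' Iterative PCA/Mahalanobis outlier removal
#'
#' Screens a cohort for multivariate outliers: the panel is z-scored, a PCA
#' is run, and each sample's squared Mahalanobis distance in the leading
#' principal component scores is compared to the chi-square quantile at the
#' chosen confidence (df = number of components) — the multivariate
#' confidence-ellipse criterion. The single worst offender beyond the cutoff
#' is removed and the screen recomputed from scratch, until no sample
#' exceeds the cutoff. One-at-a-time removal with a full refit matters:
#' a gross outlier inflates the covariance and can mask milder ones.
#'
#' @param panel A [cytokine_panel()].
#' @param confidence Confidence level of the ellipse, in (0, 1). Default
#'   0.995 (a 99.5% ellipse).
#' @param n_components Number of leading principal components defining the
#'   score space (default 2, a literal ellipse).
#' @param impute Imputation policy applied before screening.
#' @return List with `panel` (survivors, original order), `removed_ids`
#'   (sample ids in removal order) and `removed_info` (data frame with each
#'   removed sample's squared distance and the cutoff at its iteration).
#' @export
remove_outliers <- function(panel, confidence = 0.995, n_components = 2,
                            impute = "half_min") {
  stopifnot(inherits(panel, "cytokine_panel"))
  if (!(confidence > 0 && confidence < 1)) stop("confidence must be in (0, 1)")
  stopifnot(n_components >= 1)
  panel <- impute_missing(panel, impute)
  cutoff <- stats::qchisq(confidence, df = n_components)
  removed <- character(0)
  removed_info <- data.frame(sample_id = character(0), d2 = numeric(0),
                             cutoff = numeric(0), stringsAsFactors = FALSE)
  cur <- panel
  repeat {
    if (nrow(cur$x) <= n_components + 2)
      stop("outlier removal reduced the cohort to <= n_components + 2 samples; degenerate cohort")
    zs <- zscore(cur)
    pc <- stats::prcomp(zs$z, center = FALSE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    ev <- pc$sdev[seq_len(k)]^2
    ev[ev < .Machine$double.eps] <- NA  # flat directions carry no distance
    d2 <- rowSums(sweep(pc$x[, seq_len(k), drop = FALSE]^2, 2, ev, "/"), na.rm = TRUE)
    over <- which(d2 > cutoff)
    if (!length(over)) break
    worst <- over[which.max(d2[over])]  # which.max ties break at smaller index
    removed <- c(removed, rownames(cur$x)[worst])
    removed_info <- rbind(removed_info,
                          data.frame(sample_id = rownames(cur$x)[worst],
                                     d2 = unname(d2[worst]), cutoff = cutoff,
                                     stringsAsFactors = FALSE))
    cur <- subset_panel(cur, samples = -worst)
  }
  list(panel = cur, removed_ids = removed, removed_info = removed_info)
}
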