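#' Encode a two-group label vector for discriminant PLS
#'
#' @param labels Character/factor vector with exactly two distinct values.
#' @param case_label The label coded +1; the other is coded -1.
#' @return Numeric vector of +1/-1.
#' @export
encode_groups <- function(labels, case_label) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2) stop("need two distinct group labels, got one")
  if (length(lev) > 2)
    stop("discriminant PLS here is two-class; got labels: ",
         paste(lev, collapse = ", "))
  if (!case_label %in% lev) stop("case label '", case_label, "' not present")
  ifelse(labels == case_label, 1, -1)
}

# NIPALS PLS for a single response. Deterministic: for one y column each
# component has the closed form w = X'y / ||X'y||, t = Xw, followed by
# rank-one deflation of X and y.
fit_nipals <- function(z, y, ncomp = 2) {
  z <- as.matrix(z)
  n <- nrow(z); p <- ncol(z)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 samples to fit")
  if (ncomp > min(n - 1, p)) stop("ncomp exceeds min(n - 1, p)")
  yc <- y - mean(y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  Xd <- z; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("no predictive direction: cross-covariance X'y is zero at component ", a)
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Xd, t)) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
  }
  dimnames(W) <- dimnames(P) <- list(colnames(z), paste0("LV", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(z), paste0("LV", seq_len(ncomp)))
  # projection weights W(P'W)^-1 map z-scored data straight onto the scores
  Wstar <- W %*% solve(crossprod(P, W))
  dimnames(Wstar) <- dimnames(W)
  list(weights = W, x_loadings = P, scores = Tm, y_loadings = q,
       projection = Wstar, y_mean = mean(y))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Orthogonal rotation of a 2-component latent space so that the group
# separation (discriminant) or the covariance with a continuous target
# (regression) lies entirely along LV1; then sign-flip each axis so the case
# group (or the better-scoring samples) sit positive on LV1. The
# reconstruction T W' is invariant because the same rotation is applied to
# scores and weight/loading matrices.
rotate_to_lv1 <- function(fit, y, y_type) {
  Tm <- fit$scores
  if (ncol(Tm) != 2) stop("rotation requires exactly 2 components")
  if (max(abs(sweep(Tm, 2, colMeans(Tm)))) < 1e-12)
    stop("degenerate scores: all samples identical, cannot rotate")
  if (y_type == "discriminant") {
    d <- c(mean(Tm[y > 0, 1]) - mean(Tm[y <= 0, 1]),
           mean(Tm[y > 0, 2]) - mean(Tm[y <= 0, 2]))
  } else {
    yc <- y - mean(y)
    d <- c(sum(Tm[, 1] * yc), sum(Tm[, 2] * yc))
  }
  # maximizer of (cos th * d1 + sin th * d2)^2 over th, principal solution
  theta <- atan2(d[2], d[1])
  R <- rot2(theta)
  Tr <- Tm %*% R
  # orient LV1 case-positive / better-function-positive; LV2 sign fixed by
  # making its largest-magnitude weight positive (pure display convention)
  flip1 <- if (y_type == "discriminant") {
    if (mean(Tr[y > 0, 1]) < mean(Tr[y <= 0, 1])) -1 else 1
  } else if (sum(Tr[, 1] * (y - mean(y))) < 0) -1 else 1
  if (flip1 < 0) {
    # a half-turn rather than a reflection keeps R a proper rotation
    theta <- theta + pi
    R <- rot2(theta)
  }
  keep_dn <- function(m, template) { dimnames(m) <- dimnames(template); m }
  list(rotation = R, theta = theta,
       scores = keep_dn(Tm %*% R, Tm),
       weights = keep_dn(fit$weights %*% R, fit$weights),
       x_loadings = keep_dn(fit$x_loadings %*% R, fit$x_loadings),
       projection = keep_dn(fit$projection %*% R, fit$projection))
}

#' Fit a latent-variable cytokine model (PLS regression)
#'
#' The central fitting function of the package. Analyte concentrations are
#' z-scored (mean 0, sample SD 1 per analyte) and regressed against either a
#' two-group label (discriminant PLS, response coded +1 for cases and -1 for
#' controls) or a continuous clinical score, using NIPALS partial least
#' squares with two latent variables. The fitted latent space is then
#' orthogonally rotated so that the group separation (or the covariance with
#' the score) lies along the first latent variable, LV1, with cases (or
#' better function) positive. Each analyte's LV1 weight — its "loading" in
#' the biomarker sense — measures how strongly and in which direction it
#' contributes to the separating profile.
#'
#' @param panel A [cytokine_panel()], or a plain numeric matrix of
#'   concentrations (rows = samples).
#' @param target Either the name of a metadata column of `panel`, or a
#'   vector of length n. Character/factor targets give a discriminant fit;
#'   numeric targets a continuous regression.
#' @param case For discriminant fits: the label of the case group (scored
#'   positive on LV1). Required when the target is two-group.
#' @param ncomp Number of latent variables (default and study convention: 2).
#' @param rotate Apply the LV1-aligning rotation (default `TRUE`). `ncomp`
#'   must be 2 to rotate.
#' @param impute Missing-cell policy, see [impute_missing()].
#' @param scaling Optionally, a pre-computed `zscaled` object to reuse.
#' @return An object of class `cyto_pls` with components `weights` (p x 2,
#'   unit-norm columns; `weights[, "LV1"]` are the reported loadings),
#'   `x_loadings`, `projection` (weights mapping z-scored data onto scores),
#'   `scores` (n x 2), `y_loadings`, `rotation`, `scaling` (`center`/`scale`),
#'   `y`, `y_type`, `case_label`/`control_label` and `groups`.
#' @examples
#' set.seed(7)
#' cohort <- gen_cohort(synthetic_config(n_control = 10, n_case = 10,
#'                                       n_analytes = 12, seed = 7))
#' fit <- cyto_pls(cohort$panel, target = "group", case = "MLIV")
#' fit
#' head(sort(coef(fit), decreasing = TRUE))
#' @export
cyto_pls <- function(panel, target, case = NULL, ncomp = 2, rotate = TRUE,
                     impute = "half_min", scaling = NULL) {
  if (inherits(panel, "cytokine_panel")) {
    tv <- if (is.character(target) && length(target) == 1 &&
              target %in% names(panel$meta)) panel$meta[[target]] else target
    sample_ids <- panel$meta$sample_id
  } else {
    tv <- target
    sample_ids <- rownames(as.matrix(panel))
  }
  if (length(tv) != nrow(if (inherits(panel, "cytokine_panel")) panel$x else panel))
    stop("target length does not match the number of samples")
  zs <- if (is.null(scaling)) zscore(panel, impute = impute) else scaling
  groups <- NULL; case_label <- NULL; control_label <- NULL
  if (is.numeric(tv)) {
    y_type <- "regression"
    y <- as.numeric(tv)
    if (anyNA(y)) stop("continuous target contains missing values")
  } else {
    y_type <- "discriminant"
    groups <- as.character(tv)
    if (is.null(case)) stop("discriminant fit: 'case' label must be given")
    y <- encode_groups(groups, case)
    case_label <- case
    control_label <- setdiff(unique(groups), case)
  }
  fit <- fit_nipals(zs$z, y, ncomp = ncomp)
  rot <- NULL
  if (rotate) {
    if (ncomp != 2) stop("rotation is defined for 2 components")
    rot <- rotate_to_lv1(fit, y, y_type)
    fit$scores <- rot$scores
    fit$weights <- rot$weights
    fit$x_loadings <- rot$x_loadings
    fit$projection <- rot$projection
  }
  structure(list(
    weights = fit$weights, x_loadings = fit$x_loadings,
    projection = fit$projection, scores = fit$scores,
    y_loadings = fit$y_loadings, y_mean = fit$y_mean,
    rotation = if (is.null(rot)) diag(ncomp) else rot$rotation,
    theta = if (is.null(rot)) 0 else rot$theta,
    scaling = list(center = zs$center, scale = zs$scale),
    analytes = zs$analytes, sample_ids = sample_ids,
    y = y, y_type = y_type, groups = groups,
    case_label = case_label, control_label = control_label,
    ncomp = ncomp, rotated = rotate
  ), class = "cyto_pls")
}

#' @export
print.cyto_pls <- function(x, ...) {
  cat(sprintf("<cyto_pls> %s PLS, %d samples x %d analytes, %d latent variables%s\n",
              if (x$y_type == "discriminant") "discriminant" else "continuous",
              nrow(x$scores), length(x$analytes), x$ncomp,
              if (x$rotated) " (rotated to LV1)" else ""))
  if (x$y_type == "discriminant")
    cat(sprintf("  case '%s' (positive on LV1) vs '%s'\n",
                x$case_label, paste(x$control_label, collapse = "/")))
  top <- sort(abs(x$weights[, 1]), decreasing = TRUE)
  cat("  top |LV1| loadings:",
      paste(sprintf("%s (%+.2f)", names(top)[1:min(5, length(top))],
                    x$weights[names(top)[1:min(5, length(top))], 1]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cyto_pls <- function(object, ...) {
  lv1 <- object$scores[, 1]
  out <- list(model = object,
              loadings = sort(object$weights[, 1], decreasing = TRUE))
  if (object$y_type == "discriminant") {
    out$group_means <- tapply(lv1, object$groups, mean)
    out$auc <- auc_scores(lv1, object$y > 0)
  } else {
    out$cor_lv1 <- stats::cor(lv1, object$y)
  }
  class(out) <- "summary.cyto_pls"
  out
}

#' @export
print.summary.cyto_pls <- function(x, ...) {
  print(x$model)
  if (!is.null(x$auc)) {
    cat(sprintf("  LV1 group means: %s\n",
                paste(sprintf("%s %+.2f", names(x$group_means), x$group_means),
                      collapse = ", ")))
    cat(sprintf("  LV1 case-vs-control AUC: %.3f\n", x$auc))
  } else {
    cat(sprintf("  cor(LV1 score, target): %.3f\n", x$cor_lv1))
  }
  invisible(x)
}

#' Extract LV1 loadings
#'
#' @param object A `cyto_pls` fit.
#' @param component Latent variable to extract (default 1).
#' @param ... Unused.
#' @return Named numeric vector of per-analyte weights (unit-norm vector).
#' @export
coef.cyto_pls <- function(object, component = 1, ...) {
  object$weights[, component]
}

#' @export
fitted.cyto_pls <- function(object, ...) {
  drop(object$scores %*% solve(object$rotation) %*% object$y_loadings) + object$y_mean
}

#' @export
residuals.cyto_pls <- function(object, ...) {
  object$y - fitted(object)
}

#' Project new samples onto a fitted latent space
#'
#' Scores new samples on the model's latent variables. Following the study
#' convention that every dataset is z-scored internally, the new panel is by
#' default standardized with its *own* column means/SDs (`rescale =
#' "self"`) before applying the model's projection weights; use `rescale =
#' "training"` to reuse the training transform instead (e.g. for held-out
#' samples from the same cohort). Projecting the training panel with its own
#' model reproduces the training scores.
#'
#' @param object A `cyto_pls` fit.
#' @param newdata A `cytokine_panel` or matrix containing the model's
#'   analytes (matched by name, case-insensitively).
#' @param rescale `"self"` (default) or `"training"`, see Details.
#' @param impute Missing-cell policy for panels.
#' @param ... Unused.
#' @return m x ncomp matrix of latent scores.
#' @export
predict.cyto_pls <- function(object, newdata, rescale = c("self", "training"),
                             impute = "half_min", ...) {
  rescale <- match.arg(rescale)
  x <- if (inherits(newdata, "cytokine_panel")) {
    impute_missing(newdata, impute)$x
  } else as.matrix(newdata)
  idx <- match(norm_name(object$analytes), norm_name(colnames(x)))
  if (anyNA(idx))
    stop("analyte(s) missing from new data: ",
         paste(object$analytes[is.na(idx)], collapse = ", "))
  x <- x[, idx, drop = FALSE]
  z <- if (rescale == "self") {
    if (nrow(x) < 2) stop("rescale = 'self' needs at least 2 samples")
    sdv <- apply(x, 2, stats::sd)
    if (any(sdv == 0))
      stop("constant analyte column(s) in new data: ",
           paste(object$analytes[sdv == 0], collapse = ", "))
    sweep(sweep(x, 2, colMeans(x)), 2, sdv, "/")
  } else {
    sweep(sweep(x, 2, object$scaling$center), 2, object$scaling$scale, "/")
  }
  sc <- z %*% object$projection
  dimnames(sc) <- list(rownames(x), colnames(object$scores))
  sc
}

#' Plot a fitted cytokine PLS model
#'
#' Two base-graphics panels: per-sample scores in the (LV1, LV2) plane,
#' colored by group, and the ranked LV1 loading profile.
#'
#' @param x A `cyto_pls` fit.
#' @param which `"scores"`, `"loadings"` or `"both"` (default).
#' @param ... Passed to the underlying plot calls.
#' @export
plot.cyto_pls <- function(x, which = c("both", "scores", "loadings"), ...) {
  which <- match.arg(which)
  op <- NULL
  if (which == "both") { op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op)) }
  if (which %in% c("both", "scores")) {
    col <- if (x$y_type == "discriminant") ifelse(x$y > 0, 2, 4) else 1
    graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                   xlab = "LV1 score", ylab = "LV2 score",
                   main = "Latent scores", ...)
    graphics::abline(v = 0, h = 0, lty = 3)
    if (x$y_type == "discriminant")
      graphics::legend("topleft", pch = 19, col = c(4, 2),
                       legend = c(paste(x$control_label, collapse = "/"), x$case_label),
                       bty = "n")
  }
  if (which %in% c("both", "loadings")) {
    w <- sort(x$weights[, 1])
    graphics::barplot(w, las = 2, cex.names = 0.6, ylab = "LV1 loading",
                      main = "LV1 profile", ...)
  }
  invisible(x)
}

# Mann-Whitney AUC of a score against a logical case indicator
auc_scores <- function(score, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("AUC needs both cases and controls")
  r <- rank(score)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
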