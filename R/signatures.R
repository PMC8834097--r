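#' Select coincident analytes across two stability profiles
#'
#' The cross-dataset signature rule: an analyte enters the signature when
#' its LV1 loading is both strong and stable in *both* datasets — mean
#' |loading| at or above `mean_threshold` (default 0.2) and coefficient of
#' variation below `cv_threshold` (default 1) in each profile — and (by
#' default) points the same way in both, i.e. is coincident in the
#' direction separating cases from controls. Both profiles must be oriented
#' case-positive (the convention of [cyto_pls()] / [lkocv_profile()]) and
#' restricted to shared analyte names (see [harmonize()]).
#'
#' @param profile_a,profile_b `stability_profile` objects (or data frames
#'   with columns `analyte`, `mean`, `cv`).
#' @param mean_threshold Minimum |mean LV1 loading| required in both
#'   profiles (default 0.2).
#' @param cv_threshold Loadings must have CV strictly below this in both
#'   profiles (default 1).
#' @param require_direction_match Require `sign(mean_a) == sign(mean_b)`
#'   (default `TRUE`).
#' @return Object of class `signature_set`: data frame `analyte`,
#'   `direction` (`"case-up"` / `"case-down"`), `mean_a`, `mean_b`, `cv_a`,
#'   `cv_b`. Empty selection returns a zero-row set with a warning.
#' @export
select_coincident <- function(profile_a, profile_b, mean_threshold = 0.2,
                              cv_threshold = 1.0,
                              require_direction_match = TRUE) {
  stopifnot(mean_threshold > 0, cv_threshold > 0)
  a <- as.data.frame(profile_a); b <- as.data.frame(profile_b)
  shared <- intersect(a$analyte, b$analyte)
  if (!length(shared)) stop("profiles have disjoint analytes; harmonize first")
  a <- a[match(shared, a$analyte), ]; b <- b[match(shared, b$analyte), ]
  ok <- abs(a$mean) >= mean_threshold & abs(b$mean) >= mean_threshold &
    a$cv < cv_threshold & b$cv < cv_threshold
  if (require_direction_match) ok <- ok & sign(a$mean) == sign(b$mean)
  ok[is.na(ok)] <- FALSE
  out <- data.frame(analyte = shared[ok],
                    direction = ifelse(a$mean[ok] >= 0, "case-up", "case-down"),
                    mean_a = a$mean[ok], mean_b = b$mean[ok],
                    cv_a = a$cv[ok], cv_b = b$cv[ok],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) warning("no coincident analytes under the given criteria")
  structure(out, class = c("signature_set", "data.frame"),
            mean_threshold = mean_threshold, cv_threshold = cv_threshold,
            require_direction_match = require_direction_match)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d coincident analyte(s) (|mean| >= %g, CV < %g)\n",
              nrow(x), attr(x, "mean_threshold"), attr(x, "cv_threshold")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Refit a model on a reduced signature panel
#'
#' Runs the full pipeline (z-scoring, NIPALS, rotation) on the panel
#' restricted to the signature analytes — the "reduced signature" model.
#'
#' @param panel A [cytokine_panel()].
#' @param signature A `signature_set` or character vector of analyte names.
#' @param target,case,... Passed to [cyto_pls()].
#' @return A `cyto_pls` fit on the restricted panel.
#' @export
reduced_fit <- function(panel, signature, target, case = NULL, ...) {
  an <- if (inherits(signature, "data.frame")) signature$analyte else as.character(signature)
  idx <- match(norm_name(an), norm_name(colnames(panel$x)))
  if (anyNA(idx))
    stop("signature analyte(s) missing from panel: ",
         paste(an[is.na(idx)], collapse = ", "))
  cyto_pls(subset_panel(panel, analytes = idx), target, case = case, ...)
}

#' Transfer a fitted signature onto another dataset
#'
#' Scores the samples of a second panel (typically another species or
#' compartment) with a model fitted elsewhere: analyte names are harmonized
#' via `map`, the target panel is z-scored internally (each dataset on its
#' own scale), projected onto the model's latent space, and the separation
#' of the target panel's cases from controls along LV1 is summarized as an
#' AUC (with a Wilcoxon rank-sum p-value).
#'
#' @param model A `cyto_pls` fit whose analytes are to be transferred.
#' @param panel_b Target [cytokine_panel()].
#' @param case Case label in `panel_b`'s grouping column (defaults to the
#'   model's own case label).
#' @param map Optional [analyte_map()] translating the model's analyte
#'   names (`name_a`) to `panel_b`'s (`name_b`); `NULL` matches names
#'   directly. Must cover every model analyte present.
#' @param group Metadata column of `panel_b` holding the group labels.
#' @return List: `scores` (m x 2 latent scores), `auc` (LV1 case-vs-control
#'   AUC in panel_b), `p` (rank-sum p of the LV1 scores), `lv1` (named
#'   score vector), `is_case`.
#' @export
transfer_signature <- function(model, panel_b, case = NULL, map = NULL,
                               group = "group") {
  stopifnot(inherits(model, "cyto_pls"), inherits(panel_b, "cytokine_panel"))
  if (!is.null(map)) {
    map <- as.data.frame(map, stringsAsFactors = FALSE)
    need <- norm_name(model$analytes)
    hit <- match(need, norm_name(map[[1]]))
    if (anyNA(hit))
      stop("analyte map does not cover model analyte(s): ",
           paste(model$analytes[is.na(hit)], collapse = ", "))
    bnames <- map[[2]][hit]
    idx <- match(norm_name(bnames), norm_name(colnames(panel_b$x)))
    if (anyNA(idx))
      stop("mapped analyte(s) missing from target panel: ",
           paste(bnames[is.na(idx)], collapse = ", "))
    xb <- panel_b$x[, idx, drop = FALSE]
    colnames(xb) <- model$analytes
    panel_b <- cytokine_panel(xb, panel_b$meta)
  }
  sc <- predict(model, panel_b, rescale = "self")
  g <- as.character(panel_column(panel_b, c(group, "group", "group_label")))
  if (is.null(case)) case <- model$case_label
  if (is.null(case) || !case %in% g)
    stop("case label ", if (is.null(case)) "(none)" else paste0("'", case, "'"),
         " not found in target panel groups")
  is_case <- g == case
  lv1 <- stats::setNames(sc[, 1], rownames(sc))
  w <- wilcoxon_rank_sum(lv1[is_case], lv1[!is_case], mode = "normal")
  list(scores = sc, auc = auc_scores(lv1, is_case), p = w$p_raw,
       lv1 = lv1, is_case = is_case)
}
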