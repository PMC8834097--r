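#' Configuration for the synthetic cytokine cohort generator
#'
#' Describes a case-control cytokine cohort with the statistical structure
#' the analysis pipeline assumes: log-normal concentrations co-regulated by
#' one latent inflammation factor, a planted case effect on a subset of
#' analytes, an optional "mild" case subgroup with attenuated effects, and
#' ordinal clinical scores monotonically linked to the latent factor.
#'
#' Per sample i and analyte a the generator draws
#' \deqn{\log_{10} c_{ia} = \mu_a + \sigma_a\left(\lambda_a f_i +
#'   \sqrt{1-\lambda_a^2}\,\varepsilon_{ia} +
#'   \delta_a\,[\mathrm{case}_i]\,m_i\right)}
#' with latent severity \eqn{f_i \sim N(\mathrm{case\_shift}\cdot
#' [\mathrm{case}_i]\, m_i, 1)}, independent noise
#' \eqn{\varepsilon_{ia} \sim N(0,1)}, planted effect \eqn{\delta_a} (in SD
#' units of log-concentration; 0 off the planted set) and mild attenuation
#' \eqn{m_i} (`mild_attenuation` for mild cases, 1 otherwise).
#' `case_shift` defaults to 0, so with \eqn{\delta = 0} the generator is an
#' exact null: group labels carry no signal.
#'
#' @param n_control,n_case Group sizes (>= 3 each).
#' @param n_mild Number of case samples flagged "mild" (attenuated effect).
#' @param n_analytes Panel width (41 emulates a human kit, 32 a mouse kit).
#' @param analyte_names Optional character vector (length `n_analytes`);
#'   default `"CK01"...`.
#' @param planted_analytes Analytes carrying the case effect; default the
#'   first `n_planted` analytes.
#' @param n_planted Number of planted analytes when `planted_analytes` is
#'   `NULL` (default 8).
#' @param delta Planted effect size(s), SD of log-concentration (default
#'   1.5). Scalar or named per planted analyte; negative values plant
#'   case-down analytes.
#' @param case_shift Shift of the latent severity factor in cases (default
#'   0; see Details).
#' @param mild_attenuation Multiplier on effect and shift for mild cases
#'   (default 0.25).
#' @param mu,sigma,lambda Optional per-analyte baseline log10 means, SDs and
#'   latent-factor loadings; by default drawn once per cohort from
#'   U(0.5, 2.5), U(0.2, 0.5) and U(0.2, 0.7) respectively (plausible
#'   Luminex pg/mL ranges).
#' @param score_noise SD of the noise added to clinical scores (default 1).
#' @param group_labels Named pair `c(control = ..., case = ...)`.
#' @param species,compartment Metadata constants for the cohort.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_control = 18, n_case = 18, n_mild = 3,
                             n_analytes = 41, analyte_names = NULL,
                             planted_analytes = NULL, n_planted = 8,
                             delta = 1.5, case_shift = 0,
                             mild_attenuation = 0.25,
                             mu = NULL, sigma = NULL, lambda = NULL,
                             score_noise = 1,
                             group_labels = c(control = "CTRL", case = "MLIV"),
                             species = "human", compartment = "plasma",
                             seed = NULL) {
  stopifnot(n_control >= 3, n_case >= 3, n_mild >= 0, n_mild <= n_case,
            n_analytes >= 1, mild_attenuation >= 0, mild_attenuation <= 1,
            all(is.finite(delta)))
  if (is.null(analyte_names))
    analyte_names <- sprintf("CK%02d", seq_len(n_analytes))
  stopifnot(length(analyte_names) == n_analytes, !anyDuplicated(analyte_names))
  if (is.null(planted_analytes))
    planted_analytes <- analyte_names[seq_len(min(n_planted, n_analytes))]
  if (!all(planted_analytes %in% analyte_names))
    stop("planted analyte(s) not in the panel: ",
         paste(setdiff(planted_analytes, analyte_names), collapse = ", "))
  if (length(delta) == 1) {
    delta <- stats::setNames(rep(delta, length(planted_analytes)), planted_analytes)
  } else {
    stopifnot(length(delta) == length(planted_analytes))
    names(delta) <- planted_analytes
  }
  structure(list(
    n_control = n_control, n_case = n_case, n_mild = n_mild,
    n_analytes = n_analytes, analyte_names = analyte_names,
    planted_analytes = planted_analytes, delta = delta,
    case_shift = case_shift, mild_attenuation = mild_attenuation,
    mu = mu, sigma = sigma, lambda = lambda, score_noise = score_noise,
    group_labels = group_labels, species = species,
    compartment = compartment, seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic cytokine cohort
#'
#' Draws one cohort under a [synthetic_config()] and returns both the panel
#' and the ground truth needed for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List with `panel` (a [cytokine_panel()]; concentrations in
#'   pg/mL, strictly positive) and `truth` (class `synthetic_truth`:
#'   `planted_analytes`, per-analyte `direction`, per-sample latent
#'   severity `f`, the analyte parameters actually used, and the config).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$n_analytes
  an <- config$analyte_names
  mu <- if (is.null(config$mu)) stats::runif(p, 0.5, 2.5) else rep_len(config$mu, p)
  sg <- if (is.null(config$sigma)) stats::runif(p, 0.2, 0.5) else rep_len(config$sigma, p)
  lam <- if (is.null(config$lambda)) stats::runif(p, 0.2, 0.7) else rep_len(config$lambda, p)
  names(mu) <- names(sg) <- names(lam) <- an
  n0 <- config$n_control; n1 <- config$n_case; n <- n0 + n1
  is_case <- c(rep(FALSE, n0), rep(TRUE, n1))
  # mild cases are the last n_mild case samples
  is_mild <- c(rep(FALSE, n0 + n1 - config$n_mild), rep(TRUE, config$n_mild))
  atten <- ifelse(is_case, ifelse(is_mild, config$mild_attenuation, 1), 0)
  f <- stats::rnorm(n) + config$case_shift * atten
  eps <- matrix(stats::rnorm(n * p), n, p)
  dvec <- stats::setNames(numeric(p), an)
  dvec[names(config$delta)] <- config$delta
  log10c <- matrix(mu, n, p, byrow = TRUE) +
    matrix(sg, n, p, byrow = TRUE) *
      (outer(f, lam) +
         sweep(eps, 2, sqrt(1 - lam^2), "*") +
         outer(atten, dvec))
  conc <- 10^log10c
  lab <- ifelse(is_case, config$group_labels[["case"]], config$group_labels[["control"]])
  ids <- sprintf("%s%02d", lab, stats::ave(seq_len(n), lab, FUN = seq_along))
  dimnames(conc) <- list(ids, an)
  meta <- data.frame(
    sample_id = ids, group = lab,
    subgroup = ifelse(!is_case, config$group_labels[["control"]],
                      ifelse(is_mild, paste0(config$group_labels[["case"]], "-mild"),
                             paste0(config$group_labels[["case"]], "-typical"))),
    species = config$species, compartment = config$compartment,
    sex = rep_len(c("F", "M"), n),
    age = if (config$species == "human") sample(3:30, n, replace = TRUE)
          else rep(2, n),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    planted_analytes = names(config$delta),
    direction = ifelse(config$delta >= 0, "case-up", "case-down"),
    f = stats::setNames(f, ids), is_case = stats::setNames(is_case, ids),
    is_mild = stats::setNames(is_mild, ids),
    mu = mu, sigma = sg, lambda = lam, config = config
  ), class = "synthetic_truth")
  list(panel = cytokine_panel(conc, meta), truth = truth)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate clinical scores linked to the latent severity factor
#'
#' Emulates ordinal motor-function scoring: five 0-10 motor-scale scores
#' (gross motor, fine motor, upper extremity, deglutition, articulation),
#' each `round(clamp(10 - (2.5 f + score_noise * eta), 0, 10))` with
#' independent noise per scale, and a 0/1/1.5/2/3/4 muscle-tone grade
#' obtained by monotone bucketing of f (grade "1+" is encoded 1.5 to keep
#' the scale ordered). Higher latent severity f gives lower motor scores
#' and a higher tone grade.
#'
#' @param truth A `synthetic_truth` from [gen_cohort()].
#' @param score_noise Noise SD; defaults to the generating config's value.
#' @return Data frame keyed by `sample_id` with columns `bamf_gross_motor`,
#'   `bamf_fine_motor`, `bamf_upper_extremity`, `deglutition`,
#'   `articulation` (integers 0-10) and `ashworth_tone` (one of 0, 1, 1.5,
#'   2, 3, 4).
#' @export
gen_clinical_scores <- function(truth, score_noise = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(score_noise)) score_noise <- truth$config$score_noise
  f <- truth$f
  n <- length(f)
  motor <- function() as.integer(round(clamp(10 - (2.5 * f + score_noise * stats::rnorm(n)), 0, 10)))
  tone_levels <- c(0, 1, 1.5, 2, 3, 4)
  tone <- tone_levels[findInterval(f, c(-0.75, 0, 0.75, 1.5, 2.25)) + 1]
  data.frame(sample_id = names(f),
             bamf_gross_motor = motor(), bamf_fine_motor = motor(),
             bamf_upper_extremity = motor(), deglutition = motor(),
             articulation = motor(), ashworth_tone = tone,
             stringsAsFactors = FALSE)
}

#' Attach clinical scores to a panel's metadata
#'
#' @param panel A [cytokine_panel()].
#' @param scores Data frame keyed by `sample_id` (e.g. from
#'   [gen_clinical_scores()]).
#' @return The panel with score columns merged into its metadata.
#' @export
attach_scores <- function(panel, scores) {
  stopifnot(inherits(panel, "cytokine_panel"), "sample_id" %in% names(scores))
  idx <- match(panel$meta$sample_id, scores$sample_id)
  if (anyNA(idx)) stop("scores missing for sample(s): ",
                       paste(panel$meta$sample_id[is.na(idx)], collapse = ", "))
  cytokine_panel(panel$x, cbind(panel$meta,
                                scores[idx, setdiff(names(scores), "sample_id"),
                                       drop = FALSE]))
}

#' Generate two cohorts with a shared (or disjoint) planted signature
#'
#' Emulates the cross-compartment design: two independent cohorts (e.g.
#' "human plasma" and "mouse brain") whose planted analyte sets share
#' `shared_signature` with identical directions. With an empty
#' `shared_signature` the planted sets are made disjoint — the null
#' configuration for signature-transfer testing.
#'
#' @param config_a,config_b [synthetic_config()]s. Analyte names occurring
#'   in both panels are treated as already harmonized.
#' @param shared_signature Character vector of analytes planted in both
#'   cohorts (must exist in both panels), possibly empty.
#' @return List of two `list(panel, truth)` elements, `a` and `b`.
#' @export
gen_paired_datasets <- function(config_a, config_b, shared_signature = character(0)) {
  stopifnot(inherits(config_a, "synthetic_config"),
            inherits(config_b, "synthetic_config"))
  miss_a <- setdiff(shared_signature, config_a$analyte_names)
  miss_b <- setdiff(shared_signature, config_b$analyte_names)
  if (length(miss_a) || length(miss_b))
    stop("shared analyte(s) missing from a panel: ",
         paste(unique(c(miss_a, miss_b)), collapse = ", "))
  n_shared <- length(shared_signature)
  pick_extras <- function(cfg, avoid, from_end = FALSE) {
    k <- length(cfg$planted_analytes) - n_shared
    if (k <= 0) return(character(0))
    pool <- setdiff(cfg$analyte_names, c(shared_signature, avoid))
    if (length(pool) < k) stop("not enough analytes for disjoint planted sets")
    if (from_end) rev(pool)[seq_len(k)] else pool[seq_len(k)]
  }
  extras_a <- pick_extras(config_a, character(0), from_end = FALSE)
  extras_b <- pick_extras(config_b, extras_a, from_end = TRUE)
  base_delta <- function(cfg) unname(cfg$delta[1])
  reconf <- function(cfg, planted) {
    synthetic_config(
      n_control = cfg$n_control, n_case = cfg$n_case, n_mild = cfg$n_mild,
      n_analytes = cfg$n_analytes, analyte_names = cfg$analyte_names,
      planted_analytes = planted, delta = base_delta(cfg),
      case_shift = cfg$case_shift, mild_attenuation = cfg$mild_attenuation,
      mu = cfg$mu, sigma = cfg$sigma, lambda = cfg$lambda,
      score_noise = cfg$score_noise, group_labels = cfg$group_labels,
      species = cfg$species, compartment = cfg$compartment, seed = cfg$seed)
  }
  list(a = gen_cohort(reconf(config_a, c(shared_signature, extras_a))),
       b = gen_cohort(reconf(config_b, c(shared_signature, extras_b))))
}

#' Preset synthetic cohort configurations
#'
#' Ready-made configurations mirroring the study's cohort layouts:
#' * `"human41"`: 41 analytes, 18 controls vs 18 cases (3 mild), human plasma;
#' * `"mouse32"`: 32 analytes, 4 WT vs 6 KO, mouse plasma (no mild group);
#' * `"mouse_brain"`: 32 analytes, 5 WT vs 5 KO, mouse brain tissue.
#'
#' @param preset One of `"human41"`, `"mouse32"`, `"mouse_brain"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("human41", "mouse32", "mouse_brain"),
                             seed = NULL, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    human41 = list(n_control = 18, n_case = 18, n_mild = 3, n_analytes = 41,
                   species = "human", compartment = "plasma",
                   group_labels = c(control = "CTRL", case = "MLIV")),
    mouse32 = list(n_control = 4, n_case = 6, n_mild = 0, n_analytes = 32,
                   species = "mouse", compartment = "plasma",
                   group_labels = c(control = "WT", case = "KO")),
    mouse_brain = list(n_control = 5, n_case = 5, n_mild = 0, n_analytes = 32,
                       species = "mouse", compartment = "brain",
                       group_labels = c(control = "WT", case = "KO")))
  args$seed <- seed
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_config, args)
}
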