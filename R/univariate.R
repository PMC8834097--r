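# midrank-based tie correction term sum(t^3 - t) over tied groups
tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

.u_dist_cache <- new.env(parent = emptyenv())

# exact null distribution of the Mann-Whitney U statistic by enumeration of
# all rank assignments, cached per sample-size pair
exact_u_distribution <- function(na, nb) {
  key <- paste(na, nb)
  hit <- get0(key, envir = .u_dist_cache)
  if (!is.null(hit)) return(hit)
  N <- na + nb
  combs <- utils::combn(N, na)
  Us <- colSums(matrix(seq_len(N)[combs], nrow = na)) - na * (na + 1) / 2
  tab <- table(Us)
  out <- list(u = as.numeric(names(tab)), count = as.numeric(tab))
  assign(key, out, envir = .u_dist_cache)
  out
}

#' Dunn's post-hoc test of pairwise group differences on joint ranks
#'
#' Nonparametric pairwise comparison for 3+ groups (the post-hoc companion
#' of the Kruskal-Wallis test). All observations are ranked jointly with
#' midranks for ties; for each group pair the standardized difference of
#' mean ranks is
#' \deqn{z = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_i (t_i^3 - t_i)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}}
#' with two-sided normal p-values, Bonferroni-adjusted over the pairwise
#' comparisons of this one variable (m = 3 for three groups). No
#' Kruskal-Wallis gate is applied.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (2+ groups, each non-empty).
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `statistic` (Dunn z), `p_raw`, `p_adjusted`, `method`.
#' @examples
#' dunn_test(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'           rep(c("A", "B", "C"), each = 3))
#' @export
dunn_test <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups[keep])
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  cnt <- table(groups)
  if (any(cnt == 0)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  mr <- tapply(r, groups, mean)
  tie <- tie_term(r) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(base_var * (1 / cnt[[a]] + 1 / cnt[[b]]))
    z <- if (se == 0) 0 else (mr[[a]] - mr[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = a, group_b = b, statistic = z, p_raw = p,
               p_adjusted = min(1, m * p), method = "dunn",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Wilcoxon rank-sum test (exact enumeration or normal approximation)
#'
#' Two-sample rank test reporting the Mann-Whitney U statistic for sample
#' `a`. In exact mode (`auto` picks it when n_a + n_b <= 12 and there are
#' no ties) the two-sided p-value is obtained by enumerating all
#' choose(n_a + n_b, n_a) assignments of ranks to sample `a`; otherwise a
#' normal approximation with midranks, tie-corrected variance and a
#' continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`. Exact mode requires
#'   tie-free data.
#' @return Data frame row: `group_a`, `group_b`, `statistic` (U for `a`),
#'   `p_raw`, `p_adjusted` (= `p_raw`; single comparison), `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))          # exact p = 2/6
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty")
  N <- na + nb
  vals <- c(a, b)
  ties <- anyDuplicated(vals) > 0
  r <- rank(vals)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  if (mode == "auto") mode <- if (N <= 12 && !ties) "exact" else "normal"
  if (mode == "exact") {
    if (ties) stop("exact mode requires tie-free data")
    if (N > 20) stop("exact mode enumerates rank assignments; use normal mode for n_a + n_b > 20")
    # without ties the U null distribution depends only on (na, nb):
    # enumerate the choose(N, na) rank assignments once and cache
    tab <- exact_u_distribution(na, nb)
    p <- sum(tab$count[abs(tab$u - EU) >= abs(U - EU) - 1e-9]) / sum(tab$count)
    method <- "wilcoxon_exact"
  } else {
    varU <- na * nb / 12 * ((N + 1) - tie_term(r) / (N * (N - 1)))
    if (varU <= 0) {
      p <- 1
    } else {
      z <- (abs(U - EU) - 0.5) / sqrt(varU)
      z <- max(0, z)
      p <- 2 * stats::pnorm(-z)
      p <- min(1, p)
    }
    method <- "wilcoxon_normal"
  }
  data.frame(group_a = "a", group_b = "b", statistic = U, p_raw = p,
             p_adjusted = p, method = method, stringsAsFactors = FALSE)
}

#' Per-analyte univariate screen
#'
#' Applies the appropriate rank test to every analyte of a panel: Dunn's
#' test with Bonferroni correction when the grouping has 3+ levels (e.g.
#' control / typical / mild), Wilcoxon rank-sum when it has 2 (e.g. WT /
#' KO). Per-analyte failures (e.g. constant analytes under exact mode) are
#' returned as flagged rows rather than aborting the screen.
#'
#' @param panel A [cytokine_panel()].
#' @param group Name of the metadata grouping column (default `"group"`),
#'   or a vector of labels.
#' @param mode Passed to [wilcoxon_rank_sum()] for 2-group screens.
#' @return Long data frame: `analyte`, `group_a`, `group_b`, `statistic`,
#'   `p_raw`, `p_adjusted`, `method`, `note` (error message when a test
#'   failed, else `NA`).
#' @export
univariate_screen <- function(panel, group = "group", mode = "auto") {
  stopifnot(inherits(panel, "cytokine_panel"))
  g <- if (length(group) == 1 && is.character(group)) {
    as.character(panel_column(panel, c(group, "group", "group_label")))
  } else as.character(group)
  lev <- unique(g)
  out <- lapply(colnames(panel$x), function(an) {
    v <- panel$x[, an]
    res <- tryCatch({
      if (length(lev) >= 3) {
        dunn_test(v, g)
      } else {
        r <- wilcoxon_rank_sum(v[g == lev[1]], v[g == lev[2]], mode = mode)
        r$group_a <- lev[1]; r$group_b <- lev[2]
        r
      }
    }, error = function(e) {
      data.frame(group_a = NA, group_b = NA, statistic = NA_real_,
                 p_raw = NA_real_, p_adjusted = NA_real_, method = "failed",
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if (!"note" %in% names(res)) res$note <- NA_character_
    cbind(analyte = an, res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(analyte = character(0), group_a = character(0),
                      group_b = character(0), statistic = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0),
                      method = character(0), note = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
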