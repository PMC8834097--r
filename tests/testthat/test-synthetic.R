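test_that("generation is reproducible, positive, and honors requested sizes", {
  cfg <- synthetic_config(n_control = 7, n_case = 9, n_mild = 2,
                          n_analytes = 13, seed = 61)
  c1 <- gen_cohort(cfg)
  c2 <- gen_cohort(cfg)
  expect_identical(c1$panel$x, c2$panel$x)
  expect_identical(c1$truth$f, c2$truth$f)

  expect_true(all(c1$panel$x > 0))
  expect_equal(dim(c1$panel$x), c(16L, 13L))
  expect_equal(as.vector(table(c1$panel$meta$group)[c("CTRL", "MLIV")]), c(7L, 9L))
  expect_equal(sum(c1$panel$meta$subgroup == "MLIV-mild"), 2L)

  expect_error(synthetic_config(n_analytes = 5, planted_analytes = "XX"),
               "planted analyte")
})

test_that("delta = 0 with no severity shift is an exact null for group tests", {
  set.seed(62)
  pvals <- unlist(lapply(1:40, function(s) {
    co <- gen_cohort(synthetic_config(n_control = 10, n_case = 10, n_mild = 0,
                                      n_analytes = 25, delta = 0, seed = 6200 + s))
    univariate_screen(co$panel, "group")$p_raw
  }))
  # 1000 analyte-level null tests: rejection close to the nominal 5%
  expect_gt(length(pvals), 900)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("planted |LV1 loading| grows with effect size delta", {
  mean_planted <- sapply(c(0, 0.75, 1.5), function(d) {
    mean(sapply(1:6, function(s) {
      co <- gen_cohort(synthetic_config(n_mild = 0, delta = d, seed = 6300 + s))
      fit <- cyto_pls(co$panel, "group", case = "MLIV")
      mean(abs(fit$weights[co$truth$planted_analytes, 1]))
    }))
  })
  expect_true(all(diff(mean_planted) > 0))
})

test_that("clinical scores stay in range and track severity monotonically", {
  co <- gen_cohort(synthetic_config(n_control = 20, n_case = 20, n_mild = 0,
                                    case_shift = 1.5, seed = 64))
  sc <- gen_clinical_scores(co$truth, score_noise = 0)
  bamf_cols <- c("bamf_gross_motor", "bamf_fine_motor", "bamf_upper_extremity",
                 "deglutition", "articulation")
  for (col in bamf_cols) {
    expect_true(all(sc[[col]] %in% 0:10))
    # zero noise: integer scores are a monotone non-increasing function of f
    ord <- order(co$truth$f)
    expect_true(all(diff(sc[[col]][ord]) <= 0))
  }
  expect_true(all(sc$ashworth_tone %in% c(0, 1, 1.5, 2, 3, 4)))
  expect_true(all(diff(sc$ashworth_tone[order(co$truth$f)]) >= 0))
  # rounding to the ordinal grid ties some ranks; correlation stays near -1
  expect_lt(cor(co$truth$f, sc$bamf_gross_motor, method = "spearman"), -0.95)

  # with noise, scores remain in range and correlate negatively with f
  sc2 <- gen_clinical_scores(co$truth, score_noise = 1)
  expect_true(all(sc2$bamf_gross_motor %in% 0:10))
  expect_lt(cor(co$truth$f, sc2$bamf_gross_motor), 0)
})

test_that("score-regression loadings track the true severity couplings", {
  res <- sapply(65:67, function(s) {
    co <- gen_cohort(synthetic_config(n_control = 150, n_case = 150, n_mild = 0,
                                      n_analytes = 20, case_shift = 1.5, seed = s))
    panel <- attach_scores(co$panel, gen_clinical_scores(co$truth))
    fit <- cyto_pls(panel, "bamf_gross_motor")
    # analytic correlation of each analyte's log-concentration with severity
    # f: latent loading channel plus the planted effect routed through the
    # case indicator (cov(case, f) = case_shift/4, Var f = 1 + case_shift^2/4)
    tr <- co$truth
    lam <- tr$lambda
    dvec <- stats::setNames(numeric(length(lam)), names(lam))
    dvec[tr$planted_analytes] <- tr$config$delta
    cs <- tr$config$case_shift
    vf <- 1 + cs^2 / 4
    cova <- lam * vf + dvec * cs / 4
    vara <- lam^2 * vf + (1 - lam^2) + dvec^2 / 4 + 2 * lam * dvec * cs / 4
    corr_f <- cova / sqrt(vara * vf)
    w <- abs(fit$weights[, 1])
    c(track = cor(w, corr_f[names(w)], method = "spearman"),
      fit = cor(fit$scores[, 1], panel$meta$bamf_gross_motor))
  })
  expect_gt(median(res["track", ]), 0.7)
  expect_true(all(res["fit", ] > 0.5))
})

test_that("paired cohorts share exactly the requested planted signature", {
  ca <- synthetic_config(n_analytes = 20, n_planted = 8, seed = 66)
  cb <- synthetic_config(n_control = 5, n_case = 5, n_mild = 0, n_analytes = 20,
                         n_planted = 8, seed = 67,
                         group_labels = c(control = "WT", case = "KO"))
  shared <- sprintf("CK%02d", 10:16)
  pair <- gen_paired_datasets(ca, cb, shared)
  pa <- pair$a$truth$planted_analytes
  pb <- pair$b$truth$planted_analytes
  expect_true(all(shared %in% pa) && all(shared %in% pb))
  expect_setequal(intersect(pa, pb), shared)

  # empty shared signature behaves as disjoint mode
  pair0 <- gen_paired_datasets(ca, cb, character(0))
  expect_length(intersect(pair0$a$truth$planted_analytes,
                          pair0$b$truth$planted_analytes), 0)

  expect_error(gen_paired_datasets(ca, cb, "NOT-THERE"), "missing")
})

test_that("presets mirror the study cohort layouts", {
  h <- synthetic_preset("human41", seed = 1)
  expect_equal(c(h$n_control, h$n_case, h$n_mild, h$n_analytes), c(18, 18, 3, 41))
  m <- synthetic_preset("mouse32", seed = 1)
  expect_equal(c(m$n_control, m$n_case, m$n_analytes), c(4, 6, 32))
  expect_identical(unname(m$group_labels), c("WT", "KO"))
  b <- synthetic_preset("mouse_brain", seed = 1)
  expect_identical(b$compartment, "brain")
  expect_equal(c(b$n_control, b$n_case), c(5, 5))
})
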