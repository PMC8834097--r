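test_that("group encoding is +1 case / -1 control and two-class only", {
  expect_equal(encode_groups(c("CTRL", "MLIV", "MLIV"), "MLIV"), c(-1, 1, 1))
  expect_error(encode_groups(c("CTRL", "CTRL"), "CTRL"), "one")
  expect_error(encode_groups(c("A", "B", "C"), "A"), "two-class")
  expect_error(encode_groups(c("A", "B"), "Z"), "not present")
})

test_that("component-1 weights equal normalized X'y (closed-form identity)", {
  set.seed(11)
  for (i in 1:5) {
    z <- scale(matrix(rnorm(20 * 7), 20, 7))
    y <- sample(rep(c(-1, 1), 10))
    fit <- cytosig:::fit_nipals(z, y, ncomp = 2)
    w <- drop(crossprod(z, y - mean(y)))
    w <- w / sqrt(sum(w^2))
    expect_lt(max(abs(fit$weights[, 1] - w)), 1e-8)
    expect_lt(abs(sqrt(sum(fit$weights[, 1]^2)) - 1), 1e-10)
    expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-8)
  }
})

test_that("a single predictor equal to y gives perfectly correlated LV1 scores", {
  y <- rep(c(-1, 1), each = 6)
  z <- scale(matrix(y + rnorm(12, sd = 1e-8), 12, 1,
                    dimnames = list(sprintf("s%02d", 1:12), "only")))
  fit <- cytosig:::fit_nipals(z, y, ncomp = 1)
  expect_equal(abs(cor(fit$scores[, 1], y)), 1, tolerance = 1e-6)
})

test_that("NIPALS matches the independent mixOmics reference after sign alignment", {
  skip_if_not_installed("mixOmics")
  set.seed(2024)
  for (i in 1:10) {
    z <- scale(matrix(rnorm(10 * 5), 10, 5))
    y <- sample(rep(c(-1, 1), 5))
    fit <- cytosig:::fit_nipals(z, y, ncomp = 2)
    ref <- mixOmics::pls(z, y, ncomp = 2, mode = "regression", scale = FALSE)
    for (a in 1:2) {
      s <- sign(sum(fit$scores[, a] * ref$variates$X[, a]))
      expect_lt(max(abs(fit$scores[, a] - s * ref$variates$X[, a])), 1e-6)
      expect_lt(max(abs(fit$weights[, a] - s * ref$loadings$X[, a])), 1e-6)
    }
  }
})

test_that("zero cross-covariance raises a no-predictive-direction error", {
  z <- scale(matrix(rep(c(-1, 1), 4), 8, 1))
  y <- rep(c(-1, -1, 1, 1), 2)  # orthogonal to the single column
  expect_error(cytosig:::fit_nipals(cbind(z, z), y), "no predictive direction")
})

test_that("rotation aligns separation with LV1 and preserves the reconstruction", {
  co <- gen_cohort(synthetic_config(n_control = 9, n_case = 9, n_mild = 0,
                                    n_analytes = 12, seed = 55))
  y <- encode_groups(co$panel$meta$group, "MLIV")
  zs <- zscore(co$panel)
  fit <- cytosig:::fit_nipals(zs$z, y, ncomp = 2)
  rot <- cytosig:::rotate_to_lv1(fit, y, "discriminant")

  # orthogonality and reconstruction invariance
  expect_lt(max(abs(crossprod(rot$rotation) - diag(2))), 1e-10)
  expect_lt(max(abs(tcrossprod(rot$scores, rot$weights) -
                    tcrossprod(fit$scores, fit$weights))), 1e-10)
  # all group separation now on LV1, none on LV2, case positive
  expect_lt(abs(mean(rot$scores[y > 0, 2]) - mean(rot$scores[y <= 0, 2])), 1e-10)
  expect_gt(mean(rot$scores[y > 0, 1]), mean(rot$scores[y <= 0, 1]))
  # the rotated subspace is unchanged
  expect_equal(tcrossprod(qr.Q(qr(rot$scores))), tcrossprod(qr.Q(qr(fit$scores))),
               tolerance = 1e-8)
})

test_that("separation purely along one axis gives the quarter-turn cases", {
  # construct a fit whose group separation lies exactly on LV1
  y <- rep(c(-1, 1), each = 10)
  fit <- list(scores = cbind(y * 2, rep(c(-1, 1), 10)),
              weights = diag(2), x_loadings = diag(2), projection = diag(2))
  r <- cytosig:::rotate_to_lv1(fit, y, "discriminant")
  expect_equal(r$theta, 0)
  expect_equal(r$rotation, diag(2))

  # separation purely along LV2 -> 90 degrees, moved onto LV1
  fit2 <- fit
  fit2$scores <- fit$scores[, 2:1]
  r2 <- cytosig:::rotate_to_lv1(fit2, y, "discriminant")
  expect_equal(abs(r2$theta), pi / 2, tolerance = 1e-12)
  expect_lt(abs(mean(r2$scores[y > 0, 2]) - mean(r2$scores[y <= 0, 2])), 1e-10)
  expect_gt(mean(r2$scores[y > 0, 1]) - mean(r2$scores[y <= 0, 1]), 3.9)
})

test_that("label swap negates LV1; raw column rescaling leaves the fit unchanged", {
  co <- gen_cohort(synthetic_config(n_control = 8, n_case = 8, n_mild = 0,
                                    n_analytes = 10, seed = 66))
  f1 <- cyto_pls(co$panel, "group", case = "MLIV")
  f2 <- cyto_pls(co$panel, "group", case = "CTRL")
  expect_equal(f2$scores[, 1], -f1$scores[, 1], tolerance = 1e-10)
  expect_equal(f2$weights[, 1], -f1$weights[, 1], tolerance = 1e-10)

  x <- co$panel$x
  x[, 3] <- x[, 3] * 17.5  # positive rescaling is absorbed by z-scoring
  f3 <- cyto_pls(cytokine_panel(x, co$panel$meta), "group", case = "MLIV")
  expect_equal(f3$scores, f1$scores, tolerance = 1e-10)
  expect_equal(f3$weights, f1$weights, tolerance = 1e-10)
})

test_that("continuous-target fits orient LV1 toward better scores", {
  co <- gen_cohort(synthetic_config(n_control = 10, n_case = 10, n_mild = 0,
                                    n_analytes = 8, case_shift = 1.5, seed = 77))
  sc <- gen_clinical_scores(co$truth, score_noise = 0.5)
  panel <- attach_scores(co$panel, sc)
  fit <- cyto_pls(panel, "bamf_gross_motor")
  expect_identical(fit$y_type, "regression")
  expect_gt(cor(fit$scores[, 1], panel$meta$bamf_gross_motor), 0)
})

test_that("projection reproduces training scores and maps zero rows to origin", {
  co <- gen_cohort(synthetic_config(n_control = 8, n_case = 8, n_mild = 0,
                                    n_analytes = 9, seed = 88))
  fit <- cyto_pls(co$panel, "group", case = "MLIV")
  expect_lt(max(abs(predict(fit, co$panel) - fit$scores)), 1e-10)

  # an all-zero z row scores (0, 0): project raw data equal to column means
  z0 <- matrix(rep(fit$scaling$center, 2), 2, length(fit$analytes), byrow = TRUE,
               dimnames = list(c("n1", "n2"), fit$analytes))
  sc <- predict(fit, rbind(z0, co$panel$x), rescale = "training")[1:2, ]
  expect_lt(max(abs(sc)), 1e-10)

  expect_error(predict(fit, co$panel$x[, -1]), "missing")
})
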