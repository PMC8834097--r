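test_that("coincident selection honors the magnitude, CV and direction rules", {
  an <- c("IP-10", "IL-9", "Eotaxin", "IL-17", "VEGF", "IL-6")
  a <- fake_profile(an, means = c(0.50, 0.20, 0.30, -0.40, 0.50, 0.19),
                    cvs = c(0.5, 0.99, 0.5, 0.5, 0.5, 0.1))
  b <- fake_profile(an, means = c(0.45, 0.25, 0.30, -0.35, -0.50, 0.30),
                    cvs = c(0.5, 0.50, 1.00, 0.5, 0.5, 0.1))
  sig <- select_coincident(a, b)
  # IP-10: strong/stable both sides -> in; IL-9: boundary mean 0.2 counts (>=)
  # Eotaxin: CV 1.0 is not < 1 -> out; IL-17: case-down both sides -> in
  # VEGF: direction mismatch -> out; IL-6: |mean| 0.19 < 0.2 in A -> out
  expect_setequal(sig$analyte, c("IP-10", "IL-9", "IL-17"))
  expect_identical(sig$direction[sig$analyte == "IL-17"], "case-down")
  expect_identical(sig$direction[sig$analyte == "IP-10"], "case-up")

  # without the direction requirement VEGF qualifies on magnitude/stability
  sig2 <- select_coincident(a, b, require_direction_match = FALSE)
  expect_true("VEGF" %in% sig2$analyte)

  expect_error(select_coincident(a, fake_profile("ZZ", 1, 0.1)), "disjoint")
  expect_warning(select_coincident(a, b, mean_threshold = 0.96), "no coincident")
})

test_that("selection is symmetric in its two profiles", {
  set.seed(20)
  an <- sprintf("CK%02d", 1:15)
  a <- fake_profile(an, means = round(runif(15, -0.5, 0.5), 2),
                    cvs = round(runif(15, 0.1, 1.5), 2))
  b <- fake_profile(an, means = round(runif(15, -0.5, 0.5), 2),
                    cvs = round(runif(15, 0.1, 1.5), 2))
  expect_setequal(suppressWarnings(select_coincident(a, b)$analyte),
                  suppressWarnings(select_coincident(b, a)$analyte))
})

test_that("tightening either threshold never grows the signature", {
  set.seed(21)
  an <- sprintf("CK%02d", 1:20)
  for (rep in 1:5) {
    a <- fake_profile(an, runif(20, -0.6, 0.6), runif(20, 0.05, 2))
    b <- fake_profile(an, runif(20, -0.6, 0.6), runif(20, 0.05, 2))
    sel <- function(mt, ct) suppressWarnings(
      select_coincident(a, b, mean_threshold = mt, cv_threshold = ct)$analyte)
    base <- sel(0.2, 1.0)
    expect_true(all(sel(0.3, 1.0) %in% base))
    expect_true(all(sel(0.2, 0.6) %in% base))
    expect_true(all(sel(0.35, 0.5) %in% sel(0.25, 0.8)))
  }
})

test_that("reduced fit on all analytes reproduces the full model", {
  co <- gen_cohort(synthetic_config(n_control = 8, n_case = 8, n_mild = 0,
                                    n_analytes = 10, seed = 51))
  full <- cyto_pls(co$panel, "group", case = "MLIV")
  red <- reduced_fit(co$panel, colnames(co$panel$x), "group", case = "MLIV")
  expect_lt(max(abs(red$scores - full$scores)), 1e-10)

  one <- reduced_fit(co$panel, co$truth$planted_analytes[1], "group",
                     case = "MLIV", ncomp = 1, rotate = FALSE)
  expect_equal(abs(unname(one$weights[1, 1])), 1, tolerance = 1e-12)

  expect_error(reduced_fit(co$panel, "NOPE", "group", case = "MLIV"), "NOPE")
})

test_that("transfer onto the training panel itself returns the training AUC", {
  co <- gen_cohort(synthetic_config(n_control = 9, n_case = 9, n_mild = 0,
                                    n_analytes = 12, seed = 52))
  fit <- cyto_pls(co$panel, "group", case = "MLIV")
  tr <- transfer_signature(fit, co$panel)
  train_auc <- cytosig:::auc_scores(fit$scores[, 1], fit$y > 0)
  expect_equal(tr$auc, train_auc, tolerance = 1e-12)
  expect_equal(unname(tr$scores), unname(fit$scores), tolerance = 1e-10)
})

test_that("transfer AUC agrees with the pROC oracle and is scale-invariant", {
  skip_if_not_installed("pROC")
  co <- gen_cohort(synthetic_config(n_control = 8, n_case = 10, n_mild = 0,
                                    n_analytes = 10, seed = 53))
  fit <- cyto_pls(co$panel, "group", case = "MLIV")
  tr <- transfer_signature(fit, co$panel)
  ref <- suppressMessages(pROC::auc(tr$is_case, tr$lv1, direction = "<"))
  expect_equal(tr$auc, as.numeric(ref), tolerance = 1e-12)

  # positive rescaling of target columns is absorbed by internal z-scoring
  x2 <- sweep(co$panel$x, 2, runif(10, 0.5, 20), "*")
  tr2 <- transfer_signature(fit, cytokine_panel(x2, co$panel$meta))
  expect_equal(tr2$auc, tr$auc, tolerance = 1e-12)
})

test_that("transfer maps analyte names across panels and flags gaps", {
  co <- gen_cohort(synthetic_config(n_control = 8, n_case = 8, n_mild = 0,
                                    n_analytes = 6, seed = 54))
  fit <- cyto_pls(co$panel, "group", case = "MLIV")
  pb <- co$panel
  colnames(pb$x) <- paste0("m-", colnames(pb$x))
  pb <- cytokine_panel(pb$x, pb$meta)
  m <- analyte_map(fit$analytes, paste0("m-", fit$analytes))
  tr <- transfer_signature(fit, pb, map = m)
  expect_equal(tr$auc, transfer_signature(fit, co$panel)$auc, tolerance = 1e-12)

  expect_error(transfer_signature(fit, pb, map = m[-1, ]), "does not cover")
})
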