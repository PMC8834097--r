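# small deterministic fixtures built in code

tiny_panel <- function(n_per_group = 5, p = 4, seed = 1,
                       labels = c("CTRL", "MLIV")) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(10^(rnorm(n * p, mean = 1.5, sd = 0.3)), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("A%02d", 1:p)))
  meta <- data.frame(sample_id = rownames(x),
                     group = rep(labels, each = n_per_group),
                     species = "human", compartment = "plasma",
                     stringsAsFactors = FALSE)
  cytokine_panel(x, meta)
}

# stability-profile stub with chosen means/CVs, for selection-rule tests
fake_profile <- function(analytes, means, cvs) {
  data.frame(analyte = analytes, mean = means, sd = abs(means) * cvs,
             cv = cvs, stringsAsFactors = FALSE)
}

expect_panel_equal <- function(a, b) {
  expect_equal(a$x, b$x)
  expect_equal(a$meta, b$meta)
}
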