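test_that("regression r-squared behaves at the analytic anchors", {
  # exactly collinear pairs
  g <- 1:50
  expect_equal(regression_r2(g, 3 + 2 * g)$r_squared, 1)
  # independence: r-squared near zero at large n
  set.seed(5)
  expect_lt(regression_r2(rnorm(20000), rnorm(20000))$r_squared, 0.01)
  # closed-form linear-Gaussian model: fitted r^2 equals the population rho
  for (rho in c(0.5, 0.8, 0.977)) {
    p <- sample_correlated_pairs(20000, rho, seed = 11)
    expect_lt(abs(regression_r2(p$gfp, p$reporter)$r_squared - rho), 0.02)
  }
  # degenerate inputs are explicit errors
  expect_error(regression_r2(1:2, 1:2), "n < 3")
  expect_error(regression_r2(rep(1, 10), rnorm(10)), "variance")
})

test_that("r-squared is invariant under affine rescaling of either variable", {
  p <- sample_correlated_pairs(500, 0.7, seed = 13)
  r0 <- regression_r2(p$gfp, p$reporter)$r_squared
  expect_equal(regression_r2(10 * p$gfp - 3, p$reporter)$r_squared, r0)
  expect_equal(regression_r2(p$gfp, 0.02 * p$reporter + 40)$r_squared, r0)
  expect_gte(r0, 0); expect_lte(r0, 1)
})

test_that("noiseless 4PL samples are recovered to 1e-6 relative", {
  cc <- c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10, 20)
  cases <- list(c(top = 900, bottom = 50, cp50 = 7.3, hill = 1),
                c(top = 12, bottom = 0, cp50 = 2.1, hill = 2.4),
                c(top = 5e4, bottom = 1e3, cp50 = 14.9, hill = 0.7))
  for (p in cases) {
    y <- p["bottom"] + (p["top"] - p["bottom"]) / (1 + (cc / p["cp50"])^p["hill"])
    f <- fit_dose_response(cc, y)
    expect_true(f$converged)
    expect_lt(abs(f$cp50 - p["cp50"]) / p["cp50"], 1e-6)
    expect_lt(abs(f$hill - p["hill"]) / p["hill"], 1e-6)
    expect_lt(abs(f$top - p["top"]) / p["top"], 1e-6)
  }
})

test_that("dose-response fit is scale-equivariant and flags flat responses", {
  cc <- rep(c(0, 0.625, 1.25, 2.5, 5, 10, 20), 2)
  set.seed(3)
  y <- 800 / (1 + (cc / 6)^1.2) + rnorm(length(cc), 0, 10)
  f1 <- fit_dose_response(cc, y)
  f2 <- fit_dose_response(cc, y * 1234)
  expect_equal(f1$cp50, f2$cp50, tolerance = 1e-6)
  expect_equal(f1$hill, f2$hill, tolerance = 1e-6)
  # flat response: non-convergence, no CP50
  flat <- fit_dose_response(cc, 5 + rnorm(length(cc), 0, 1))
  expect_false(flat$converged)
  expect_true(is.na(flat$cp50))
  # input contract
  expect_error(fit_dose_response(c(0, 1, 2), c(1, 2, 3)), "5 distinct")
  expect_error(fit_dose_response(c(1, 2, 4, 8, 16), rep(1, 5)), "including 0")
})

test_that("replicate-wise fits give the SEM of CP50", {
  cc <- rep(c(0, 0.625, 1.25, 2.5, 5, 10, 20), 3)
  reps <- rep(1:3, each = 7)
  set.seed(7)
  y <- 900 / (1 + (cc / 7.3)) * exp(rnorm(21, 0, 0.04))
  f <- fit_dose_response(cc, y, reps, fix_bottom = 0)
  expect_equal(f$n_replicates, 3)
  expect_length(f$replicate_cp50, 3)
  expect_equal(f$se_cp50, sd(f$replicate_cp50) / sqrt(3))
})

test_that("paired one-tailed t-test matches its Student-t oracle", {
  # d = (1, 2, 3): t = 2/(1/sqrt(3)), df = 2
  r <- paired_one_tailed_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.03708995, tolerance = 1e-6)
  # cross-check against the reference implementation
  tt <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE, alternative = "greater")
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  # symmetric differences with zero mean
  expect_equal(paired_one_tailed_t(c(1, 3), c(3, 1))$p, 0.5)
  # identical vectors: 0/0 resolved to t = 0, p = 0.5 by convention
  z <- paired_one_tailed_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(z$t, 0); expect_equal(z$p, 0.5); expect_true(z$zero_variance)
  # zero-variance nonzero mean: machine-floor p with a flag
  w <- paired_one_tailed_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(w$zero_variance)
  expect_lt(w$p, 1e-300)
  expect_error(paired_one_tailed_t(1:3, 1:2), "equal length")
  expect_error(paired_one_tailed_t(1, 2), "n >= 2")
})

test_that("toxicity curve normalises selected counts to controls", {
  qc <- data.frame(well = c("A1", "B1", "A2", "B2", "A3", "B3"),
                   concentration = c(0, 0, 5, 5, 20, 20),
                   replicate = c(1, 2, 1, 2, 1, 2),
                   selected = c(100, 104, 98, 106, 101, 99))
  tox <- toxicity_curve(qc, c("A1", "B1"))
  expect_equal(tox$concentration, c(0, 5, 20))
  expect_equal(tox$percent_selected[1], 100)
  expect_true(all(abs(tox$percent_selected - 100) < 5))
  # ramped damage: strictly decreasing
  qc2 <- qc; qc2$selected <- c(100, 104, 60, 64, 21, 19)
  tox2 <- toxicity_curve(qc2, c("A1", "B1"))
  expect_true(all(diff(tox2$percent_selected) < 0))
  # controls only: single point at 100
  tox3 <- toxicity_curve(qc[qc$concentration == 0, ], c("A1", "B1"))
  expect_equal(tox3$percent_selected, 100)
  # zero control counts are an error
  qc4 <- qc; qc4$selected[1:2] <- 0
  expect_error(toxicity_curve(qc4, c("A1", "B1")), "zero selected")
})

test_that("mask comparison reports differences and the planned one-tailed test", {
  mk <- function(cp50s) {
    f <- list(cp50 = mean(cp50s), hill = 1, top = 1, bottom = 0,
              se_cp50 = sd(cp50s) / sqrt(length(cp50s)), se_cp50_fit = NA,
              n_replicates = length(cp50s), converged = TRUE,
              residual_sd = 0, replicate_cp50 = setNames(cp50s, seq_along(cp50s)))
    class(f) <- "capa_fit"; f
  }
  # identical per-replicate CP50s: difference 0, p = 0.5
  cmp <- compare_masks(mk(c(7, 8, 9)), mk(c(7, 8, 9)))
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p, 0.5)
  # whole-cell consistently above organelle: small p, positive difference
  cmp2 <- compare_masks(mk(c(8.0, 8.2, 7.9)), mk(c(7.2, 7.5, 7.3)))
  expect_gt(cmp2$difference, 0)
  expect_lt(cmp2$p, 0.05)
  # mismatched replicates
  bad <- mk(c(7, 8)); bad$replicate_cp50 <- setNames(c(7, 8), c("4", "5"))
  expect_error(compare_masks(mk(c(7, 8, 9)), bad), "matching replicates")
})
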