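test_that("occupancy response follows the Hill blocking curve", {
  # midpoint, zero-dose and 3x-midpoint anchors
  expect_equal(occupancy_response(7.3, 7.3, 1), 0.5)
  expect_equal(occupancy_response(7.3, 7.3, 2.7), 0.5)
  expect_equal(occupancy_response(0, 5, 1), 0)
  expect_equal(occupancy_response(3 * 5, 5, 1), 0.75)
  # monotone non-decreasing in concentration for a grid of slopes
  for (h in c(0.5, 1, 2)) {
    cc <- seq(0, 40, by = 0.5)
    th <- occupancy_response(cc, 7.3, h)
    expect_true(all(diff(th) >= 0))
    expect_true(all(th >= 0 & th < 1))
  }
  expect_error(occupancy_response(1, -1, 1), "cp50")
  expect_error(occupancy_response(1, 5, 0), "Hill")
  expect_error(occupancy_response(-1, 5, 1), "concentration")
})

test_that("population sampling is deterministic and honours the config", {
  cfg <- quick_config()
  a <- sample_population(cfg, "stable", 5, seed = 9)
  b <- sample_population(cfg, "stable", 5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, sample_population(cfg, "stable", 5, seed = 10)))
  # occupancy equals the Hill response at the well concentration
  expect_true(all(a$occupancy ==
                    occupancy_response(5, cfg$cp50_true, cfg$hill_true)))
  # no damage, pure-normal mixture
  cfg2 <- quick_config(p_damaged = 0,
                       transient_mix = c(p_non = 0, p_normal = 1, p_over = 0))
  p <- sample_population(cfg2, "transient", 0, seed = 1)
  expect_true(all(!p$damaged))
  expect_true(all(p$expr_class == "normal"))
})

test_that("damage and expression-class frequencies converge to the configured rates", {
  cfg <- capa_config()
  dam <- integer(0); cls <- character(0); expr <- numeric(0)
  for (f in 1:170) {
    p <- sample_population(cfg, "transient", 0, seed = 7000 + f)
    dam <- c(dam, p$damaged); cls <- c(cls, p$expr_class)
    expr <- c(expr, p$expression[p$expr_class == "over"])
  }
  n <- length(dam)
  expect_gte(n, 10000)
  expect_lt(abs(mean(dam) - cfg$p_damaged), 0.01)
  expect_lt(abs(mean(cls == "over") - 0.6), 0.02)
  expect_lt(abs(mean(cls == "non") - 0.2), 0.02)
  # over-expressers at >= 10x the median expression
  expect_true(all(expr >= 10 * cfg$expression_median))
})

test_that("log-normal expression matches the configured median and CV", {
  cfg <- capa_config()
  e <- numeric(0)
  for (f in 1:100)
    e <- c(e, sample_population(cfg, "stable", 0, seed = f)$expression)
  expect_lt(abs(median(e) / cfg$expression_median - 1), 0.05)
  expect_lt(abs(sd(e) / mean(e) - cfg$expression_cv), 0.05)
})

test_that("noise-free rendering deposits the exact specific reporter signal", {
  cfg <- noise_off(quick_config(offtarget_amplitude = 0, p_damaged = 0))
  pop <- sample_population(cfg, "stable", 5, seed = 3)
  imgs <- render_field(pop, cfg, seed = 4)
  truth <- attr(imgs, "organelle_truth")
  off <- cfg$camera$offset
  # no off-target, no noise: reporter is exactly the offset outside organelles
  expect_true(all(imgs$reporter[!truth] == off))
  # a single isolated cell: the mean specific reporter signal on its
  # texture equals reporter_gain * expression * (1 - occupancy) exactly
  theta <- occupancy_response(5, cfg$cp50_true, cfg$hill_true)
  one <- data.frame(cell_id = 1L, y_px = 128, x_px = 128, expression = 1.7,
                    occupancy = theta, damaged = FALSE,
                    expr_class = "normal", organelle_kind = "mitochondria",
                    stringsAsFactors = FALSE)
  im1 <- render_field(one, cfg, seed = 8)
  t1 <- attr(im1, "organelle_truth")
  expect_gt(sum(t1), 0)
  expect_equal(mean(im1$reporter[t1]) - off,
               round(cfg$reporter_gain * 1.7 * (1 - theta)),
               tolerance = 0.51)
})

test_that("full occupancy silences the reporter on the organelle", {
  cfg <- noise_off(quick_config(offtarget_amplitude = 0, p_damaged = 0))
  pop <- sample_population(cfg, "stable", 5, seed = 3)
  pop$occupancy <- 1
  imgs <- render_field(pop, cfg, seed = 4)
  expect_true(all(imgs$reporter == cfg$camera$offset))
})

test_that("rendering validates centroids and rejects overfull fields", {
  cfg <- quick_config()
  pop <- sample_population(cfg, "stable", 0, seed = 1)
  bad <- pop; bad$x_px[1] <- 1e4
  expect_error(render_field(bad, cfg, seed = 1), "inside the field")
  expect_error(sample_population(cfg, "stable", 0, seed = 1, n = 500),
               "overfull")
})

test_that("plate building writes a deterministic, complete plate", {
  cfg <- quick_config()
  lay <- plate_layout(c(0, 1.25, 2.5, 5, 10, 20), n_replicates = 2, n_fields = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- build_plate(lay, cfg, "stable", seed = 5, out_dir = d1)
  p2 <- build_plate(lay, cfg, "stable", seed = 5, out_dir = d2)
  # bookkeeping: one image per well-field, controls at concentration 0
  expect_length(p1$files, nrow(lay$wells))
  expect_equal(sum(lay$wells$concentration > 0), 10)
  expect_length(lay$control_wells, 2)
  # zero-concentration wells carry zero occupancy
  gt <- p1$ground_truth
  expect_true(all(gt$occupancy[gt$well %in% lay$control_wells] == 0))
  expect_identical(colnames(gt)[1:9],
                   c("cell_id", "well", "field", "x_px", "y_px", "expression",
                     "occupancy", "damaged", "expr_class"))
  # byte-identical ground truth across runs with the same master seed
  expect_identical(unname(tools::md5sum(file.path(d1, "ground_truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "ground_truth.csv"))))
  expect_identical(unname(tools::md5sum(p1$files[1])),
                   unname(tools::md5sum(p2$files[1])))
})

test_that("ground-truth occupancy is monotone across a concentration series", {
  cfg <- quick_config()
  cc <- c(0, 0.625, 2.5, 10, 40)
  occ <- vapply(cc, function(c)
    mean(sample_population(cfg, "stable", c, seed = 2)$occupancy), numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("correlated pair generator hits a prescribed population r-squared", {
  for (rho in c(0.3, 0.7, 0.95)) {
    p <- sample_correlated_pairs(20000, rho, seed = 17)
    r2 <- regression_r2(p$gfp, p$reporter)$r_squared
    expect_lt(abs(r2 - rho), 0.03)
  }
  expect_error(sample_correlated_pairs(10, 1.2), "r_squared")
})
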