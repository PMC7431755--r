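# handmade field: one square cell with a known-intensity organelle strip
toy_field <- function(v_body = 500, v_org = 2000, bg = 100) {
  dim <- c(128L, 128L)
  nuc <- matrix(bg, dim[1], dim[2]); gfp <- matrix(bg, dim[1], dim[2])
  rep_ <- matrix(bg, dim[1], dim[2])
  cells <- matrix(0L, dim[1], dim[2]); nl <- matrix(0L, dim[1], dim[2])
  org <- matrix(FALSE, dim[1], dim[2])
  cells[40:80, 40:80] <- 1L
  nl[55:65, 55:65] <- 1L
  org[45:50, 40:80] <- TRUE
  gfp[cells == 1L] <- bg + v_body
  gfp[org] <- bg + v_org
  rep_[cells == 1L] <- bg + v_body
  rep_[org] <- bg + v_org
  nuc[nl == 1L] <- bg + 3000
  imgs <- structure(list(nuclear = nuc, gfp = gfp, reporter = rep_),
                    class = "capa_field")
  bgl <- list(level = bg, sd = 0)
  masks <- structure(list(nuclei_labels = nl, cell_labels = cells,
                          organelle_mask = org,
                          dark_mask = matrix(FALSE, dim[1], dim[2]),
                          background = list(nuclear = bgl, gfp = bgl,
                                            reporter = bgl),
                          n_border_discarded = 0L),
                     class = "capa_masks")
  list(images = imgs, masks = masks)
}

test_that("feature extraction subtracts background from uniform regions exactly", {
  tf <- toy_field(v_body = 500, v_org = 2000, bg = 100)
  rec <- extract_features(tf$images, tf$masks, "A01", 1, 0)
  expect_equal(nrow(rec), 1)
  org_px <- sum(tf$masks$organelle_mask)
  body_px <- sum(tf$masks$cell_labels == 1L)
  expect_equal(rec$gfp_mean_organelle, 2000)
  expect_equal(rec$rep_mean_organelle, 2000)
  expect_equal(rec$gfp_mean_body,
               (500 * (body_px - org_px) + 2000 * org_px) / body_px)
  expect_equal(rec$nuc_area, 121)
  expect_equal(rec$nuc_mean_intensity, 3000)
  expect_equal(rec$organelle_area, org_px)
})

test_that("organelle-restricted reporter ignores off-target puncta", {
  cfg0 <- noise_off(quick_config(offtarget_amplitude = 0, p_damaged = 0))
  cfg1 <- noise_off(quick_config(offtarget_amplitude = 0.3, p_damaged = 0))
  pop <- sample_population(cfg0, "stable", 2.5, seed = 91)
  a <- render_field(pop, cfg0, seed = 92)
  b <- render_field(pop, cfg1, seed = 92)
  ma <- segment_field(a, cfg0$segmentation)
  mb <- segment_field(b, cfg1$segmentation)
  ra <- extract_features(a, ma, "A", 1, 2.5, cfg0$segmentation)
  rb <- extract_features(b, mb, "A", 1, 2.5, cfg1$segmentation)
  m <- match(rb$cell_id, ra$cell_id)
  ok <- !is.na(m) & is.finite(rb$rep_mean_organelle) &
    is.finite(ra$rep_mean_organelle[m])
  # organelle means barely move; body means rise with the puncta
  rel <- abs(rb$rep_mean_organelle[ok] - ra$rep_mean_organelle[m][ok]) /
    pmax(ra$rep_mean_organelle[m][ok], 1)
  expect_lt(median(rel), 0.02)
  expect_gt(mean(rb$rep_mean_body[ok] - ra$rep_mean_body[m][ok]), 0)
})

test_that("noise-free organelle GFP is proportional to expression", {
  # few, widely separated cells: no texture overlap between neighbours
  cfg <- noise_off(capa_config(n_cells_per_field = 6L, p_damaged = 0,
                               offtarget_amplitude = 0))
  q <- quantified_field(cfg, "stable", 0, seed = 101)
  r <- q$records[is.finite(q$records$gfp_mean_organelle) &
                   !is.na(q$records$true_expression), ]
  ratio <- r$gfp_mean_organelle / (cfg$gfp_gain * r$true_expression)
  # constant of proportionality within 2% across cells
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})

test_that("damage flag honours its thresholds at the boundary", {
  thr <- list(A_min = 100, I_max = 4000, F_max = 0.05, frag_min_area = 120)
  base <- data.frame(nuc_area = 300, nuc_mean_intensity = 2500,
                     organelle_n_components = 5, organelle_area = 500)
  expect_false(flag_damaged(base, thr))
  expect_true(flag_damaged(transform(base, nuc_area = 99), thr))
  expect_true(flag_damaged(transform(base, nuc_mean_intensity = 4001), thr))
  # fragmentation just above / below the limit
  expect_true(flag_damaged(transform(base, organelle_n_components = 26), thr))  # 0.052
  expect_false(flag_damaged(transform(base, organelle_n_components = 24), thr)) # 0.048
  # below the minimum organelle area the index is not trusted
  expect_false(flag_damaged(transform(base, organelle_n_components = 26,
                                      organelle_area = 100), thr))
  # missing nuclear features yield NA (excluded, counted separately)
  expect_true(is.na(flag_damaged(transform(base, nuc_area = NA), thr)))
})

test_that("selected-flag algebra holds on every record", {
  cfg <- quick_config()
  r <- quantified_population(cfg, "stable", 6, seed0 = 110)
  expect_true(all(r$selected == (!r$qc_damaged & !r$qc_gated_out), na.rm = TRUE))
  expect_true(all(is.na(r$selected) == is.na(r$qc_damaged)))
})

test_that("no damage configured implies almost no damage flagged", {
  # full-size fields: the control calibration needs a few hundred cells
  cfg <- capa_config(p_damaged = 0)
  r <- quantified_population(cfg, "stable", 6, seed0 = 120)
  expect_gte(nrow(r), 300)
  expect_lte(mean(r$qc_damaged, na.rm = TRUE), 0.01)
})

test_that("off-target index responds to the configured amplitude", {
  cfg0 <- noise_off(quick_config(offtarget_amplitude = 0, p_damaged = 0))
  pop <- sample_population(cfg0, "stable", 2.5, seed = 131)
  idx_at <- function(amp, use_truth = FALSE) {
    cfg <- noise_off(quick_config(offtarget_amplitude = amp, p_damaged = 0))
    imgs <- render_field(pop, cfg, seed = 132)
    m <- segment_field(imgs, cfg$segmentation)
    if (use_truth)   # exact organelle mask isolates the index itself
      m$organelle_mask <- attr(imgs, "organelle_truth") & m$cell_labels > 0
    median(offtarget_index(imgs, m), na.rm = TRUE)
  }
  # with the exact mask and no puncta the index vanishes
  expect_lt(idx_at(0, use_truth = TRUE), 0.01)
  # with estimated masks it grows monotonically with the amplitude
  iv <- vapply(c(0, 0.1, 0.2, 0.3), idx_at, numeric(1))
  expect_lt(iv[1], 0.2)            # residual: texture pixels missed by the mask
  expect_true(all(diff(iv) > 0))   # monotone in amplitude on a fixed seed
  # occupancy 1 with puncta on: only off-target remains
  cfg <- noise_off(quick_config(offtarget_amplitude = 0.3, p_damaged = 0))
  pop1 <- pop; pop1$occupancy <- 1
  imgs <- render_field(pop1, cfg, seed = 133)
  m <- segment_field(imgs, cfg$segmentation)
  expect_gt(median(offtarget_index(imgs, m), na.rm = TRUE), 0.9)
})

test_that("doubling the camera offset leaves background-subtracted means unchanged", {
  cfg1 <- noise_off(quick_config(p_damaged = 0))
  cfg2 <- cfg1; cfg2$camera$offset <- 200
  pop <- sample_population(cfg1, "stable", 2.5, seed = 141)
  a <- render_field(pop, cfg1, seed = 142)
  b <- render_field(pop, cfg2, seed = 142)
  ma <- segment_field(a, cfg1$segmentation)
  mb <- segment_field(b, cfg2$segmentation)
  ra <- extract_features(a, ma, "A", 1, 2.5, cfg1$segmentation)
  rb <- extract_features(b, mb, "A", 1, 2.5, cfg2$segmentation)
  m <- match(rb$cell_id, ra$cell_id)
  expect_equal(rb$gfp_mean_body, ra$gfp_mean_body[m], tolerance = 1e-6)
  expect_equal(rb$rep_mean_body, ra$rep_mean_body[m], tolerance = 1e-6)
})

test_that("QC summary counts per well add up", {
  cfg <- quick_config()
  lay <- plate_layout(c(0, 5), n_replicates = 2, n_fields = 1)
  d <- withr::local_tempdir()
  res <- suppressMessages(
    run_pipeline(cfg, d, "stable", stages = c("simulate", "segment", "quantify"),
                 layout = lay, seed = 7))
  qc <- res$qc
  expect_setequal(qc$well, lay$wells$well_id)
  agg <- table(res$records$well)
  expect_equal(qc$total, as.integer(agg[qc$well]))
  expect_true(all(qc$selected + qc$damaged + qc$gated + qc$missing_features
                  <= qc$total))
})
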