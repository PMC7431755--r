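# shared fixtures: all synthetic, generated in code at test time

# small, fast field for unit tests
quick_config <- function(...) {
  capa_config(field_size_px = c(256L, 256L), n_cells_per_field = 12L, ...)
}

# disable the camera noise terms (renders become deterministic given seed)
noise_off <- function(config) {
  config$camera$read_noise_sd <- 0
  config$camera$poisson_scale <- 0
  config
}

# sample + render + segment + extract one field; truth matched by the cell
# label found at each ground-truth centroid
quantified_field <- function(config, mode = "stable", concentration = 0,
                             seed = 1, well = "A01", field = 1L) {
  pop <- sample_population(config, mode, concentration, seed = seed)
  imgs <- render_field(pop, config, seed = seed + 5000L)
  masks <- segment_field(imgs, config$segmentation)
  rec <- extract_features(imgs, masks, well, field, concentration,
                          config$segmentation)
  lab <- masks$cell_labels[cbind(round(pop$y_px), round(pop$x_px))]
  m <- match(rec$cell_id, lab)
  rec$true_damaged <- pop$damaged[m]
  rec$true_class <- pop$expr_class[m]
  rec$true_expression <- pop$expression[m]
  rec$true_occupancy <- pop$occupancy[m]
  list(pop = pop, images = imgs, masks = masks, records = rec)
}

# pool several quantified fields into one QC-ready record table
quantified_population <- function(config, mode, n_fields, concentration = 0,
                                  seed0 = 100, apply_filters = TRUE) {
  recs <- vector("list", n_fields)
  sds <- numeric(n_fields)
  for (f in seq_len(n_fields)) {
    q <- quantified_field(config, mode, concentration, seed = seed0 + f,
                          well = sprintf("W%03d", f), field = 1L)
    recs[[f]] <- q$records
    sds[f] <- q$masks$background$gfp$sd
  }
  recs <- do.call(rbind, recs)
  if (apply_filters)
    recs <- apply_qc(recs, unique(recs$well), stats::median(sds),
                     config$quantify)
  recs
}
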