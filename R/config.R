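#' Simulation and analysis configuration
#'
#' Builds the single configuration object used by every stage of the HC CAPA
#' pipeline. Top-level fields parameterise the synthetic plate generator;
#' the `geometry`, `segmentation`, `quantify` and `fit` sections hold the
#' rendering geometry and the analysis parameters. Every numeric default of
#' the pipeline lives here, never hard-coded in the stages.
#'
#' @param field_size_px integer pair, image size in pixels (rows, cols).
#' @param pixel_size_um physical pixel size in micrometres.
#' @param n_cells_per_field number of cells placed per field.
#' @param expression_median,expression_cv median and coefficient of variation
#'   of the per-cell log-normal HaloTag-GFP expression (dimensionless units).
#' @param gfp_gain,reporter_gain detector counts per expression unit for the
#'   GFP and reporter channels.
#' @param cp50_true ground-truth half-maximal penetration concentration (uM).
#' @param hill_true ground-truth Hill slope of the occupancy response.
#' @param offtarget_amplitude amplitude of off-target reporter puncta as a
#'   fraction of the cell's maximal specific reporter signal.
#' @param offtarget_puncta_per_cell number of off-target puncta per cell.
#' @param p_damaged probability that a cell is rendered as damaged
#'   (condensed nucleus, fragmented organelle network).
#' @param transient_mix named probabilities `p_non`, `p_normal`, `p_over`
#'   of the transient-transfection expression classes; must sum to 1.
#' @param camera list `read_noise_sd`, `poisson_scale`, `offset` describing
#'   the Poisson-Gaussian detector model. `poisson_scale = 0` disables shot
#'   noise and `read_noise_sd = 0` disables read noise (noise-free renders).
#' @param seed default master seed for plate generation.
#' @param geometry,segmentation,quantify,fit optional lists overriding
#'   individual entries of the corresponding default sections (see Details).
#'
#' @details
#' `geometry` controls rendering: nucleus/cell radii (px), minimum
#' centre-to-centre separation, mitochondrial filament walks, Golgi puncta
#' cluster, damaged-cell fragment specks and nuclear condensation factors.
#' `segmentation` holds blur sigmas, nucleus area limits, watershed
#' tolerance, the cell-body growth limit, the top-hat structuring element
#' size and the robust organelle threshold factor `k_mad`.
#' `quantify` holds the damaged-cell calibration factor `k_damage`, the
#' transfection-gate defaults `d_min` and `g_min_sd` and the dark-region
#' factor `dark_m`. `fit` holds the dose-response options.
#'
#' @return A list of class `capa_config`.
#' @examples
#' cfg <- capa_config(n_cells_per_field = 20, seed = 7)
#' cfg$cp50_true
#' @export
capa_config <- function(field_size_px = c(512L, 512L),
                        pixel_size_um = 0.65,
                        n_cells_per_field = 60L,
                        expression_median = 1.0,
                        expression_cv = 0.4,
                        gfp_gain = 5000,
                        reporter_gain = 4000,
                        cp50_true = 7.3,
                        hill_true = 1.0,
                        offtarget_amplitude = 0.15,
                        offtarget_puncta_per_cell = 6L,
                        p_damaged = 0.15,
                        transient_mix = c(p_non = 0.2, p_normal = 0.2, p_over = 0.6),
                        camera = list(read_noise_sd = 2, poisson_scale = 0.5, offset = 100),
                        seed = 1L,
                        geometry = list(),
                        segmentation = list(),
                        quantify = list(),
                        fit = list()) {
  geom_default <- list(
    nucleus_radius_px = 10,
    cell_radius_px = 28,
    min_separation_px = 40,
    nuclear_gain = 3000,
    filament_n = 6,
    filament_steps = 130,
    golgi_puncta_n = 12,
    golgi_punctum_radius_px = 3,
    golgi_cluster_sd_px = 5,
    damaged_nucleus_scale = 0.35,
    damaged_nucleus_brightness = 1.8,
    damaged_fragment_n = 35,
    damaged_fragment_radius_px = 1.5,
    offtarget_punctum_radius_px = 3.5,
    offtarget_amp_cv = 0.35,
    offtarget_field_cv = 0.6,
    over_expression_min_fold = 10,
    over_expression_max_fold = 25,
    non_expression_fold = 0.01
  )
  seg_default <- list(
    nuc_blur_sigma = 2,
    nuc_min_area = 40,
    nuc_max_area = 1500,
    watershed_tolerance = 2,
    body_blur_sigma = 3,
    body_max_grow_px = 20,
    body_max_radius_px = 34,
    body_fg_k = 3,
    propagate_lambda = 1e-4,
    tophat_size = 9,
    organelle_k_mad = 3,
    dark_m = 2
  )
  qc_default <- list(
    k_damage = 4,
    frag_fold = 40,
    d_min = 0.25,
    g_min_sd = 3,
    g_min_frac = 0.05,
    frag_min_area = 120
  )
  fit_default <- list(
    fix_bottom = 0,
    aggregate = "median"
  )

  cfg <- list(
    field_size_px = as.integer(field_size_px),
    pixel_size_um = pixel_size_um,
    n_cells_per_field = as.integer(n_cells_per_field),
    expression_median = expression_median,
    expression_cv = expression_cv,
    gfp_gain = gfp_gain,
    reporter_gain = reporter_gain,
    cp50_true = cp50_true,
    hill_true = hill_true,
    offtarget_amplitude = offtarget_amplitude,
    offtarget_puncta_per_cell = as.integer(offtarget_puncta_per_cell),
    p_damaged = p_damaged,
    transient_mix = transient_mix,
    camera = utils::modifyList(list(read_noise_sd = 2, poisson_scale = 0.5, offset = 100),
                               as.list(camera)),
    seed = as.integer(seed),
    geometry = utils::modifyList(geom_default, as.list(geometry)),
    segmentation = utils::modifyList(seg_default, as.list(segmentation)),
    quantify = utils::modifyList(qc_default, as.list(quantify)),
    fit = utils::modifyList(fit_default, as.list(fit))
  )
  class(cfg) <- "capa_config"
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' Checks the invariants of a [capa_config()] object: probabilities in
#' \[0, 1\], transfection mixture summing to one, positive `cp50_true` and
#' `hill_true`, field dimensions of at least 128 px.
#'
#' @param config a `capa_config` object.
#' @return `config`, invisibly, if valid; otherwise an error of class
#'   `capa_error`.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "capa_config"))
  if (length(config$field_size_px) != 2L || any(config$field_size_px < 128L))
    capa_stop("field_size_px must be two integers >= 128")
  if (config$cp50_true <= 0) capa_stop("cp50_true must be > 0")
  if (config$hill_true <= 0) capa_stop("hill_true must be > 0")
  probs <- c(config$p_damaged, config$offtarget_amplitude, config$transient_mix)
  if (any(probs < 0) || any(config$transient_mix > 1) || config$p_damaged > 1)
    capa_stop("probabilities must lie in [0, 1]")
  if (abs(sum(config$transient_mix) - 1) > 1e-12)
    capa_stop("transient_mix must sum to 1 (got ", sum(config$transient_mix), ")")
  if (config$expression_median <= 0 || config$expression_cv < 0)
    capa_stop("expression_median must be > 0 and expression_cv >= 0")
  invisible(config)
}

#' Read / write configuration files
#'
#' The on-disk configuration is a YAML file whose keys mirror the
#' [capa_config()] fields exactly; nested sections (`camera`,
#' `transient_mix`, `geometry`, `segmentation`, `quantify`, `fit`) are YAML
#' mappings.
#'
#' @param path file path of the YAML configuration.
#' @return `read_config()` returns a validated `capa_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) capa_stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(capa_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    capa_stop("unknown config fields: ", paste(extra, collapse = ", "))
  if (!is.null(raw$transient_mix)) raw$transient_mix <- unlist(raw$transient_mix)
  do.call(capa_config, raw)
}

#' @rdname read_config
#' @param config a `capa_config` object.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  # named atomic vectors serialise as YAML sequences; keep the names
  out$transient_mix <- as.list(out$transient_mix)
  out$field_size_px <- as.list(out$field_size_px)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 digest of the canonical YAML serialisation; used in run manifests to
#' tie outputs to the exact configuration that produced them.
#'
#' @param config a `capa_config` object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

# error helper: user-facing errors carry class capa_error so the CLI can
# distinguish them (exit 1) from internal failures (exit 2)
capa_stop <- function(...) {
  stop(structure(class = c("capa_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a reproducible child seed
#'
#' Deterministic stream seeds for per-field generation: a polynomial rolling
#' hash of the master seed and the string identifiers, reduced modulo
#' 2^31 - 1 so the result is a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param ... well id, field index, stage name, ... (coerced to character).
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "/")
  h <- as.double(master_seed %% 2147483647)
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Plate layouts
#'
#' Describes a multiwell plate: one row per well with its transporter
#' concentration (uM), replicate index and number of imaged fields. Wells at
#' concentration 0 are the untreated controls. The default layout is a
#' serial dilution spanning the assay's working range, with one control
#' well per replicate.
#'
#' @param concentrations vector of transporter concentrations (uM); must
#'   include 0 (the controls).
#' @param n_replicates number of replicate well series.
#' @param n_fields fields imaged per well.
#' @return A list of class `capa_layout` with elements `wells` (data.frame:
#'   `well_id`, `concentration`, `replicate`, `n_fields`) and
#'   `control_wells`.
#' @examples
#' lay <- plate_layout(c(0, 2.5, 5, 10, 20), n_replicates = 2)
#' lay$control_wells
#' @export
plate_layout <- function(concentrations = c(0, 0.3125, 0.625, 1.25, 2.5, 5, 10, 20),
                         n_replicates = 3L,
                         n_fields = 1L) {
  if (any(concentrations < 0)) capa_stop("concentrations must be >= 0")
  if (!any(concentrations == 0)) capa_stop("layout needs at least one control (concentration 0) well")
  concentrations <- sort(unique(concentrations))
  wells <- expand.grid(ci = seq_along(concentrations),
                       replicate = seq_len(n_replicates))
  wells <- data.frame(
    well_id = sprintf("%s%02d", LETTERS[wells$replicate], wells$ci),
    concentration = concentrations[wells$ci],
    replicate = wells$replicate,
    n_fields = as.integer(n_fields),
    stringsAsFactors = FALSE
  )
  structure(list(wells = wells,
                 control_wells = wells$well_id[wells$concentration == 0]),
            class = "capa_layout")
}

#' @export
print.capa_layout <- function(x, ...) {
  cat("HC CAPA plate layout:", nrow(x$wells), "wells,",
      length(unique(x$wells$concentration)), "concentrations,",
      max(x$wells$replicate), "replicates,",
      length(x$control_wells), "control wells\n")
  invisible(x)
}
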