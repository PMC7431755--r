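#' Fractional HaloTag occupancy at a transporter concentration
#'
#' Hill-type blocking curve of the CAPA mechanism: a chloroalkane-tagged
#' cargo that reaches the cytosol reacts with HaloTags, so the fraction of
#' blocked (occupied) tags rises with the transporter concentration and is
#' 1/2 at the half-maximal penetration concentration CP50.
#'
#' @param c transporter concentration (uM), vectorised, must be >= 0.
#' @param cp50 half-maximal penetration concentration (uM), > 0.
#' @param h Hill slope (dimensionless), > 0.
#' @return Occupancy fraction `c^h / (c^h + cp50^h)` in \[0, 1\], monotone
#'   non-decreasing in `c`.
#' @examples
#' occupancy_response(7.3, cp50 = 7.3, h = 2)   # 0.5 at the midpoint
#' occupancy_response(c(0, 21.9), 7.3, 1)       # 0 and 0.75
#' @export
occupancy_response <- function(c, cp50, h) {
  if (!is.numeric(cp50) || length(cp50) != 1L || !is.finite(cp50) || cp50 <= 0)
    capa_stop("cp50 must be a single positive number")
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    capa_stop("Hill slope h must be a single positive number")
  if (any(c < 0)) capa_stop("concentration must be >= 0")
  # (cp50/c)^h form avoids overflow for large c; c = 0 maps to exactly 0
  ifelse(c == 0, 0, 1 / (1 + (cp50 / c)^h))
}

# log-normal parameters from median and CV
lnorm_params <- function(median, cv) {
  list(meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

# jittered-grid placement with minimum-distance rejection; overlap beyond
# the configured separation is not modelled
place_centroids <- function(n, field_size, geom) {
  margin <- geom$cell_radius_px + 2
  h <- field_size[1] - 2 * margin
  w <- field_size[2] - 2 * margin
  if (h <= 0 || w <= 0) capa_stop("field too small for the configured cell radius")
  k <- ceiling(sqrt(n * max(h, w) / min(h, w)))
  ny <- max(1L, round(k * h / max(h, w)))
  nx <- ceiling(n / ny)
  while (ny * nx < n) nx <- nx + 1L
  pitch_y <- h / ny
  pitch_x <- w / nx
  if (min(pitch_y, pitch_x) < geom$min_separation_px * 0.8)
    capa_stop("overfull field: cannot place ", n, " cells at separation ",
              geom$min_separation_px, " px in ", field_size[1], "x", field_size[2])
  gy <- margin + (rep(seq_len(ny), times = nx) - 0.5) * pitch_y
  gx <- margin + (rep(seq_len(nx), each = ny) - 0.5) * pitch_x
  jit <- 0.18
  for (attempt in 1:25) {
    keep <- sample.int(length(gy), n)
    y <- gy[keep] + stats::runif(n, -jit * pitch_y, jit * pitch_y)
    x <- gx[keep] + stats::runif(n, -jit * pitch_x, jit * pitch_x)
    d2 <- as.matrix(stats::dist(cbind(y, x)))^2
    diag(d2) <- Inf
    if (min(d2) >= geom$min_separation_px^2) return(cbind(y = y, x = x))
  }
  capa_stop("overfull field: placement failed after 25 attempts for ", n, " cells")
}

#' Sample a ground-truth cell population
#'
#' Draws the latent per-cell state of one synthetic field: log-normal
#' HaloTag-GFP expression, HaloTag occupancy from the Hill blocking curve at
#' the given transporter concentration, a Bernoulli damage flag, an
#' expression class, and a jittered-grid centroid inside the field.
#'
#' In `"stable"` mode every cell is a normal expresser with the organelle
#' reporter on the mitochondrial network (a stable HaloTag-GFP line). In
#' `"transient"` mode the expression class is drawn from
#' `config$transient_mix`: non-expressers get ~zero expression,
#' over-expressers at least `over_expression_min_fold` times the median, and
#' the organelle is a peri-nuclear Golgi cluster.
#'
#' @param config a [capa_config()] object.
#' @param mode `"stable"` or `"transient"`.
#' @param concentration transporter concentration (uM), >= 0.
#' @param seed integer seed; identical config + seed gives an identical
#'   table.
#' @param n number of cells (default `config$n_cells_per_field`; must fit
#'   into the field at the configured separation).
#' @return A data.frame with one row per cell: `cell_id`, `y_px`, `x_px`,
#'   `expression`, `occupancy`, `damaged`, `expr_class`, `organelle_kind`.
#' @examples
#' cfg <- capa_config(n_cells_per_field = 12)
#' pop <- sample_population(cfg, "stable", concentration = 7.3, seed = 1)
#' mean(pop$occupancy)  # 0.5 at c = CP50 for undamaged cells
#' @export
sample_population <- function(config, mode = c("stable", "transient"),
                              concentration, seed, n = config$n_cells_per_field) {
  validate_config(config)
  mode <- match.arg(mode)
  if (concentration < 0) capa_stop("concentration must be >= 0")
  set.seed(seed)
  geom <- config$geometry

  cent <- place_centroids(n, config$field_size_px, geom)
  lp <- lnorm_params(config$expression_median, config$expression_cv)
  expression <- stats::rlnorm(n, lp$meanlog, lp$sdlog)

  if (mode == "stable") {
    expr_class <- rep("normal", n)
    organelle_kind <- rep("mitochondria", n)
  } else {
    expr_class <- sample(c("non", "normal", "over"), n, replace = TRUE,
                         prob = config$transient_mix)
    organelle_kind <- rep("golgi", n)
    is_non <- expr_class == "non"
    is_over <- expr_class == "over"
    expression[is_non] <- expression[is_non] * geom$non_expression_fold
    expression[is_over] <- config$expression_median *
      stats::runif(sum(is_over), geom$over_expression_min_fold,
                   geom$over_expression_max_fold)
  }

  damaged <- stats::runif(n) < config$p_damaged
  theta <- occupancy_response(concentration, config$cp50_true, config$hill_true)

  data.frame(
    cell_id = seq_len(n),
    y_px = cent[, "y"],
    x_px = cent[, "x"],
    expression = expression,
    occupancy = rep(theta, n),
    damaged = damaged,
    expr_class = expr_class,
    organelle_kind = organelle_kind,
    stringsAsFactors = FALSE
  )
}

# pixel index helpers ---------------------------------------------------

disk_offsets <- function(r) {
  ri <- ceiling(r)
  dy <- rep(-ri:ri, times = 2 * ri + 1)
  dx <- rep(-ri:ri, each = 2 * ri + 1)
  keep <- dy^2 + dx^2 <= r^2
  cbind(dy = dy[keep], dx = dx[keep])
}

# linear indices of a disk at (y, x), clipped to the field
disk_idx <- function(y, x, offs, dim) {
  yy <- round(y) + offs[, 1]
  xx <- round(x) + offs[, 2]
  keep <- yy >= 1 & yy <= dim[1] & xx >= 1 & xx <= dim[2]
  yy[keep] + (xx[keep] - 1L) * dim[1]
}

# mitochondrial network: self-avoidingish random-walk filaments confined to
# the cell body disk, dilated to ~3 px width
filament_pixels <- function(y0, x0, geom, dim) {
  rmax <- geom$cell_radius_px - 1
  pts_y <- integer(0); pts_x <- integer(0)
  for (f in seq_len(geom$filament_n)) {
    ang <- stats::runif(1, 0, 2 * pi)
    r0 <- stats::runif(1, geom$nucleus_radius_px * 0.4, geom$nucleus_radius_px + 3)
    y <- y0 + r0 * sin(ang); x <- x0 + r0 * cos(ang)
    dir <- stats::runif(1, 0, 2 * pi)
    for (s in seq_len(geom$filament_steps)) {
      dir <- dir + stats::rnorm(1, 0, 0.45)
      y2 <- y + sin(dir); x2 <- x + cos(dir)
      if ((y2 - y0)^2 + (x2 - x0)^2 > rmax^2) {  # reflect back inward
        dir <- atan2(y0 - y, x0 - x) + stats::rnorm(1, 0, 0.3)
        y2 <- y + sin(dir); x2 <- x + cos(dir)
      }
      y <- y2; x <- x2
      pts_y <- c(pts_y, round(y)); pts_x <- c(pts_x, round(x))
    }
  }
  keep <- pts_y >= 2 & pts_y <= dim[1] - 1 & pts_x >= 2 & pts_x <= dim[2] - 1
  pts_y <- pts_y[keep]; pts_x <- pts_x[keep]
  # dilate walk path by a plus-shaped element for ~3 px filament width
  yy <- c(pts_y, pts_y + 1L, pts_y - 1L, pts_y, pts_y)
  xx <- c(pts_x, pts_x, pts_x, pts_x + 1L, pts_x - 1L)
  unique(yy + (xx - 1L) * dim[1])
}

golgi_pixels <- function(y0, x0, geom, dim) {
  ang <- stats::runif(1, 0, 2 * pi)
  rad <- stats::runif(1, geom$nucleus_radius_px + 2, geom$nucleus_radius_px + 7)
  cy <- y0 + rad * sin(ang); cx <- x0 + rad * cos(ang)
  offs <- disk_offsets(geom$golgi_punctum_radius_px)
  rmax2 <- (geom$cell_radius_px - geom$golgi_punctum_radius_px - 1)^2
  idx <- integer(0)
  for (p in seq_len(geom$golgi_puncta_n)) {
    # resample puncta that would leave the cell body
    for (try in 1:8) {
      py <- cy + stats::rnorm(1, 0, geom$golgi_cluster_sd_px)
      px <- cx + stats::rnorm(1, 0, geom$golgi_cluster_sd_px)
      if ((py - y0)^2 + (px - x0)^2 <= rmax2) break
      py <- NA
    }
    if (is.na(py)) next
    idx <- c(idx, disk_idx(py, px, offs, dim))
  }
  unique(idx)
}

fragment_pixels <- function(y0, x0, geom, dim) {
  offs <- disk_offsets(geom$damaged_fragment_radius_px)
  rmax <- geom$cell_radius_px - geom$damaged_fragment_radius_px - 1
  n <- geom$damaged_fragment_n
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- rmax * sqrt(stats::runif(n))
  idx <- integer(0)
  for (p in seq_len(n))
    idx <- c(idx, disk_idx(y0 + rad[p] * sin(ang[p]),
                           x0 + rad[p] * cos(ang[p]), offs, dim))
  unique(idx)
}

# Poisson-Gaussian sCMOS approximation; scale 0 / sd 0 disable each term
apply_camera <- function(signal, camera) {
  out <- signal
  if (camera$poisson_scale > 0)
    out[] <- stats::rpois(length(signal), signal / camera$poisson_scale) *
      camera$poisson_scale
  out <- out + camera$offset
  if (camera$read_noise_sd > 0)
    out <- out + stats::rnorm(length(signal), 0, camera$read_noise_sd)
  matrix(pmin(pmax(round(out), 0), 65535), nrow(signal), ncol(signal))
}

#' Render one synthetic field
#'
#' Turns a ground-truth cell table into the three co-registered channel
#' images of one microscope field: nuclear stain (disks, condensed and
#' brighter for damaged cells), GFP (organelle texture: mitochondrial
#' filament walks or a peri-nuclear Golgi puncta cluster; whole-body fill
#' for over-expressers; fragmented specks for damaged cells) and the
#' reporter, deposited on the organelle texture in proportion to
#' `expression * (1 - occupancy)` plus concentration-independent off-target
#' puncta inside the cell body but outside the organelle. Off-target
#' staining is stochastic, as dye retention is in practice: the puncta
#' count is Poisson, each punctum's amplitude carries log-normal jitter,
#' and a log-normal per-field scale models field-to-field washing
#' variability. All channels pass the Poisson-Gaussian camera model and
#' clip to 16 bit.
#'
#' @param cells data.frame from [sample_population()].
#' @param config a [capa_config()] object.
#' @param seed integer seed for the rendering randomness.
#' @return A list of class `capa_field`: integer-valued matrices `nuclear`,
#'   `gfp`, `reporter`, plus ground-truth attributes `organelle_truth`
#'   (logical matrix of true organelle texture pixels) and `pixel_size_um`.
#' @export
render_field <- function(cells, config, seed) {
  validate_config(config)
  dim <- config$field_size_px
  geom <- config$geometry
  if (any(cells$y_px < 1 | cells$y_px > dim[1] | cells$x_px < 1 | cells$x_px > dim[2]))
    capa_stop("cell centroids must lie inside the field")
  set.seed(seed)

  nuc <- matrix(0, dim[1], dim[2])
  gfp <- matrix(0, dim[1], dim[2])
  rep_ <- matrix(0, dim[1], dim[2])
  org_truth <- matrix(FALSE, dim[1], dim[2])

  # off-target staining varies between fields (dye retention / washing):
  # one multiplicative log-normal scale per field
  field_scale <- if (geom$offtarget_field_cv > 0) {
    lpf <- lnorm_params(1, geom$offtarget_field_cv)
    stats::rlnorm(1, lpf$meanlog, lpf$sdlog)
  } else 1

  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    # nucleus: damaged cells condense (smaller, brighter)
    rn <- geom$nucleus_radius_px * stats::runif(1, 0.92, 1.08)
    bright <- geom$nuclear_gain * stats::runif(1, 0.9, 1.1)
    if (ci$damaged) {
      rn <- rn * geom$damaged_nucleus_scale
      bright <- bright * geom$damaged_nucleus_brightness
    }
    nidx <- disk_idx(ci$y_px, ci$x_px, disk_offsets(rn), dim)
    nuc[nidx] <- pmax(nuc[nidx], bright)

    # organelle texture
    if (ci$damaged) {
      oidx <- fragment_pixels(ci$y_px, ci$x_px, geom, dim)
    } else if (ci$expr_class == "over") {
      oidx <- disk_idx(ci$y_px, ci$x_px, disk_offsets(geom$cell_radius_px), dim)
    } else if (ci$organelle_kind == "golgi") {
      oidx <- golgi_pixels(ci$y_px, ci$x_px, geom, dim)
    } else {
      oidx <- filament_pixels(ci$y_px, ci$x_px, geom, dim)
    }
    if (length(oidx)) {
      gfp[oidx] <- pmax(gfp[oidx], config$gfp_gain * ci$expression)
      spec <- config$reporter_gain * ci$expression * (1 - ci$occupancy)
      rep_[oidx] <- pmax(rep_[oidx], spec)
      org_truth[oidx] <- TRUE
    }

    # off-target reporter: puncta in the body, outside the organelle texture,
    # amplitude relative to the cell's maximal (occupancy-0) specific signal
    # the off-target randomness is consumed even at amplitude 0 so renders
    # with the same seed differ only in the deposited puncta intensity
    if (config$offtarget_puncta_per_cell > 0 && ci$expr_class != "non") {
      amp0 <- config$offtarget_amplitude * config$reporter_gain *
        ci$expression * field_scale
      n_punc <- stats::rpois(1, config$offtarget_puncta_per_cell)
      poffs <- disk_offsets(geom$offtarget_punctum_radius_px)
      lpa <- lnorm_params(1, max(geom$offtarget_amp_cv, 1e-9))
      placed <- 0L; tries <- 0L
      rmax <- geom$cell_radius_px - geom$offtarget_punctum_radius_px - 1
      while (placed < n_punc && tries < 60L) {
        tries <- tries + 1L
        a <- stats::runif(1, 0, 2 * pi); r <- rmax * sqrt(stats::runif(1))
        pidx <- disk_idx(ci$y_px + r * sin(a), ci$x_px + r * cos(a), poffs, dim)
        pidx <- pidx[!org_truth[pidx]]
        if (length(pidx) < nrow(poffs) * 0.6) next  # overlaps organelle; retry
        jit <- stats::rlnorm(1, lpa$meanlog, lpa$sdlog)
        if (amp0 > 0) rep_[pidx] <- rep_[pidx] + amp0 * jit
        placed <- placed + 1L
      }
    }
  }

  out <- list(nuclear = apply_camera(nuc, config$camera),
              gfp = apply_camera(gfp, config$camera),
              reporter = apply_camera(rep_, config$camera))
  attr(out, "organelle_truth") <- org_truth
  attr(out, "pixel_size_um") <- config$pixel_size_um
  class(out) <- "capa_field"
  out
}

#' @export
print.capa_field <- function(x, ...) {
  cat("HC CAPA field:", nrow(x$nuclear), "x", ncol(x$nuclear),
      "px, channels nuclear/gfp/reporter (16-bit)\n")
  invisible(x)
}

#' Generate a synthetic plate on disk
#'
#' Builds every field of every well of a layout: the per-well transporter
#' concentration drives the HaloTag occupancy, per-field seeds are derived
#' deterministically from the master seed, images are written as multi-page
#' 16-bit TIFFs (page order nuclear, GFP, reporter; files
#' `<well>_f<field>.tif`) and the master ground-truth table as
#' `ground_truth.csv`.
#'
#' @param layout a [plate_layout()].
#' @param config a [capa_config()].
#' @param mode `"stable"` or `"transient"` (see [sample_population()]).
#' @param seed master seed; the same seed reproduces the plate bit for bit.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `dir`, `layout`, `ground_truth`
#'   (data.frame with columns cell_id, well, field, x_px, y_px, expression,
#'   occupancy, damaged, expr_class) and the image file paths.
#' @export
build_plate <- function(layout, config, mode = c("stable", "transient"),
                        seed = config$seed, out_dir) {
  mode <- match.arg(mode)
  validate_config(config)
  stopifnot(inherits(layout, "capa_layout"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- list()
  files <- character(0)
  for (w in seq_len(nrow(layout$wells))) {
    well <- layout$wells[w, ]
    for (f in seq_len(well$n_fields)) {
      cells <- sample_population(config, mode, well$concentration,
                                 seed = derive_seed(seed, well$well_id, f, "pop"))
      imgs <- render_field(cells, config,
                           seed = derive_seed(seed, well$well_id, f, "render"))
      path <- file.path(out_dir, sprintf("%s_f%d.tif", well$well_id, f))
      write_field_tiff(imgs, path)
      files <- c(files, path)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = cells$cell_id, well = well$well_id, field = f,
        x_px = cells$x_px, y_px = cells$y_px,
        expression = cells$expression, occupancy = cells$occupancy,
        damaged = cells$damaged, expr_class = cells$expr_class,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(layout$wells, file.path(out_dir, "layout.csv"), row.names = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(dir = out_dir, layout = layout, ground_truth = truth,
                 files = files))
}

#' Draw per-cell intensity pairs with a prescribed population r-squared
#'
#' Generates (GFP, reporter) pairs from the linear-Gaussian model
#' `R = slope * G + eps` with `var(eps) = slope^2 * var(G) * (1 - rho) / rho`,
#' whose population coefficient of determination of the reporter-on-GFP
#' regression is exactly `rho = r_squared`. Used to exercise the per-cell
#' correlation QC machinery at a known truth.
#'
#' @param n number of cells.
#' @param r_squared target population r-squared in (0, 1).
#' @param slope regression slope (response units per GFP unit).
#' @param gfp_median,gfp_cv log-normal parameters of the GFP marginal.
#' @param seed integer seed.
#' @return data.frame with columns `gfp`, `reporter`.
#' @export
sample_correlated_pairs <- function(n, r_squared, slope = 0.8,
                                    gfp_median = 5000, gfp_cv = 0.4,
                                    seed = NULL) {
  if (r_squared <= 0 || r_squared >= 1)
    capa_stop("r_squared must lie strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lp <- lnorm_params(gfp_median, gfp_cv)
  g <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
  var_g <- (exp(lp$sdlog^2) - 1) * exp(2 * lp$meanlog + lp$sdlog^2)
  sd_eps <- sqrt(slope^2 * var_g * (1 - r_squared) / r_squared)
  data.frame(gfp = g, reporter = slope * g + stats::rnorm(n, 0, sd_eps))
}
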