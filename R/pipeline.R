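#' Read and write field image stacks
#'
#' One field is a multi-page 16-bit TIFF with fixed page order
#' (nuclear, GFP, reporter), filename `<well>_f<field>.tif`.
#'
#' @param images a `capa_field` (list of matrices `nuclear`, `gfp`,
#'   `reporter` with integer values in 0..65535).
#' @param path TIFF file path.
#' @return `write_field_tiff()` returns `path` invisibly;
#'   `read_field_tiff()` returns a `capa_field`.
#' @export
write_field_tiff <- function(images, path) {
  pages <- lapply(images[c("nuclear", "gfp", "reporter")], function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  if (!file.exists(path)) capa_stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 3L)
    capa_stop(path, ": expected 3 pages (nuclear, GFP, reporter), found ",
              length(pages))
  bits <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bits) && bits != 16L)
    capa_stop(path, ": expected 16-bit pages, found ", bits, "-bit")
  if (max(vapply(pages, max, numeric(1))) <= 1 + 1e-9 &&
      !is.integer(pages[[1]]))
    pages <- lapply(pages, function(p) round(p * 65535))
  out <- list(nuclear = pages[[1]], gfp = pages[[2]], reporter = pages[[3]])
  class(out) <- "capa_field"
  out
}

#' Read a plate directory
#'
#' Loads the layout (`layout.csv`) and all field images of a plate
#' directory following the `<well>_f<field>.tif` convention, validating
#' that every well of the layout is present with the right page count and
#' bit depth.
#'
#' @param path plate directory (as written by [build_plate()]).
#' @return list of class `capa_plate`: `layout` (a `capa_layout`),
#'   `fields` (named list of `capa_field`s, names `<well>_f<field>`),
#'   `dir`.
#' @export
read_plate <- function(path) {
  layout_file <- file.path(path, "layout.csv")
  if (!file.exists(layout_file))
    capa_stop("no layout file at ", layout_file)
  wells <- utils::read.csv(layout_file, stringsAsFactors = FALSE)
  layout <- structure(list(wells = wells,
                           control_wells = wells$well_id[wells$concentration == 0]),
                      class = "capa_layout")
  fields <- list()
  for (w in seq_len(nrow(wells))) {
    for (f in seq_len(wells$n_fields[w])) {
      key <- sprintf("%s_f%d", wells$well_id[w], f)
      fp <- file.path(path, paste0(key, ".tif"))
      if (!file.exists(fp))
        capa_stop("layout references well ", wells$well_id[w],
                  " but image ", fp, " is missing")
      fields[[key]] <- read_field_tiff(fp)
    }
  }
  structure(list(layout = layout, fields = fields, dir = path),
            class = "capa_plate")
}

#' @export
print.capa_plate <- function(x, ...) {
  cat("HC CAPA plate:", length(x$fields), "fields,",
      nrow(x$layout$wells), "wells at", x$dir, "\n")
  invisible(x)
}

# segment + quantify every field of a plate; returns records + per-well
# border-discard counts
quantify_plate <- function(plate, config, mask_dir = NULL) {
  params <- config$segmentation
  records <- list()
  border <- integer(0)
  gfp_bg_sd <- numeric(0)
  for (key in names(plate$fields)) {
    wf <- strsplit(key, "_f")[[1]]
    well <- wf[1]; fidx <- as.integer(wf[2])
    conc <- plate$layout$wells$concentration[match(well, plate$layout$wells$well_id)]
    masks <- segment_field(plate$fields[[key]], params)
    if (!is.null(mask_dir)) write_mask_tiff(masks, file.path(mask_dir, paste0(key, "_masks.tif")))
    rec <- extract_features(plate$fields[[key]], masks, well, fidx, conc, params)
    records[[key]] <- rec
    border[key] <- masks$n_border_discarded
    gfp_bg_sd[key] <- masks$background$gfp$sd
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  list(records = records, border = border, gfp_bg_sd = stats::median(gfp_bg_sd))
}

#' @rdname write_field_tiff
#' @param masks a `capa_masks`; written as a 4-page 16-bit label TIFF
#'   (nuclei, cell bodies, organelle, dark region).
#' @export
write_mask_tiff <- function(masks, path) {
  pages <- list(masks$nuclei_labels, masks$cell_labels,
                masks$organelle_mask * 1L, masks$dark_mask * 1L)
  tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# per-well aggregated responses for one mask ("organelle" or "body")
well_responses <- function(records, layout, mask = c("organelle", "body"),
                           aggregate = "median") {
  mask <- match.arg(mask)
  col <- if (mask == "organelle") "rep_mean_organelle" else "rep_mean_body"
  sel <- records[records$selected %in% TRUE & is.finite(records[[col]]), ]
  aggfun <- if (aggregate == "median") stats::median else mean
  sp <- split(sel[[col]], sel$well)
  resp <- vapply(sp, aggfun, numeric(1))
  m <- match(names(resp), layout$wells$well_id)
  data.frame(well = names(resp),
             concentration = layout$wells$concentration[m],
             replicate = layout$wells$replicate[m],
             response = as.numeric(resp),
             n_cells = vapply(sp, length, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Fit both masks on a quantified plate
#'
#' Aggregates selected-cell reporter means per well (median by default),
#' fits the dose-response for the organelle and whole-cell-body masks
#' (bottom fixed per `config$fit$fix_bottom`), computes each mask's
#' per-cell GFP-reporter r^2, and the paired mask comparison. The r^2 is
#' computed on cells pooled from the untreated control wells: pooling
#' across transporter concentrations would mix dose levels into the
#' correlation and say nothing about mask accuracy.
#'
#' @param records CellRecord data.frame with QC flags filled.
#' @param layout a `capa_layout`.
#' @param config a [capa_config()].
#' @return list: `fits` (per mask `capa_fit`), `r_squared` (per mask
#'   `capa_regression`), `comparison` (`capa_mask_comparison` or NULL),
#'   `responses` (per mask data.frame).
#' @export
fit_plate <- function(records, layout, config = capa_config()) {
  out <- list(fits = list(), r_squared = list(), responses = list())
  for (mask in c("organelle", "body")) {
    resp <- well_responses(records, layout, mask, config$fit$aggregate)
    fit <- fit_dose_response(resp$concentration, resp$response, resp$replicate,
                             fix_bottom = config$fit$fix_bottom)
    out$responses[[mask]] <- resp
    out$fits[[mask]] <- fit
    sel <- records[records$selected %in% TRUE &
                     records$well %in% layout$control_wells, ]
    if (nrow(sel) < 3) sel <- records[records$selected %in% TRUE, ]
    gcol <- if (mask == "organelle") "gfp_mean_organelle" else "gfp_mean_body"
    rcol <- if (mask == "organelle") "rep_mean_organelle" else "rep_mean_body"
    out$r_squared[[mask]] <- tryCatch(regression_r2(sel[[gcol]], sel[[rcol]]),
                                      error = function(e) NULL)
  }
  out$comparison <- tryCatch(compare_masks(out$fits$body, out$fits$organelle),
                             error = function(e) NULL)
  out
}

#' Run the HC CAPA pipeline
#'
#' Orchestrates simulate -> segment -> quantify -> fit -> report on one
#' synthetic plate. Each stage reads the previous stage's outputs from
#' `out_dir`, so stages can be re-run individually; a rerun with the same
#' config and seed reproduces the results (bit-identical tables). Writes
#' per-cell records (`cells.csv`), QC counts (`qc_summary.json` and
#' `.csv`), dose-response results (`results.json`), the toxicity table
#' (`toxicity.csv`), the mask comparison (`comparison.json`), report plots
#' and a run manifest (`manifest.json`).
#'
#' @param config a [capa_config()].
#' @param out_dir output directory.
#' @param mode `"stable"` or `"transient"`.
#' @param stages character subset of
#'   `c("simulate", "segment", "quantify", "fit", "report")` (in order).
#' @param layout a [plate_layout()] (default layout if NULL).
#' @param seed master seed (default `config$seed`).
#' @return Invisibly, a list with the manifest and (when computed) the
#'   records, QC summary, fits, toxicity curve and comparison.
#' @export
run_pipeline <- function(config = capa_config(), out_dir,
                         mode = c("stable", "transient"),
                         stages = c("simulate", "segment", "quantify", "fit", "report"),
                         layout = NULL, seed = config$seed) {
  mode <- match.arg(mode)
  all_stages <- c("simulate", "segment", "quantify", "fit", "report")
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) capa_stop("no valid stages requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }
  if (is.null(layout)) layout <- plate_layout()
  outputs <- character(0)
  result <- list()

  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      stop(e)
    })
  }

  if ("simulate" %in% stages) stage_wrap("simulate", {
    logf("simulate: ", nrow(layout$wells), " wells (", mode, " mode, seed ", seed, ")")
    plate <- build_plate(layout, config, mode, seed, out_dir)
    outputs <- c(outputs, plate$files, file.path(out_dir, "ground_truth.csv"))
  })

  need_plate <- any(c("segment", "quantify") %in% stages)
  if (need_plate) {
    plate <- stage_wrap("segment", read_plate(out_dir))
    logf("segment+quantify: ", length(plate$fields), " fields")
    q <- stage_wrap("quantify", quantify_plate(plate, config, mask_dir = out_dir))
    gate_sd <- q$gfp_bg_sd
    records <- stage_wrap("quantify",
      apply_qc(q$records, plate$layout$control_wells, gate_sd, config$quantify))
    qc <- qc_summary(records, plate$layout)
    qc$border_discarded <- vapply(qc$well, function(w) {
      keys <- grep(paste0("^", w, "_f"), names(q$border))
      sum(q$border[keys])
    }, numeric(1))
    utils::write.csv(records, file.path(out_dir, "cells.csv"), row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc_summary.csv"), row.names = FALSE)
    jsonlite::write_json(qc, file.path(out_dir, "qc_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, file.path(out_dir, c("cells.csv", "qc_summary.csv", "qc_summary.json")))
    logf("quantify: ", nrow(records), " cells, ", sum(records$selected, na.rm = TRUE),
         " selected (", sum(records$qc_damaged, na.rm = TRUE), " damaged, ",
         sum(records$qc_gated_out, na.rm = TRUE), " gated, ",
         sum(qc$border_discarded), " border-discarded)")
    result$records <- records
    result$qc <- qc
    result$layout <- plate$layout
  }

  if ("fit" %in% stages) stage_wrap("fit", {
    if (is.null(result$records)) {
      cf <- file.path(out_dir, "cells.csv")
      if (!file.exists(cf)) capa_stop("fit stage needs cells.csv (run quantify first)")
      result$records <- utils::read.csv(cf, stringsAsFactors = FALSE)
      result$qc <- utils::read.csv(file.path(out_dir, "qc_summary.csv"),
                                   stringsAsFactors = FALSE)
      result$layout <- read_plate(out_dir)$layout
    }
    fits <- fit_plate(result$records, result$layout, config)
    tox <- toxicity_curve(result$qc, result$layout$control_wells)
    utils::write.csv(tox, file.path(out_dir, "toxicity.csv"), row.names = FALSE)
    res_json <- lapply(c(organelle = "organelle", body = "body"), function(m) {
      f <- fits$fits[[m]]; r <- fits$r_squared[[m]]
      list(cp50 = f$cp50, se_cp50 = f$se_cp50, hill = f$hill, top = f$top,
           bottom = f$bottom, converged = f$converged,
           r_squared = if (!is.null(r)) r$r_squared else NA,
           n_cells = if (!is.null(r)) r$n_cells else 0)
    })
    jsonlite::write_json(res_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (!is.null(fits$comparison))
      jsonlite::write_json(unclass(fits$comparison),
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    outputs <- c(outputs, file.path(out_dir, c("results.json", "toxicity.csv", "comparison.json")))
    for (m in c("organelle", "body"))
      if (fits$fits[[m]]$converged)
        logf("fit (", m, " mask): CP50 = ", signif(fits$fits[[m]]$cp50, 3),
             " +/- ", signif(fits$fits[[m]]$se_cp50, 2), " uM, r^2 = ",
             signif(fits$r_squared[[m]]$r_squared, 3))
    result$fits <- fits
    result$toxicity <- tox
  })

  if ("report" %in% stages) stage_wrap("report", {
    if (is.null(result$fits)) capa_stop("report stage needs fit results")
    paths <- write_report_plots(result, out_dir)
    outputs <- c(outputs, paths)
    logf("report: ", length(paths), " plots written")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("hccapa")),
    config_hash = config_hash(config),
    master_seed = seed,
    mode = mode,
    stages = stages,
    out_dir = normalizePath(out_dir),
    outputs = sort(unique(basename(outputs))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

# dose-response, toxicity and correlation plots for the report stage
write_report_plots <- function(result, out_dir) {
  paths <- character(0)
  dev_open <- function(path) {
    ok <- tryCatch({ grDevices::png(path, width = 900, height = 650, res = 120); TRUE },
                   error = function(e) FALSE)
    if (!ok) { path <- sub("\\.png$", ".pdf", path); grDevices::pdf(path, 7, 5) }
    path
  }
  fits <- result$fits

  # dose-response: per-well responses + fitted curves, both masks
  df <- do.call(rbind, lapply(names(fits$responses), function(m)
    cbind(fits$responses[[m]], mask = m)))
  curves <- do.call(rbind, lapply(names(fits$fits), function(m) {
    f <- fits$fits[[m]]
    if (!f$converged) return(NULL)
    cc <- c(0, exp(seq(log(0.05), log(max(df$concentration)), length.out = 80)))
    data.frame(concentration = cc,
               response = fourpl(cc, f$top, f$bottom, log(f$cp50), log(f$hill)),
               mask = m)
  }))
  p1 <- ggplot2::ggplot(df, ggplot2::aes(x = concentration, y = response,
                                         colour = mask)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::labs(x = "transporter concentration (uM)",
                  y = "reporter response (counts)",
                  title = "HC CAPA dose-response") +
    ggplot2::theme_bw()
  path <- dev_open(file.path(out_dir, "dose_response.png"))
  print(p1); grDevices::dev.off(); paths <- c(paths, path)

  # toxicity
  tox <- result$toxicity
  p2 <- ggplot2::ggplot(tox, ggplot2::aes(x = concentration, y = percent_selected)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = percent_selected - sem,
                                        ymax = percent_selected + sem), width = 0.1) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::ylim(0, NA) +
    ggplot2::labs(x = "transporter concentration (uM)",
                  y = "selected cells (% of control)",
                  title = "Toxicity (damage-free selection)") +
    ggplot2::theme_bw()
  path <- dev_open(file.path(out_dir, "toxicity.png"))
  print(p2); grDevices::dev.off(); paths <- c(paths, path)

  # per-cell correlation scatter
  sel <- result$records[result$records$selected %in% TRUE, ]
  if (nrow(sel) > 3) {
    p3 <- ggplot2::ggplot(sel, ggplot2::aes(x = gfp_mean_organelle,
                                            y = rep_mean_organelle)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "GFP mean (organelle mask)",
                    y = "reporter mean (organelle mask)",
                    title = "Per-cell GFP vs reporter (selected cells)") +
      ggplot2::theme_bw()
    path <- dev_open(file.path(out_dir, "correlation_organelle.png"))
    print(p3); grDevices::dev.off(); paths <- c(paths, path)
  }
  paths
}

# pseudo-log transform without depending on scales >= versions: fall back
# to identity if scales is unavailable
scales_pseudo_log <- function() {
  if (requireNamespace("scales", quietly = TRUE))
    scales::pseudo_log_trans(sigma = 0.3, base = 10)
  else "identity"
}
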