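#' Extract per-cell features from one field
#'
#' Measures, for every segmented cell, the background-subtracted mean GFP
#' and reporter intensities inside the whole cell body and inside the
#' organelle mask restricted to that body, the nuclear morphology
#' (area, mean intensity), the organelle fragmentation features
#' (component count, area), and the dark-region fraction. Cells whose
#' organelle mask is empty get missing organelle intensities and are
#' flagged (`qc_empty_organelle`); they stay in whole-body statistics.
#'
#' @param images a `capa_field` (channels `nuclear`, `gfp`, `reporter`).
#' @param masks a `capa_masks` from [segment_field()].
#' @param well,field identifiers copied into every record.
#' @param concentration transporter concentration (uM) of the well.
#' @param params segmentation parameter list (for the dark threshold).
#' @return data.frame with one row per cell: cell_id, well, field,
#'   concentration, gfp_mean_body, gfp_mean_organelle, rep_mean_body,
#'   rep_mean_organelle, gfp_uq_organelle (upper-quartile organelle GFP,
#'   used by the transfection gate), nuc_area, nuc_mean_intensity,
#'   organelle_n_components, organelle_area, dark_fraction,
#'   qc_empty_organelle, plus placeholder QC flags (`qc_damaged`,
#'   `qc_gated_out`, `selected`) filled by [apply_qc()].
#' @export
extract_features <- function(images, masks, well = "", field = 1L,
                             concentration = NA_real_,
                             params = capa_config()$segmentation) {
  cl <- masks$cell_labels
  ids <- sort(unique(cl[cl > 0L]))
  empty <- data.frame(cell_id = integer(0))
  if (!length(ids)) return(empty)

  bg <- masks$background
  nb <- max(cl)

  body_idx <- which(cl > 0L)
  blab <- cl[body_idx]
  body_area <- tabulate(blab, nbins = nb)
  gfp_body <- rowsum(as.numeric(images$gfp[body_idx]), blab)[, 1]
  rep_body <- rowsum(as.numeric(images$reporter[body_idx]), blab)[, 1]
  got <- as.integer(rownames(rowsum(as.numeric(images$gfp[body_idx]), blab)))

  org_idx <- which(masks$organelle_mask & cl > 0L)
  olab <- cl[org_idx]
  org_area <- tabulate(olab, nbins = nb)
  gfp_org <- rep(0, nb); rep_org <- rep(0, nb)
  if (length(org_idx)) {
    s <- rowsum(as.numeric(images$gfp[org_idx]), olab)
    gfp_org[as.integer(rownames(s))] <- s[, 1]
    s <- rowsum(as.numeric(images$reporter[org_idx]), olab)
    rep_org[as.integer(rownames(s))] <- s[, 1]
  }

  nl <- masks$nuclei_labels
  nuc_idx <- which(nl > 0L)
  nlab <- nl[nuc_idx]
  nuc_area <- tabulate(nlab, nbins = nb)
  nuc_sum <- rep(NA_real_, nb)
  if (length(nuc_idx)) {
    s <- rowsum(as.numeric(images$nuclear[nuc_idx]), nlab)
    nuc_sum[as.integer(rownames(s))] <- s[, 1]
  }

  # organelle fragmentation: connected components of the organelle mask,
  # attributed to the cell owning their pixels
  n_comp <- rep(0L, nb)
  if (length(org_idx)) {
    comp <- EBImage::bwlabel(masks$organelle_mask)
    comp <- matrix(as.integer(EBImage::imageData(comp)), nrow(cl), ncol(cl))
    cc <- comp[org_idx]
    owner <- tapply(olab, cc, function(v) v[1])
    tab <- table(factor(unname(owner), levels = seq_len(nb)))
    n_comp <- as.integer(tab)
  }

  # per-cell upper-quartile organelle GFP: robust both to the occasional
  # boundary pixel annexed from a bright neighbour (which dominates the
  # mean) and to dilution of the mask by isolated noise detections in
  # otherwise dark cells (which drags down the median)
  gfp_uq_org <- rep(NA_real_, nb)
  if (length(org_idx)) {
    mo <- tapply(as.numeric(images$gfp[org_idx]), olab,
                 stats::quantile, probs = 0.75, names = FALSE)
    gfp_uq_org[as.integer(names(mo))] <- mo
  }

  dark <- dark_region_fraction(images$gfp, cl, bg$gfp, params)
  dark_full <- rep(NA_real_, nb)
  dark_full[as.integer(names(dark))] <- dark

  df <- data.frame(
    cell_id = ids,
    well = well,
    field = as.integer(field),
    concentration = concentration,
    gfp_mean_body = gfp_body[match(ids, got)] / body_area[ids] - bg$gfp$level,
    gfp_mean_organelle = ifelse(org_area[ids] > 0,
                                gfp_org[ids] / pmax(org_area[ids], 1) - bg$gfp$level,
                                NA_real_),
    rep_mean_body = rep_body[match(ids, got)] / body_area[ids] - bg$reporter$level,
    rep_mean_organelle = ifelse(org_area[ids] > 0,
                                rep_org[ids] / pmax(org_area[ids], 1) - bg$reporter$level,
                                NA_real_),
    gfp_uq_organelle = gfp_uq_org[ids] - bg$gfp$level,
    nuc_area = nuc_area[ids],
    nuc_mean_intensity = nuc_sum[ids] / pmax(nuc_area[ids], 1) - bg$nuclear$level,
    organelle_n_components = n_comp[ids],
    organelle_area = org_area[ids],
    dark_fraction = dark_full[ids],
    qc_empty_organelle = org_area[ids] == 0,
    qc_damaged = NA,
    qc_gated_out = NA,
    selected = NA,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Calibrate damaged-cell thresholds on control wells
#'
#' The damage criteria are control-relative: thresholds are robust
#' (median +/- k * MAD) limits of the untreated control-well population,
#' which tolerates the damaged subpopulation itself (median and MAD stay
#' anchored on the healthy mode for contamination well below 50%).
#'
#' @param records CellRecord data.frame from control wells.
#' @param k robustness factor (default from config, `k_damage`).
#' @param frag_fold fold change over the control median that defines the
#'   fragmentation limit. The index's healthy spread is a *multiplicative*
#'   band whose MAD shrinks or swells with the contamination level, so a
#'   fixed fold over the robust median is the stable rule: true
#'   fragmentation elevates the index by about two orders of magnitude,
#'   the healthy tail by well under `frag_fold`.
#' @param frag_min_area minimum organelle area (px^2) for the fragmentation
#'   index to be meaningful; below it the component/area ratio of a dim,
#'   sparsely detected network mimics true fragmentation.
#' @return list with `A_min` (nuclear condensation: minimum nucleus area,
#'   px^2), `I_max` (maximum nuclear mean intensity), `F_max` (maximum
#'   organelle fragmentation index, components per px^2) and
#'   `frag_min_area`.
#' @export
calibrate_damage_thresholds <- function(records,
                                        k = capa_config()$quantify$k_damage,
                                        frag_fold = capa_config()$quantify$frag_fold,
                                        frag_min_area = capa_config()$quantify$frag_min_area) {
  ok <- !is.na(records$nuc_area) & records$nuc_area > 0
  if (sum(ok) < 10) capa_stop("too few control cells (", sum(ok), ") to calibrate")
  a <- records$nuc_area[ok]
  i <- records$nuc_mean_intensity[ok]
  fr <- records$organelle_n_components / pmax(records$organelle_area, 1)
  fr <- fr[ok & records$organelle_area >= frag_min_area &
             records$organelle_n_components > 0]
  list(A_min = stats::median(a) - k * stats::mad(a),
       I_max = stats::median(i) + k * stats::mad(i),
       F_max = frag_fold * stats::median(fr),
       frag_min_area = frag_min_area)
}

#' Flag damaged cells
#'
#' A cell is flagged as damaged (early apoptosis / abnormal organelle
#' network) if its nucleus is condensed (area below `A_min`), its nuclear
#' mean intensity exceeds `I_max`, or its organelle fragmentation index
#' (components / organelle area) exceeds `F_max`. Records with missing
#' nuclear features return NA and are excluded and counted separately by
#' [apply_qc()].
#'
#' @param records CellRecord data.frame.
#' @param thresholds list from [calibrate_damage_thresholds()].
#' @return Logical vector (NA where nuclear features are missing).
#' @export
flag_damaged <- function(records, thresholds) {
  fmin <- if (is.null(thresholds$frag_min_area)) 0 else thresholds$frag_min_area
  frag <- records$organelle_n_components / pmax(records$organelle_area, 1)
  frag[records$organelle_area < pmax(fmin, 1)] <- NA_real_
  cond <- records$nuc_area < thresholds$A_min
  bright <- records$nuc_mean_intensity > thresholds$I_max
  fragd <- !is.na(frag) & frag > thresholds$F_max
  out <- cond | bright | fragd
  out[is.na(records$nuc_area) | records$nuc_area == 0] <- NA
  out
}

#' Transfection gate
#'
#' Removes cells incompatible with localized quantification in transient
#' transfections: over-expressers whose GFP fills the whole body
#' (dark-region fraction below `d_min`) and non- or under-expressers whose
#' organelle GFP is below `g_min` (or whose organelle mask is empty).
#'
#' @param records CellRecord data.frame with `dark_fraction` computed.
#' @param thresholds list with `d_min` (minimum dark-region fraction) and
#'   `g_min` (minimum background-subtracted organelle GFP).
#' @return Logical vector: TRUE = gated out.
#' @export
transfection_gate <- function(records, thresholds) {
  over <- !is.na(records$dark_fraction) & records$dark_fraction < thresholds$d_min
  # upper-quartile organelle GFP (robust to annexed bright boundary pixels
  # and to noise dilution of the mask) where available, mean otherwise
  g <- if (!is.null(records$gfp_uq_organelle)) records$gfp_uq_organelle
       else records$gfp_mean_organelle
  under <- is.na(g) | g < thresholds$g_min
  over | under
}

#' Per-cell off-target index
#'
#' Fraction of a cell's integrated reporter signal that lies outside its
#' organelle mask: (body integral - organelle integral) / body integral of
#' the background-subtracted reporter, floored at 0. Missing where the body
#' integral is not positive.
#'
#' @param images a `capa_field`.
#' @param masks a `capa_masks`.
#' @return Named numeric vector, one index in \[0,1\] per cell id.
#' @export
offtarget_index <- function(images, masks) {
  cl <- masks$cell_labels
  ids <- sort(unique(cl[cl > 0L]))
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  bgl <- masks$background$reporter$level
  nb <- max(cl)
  body_idx <- which(cl > 0L)
  tot <- rep(NA_real_, nb)
  s <- rowsum(as.numeric(images$reporter[body_idx]) - bgl, cl[body_idx])
  tot[as.integer(rownames(s))] <- s[, 1]
  org <- rep(0, nb)
  org_idx <- which(masks$organelle_mask & cl > 0L)
  if (length(org_idx)) {
    s <- rowsum(as.numeric(images$reporter[org_idx]) - bgl, cl[org_idx])
    org[as.integer(rownames(s))] <- s[, 1]
  }
  out <- pmax((tot[ids] - org[ids]) / tot[ids], 0)
  out[!is.finite(out) | tot[ids] <= 0] <- NA_real_
  stats::setNames(out, ids)
}

#' Apply both QC filters and the selected-flag algebra
#'
#' Fills `qc_damaged`, `qc_gated_out` and
#' `selected = !qc_damaged & !qc_gated_out` on a CellRecord table. Damage
#' thresholds are calibrated on the control wells of the same table unless
#' supplied. The transfection gate's minimum-expression threshold `g_min`
#' is the larger of `g_min_sd` GFP background SDs (records carry
#' background-subtracted intensities) and `g_min_frac` times the population
#' median organelle GFP: an absolute background floor alone cannot separate
#' true faint expression from off-cell spillover of neighbouring bright
#' cells, so the floor is anchored to the expressing population.
#'
#' @param records CellRecord data.frame (pooled over wells/fields).
#' @param control_wells character vector of control well ids.
#' @param gfp_bg_sd background SD of the GFP channel (counts); used for the
#'   default `g_min`.
#' @param quantify_params list (see [capa_config()] `quantify` section).
#' @param damage_thresholds optional precomputed thresholds.
#' @return `records` with the QC flags filled; attribute `qc_thresholds`
#'   holds the thresholds used.
#' @export
apply_qc <- function(records, control_wells, gfp_bg_sd,
                     quantify_params = capa_config()$quantify,
                     damage_thresholds = NULL) {
  if (is.null(damage_thresholds)) {
    ctrl <- records[records$well %in% control_wells, ]
    if (!nrow(ctrl)) capa_stop("no control-well records to calibrate damage thresholds")
    damage_thresholds <- calibrate_damage_thresholds(ctrl, quantify_params$k_damage,
                                                     quantify_params$frag_fold,
                                                     quantify_params$frag_min_area)
  }
  g_floor <- quantify_params$g_min_sd * gfp_bg_sd
  gcal <- if (!is.null(records$gfp_uq_organelle)) records$gfp_uq_organelle
          else records$gfp_mean_organelle
  # anchor the minimum-expression floor on the localized expressers: cells
  # passing the dark-region test (over-expressers fail it, and their
  # saturated or near-empty organelle masks would corrupt any population
  # quantile); the upper quartile of that subset sits in the
  # normal-expresser mode even when non-expressers are as abundant
  dark_ok <- !is.na(records$dark_fraction) &
    records$dark_fraction >= quantify_params$d_min
  g_rel <- quantify_params$g_min_frac *
    stats::quantile(gcal[dark_ok], 0.75, na.rm = TRUE, names = FALSE)
  if (!is.finite(g_rel)) g_rel <- 0
  gate_thr <- list(d_min = quantify_params$d_min,
                   g_min = max(g_floor, g_rel, na.rm = TRUE))
  records$qc_damaged <- flag_damaged(records, damage_thresholds)
  records$qc_gated_out <- transfection_gate(records, gate_thr)
  records$selected <- !records$qc_damaged & !records$qc_gated_out
  attr(records, "qc_thresholds") <- c(damage_thresholds, gate_thr)
  records
}

#' Per-well QC summary
#'
#' Counts, per well, the cells at each QC stage: total records, cells with
#' missing nuclear features (excluded from damage assessment), damaged,
#' gated out, and selected. Border-discarded counts are added by the
#' pipeline, which sees the masks.
#'
#' @param records CellRecord data.frame with QC flags filled.
#' @param layout a [plate_layout()] (to attach concentration/replicate).
#' @return data.frame, one row per well.
#' @export
qc_summary <- function(records, layout) {
  agg <- function(f) sapply(split(records, records$well), f)
  wells <- sort(unique(records$well))
  sp <- split(records, records$well)
  out <- data.frame(
    well = wells,
    total = sapply(sp, nrow),
    missing_features = sapply(sp, function(d) sum(is.na(d$qc_damaged))),
    damaged = sapply(sp, function(d) sum(d$qc_damaged, na.rm = TRUE)),
    gated = sapply(sp, function(d) sum(d$qc_gated_out & !(d$qc_damaged %in% TRUE),
                                       na.rm = TRUE)),
    selected = sapply(sp, function(d) sum(d$selected, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  m <- match(out$well, layout$wells$well_id)
  out$concentration <- layout$wells$concentration[m]
  out$replicate <- layout$wells$replicate[m]
  rownames(out) <- NULL
  out
}
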