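#' Segment nuclei from the nuclear-stain channel
#'
#' Otsu global threshold on a Gaussian-smoothed image, hole filling, then a
#' distance-transform watershed to split touching nuclei. Components outside
#' the configured area range are removed and labels renumbered 1..K.
#'
#' @param nuclear_img single-channel 2-D matrix (16-bit counts).
#' @param params segmentation parameter list (see [capa_config()],
#'   section `segmentation`).
#' @return Integer label matrix; 0 is background. A blank image yields zero
#'   labels, not an error.
#' @export
segment_nuclei <- function(nuclear_img, params = capa_config()$segmentation) {
  stopifnot(is.matrix(nuclear_img))
  x <- nuclear_img / 65535
  b <- EBImage::gblur(x, params$nuc_blur_sigma)
  if (diff(range(b)) < 1e-5) return(matrix(0L, nrow(x), ncol(x)))
  th <- EBImage::otsu(EBImage::Image(b), range = range(b))
  mask <- b > th
  if (!any(mask)) return(matrix(0L, nrow(x), ncol(x)))
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::watershed(EBImage::distmap(mask),
                               tolerance = params$watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(x), ncol(x))
  prune_labels(labels, params$nuc_min_area, params$nuc_max_area)
}

# remove body pixels farther than max_radius from their own nucleus
# centroid: bounds each cell and stops growth into a neighbour's territory
clip_to_radius <- function(bodies, nuclei_labels, max_radius) {
  nb <- max(nuclei_labels)
  if (nb == 0L) return(bodies)
  idx <- which(nuclei_labels > 0L)
  lab <- nuclei_labels[idx]
  ry <- (idx - 1L) %% nrow(bodies) + 1L
  rx <- (idx - 1L) %/% nrow(bodies) + 1L
  cy <- rep(NA_real_, nb); cx <- rep(NA_real_, nb)
  sy <- rowsum(as.numeric(ry), lab); ar <- tabulate(lab, nbins = nb)
  cy[as.integer(rownames(sy))] <- sy[, 1]
  sx <- rowsum(as.numeric(rx), lab)
  cx[as.integer(rownames(sx))] <- sx[, 1]
  cy <- cy / ar; cx <- cx / ar
  bidx <- which(bodies > 0L)
  bl <- bodies[bidx]
  by <- (bidx - 1L) %% nrow(bodies) + 1L
  bx <- (bidx - 1L) %/% nrow(bodies) + 1L
  far <- (by - cy[bl])^2 + (bx - cx[bl])^2 > max_radius^2
  bodies[bidx[which(far)]] <- 0L
  bodies
}

# drop labelled components outside [min_area, max_area], relabel 1..K
prune_labels <- function(labels, min_area, max_area) {
  if (max(labels) == 0L) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_area & areas <= max_area)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Segment cell bodies by seeded growth from the nuclei
#'
#' Grows one body per nucleus over a smoothed combined GFP + nuclear
#' intensity landscape (EBImage Voronoi propagation), restricted to the
#' union of the global foreground (landscape above a robust
#' median + k*MAD threshold) and a maximum growth radius around each
#' nucleus. Bodies are pairwise disjoint and carry their nucleus id.
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param gfp_img,nuclear_img channel matrices (16-bit counts).
#' @param params segmentation parameter list.
#' @return Integer label matrix of cell bodies (ids match nucleus ids);
#'   empty (all zero) when there are no nuclei.
#' @export
segment_cell_bodies <- function(nuclei_labels, gfp_img, nuclear_img,
                                params = capa_config()$segmentation) {
  if (max(nuclei_labels) == 0L)
    return(matrix(0L, nrow(gfp_img), ncol(gfp_img)))
  land <- EBImage::gblur(gfp_img / 65535, params$body_blur_sigma) +
    EBImage::gblur(nuclear_img / 65535, params$body_blur_sigma)
  fg_thr <- stats::median(land) + params$body_fg_k * stats::mad(land)
  grow <- EBImage::makeBrush(2 * round(params$body_max_grow_px) + 1, "disc")
  mask <- (land > fg_thr) | (EBImage::dilate(nuclei_labels > 0, grow) > 0)
  bodies <- EBImage::propagate(EBImage::Image(land), EBImage::Image(nuclei_labels),
                               mask = mask, lambda = params$propagate_lambda)
  bodies <- matrix(as.integer(EBImage::imageData(bodies)), nrow(gfp_img), ncol(gfp_img))
  clip_to_radius(bodies, nuclei_labels, params$body_max_radius_px)
}

#' Per-cell organelle mask from the GFP channel
#'
#' White top-hat filtering suppresses the smooth cytoplasmic component;
#' within each cell body, pixels whose top-hat response exceeds the cell's
#' median + k*MAD are marked as organelle. The mask is clipped to the cell
#' body by construction. Cells with (near) zero GFP variance get an empty
#' mask and are flagged downstream, not here.
#'
#' @param gfp_img GFP channel matrix (16-bit counts).
#' @param cell_labels integer label matrix from [segment_cell_bodies()].
#' @param params segmentation parameter list.
#' @return Logical matrix, TRUE on organelle pixels.
#' @export
segment_organelles <- function(gfp_img, cell_labels,
                               params = capa_config()$segmentation) {
  out <- matrix(FALSE, nrow(gfp_img), ncol(gfp_img))
  if (max(cell_labels) == 0L) return(out)
  th <- EBImage::whiteTopHat(gfp_img / 65535,
                             EBImage::makeBrush(params$tophat_size, "disc"))
  th <- as.numeric(EBImage::imageData(th))
  idx <- which(cell_labels > 0L)
  lab <- cell_labels[idx]
  v <- th[idx]
  med <- tapply(v, lab, stats::median)
  madv <- tapply(v, lab, stats::mad)
  thr <- med[as.character(lab)] + params$organelle_k_mad * madv[as.character(lab)]
  # cap at the field-level robust threshold: in cells whose body is densely
  # covered by organelle texture the per-cell median/MAD sit on the texture
  # itself and the uncapped threshold would empty the mask
  thr_field <- stats::median(v) + params$organelle_k_mad * stats::mad(v)
  thr <- pmin(thr, thr_field)
  # absolute floor: a flat (zero-variance) cell must yield an empty mask
  out[idx[v > pmax(thr, 1e-4)]] <- TRUE
  out
}

#' Estimate the per-channel background outside the cells
#'
#' Background level is the median of pixels outside all cell bodies;
#' background SD is the scaled median absolute deviation (consistent for a
#' Gaussian) of the same pixels.
#'
#' @param img channel matrix.
#' @param cell_labels cell-body label matrix.
#' @return list with `level` and `sd`.
#' @export
estimate_background <- function(img, cell_labels) {
  px <- img[cell_labels == 0L]
  if (!length(px)) capa_stop("no background pixels: cells cover the field")
  list(level = stats::median(px), sd = stats::mad(px))
}

#' Per-cell dark-region fraction
#'
#' Fraction of each cell body at background GFP level: pixels with
#' GFP <= background level + m * background SD. Cells whose whole body
#' fluoresces (over-expressers) score ~0; non-expressers score ~1.
#'
#' @param gfp_img GFP channel matrix.
#' @param cell_labels cell-body label matrix.
#' @param background list with `level` and `sd` (from
#'   [estimate_background()]).
#' @param params segmentation parameter list (uses `dark_m`).
#' @return Named numeric vector, one fraction in \[0,1\] per cell id.
#' @export
dark_region_fraction <- function(gfp_img, cell_labels, background,
                                 params = capa_config()$segmentation) {
  if (max(cell_labels) == 0L) return(stats::setNames(numeric(0), character(0)))
  idx <- which(cell_labels > 0L)
  areas <- tabulate(cell_labels[idx], nbins = max(cell_labels))
  if (any(areas[unique(cell_labels[idx])] == 0))
    capa_stop("zero-area cell label encountered")
  thr <- background$level + params$dark_m * background$sd
  dark <- gfp_img[idx] <= thr
  frac <- tapply(dark, cell_labels[idx], mean)
  stats::setNames(as.numeric(frac), names(frac))
}

#' Build the full mask set for one field
#'
#' Runs nucleus, cell-body, organelle and dark-region segmentation and
#' enforces the mask invariants: one body per nucleus, organelle and dark
#' masks inside cell bodies, organelle and dark masks disjoint. Cells
#' touching the field border are removed from all masks (partial cells bias
#' intensity features); their count is recorded.
#'
#' @param images a `capa_field` (list with `nuclear`, `gfp`, `reporter`).
#' @param params segmentation parameter list.
#' @return A list of class `capa_masks`: `nuclei_labels`, `cell_labels`,
#'   `organelle_mask`, `dark_mask`, `background` (per channel),
#'   `n_border_discarded`.
#' @export
segment_field <- function(images, params = capa_config()$segmentation) {
  nuclei <- segment_nuclei(images$nuclear, params)
  bodies <- segment_cell_bodies(nuclei, images$gfp, images$nuclear, params)

  # discard border-touching cells from both label images
  n_border <- 0L
  if (max(bodies) > 0L) {
    border_ids <- unique(c(bodies[1, ], bodies[nrow(bodies), ],
                           bodies[, 1], bodies[, ncol(bodies)]))
    border_ids <- border_ids[border_ids > 0L]
    n_border <- length(border_ids)
    if (n_border) {
      bodies[bodies %in% border_ids] <- 0L
      nuclei[nuclei %in% border_ids] <- 0L
    }
  }
  # a nucleus whose body vanished (should not happen) is dropped too
  nuclei[bodies == 0L & nuclei > 0L] <- 0L

  organelle <- segment_organelles(images$gfp, bodies, params)
  bg <- list(nuclear = estimate_background(images$nuclear, bodies),
             gfp = estimate_background(images$gfp, bodies),
             reporter = estimate_background(images$reporter, bodies))
  thr_dark <- bg$gfp$level + params$dark_m * bg$gfp$sd
  dark <- (images$gfp <= thr_dark) & (bodies > 0L) & !organelle

  structure(list(nuclei_labels = nuclei, cell_labels = bodies,
                 organelle_mask = organelle, dark_mask = dark,
                 background = bg, n_border_discarded = n_border),
            class = "capa_masks")
}

#' @export
print.capa_masks <- function(x, ...) {
  cat("HC CAPA mask set:", max(x$cell_labels), "cells,",
      sum(x$organelle_mask), "organelle px,",
      x$n_border_discarded, "border cells discarded\n")
  invisible(x)
}
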