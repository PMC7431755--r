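#' Per-cell GFP-reporter regression
#'
#' Ordinary least squares of the reporter intensity on the GFP intensity
#' across cells. The coefficient of determination r^2 = 1 - SS_res/SS_tot
#' of this regression is the assay's mask-accuracy metric: GFP is
#' proportional to the HaloTag amount, so a mask that captures only
#' specific reporter signal correlates tightly with it.
#'
#' @param gfp,reporter numeric vectors of per-cell intensities (pairs with
#'   missing values are dropped).
#' @return A list of class `capa_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_cells`.
#' @examples
#' p <- sample_correlated_pairs(1000, r_squared = 0.9, seed = 1)
#' regression_r2(p$gfp, p$reporter)$r_squared
#' @export
regression_r2 <- function(gfp, reporter) {
  ok <- is.finite(gfp) & is.finite(reporter)
  gfp <- gfp[ok]; reporter <- reporter[ok]
  n <- length(gfp)
  if (n < 3) capa_stop("regression undefined for n < 3 (got ", n, ")")
  if (stats::var(gfp) == 0) capa_stop("regression undefined: zero predictor variance")
  fit <- stats::lm(reporter ~ gfp)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((reporter - mean(reporter))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_cells = n),
            class = "capa_regression")
}

#' @export
print.capa_regression <- function(x, ...) {
  cat(sprintf("per-cell regression: reporter = %.4g + %.4g * GFP, r^2 = %.4f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n_cells))
  invisible(x)
}

# 4PL mean function; c = 0 is the exact top asymptote ((c/cp50)^h -> 0)
fourpl <- function(c, top, bottom, lcp50, lhill) {
  f <- numeric(length(c))
  pos <- c > 0
  f[!pos] <- top
  f[pos] <- bottom + (top - bottom) /
    (1 + exp(exp(lhill) * (log(c[pos]) - lcp50)))
  f
}

fit_4pl_single <- function(conc, resp, fix_bottom = NULL) {
  sc <- max(abs(resp))
  if (sc == 0) sc <- 1
  y <- resp / sc
  start <- list(top = max(y), lcp50 = mean(log(range(conc[conc > 0]))), lhill = 0)
  form <- if (is.null(fix_bottom)) {
    start$bottom <- min(y)
    y ~ fourpl(conc, top, bottom, lcp50, lhill)
  } else {
    fb <- fix_bottom / sc
    y ~ fourpl(conc, top, fb, lcp50, lhill)
  }
  # two stages: Levenberg-Marquardt at default tolerances from the coarse
  # start, then a tight refinement from the solution (a tight tolerance
  # from a distant start can abort on a near-singular initial Jacobian)
  fit <- minpack.lm::nlsLM(form, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = as.list(stats::coef(fit)),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-14, ptol = 1e-14, maxiter = 200)),
    error = function(e) fit)
  cf <- stats::coef(fit)
  se_lcp50 <- tryCatch(sqrt(diag(stats::vcov(fit)))["lcp50"],
                       error = function(e) NA_real_)
  list(cp50 = exp(unname(cf["lcp50"])),
       hill = exp(unname(cf["lhill"])),
       top = unname(cf["top"]) * sc,
       bottom = if (is.null(fix_bottom)) unname(cf["bottom"]) * sc else fix_bottom,
       se_cp50_fit = exp(unname(cf["lcp50"])) * unname(se_lcp50),
       residual_sd = stats::sigma(fit) * sc)
}

#' Fit the four-parameter logistic dose-response
#'
#' Fits the descending 4PL
#' `S(c) = bottom + (top - bottom) / (1 + (c/cp50)^hill)` to per-well
#' aggregated reporter responses by nonlinear least squares, with `cp50`
#' and `hill` optimised in log space. Untreated wells (c = 0) enter as
#' exact top-asymptote observations, not as log-axis points. A pooled fit
#' over all wells gives the central estimate; when replicate ids are
#' supplied, per-replicate fits give `se_cp50` as the SEM of the replicate
#' CP50s (the single-fit covariance SE is kept as a diagnostic,
#' `se_cp50_fit`).
#'
#' A flat response (dynamic range below 3x the within-concentration noise)
#' is flagged as non-converged and no CP50 is reported.
#'
#' @param concentration numeric vector of well concentrations (uM),
#'   at least 5 distinct values including 0.
#' @param response per-well aggregated, background-subtracted reporter
#'   responses.
#' @param replicate optional replicate id per well; with >= 2 replicates
#'   `se_cp50` and `replicate_cp50` are computed.
#' @param fix_bottom fix the bottom asymptote at this value (e.g. 0 for the
#'   specific CAPA signal, which vanishes at full HaloTag blocking);
#'   `NULL` (default) leaves it free.
#' @return A list of class `capa_fit`: `cp50`, `hill`, `top`, `bottom`,
#'   `se_cp50`, `se_cp50_fit`, `n_replicates`, `converged`, `residual_sd`,
#'   `replicate_cp50`.
#' @export
fit_dose_response <- function(concentration, response, replicate = NULL,
                              fix_bottom = NULL) {
  ok <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[ok]; response <- response[ok]
  if (!is.null(replicate)) replicate <- replicate[ok]
  if (length(unique(concentration)) < 5 || !any(concentration == 0))
    capa_stop("need >= 5 distinct concentrations including 0")

  mu <- tapply(response, concentration, mean)
  within_sd <- stats::sd(response - mu[as.character(concentration)])
  rng <- diff(range(mu))
  if (is.na(within_sd)) within_sd <- 0
  failed <- list(cp50 = NA_real_, hill = NA_real_, top = max(response),
                 bottom = if (is.null(fix_bottom)) min(response) else fix_bottom,
                 se_cp50 = NA_real_, se_cp50_fit = NA_real_,
                 n_replicates = if (is.null(replicate)) 1L else length(unique(replicate)),
                 converged = FALSE, residual_sd = within_sd,
                 replicate_cp50 = NULL)
  class(failed) <- "capa_fit"
  if (rng <= 3 * within_sd || rng == 0) return(failed)

  pooled <- tryCatch(fit_4pl_single(concentration, response, fix_bottom),
                     error = function(e) NULL)
  if (is.null(pooled)) return(failed)

  rep_cp50 <- NULL
  se <- NA_real_
  n_rep <- 1L
  if (!is.null(replicate) && length(unique(replicate)) >= 2) {
    reps <- sort(unique(replicate))
    n_rep <- length(reps)
    rep_cp50 <- vapply(reps, function(r) {
      i <- replicate == r
      tryCatch(fit_4pl_single(concentration[i], response[i], fix_bottom)$cp50,
               error = function(e) NA_real_)
    }, numeric(1))
    names(rep_cp50) <- reps
    if (sum(is.finite(rep_cp50)) >= 2)
      se <- stats::sd(rep_cp50, na.rm = TRUE) / sqrt(sum(is.finite(rep_cp50)))
  }

  structure(list(cp50 = pooled$cp50, hill = pooled$hill, top = pooled$top,
                 bottom = pooled$bottom, se_cp50 = se,
                 se_cp50_fit = pooled$se_cp50_fit, n_replicates = n_rep,
                 converged = TRUE, residual_sd = pooled$residual_sd,
                 replicate_cp50 = rep_cp50),
            class = "capa_fit")
}

#' @export
print.capa_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dose-response fit: not converged (flat response)\n")
  } else {
    cat(sprintf("dose-response fit: CP50 = %.3g +/- %.2g uM (hill %.2f, top %.3g, bottom %.3g, %d replicates)\n",
                x$cp50, x$se_cp50, x$hill, x$top, x$bottom, x$n_replicates))
  }
  invisible(x)
}

#' Toxicity curve from per-well selected-cell counts
#'
#' Toxicity readout of the assay: the percentage of damage-free cells that
#' pass selection, relative to the untreated controls, as a function of the
#' transporter concentration. A non-toxic transporter gives a flat curve at
#' 100%.
#'
#' @param qc data.frame from [qc_summary()] (columns `well`,
#'   `concentration`, `replicate`, `selected`).
#' @param control_wells character vector of control well ids present in
#'   `qc` with nonzero selected counts.
#' @return A data.frame of class `capa_toxicity`: `concentration`,
#'   `percent_selected`, `sem`, `n_replicates`.
#' @export
toxicity_curve <- function(qc, control_wells) {
  ctrl <- qc[qc$well %in% control_wells, ]
  if (!nrow(ctrl)) capa_stop("no control wells present in the QC table")
  ref <- mean(ctrl$selected)
  if (ref == 0) capa_stop("control wells have zero selected cells")
  pct <- 100 * qc$selected / ref
  sp <- split(pct, qc$concentration)
  out <- data.frame(
    concentration = as.numeric(names(sp)),
    percent_selected = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                 numeric(1)),
    n_replicates = vapply(sp, length, numeric(1))
  )
  out <- out[order(out$concentration), ]
  rownames(out) <- NULL
  class(out) <- c("capa_toxicity", "data.frame")
  out
}

#' Paired one-tailed Student's t-test
#'
#' Upper-tailed paired t-test: `t = mean(d) / (sd(d)/sqrt(n))` with
#' `d = x - y` and `df = n - 1`; p is the upper-tail Student-t
#' probability. Degenerate cases follow a documented convention: identical
#' pairs (0/0) give t = 0, p = 0.5; zero-variance differences with nonzero
#' mean give p at the machine floor with `zero_variance = TRUE`.
#'
#' @param x,y paired numeric vectors (pairing by replicate), equal length,
#'   n >= 2.
#' @return list: `t`, `df`, `p`, `zero_variance`.
#' @examples
#' paired_one_tailed_t(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_one_tailed_t <- function(x, y) {
  if (length(x) != length(y)) capa_stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) capa_stop("paired t-test needs n >= 2")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1L, p = 0.5, zero_variance = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L,
                p = if (mean(d) > 0) .Machine$double.xmin else 1,
                zero_variance = TRUE))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L, p = stats::pt(t, n - 1, lower.tail = FALSE),
       zero_variance = FALSE)
}

#' Compare the whole-cell and organelle mask dose-response fits
#'
#' Reports the CP50 difference, percent difference and SE ratio between the
#' whole-cell-body and organelle masks, and the paired one-tailed t-test of
#' the per-replicate CP50s under the a-priori alternative that the
#' whole-cell estimate exceeds the organelle estimate (the whole-cell mask
#' admits off-target reporter signal). No multiple-testing correction: a
#' single planned comparison.
#'
#' @param fit_body,fit_organelle `capa_fit` objects fitted on the same
#'   replicates.
#' @return list of class `capa_mask_comparison`: `cp50_body`,
#'   `cp50_organelle`, `difference`, `percent_difference`, `se_ratio`,
#'   `t`, `df`, `p`.
#' @export
compare_masks <- function(fit_body, fit_organelle) {
  rb <- fit_body$replicate_cp50
  ro <- fit_organelle$replicate_cp50
  if (is.null(rb) || is.null(ro) || length(rb) != length(ro) ||
      !identical(names(rb), names(ro)))
    capa_stop("mask fits must carry per-replicate CP50s on matching replicates")
  tt <- paired_one_tailed_t(rb, ro)
  structure(list(
    cp50_body = fit_body$cp50,
    cp50_organelle = fit_organelle$cp50,
    difference = fit_body$cp50 - fit_organelle$cp50,
    percent_difference = 100 * (fit_body$cp50 - fit_organelle$cp50) /
      fit_organelle$cp50,
    se_ratio = fit_organelle$se_cp50 / fit_body$se_cp50,
    t = tt$t, df = tt$df, p = tt$p, zero_variance = tt$zero_variance
  ), class = "capa_mask_comparison")
}

#' @export
print.capa_mask_comparison <- function(x, ...) {
  cat(sprintf("mask comparison: CP50 whole-cell %.3g vs organelle %.3g uM (%+.1f%%), p = %.3g (paired one-tailed t, df %d)\n",
              x$cp50_body, x$cp50_organelle, x$percent_difference, x$p, x$df))
  invisible(x)
}
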