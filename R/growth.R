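# Growth-curve summarisation: smoothing-spline fits, AUC over a fixed
# window, and relative growth G against no-chemical controls.
#
# AUC is the fitness endpoint: it combines lag, growth rate and carrying
# capacity into one number and is robust to which phase a stressor hits.

#' Fit a smoothing spline to one well's growth curve
#'
#' A cubic smoothing spline with the smoothing parameter chosen by
#' generalized cross-validation (an interpolating spline on hourly
#' plate-reader data would chase noise).  Constants and straight lines
#' lie in the penalty's null space and are reproduced exactly.
#'
#' @param times hours, strictly increasing, at least 4 points.
#' @param od OD readings; negative values are clamped to 0 with a warning.
#' @param spar optional fixed smoothing parameter (overrides GCV).
#' @return an object of class `growth_curve`, evaluable with
#'   [predict()] on `[min(times), max(times)]`.
#' @export
fit_growth_curve <- function(times, od, spar = NULL) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od))
    .stop_class("stressmix_validation", "times and od differ in length")
  if (length(times) < 4L)
    .stop_class("stressmix_insufficient_data",
                "need at least 4 time points to fit a growth curve (got %d)",
                length(times))
  if (any(diff(times) <= 0))
    .stop_class("stressmix_validation", "times must be strictly increasing")
  if (any(od < 0)) {
    warning("negative OD reading(s) clamped to 0 before fitting")
    od <- pmax(od, 0)
  }
  fit <- if (is.null(spar)) {
    stats::smooth.spline(times, od, cv = FALSE, keep.data = FALSE)
  } else {
    stats::smooth.spline(times, od, spar = spar, keep.data = FALSE)
  }
  structure(list(fit = fit, support = range(times)),
            class = "growth_curve")
}

#' @export
predict.growth_curve <- function(object, newdata, clamp = TRUE, ...) {
  y <- stats::predict(object$fit, as.numeric(newdata))$y
  if (clamp) y <- pmax(y, 0) # fitted OD is physically non-negative
  y
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Smoothing-spline growth curve on [%g, %g] h (df = %.1f)\n",
              x$support[1], x$support[2], x$fit$df))
  invisible(x)
}

#' Integrate a fitted growth curve over a time window
#'
#' Integrates the fitted piecewise-cubic spline (clamped at 0 from
#' below) segment by segment with 5-point Gauss-Legendre rules, which
#' are exact for cubics; this integrates the fitted curve itself rather
#' than applying a quadrature to the raw readings.
#'
#' @param curve a [fit_growth_curve()] result.
#' @param t0,t1 window in hours; must lie within the fitted support.
#'   Defaults to 0-72 h.
#' @return the AUC in OD·hours (non-negative).
#' @export
integrate_auc <- function(curve, t0 = 0, t1 = 72) {
  stopifnot(inherits(curve, "growth_curve"))
  if (t1 <= t0)
    .stop_class("stressmix_validation", "empty integration window [%g, %g]", t0, t1)
  eps <- 1e-8 * max(1, abs(curve$support))
  if (t0 < curve$support[1] - eps || t1 > curve$support[2] + eps)
    .stop_class("stressmix_validation",
                "window [%g, %g] outside fitted support [%g, %g]",
                t0, t1, curve$support[1], curve$support[2])
  # segment at the spline knots so each piece is a single cubic
  knots <- curve$fit$fit$knot * curve$fit$fit$range + curve$fit$fit$min
  breaks <- sort(unique(c(t0, t1, knots[knots > t0 & knots < t1])))
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1L]
  half <- (hi - lo) / 2
  mid <- (hi + lo) / 2
  total <- 0
  for (i in seq_along(.gl5$x)) {
    y <- predict(curve, mid + half * .gl5$x[i])
    total <- total + sum(.gl5$w[i] * half * y)
  }
  max(total, 0)
}

#' Compute per-well AUCs for a whole plate
#'
#' Fits a spline to every well and integrates it over the window.
#'
#' @param plate a `plate_table` (see [read_plate_table()]).
#' @param window two hours, default `c(0, 72)`.
#' @param baseline if `TRUE`, subtract per well the minimum of its first
#'   three readings before fitting (off by default: raw absorbance).
#' @param spar optional fixed smoothing parameter passed to the spline.
#' @return data.frame `culture, mixture, replicate, well, auc` with the
#'   panel attached as an attribute.
#' @export
plate_auc <- function(plate, window = c(0, 72), baseline = FALSE, spar = NULL) {
  wells <- split(seq_len(nrow(plate)), plate$well)
  res <- lapply(wells, function(idx) {
    rows <- plate[idx, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    od <- rows$od
    if (baseline) od <- pmax(od - min(od[seq_len(min(3L, length(od)))]), 0)
    curve <- fit_growth_curve(rows$time_h, od, spar = spar)
    data.frame(culture = rows$culture[1], mixture = rows$mixture[1],
               replicate = rows$replicate[1], well = rows$well[1],
               auc = integrate_auc(curve, window[1], window[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[order(out$culture, out$mixture, out$replicate), , drop = FALSE]
  structure(out, panel = attr(plate, "panel"), window = window,
            class = c("auc_table", "data.frame"))
}

#' Relative growth of a treatment against the control pool
#'
#' `G = mean(treatment AUC) / mean(control AUC)` for one culture and one
#' mixture; replicate-level AUC lists are retained for bootstrapping.
#'
#' @param treatment_aucs numeric vector of treatment replicate AUCs
#'   (at least 1).
#' @param control_aucs numeric vector of control AUCs (at least 2).
#' @return an object of class `relative_growth` with elements `g_point`,
#'   `g_replicates` and `control_replicates`.
#' @export
relative_growth <- function(treatment_aucs, control_aucs) {
  if (length(treatment_aucs) < 1L || length(control_aucs) < 2L)
    .stop_class("stressmix_insufficient_data",
                "need >= 1 treatment and >= 2 control AUCs (got %d, %d)",
                length(treatment_aucs), length(control_aucs))
  m_ctrl <- mean(control_aucs)
  if (m_ctrl <= 0)
    .stop_class("stressmix_undefined_ratio",
                "mean control AUC is zero; relative growth undefined")
  structure(list(g_point = mean(treatment_aucs) / m_ctrl,
                 g_replicates = as.numeric(treatment_aucs),
                 control_replicates = as.numeric(control_aucs)),
            class = "relative_growth")
}

#' @export
print.relative_growth <- function(x, ...) {
  cat(sprintf("Relative growth G = %.4f (%d treatment, %d control replicates)\n",
              x$g_point, length(x$g_replicates), length(x$control_replicates)))
  invisible(x)
}
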