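# Oxygen-hemoglobin dissociation curves (Hill form) and the Bohr-shift
# model built from printed P50 anchor points.

#' Construct an O2-Hb dissociation curve
#'
#' A dissociation curve in Hill form is fully determined by its P50 (the PO2
#' at which hemoglobin is half saturated) and the cooperativity exponent
#' `hill_n`: saturation at partial pressure P is
#' \deqn{S(P) = P^n / (P^n + P_{50}^n).}
#'
#' @param p50 PO2 at 50% saturation, mmHg (> 0).
#' @param hill_n Hill cooperativity coefficient (> 0). Whole-blood avian
#'   curves are typically near 3.
#' @param label Free-text label, e.g. `"emperor pH 7.3"`.
#' @return An object of class `dissociation_curve`.
#' @export
#' @examples
#' cv <- dissociation_curve(31, 3, "emperor pH 7.4")
#' hb_saturation(31, cv)  # exactly 0.5 by definition of P50
dissociation_curve <- function(p50, hill_n = o2_params()$emperor_hill_n,
                               label = "") {
  stopifnot(is.numeric(p50), length(p50) == 1L, is.finite(p50),
            is.numeric(hill_n), length(hill_n) == 1L, is.finite(hill_n))
  if (p50 <= 0) stop("`p50` must be positive", call. = FALSE)
  if (hill_n <= 0) stop("`hill_n` must be positive", call. = FALSE)
  structure(list(p50 = p50, hill_n = hill_n, label = as.character(label)),
            class = "dissociation_curve")
}

#' @export
print.dissociation_curve <- function(x, ...) {
  cat(sprintf("<dissociation_curve> %s: P50 = %.4g mmHg, n = %.5g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$p50, x$hill_n))
  invisible(x)
}

#' Built-in giant fulmar dissociation curve
#'
#' The giant fulmar (a lower O2-affinity comparison species) curve is defined
#' by the printed Hill-plot regression
#' `log10[S/(100 - S)] = 2.74683 * log10(PO2) - 4.52219`, i.e. a Hill curve
#' with `hill_n = 2.74683` and `p50 = 10^(4.52219/2.74683)` (44.3 mmHg,
#' 44 to the nearest integer).
#'
#' @return A `dissociation_curve`.
#' @export
#' @examples
#' round(fulmar_curve()$p50)
fulmar_curve <- function() {
  p <- o2_params()
  dissociation_curve(p50 = 10^(p$fulmar_hill_intercept / p$fulmar_hill_slope),
                     hill_n = p$fulmar_hill_slope,
                     label = "giant fulmar")
}

#' Hb saturation at a given PO2
#'
#' @param po2 Partial pressure of O2, mmHg (vectorised, all >= 0).
#' @param curve A [dissociation_curve()].
#' @return Saturation as a fraction in `[0, 1]`; 0 at `po2 = 0`, strictly
#'   increasing in `po2`.
#' @export
hb_saturation <- function(po2, curve) {
  stopifnot(inherits(curve, "dissociation_curve"), is.numeric(po2))
  if (any(!is.finite(po2)) || any(po2 < 0)) {
    stop("`po2` must be finite and non-negative", call. = FALSE)
  }
  # 1/(1 + (p50/p)^n) avoids overflow of p^n at large p
  out <- ifelse(po2 == 0, 0, 1 / (1 + (curve$p50 / po2)^curve$hill_n))
  unname(out)
}

#' PO2 at a given Hb saturation (inverse Hill curve)
#'
#' @param sat Saturation fraction, strictly inside `(0, 1)` (vectorised).
#' @param curve A [dissociation_curve()].
#' @return PO2 in mmHg; exact inverse of [hb_saturation()].
#' @export
#' @examples
#' po2_at_saturation(0.5, fulmar_curve())  # 44.3 mmHg
po2_at_saturation <- function(sat, curve) {
  stopifnot(inherits(curve, "dissociation_curve"), is.numeric(sat))
  if (any(!is.finite(sat)) || any(sat <= 0) || any(sat >= 1)) {
    stop("`sat` must lie strictly within (0, 1)", call. = FALSE)
  }
  unname(curve$p50 * (sat / (1 - sat))^(1 / curve$hill_n))
}

#' Construct a Bohr-shift model from P50 anchor points
#'
#' The Bohr effect (loss of Hb-O2 affinity with acidosis) is represented by a
#' set of printed `(pH, P50)` anchors. Between anchors, `log10(P50)` is
#' interpolated linearly in pH; outside the anchor range extrapolation uses
#' the overall Bohr slope `d(log10 P50)/d(pH)` fitted by least squares to all
#' anchors.
#'
#' @param anchors_ph Anchor pH values (>= 2, strictly increasing after sort).
#' @param anchors_p50 Anchor P50 values, mmHg; must strictly decrease as pH
#'   increases.
#' @return An object of class `bohr_model` with elements `anchors` (a
#'   data.frame), `bohr_slope` (< 0) and `range` (allowed pH span, anchors
#'   +/- 0.2).
#' @export
#' @examples
#' bm <- emperor_bohr()
#' bm$bohr_slope  # about -0.42
bohr_model <- function(anchors_ph, anchors_p50) {
  stopifnot(is.numeric(anchors_ph), is.numeric(anchors_p50),
            length(anchors_ph) == length(anchors_p50),
            length(anchors_ph) >= 2L,
            all(is.finite(anchors_ph)), all(is.finite(anchors_p50)),
            all(anchors_p50 > 0))
  o <- order(anchors_ph)
  ph <- anchors_ph[o]
  p50 <- anchors_p50[o]
  if (any(diff(ph) <= 0)) stop("anchor pH values must be distinct", call. = FALSE)
  if (any(diff(p50) >= 0)) {
    stop("anchor P50 must strictly decrease as pH increases (Bohr direction)",
         call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(log10(p50) ~ ph))[2L])
  if (slope >= 0) stop("fitted Bohr slope must be negative", call. = FALSE)
  structure(list(anchors = data.frame(ph = ph, p50 = p50),
                 bohr_slope = slope,
                 range = c(min(ph) - 0.2, max(ph) + 0.2)),
            class = "bohr_model")
}

#' @export
print.bohr_model <- function(x, ...) {
  cat(sprintf("<bohr_model> %d anchors, pH %.4g-%.4g, Bohr slope %.4f\n",
              nrow(x$anchors), min(x$anchors$ph), max(x$anchors$ph),
              x$bohr_slope))
  invisible(x)
}

#' Built-in emperor penguin Bohr model
#'
#' Anchors the printed whole-blood P50 values of 28, 31, 35 and 37 mmHg at
#' pH 7.5, 7.4, 7.3 and 7.2. (An alternative printed value of 27 mmHg at
#' pH 7.5 exists in the literature summary; the figure-legend value 28 is
#' adopted.)
#'
#' @return A [bohr_model()].
#' @export
emperor_bohr <- function() {
  p <- o2_params()
  bohr_model(p$emperor_anchor_ph, p$emperor_anchor_p50)
}

#' P50 at a given pH under a Bohr model
#'
#' Exact at anchors; log-linear interpolation between anchors; slope-based
#' extrapolation within 0.2 pH units beyond the anchor range (flagged with a
#' message, since anything below the lowest anchor is outside the evidence).
#'
#' @param ph Blood pH (vectorised).
#' @param model A [bohr_model()].
#' @return P50 in mmHg.
#' @export
#' @examples
#' p50_at_ph(7.3, emperor_bohr())  # 35, an anchor
p50_at_ph <- function(ph, model = emperor_bohr()) {
  stopifnot(inherits(model, "bohr_model"), is.numeric(ph), all(is.finite(ph)))
  lo <- model$range[1L]
  hi <- model$range[2L]
  if (any(ph < lo - 1e-12) || any(ph > hi + 1e-12)) {
    stop(sprintf("pH outside supported range [%.2f, %.2f]", lo, hi),
         call. = FALSE)
  }
  a <- model$anchors
  if (any(ph < min(a$ph) | ph > max(a$ph))) {
    message("pH outside anchor range; extrapolating with fitted Bohr slope")
  }
  logp50 <- vapply(ph, function(x) {
    if (x <= min(a$ph)) {
      log10(a$p50[1L]) + model$bohr_slope * (x - a$ph[1L])
    } else if (x >= max(a$ph)) {
      n <- nrow(a)
      log10(a$p50[n]) + model$bohr_slope * (x - a$ph[n])
    } else {
      stats::approx(a$ph, log10(a$p50), xout = x)$y
    }
  }, numeric(1L))
  10^logp50
}

#' Dissociation curve for a given pH
#'
#' @param ph Blood pH.
#' @param model A [bohr_model()].
#' @param hill_n Hill coefficient shared by all pH-variant curves.
#' @return A [dissociation_curve()] with P50 set by [p50_at_ph()].
#' @export
curve_at_ph <- function(ph, model = emperor_bohr(),
                        hill_n = o2_params()$emperor_hill_n) {
  stopifnot(length(ph) == 1L)
  dissociation_curve(p50 = p50_at_ph(ph, model), hill_n = hill_n,
                     label = sprintf("pH %.2f", ph))
}

#' Saturation difference between two pH curves (Bohr-shift magnitude)
#'
#' The loss of saturation, in percentage points, at a given PO2 when blood pH
#' falls from `ph_hi` to `ph_lo` under a Bohr model. Non-negative for all
#' PO2; vanishes at PO2 = 0 and as PO2 grows large.
#'
#' @param po2 PO2 in mmHg (vectorised).
#' @param ph_hi,ph_lo Higher and lower pH (`ph_hi > ph_lo`).
#' @param model A [bohr_model()].
#' @param hill_n Shared Hill coefficient.
#' @return Percentage points (0-100 scale).
#' @export
saturation_difference <- function(po2, ph_hi, ph_lo, model = emperor_bohr(),
                                  hill_n = o2_params()$emperor_hill_n) {
  if (ph_hi <= ph_lo) stop("`ph_hi` must exceed `ph_lo`", call. = FALSE)
  hi <- curve_at_ph(ph_hi, model, hill_n)
  lo <- curve_at_ph(ph_lo, model, hill_n)
  100 * (hb_saturation(po2, hi) - hb_saturation(po2, lo))
}
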