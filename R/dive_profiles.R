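# Dive PO2/depth time series: phase segmentation, conversion to saturation
# profiles, depth-dependent respiratory PO2, and post-dive recovery times.

#' Construct a dive record
#'
#' One dive plus its tracked post-dive surface interval: an ordered series of
#' (time s, depth m, PO2 mmHg) samples from an arterial or venous electrode.
#'
#' @param df Data.frame with numeric columns `t` (s, strictly increasing),
#'   `depth` (m, >= 0) and `po2` (mmHg, >= 0).
#' @param dive_id Identifier for the dive.
#' @param site `"arterial"` or `"venous"`.
#' @return The data.frame with class `dive_record` and attributes `dive_id`
#'   and `site`.
#' @export
dive_record <- function(df, dive_id = "dive1", site = c("arterial", "venous")) {
  site <- match.arg(site)
  stopifnot(is.data.frame(df), all(c("t", "depth", "po2") %in% names(df)),
            nrow(df) >= 1L)
  if (any(diff(df$t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (any(df$depth < 0)) stop("`depth` must be non-negative", call. = FALSE)
  if (any(df$po2 < 0)) stop("`po2` must be non-negative", call. = FALSE)
  structure(df, dive_id = dive_id, site = site,
            class = c("dive_record", class(df)))
}

#' Segment a depth record into dive phases
#'
#' Samples deeper than `dive_threshold` are submerged; the dive is the
#' longest maximal submerged run. Within the dive, samples are labelled
#' `descent` where depth is locally increasing, `ascent` where locally
#' decreasing and `bottom` otherwise; samples outside the dive are `surface`.
#' Dive duration is the time spanned by the submerged run.
#'
#' @param record A [dive_record()].
#' @param dive_threshold Depth threshold in metres (default 1, excluding
#'   surface splashes).
#' @return A list: `phase` (character vector, one label per sample),
#'   `duration_min`, `dive_start`, `dive_end` and `surface_start` (equal to
#'   `dive_end`; seconds). A record that never submerges yields a
#'   zero-duration dive with a warning.
#' @export
segment_phases <- function(record, dive_threshold = 1) {
  stopifnot(inherits(record, "dive_record"))
  depth <- record$depth
  t <- record$t
  sub <- depth > dive_threshold
  phase <- rep("surface", length(depth))
  if (!any(sub)) {
    warning("record never exceeds the dive threshold: zero-duration dive",
            call. = FALSE)
    return(list(phase = phase, duration_min = 0,
                dive_start = NA_real_, dive_end = NA_real_,
                surface_start = t[1L]))
  }
  runs <- rle(sub)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  subruns <- which(runs$values)
  span <- t[ends[subruns]] - t[starts[subruns]]
  k <- subruns[which.max(span)]
  idx <- starts[k]:ends[k]
  d <- diff(depth[idx])
  # forward difference; last in-dive sample inherits the backward difference
  fwd <- ifelse(d > 0, "descent", ifelse(d < 0, "ascent", "bottom"))
  lab <- c(fwd, if (length(fwd)) fwd[length(fwd)] else "bottom")
  phase[idx] <- lab
  list(phase = phase,
       duration_min = (t[max(idx)] - t[min(idx)]) / 60,
       dive_start = t[min(idx)], dive_end = t[max(idx)],
       surface_start = t[max(idx)])
}

#' Convert a PO2 record to a saturation profile at a given pH
#'
#' Pointwise application of the dissociation curve for `ph` (or an explicit
#' `curve`, e.g. [fulmar_curve()]) to the record's PO2 series, with phase
#' labels from [segment_phases()].
#'
#' @param record A [dive_record()].
#' @param ph Blood pH at which to evaluate saturation (ignored when `curve`
#'   is supplied).
#' @param bohr A [bohr_model()].
#' @param hill_n Shared Hill coefficient.
#' @param curve Optional explicit [dissociation_curve()] overriding
#'   `ph`/`bohr`.
#' @param dive_threshold Passed to [segment_phases()].
#' @return A data.frame of class `saturation_profile` with columns `t`,
#'   `depth`, `po2`, `saturation`, `phase` and attributes `dive_id`, `site`,
#'   `ph`, `surface_start`, `duration_min`.
#' @export
profile_to_saturation <- function(record, ph = 7.5, bohr = emperor_bohr(),
                                  hill_n = o2_params()$emperor_hill_n,
                                  curve = NULL, dive_threshold = 1) {
  stopifnot(inherits(record, "dive_record"))
  if (is.null(curve)) curve <- curve_at_ph(ph, bohr, hill_n)
  seg <- segment_phases(record, dive_threshold)
  out <- data.frame(t = record$t, depth = record$depth, po2 = record$po2,
                    saturation = hb_saturation(record$po2, curve),
                    phase = seg$phase)
  structure(out, dive_id = attr(record, "dive_id"),
            site = attr(record, "site"),
            ph = ph, curve_label = curve$label,
            surface_start = seg$surface_start,
            duration_min = seg$duration_min,
            class = c("saturation_profile", "data.frame"))
}

#' Respiratory PO2 at depth
#'
#' Ambient pressure is modelled as 760 mmHg per atmosphere absolute with one
#' additional atmosphere per 10 m of seawater; water-vapour pressure
#' (47 mmHg) is subtracted before applying the respiratory O2 fraction:
#' `po2 = fo2 * (760 * (1 + depth/10) - 47)`. With a 4% respiratory O2
#' fraction this gives 28.5 mmHg (about 29) at the surface and 119.7 (about
#' 120) at 30 m.
#'
#' @param fo2 Respiratory O2 fraction in `[0, 1]`.
#' @param depth Depth in metres (>= 0, vectorised).
#' @return PO2 in mmHg (unrounded).
#' @export
respiratory_po2 <- function(fo2, depth) {
  p <- o2_params()
  if (any(fo2 < 0 | fo2 > 1)) stop("`fo2` must lie in [0, 1]", call. = FALSE)
  if (any(depth < 0)) stop("`depth` must be non-negative", call. = FALSE)
  fo2 * (p$mmhg_per_ata * (1 + depth / p$m_per_ata) - p$water_vapor_mmhg)
}

#' Post-dive saturation recovery time
#'
#' Time from surfacing until saturation first regains its baseline (0.90
#' arterial, 0.80 venous by default), in minutes. Crossings between samples
#' are located by linear interpolation; a profile already at or above
#' baseline at surfacing recovers in 0 min; a profile that never regains
#' baseline before the series ends returns `Inf` ("not reached"), which
#' orders after every finite recovery time.
#'
#' @param profile A [profile_to_saturation()] result.
#' @param baseline Saturation baseline in `(0, 1)`; defaults by site.
#' @param surface_start Surfacing time in seconds; defaults to the profile's
#'   `surface_start` attribute.
#' @return Minutes (possibly `Inf`).
#' @export
recovery_time <- function(profile, baseline = NULL, surface_start = NULL) {
  stopifnot(inherits(profile, "saturation_profile"))
  if (is.null(baseline)) {
    p <- o2_params()
    baseline <- if (identical(attr(profile, "site"), "venous"))
      p$venous_baseline_sat else p$arterial_baseline_sat
  }
  if (baseline <= 0 || baseline >= 1) {
    stop("`baseline` must lie strictly within (0, 1)", call. = FALSE)
  }
  if (is.null(surface_start)) surface_start <- attr(profile, "surface_start")
  t <- profile$t
  s <- profile$saturation
  if (surface_start < t[1L] || surface_start > t[length(t)]) {
    stop("`surface_start` lies outside the recorded series", call. = FALSE)
  }
  s0 <- stats::approx(t, s, xout = surface_start)$y
  if (s0 >= baseline) return(0)
  post <- which(t > surface_start)
  hit <- post[s[post] >= baseline]
  if (!length(hit)) return(Inf)
  j <- hit[1L]
  t_prev <- if (j > 1L && t[j - 1L] >= surface_start) t[j - 1L] else surface_start
  s_prev <- if (j > 1L && t[j - 1L] >= surface_start) s[j - 1L] else s0
  t_cross <- t_prev + (baseline - s_prev) / (s[j] - s_prev) * (t[j] - t_prev)
  (t_cross - surface_start) / 60
}
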