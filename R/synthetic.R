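# Seeded generators for blood-sample panels and dive PO2/depth records with
# the statistical structure the downstream analysis assumes.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic blood-sample panel
#'
#' Generated pH follows the linear mixed-model structure assumed by the
#' analysis:
#' `ph = intercept + slope_pco2*pco2 + slope_lactate*lactate +
#'  condition_effect + penguin_offset + noise`,
#' with Gaussian penguin offsets and residuals. Default slopes are the
#' study's reported effects (-0.034 pH per 10 mmHg PCO2, -0.09 pH per
#' 10 mmol/l lactate); the default intercept places resting samples
#' (PCO2 ~35 mmHg, lactate ~1) near the reported resting mean pH of 7.51.
#'
#' @param n_penguins,samples_per_penguin Panel dimensions.
#' @param pco2_range,lactate_range Uniform sampling ranges for the
#'   predictors.
#' @param slope_pco2,slope_lactate Generating slopes (pH per mmHg, pH per
#'   mmol/l).
#' @param intercept pH at zero predictors.
#' @param penguin_sd,residual_sd Gaussian s.d. of penguin offsets and
#'   residual noise (pH units).
#' @param condition_effects Named numeric offsets per sampling condition
#'   (zero by default so noise-free panels recover the slopes exactly).
#' @param seed Integer seed; one seed drives all draws.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_penguins = 12, samples_per_penguin = 3,
                       pco2_range = c(25, 100), lactate_range = c(0.3, 1.4),
                       slope_pco2 = -0.0034, slope_lactate = -0.009,
                       intercept = 7.655, penguin_sd = 0.02,
                       residual_sd = 0.02,
                       condition_effects = c(rest = 0, dive = 0,
                                             anesthesia = 0, restraint = 0),
                       seed = 1L) {
  stopifnot(n_penguins >= 1, samples_per_penguin >= 1,
            penguin_sd >= 0, residual_sd >= 0,
            diff(pco2_range) > 0, diff(lactate_range) > 0,
            all(.conditions %in% names(condition_effects)))
  structure(as.list(environment()), class = "panel_spec")
}

#' Generate a blood-sample panel from a [panel_spec()]
#'
#' @param spec A [panel_spec()].
#' @return A [blood_samples()] data.frame with the generating spec attached
#'   as attribute `"spec"`. Identical for identical seeds.
#' @export
gen_blood_panel <- function(spec = panel_spec()) {
  stopifnot(inherits(spec, "panel_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_penguins * spec$samples_per_penguin
    ids <- rep(sprintf("P%02d", seq_len(spec$n_penguins)),
               each = spec$samples_per_penguin)
    offsets <- stats::rnorm(spec$n_penguins, 0, spec$penguin_sd)
    pco2 <- stats::runif(n, spec$pco2_range[1L], spec$pco2_range[2L])
    lactate <- stats::runif(n, spec$lactate_range[1L], spec$lactate_range[2L])
    condition <- sample(.conditions, n, replace = TRUE)
    ph <- spec$intercept + spec$slope_pco2 * pco2 +
      spec$slope_lactate * lactate +
      unname(spec$condition_effects[condition]) +
      rep(offsets, each = spec$samples_per_penguin) +
      stats::rnorm(n, 0, spec$residual_sd)
    df <- data.frame(penguin_id = ids,
                     ph = pmin(pmax(ph, 6.51), 7.99),
                     pco2 = pco2,
                     po2 = stats::runif(n, 30, 95),
                     lactate = lactate,
                     body_mass = stats::runif(n, 22, 30),
                     site = sample(.sites, n, replace = TRUE),
                     condition = condition)
    structure(blood_samples(df), spec = spec)
  })
}

#' Generate a study-like blood panel honouring the printed extremes
#'
#' A 47-sample, 18-penguin panel shaped like the study's supplementary
#' sample table: 32 low-lactate samples (12 resting, 14 intradive, 6 under
#' anesthesia) and 15 high-lactate samples. Four printed extreme samples are
#' embedded verbatim (two anesthetized surface-group samples with pH
#' 7.23/7.25 at PCO2 72/85 mmHg; the two highest-lactate restraint samples
#' with pH 7.29/7.31 at lactate 15.4/17.0 mmol/l), four low-lactate samples
#' carry implausible PCO2 >= 93 mmHg with pH below 7.3, and a fifth
#' sub-7.30 sample is an anesthesia sample at PCO2 74 mmHg. Generated
#' retained samples are clamped to the printed group minima (pH >= 7.30
#' low-lactate, >= 7.29 surface group) so [select_ph_lower_bound()] returns
#' 7.3 for any seed.
#'
#' @param seed Integer seed.
#' @return A [blood_samples()] data.frame.
#' @export
gen_study_panel <- function(seed = 1L) {
  .with_seed(seed, {
    eff <- c(rest = 0, dive = -0.04, anesthesia = -0.06, restraint = -0.12)
    model_ph <- function(pco2, lactate, condition, offset) {
      7.655 - 0.0034 * pco2 - 0.009 * lactate + unname(eff[condition]) +
        offset + stats::rnorm(length(pco2), 0, 0.02)
    }
    low_ids <- rep(sprintf("L%02d", 1:12), length.out = 32)
    low_off <- stats::setNames(stats::rnorm(12, 0, 0.02), sprintf("L%02d", 1:12))
    low_cond <- c(rep("rest", 12), rep("dive", 13), rep("anesthesia", 7))
    low_pco2 <- c(seq(32, 42, length.out = 12),          # resting
                  seq(45, 88, length.out = 13),          # intradive
                  c(55, 62, 74, 93, 95, 97, 100))        # anesthesia
    low_lact <- stats::runif(32, 0.3, 1.4)
    low_ph <- model_ph(low_pco2, low_lact, low_cond, low_off[low_ids])
    # printed extremes: four implausible-PCO2 samples below pH 7.3, plus the
    # ambiguous fifth sub-7.30 sample (anesthesia, PCO2 74, excluded by the
    # anesthesia/PCO2 > 70 rule)
    low_ph[low_pco2 >= 93] <- c(7.26, 7.25, 7.24, 7.22)
    low_ph[low_pco2 == 74] <- 7.295
    retained <- low_pco2 < 93 & !(low_cond == "anesthesia" & low_pco2 > 70)
    low_ph[retained] <- pmax(low_ph[retained], 7.30)

    high_ids <- rep(sprintf("S%02d", 1:6), length.out = 11)
    high_off <- stats::setNames(stats::rnorm(6, 0, 0.02), sprintf("S%02d", 1:6))
    high_pco2 <- stats::runif(11, 40, 69)
    high_lact <- stats::runif(11, 2, 10)
    high_ph <- pmax(model_ph(high_pco2, high_lact, rep("restraint", 11),
                             high_off[high_ids]), 7.29)
    printed <- data.frame(
      penguin_id = c("S07", "S08", "S09", "S10"),
      ph = c(7.23, 7.25, 7.29, 7.31),
      pco2 = c(72, 85, 37, 38),
      lactate = c(2.5, 3.0, 15.4, 17.0),
      condition = c("anesthesia", "anesthesia", "restraint", "restraint"))

    n_all <- 32 + 11 + 4
    df <- data.frame(
      penguin_id = c(low_ids, high_ids, printed$penguin_id),
      ph = c(low_ph, high_ph, printed$ph),
      pco2 = c(low_pco2, high_pco2, printed$pco2),
      po2 = stats::runif(n_all, 30, 95),
      lactate = c(low_lact, high_lact, printed$lactate),
      body_mass = stats::runif(n_all, 22, 30),
      site = sample(.sites, n_all, replace = TRUE),
      condition = c(low_cond, rep("restraint", 11), printed$condition))
    blood_samples(df)
  })
}

#' Specification for a synthetic dive record
#'
#' Shapes are phenomenological templates of the published profiles, not a
#' gas-exchange simulation: a trapezoidal depth profile (descent, bottom,
#' ascent); arterial PO2 that rises with compression early in the dive and
#' falls to `po2_end_target` during ascent; venous PO2 that declines
#' monotonically; and post-surfacing PO2 relaxing exponentially toward
#' `po2_resting` with fractional deficit-clearance rate `recovery_rate`
#' (%/min). The depth template is deterministic; Gaussian noise (s.d.
#' `noise_sd` mmHg) is added to PO2.
#'
#' @param duration Dive duration, min.
#' @param max_depth Maximum depth, m.
#' @param surface_minutes Tracked post-dive interval, min.
#' @param po2_start,po2_end_target,po2_resting Start-of-dive, end-of-dive
#'   target and resting PO2, mmHg; defaults depend on `site`.
#' @param recovery_rate Percentage of the remaining PO2 deficit cleared per
#'   minute at the surface.
#' @param sampling_dt Sampling interval, s.
#' @param site `"arterial"` or `"venous"`.
#' @param noise_sd PO2 noise s.d., mmHg.
#' @param seed Integer seed.
#' @return A list of class `dive_spec`.
#' @export
dive_spec <- function(duration = 6, max_depth = 50, surface_minutes = 5,
                      site = c("arterial", "venous"),
                      po2_start = NULL, po2_end_target = NULL,
                      po2_resting = NULL, recovery_rate = 45,
                      sampling_dt = 5, noise_sd = 2, seed = 1L) {
  site <- match.arg(site)
  if (is.null(po2_start)) po2_start <- if (site == "arterial") 85 else 60
  if (is.null(po2_end_target)) po2_end_target <- if (site == "arterial") 35 else 20
  if (is.null(po2_resting)) po2_resting <- if (site == "arterial") 90 else 60
  stopifnot(duration > 0, max_depth > 0, surface_minutes > 0,
            sampling_dt > 0, recovery_rate > 0, noise_sd >= 0,
            po2_start > 0, po2_end_target >= 0, po2_resting > 0)
  structure(as.list(environment()), class = "dive_spec")
}

#' Generate a dive record from a [dive_spec()]
#'
#' @param spec A [dive_spec()].
#' @return A [dive_record()] with the generating spec attached as attribute
#'   `"spec"`. The depth template is identical across seeds for the same
#'   spec; only the PO2 noise realisation changes.
#' @export
gen_dive_record <- function(spec = dive_spec()) {
  stopifnot(inherits(spec, "dive_spec"))
  .with_seed(spec$seed, {
    T_d <- spec$duration * 60
    t <- seq(0, T_d + spec$surface_minutes * 60, by = spec$sampling_dt)
    if (t[length(t)] < T_d + spec$surface_minutes * 60) {
      t <- c(t, T_d + spec$surface_minutes * 60)
    }
    # trapezoidal depth: 25% descent, 50% bottom, 25% ascent (deterministic)
    depth <- stats::approx(
      x = c(0, 0.25 * T_d, 0.75 * T_d, T_d, t[length(t)]),
      y = c(0, spec$max_depth, spec$max_depth, 0, 0),
      xout = t)$y
    in_dive <- t <= T_d
    u <- t[in_dive] / T_d
    if (spec$site == "arterial") {
      peak <- spec$po2_start + 0.6 * spec$max_depth
      po2_dive <- stats::approx(
        x = c(0, 0.25, 0.75, 1),
        y = c(spec$po2_start, peak, 0.8 * peak, spec$po2_end_target),
        xout = u)$y
    } else {
      po2_dive <- spec$po2_end_target +
        (spec$po2_start - spec$po2_end_target) * (1 - u)^1.5
    }
    k <- spec$recovery_rate / 100                      # per min
    ts <- (t[!in_dive] - T_d) / 60
    po2_surf <- spec$po2_resting +
      (spec$po2_end_target - spec$po2_resting) * exp(-k * ts)
    po2 <- c(po2_dive, po2_surf)
    po2 <- pmax(po2 + stats::rnorm(length(po2), 0, spec$noise_sd), 0)
    rec <- dive_record(data.frame(t = t, depth = depth, po2 = po2),
                       dive_id = sprintf("sim-%s-%ds", spec$site, spec$seed),
                       site = spec$site)
    attr(rec, "spec") <- spec
    rec
  })
}
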