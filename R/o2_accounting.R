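# Blood O2 content, compartment stores, net depletion and contribution to
# diving metabolic rate (DMR), plus cohort summaries and paired tests.

#' Blood O2 transport constants
#'
#' Defaults are the printed study constants: Hb 18.3 g/dl, O2 capacity
#' 1.34 ml O2/g Hb, dissolved O2 solubility 0.003 ml O2/dl/mmHg, blood volume
#' 100 ml/kg split 0.33 arterial / 0.67 venous.
#'
#' @param hb_conc Hemoglobin concentration, g/dl.
#' @param o2_capacity O2 binding capacity, ml O2 per g Hb.
#' @param solubility Dissolved O2, ml O2/dl per mmHg.
#' @param blood_volume Blood volume, ml/kg.
#' @param arterial_fraction,venous_fraction Compartment fractions; must sum
#'   to 1.
#' @return An object of class `blood_constants`.
#' @export
blood_constants <- function(hb_conc = o2_params()$hb_conc_g_dl,
                            o2_capacity = o2_params()$o2_capacity_ml_g,
                            solubility = o2_params()$solubility_ml_dl_mmhg,
                            blood_volume = o2_params()$blood_volume_ml_kg,
                            arterial_fraction = o2_params()$arterial_fraction,
                            venous_fraction = o2_params()$venous_fraction) {
  vals <- c(hb_conc, o2_capacity, solubility, blood_volume,
            arterial_fraction, venous_fraction)
  stopifnot(all(is.finite(vals)), all(vals > 0))
  if (abs(arterial_fraction + venous_fraction - 1) > 1e-9) {
    stop("arterial and venous fractions must sum to 1", call. = FALSE)
  }
  structure(list(hb_conc = hb_conc, o2_capacity = o2_capacity,
                 solubility = solubility, blood_volume = blood_volume,
                 arterial_fraction = arterial_fraction,
                 venous_fraction = venous_fraction),
            class = "blood_constants")
}

#' Total blood O2 content
#'
#' `content = sat * o2_capacity * hb_conc + solubility * po2`, in ml O2/dl:
#' Hb-bound O2 plus dissolved O2. Linear in both arguments.
#'
#' @param sat Hb saturation fraction in `[0, 1]` (vectorised).
#' @param po2 PO2 in mmHg (>= 0, vectorised).
#' @param constants A [blood_constants()].
#' @return ml O2 per dl of blood.
#' @export
#' @examples
#' o2_content(1, 100)  # 1.34*18.3 + 0.3 = 24.82
o2_content <- function(sat, po2, constants = blood_constants()) {
  stopifnot(inherits(constants, "blood_constants"), is.numeric(sat),
            is.numeric(po2))
  if (any(sat < 0 | sat > 1)) stop("`sat` must lie in [0, 1]", call. = FALSE)
  if (any(po2 < 0)) stop("`po2` must be non-negative", call. = FALSE)
  sat * constants$o2_capacity * constants$hb_conc + constants$solubility * po2
}

#' Compartment O2 store from blood content
#'
#' Scales ml O2/dl content to a mass-specific store:
#' `content * (blood_volume / 100) * site_fraction` in ml O2/kg (blood volume
#' in ml/kg divided by 100 ml/dl).
#'
#' @param content Blood O2 content, ml O2/dl (>= 0).
#' @param site `"arterial"` or `"venous"`.
#' @param constants A [blood_constants()].
#' @return ml O2 per kg body mass.
#' @export
compartment_store <- function(content, site, constants = blood_constants()) {
  site <- match.arg(site, c("arterial", "venous"))
  if (any(content < 0)) stop("`content` must be non-negative", call. = FALSE)
  frac <- if (site == "arterial") constants$arterial_fraction else constants$venous_fraction
  content * (constants$blood_volume / 100) * frac
}

#' O2 store depletion for one dive
#'
#' Chains the dissociation curve, content formula and compartment scaling for
#' the start and end of a dive. The initial state is evaluated at resting pH
#' (7.5 by convention) and the final state at the caller's end-of-dive pH
#' (7.4 or 7.3 in the source analysis). Net depletion is initial minus final
#' (negative values, i.e. repletion, pass through untouched) and the DMR
#' contribution is net depletion divided by dive duration.
#'
#' @param initial,final Numeric vectors `c(po2 = , ph = )` describing the
#'   start- and end-of-dive blood state.
#' @param site `"arterial"` or `"venous"`.
#' @param duration Dive duration in minutes (> 0).
#' @param bohr A [bohr_model()].
#' @param constants A [blood_constants()].
#' @param hill_n Hill coefficient shared across pH-variant curves.
#' @return An object of class `store_result`: `initial`, `final`,
#'   `net_depletion`, `pct_net_depletion`, `dmr_contribution` (all per kg),
#'   `site`, `ph_final`, `duration`.
#' @export
store_result <- function(initial, final, site, duration,
                         bohr = emperor_bohr(),
                         constants = blood_constants(),
                         hill_n = o2_params()$emperor_hill_n) {
  site <- match.arg(site, c("arterial", "venous"))
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be a positive number of minutes", call. = FALSE)
  }
  state_store <- function(state) {
    stopifnot(all(c("po2", "ph") %in% names(state)))
    sat <- hb_saturation(state[["po2"]], curve_at_ph(state[["ph"]], bohr, hill_n))
    compartment_store(o2_content(sat, state[["po2"]], constants), site, constants)
  }
  s0 <- state_store(initial)
  s1 <- state_store(final)
  net <- s0 - s1
  structure(list(initial = s0, final = s1, net_depletion = net,
                 pct_net_depletion = if (s0 > 0) 100 * net / s0 else NA_real_,
                 dmr_contribution = net / duration,
                 site = site, ph_final = final[["ph"]], duration = duration),
            class = "store_result")
}

#' @export
print.store_result <- function(x, ...) {
  cat(sprintf(
    "<store_result> %s, %.3g min, final pH %.2f\n  initial %.2f -> final %.2f ml O2/kg; net %.2f (%.1f%%); DMR %.3f ml O2/kg/min\n",
    x$site, x$duration, x$ph_final, x$initial, x$final, x$net_depletion,
    x$pct_net_depletion, x$dmr_contribution))
  invisible(x)
}

#' Summarise store results across dives
#'
#' Median, maximum, minimum and quartiles (linear interpolation between order
#' statistics, `stats::quantile` type 7) of initial store, final store, net
#' depletion, percentage net depletion and DMR contribution, grouped by site
#' and final pH.
#'
#' @param results A list of [store_result()] objects (non-empty).
#' @return A data.frame with one row per (site, ph_final, statistic).
#' @export
summarize_stores <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L,
            all(vapply(results, inherits, logical(1L), "store_result")))
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(site = r$site, ph_final = r$ph_final, initial = r$initial,
               final = r$final, net_depletion = r$net_depletion,
               pct_net_depletion = r$pct_net_depletion,
               dmr_contribution = r$dmr_contribution)
  }))
  metrics <- c("initial", "final", "net_depletion", "pct_net_depletion",
               "dmr_contribution")
  stats_fun <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2L], max = max(v), min = min(v), q25 = q[1L], q75 = q[3L])
  }
  groups <- unique(df[, c("site", "ph_final")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- df[df$site == groups$site[i] & df$ph_final == groups$ph_final[i], ]
    stat_mat <- vapply(metrics, function(m) stats_fun(g[[m]]),
                       numeric(5L))
    data.frame(site = groups$site[i], ph_final = groups$ph_final[i],
               statistic = c("median", "max", "min", "q25", "q75"),
               stat_mat, row.names = NULL)
  }))
  out
}

#' Paired comparison of O2 transport quantities (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on paired differences, used to compare
#' quantities computed at two final pH values over the same dives. If every
#' difference is zero the statistic is undefined and is reported as such.
#'
#' @param values_a,values_b Paired numeric vectors of equal length (>= 5).
#' @return A list with `statistic` (V), `p.value` and `method`; both numeric
#'   entries `NA` with a note when all differences are zero.
#' @export
paired_comparison <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b))
  if (length(values_a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- values_a - values_b
  if (all(d == 0)) {
    warning("all paired differences are zero; test statistic undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p.value = NA_real_,
                method = "Wilcoxon signed-rank (undefined: all ties)"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = TRUE,
                       alternative = "two.sided", exact = NULL))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = wt$method)
}
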