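# Blood-chemistry panels: pH vs PCO2 / lactate mixed models and the
# exclusion-then-floor rule that selects the lower bound for blood pH.

.sample_cols <- c("penguin_id", "ph", "pco2", "po2", "lactate",
                  "body_mass", "site", "condition")
.sites <- c("arterial", "venous")
.conditions <- c("rest", "dive", "anesthesia", "restraint")

#' Validate a blood-sample panel
#'
#' A panel is a data.frame with one row per blood sample: `penguin_id`, `ph`,
#' `pco2` (mmHg), `po2` (mmHg), `lactate` (mmol/l), `body_mass` (kg), `site`
#' (arterial/venous) and `condition` (rest/dive/anesthesia/restraint).
#' Physiological invariants are checked: 6.5 < pH < 8.0, PCO2 > 0,
#' lactate >= 0.
#'
#' @param df A data.frame with at least the columns above.
#' @return The validated data.frame with class `blood_samples` prepended.
#' @export
blood_samples <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.sample_cols, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df)) {
    if (any(df$ph <= 6.5 | df$ph >= 8.0)) {
      stop("pH out of physiological range (6.5, 8.0)", call. = FALSE)
    }
    if (any(df$pco2 <= 0)) stop("PCO2 must be positive", call. = FALSE)
    if (any(df$lactate < 0)) stop("lactate must be non-negative", call. = FALSE)
    if (!all(df$site %in% .sites)) {
      stop("site must be 'arterial' or 'venous'", call. = FALSE)
    }
    if (!all(df$condition %in% .conditions)) {
      stop("condition must be one of: ", paste(.conditions, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!inherits(df, "blood_samples")) class(df) <- c("blood_samples", class(df))
  df
}

#' Split a blood panel into dive-relevant and surface-relevant groups
#'
#' Samples with lactate below the resting criterion (1.5 mmol/l) inform blood
#' pH during dives (lactate does not rise until after long dives); samples
#' above it inform the post-dive surface interval. For the pH-lactate
#' regression, the surface group is additionally restricted to
#' PCO2 < 70 mmHg so the lactate effect is not confounded with CO2 retention.
#' Samples at exactly the criterion are assigned to the dive group and noted.
#'
#' @param samples A [blood_samples()] panel.
#' @param lactate_split Criterion, mmol/l (default 1.5).
#' @param pco2_max PCO2 ceiling for the lactate-regression subset (default 70).
#' @return A list with elements `dive_group`, `surface_group` and
#'   `lactate_regression` (the filtered surface subset), each a
#'   `blood_samples` data.frame (possibly empty).
#' @export
partition_samples <- function(samples,
                              lactate_split = o2_params()$lactate_split_mmol_l,
                              pco2_max = o2_params()$lactate_model_pco2_max_mmhg) {
  samples <- blood_samples(as.data.frame(samples))
  at_split <- samples$lactate == lactate_split
  if (any(at_split)) {
    message(sum(at_split), " sample(s) at lactate exactly ", lactate_split,
            " mmol/l assigned to the dive group")
  }
  dive <- samples[samples$lactate <= lactate_split, , drop = FALSE]
  surf <- samples[samples$lactate > lactate_split, , drop = FALSE]
  lreg <- surf[surf$pco2 < pco2_max, , drop = FALSE]
  list(dive_group = blood_samples(dive),
       surface_group = blood_samples(surf),
       lactate_regression = blood_samples(lreg))
}

#' Fit a random-intercept model of pH on a single blood-gas predictor
#'
#' Fits `ph ~ predictor + (1 | penguin_id)` by REML (lme4). Goodness of fit
#' is summarised by the marginal r2 (fixed effects only) and conditional r2
#' (fixed + penguin random intercepts), computed from the variance
#' decomposition `var_fixed / (var_fixed + var_random + var_residual)` and
#' `(var_fixed + var_random) / (same denominator)`.
#'
#' With a single penguin the random intercept is inestimable; the fit falls
#' back to ordinary least squares with `var_random = 0` and a warning.
#'
#' @param samples A [blood_samples()] panel (>= 3 samples).
#' @param predictor `"pco2"` or `"lactate"`.
#' @return An object of class `ph_model_fit`: `slope`, `se_slope`,
#'   `intercept`, `penguin_intercepts`, `var_fixed`, `var_random`,
#'   `var_residual`, `r2_marginal`, `r2_conditional`, `n`, `n_penguins`,
#'   `predictor`, `aic` and the underlying `fit`.
#' @export
fit_random_intercept <- function(samples, predictor = c("pco2", "lactate")) {
  predictor <- match.arg(predictor)
  samples <- blood_samples(as.data.frame(samples))
  if (nrow(samples) < 3L) stop("need at least 3 samples", call. = FALSE)
  x <- samples[[predictor]]
  ids <- as.character(samples$penguin_id)
  n_penguins <- length(unique(ids))

  if (n_penguins < 2L) {
    warning("single penguin: falling back to ordinary least squares",
            call. = FALSE)
    fit <- stats::lm(samples$ph ~ x)
    cf <- summary(fit)$coefficients
    vf <- stats::var(stats::fitted(fit))
    ve <- summary(fit)$sigma^2
    pint <- stats::setNames(0, unique(ids))
    res <- list(slope = unname(cf[2L, 1L]), se_slope = unname(cf[2L, 2L]),
                intercept = unname(cf[1L, 1L]), penguin_intercepts = pint,
                var_fixed = vf, var_random = 0, var_residual = ve,
                n = nrow(samples), n_penguins = 1L, predictor = predictor,
                aic = stats::AIC(fit), fit = fit)
  } else {
    dat <- data.frame(ph = samples$ph, x = x, penguin_id = ids)
    fit <- lme4::lmer(ph ~ x + (1 | penguin_id), data = dat, REML = TRUE)
    cf <- stats::coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vr <- vc$vcov[vc$grp == "penguin_id"]
    ve <- vc$vcov[vc$grp == "Residual"]
    vf <- stats::var(stats::predict(fit, re.form = NA))
    re <- lme4::ranef(fit)$penguin_id
    res <- list(slope = unname(cf[2L, 1L]), se_slope = unname(cf[2L, 2L]),
                intercept = unname(cf[1L, 1L]),
                penguin_intercepts = stats::setNames(re[[1L]], rownames(re)),
                var_fixed = vf, var_random = vr, var_residual = ve,
                n = nrow(samples), n_penguins = n_penguins,
                predictor = predictor, aic = stats::AIC(fit), fit = fit)
  }
  denom <- res$var_fixed + res$var_random + res$var_residual
  res$r2_marginal <- res$var_fixed / denom
  res$r2_conditional <- (res$var_fixed + res$var_random) / denom
  structure(res, class = "ph_model_fit")
}

#' @export
print.ph_model_fit <- function(x, ...) {
  cat(sprintf(
    "<ph_model_fit> pH ~ %s + (1 | penguin)\n  slope %.5f (SE %.5f), n = %d samples / %d penguins\n  r2 marginal %.3f, conditional %.3f\n",
    x$predictor, x$slope, x$se_slope, x$n, x$n_penguins,
    x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Compare candidate fixed-effect sets for the pH model by AIC
#'
#' Fits each candidate set of fixed effects (with a penguin random intercept,
#' by maximum likelihood so AICs are comparable) and applies the selection
#' rule: among models within 2 AIC units of the best, keep the one with the
#' fewest fixed effects.
#'
#' @param samples A [blood_samples()] panel.
#' @param candidates A list of character vectors naming sample columns (e.g.
#'   `list("pco2", c("pco2", "condition"))`). Condition is treated as a
#'   categorical covariate with rest as the reference level.
#' @return A list with `table` (term count, AIC, delta-AIC per candidate) and
#'   `best` (index of the selected candidate).
#' @export
compare_ph_models <- function(samples, candidates) {
  samples <- blood_samples(as.data.frame(samples))
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  dat <- as.data.frame(samples)
  dat$penguin_id <- as.character(dat$penguin_id)
  dat$condition <- stats::relevel(factor(dat$condition, levels = .conditions),
                                  ref = "rest")
  dat$site <- factor(dat$site, levels = .sites)
  aic <- vapply(candidates, function(terms) {
    fml <- stats::reformulate(c(terms, "(1 | penguin_id)"), response = "ph")
    stats::AIC(lme4::lmer(fml, data = dat, REML = FALSE))
  }, numeric(1L))
  nterms <- lengths(candidates)
  delta <- aic - min(aic)
  eligible <- which(delta < 2)
  best <- eligible[order(nterms[eligible], aic[eligible])][1L]
  list(table = data.frame(
         model = vapply(candidates, paste, character(1L), collapse = " + "),
         n_terms = nterms, aic = aic, delta_aic = delta),
       best = best)
}

# round to nearest 0.1 pH unit (R round: half-to-even at exact halves)
.round_ph <- function(x) round(x, 1L)

#' Select the lower bound for blood pH from partitioned sample groups
#'
#' Implements the exclusion-then-round rule used to bound pH during dives and
#' surface intervals: drop samples with PCO2 >= 93 mmHg (an implausible value
#' in an awake or diving bird) and anesthesia samples with PCO2 > 70 mmHg;
#' take the minimum remaining pH in each group; round to one decimal; return
#' the smaller of the two group bounds.
#'
#' @param dive_group,surface_group `blood_samples` data.frames, e.g. from
#'   [partition_samples()]; both non-empty.
#' @param pco2_exclude PCO2 exclusion threshold, mmHg (default 93).
#' @param anesthesia_pco2_max PCO2 ceiling for anesthesia samples (default 70).
#' @return The pH lower bound (one decimal), with attribute `"details"`
#'   holding the per-group retained minima and bounds.
#' @export
select_ph_lower_bound <- function(dive_group, surface_group,
                                  pco2_exclude = o2_params()$pco2_exclusion_mmhg,
                                  anesthesia_pco2_max = o2_params()$anesthesia_pco2_max_mmhg) {
  retain <- function(g) {
    g <- blood_samples(as.data.frame(g))
    if (!nrow(g)) stop("group is empty", call. = FALSE)
    keep <- g$pco2 < pco2_exclude &
      !(g$condition == "anesthesia" & g$pco2 > anesthesia_pco2_max)
    g[keep, , drop = FALSE]
  }
  d <- retain(dive_group)
  s <- retain(surface_group)
  if (!nrow(d) || !nrow(s)) {
    stop("no samples remain after exclusions: no pH bound available",
         call. = FALSE)
  }
  mins <- c(dive = min(d$ph), surface = min(s$ph))
  bounds <- .round_ph(mins)
  structure(min(bounds),
            details = list(retained_min = mins, group_bounds = bounds))
}

#' Mean and s.d. of resting blood pH
#'
#' The resting-condition subset defines the upper bound for blood pH (7.5
#' after rounding to one decimal in the source study).
#'
#' @param samples A [blood_samples()] panel containing resting samples.
#' @return Named numeric vector `c(mean = , sd = )`; `sd` is 0 for a single
#'   sample.
#' @export
resting_ph_summary <- function(samples) {
  samples <- blood_samples(as.data.frame(samples))
  rest <- samples$ph[samples$condition == "rest"]
  if (!length(rest)) stop("no resting samples", call. = FALSE)
  c(mean = mean(rest), sd = if (length(rest) > 1L) stats::sd(rest) else 0)
}
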