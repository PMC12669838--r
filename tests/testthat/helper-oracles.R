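# Independent brute-force oracles used to cross-check package routines.

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign assignments (valid for untied, nonzero differences, n <= ~12).
wilcoxon_oracle <- function(a, b) {
  d <- a - b
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1L, function(s) sum(r[unlist(s)]))
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(statistic = v_obs, p.value = min(1, 2 * min(p_le, p_ge)))
}

# Sort-and-interpolate quantile (the type-7 rule) written from the
# definition: h = (n-1)p + 1 on the order statistics.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(s[n])
    s[lo] + (h - lo) * (s[lo + 1] - s[lo])
  }, numeric(1L))
}

# Hill-curve saturation written directly from the closed form, independent
# of the package's parameterisation.
hill_oracle <- function(po2, p50, n) po2^n / (po2^n + p50^n)

# A minimal valid blood-sample data.frame for constructing edge cases.
make_samples <- function(ph, pco2 = 45, lactate = 1.0, condition = "rest",
                         penguin_id = NULL, site = "venous", po2 = 60,
                         body_mass = 25) {
  n <- length(ph)
  if (is.null(penguin_id)) penguin_id <- sprintf("P%02d", seq_len(n))
  blood_samples(data.frame(
    penguin_id = rep_len(penguin_id, n), ph = rep_len(ph, n),
    pco2 = rep_len(pco2, n), po2 = rep_len(po2, n),
    lactate = rep_len(lactate, n), body_mass = rep_len(body_mass, n),
    site = rep_len(site, n), condition = rep_len(condition, n)))
}
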