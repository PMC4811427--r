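# shared fixtures: small rate models and a memoised default validation run

const_rate_model <- function(i = 0.01, m0 = 0.02, m1 = 0.02, ref = 2000) {
  rate_model(function(t, a) rep(i, length(t)),
             function(t, a) rep(m0, length(t)),
             function(t, a) rep(m1, length(t)),
             reference_time = ref)
}

# closed-form prevalence for constant incidence and m1 = m0, zero at a_min
closed_form_p <- function(i, ages, a_min = min(ages)) {
  1 - exp(-i * (ages - a_min))
}

# the default Danish-like validation is used by several files; run it once
.cache <- new.env(parent = emptyenv())

cached_validation <- function() {
  if (is.null(.cache$val)) .cache$val <- run_validation()
  .cache$val
}

# restrict a cross-section to a subset of its ages
subset_cross_section <- function(cs, keep) {
  sel <- cs$ages %in% keep
  cross_section(cs$time, cs$ages[sel], cs$prevalence[sel],
                sigma = cs$sigma[sel], n = cs$n[sel])
}

# a consistent survey pair: cs1 and cs2 generated by exact first-order
# propagation from a chosen prevalence/incidence at t*, so the least-squares
# objective is exactly zero at the generating incidence
consistent_pair <- function(ages = seq(40.5, 60.5, by = 1),
                            t1 = 2000, t2 = 2001,
                            p_star = 0.05 + 0.002 * (ages - min(ages)),
                            i_true = 0.008 + 1e-4 * (ages - min(ages)),
                            m = 0.015, R = 2) {
  h <- (t2 - t1) / 2
  mort <- mortality_input((t1 + t2) / 2, ages, m = m, R = R)
  f <- pde_rhs_par(p_star, i_true, mort$m, mort$R)
  cs1 <- cross_section(t1, ages - h, p_star - h * f)
  cs2 <- cross_section(t2, ages + h, p_star + h * f)
  list(cs1 = cs1, cs2 = cs2, mort = mort, ages = ages,
       p_star = p_star, i_true = i_true, h = h)
}
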