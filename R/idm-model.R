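#' Illness-death model state algebra
#'
#' The illness-death model (IDM) for an irreversible disease has three states,
#' Healthy -> Ill -> Dead, with transition rates \code{i} (incidence),
#' \code{m0} (mortality of the healthy) and \code{m1} (mortality of the ill),
#' all per person-year and depending on calendar time \code{t} and age
#' \code{a}. The age-specific prevalence \eqn{p(t,a)} (proportion ill) then
#' satisfies a first-order PDE along cohort lines (the characteristics
#' \eqn{t - a = const}):
#' \deqn{(\partial_t + \partial_a) p = (1-p)\,\{i - p\,(m_1 - m_0)\}}
#' Equivalently, writing the general mortality \eqn{m = p m_1 + (1-p) m_0} and
#' the mortality rate ratio \eqn{R = m_1/m_0}, the excess-mortality term can be
#' expressed through the population attributable risk (PAR):
#' \deqn{(\partial_t + \partial_a) p = (1-p)\,\{i - m\,\mathrm{PAR}(p, R)\}}
#' with \eqn{\mathrm{PAR}(p,R) = p(R-1)/(p(R-1)+1)}. The two right-hand sides
#' are algebraically identical because \eqn{p(R-1)+1 = m/m_0} and hence
#' \eqn{m\,\mathrm{PAR} = p(m_1-m_0)}.
#'
#' @name idm_model
#' @keywords internal
NULL

.check_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must be a finite probability in [0, 1]", what),
         call. = FALSE)
  }
  invisible(p)
}

.check_rate <- function(x, what) {
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite", what), call. = FALSE)
  }
  invisible(x)
}

#' PDE right-hand side, excess-mortality form
#'
#' Rate of change of the prevalence along a cohort characteristic,
#' \eqn{(1-p)\{i - p(m_1-m_0)\}}, given the incidence and the two
#' state-specific mortality rates. Vectorised over all arguments.
#'
#' @param p prevalence (proportion ill), in \eqn{[0, 1]}.
#' @param i incidence rate (per person-year).
#' @param m0 mortality rate of the healthy (per person-year).
#' @param m1 mortality rate of the ill (per person-year).
#' @return Rate of change of prevalence per year along the characteristic.
#' @seealso [pde_rhs_par()] for the equivalent form in terms of general
#'   mortality and the mortality rate ratio.
#' @examples
#' pde_rhs_excess(p = 0, i = 0.01, m0 = 0.02, m1 = 0.02)  # = i
#' @export
pde_rhs_excess <- function(p, i, m0, m1) {
  .check_prob(p)
  .check_rate(i, "i"); .check_rate(m0, "m0"); .check_rate(m1, "m1")
  (1 - p) * (i - p * (m1 - m0))
}

#' PDE right-hand side, mortality-ratio (PAR) form
#'
#' Rate of change of the prevalence along a cohort characteristic expressed
#' through the general mortality \code{m} and the mortality rate ratio
#' \code{R}: \eqn{(1-p)\{i - m\,\mathrm{PAR}(p,R)\}}. Identical to
#' [pde_rhs_excess()] whenever \eqn{m = p m_1 + (1-p) m_0} and
#' \eqn{R = m_1/m_0}.
#'
#' @inheritParams pde_rhs_excess
#' @param m general (all-cause, whole-population) mortality rate.
#' @param R mortality rate ratio \eqn{m_1/m_0} (dimensionless, > 0).
#' @return Rate of change of prevalence per year along the characteristic.
#' @export
pde_rhs_par <- function(p, i, m, R) {
  .check_prob(p)
  .check_rate(i, "i"); .check_rate(m, "m"); .check_rate(R, "R")
  (1 - p) * (i - m * par_fraction(p, R))
}

#' Population attributable risk
#'
#' The proportion of deaths attributable to the disease,
#' \eqn{p(R-1)/(p(R-1)+1)}, for prevalence \code{p} and mortality rate ratio
#' \code{R}. Lies in \eqn{[0, 1)} for \eqn{R \ge 1} and is negative (but
#' > -1) for \eqn{R < 1}.
#'
#' @inheritParams pde_rhs_par
#' @return Attributable proportion per element.
#' @export
par_fraction <- function(p, R) {
  .check_prob(p)
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("`R` must be finite and > 0", call. = FALSE)
  }
  denom <- p * (R - 1) + 1
  if (any(denom <= 0)) {
    bad <- which(denom <= 0)[1L]
    stop(sprintf(
      "population attributable risk undefined: p(R-1)+1 <= 0 at p=%g, R=%g",
      rep(p, length.out = length(denom))[bad],
      rep(R, length.out = length(denom))[bad]), call. = FALSE)
  }
  p * (R - 1) / denom
}

#' General mortality of the whole population
#'
#' The all-cause mortality of the mixed population,
#' \eqn{m = p\,m_1 + (1-p)\,m_0}: a convex combination of the state-specific
#' rates weighted by the prevalence.
#'
#' @inheritParams pde_rhs_excess
#' @return General mortality rate per person-year.
#' @export
general_mortality <- function(p, m0, m1) {
  .check_prob(p)
  .check_rate(m0, "m0"); .check_rate(m1, "m1")
  p * m1 + (1 - p) * m0
}

#' Rate model for the illness-death model
#'
#' Bundles the three transition-rate surfaces of the illness-death model as
#' functions of calendar time and age. The functions must be vectorised over
#' both arguments and return nonnegative finite rates per person-year on the
#' supported domain. A mortality rate ratio below 1 (ill persons dying at a
#' lower rate than healthy ones) is mathematically admissible but
#' epidemiologically unusual; it triggers a warning at validation points.
#'
#' @param incidence function \code{(time, age) -> rate}: incidence \eqn{i}.
#' @param mortality_healthy function \code{(time, age) -> rate}: \eqn{m_0}.
#' @param mortality_ill function \code{(time, age) -> rate}: \eqn{m_1}.
#' @param reference_time calendar year the rate curves are anchored at.
#' @param check_times,check_ages optional vectors of times and ages at which
#'   the rate functions are validated (nonnegative, finite, \eqn{m_1 \ge m_0}
#'   warning).
#' @return An object of class \code{"rate_model"}.
#' @export
rate_model <- function(incidence, mortality_healthy, mortality_ill,
                       reference_time,
                       check_times = NULL, check_ages = NULL) {
  stopifnot(is.function(incidence), is.function(mortality_healthy),
            is.function(mortality_ill),
            is.numeric(reference_time), length(reference_time) == 1L)
  obj <- structure(
    list(incidence = incidence,
         mortality_healthy = mortality_healthy,
         mortality_ill = mortality_ill,
         reference_time = reference_time),
    class = "rate_model")
  if (!is.null(check_times) && !is.null(check_ages)) {
    tt <- rep(check_times, each = length(check_ages))
    aa <- rep(check_ages, times = length(check_times))
    iv <- incidence(tt, aa)
    m0 <- mortality_healthy(tt, aa)
    m1 <- mortality_ill(tt, aa)
    if (any(!is.finite(iv)) || any(iv < 0) ||
        any(!is.finite(m0)) || any(m0 < 0) ||
        any(!is.finite(m1)) || any(m1 < 0)) {
      stop("rate model produces negative or non-finite rates on the checked domain",
           call. = FALSE)
    }
    if (any(m1 < m0)) {
      warning("mortality of the ill below mortality of the healthy (R < 1) ",
              "at some checked (time, age) points; epidemiologically unusual",
              call. = FALSE)
    }
  }
  obj
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Illness-death rate model (i, m0, m1), reference year",
      x$reference_time, "\n")
  invisible(x)
}

#' Mortality input at one estimation time
#'
#' Age-specific general mortality \code{m} and mortality rate ratio \code{R}
#' observed (or assumed known) at a single calendar time, as required by the
#' incidence estimators.
#'
#' @param time calendar year the mortality refers to.
#' @param ages strictly increasing ages (years).
#' @param m general mortality per age (per person-year, >= 0).
#' @param R mortality rate ratio per age (dimensionless, > 0).
#' @return An object of class \code{"mortality_input"}.
#' @export
mortality_input <- function(time, ages, m, R) {
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time))
  ages <- as.numeric(ages)
  if (length(ages) < 1L || is.unsorted(ages, strictly = TRUE)) {
    stop("`ages` must be strictly increasing", call. = FALSE)
  }
  m <- rep(as.numeric(m), length.out = length(ages))
  R <- rep(as.numeric(R), length.out = length(ages))
  if (any(!is.finite(m)) || any(m < 0)) stop("`m` must be >= 0", call. = FALSE)
  if (any(!is.finite(R)) || any(R <= 0)) stop("`R` must be > 0", call. = FALSE)
  structure(list(time = time, ages = ages, m = m, R = R),
            class = "mortality_input")
}

#' @export
print.mortality_input <- function(x, ...) {
  cat(sprintf("Mortality input at t=%g: %d ages in [%g, %g]\n",
              x$time, length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}
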