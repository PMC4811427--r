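#' Prevalence cross-section
#'
#' One survey's age-specific prevalence at a fixed calendar time, with
#' optional standard errors and sample sizes of the prevalence proportions.
#'
#' @param time calendar year of the survey.
#' @param ages strictly increasing ages (years).
#' @param prevalence prevalence proportion per age, in \eqn{[0, 1)}.
#' @param sigma optional standard error of each prevalence (>= 0).
#' @param n optional sample size per age (>= 1).
#' @return An object of class \code{"cross_section"}.
#' @export
cross_section <- function(time, ages, prevalence, sigma = NULL, n = NULL) {
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time))
  ages <- as.numeric(ages)
  prevalence <- as.numeric(prevalence)
  if (length(ages) < 1L || is.unsorted(ages, strictly = TRUE)) {
    stop("`ages` must be strictly increasing", call. = FALSE)
  }
  if (length(prevalence) != length(ages)) {
    stop("`prevalence` must have one value per age", call. = FALSE)
  }
  if (any(!is.finite(prevalence)) || any(prevalence < 0) || any(prevalence >= 1)) {
    bad <- which(!is.finite(prevalence) | prevalence < 0 | prevalence >= 1)[1L]
    stop(sprintf("prevalence must lie in [0, 1): offending cell (t=%g, a=%g, p=%g)",
                 time, ages[bad], prevalence[bad]), call. = FALSE)
  }
  if (!is.null(sigma)) {
    sigma <- rep(as.numeric(sigma), length.out = length(ages))
    if (any(sigma < 0, na.rm = TRUE)) stop("`sigma` must be >= 0", call. = FALSE)
  }
  if (!is.null(n)) {
    n <- rep(as.numeric(n), length.out = length(ages))
    if (any(n < 1, na.rm = TRUE)) stop("`n` must be >= 1", call. = FALSE)
  }
  structure(list(time = time, ages = ages, prevalence = prevalence,
                 sigma = sigma, n = n),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Cross-section at t=%g: %d ages in [%g, %g], p in [%.4g, %.4g]%s\n",
              x$time, length(x$ages), min(x$ages), max(x$ages),
              min(x$prevalence), max(x$prevalence),
              if (is.null(x$sigma)) "" else ", with standard errors"))
  invisible(x)
}

#' @export
as.data.frame.cross_section <- function(x, ...) {
  d <- data.frame(time = x$time, age = x$ages, prevalence = x$prevalence)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  if (!is.null(x$n)) d$n <- x$n
  d
}

.node_tol <- 1e-8

# index of `values` in cs$ages with exact node matching (no interpolation)
.age_index <- function(cs, values, what) {
  idx <- vapply(values, function(a) {
    j <- which(abs(cs$ages - a) < .node_tol)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1L))
  if (anyNA(idx)) {
    stop(sprintf("age node %g not present in the cross-section at t=%g (%s)",
                 values[which(is.na(idx))[1L]], cs$time, what), call. = FALSE)
  }
  idx
}

# shared geometry of a consecutive pair of cross-sections and an estimation
# time t* strictly between them
.pair_setup <- function(cs1, cs2, t_star) {
  stopifnot(inherits(cs1, "cross_section"), inherits(cs2, "cross_section"))
  if (cs1$time >= cs2$time) {
    tmp <- cs1; cs1 <- cs2; cs2 <- tmp
  }
  if (!(t_star > cs1$time && t_star < cs2$time)) {
    stop(sprintf("estimation time t*=%g must lie strictly between the surveys (%g, %g)",
                 t_star, cs1$time, cs2$time), call. = FALSE)
  }
  list(cs1 = cs1, cs2 = cs2, t_star = t_star,
       h1 = t_star - cs1$time, h2 = cs2$time - t_star)
}

# ages a for which both characteristic endpoints (t1, a-h1) and (t2, a+h2)
# exist on the surveys' age grids
.estimate_ages <- function(ps) {
  a1 <- ps$cs1$ages + ps$h1
  a2 <- ps$cs2$ages - ps$h2
  keep <- vapply(a1, function(a) any(abs(a2 - a) < .node_tol), logical(1L))
  a1[keep]
}

#' Prevalence at an estimation point between two surveys
#'
#' Approximates \eqn{p(t^\star, a)} by the convex combination of the two
#' survey prevalences along the cohort characteristic through
#' \eqn{(t^\star, a)}:
#' \deqn{p(t^\star, a) \approx \frac{h_2}{h_1+h_2} p(t_1, a-h_1)
#'   + \frac{h_1}{h_1+h_2} p(t_2, a+h_2)}
#' with \eqn{h_1 = t^\star - t_1}, \eqn{h_2 = t_2 - t^\star}. Both endpoint
#' ages must be exact nodes of the respective surveys (no age interpolation);
#' with yearly surveys and \eqn{t^\star} at the midpoint this is why
#' estimates live on the half-offset ages 30.5, 31.5, ...
#'
#' @param cs1,cs2 the two [cross_section()]s (any order).
#' @param t_star estimation time, strictly between the survey times.
#' @param age age(s) at which to interpolate (years).
#' @return Prevalence per requested age.
#' @export
midpoint_prevalence <- function(cs1, cs2, t_star, age) {
  ps <- .pair_setup(cs1, cs2, t_star)
  i1 <- .age_index(ps$cs1, age - ps$h1, "needed at a - h1")
  i2 <- .age_index(ps$cs2, age + ps$h2, "needed at a + h2")
  w <- ps$h1 + ps$h2
  (ps$h2 / w) * ps$cs1$prevalence[i1] + (ps$h1 / w) * ps$cs2$prevalence[i2]
}

#' Derivative of prevalence along the cohort characteristic
#'
#' Centered finite difference of the prevalence along the characteristic
#' through \eqn{(t^\star, a)}:
#' \eqn{[p(t_2, a+h_2) - p(t_1, a-h_1)] / (h_1 + h_2)}, a second-order
#' accurate estimate of \eqn{(\partial_t + \partial_a) p} at \eqn{t^\star}.
#'
#' @inheritParams midpoint_prevalence
#' @return Rate of change of prevalence per year, per requested age.
#' @export
characteristic_derivative <- function(cs1, cs2, t_star, age) {
  ps <- .pair_setup(cs1, cs2, t_star)
  i1 <- .age_index(ps$cs1, age - ps$h1, "needed at a - h1")
  i2 <- .age_index(ps$cs2, age + ps$h2, "needed at a + h2")
  (ps$cs2$prevalence[i2] - ps$cs1$prevalence[i1]) / (ps$h1 + ps$h2)
}

#' Incidence estimate container
#'
#' @param t_star estimation time (year).
#' @param ages estimate ages (typically half-offset years).
#' @param incidence nonnegative incidence rate per age (per person-year).
#' @param method \code{"direct"} or \code{"least_squares"}.
#' @param lower,upper optional bootstrap bounds per age.
#' @param clamped logical per age: raw estimate was negative and truncated at 0.
#' @return An object of class \code{"incidence_estimate"}.
#' @export
incidence_estimate <- function(t_star, ages, incidence, method,
                               lower = NULL, upper = NULL, clamped = NULL) {
  if (any(incidence < 0)) stop("incidence must be >= 0", call. = FALSE)
  if (is.null(clamped)) clamped <- rep(FALSE, length(ages))
  structure(list(t_star = t_star, ages = as.numeric(ages),
                 incidence = as.numeric(incidence), method = method,
                 lower = lower, upper = upper, clamped = clamped),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("Incidence estimate (%s) at t*=%g: %d ages, %d clamped to 0\n",
              x$method, x$t_star, length(x$ages), sum(x$clamped)))
  invisible(x)
}

#' @export
as.data.frame.incidence_estimate <- function(x, ...) {
  d <- data.frame(time = x$t_star, age = x$ages, incidence = x$incidence)
  d$lower <- if (is.null(x$lower)) NA_real_ else x$lower
  d$upper <- if (is.null(x$upper)) NA_real_ else x$upper
  d$clamped <- x$clamped
  d
}

# restrict a mortality input to the estimate ages (must all be covered)
.mort_at <- function(mort, ages) {
  stopifnot(inherits(mort, "mortality_input"))
  idx <- vapply(ages, function(a) {
    j <- which(abs(mort$ages - a) < .node_tol)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1L))
  if (anyNA(idx)) {
    stop(sprintf("mortality input at t=%g does not cover estimate age %g",
                 mort$time, ages[which(is.na(idx))[1L]]), call. = FALSE)
  }
  list(m = mort$m[idx], R = mort$R[idx])
}

.check_singularity <- function(p_star, t_star, ages, eps) {
  if (any(p_star >= 1 - eps)) {
    bad <- which(p_star >= 1 - eps)[1L]
    stop(sprintf("prevalence too close to 1 at (t*=%g, a=%g): estimator singular",
                 t_star, ages[bad]), call. = FALSE)
  }
}

#' Direct inversion estimator of the age-specific incidence
#'
#' Solves the illness-death PDE for the incidence at an estimation time
#' between two prevalence surveys:
#' \deqn{\hat i(t^\star, a) = \frac{(\partial_t+\partial_a)p}{1 - p}
#'   + m\,\mathrm{PAR}(p, R)}
#' with the characteristic derivative and the midpoint prevalence computed
#' from the two surveys and \eqn{(m, R)} supplied at \eqn{t^\star}. Raw
#' negative estimates are truncated at 0 and flagged.
#'
#' @inheritParams midpoint_prevalence
#' @param mort a [mortality_input()] at a time strictly between the surveys;
#'   its time is used as \eqn{t^\star} and its ages must cover the estimate
#'   ages.
#' @param eps singularity guard: error when the midpoint prevalence exceeds
#'   \eqn{1 - } \code{eps}.
#' @return An [incidence_estimate()] on the offset age grid.
#' @export
direct_incidence <- function(cs1, cs2, mort, eps = 1e-9) {
  ps <- .pair_setup(cs1, cs2, mort$time)
  ages <- .estimate_ages(ps)
  if (!length(ages)) stop("no common characteristic age nodes between the surveys",
                          call. = FALSE)
  mr <- .mort_at(mort, ages)
  p_star <- midpoint_prevalence(ps$cs1, ps$cs2, ps$t_star, ages)
  .check_singularity(p_star, ps$t_star, ages, eps)
  dpdc <- characteristic_derivative(ps$cs1, ps$cs2, ps$t_star, ages)
  raw <- dpdc / (1 - p_star) + mr$m * par_fraction(p_star, mr$R)
  incidence_estimate(ps$t_star, ages, pmax(raw, 0), method = "direct",
                     clamped = raw < 0)
}

#' First-order characteristic propagation of prevalence to the survey times
#'
#' Given the prevalence and an incidence guess at the estimation time,
#' propagates the prevalence forward to \eqn{t_2} and backward to \eqn{t_1}
#' along the cohort characteristics using one first-order (Euler) step of the
#' PDE in its mortality-ratio form. Propagated values outside \eqn{[0, 1]}
#' are clipped with a warning.
#'
#' @param p_star prevalence at the estimation time, one value per
#'   \code{mort$ages}.
#' @param i_guess nonnegative incidence guess, same layout.
#' @param mort a [mortality_input()] carrying the ages, \code{m} and \code{R}.
#' @param h1,h2 backward and forward time offsets (years).
#' @param variant age pairing of the backward step: \code{"characteristic"}
#'   (default) predicts \eqn{p(t_1, a-h_1)} from the node at age \eqn{a},
#'   following the cohort line; \code{"literal"} predicts \eqn{p(t_1, a+h_1)}
#'   instead.
#' @return List with \code{ages1}, \code{p1} (predicted at \eqn{t_1}),
#'   \code{ages2}, \code{p2} (predicted at \eqn{t_2}) and a logical
#'   \code{clipped} per node pair.
#' @export
predict_cross_sections <- function(p_star, i_guess, mort, h1, h2,
                                   variant = c("characteristic", "literal")) {
  variant <- match.arg(variant)
  stopifnot(inherits(mort, "mortality_input"),
            length(p_star) == length(mort$ages),
            length(i_guess) == length(mort$ages))
  if (any(i_guess < 0)) stop("`i_guess` must be >= 0", call. = FALSE)
  .check_prob(p_star, "p_star")
  f <- pde_rhs_par(p_star, i_guess, mort$m, mort$R)
  p2 <- p_star + h2 * f
  p1 <- p_star - h1 * f
  clipped <- p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1
  if (any(clipped)) {
    warning(sprintf("%d propagated prevalence value(s) clipped to [0, 1]",
                    sum(clipped)), call. = FALSE)
    p1 <- pmin(pmax(p1, 0), 1)
    p2 <- pmin(pmax(p2, 0), 1)
  }
  ages1 <- if (variant == "characteristic") mort$ages - h1 else mort$ages + h1
  list(ages1 = ages1, p1 = p1,
       ages2 = mort$ages + h2, p2 = p2,
       clipped = clipped)
}

# sigma with the equal-weight default of 1 when a survey carries no
# standard errors
.sigma_at <- function(cs, idx) {
  if (is.null(cs$sigma)) rep(1, length(idx)) else cs$sigma[idx]
}

#' Standardized squared error of an incidence guess
#'
#' The weighted least-squares objective
#' \eqn{X^2(i^{(g)}) = \sum_{j,k} [p(t_j,a_k) - p(t_j,a_k\,|\,i^{(g)})]^2
#'   / \sigma_{jk}^2}
#' comparing the observed survey prevalences with their first-order
#' characteristic predictions under the incidence guess. Only survey cells
#' reachable by the propagation contribute; unset standard errors default
#' to 1 (equal weights).
#'
#' @param i_guess nonnegative incidence guess on the estimate ages (the ages
#'   shared by the characteristic geometry; see [direct_incidence()]).
#' @inheritParams direct_incidence
#' @inheritParams predict_cross_sections
#' @return The scalar objective value.
#' @export
chi_square <- function(i_guess, cs1, cs2, mort,
                       variant = c("characteristic", "literal")) {
  variant <- match.arg(variant)
  ps <- .pair_setup(cs1, cs2, mort$time)
  ages <- .estimate_ages(ps)
  mr <- .mort_at(mort, ages)
  m_in <- mortality_input(mort$time, ages, mr$m, mr$R)
  p_star <- midpoint_prevalence(ps$cs1, ps$cs2, ps$t_star, ages)
  stopifnot(length(i_guess) == length(ages))
  pred <- predict_cross_sections(p_star, i_guess, m_in, ps$h1, ps$h2, variant)
  ok1 <- vapply(pred$ages1, function(a) any(abs(ps$cs1$ages - a) < .node_tol),
                logical(1L))
  i1 <- .age_index(ps$cs1, pred$ages1[ok1], "prediction target at t1")
  i2 <- .age_index(ps$cs2, pred$ages2, "prediction target at t2")
  s1 <- .sigma_at(ps$cs1, i1); s2 <- .sigma_at(ps$cs2, i2)
  r1 <- ps$cs1$prevalence[i1] - pred$p1[ok1]
  r2 <- ps$cs2$prevalence[i2] - pred$p2
  if (any(s1 == 0 & r1 != 0) || any(s2 == 0 & r2 != 0)) {
    stop("standard error 0 with a nonzero residual: infinite weight",
         call. = FALSE)
  }
  sum((r1[s1 > 0] / s1[s1 > 0])^2) + sum((r2[s2 > 0] / s2[s2 > 0])^2)
}

#' Weighted nonnegative least-squares estimator of the incidence
#'
#' Minimizes [chi_square()] over nonnegative incidence guesses. Each
#' \eqn{i^{(g)}(a)} enters exactly two residual cells (one per survey), so
#' the problem decouples into independent scalar weighted least-squares
#' problems with a closed-form solution, projected onto \eqn{[0, \infty)};
#' truncated ages are flagged. With equal weights and noise-free data the
#' result coincides with the direct inversion estimator.
#'
#' @inheritParams direct_incidence
#' @inheritParams predict_cross_sections
#' @return An [incidence_estimate()] on the offset age grid.
#' @export
ls_incidence <- function(cs1, cs2, mort, eps = 1e-9,
                         variant = c("characteristic", "literal")) {
  variant <- match.arg(variant)
  ps <- .pair_setup(cs1, cs2, mort$time)
  ages <- .estimate_ages(ps)
  if (!length(ages)) stop("no common characteristic age nodes between the surveys",
                          call. = FALSE)
  mr <- .mort_at(mort, ages)
  p_star <- midpoint_prevalence(ps$cs1, ps$cs2, ps$t_star, ages)
  .check_singularity(p_star, ps$t_star, ages, eps)
  h1 <- ps$h1; h2 <- ps$h2
  par_term <- (1 - p_star) * mr$m * par_fraction(p_star, mr$R)

  # residual cell at t2 is always (t2, a + h2)
  i2 <- .age_index(ps$cs2, ages + h2, "survey cell at t2")
  A2 <- ps$cs2$prevalence[i2] - p_star + h2 * par_term
  s2 <- .sigma_at(ps$cs2, i2)

  # residual cell at t1 depends on the propagation variant
  a1 <- if (variant == "characteristic") ages - h1 else ages + h1
  have1 <- vapply(a1, function(a) any(abs(ps$cs1$ages - a) < .node_tol),
                  logical(1L))
  A1 <- rep(NA_real_, length(ages)); s1 <- rep(Inf, length(ages))
  if (any(have1)) {
    i1 <- .age_index(ps$cs1, a1[have1], "survey cell at t1")
    A1[have1] <- ps$cs1$prevalence[i1] - p_star[have1] - h1 * par_term[have1]
    s1[have1] <- .sigma_at(ps$cs1, i1)
  }
  if (any(s1 == 0) || any(s2 == 0)) {
    stop("standard error 0 gives an infinite weight; use a positive sigma",
         call. = FALSE)
  }

  # minimize (A2 - h2 u)^2/s2^2 + (A1 + h1 u)^2/s1^2 over u = (1-p*) i
  w1 <- ifelse(is.finite(s1), 1 / s1^2, 0)
  w2 <- 1 / s2^2
  num <- h2 * A2 * w2 - h1 * ifelse(w1 > 0, A1, 0) * w1
  den <- h2^2 * w2 + h1^2 * w1
  u <- num / den
  raw <- u / (1 - p_star)
  incidence_estimate(ps$t_star, ages, pmax(raw, 0), method = "least_squares",
                     clamped = raw < 0)
}

#' Estimate an incidence series from consecutive cross-sections
#'
#' Applies the direct or least-squares estimator to every consecutive pair
#' of a time-ordered series of cross-sections, yielding one estimate per
#' between-survey interval (e.g. yearly surveys 1995..2004 give estimates at
#' 1995.5, ..., 2003.5).
#'
#' @param cross_sections list of [cross_section()]s (any order; sorted by
#'   time internally).
#' @param mortality list of [mortality_input()]s, one whose time falls
#'   strictly inside each consecutive survey interval.
#' @param method \code{"direct"} or \code{"least_squares"}.
#' @param ... passed to the per-pair estimator.
#' @return List of [incidence_estimate()]s ordered by estimation time.
#' @export
estimate_series <- function(cross_sections, mortality,
                            method = c("direct", "least_squares"), ...) {
  method <- match.arg(method)
  stopifnot(length(cross_sections) >= 2L)
  ord <- order(vapply(cross_sections, `[[`, numeric(1L), "time"))
  cross_sections <- cross_sections[ord]
  mt <- vapply(mortality, `[[`, numeric(1L), "time")
  est_fun <- if (method == "direct") direct_incidence else ls_incidence
  lapply(seq_len(length(cross_sections) - 1L), function(j) {
    cs1 <- cross_sections[[j]]; cs2 <- cross_sections[[j + 1L]]
    in_gap <- which(mt > cs1$time & mt < cs2$time)
    if (length(in_gap) != 1L) {
      stop(sprintf(
        "need exactly one mortality input with time in (%g, %g); found %d",
        cs1$time, cs2$time, length(in_gap)), call. = FALSE)
    }
    est_fun(cs1, cs2, mortality[[in_gap]], ...)
  })
}

#' Annual percentage change of the incidence at one age
#'
#' Fits ordinary least squares of \eqn{\log \hat i(t^\star, a)} on
#' \eqn{t^\star} across a series of incidence estimates and reports the
#' secular trend as \eqn{100\,(e^{\mathrm{slope}} - 1)} percent per year.
#'
#' @param estimates list of [incidence_estimate()]s (>= 3).
#' @param age the age (on the estimates' grid) whose series is examined.
#' @return Annual percentage change (scalar, in percent).
#' @export
trend_fit <- function(estimates, age) {
  stopifnot(length(estimates) >= 3L)
  pts <- lapply(estimates, function(e) {
    j <- which(abs(e$ages - age) < .node_tol)
    if (length(j) != 1L) {
      stop(sprintf("age %g not present in the estimate at t*=%g", age, e$t_star),
           call. = FALSE)
    }
    c(t = e$t_star, i = e$incidence[j])
  })
  tt <- vapply(pts, `[`, numeric(1L), "t")
  ii <- vapply(pts, `[`, numeric(1L), "i")
  if (any(ii <= 0)) {
    stop(sprintf(
      "incidence at age %g is zero at t*=%g; the log-linear trend is undefined, try another age",
      age, tt[which(ii <= 0)[1L]]), call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(log(ii) ~ tt))[2L])
  100 * (exp(slope) - 1)
}
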