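#' Rectangular age-time grid for prevalence simulation
#'
#' Defines the calendar times and ages at which a simulated prevalence surface
#' is sampled, plus the Runge-Kutta integration substep used along cohort
#' lines. Ages must be uniformly spaced; time offsets must be integer
#' multiples of the age step so that every grid node lies on a cohort
#' characteristic through the first time slice or the minimum-age boundary.
#'
#' @param times strictly increasing calendar years.
#' @param ages strictly increasing, uniformly spaced ages (years).
#' @param integration_substep Runge-Kutta step along the characteristic
#'   (years); must divide the age step evenly. Default 0.1.
#' @return An object of class \code{"age_time_grid"}.
#' @export
age_time_grid <- function(times, ages, integration_substep = 0.1) {
  times <- as.numeric(times); ages <- as.numeric(ages)
  tol <- 1e-9
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (length(ages) < 2L || is.unsorted(ages, strictly = TRUE)) {
    stop("`ages` must be strictly increasing with at least two nodes",
         call. = FALSE)
  }
  age_step <- ages[2L] - ages[1L]
  if (max(abs(diff(ages) - age_step)) > tol) {
    stop("`ages` must be uniformly spaced", call. = FALSE)
  }
  off <- (times - times[1L]) / age_step
  if (max(abs(off - round(off))) > tol) {
    stop("time offsets must be integer multiples of the age step",
         call. = FALSE)
  }
  nsub <- age_step / integration_substep
  if (integration_substep <= 0 || abs(nsub - round(nsub)) > tol) {
    stop("`integration_substep` must be positive and divide the age step evenly",
         call. = FALSE)
  }
  structure(list(times = times, ages = ages, age_step = age_step,
                 integration_substep = integration_substep),
            class = "age_time_grid")
}

#' @export
print.age_time_grid <- function(x, ...) {
  cat(sprintf("Age-time grid: t in [%g, %g], a in [%g, %g] (step %g, substep %g)\n",
              min(x$times), max(x$times), min(x$ages), max(x$ages),
              x$age_step, x$integration_substep))
  invisible(x)
}

# One classical RK4 step for a batch of cohorts at positions (t, a),
# advancing the prevalence by h along the characteristic.
.rk4_step <- function(model, t, a, p, h) {
  f <- function(tt, aa, pp) {
    # intermediate stage values may overshoot [0, 1] on a diverging
    # trajectory; clamp them so the step completes and the caller's
    # range check reports the offending node
    pp <- pmin(pmax(pp, 0), 1)
    pde_rhs_excess(pp,
                   model$incidence(tt, aa),
                   model$mortality_healthy(tt, aa),
                   model$mortality_ill(tt, aa))
  }
  k1 <- f(t, a, p)
  k2 <- f(t + h / 2, a + h / 2, p + h / 2 * k1)
  k3 <- f(t + h / 2, a + h / 2, p + h / 2 * k2)
  k4 <- f(t + h, a + h, p + h * k3)
  p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Simulate a prevalence surface from an illness-death rate model
#'
#' Integrates the illness-death PDE along cohort characteristics with a
#' classical 4th-order Runge-Kutta scheme and samples the solution on the
#' grid. Cohorts alive at the first time start from \code{p0}; cohorts
#' reaching the minimum age later start from the boundary prevalence
#' (constant \code{p0[1]} unless overridden).
#'
#' @param model a [rate_model()].
#' @param p0 initial age-specific prevalence at \code{grid$times[1]}, one
#'   value per grid age, all in \eqn{[0, 1)}.
#' @param grid an [age_time_grid()].
#' @param boundary prevalence at the minimum age for later entry cohorts:
#'   either a single number (default \code{p0[1]}), a numeric vector with one
#'   value per time after the first, or a function of time.
#' @param half_grid if \code{TRUE}, additionally sample the surface at the
#'   midpoint grid (times between consecutive survey times, ages offset by
#'   half the time spacing) used by the estimators' validation; requires
#'   uniformly spaced times.
#' @return An object of class \code{"prevalence_surface"}: list with
#'   \code{times}, \code{ages}, matrix \code{p} (times x ages), the
#'   \code{grid}, and when requested a \code{half} component with the
#'   midpoint-sampled surface.
#' @export
simulate_prevalence <- function(model, p0, grid, boundary = NULL,
                                half_grid = FALSE) {
  stopifnot(inherits(model, "rate_model"), inherits(grid, "age_time_grid"))
  times <- grid$times; ages <- grid$ages
  h <- grid$integration_substep; astep <- grid$age_step
  tol <- 1e-9
  p0 <- as.numeric(p0)
  if (length(p0) != length(ages)) {
    stop("`p0` must have one value per grid age", call. = FALSE)
  }
  if (any(p0 < 0) || any(p0 >= 1)) {
    stop("`p0` must lie in [0, 1)", call. = FALSE)
  }
  nt <- length(times); na <- length(ages)
  t_min <- times[1L]; t_max <- times[nt]
  a_min <- ages[1L]; a_max <- ages[na]

  b_of <- if (is.null(boundary)) {
    function(t) rep(p0[1L], length(t))
  } else if (is.function(boundary)) {
    boundary
  } else if (is.numeric(boundary) && length(boundary) == 1L) {
    function(t) rep(boundary, length(t))
  } else if (is.numeric(boundary) && length(boundary) == nt - 1L) {
    function(t) boundary[match(t, times[-1L])]
  } else {
    stop("`boundary` must be NULL, a number, a function, or one value per later time",
         call. = FALSE)
  }

  # cohort starts: first time slice at every age, then the minimum-age
  # boundary at every later time
  t0 <- c(rep(t_min, na), if (nt > 1L) times[-1L])
  a0 <- c(ages, rep(a_min, nt - 1L))
  p_init <- c(p0, if (nt > 1L) b_of(times[-1L]))
  if (any(p_init < 0) || any(p_init >= 1)) {
    stop("boundary prevalence must lie in [0, 1)", call. = FALSE)
  }
  s_max <- pmin(t_max - t0, a_max - a0)
  K <- as.integer(round(s_max / h))
  K_max <- max(K)
  nc <- length(t0)

  traj <- matrix(NA_real_, nrow = K_max + 1L, ncol = nc)
  traj[1L, ] <- p_init
  p_cur <- p_init
  if (K_max > 0L) {
    for (k in seq_len(K_max)) {
      act <- which(K >= k)
      s <- (k - 1L) * h
      p_new <- .rk4_step(model, t0[act] + s, a0[act] + s, p_cur[act], h)
      p_new[p_new < 0 & p_new > -1e-12] <- 0
      if (any(p_new < 0) || any(p_new >= 1)) {
        bad <- act[which(p_new < 0 | p_new >= 1)[1L]]
        stop(sprintf(
          "prevalence left [0, 1) during integration at (t=%g, a=%g)",
          t0[bad] + s + h, a0[bad] + s + h), call. = FALSE)
      }
      p_cur[act] <- p_new
      traj[k + 1L, act] <- p_new
    }
  }

  # sample the trajectories onto the grid: node (t, a) lies on the cohort
  # with t - a = t0 - a0, at arclength s = t - t0
  P <- matrix(NA_real_, nrow = nt, ncol = na,
              dimnames = list(format(times), format(ages)))
  for (c_i in seq_len(nc)) {
    tt <- times[times >= t0[c_i] - tol & times <= t0[c_i] + s_max[c_i] + tol]
    s <- tt - t0[c_i]
    aa <- a0[c_i] + s
    keep <- aa >= a_min - tol & aa <= a_max + tol
    tt <- tt[keep]; s <- s[keep]; aa <- aa[keep]
    if (!length(tt)) next
    ti <- match(tt, times)
    ai <- as.integer(round((aa - a_min) / astep)) + 1L
    ki <- as.integer(round(s / h)) + 1L
    P[cbind(ti, ai)] <- traj[cbind(ki, rep(c_i, length(ki)))]
  }
  if (anyNA(P)) stop("internal error: grid node not covered by any cohort")

  out <- structure(list(times = times, ages = ages, p = P, grid = grid),
                   class = "prevalence_surface")

  if (half_grid) {
    if (nt < 2L) stop("`half_grid` requires at least two times", call. = FALSE)
    dts <- diff(times)
    if (max(abs(dts - dts[1L])) > tol) {
      stop("`half_grid` requires uniformly spaced times", call. = FALSE)
    }
    hs <- dts[1L] / 2
    if (abs(hs / h - round(hs / h)) > tol) {
      stop("half-grid offset must be a multiple of the integration substep",
           call. = FALSE)
    }
    half_times <- times[-nt] + hs
    half_ages <- ages[ages + 2 * hs <= a_max + tol] + hs
    Ph <- matrix(NA_real_, nrow = length(half_times), ncol = length(half_ages),
                 dimnames = list(format(half_times), format(half_ages)))
    for (c_i in seq_len(nc)) {
      tt <- half_times[half_times >= t0[c_i] - tol &
                       half_times <= t0[c_i] + s_max[c_i] + tol]
      s <- tt - t0[c_i]
      aa <- a0[c_i] + s
      keep <- aa >= min(half_ages) - tol & aa <= max(half_ages) + tol
      tt <- tt[keep]; s <- s[keep]; aa <- aa[keep]
      if (!length(tt)) next
      ti <- match(tt, half_times)
      ai <- as.integer(round((aa - half_ages[1L]) / astep)) + 1L
      ki <- as.integer(round(s / h)) + 1L
      Ph[cbind(ti, ai)] <- traj[cbind(ki, rep(c_i, length(ki)))]
    }
    if (anyNA(Ph)) stop("internal error: half-grid node not covered")
    out$half <- list(times = half_times, ages = half_ages, p = Ph)
  }
  out
}

#' @export
print.prevalence_surface <- function(x, ...) {
  cat(sprintf("Prevalence surface: %d times x %d ages, p in [%.4g, %.4g]\n",
              length(x$times), length(x$ages), min(x$p), max(x$p)))
  invisible(x)
}

#' Extract survey cross-sections from a prevalence surface
#'
#' Slices a simulated prevalence surface at the requested calendar times,
#' returning one complete-survey cross-section per time (no sampling error:
#' standard errors and sample sizes unset).
#'
#' @param surface a [simulate_prevalence()] result.
#' @param times calendar years to extract; must be grid times.
#' @return List of [cross_section()] objects, one per requested time.
#' @export
cross_sections_from_surface <- function(surface, times) {
  stopifnot(inherits(surface, "prevalence_surface"))
  idx <- match(times, surface$times)
  if (anyNA(idx)) {
    stop(sprintf("time(s) %s not on the surface grid; available: %s",
                 paste(times[is.na(idx)], collapse = ", "),
                 paste(surface$times, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_along(idx), function(j) {
    cross_section(time = times[j], ages = surface$ages,
                  prevalence = surface$p[idx[j], ])
  })
}
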