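#' Binomial standard error of a prevalence proportion
#'
#' Standard error of an observed prevalence proportion from a simple random
#' sample of size \code{n}: \eqn{\sqrt{p(1-p)/n}}.
#'
#' @param p prevalence proportion in \eqn{[0, 1]}.
#' @param n sample size (>= 1).
#' @return Standard error, vectorised.
#' @export
binomial_sigma <- function(p, n) {
  .check_prob(p)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  sqrt(p * (1 - p) / n)
}

#' Survey sampling-noise specification
#'
#' Describes how a survey samples the population: age groups (closed lower
#' bound, closed upper bound, in years) with one sample size each. The
#' default emulates a survey with 5-year age groups from 30-34 to 95-99 and
#' sample sizes decreasing with age; these sizes are a synthetic stand-in for
#' a realistic grouped survey design, not register counts.
#'
#' @param age_groups two-column matrix or data frame of group bounds
#'   \code{(lower, upper)}; groups must not overlap.
#' @param n sample size per group (>= 1).
#' @param seed optional integer seed applied by consumers that own the
#'   randomness (e.g. [bootstrap_incidence()]).
#' @return An object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(age_groups = cbind(lower = seq(30, 95, by = 5),
                                          upper = seq(34, 99, by = 5)),
                       n = c(2000, 2000, 1500, 1500, 1000, 1000, 750, 750,
                             500, 500, 250, 250, 100, 100),
                       seed = NULL) {
  age_groups <- as.matrix(age_groups)
  stopifnot(ncol(age_groups) == 2L)
  lower <- as.numeric(age_groups[, 1L]); upper <- as.numeric(age_groups[, 2L])
  if (any(upper < lower)) stop("group upper bound below lower bound", call. = FALSE)
  ord <- order(lower)
  lower <- lower[ord]; upper <- upper[ord]
  if (any(lower[-1L] <= upper[-length(upper)])) {
    stop("age groups must not overlap", call. = FALSE)
  }
  n <- rep(as.numeric(n), length.out = length(lower))[ord]
  if (any(n < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  structure(list(lower = lower, upper = upper, n = n, seed = seed),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise spec: %d age groups %g-%g, n from %g to %g\n",
              length(x$lower), min(x$lower), max(x$upper), max(x$n), min(x$n)))
  invisible(x)
}

# group index per age; error on uncovered ages
.group_of <- function(spec, ages) {
  g <- vapply(ages, function(a) {
    j <- which(a >= spec$lower - 1e-9 & a <= spec$upper + 1e-9)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1L))
  if (anyNA(g)) {
    stop(sprintf("age %g not assignable to any noise-spec group",
                 ages[which(is.na(g))[1L]]), call. = FALSE)
  }
  g
}

#' Superimpose binomial survey noise on a cross-section
#'
#' Emulates grouped survey sampling: for every age group the prevalence at
#' the group's representative age (the midpoint, resolved to the nearest
#' grid age) is replaced by a draw \eqn{X/n} with
#' \eqn{X \sim \mathrm{Binomial}(n, p)}, i.e. mean-zero additive noise with
#' exactly the binomial variance \eqn{p(1-p)/n}. The noisy group value is
#' broadcast to all member ages and the plug-in standard error
#' [binomial_sigma()] is recorded. Uses R's global random number generator;
#' seed it (or pass \code{seed}) for reproducibility.
#'
#' @param cs a [cross_section()]; all its ages must fall into spec groups.
#' @param spec a [noise_spec()].
#' @param seed optional integer seed set before drawing.
#' @return A new [cross_section()] with noisy prevalence, \code{sigma} and
#'   \code{n} filled in.
#' @export
add_binomial_noise <- function(cs, spec, seed = NULL) {
  stopifnot(inherits(cs, "cross_section"), inherits(spec, "noise_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- .group_of(spec, cs$ages)
  groups <- sort(unique(g))
  p_noisy <- numeric(length(cs$ages))
  for (k in groups) {
    member <- which(g == k)
    mid <- (spec$lower[k] + spec$upper[k]) / 2
    rep_idx <- member[which.min(abs(cs$ages[member] - mid))]
    p_rep <- cs$prevalence[rep_idx]
    draw <- stats::rbinom(1L, size = spec$n[k], prob = p_rep) / spec$n[k]
    p_noisy[member] <- draw
  }
  # a draw of exactly n successes would put p at 1; keep within [0, 1)
  p_noisy <- pmin(p_noisy, 1 - 1e-12)
  nn <- spec$n[g]
  cross_section(cs$time, cs$ages, p_noisy,
                sigma = binomial_sigma(pmin(p_noisy, 1), nn), n = nn)
}

#' Percentile bootstrap of the incidence under survey noise
#'
#' Quantifies the sampling uncertainty of an incidence estimate by
#' resampling: each of \code{B} replicates redraws both surveys' grouped
#' prevalences from their binomial sampling distributions
#' (around the observed prevalences, with the spec's group sample sizes),
#' re-estimates the incidence, and the per-age median and 2.5\%/97.5\%
#' empirical percentiles (linear-interpolation definition, R quantile type
#' 7) are reported. Replicates on which the estimator fails (e.g. the
#' prevalence-near-1 guard) are excluded and counted.
#'
#' @inheritParams direct_incidence
#' @param spec a [noise_spec()] describing the survey design.
#' @param B number of bootstrap replicates (default 2000).
#' @param method \code{"direct"} (default) or \code{"least_squares"}.
#' @param seed integer seed governing all replicate noise; defaults to
#'   \code{spec$seed} when set.
#' @return An object of class \code{"bootstrap_result"}: \code{t_star},
#'   \code{ages}, per-age \code{median}, \code{lower}, \code{upper},
#'   \code{B}, and \code{n_failed}.
#' @export
bootstrap_incidence <- function(cs1, cs2, mort, spec, B = 2000,
                                method = c("direct", "least_squares"),
                                seed = NULL) {
  method <- match.arg(method)
  stopifnot(B >= 1)
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  est_fun <- if (method == "direct") direct_incidence else ls_incidence
  template <- est_fun(cs1, cs2, mort)
  draws <- matrix(NA_real_, nrow = B, ncol = length(template$ages))
  n_failed <- 0L
  for (b in seq_len(B)) {
    rep1 <- add_binomial_noise(cs1, spec)
    rep2 <- add_binomial_noise(cs2, spec)
    est <- tryCatch(est_fun(rep1, rep2, mort), error = function(e) NULL)
    if (is.null(est)) {
      n_failed <- n_failed + 1L
    } else {
      draws[b, ] <- est$incidence
    }
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(t_star = template$t_star, ages = template$ages,
                 median = qs[2L, ], lower = qs[1L, ], upper = qs[3L, ],
                 B = B, n_failed = n_failed, method = method),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap incidence (%s) at t*=%g: B=%d (%d failed), %d ages\n",
    x$method, x$t_star, x$B, x$n_failed, length(x$ages)))
  invisible(x)
}

#' @export
as.data.frame.bootstrap_result <- function(x, ...) {
  data.frame(time = x$t_star, age = x$ages, median = x$median,
             lower = x$lower, upper = x$upper)
}
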