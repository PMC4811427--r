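make_pair <- function(p1, p2, t1 = 1995, t2 = 1996, ages = 30:40) {
  list(cs1 = cross_section(t1, ages, rep(p1, length(ages)) ),
       cs2 = cross_section(t2, ages, rep(p2, length(ages))))
}

test_that("midpoint prevalence is the convex combination along the cohort line", {
  ages <- 30:40
  p1 <- 0.10 + 0.002 * (ages - 30)
  p2 <- 0.11 + 0.002 * (ages - 30)
  cs1 <- cross_section(1995, ages, p1)
  cs2 <- cross_section(1996, ages, p2)
  # symmetric offsets: plain average of the two endpoint nodes
  expect_equal(midpoint_prevalence(cs1, cs2, 1995.5, 35.5),
               (p1[6] + p2[7]) / 2)
  # constants are preserved
  pr <- make_pair(0.07, 0.07)
  expect_equal(midpoint_prevalence(pr$cs1, pr$cs2, 1995.5, 34.5), 0.07)
  # asymmetric t*: weights h2 and h1 over h1 + h2
  expect_equal(midpoint_prevalence(cs1, cs2, 1995.25, 33.25),
               0.75 * p1[4] + 0.25 * p2[5])
  # survey order must not matter
  expect_equal(midpoint_prevalence(cs2, cs1, 1995.5, 35.5),
               midpoint_prevalence(cs1, cs2, 1995.5, 35.5))
  expect_error(midpoint_prevalence(cs1, cs2, 1995.5, 29.5), "age node")
  expect_error(midpoint_prevalence(cs1, cs2, 1995, 35.5), "strictly between")
})

test_that("characteristic derivative is the centered difference", {
  pr <- make_pair(0.10, 0.11)
  expect_equal(characteristic_derivative(pr$cs1, pr$cs2, 1995.5, 35.5), 0.01)
  flat <- make_pair(0.08, 0.08)
  expect_equal(characteristic_derivative(flat$cs1, flat$cs2, 1995.5, 35.5), 0)
})

test_that("characteristic derivative matches the analytic PDE rhs on a simulated surface", {
  i <- 0.03; m0 <- 0.01; m1 <- 0.04
  model <- const_rate_model(i = i, m0 = m0, m1 = m1)
  g <- age_time_grid(2000:2002, 30:60)
  s <- simulate_prevalence(model, rep(0, 31), g, half_grid = TRUE)
  css <- cross_sections_from_surface(s, 2000:2001)
  ages <- seq(35.5, 55.5, by = 1)
  d <- characteristic_derivative(css[[1]], css[[2]], 2000.5, ages)
  p_true <- s$half$p[1, match(ages, s$half$ages)]
  expect_equal(d, unname(pde_rhs_excess(p_true, i, m0, m1)),
               tolerance = 1e-3)
})

test_that("direct estimation recovers zero and constant incidence", {
  # identically empty surveys: no incidence, nothing clamped
  zero <- make_pair(0, 0)
  mort <- mortality_input(1995.5, seq(30.5, 39.5, 1), m = 0.02, R = 2)
  est <- direct_incidence(zero$cs1, zero$cs2, mort)
  expect_true(all(est$incidence == 0))
  expect_false(any(est$clamped))
  # stationary prevalence with R = 1: both terms vanish
  stat <- make_pair(0.12, 0.12)
  mort1 <- mortality_input(1995.5, seq(30.5, 39.5, 1), m = 0.02, R = 1)
  est1 <- direct_incidence(stat$cs1, stat$cs2, mort1)
  expect_true(all(est1$incidence == 0))
  # constant-rate simulation: estimate approximates the generating incidence
  i <- 0.02; m0 <- 0.015; m1 <- 0.045
  model <- const_rate_model(i = i, m0 = m0, m1 = m1)
  g <- age_time_grid(2000:2001, 30:70)
  s <- simulate_prevalence(model, rep(0, 41), g, half_grid = TRUE)
  css <- cross_sections_from_surface(s, 2000:2001)
  a_half <- s$half$ages
  p_true <- s$half$p[1, ]
  mort2 <- mortality_input(2000.5, a_half,
                           m = general_mortality(p_true, m0, m1), R = m1 / m0)
  est2 <- direct_incidence(css[[1]], css[[2]], mort2)
  expect_lt(max(abs(est2$incidence - i) / i), 1e-3)
})

test_that("negative raw estimates are truncated at zero and flagged", {
  # prevalence collapsing much faster than mortality can explain
  falling <- make_pair(0.20, 0.05)
  mort <- mortality_input(1995.5, seq(30.5, 39.5, 1), m = 0.001, R = 1.1)
  est <- direct_incidence(falling$cs1, falling$cs2, mort)
  expect_true(all(est$incidence == 0))
  expect_true(all(est$clamped))
  ls <- ls_incidence(falling$cs1, falling$cs2, mort)
  expect_true(all(ls$incidence == 0))
  expect_true(all(ls$clamped))
})

test_that("the singularity guard rejects prevalence near one", {
  near1 <- make_pair(1 - 1e-12, 1 - 1e-12)
  mort <- mortality_input(1995.5, seq(30.5, 39.5, 1), m = 0.02, R = 2)
  expect_error(direct_incidence(near1$cs1, near1$cs2, mort), "singular")
})

test_that("first-order propagation is consistent with the direct inversion", {
  cp <- consistent_pair()
  # the generating incidence reproduces both surveys to machine precision
  expect_lt(chi_square(cp$i_true, cp$cs1, cp$cs2, cp$mort), 1e-24)
  # identity at zero offsets
  pred0 <- predict_cross_sections(cp$p_star, cp$i_true, cp$mort, 0, 0)
  expect_equal(pred0$p1, cp$p_star)
  expect_equal(pred0$p2, cp$p_star)
  # frozen dynamics: zero incidence and mortality shift nothing
  m0in <- mortality_input(2000.5, cp$ages, m = 0, R = 2)
  predf <- predict_cross_sections(cp$p_star, rep(0, length(cp$ages)), m0in,
                                  0.5, 0.5)
  expect_equal(predf$p1, cp$p_star)
  expect_equal(predf$p2, cp$p_star)
  expect_equal(predf$ages1, cp$ages - 0.5)
  expect_equal(predf$ages2, cp$ages + 0.5)
})

test_that("the standardized squared error scales and sums as defined", {
  cp <- consistent_pair()
  n_age <- length(cp$ages)
  # perturb the guess at one age by delta; with infinite weight on the first
  # survey only the t2 cell contributes: residual h2 (1-p*) delta
  k <- 5L
  delta <- 0.01 / (cp$h * (1 - cp$p_star[k]))
  i_g <- cp$i_true; i_g[k] <- i_g[k] + delta
  cs1_inf <- cross_section(cp$cs1$time, cp$cs1$ages, cp$cs1$prevalence,
                           sigma = rep(Inf, n_age))
  cs2_s <- cross_section(cp$cs2$time, cp$cs2$ages, cp$cs2$prevalence,
                         sigma = rep(0.005, n_age))
  expect_equal(chi_square(i_g, cs1_inf, cs2_s, cp$mort), (0.01 / 0.005)^2,
               tolerance = 1e-10)
  # doubling every sigma divides the score by four
  cs1_a <- cross_section(cp$cs1$time, cp$cs1$ages, cp$cs1$prevalence,
                         sigma = rep(0.01, n_age))
  cs2_a <- cross_section(cp$cs2$time, cp$cs2$ages, cp$cs2$prevalence,
                         sigma = rep(0.01, n_age))
  cs1_b <- cross_section(cp$cs1$time, cp$cs1$ages, cp$cs1$prevalence,
                         sigma = rep(0.02, n_age))
  cs2_b <- cross_section(cp$cs2$time, cp$cs2$ages, cp$cs2$prevalence,
                         sigma = rep(0.02, n_age))
  x_a <- chi_square(i_g, cs1_a, cs2_a, cp$mort)
  x_b <- chi_square(i_g, cs1_b, cs2_b, cp$mort)
  expect_equal(x_a / x_b, 4, tolerance = 1e-10)
  # zero sigma with a nonzero residual is an infinite weight
  cs2_z <- cross_section(cp$cs2$time, cp$cs2$ages, cp$cs2$prevalence,
                         sigma = rep(0, n_age))
  expect_error(chi_square(i_g, cs1_a, cs2_z, cp$mort), "infinite weight")
})

test_that("closed-form least squares agrees with a numerical scalar search", {
  cp <- consistent_pair()
  set.seed(7)
  n_age <- length(cp$ages)
  noise1 <- rnorm(n_age, 0, 0.004)
  noise2 <- rnorm(n_age, 0, 0.002)
  cs1 <- cross_section(cp$cs1$time, cp$cs1$ages,
                       pmin(pmax(cp$cs1$prevalence + noise1, 0), 0.9),
                       sigma = rep(0.004, n_age))
  cs2 <- cross_section(cp$cs2$time, cp$cs2$ages,
                       pmin(pmax(cp$cs2$prevalence + noise2, 0), 0.9),
                       sigma = rep(0.002, n_age))
  est <- ls_incidence(cs1, cs2, cp$mort)
  # coordinate-wise bounded search over the decoupled scalar objectives
  for (k in c(1L, 8L, n_age)) {
    g <- function(x) {
      v <- est$incidence; v[k] <- x
      chi_square(v, cs1, cs2, cp$mort)
    }
    opt <- stats::optimize(g, c(0, max(est$incidence) * 3 + 0.05),
                           tol = 1e-12)
    if (est$incidence[k] > 0) {
      expect_equal(opt$minimum, est$incidence[k], tolerance = 1e-5)
    }
    expect_lte(g(est$incidence[k]), opt$objective + 1e-10)
  }
})

test_that("an infinite-variance survey cell hands the estimate to the other survey", {
  cp <- consistent_pair()
  set.seed(11)
  n_age <- length(cp$ages)
  p2 <- pmin(pmax(cp$cs2$prevalence + rnorm(n_age, 0, 0.002), 0), 0.9)
  sig2 <- rep(0.002, n_age); sig2[4] <- Inf
  cs2 <- cross_section(cp$cs2$time, cp$cs2$ages, p2, sigma = sig2)
  est <- ls_incidence(cp$cs1, cs2, cp$mort)
  expect_false(est$clamped[4])
  # at the infinite-variance age the t1 residual is interpolated exactly
  pred <- predict_cross_sections(
    midpoint_prevalence(cp$cs1, cs2, cp$mort$time, cp$ages),
    est$incidence, cp$mort, cp$h, cp$h)
  expect_equal(pred$p1[4], cp$cs1$prevalence[4], tolerance = 1e-12)
})

test_that("noise-free equal-weight least squares equals the direct inversion", {
  val <- cached_validation()
  css <- cross_sections_from_surface(val$surface, val$surface$times[1:2])
  mort <- val$mortality[[1]]
  d <- direct_incidence(css[[1]], css[[2]], mort)
  l <- ls_incidence(css[[1]], css[[2]], mort)
  expect_equal(l$incidence, d$incidence, tolerance = 1e-12)
  expect_equal(l$ages, d$ages)
})

test_that("the literal backward-step variant runs but is less accurate noise-free", {
  val <- cached_validation()
  css <- cross_sections_from_surface(val$surface, val$surface$times[1:2])
  mort <- val$mortality[[1]]
  lit <- ls_incidence(css[[1]], css[[2]], mort, variant = "literal")
  chr <- ls_incidence(css[[1]], css[[2]], mort, variant = "characteristic")
  truth <- val$truth[1, match(chr$ages, as.numeric(colnames(val$truth)))]
  err <- function(e) {
    idx <- match(chr$ages, e$ages)
    max(abs(e$incidence[idx] - truth) / truth, na.rm = TRUE)
  }
  expect_lt(err(chr), err(lit))
})

test_that("series estimation pairs consecutive surveys at midpoint times", {
  val <- cached_validation()
  css <- cross_sections_from_surface(val$surface, val$surface$times)
  ests <- estimate_series(css, val$mortality, method = "direct")
  expect_length(ests, 9L)
  expect_equal(vapply(ests, `[[`, numeric(1), "t_star"),
               seq(1995.5, 2003.5, by = 1))
  # permuting the input order changes nothing
  set.seed(3)
  perm <- sample(length(css))
  ests_p <- estimate_series(css[perm], rev(val$mortality), method = "direct")
  expect_equal(lapply(ests_p, `[[`, "incidence"),
               lapply(ests, `[[`, "incidence"))
  # two surveys reduce to the single-pair estimator
  two <- estimate_series(css[1:2], val$mortality[1], method = "direct")
  expect_length(two, 1L)
  expect_equal(two[[1]]$incidence,
               direct_incidence(css[[1]], css[[2]], val$mortality[[1]])$incidence)
  # a missing mid-interval mortality input is an error
  expect_error(estimate_series(css[1:3], val$mortality[1], method = "direct"),
               "exactly one mortality input")
})

test_that("the log-linear trend fit recovers exact exponential growth", {
  ages <- seq(60.5, 70.5, by = 1)
  mk <- function(t, f) incidence_estimate(t, ages,
                                          0.01 * f^(t - 2000) + 0 * ages,
                                          method = "direct")
  ests <- lapply(seq(2000.5, 2008.5, by = 1), mk, f = 1.053)
  expect_equal(trend_fit(ests, 65.5), 5.3, tolerance = 1e-10)
  flat <- lapply(seq(2000.5, 2008.5, by = 1), mk, f = 1)
  expect_equal(trend_fit(flat, 65.5), 0, tolerance = 1e-12)
  zero <- lapply(seq(2000.5, 2002.5, by = 1), function(t) {
    incidence_estimate(t, ages, rep(0, length(ages)), method = "direct")
  })
  expect_error(trend_fit(zero, 65.5), "another age")
})
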