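test_that("effective competition reduces to bare competition without mutualism", {
  net <- generate_random_network(6, 5, 0.3, seed = 1)
  comm <- assemble_community(net, meta_parameters(rho = 0.2, gamma0 = 0),
                             seed = 2)
  st <- equilibrium_state(comm)
  expect_equal(unname(effective_competition(comm, st, "P")), unname(comm$beta_p))
  expect_equal(unname(effective_competition(comm, st, "A")), unname(comm$beta_a))
})

test_that("the fold matches an independently coded Schur complement", {
  comm <- mean_field_2x2()
  st <- equilibrium_state(comm)
  # independent oracle: build the linearized slopes from first principles
  slope <- function(gamma, h, partner_n) {
    G <- as.vector(gamma %*% partner_n)
    gamma / (1 + h * G)^2
  }
  GP <- slope(comm$gamma_p, comm$h_p, st$n_a)
  GA <- slope(comm$gamma_a, comm$h_a, st$n_p)
  C_oracle <- comm$beta_p - GP %*% solve(comm$beta_a) %*% GA
  expect_equal(effective_competition(comm, st, "P"), C_oracle,
               tolerance = 1e-12)
  # mutualism lowers the effective off-diagonal below the bare rho = 0.1
  C <- effective_competition(comm, st, "P")
  expect_lt(C[1, 2], 0.1)
  expect_lt(C[2, 1], 0.1)
})

test_that("h -> 0 gives the bilinear fold exactly", {
  net <- generate_random_network(5, 6, 0.3, seed = 3)
  comm <- assemble_community(net, meta_parameters(rho = 0.1, h = 0), seed = 4)
  st <- equilibrium_state(comm)
  C <- effective_competition(comm, st, "P")
  expect_equal(C, comm$beta_p - comm$gamma_p %*% solve(comm$beta_a) %*%
                 comm$gamma_a, tolerance = 1e-12)
})

test_that("rho_eff recovers mean-field values and validates input", {
  C <- matrix(0.1, 5, 5)
  diag(C) <- 1
  expect_equal(rho_eff(C), 0.1) # lambda1 = 1.4
  expect_equal(rho_eff(diag(4)), 0)
  expect_error(rho_eff(matrix(1, 1, 1)), "single species")
  expect_error(rho_eff(matrix(1, 2, 3)), "square")
  # normalized variant agrees when the diagonal is already 1
  expect_equal(rho_eff(C, normalize = TRUE), 0.1)
})

test_that("mutualism lowers effective below bare competition", {
  for (s in 1:8) {
    rho <- c(0.0125, 0.05, 0.15)[s %% 3 + 1]
    comm <- small_community(seed = s, np = 12, na = 12, rho = rho,
                            connectance = 0.25)
    st <- equilibrium_state(comm)
    expect_lt(rho_eff(effective_competition(comm, st, "P")), rho)
    expect_lt(rho_eff(effective_competition(comm, st, "A")), rho)
  }
})

test_that("critical competition has its closed forms", {
  expect_equal(rho_c(complete_net(4, 7), "P"), 1)
  expect_equal(rho_c(complete_net(4, 7), "A"), 1)
  for (s in c(3, 5, 8)) {
    expect_equal(rho_c(matching_net(s), "P"), 1 / s)
  }
  # star: one plant with all links, others isolated (excluded guild-side)
  star <- bipartite_network(rbind(rep(1, 4), matrix(0, 2, 4)))
  expect_equal(rho_c(star, "P"), 1 / 3) # only mu_11 != 0
  empty <- bipartite_network(matrix(0, 2, 2))
  expect_error(rho_c(empty, "P"), "no mutualistic links")
  # independent summation oracle on a random network
  net <- generate_random_network(6, 9, 0.3, seed = 11)
  a <- net$incidence
  mu <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) mu[i, j] <- sum(a[i, ] * a[j, ])
  expect_equal(rho_c(net, "P"), sum(mu) / (6 * sum(diag(mu))))
})

test_that("regime distance arithmetic and guards", {
  expect_equal(regime_distance(0.2, 0.2), 0)
  expect_equal(regime_distance(0.2, 0), 1)
  expect_equal(regime_distance(0.08, 0.12), -0.5)
  expect_error(regime_distance(0, 0.1), "positive")
  expect_warning(d <- regime_distance(0.05, 0.2), "outside")
  expect_equal(as.numeric(d), -3)
  expect_true(attr(d, "clamped"))
})

test_that("analytic critical perturbation follows the closed form", {
  expect_equal(predict_delta_c(10, 0.1), 9 / 19)
  expect_equal(predict_delta_c(10, 0.999), s_eff(0.999) / (10 + s_eff(0.999)),
               tolerance = 1e-12)
  expect_lt(predict_delta_c(10, 0.999), 1e-2) # S_eff -> 0 limit
  expect_equal(predict_delta_c(10, 0.1, eta_prime = 2, eta_0 = 0.1),
               (9 / 19 - 0.1) / 2)
  expect_error(predict_delta_c(10, 1.2), "0, 1")
  expect_error(predict_delta_c(10, 0.1, eta_prime = 0), "positive")
})

test_that("growth-rate perturbations stay in their envelope", {
  alpha <- c(1, 2, 0.5)
  expect_identical(perturb_growth_rates(alpha, 0), alpha)
  set.seed(1)
  for (i in 1:100) {
    out <- perturb_growth_rates(rep(1, 100), 1)
    expect_true(all(out >= 0 & out <= 2))
  }
  expect_error(perturb_growth_rates(alpha, 1.2), "0, 1")
  expect_error(perturb_growth_rates(alpha, -0.1), "0, 1")
})

test_that("extinction fractions are zero at zero perturbation and reproducible", {
  comm <- small_community(seed = 4, np = 8, na = 8)
  st <- integrate_to_steady_state(comm, equilibrium_state(comm))$state
  out <- extinction_fraction_curve(comm, st, deltas = 0, n_draws = 3, seed = 1)
  expect_equal(out$fraction, 0)
  a <- extinction_fraction_curve(comm, st, deltas = 0.6, n_draws = 1, seed = 9)
  b <- extinction_fraction_curve(comm, st, deltas = 0.6, n_draws = 1, seed = 9)
  expect_identical(a, b)
  expect_true(a$fraction %in% c(0, 1))
})

test_that("numerical critical perturbation brackets and refines", {
  comm <- small_community(seed = 6, np = 8, na = 8, rho = 0.15,
                          connectance = 0.25)
  st <- integrate_to_steady_state(comm, equilibrium_state(comm))$state
  grid <- default_grid <- exp(seq(log(0.02), log(1), length.out = 8))
  dc50 <- estimate_delta_c_numeric(comm, st, grid = grid, n_draws = 10,
                                   threshold = 0.5, seed = 3)
  dc0 <- estimate_delta_c_numeric(comm, st, grid = grid, n_draws = 10,
                                  threshold = 0, seed = 3)
  expect_lte(as.numeric(dc0), as.numeric(dc50)) # any-extinction is reached first
  expect_false(attr(dc50, "upper_bound"))
  expect_s3_class(attr(dc50, "curve"), "tbl_df")
  expect_error(estimate_delta_c_numeric(comm, st, grid = c(0.5, 0.1)),
               "ascending")
  expect_error(estimate_delta_c_numeric(comm, st, grid = c(0, 0.5)),
               "ascending|\\(0, 1\\]")
})

test_that("calibration recovers known eta coefficients", {
  set.seed(2)
  x <- runif(20, 0.2, 0.9)
  data <- tibble::tibble(s_frac = x, delta_c_num = (x - 0.1) / 2)
  cal <- calibrate_delta_c(data)
  expect_equal(cal$eta_prime, 2, tolerance = 1e-8)
  expect_equal(cal$eta_0, 0.1, tolerance = 1e-8)
  bad <- tibble::tibble(s_frac = x, delta_c_num = -x)
  expect_error(calibrate_delta_c(bad), "slope")
})

test_that("stability summary degrades to NA on degenerate systems", {
  lone <- assemble_community(bipartite_network(matrix(0, 1, 1)),
                             meta_parameters(rho = 0.5, epsilon = 0), seed = 1)
  sm <- stability_summary(lone, equilibrium_state(lone))
  expect_true(is.na(sm$rho_eff_p)) # single-species guild
  expect_true(is.na(sm$rho_c_p))   # no links
  expect_true(is.na(sm$delta_c))
})
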