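#' Effective competition matrix of one guild
#'
#' Folds the linearized mutualistic pathways into the within-guild competition
#' by guild elimination (Schur complement) of the steady-state linearization:
#' for plants, `C = beta_P - G_P beta_A^{-1} G_A`, where `G` holds the
#' saturation-corrected mutualistic slopes
#' `G_ik = gamma_ik / (1 + h_i sum_l gamma_il N_l)^2` evaluated at the steady
#' state. With no mutualism (`gamma = 0`) this returns the bare competition
#' matrix exactly; with `h -> 0` it tends to the bilinear fold
#' `beta_P - gamma_P beta_A^{-1} gamma_A`.
#'
#' @param comm an `ecoevo_community`.
#' @param state the steady state at which the linearization is taken.
#' @param guild `"P"` (plants) or `"A"` (animals).
#' @return square effective competition matrix for the guild.
#' @export
effective_competition <- function(comm, state, guild = c("P", "A")) {
  guild <- match.arg(guild)
  slope_p <- comm$gamma_p /
    (1 + comm$h_p * as.vector(comm$gamma_p %*% state$n_a))^2
  slope_a <- comm$gamma_a /
    (1 + comm$h_a * as.vector(comm$gamma_a %*% state$n_p))^2
  fold <- function(beta_self, slope_self, beta_other, slope_other) {
    inv <- tryCatch(solve(beta_other),
                    error = function(e) stop(
                      "singular within-guild competition matrix in fold: ",
                      conditionMessage(e), call. = FALSE))
    beta_self - slope_self %*% inv %*% slope_other
  }
  if (guild == "P") {
    fold(comm$beta_p, slope_p, comm$beta_a, slope_a)
  } else {
    fold(comm$beta_a, slope_a, comm$beta_p, slope_p)
  }
}

#' Effective interspecific competition from an effective competition matrix
#'
#' Takes the leading (Perron) eigenvalue `lambda_1` of `C` and returns
#' `(lambda_1 - 1) / (S - 1)`: the interspecific strength of the mean-field
#' competitive system, at unit intraspecific competition, with the same
#' leading eigenvalue. For the exact mean-field matrix (diagonal 1,
#' off-diagonal `rho`) this recovers `rho`. The formula is applied to `C` on
#' the original scale (intraspecific competition `beta0 = 1`) by default:
#' mutualism lowers self-competition along with the off-diagonals, and
#' rescaling to a unit diagonal first (`normalize = TRUE`,
#' `C'_ij = C_ij / sqrt(C_ii C_jj)`) re-inflates the off-diagonal part enough
#' to break the defining property that mutualistic interactions reduce the
#' effective competition below the bare `rho`.
#'
#' @param C square effective competition matrix (at least 2 species).
#' @param normalize rescale `C` to unit diagonal before taking the
#'   eigenvalue.
#' @return dimensionless effective interspecific competition.
#' @export
rho_eff <- function(C, normalize = FALSE) {
  s <- nrow(C)
  if (is.null(s) || s != ncol(C)) stop("C must be square", call. = FALSE)
  if (s < 2) stop("effective competition undefined for a single species",
                  call. = FALSE)
  d <- diag(C)
  if (any(d <= 0)) stop("nonpositive self-competition on the diagonal",
                        call. = FALSE)
  Cn <- if (normalize) C / sqrt(outer(d, d)) else C
  ev <- eigen(Cn, only.values = TRUE)$values
  lead <- ev[which.max(Mod(ev))]
  if (abs(Im(lead)) > 1e-8 * max(1, Mod(lead))) {
    stop("leading eigenvalue of the effective competition matrix is not real",
         call. = FALSE)
  }
  (Re(lead) - 1) / (s - 1)
}

#' Mutualistic overlap matrix of a guild
#'
#' `mu_ij` counts the mutualistic partners shared by species `i` and `j` of
#' the guild (`mu_ii` is the degree of `i`).
#'
#' @param net a [bipartite_network()].
#' @param guild `"P"` or `"A"`.
#' @return symmetric integer matrix.
#' @export
overlap_matrix <- function(net, guild = c("P", "A")) {
  guild <- match.arg(guild)
  a <- net$incidence
  if (guild == "P") tcrossprod(a) else crossprod(a)
}

#' Critical competition of a guild
#'
#' The threshold on effective interspecific competition below which mutualism
#' increases structural stability, computed from the mutualistic overlap:
#' `rho_c = sum_ij mu_ij / (S * sum_i mu_ii)`. Depends only on the binary
#' incidence. Equals 1 on a complete network and `1/S` on a perfect matching.
#'
#' @param net a [bipartite_network()].
#' @param guild `"P"` or `"A"`.
#' @return dimensionless critical competition.
#' @export
rho_c <- function(net, guild = c("P", "A")) {
  guild <- match.arg(guild)
  mu <- overlap_matrix(net, guild)
  denom <- sum(diag(mu))
  if (denom == 0) {
    stop("guild has no mutualistic links: critical competition undefined",
         call. = FALSE)
  }
  sum(mu) / (nrow(mu) * denom)
}

#' Regime distance between critical and effective competition
#'
#' `D = (rho_c - rho_eff) / rho_c`, positive when mutualism favours structural
#' stability (`rho_eff < rho_c`) and negative when it is detrimental. Values
#' outside `[-1, 1]` are reported with a warning (and flagged via the
#' `clamped` attribute) but returned unclamped.
#'
#' @param rho_c critical competition (must be positive).
#' @param rho_eff effective interspecific competition.
#' @return dimensionless regime distance.
#' @export
regime_distance <- function(rho_c, rho_eff) {
  if (any(rho_c <= 0)) stop("rho_c must be positive", call. = FALSE)
  d <- (rho_c - rho_eff) / rho_c
  if (any(d < -1 | d > 1)) {
    warning("regime distance outside [-1, 1]")
    attr(d, "clamped") <- TRUE
  }
  d
}

#' Effective biodiversity scale
#'
#' `S_eff = (1 - rho_eff) / rho_eff`, the natural number-of-species scale set
#' by the effective competition.
#'
#' @param rho_eff effective competition in `(0, 1)`.
#' @return nonnegative scalar.
#' @export
s_eff <- function(rho_eff) {
  if (any(rho_eff <= 0 | rho_eff >= 1)) {
    stop("rho_eff must lie in (0, 1)", call. = FALSE)
  }
  (1 - rho_eff) / rho_eff
}

#' Analytic critical perturbation
#'
#' Predicted critical amplitude of uniform growth-rate perturbations,
#' `Delta_c = (1/eta') (S_eff / (S + S_eff) - eta_0)` with
#' `S_eff = (1 - rho_eff)/rho_eff`. `eta'` and `eta_0` (perturbation
#' propagation and baseline vulnerability) are supplied by the caller or
#' obtained with [calibrate_delta_c()]; the default `(1, 0)` yields an
#' uncalibrated monotone score of structural stability.
#'
#' @param s guild richness (vectorized).
#' @param rho_eff effective competition in `(0, 1)` (vectorized).
#' @param eta_prime,eta_0 calibration coefficients (`eta_prime > 0`).
#' @return predicted critical perturbation amplitude(s).
#' @examples
#' predict_delta_c(10, 0.1) # 9/19
#' @export
predict_delta_c <- function(s, rho_eff, eta_prime = 1, eta_0 = 0) {
  if (eta_prime <= 0) stop("eta_prime must be positive", call. = FALSE)
  se <- s_eff(rho_eff)
  (se / (s + se) - eta_0) / eta_prime
}

#' Perturb growth rates uniformly
#'
#' `alpha_i(Delta) = alpha_i (1 + Delta r_i)` with fresh i.i.d.
#' `r_i ~ U(-1, 1)` per call. At `Delta = 1` a growth rate can be driven to
#' zero; `Delta = 0` returns the baseline exactly.
#'
#' @param alpha baseline growth rates.
#' @param delta perturbation amplitude in `[0, 1]`.
#' @return perturbed growth rates, within `alpha * [1 - delta, 1 + delta]`.
#' @export
perturb_growth_rates <- function(alpha, delta) {
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]", call. = FALSE)
  if (delta == 0) return(alpha)
  alpha * (1 + delta * runif(length(alpha), -1, 1))
}

#' Extinction fraction under growth-rate perturbations
#'
#' For each amplitude, draws `n_draws` independent uniform growth-rate
#' perturbations of the steady state, integrates to the new steady state, and
#' reports the fraction of runs in which at least one species went extinct.
#'
#' @param comm an `ecoevo_community` at steady state `state`.
#' @param state matching steady [community_state()].
#' @param deltas perturbation amplitudes.
#' @param n_draws Monte-Carlo draws per amplitude.
#' @param seed seed; draw-level seeds are derived per amplitude and draw.
#' @param control a [steady_state_control()].
#' @return tibble with columns `delta`, `fraction`, `n_draws`.
#' @export
extinction_fraction_curve <- function(comm, state, deltas, n_draws = 50,
                                      seed = 1,
                                      control = steady_state_control()) {
  fractions <- vapply(seq_along(deltas), function(i) {
    ext <- vapply(seq_len(n_draws), function(j) {
      set.seed(derive_seed(seed, "extinction", i, j))
      ap <- perturb_growth_rates(comm$alpha_p, deltas[i])
      aa <- perturb_growth_rates(comm$alpha_a, deltas[i])
      res <- tryCatch(
        integrate_to_steady_state(comm, state, ap, aa, control),
        ecoevonet_divergence = function(e) {
          stop(sprintf("integration diverged at delta = %g, draw %d: %s",
                       deltas[i], j, conditionMessage(e)), call. = FALSE)
        }
      )
      length(res$extinct_plants) + length(res$extinct_animals) > 0
    }, logical(1))
    mean(ext)
  }, numeric(1))
  tibble::tibble(delta = deltas, fraction = fractions, n_draws = n_draws)
}

default_delta_grid <- function(n = 40, lo = 0.005, hi = 1) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Numerical critical perturbation
#'
#' Scans an ascending amplitude grid for the smallest amplitude whose
#' extinction fraction reaches `threshold` (with `threshold = 0` meaning any
#' observed extinction), then refines by one bisection level between the
#' bracketing grid points. If no grid point reaches the threshold the largest
#' grid amplitude is returned with attribute `upper_bound = TRUE` (the system
#' is more stable than the grid maximum).
#'
#' @param comm an `ecoevo_community` at steady state `state`.
#' @param state matching steady [community_state()].
#' @param grid ascending amplitudes in `(0, 1]`; default 40 log-spaced points
#'   in `[0.005, 1]`.
#' @param n_draws Monte-Carlo draws per amplitude.
#' @param threshold extinction-fraction threshold (default 0.5).
#' @param seed seed for the perturbation draws.
#' @param control a [steady_state_control()].
#' @return the estimated critical amplitude, with attributes `upper_bound`
#'   (logical) and `curve` (the tibble of evaluated fractions).
#' @export
estimate_delta_c_numeric <- function(comm, state, grid = default_delta_grid(),
                                     n_draws = 50, threshold = 0.5, seed = 1,
                                     control = steady_state_control()) {
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid > 1)) {
    stop("grid must be strictly ascending within (0, 1]", call. = FALSE)
  }
  hit <- function(frac) if (threshold > 0) frac >= threshold else frac > 0
  evaluated <- list()
  frac_at <- function(delta, key) {
    f <- extinction_fraction_curve(comm, state, delta, n_draws,
                                   seed = derive_seed(seed, "deltac", key),
                                   control = control)$fraction
    evaluated[[length(evaluated) + 1]] <<- c(delta = delta, fraction = f)
    f
  }
  result <- NULL
  for (i in seq_along(grid)) {
    f <- frac_at(grid[i], i)
    if (hit(f)) {
      if (i == 1) {
        result <- grid[1]
      } else {
        mid <- sqrt(grid[i - 1] * grid[i]) # log-scale bisection
        fm <- frac_at(mid, -i)
        result <- if (hit(fm)) mid else grid[i]
      }
      break
    }
  }
  curve <- dplyr::arrange(
    tibble::as_tibble(do.call(rbind, evaluated)), .data$delta)
  upper <- is.null(result)
  if (upper) result <- grid[length(grid)]
  structure(result, upper_bound = upper, curve = curve)
}

#' Calibrate the analytic critical perturbation
#'
#' Least-squares fit of the coefficients `(eta_prime, eta_0)` of
#' [predict_delta_c()] so that `Delta_c = (1/eta') (x - eta_0)` best matches
#' numerically estimated critical perturbations, where
#' `x = S_eff / (S + S_eff)` of the least stable guild.
#'
#' @param data data frame with columns `s_frac` (the `x` above) and
#'   `delta_c_num` (numerical estimates), one row per system.
#' @return list with `eta_prime`, `eta_0`, and the underlying `lm` fit.
#' @export
calibrate_delta_c <- function(data) {
  stopifnot(all(c("s_frac", "delta_c_num") %in% names(data)), nrow(data) >= 3)
  fit <- lm(delta_c_num ~ s_frac, data = data)
  slope <- coef(fit)[["s_frac"]]
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration failed: non-positive slope of delta_c on s_frac",
         call. = FALSE)
  }
  list(eta_prime = 1 / slope,
       eta_0 = -coef(fit)[["(Intercept)"]] / slope,
       fit = fit)
}

#' Guild-level predictor of structural stability
#'
#' `min` over guilds of `S_eff / (S + S_eff)`: the system-level regressor used
#' by [calibrate_delta_c()] and, rescaled by `(eta_prime, eta_0)`, the
#' analytic critical perturbation.
#'
#' @param comm an `ecoevo_community`.
#' @param state steady state for the linearization.
#' @return scalar in `(0, 1)`.
#' @export
delta_c_regressor <- function(comm, state) {
  frac <- function(guild, s) {
    re <- rho_eff(effective_competition(comm, state, guild))
    se <- s_eff(re)
    se / (s + se)
  }
  min(frac("P", length(comm$alpha_p)), frac("A", length(comm$alpha_a)))
}

#' Bundle of structural-stability metrics
#'
#' Effective and critical competition, regime distance, effective biodiversity
#' scale, and analytic critical perturbation per guild, plus the system-level
#' `delta_c = min` over guilds. Metrics whose preconditions fail on a
#' degenerate system (single-species guild, guild without links, effective
#' competition outside `(0, 1)`) are returned as `NA`.
#'
#' @param comm an `ecoevo_community`.
#' @param state steady [community_state()].
#' @param eta_prime,eta_0 coefficients for the analytic critical perturbation.
#' @return one-row tibble.
#' @export
stability_summary <- function(comm, state, eta_prime = 1, eta_0 = 0) {
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  re_p <- safely(rho_eff(effective_competition(comm, state, "P")))
  re_a <- safely(rho_eff(effective_competition(comm, state, "A")))
  rc_p <- safely(rho_c(comm$network, "P"))
  rc_a <- safely(rho_c(comm$network, "A"))
  sp <- length(comm$alpha_p)
  sa <- length(comm$alpha_a)
  dc_p <- safely(predict_delta_c(sp, re_p, eta_prime, eta_0))
  dc_a <- safely(predict_delta_c(sa, re_a, eta_prime, eta_0))
  tibble::tibble(
    rho_eff_p = re_p, rho_eff_a = re_a,
    rho_c_p = rc_p, rho_c_a = rc_a,
    d_p = safely(suppressWarnings(regime_distance(rc_p, re_p))),
    d_a = safely(suppressWarnings(regime_distance(rc_a, re_a))),
    s_eff_p = safely(s_eff(re_p)), s_eff_a = safely(s_eff(re_a)),
    delta_c_p = dc_p, delta_c_a = dc_a,
    delta_c = if (all(is.na(c(dc_p, dc_a)))) NA_real_ else
      min(c(dc_p, dc_a), na.rm = TRUE)
  )
}
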