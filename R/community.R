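#' Meta-parameters of the mutualistic community model
#'
#' Defaults parameterize a weak-mutualistic facultative regime: mutualistic
#' strength `gamma0 = 0.15`, handling time `h = 0.1` (so the maximum
#' mutualistic benefit per species is `1/h = 10`), intraspecific competition
#' `beta0 = 1`, and a prescribed equilibrium abundance `n_star = 1` for every
#' species. Each realized parameter is jittered uniformly within a relative
#' half-width `epsilon` (10% by default) of its meta-value, except the
#' interspecific competition `rho`, which is held exact because it is the
#' swept control parameter.
#'
#' @param rho interspecific within-guild competition, in `(0, beta0)`.
#' @param gamma0 mean mutualistic interaction strength.
#' @param h handling time (saturation) meta-parameter.
#' @param beta0 intraspecific competition.
#' @param epsilon relative half-width of the uniform parameter noise.
#' @param n_star target equilibrium abundance for all species.
#' @param extinction_threshold abundance below which a species is removed.
#' @param jitter_h also jitter per-species handling times by `epsilon`.
#' @param feasibility_retries redraws of the stochastic factors allowed before
#'   assembly is declared infeasible.
#' @return a list of class `meta_parameters`.
#' @export
meta_parameters <- function(rho, gamma0 = 0.15, h = 0.1, beta0 = 1,
                            epsilon = 0.1, n_star = 1,
                            extinction_threshold = 1e-8,
                            jitter_h = TRUE, feasibility_retries = 100L) {
  stopifnot(rho > 0, beta0 > rho, gamma0 >= 0, h >= 0,
            epsilon >= 0, epsilon < 1, n_star > 0, extinction_threshold > 0)
  structure(
    list(rho = rho, gamma0 = gamma0, h = h, beta0 = beta0, epsilon = epsilon,
         n_star = n_star, extinction_threshold = extinction_threshold,
         jitter_h = jitter_h,
         feasibility_retries = as.integer(feasibility_retries)),
    class = "meta_parameters"
  )
}

new_community <- function(network, beta_p, beta_a, gamma_p, gamma_a,
                          alpha_p, alpha_a, h_p, h_a, meta, seed) {
  structure(
    list(network = network, beta_p = beta_p, beta_a = beta_a,
         gamma_p = gamma_p, gamma_a = gamma_a,
         alpha_p = alpha_p, alpha_a = alpha_a, h_p = h_p, h_a = h_a,
         meta = meta, seed = seed),
    class = "ecoevo_community"
  )
}

#' @export
print.ecoevo_community <- function(x, ...) {
  cat(sprintf(
    "<ecoevo_community> %d plants + %d animals, rho = %g, gamma0 = %g\n",
    length(x$alpha_p), length(x$alpha_a), x$meta$rho, x$meta$gamma0
  ))
  invisible(x)
}

#' Community state
#'
#' Abundance vectors for both guilds at a point in time. Species are alive by
#' presence: extinct species are removed from state and community alike.
#'
#' @param n_p,n_a named nonnegative abundance vectors (names = species ids).
#' @param time integration time attained.
#' @return a list of class `community_state`.
#' @export
community_state <- function(n_p, n_a, time = 0) {
  if (any(n_p < 0) || any(n_a < 0)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  structure(list(n_p = n_p, n_a = n_a, time = time), class = "community_state")
}

#' Assemble a feasible community on a network
#'
#' Draws the stochastic parameters and solves for the intrinsic growth rates
#' so that the prescribed abundance `n_star` is an exact interior fixed point.
#' Competition is mean-field within guilds,
#' `beta_ij = (rho + delta_ij (beta0 - rho)) b_ij`, and mutualism is supported
#' exactly on the network, `gamma_ik = a_ik gamma0 c_ik`, with `b_ij`, `c_ik`
#' i.i.d. uniform on `[1 - epsilon, 1 + epsilon]` (independently for the
#' plant-side and animal-side strengths of each link). Growth rates are then
#' fixed by the equilibrium balance
#' `alpha_i = sum_j beta_ij n* - (sum_k gamma_ik n*) / (1 + h_i sum_l gamma_il n*)`.
#' If any `alpha_i <= 0` the stochastic factors are redrawn, up to
#' `meta$feasibility_retries` times.
#'
#' @param net a [bipartite_network()].
#' @param meta a [meta_parameters()] object.
#' @param seed integer seed for the stochastic factors.
#' @return an `ecoevo_community`; its baseline growth rates are treated as
#'   immutable for the rest of the community's life.
#' @examples
#' net <- generate_random_network(6, 6, 0.3, seed = 1)
#' comm <- assemble_community(net, meta_parameters(rho = 0.1), seed = 2)
#' max(abs(unlist(community_derivatives(comm, equilibrium_state(comm)))))
#' @export
assemble_community <- function(net, meta, seed) {
  sp <- n_plants(net)
  sa <- n_animals(net)
  set.seed(as.integer(seed))
  for (try in seq_len(meta$feasibility_retries)) {
    draw <- function(n) runif(n, 1 - meta$epsilon, 1 + meta$epsilon)
    beta_p <- (matrix(meta$rho, sp, sp) +
                 diag(meta$beta0 - meta$rho, sp)) * matrix(draw(sp * sp), sp, sp)
    beta_a <- (matrix(meta$rho, sa, sa) +
                 diag(meta$beta0 - meta$rho, sa)) * matrix(draw(sa * sa), sa, sa)
    gamma_p <- net$incidence * meta$gamma0 * matrix(draw(sp * sa), sp, sa)
    gamma_a <- t(net$incidence) * meta$gamma0 * matrix(draw(sa * sp), sa, sp)
    h_p <- if (meta$jitter_h) meta$h * draw(sp) else rep(meta$h, sp)
    h_a <- if (meta$jitter_h) meta$h * draw(sa) else rep(meta$h, sa)
    ns <- meta$n_star
    gp_tot <- rowSums(gamma_p) * ns
    ga_tot <- rowSums(gamma_a) * ns
    alpha_p <- rowSums(beta_p) * ns - gp_tot / (1 + h_p * gp_tot)
    alpha_a <- rowSums(beta_a) * ns - ga_tot / (1 + h_a * ga_tot)
    if (all(alpha_p > 0) && all(alpha_a > 0)) {
      names(alpha_p) <- net$plant_ids
      names(alpha_a) <- net$animal_ids
      return(new_community(net, beta_p, beta_a, gamma_p, gamma_a,
                           alpha_p, alpha_a, h_p, h_a, meta, seed))
    }
  }
  stop(sprintf(
    "assembly infeasible: no positive growth-rate solution in %d redraws",
    meta$feasibility_retries
  ), call. = FALSE)
}

#' Equilibrium state of a freshly assembled community
#'
#' @param comm an `ecoevo_community`.
#' @return the prescribed fixed point `N = n_star` as a [community_state()].
#' @export
equilibrium_state <- function(comm) {
  ns <- comm$meta$n_star
  community_state(
    setNames(rep(ns, length(comm$alpha_p)), comm$network$plant_ids),
    setNames(rep(ns, length(comm$alpha_a)), comm$network$animal_ids)
  )
}

#' Time derivatives of the community dynamics
#'
#' Evaluates `dN_i/dt = N_i (alpha_i - sum_j beta_ij N_j +
#' sum_k gamma_ik N_k / (1 + h_i sum_l gamma_il N_l))` for plants, and
#' symmetrically for animals.
#'
#' @param comm an `ecoevo_community`.
#' @param state a [community_state()] matching the community's dimensions.
#' @param alpha_p,alpha_a optional growth-rate overrides (e.g. environmental
#'   perturbations of the baseline).
#' @return list with numeric vectors `dn_p`, `dn_a`.
#' @export
community_derivatives <- function(comm, state,
                                  alpha_p = comm$alpha_p,
                                  alpha_a = comm$alpha_a) {
  if (length(state$n_p) != length(comm$alpha_p) ||
      length(state$n_a) != length(comm$alpha_a)) {
    stop("state dimensions do not match community", call. = FALSE)
  }
  if (any(state$n_p < 0) || any(state$n_a < 0)) {
    stop("negative abundances violate the state contract", call. = FALSE)
  }
  np <- state$n_p
  na <- state$n_a
  gp <- as.vector(comm$gamma_p %*% na)
  ga <- as.vector(comm$gamma_a %*% np)
  list(
    dn_p = np * (alpha_p - as.vector(comm$beta_p %*% np) +
                   gp / (1 + comm$h_p * gp)),
    dn_a = na * (alpha_a - as.vector(comm$beta_a %*% na) +
                   ga / (1 + comm$h_a * ga))
  )
}

#' Steady-state solver settings
#'
#' Convergence requires the relative derivative
#' `max_i |dN_i/dt| / max(N_i, extinction_threshold)` to stay below `rel_tol`
#' across a window of `window` time units; integration is abandoned at
#' `t_max`.
#'
#' @param rel_tol relative derivative tolerance.
#' @param window sustain window (time units).
#' @param t_chunk initial chunk length between convergence checks (grows
#'   geometrically up to `t_chunk_max`).
#' @param t_chunk_max largest chunk length.
#' @param t_max maximum integration horizon.
#' @param rtol,atol solver (lsoda) tolerances.
#' @return a list of class `steady_state_control`.
#' @export
steady_state_control <- function(rel_tol = 1e-9, window = 1, t_chunk = 5,
                                 t_chunk_max = 160, t_max = 5000,
                                 rtol = 1e-8, atol = 1e-12) {
  structure(list(rel_tol = rel_tol, window = window, t_chunk = t_chunk,
                 t_chunk_max = t_chunk_max, t_max = t_max,
                 rtol = rtol, atol = atol),
            class = "steady_state_control")
}

pack_parms <- function(comm, alpha_p, alpha_a) {
  c(length(alpha_p), length(alpha_a),
    as.vector(t(comm$beta_p)), as.vector(t(comm$beta_a)),
    as.vector(t(comm$gamma_p)), as.vector(t(comm$gamma_a)),
    alpha_p, alpha_a, comm$h_p, comm$h_a)
}

rel_residual <- function(comm, n, alpha_p, alpha_a, thr) {
  sp <- length(comm$alpha_p)
  st <- community_state(pmax(n[seq_len(sp)], 0),
                        pmax(n[-seq_len(sp)], 0))
  d <- community_derivatives(comm, st, alpha_p, alpha_a)
  dv <- c(d$dn_p, d$dn_a)
  max(abs(dv) / pmax(c(st$n_p, st$n_a), thr))
}

subset_community <- function(comm, keep_p, keep_a) {
  net <- bipartite_network(
    comm$network$incidence[keep_p, keep_a, drop = FALSE],
    comm$network$plant_ids[keep_p], comm$network$animal_ids[keep_a]
  )
  new_community(net,
                comm$beta_p[keep_p, keep_p, drop = FALSE],
                comm$beta_a[keep_a, keep_a, drop = FALSE],
                comm$gamma_p[keep_p, keep_a, drop = FALSE],
                comm$gamma_a[keep_a, keep_p, drop = FALSE],
                comm$alpha_p[keep_p], comm$alpha_a[keep_a],
                comm$h_p[keep_p], comm$h_a[keep_a],
                comm$meta, comm$seed)
}

integrate_once <- function(comm, n0, alpha_p, alpha_a, control) {
  .Call(eem_set_parms, pack_parms(comm, alpha_p, alpha_a))
  thr <- comm$meta$extinction_threshold
  t <- 0
  chunk <- control$t_chunk
  n <- n0
  res <- rel_residual(comm, n, alpha_p, alpha_a, thr)
  if (res < control$rel_tol) return(list(n = pmax(n, 0), time = 0, converged = TRUE))
  while (t < control$t_max) {
    tend <- min(t + chunk, control$t_max)
    times <- unique(c(t, max(t, tend - control$window), tend))
    out <- deSolve::lsoda(n, times, func = "eem_derivs", parms = NULL,
                          dllname = "ecoevonet", rtol = control$rtol,
                          atol = control$atol)
    if (nrow(out) < length(times)) { # solver failure
      break
    }
    n_mid <- pmax(out[nrow(out) - 1, -1], 0)
    n <- pmax(out[nrow(out), -1], 0)
    # parameters must be re-staged in case a nested call re-used the buffer
    .Call(eem_set_parms, pack_parms(comm, alpha_p, alpha_a))
    r_mid <- rel_residual(comm, n_mid, alpha_p, alpha_a, thr)
    r_end <- rel_residual(comm, n, alpha_p, alpha_a, thr)
    if (r_mid < control$rel_tol && r_end < control$rel_tol) {
      return(list(n = n, time = tend, converged = TRUE))
    }
    t <- tend
    chunk <- min(chunk * 2, control$t_chunk_max)
  }
  list(n = n, time = t, converged = FALSE)
}

#' Integrate the community dynamics to a steady state
#'
#' Runs the saturating Lotka-Volterra dynamics (adaptive, stiffness-switching
#' lsoda with a compiled derivative) until the steady-state criterion of
#' [steady_state_control()] holds, then prunes species whose abundance fell
#' below the extinction threshold and re-integrates the reduced system until
#' the composition is stable.
#'
#' @param comm an `ecoevo_community`.
#' @param state a nonnegative starting [community_state()].
#' @param alpha_p,alpha_a optional growth-rate overrides (perturbed rates);
#'   defaults are the community's baseline rates.
#' @param control a [steady_state_control()].
#' @return list with elements `community` (pruned), `state` (steady state),
#'   `extinct_plants`, `extinct_animals` (labels removed), `collapsed`
#'   (a guild lost all species), `converged`, `time`.
#'   Non-convergence signals a classed error (`ecoevonet_divergence`) carrying
#'   the last state.
#' @export
integrate_to_steady_state <- function(comm, state,
                                      alpha_p = comm$alpha_p,
                                      alpha_a = comm$alpha_a,
                                      control = steady_state_control()) {
  if (any(state$n_p < 0) || any(state$n_a < 0)) {
    stop("starting abundances must be nonnegative", call. = FALSE)
  }
  thr <- comm$meta$extinction_threshold
  extinct_p <- character()
  extinct_a <- character()
  total_time <- 0
  repeat {
    n0 <- c(state$n_p, state$n_a)
    res <- integrate_once(comm, n0, alpha_p, alpha_a, control)
    total_time <- total_time + res$time
    sp <- length(comm$alpha_p)
    n_p <- setNames(res$n[seq_len(sp)], comm$network$plant_ids)
    n_a <- setNames(res$n[-seq_len(sp)], comm$network$animal_ids)
    if (!res$converged) {
      cond <- structure(
        class = c("ecoevonet_divergence", "error", "condition"),
        list(message = sprintf(
          "dynamics did not reach steady state within t = %g", control$t_max),
          call = sys.call(-1),
          state = community_state(n_p, n_a, total_time))
      )
      stop(cond)
    }
    dead_p <- n_p < thr
    dead_a <- n_a < thr
    if (!any(dead_p) && !any(dead_a)) {
      return(list(community = comm,
                  state = community_state(n_p, n_a, total_time),
                  extinct_plants = extinct_p, extinct_animals = extinct_a,
                  collapsed = FALSE, converged = TRUE, time = total_time))
    }
    extinct_p <- c(extinct_p, names(n_p)[dead_p])
    extinct_a <- c(extinct_a, names(n_a)[dead_a])
    if (all(dead_p) || all(dead_a)) {
      return(list(community = comm, state = community_state(n_p, n_a, total_time),
                  extinct_plants = extinct_p, extinct_animals = extinct_a,
                  collapsed = TRUE, converged = TRUE, time = total_time))
    }
    keep_p <- !dead_p
    keep_a <- !dead_a
    comm <- subset_community(comm, keep_p, keep_a)
    alpha_p <- alpha_p[keep_p]
    alpha_a <- alpha_a[keep_a]
    state <- community_state(n_p[keep_p], n_a[keep_a])
  }
}

#' Community-level diversity and biomass metrics
#'
#' @param state a [community_state()].
#' @return one-row tibble with `richness` (species with positive abundance in
#'   both guilds pooled), `effective_diversity` (exponential of the Shannon
#'   entropy of biomass proportions, the "true diversity"), and
#'   `total_biomass`.
#' @examples
#' community_metrics(community_state(c(a = 0.75), c(b = 0.25)))
#' @export
community_metrics <- function(state) {
  n <- c(state$n_p, state$n_a)
  n <- n[n > 0]
  if (length(n) == 0) {
    return(tibble::tibble(richness = 0, effective_diversity = 0,
                          total_biomass = 0))
  }
  p <- n / sum(n)
  tibble::tibble(
    richness = length(n),
    effective_diversity = exp(-sum(p * log(p))),
    total_biomass = sum(n)
  )
}

#' Write a community snapshot
#'
#' Writes a per-species table (guild, id, alpha, abundance) and the network
#' edge list next to it.
#'
#' @param comm an `ecoevo_community`.
#' @param state matching [community_state()].
#' @param path base path; `<path>_species.csv` and `<path>_edges.csv` are
#'   written.
#' @return tibble of the species table, invisibly.
#' @export
write_community_snapshot <- function(comm, state, path) {
  species <- tibble::tibble(
    guild = c(rep("P", length(state$n_p)), rep("A", length(state$n_a))),
    id = c(names(state$n_p), names(state$n_a)),
    alpha = c(comm$alpha_p, comm$alpha_a),
    abundance = c(state$n_p, state$n_a)
  )
  write.csv(species, paste0(path, "_species.csv"), row.names = FALSE,
            quote = FALSE)
  write_edge_list(comm$network, paste0(path, "_edges.csv"))
  invisible(species)
}

#' Read a community snapshot written by [write_community_snapshot()]
#'
#' @param path base path used when writing.
#' @return list with tibbles `species` and `edges`.
#' @export
read_community_snapshot <- function(path) {
  list(
    species = tibble::as_tibble(
      read.csv(paste0(path, "_species.csv"), stringsAsFactors = FALSE)),
    edges = tibble::as_tibble(
      read.csv(paste0(path, "_edges.csv"), stringsAsFactors = FALSE))
  )
}
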