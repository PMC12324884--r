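#' Configuration of the eco-evolutionary loop
#'
#' @param p probability that an evolutionary event is a link swap.
#' @param q probability of link creation given the event is not a swap (so
#'   kinds have probabilities `p`, `(1-p)q`, `(1-p)(1-q)` for swap, create,
#'   delete).
#' @param delta environmental perturbation amplitude in `[0, 1]`, applied as
#'   fresh uniform multiplicative noise on the immutable assembly-time growth
#'   rates at every step (perturbations do not compound).
#' @param selection if `TRUE`, an event is accepted only when the focal
#'   species' equilibrium biomass strictly increases (a focal species that
#'   goes extinct is rejected); if `FALSE` all events are accepted.
#' @param halt_window stop once this many consecutive substitutions have
#'   passed without any extinction (evolutionary persistence).
#' @param max_substitutions hard cap on accepted events.
#' @param record_every record metrics every this many substitutions (plus both
#'   endpoints).
#' @param seed integer seed; a trajectory is fully reproducible from it.
#' @param nodf_null null-ensemble size for the `nodf_c` column of records
#'   (0 skips it).
#' @param eta_prime,eta_0 coefficients for the analytic critical perturbation
#'   reported in records.
#' @param max_mutation_factor safety cap: at most
#'   `max_mutation_factor * max(1, max_substitutions)` proposed mutations.
#' @param control a [steady_state_control()].
#' @return a list of class `evolution_config`.
#' @export
evolution_config <- function(p = 0.5, q = 0.5, delta = 0, selection = TRUE,
                             halt_window = 350, max_substitutions = 2000,
                             record_every = 25, seed = 1, nodf_null = 100,
                             eta_prime = 1, eta_0 = 0,
                             max_mutation_factor = 20,
                             control = steady_state_control()) {
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1, delta >= 0, delta <= 1,
            halt_window >= 0, max_substitutions >= 0,
            record_every >= 1, max_mutation_factor >= 1)
  structure(
    list(p = p, q = q, delta = delta, selection = isTRUE(selection),
         halt_window = halt_window, max_substitutions = max_substitutions,
         record_every = record_every, seed = as.integer(seed),
         nodf_null = nodf_null, eta_prime = eta_prime, eta_0 = eta_0,
         max_mutation_factor = max_mutation_factor, control = control),
    class = "evolution_config"
  )
}

focal_links <- function(net, guild, focal) {
  if (guild == "P") {
    net$animal_ids[net$incidence[focal, ] == 1]
  } else {
    net$plant_ids[net$incidence[, focal] == 1]
  }
}

focal_nonpartners <- function(net, guild, focal) {
  if (guild == "P") {
    net$animal_ids[net$incidence[focal, ] == 0]
  } else {
    net$plant_ids[net$incidence[, focal] == 0]
  }
}

#' Propose an evolutionary event
#'
#' Picks a focal species uniformly over all present species of both guilds and
#' an event kind with probabilities `(p, (1-p)q, (1-p)(1-q))` for
#' (swap, create, delete). A swap re-targets a uniformly chosen existing link
#' of the focal species to a uniformly chosen current non-partner (the focal
#' end stays attached); create adds a link to a uniform non-partner; delete
#' removes a uniform existing link. Kinds infeasible for the drawn species
#' (nothing to swap or delete, or no non-partner to link) are resampled, so
#' realized kind frequencies are conditional on feasibility. Draws come from
#' the current RNG stream.
#'
#' @param net a [bipartite_network()].
#' @param cfg an [evolution_config()] (only `p`, `q` are used).
#' @return a list with `guild`, `focal`, `kind`, `old_partner`, `new_partner`,
#'   or `NULL` when no feasible event exists (degenerate system; halt signal).
#' @export
propose_event <- function(net, cfg) {
  ids <- c(net$plant_ids, net$animal_ids)
  guilds <- c(rep("P", n_plants(net)), rep("A", n_animals(net)))
  # a feasible event exists iff some species has a link or a non-partner,
  # which fails only in pathological single-cell networks
  for (attempt in seq_len(1000L)) {
    i <- sample.int(length(ids), 1)
    guild <- guilds[i]
    focal <- ids[i]
    u <- runif(1)
    kind <- if (u < cfg$p) "swap" else if (u < cfg$p + (1 - cfg$p) * cfg$q) {
      "create"
    } else {
      "delete"
    }
    partners <- focal_links(net, guild, focal)
    others <- focal_nonpartners(net, guild, focal)
    if (kind == "swap" && length(partners) >= 1 && length(others) >= 1) {
      return(list(guild = guild, focal = focal, kind = "swap",
                  old_partner = sample(partners, 1),
                  new_partner = sample(others, 1)))
    }
    if (kind == "create" && length(others) >= 1) {
      return(list(guild = guild, focal = focal, kind = "create",
                  old_partner = NA_character_,
                  new_partner = sample(others, 1)))
    }
    if (kind == "delete" && length(partners) >= 1) {
      return(list(guild = guild, focal = focal, kind = "delete",
                  old_partner = sample(partners, 1),
                  new_partner = NA_character_))
    }
  }
  NULL
}

# Apply an event to the community: update incidence and draw fresh interaction
# strengths (both directional slopes) for new or re-targeted links.
apply_event <- function(comm, event) {
  net <- comm$network
  meta <- comm$meta
  link <- function(plant, animal) {
    i <- match(plant, net$plant_ids)
    k <- match(animal, net$animal_ids)
    c(i = i, k = k)
  }
  set_link <- function(comm, plant, animal, on) {
    ik <- link(plant, animal)
    comm$network$incidence[ik["i"], ik["k"]] <- as.numeric(on)
    if (on) {
      comm$gamma_p[ik["i"], ik["k"]] <-
        meta$gamma0 * runif(1, 1 - meta$epsilon, 1 + meta$epsilon)
      comm$gamma_a[ik["k"], ik["i"]] <-
        meta$gamma0 * runif(1, 1 - meta$epsilon, 1 + meta$epsilon)
    } else {
      comm$gamma_p[ik["i"], ik["k"]] <- 0
      comm$gamma_a[ik["k"], ik["i"]] <- 0
    }
    comm
  }
  pa <- function(partner) {
    if (event$guild == "P") c(event$focal, partner) else c(partner, event$focal)
  }
  if (event$kind %in% c("swap", "delete")) {
    old <- pa(event$old_partner)
    comm <- set_link(comm, old[1], old[2], FALSE)
  }
  if (event$kind %in% c("swap", "create")) {
    new <- pa(event$new_partner)
    comm <- set_link(comm, new[1], new[2], TRUE)
  }
  comm
}

#' One step of the eco-evolutionary process
#'
#' Applies a proposed link mutation, perturbs the growth rates from the
#' immutable assembly baseline with amplitude `delta`, integrates to the new
#' steady state (pruning extinctions), and applies the selection rule: under
#' selection the event is accepted only if the focal species' equilibrium
#' biomass strictly exceeds its pre-event biomass (extinct focal species are
#' rejected); without selection every event is accepted. Rejection restores
#' the pre-event community and state exactly (including the perturbation,
#' which is discarded). Uses the current RNG stream.
#'
#' @param comm an `ecoevo_community` at the steady state `state`.
#' @param state pre-event steady [community_state()].
#' @param cfg an [evolution_config()].
#' @return list with `accepted`, `community`, `state`, `event`,
#'   `n_extinctions` (0 on rejection), `collapsed`, and `reason` (`"halt"`
#'   when no feasible event exists, `"divergence"` when integration failed and
#'   the event was rejected, otherwise `NA`).
#' @export
evolution_step <- function(comm, state, cfg) {
  event <- propose_event(comm$network, cfg)
  if (is.null(event)) {
    return(list(accepted = FALSE, community = comm, state = state,
                event = NULL, n_extinctions = 0L, collapsed = FALSE,
                reason = "halt"))
  }
  cand <- apply_event(comm, event)
  ap <- perturb_growth_rates(cand$alpha_p, cfg$delta)
  aa <- perturb_growth_rates(cand$alpha_a, cfg$delta)
  res <- tryCatch(
    integrate_to_steady_state(cand, state, ap, aa, cfg$control),
    ecoevonet_divergence = function(e) NULL
  )
  if (is.null(res)) {
    return(list(accepted = FALSE, community = comm, state = state,
                event = event, n_extinctions = 0L, collapsed = FALSE,
                reason = "divergence"))
  }
  if (cfg$selection) {
    old_b <- if (event$guild == "P") {
      state$n_p[[event$focal]]
    } else {
      state$n_a[[event$focal]]
    }
    new_ns <- if (event$guild == "P") res$state$n_p else res$state$n_a
    accepted <- event$focal %in% names(new_ns) &&
      new_ns[[event$focal]] > old_b
  } else {
    accepted <- TRUE
  }
  if (!accepted) {
    return(list(accepted = FALSE, community = comm, state = state,
                event = event, n_extinctions = 0L, collapsed = FALSE,
                reason = NA_character_))
  }
  list(accepted = TRUE, community = res$community, state = res$state,
       event = event,
       n_extinctions = length(res$extinct_plants) + length(res$extinct_animals),
       collapsed = res$collapsed, reason = NA_character_)
}

#' Run an eco-evolutionary trajectory
#'
#' Assembles a feasible community on the starting network and iterates
#' [evolution_step()] counting substitutions (accepted events only). The run
#' halts at evolutionary persistence (no extinction over the last
#' `halt_window` substitutions), at `max_substitutions`, on community collapse
#' (a guild losing all species), when no feasible event exists, or when the
#' mutation safety budget is exhausted. Metrics are recorded every
#' `record_every` substitutions and at both endpoints.
#'
#' @param net a starting [bipartite_network()].
#' @param meta a [meta_parameters()].
#' @param cfg an [evolution_config()]; all randomness derives from `cfg$seed`.
#' @return a tibble of class `ecoevo_trajectory`, one row per record, with
#'   community metrics, topology metrics, and stability metrics; attributes
#'   `halt_reason`, `n_mutations`, `n_substitutions`, `config`.
#' @examples
#' \donttest{
#' net <- generate_random_network(8, 8, 0.25, seed = 1)
#' traj <- run_trajectory(net, meta_parameters(rho = 0.05),
#'                        evolution_config(max_substitutions = 10,
#'                                         halt_window = 10, seed = 1,
#'                                         nodf_null = 20))
#' traj
#' }
#' @export
run_trajectory <- function(net, meta, cfg) {
  comm <- assemble_community(net, meta, derive_seed(cfg$seed, "assembly"))
  state <- equilibrium_state(comm)
  records <- list()
  make_record <- function(substitution, mutation, accepted) {
    saved <- .Random.seed
    on.exit(assign(".Random.seed", saved, envir = globalenv()), add = TRUE)
    rec <- dplyr::bind_cols(
      tibble::tibble(substitution = substitution, mutation = mutation,
                     accepted = accepted),
      community_metrics(state),
      topology_summary(comm$network, n_null = cfg$nodf_null,
                       null_seed = derive_seed(cfg$seed, "nodf", substitution)),
      stability_summary(comm, state, cfg$eta_prime, cfg$eta_0)
    )
    records[[length(records) + 1]] <<- rec
  }
  set.seed(derive_seed(cfg$seed, "evolution"))
  make_record(0L, 0L, NA)
  substitution <- 0L
  mutation <- 0L
  last_extinction <- 0L
  last_recorded <- 0L
  halt_reason <- "max_substitutions"
  mutation_budget <- cfg$max_mutation_factor * max(1, cfg$max_substitutions)
  while (substitution < cfg$max_substitutions) {
    if (cfg$halt_window > 0 &&
        substitution - last_extinction >= cfg$halt_window) {
      halt_reason <- "persistence"
      break
    }
    if (mutation >= mutation_budget) {
      halt_reason <- "mutation_budget"
      break
    }
    mutation <- mutation + 1L
    step <- evolution_step(comm, state, cfg)
    if (!is.null(step$reason) && !is.na(step$reason) &&
        step$reason == "halt") {
      halt_reason <- "no_feasible_event"
      break
    }
    if (!step$accepted) next
    substitution <- substitution + 1L
    comm <- step$community
    state <- step$state
    if (step$n_extinctions > 0) last_extinction <- substitution
    if (step$collapsed) {
      halt_reason <- "collapse"
      break
    }
    if (substitution %% cfg$record_every == 0) {
      make_record(substitution, mutation, TRUE)
      last_recorded <- substitution
    }
  }
  if (substitution != last_recorded || substitution == 0L) {
    if (substitution > 0L) make_record(substitution, mutation, TRUE)
  }
  out <- dplyr::bind_rows(records)
  attr(out, "halt_reason") <- halt_reason
  attr(out, "n_mutations") <- mutation
  attr(out, "n_substitutions") <- substitution
  attr(out, "config") <- cfg
  class(out) <- c("ecoevo_trajectory", class(out))
  out
}

#' Write a trajectory and its metadata
#'
#' @param traj an `ecoevo_trajectory`.
#' @param path base path; `<path>.csv` (tidy records) and `<path>.json`
#'   (halt reason, counters, configuration) are written.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), paste0(path, ".csv"), row.names = FALSE,
            quote = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- attr(traj, "config")
    meta <- list(
      halt_reason = attr(traj, "halt_reason"),
      n_mutations = attr(traj, "n_mutations"),
      n_substitutions = attr(traj, "n_substitutions"),
      config = cfg[setdiff(names(cfg), "control")]
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Mutation time-scale of the evolutionary events
#'
#' Converts a per-site per-generation mutation rate into the per-individual
#' and per-generation probabilities of at least one mutation at a locus, and
#' the expected (geometric) waiting time between mutations, supporting the
#' separation of ecological and evolutionary time-scales assumed by the
#' model.
#'
#' @param mu_site per-site per-generation mutation rate.
#' @param locus_bp locus length in base pairs.
#' @param pop_size population size.
#' @return one-row tibble with `p_individual`, `p_generation`,
#'   `expected_wait_generations` (`Inf` when the rate is zero).
#' @examples
#' mutation_timescale(3.6e-9, 1000, 1e4)
#' @export
mutation_timescale <- function(mu_site, locus_bp, pop_size) {
  stopifnot(mu_site >= 0, locus_bp > 0, pop_size > 0)
  p_ind <- 1 - (1 - mu_site)^locus_bp
  p_gen <- 1 - (1 - p_ind)^pop_size
  tibble::tibble(
    p_individual = p_ind,
    p_generation = p_gen,
    expected_wait_generations = if (p_gen > 0) 1 / p_gen else Inf
  )
}
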