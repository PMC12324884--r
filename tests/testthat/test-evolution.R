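test_that("event kinds follow their probabilities when all are feasible", {
  # every species has links and non-partners, so no kind is ever resampled
  inc <- matrix(0, 6, 6)
  for (i in 1:6) inc[i, ((i - 1 + 0:2) %% 6) + 1] <- 1
  net <- bipartite_network(inc)
  cfg <- evolution_config(p = 0.5, q = 0.5, seed = 1)
  set.seed(10)
  kinds <- replicate(10000, propose_event(net, cfg)$kind)
  obs <- table(factor(kinds, levels = c("swap", "create", "delete")))
  chi <- chisq.test(obs, p = c(0.5, 0.25, 0.25))
  expect_gt(chi$p.value, 0.001)

  set.seed(11)
  cfg1 <- evolution_config(p = 1, seed = 1)
  expect_true(all(replicate(200, propose_event(net, cfg1)$kind) == "swap"))
})

test_that("infeasible kinds are resampled, not emitted", {
  # empty incidence: only creation is possible
  net <- bipartite_network(matrix(0, 3, 3))
  cfg <- evolution_config(p = 0.9, q = 0.1, seed = 1)
  set.seed(3)
  evs <- replicate(200, propose_event(net, cfg), simplify = FALSE)
  expect_true(all(vapply(evs, `[[`, "", "kind") == "create"))
  # complete incidence: creation is impossible
  full <- complete_net(3, 3)
  set.seed(4)
  cfgc <- evolution_config(p = 0.05, q = 0.95, seed = 1)
  evs <- replicate(200, propose_event(full, cfgc), simplify = FALSE)
  expect_true(all(vapply(evs, `[[`, "", "kind") %in% c("swap", "delete")))
})

test_that("events edit the incidence and strengths coherently", {
  comm <- small_community(seed = 8, np = 6, na = 6)
  set.seed(5)
  for (i in 1:50) {
    ev <- propose_event(comm$network, evolution_config(seed = 1))
    cand <- apply_event(comm, ev)
    # gamma support matches incidence in both directions
    expect_true(all((cand$gamma_p > 0) == (cand$network$incidence == 1)))
    expect_true(all((cand$gamma_a > 0) == (t(cand$network$incidence) == 1)))
    dL <- sum(cand$network$incidence) - sum(comm$network$incidence)
    expect_equal(dL, switch(ev$kind, swap = 0, create = 1, delete = -1))
    comm <- cand
  }
})

test_that("selection rejects zero-effect changes and rollback is exact", {
  # gamma0 = 0: every link strength is zero, so no event can change biomass
  net <- generate_random_network(5, 5, 0.4, seed = 2)
  comm <- assemble_community(net, meta_parameters(rho = 0.1, gamma0 = 0),
                             seed = 3)
  st <- integrate_to_steady_state(comm, equilibrium_state(comm))$state
  cfg <- evolution_config(delta = 0, selection = TRUE, seed = 1)
  set.seed(6)
  for (i in 1:15) {
    step <- evolution_step(comm, st, cfg)
    expect_false(step$accepted)
    expect_identical(step$community, comm)
    expect_identical(step$state, st)
    expect_equal(step$n_extinctions, 0L)
  }
})

test_that("without selection every event is accepted", {
  comm <- small_community(seed = 9, np = 6, na = 6)
  st <- equilibrium_state(comm)
  cfg <- evolution_config(delta = 0, selection = FALSE, seed = 1)
  set.seed(7)
  for (i in 1:10) {
    step <- evolution_step(comm, st, cfg)
    expect_true(step$accepted)
    comm <- step$community
    st <- step$state
  }
})

test_that("accepted selective events strictly increase focal biomass", {
  comm <- small_community(seed = 10, np = 8, na = 8, rho = 0.15,
                          connectance = 0.25)
  st <- equilibrium_state(comm)
  cfg <- evolution_config(delta = 0, selection = TRUE, seed = 1)
  set.seed(8)
  accepted <- 0
  for (i in 1:60) {
    step <- evolution_step(comm, st, cfg)
    if (step$accepted) {
      guild_old <- if (step$event$guild == "P") st$n_p else st$n_a
      guild_new <- if (step$event$guild == "P") step$state$n_p else step$state$n_a
      expect_gt(guild_new[[step$event$focal]], guild_old[[step$event$focal]])
      accepted <- accepted + 1
      comm <- step$community
      st <- step$state
    }
  }
  expect_gt(accepted, 0)
})

test_that("trajectories record endpoints and keep richness non-increasing", {
  net <- generate_random_network(8, 8, 0.25, seed = 12)
  meta <- meta_parameters(rho = 0.1)
  cfg0 <- evolution_config(max_substitutions = 0, seed = 5, nodf_null = 10)
  t0 <- run_trajectory(net, meta, cfg0)
  expect_equal(nrow(t0), 1)
  expect_equal(t0$substitution, 0L)
  expect_equal(t0$richness, 16)

  cfg <- evolution_config(delta = 0.05, selection = TRUE, halt_window = 40,
                          max_substitutions = 40, record_every = 10,
                          seed = 5, nodf_null = 10)
  traj <- run_trajectory(net, meta, cfg)
  expect_equal(traj$substitution[1], 0L)
  expect_equal(traj$substitution[nrow(traj)], attr(traj, "n_substitutions"))
  expect_true(all(diff(traj$richness) <= 0))
  expect_true(all(diff(traj$substitution) > 0))
})

test_that("substitutions equal mutations under no selection", {
  net <- generate_random_network(6, 6, 0.3, seed = 13)
  cfg <- evolution_config(delta = 0, selection = FALSE, halt_window = 20,
                          max_substitutions = 20, record_every = 10,
                          seed = 2, nodf_null = 10)
  traj <- run_trajectory(net, meta_parameters(rho = 0.05), cfg)
  expect_equal(attr(traj, "n_substitutions"), attr(traj, "n_mutations"))
})

test_that("trajectory files round-trip records and metadata", {
  net <- generate_random_network(6, 6, 0.3, seed = 14)
  cfg <- evolution_config(max_substitutions = 5, halt_window = 5,
                          selection = FALSE, seed = 3, nodf_null = 10)
  traj <- run_trajectory(net, meta_parameters(rho = 0.1), cfg)
  base <- file.path(withr::local_tempdir(), "traj")
  write_trajectory(traj, base)
  back <- utils::read.csv(paste0(base, ".csv"))
  expect_equal(nrow(back), nrow(traj))
  expect_equal(back$richness, traj$richness)
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(meta$n_substitutions, attr(traj, "n_substitutions"))
})

test_that("mutation time-scale arithmetic matches the geometric model", {
  ts <- mutation_timescale(3.6e-9, 1000, 1e4)
  expect_equal(ts$p_individual, 3.6e-6, tolerance = 1e-3)
  ts2 <- mutation_timescale(1e-6 / 1000, 1000, 1e4) # p_individual ~ 1e-6
  expect_equal(ts2$p_generation, 1 - (1 - 1e-6)^1e4, tolerance = 1e-4)
  expect_equal(ts2$expected_wait_generations, 1 / ts2$p_generation)
  z <- mutation_timescale(0, 1000, 1e4)
  expect_equal(z$p_generation, 0)
  expect_equal(z$expected_wait_generations, Inf)
})
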