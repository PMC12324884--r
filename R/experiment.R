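#' Factorial experiment grid
#'
#' The full-factorial design over interspecific competition, environmental
#' perturbation amplitude, selection regime and replicate. Defaults follow the
#' standard sweep: seven competition values, four perturbation amplitudes, two
#' selection regimes and 50 replicates (2800 trajectories).
#'
#' @param rho_values interspecific competition values in `(0, 1)`.
#' @param delta_values perturbation amplitudes in `[0, 1]`. With
#'   `relative_delta = TRUE` these are interpreted as fractions `delta` of the
#'   starting system's analytic critical perturbation (`Delta = delta *
#'   Delta_c`).
#' @param selection_regimes logical vector of selection regimes.
#' @param n_replicates replicates per cell.
#' @param base_seed base seed; per-run seeds derive from it and the cell
#'   coordinates, so adding replicates never reshuffles existing runs.
#' @param relative_delta interpret `delta_values` relative to the analytic
#'   critical perturbation of each starting system.
#' @return a list of class `experiment_grid`.
#' @export
experiment_grid <- function(rho_values = c(0.0125, 0.025, 0.05, 0.075,
                                           0.1, 0.125, 0.15),
                            delta_values = c(0, 0.025, 0.05, 0.1),
                            selection_regimes = c(TRUE, FALSE),
                            n_replicates = 50, base_seed = 1,
                            relative_delta = FALSE) {
  stopifnot(all(rho_values > 0 & rho_values < 1),
            all(delta_values >= 0 & delta_values <= 1),
            n_replicates >= 1)
  structure(
    list(rho_values = rho_values, delta_values = delta_values,
         selection_regimes = selection_regimes,
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed),
         relative_delta = isTRUE(relative_delta)),
    class = "experiment_grid"
  )
}

#' Enumerate the runs of an experiment grid
#'
#' Deterministic enumeration of the full factorial product, with one
#' reproducible derived seed per run.
#'
#' @param grid an [experiment_grid()].
#' @return tibble with columns `rho`, `delta`, `selection`, `replicate`,
#'   `seed`; `nrow` equals the factorial product.
#' @examples
#' nrow(enumerate_grid(experiment_grid())) # 7 * 4 * 2 * 50
#' @export
enumerate_grid <- function(grid) {
  runs <- tidyr::expand_grid(
    rho = grid$rho_values,
    delta = grid$delta_values,
    selection = grid$selection_regimes,
    replicate = seq_len(grid$n_replicates)
  )
  runs$seed <- purrr::pmap_int(runs, function(rho, delta, selection, replicate) {
    derive_seed(grid$base_seed, "run",
                match(rho, grid$rho_values),
                match(delta, grid$delta_values),
                as.integer(selection), replicate)
  })
  runs
}

#' Run an experiment grid of eco-evolutionary trajectories
#'
#' Runs one trajectory per enumerated grid row on the same starting network.
#' Runs are mutually independent (each derives its own seed), so serial and
#' concurrent execution give identical tables. Per-run failures are logged in
#' the `failed`/`message` columns of the attached run table rather than
#' aborting the grid.
#'
#' @param grid an [experiment_grid()].
#' @param net the starting [bipartite_network()] used in every run.
#' @param meta_fn function `rho -> meta_parameters`; defaults to
#'   [meta_parameters()] with the remaining defaults.
#' @param max_substitutions,halt_window,record_every,nodf_null scale overrides
#'   passed to every run's [evolution_config()].
#' @param eta_prime,eta_0 analytic critical perturbation coefficients for
#'   recorded metrics (and for relative-perturbation mode).
#' @param control a [steady_state_control()].
#' @return tibble of trajectory records tagged with `rho`, `delta`,
#'   `selection`, `replicate`, `seed`; attribute `runs` holds the run table
#'   with failure flags.
#' @export
run_grid <- function(grid, net, meta_fn = function(rho) meta_parameters(rho = rho),
                     max_substitutions = 2000, halt_window = 350,
                     record_every = 25, nodf_null = 100,
                     eta_prime = 1, eta_0 = 0,
                     control = steady_state_control()) {
  runs <- enumerate_grid(grid)
  runs$failed <- FALSE
  runs$message <- NA_character_
  out <- vector("list", nrow(runs))
  for (r in seq_len(nrow(runs))) {
    row <- runs[r, ]
    meta <- meta_fn(row$rho)
    delta_abs <- row$delta
    result <- tryCatch({
      if (grid$relative_delta && row$delta > 0) {
        comm0 <- assemble_community(net, meta,
                                    derive_seed(row$seed, "assembly"))
        dc <- predict_delta_c(
          min(length(comm0$alpha_p), length(comm0$alpha_a)),
          rho_eff(effective_competition(comm0, equilibrium_state(comm0), "P")),
          eta_prime, eta_0)
        delta_abs <- min(1, max(0, row$delta * dc))
      }
      cfg <- evolution_config(
        delta = delta_abs, selection = row$selection,
        halt_window = halt_window, max_substitutions = max_substitutions,
        record_every = record_every, seed = row$seed, nodf_null = nodf_null,
        eta_prime = eta_prime, eta_0 = eta_0, control = control)
      traj <- run_trajectory(net, meta, cfg)
      dplyr::bind_cols(
        tibble::tibble(rho = row$rho, delta = row$delta,
                       selection = row$selection, replicate = row$replicate,
                       seed = row$seed,
                       halt_reason = attr(traj, "halt_reason")),
        tibble::as_tibble(traj)
      )
    }, error = function(e) {
      runs$failed[r] <<- TRUE
      runs$message[r] <<- conditionMessage(e)
      NULL
    })
    out[[r]] <- result
  }
  tab <- dplyr::bind_rows(out)
  attr(tab, "runs") <- runs
  tab
}

#' Final state of each trajectory in a grid table
#'
#' @param grid_table output of [run_grid()].
#' @return tibble with one row per run: the last record of each trajectory.
#' @export
final_records <- function(grid_table) {
  grid_table |>
    dplyr::group_by(.data$rho, .data$delta, .data$selection,
                    .data$replicate) |>
    dplyr::slice_max(.data$substitution, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Regress normalized final diversity on predicted structural stability
#'
#' Ordinary least squares of final richness, normalized by starting richness,
#' on the analytic critical perturbation of the starting system, per
#' `(delta, selection)` stratum. A slope near one means the starting
#' structural stability accurately predicts the evolutionary outcome.
#'
#' @param data data frame with columns `delta_c_start` (predictor) and
#'   `diversity_ratio` (final / initial richness), plus optional stratum
#'   columns `delta`, `selection`.
#' @return object of class `ecoevo_regression`: a tibble of per-stratum fits
#'   with [tidy()] and [glance()] methods.
#' @export
regress_diversity_on_stability <- function(data) {
  stopifnot(all(c("delta_c_start", "diversity_ratio") %in% names(data)))
  strata <- intersect(c("delta", "selection"), names(data))
  grouped <- if (length(strata)) {
    dplyr::group_by(data, dplyr::across(dplyr::all_of(strata)))
  } else {
    data
  }
  fits <- grouped |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) stop("need at least 3 points per stratum", call. = FALSE)
      if (sd(d$delta_c_start) == 0) {
        stop("degenerate predictor: no variance in delta_c_start",
             call. = FALSE)
      }
      fit <- lm(diversity_ratio ~ delta_c_start, data = d)
      sm <- summary(fit)
      tibble::tibble(
        slope = coef(fit)[["delta_c_start"]],
        intercept = coef(fit)[["(Intercept)"]],
        slope_stderr = sm$coefficients["delta_c_start", "Std. Error"],
        r_squared = sm$r.squared,
        n_points = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  structure(fits, class = c("ecoevo_regression", class(fits)))
}

#' @export
tidy.ecoevo_regression <- function(x, ...) {
  class(x) <- setdiff(class(x), "ecoevo_regression")
  tibble::as_tibble(x)
}

#' @export
glance.ecoevo_regression <- function(x, ...) {
  tibble::tibble(
    n_strata = nrow(x),
    mean_slope = mean(x$slope),
    mean_r_squared = mean(x$r_squared)
  )
}

#' Power-law exponent of critical competition versus richness
#'
#' Per guild, the OLS slope of `log(rho_c)` on `log(richness)` across a set of
#' networks. For perfect matchings (`rho_c = 1/S`) the exponent is exactly -1.
#' Networks on which `rho_c` is undefined are skipped (and counted).
#'
#' @param networks list of [bipartite_network()] objects (at least 3 usable).
#' @return tibble with one row per guild: `guild`, `exponent`, `intercept`,
#'   `r_squared`, `n_networks`, `n_skipped`.
#' @export
fit_powerlaw_rho_c_vs_richness <- function(networks) {
  per_guild <- function(guild) {
    vals <- purrr::map(networks, function(net) {
      s <- if (guild == "P") n_plants(net) else n_animals(net)
      rc <- tryCatch(rho_c(net, guild), error = function(e) NA_real_)
      c(s = s, rc = rc)
    })
    tab <- do.call(rbind, vals)
    ok <- !is.na(tab[, "rc"])
    tab <- tab[ok, , drop = FALSE]
    if (nrow(tab) < 3) stop("need at least 3 networks with defined rho_c",
                            call. = FALSE)
    if (sd(log(tab[, "s"])) == 0) {
      stop("richness does not vary across networks: slope undefined",
           call. = FALSE)
    }
    fit <- lm(log(tab[, "rc"]) ~ log(tab[, "s"]))
    tibble::tibble(
      guild = guild,
      exponent = coef(fit)[[2]],
      intercept = coef(fit)[[1]],
      r_squared = summary(fit)$r.squared,
      n_networks = nrow(tab),
      n_skipped = sum(!ok)
    )
  }
  dplyr::bind_rows(per_guild("P"), per_guild("A"))
}
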