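#' Bipartite mutualistic network
#'
#' A binary plant-by-animal incidence structure: rows are plants, columns are
#' animals, and `incidence[i, k] == 1` records a mutualistic link between
#' plant `i` and animal `k`. This is the object the evolutionary dynamics
#' rewires.
#'
#' @param incidence binary matrix (plants in rows, animals in columns).
#' @param plant_ids,animal_ids optional character labels; defaults are
#'   `P1..Pn` / `A1..An`. Labels must be unique within and across guilds.
#' @return an object of class `bipartite_network` with fields `incidence`,
#'   `plant_ids`, `animal_ids`.
#' @examples
#' net <- bipartite_network(matrix(c(1, 0, 0, 1), 2, 2))
#' net
#' @export
bipartite_network <- function(incidence, plant_ids = NULL, animal_ids = NULL) {
  incidence <- as.matrix(incidence)
  if (length(incidence) == 0 || nrow(incidence) < 1 || ncol(incidence) < 1) {
    stop("incidence must have at least one plant and one animal", call. = FALSE)
  }
  if (!all(incidence %in% c(0, 1))) {
    stop("incidence entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(incidence) <- "double"
  if (is.null(plant_ids)) plant_ids <- rownames(incidence)
  if (is.null(plant_ids)) plant_ids <- paste0("P", seq_len(nrow(incidence)))
  if (is.null(animal_ids)) animal_ids <- colnames(incidence)
  if (is.null(animal_ids)) animal_ids <- paste0("A", seq_len(ncol(incidence)))
  plant_ids <- as.character(plant_ids)
  animal_ids <- as.character(animal_ids)
  if (length(plant_ids) != nrow(incidence) || length(animal_ids) != ncol(incidence)) {
    stop("label lengths do not match incidence dimensions", call. = FALSE)
  }
  if (anyDuplicated(c(plant_ids, animal_ids)) > 0) {
    stop("species labels must be unique within and across guilds", call. = FALSE)
  }
  dimnames(incidence) <- list(plant_ids, animal_ids)
  structure(
    list(plant_ids = plant_ids, animal_ids = animal_ids, incidence = incidence),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> %d plants x %d animals, %d links (connectance %.4f)\n",
    nrow(x$incidence), ncol(x$incidence), sum(x$incidence),
    sum(x$incidence) / length(x$incidence)
  ))
  invisible(x)
}

n_plants <- function(net) nrow(net$incidence)
n_animals <- function(net) ncol(net$incidence)
n_links <- function(net) sum(net$incidence)

#' Generate a uniformly random bipartite network at exact connectance
#'
#' Places exactly `round(connectance * n_plants * n_animals)` links uniformly
#' at random without replacement, so realized connectance is exact rather than
#' binomial. With `forbid_isolated = TRUE` (the default, appropriate for
#' starting networks) whole networks are resampled until every species has at
#' least one link; species may still lose all links later under evolution.
#'
#' @param n_plants,n_animals guild sizes (positive integers).
#' @param connectance target fraction of realized links in `(0, 1]`.
#' @param seed integer seed; the same seed reproduces the same network.
#' @param forbid_isolated resample until no species has degree zero.
#' @param max_attempts resampling budget for `forbid_isolated`.
#' @return a [bipartite_network()].
#' @examples
#' net <- generate_random_network(10, 12, 0.2, seed = 1)
#' sum(net$incidence) # exactly round(0.2 * 120)
#' @export
generate_random_network <- function(n_plants, n_animals, connectance, seed,
                                    forbid_isolated = TRUE,
                                    max_attempts = 1000L) {
  stopifnot(n_plants >= 1, n_animals >= 1)
  if (!(connectance > 0 && connectance <= 1)) {
    stop("connectance must be in (0, 1]", call. = FALSE)
  }
  L <- round(connectance * n_plants * n_animals)
  if (L < 1) stop("connectance too low: no links to place", call. = FALSE)
  if (forbid_isolated && L < max(n_plants, n_animals)) {
    stop(sprintf(
      "forbid_isolated infeasible: %d links cannot cover %d species",
      L, max(n_plants, n_animals)
    ), call. = FALSE)
  }
  set.seed(as.integer(seed))
  for (attempt in seq_len(max_attempts)) {
    inc <- matrix(0, n_plants, n_animals)
    inc[sample.int(n_plants * n_animals, L)] <- 1
    if (!forbid_isolated ||
        (all(rowSums(inc) >= 1) && all(colSums(inc) >= 1))) {
      return(bipartite_network(inc))
    }
  }
  stop("could not place links without isolated species within attempt budget",
       call. = FALSE)
}

#' Drop species from a network
#'
#' Removes the named species (rows/columns and all their links) atomically.
#' @param net a [bipartite_network()].
#' @param plants,animals character vectors of labels to drop.
#' @return the reduced network.
#' @export
drop_species <- function(net, plants = character(), animals = character()) {
  keep_p <- !(net$plant_ids %in% plants)
  keep_a <- !(net$animal_ids %in% animals)
  if (!any(keep_p) || !any(keep_a)) {
    stop("cannot drop all species of a guild", call. = FALSE)
  }
  bipartite_network(net$incidence[keep_p, keep_a, drop = FALSE],
                    net$plant_ids[keep_p], net$animal_ids[keep_a])
}
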