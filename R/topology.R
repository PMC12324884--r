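#' Shared-partner nestedness of a binary incidence matrix
#'
#' Pairwise shared-partner nestedness: the number of mutualistic partners
#' shared by each within-guild species pair, summed over ordered pairs of both
#' guilds and normalized by the total number of within-guild pairs,
#' \deqn{[\sum_{i<j}\sum_k a_{ik} a_{jk} + \sum_{i<j}\sum_k a_{ki} a_{kj}] /
#'       [S_P(S_P-1)/2 + S_A(S_A-1)/2].}
#' Note this is a raw shared-partner statistic, not the percentage-scaled
#' decreasing-fill NODF of Almeida-Neto et al.; it is zero when no two species
#' of a guild share a partner.
#'
#' @param net a [bipartite_network()].
#' @return nonnegative scalar; 0 (with a warning) when both guilds have a
#'   single species so no pair exists.
#' @export
nestedness_nodf <- function(net) {
  sp <- n_plants(net)
  sa <- n_animals(net)
  pairs <- sp * (sp - 1) / 2 + sa * (sa - 1) / 2
  if (pairs == 0) {
    warning("no within-guild species pairs; nestedness undefined, returning 0")
    return(0)
  }
  a <- net$incidence
  shared_p <- tcrossprod(a)   # plants x plants, shared animal partners
  shared_a <- crossprod(a)    # animals x animals, shared plant partners
  tot <- (sum(shared_p) - sum(diag(shared_p)) +
          sum(shared_a) - sum(diag(shared_a))) / 2
  tot / pairs
}

#' Ecological overlap of mutualistic partner sets
#'
#' Mean Jaccard overlap of partner sets over all within-guild species pairs
#' (both guilds pooled): |shared partners| / |union of partners|, with pairs
#' whose union is empty contributing 0.
#'
#' @param net a [bipartite_network()].
#' @return fraction in `[0, 1]`; 0 with a warning when no pair exists.
#' @export
ecological_overlap <- function(net) {
  guild_overlap <- function(m) {
    s <- nrow(m)
    if (s < 2) return(c(0, 0))
    shared <- tcrossprod(m)
    deg <- rowSums(m)
    uni <- outer(deg, deg, "+") - shared
    frac <- ifelse(uni > 0, shared / uni, 0)
    c(sum(frac[upper.tri(frac)]), s * (s - 1) / 2)
  }
  p <- guild_overlap(net$incidence)
  a <- guild_overlap(t(net$incidence))
  if (p[2] + a[2] == 0) {
    warning("no within-guild species pairs; overlap undefined, returning 0")
    return(0)
  }
  (p[1] + a[1]) / (p[2] + a[2])
}

#' Null-normalized nestedness
#'
#' Nestedness of the network divided by the mean nestedness of a null ensemble
#' of uniformly random bipartite networks with the same guild sizes and the
#' same number of links, so that networks of different size and connectance
#' are comparable.
#'
#' @param net a [bipartite_network()].
#' @param n_null null-ensemble size.
#' @param seed seed for the null ensemble.
#' @return nonnegative scalar; 0 when the null mean is 0.
#' @export
nestedness_nodf_c <- function(net, n_null = 100, seed = 1) {
  obs <- suppressWarnings(nestedness_nodf(net))
  L <- n_links(net)
  if (L == 0) return(0)
  cells <- n_plants(net) * n_animals(net)
  null_vals <- vapply(seq_len(n_null), function(i) {
    set.seed(derive_seed(seed, "nodf-null", i))
    inc <- matrix(0, n_plants(net), n_animals(net))
    inc[sample.int(cells, L)] <- 1
    suppressWarnings(nestedness_nodf(bipartite_network(inc)))
  }, numeric(1))
  m <- mean(null_vals)
  if (m == 0) return(0)
  obs / m
}

#' Degree assortativity over mutualistic links
#'
#' Pearson correlation, across links, of the degree of the plant endpoint and
#' the degree of the animal endpoint. Degenerate cases (no variance on either
#' side, fewer than 2 links) return 0 by contract.
#'
#' @param net a [bipartite_network()].
#' @return correlation in `[-1, 1]`.
#' @export
degree_assortativity <- function(net) {
  idx <- which(net$incidence == 1, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  dp <- rowSums(net$incidence)[idx[, 1]]
  da <- colSums(net$incidence)[idx[, 2]]
  if (sd(dp) == 0 || sd(da) == 0) return(0)
  cor(dp, da)
}

#' Topology summary of a bipartite network
#'
#' One row of the standard topology metrics: guild richness, link count,
#' connectance `L / (S_P * S_A)`, nestedness ([nestedness_nodf()]) and its
#' null-normalized version, ecological overlap, pooled population standard
#' deviation of species degrees, link-endpoint degree assortativity, and the
#' number of connected components of the bipartite graph.
#'
#' @param net a [bipartite_network()].
#' @param n_null,null_seed null-ensemble settings for `nodf_c`; set
#'   `n_null = 0` to skip (returns `NA`).
#' @return a one-row tibble.
#' @examples
#' topology_summary(generate_random_network(8, 8, 0.3, seed = 1))
#' @export
topology_summary <- function(net, n_null = 100, null_seed = 1) {
  deg <- c(rowSums(net$incidence), colSums(net$incidence))
  g <- igraph::graph_from_biadjacency_matrix(net$incidence)
  tibble::tibble(
    richness_p = n_plants(net),
    richness_a = n_animals(net),
    links = n_links(net),
    connectance = n_links(net) / (n_plants(net) * n_animals(net)),
    nodf = suppressWarnings(nestedness_nodf(net)),
    nodf_c = if (n_null > 0) nestedness_nodf_c(net, n_null, null_seed) else NA_real_,
    overlap = suppressWarnings(ecological_overlap(net)),
    degree_sd = sqrt(mean((deg - mean(deg))^2)),
    assortativity = degree_assortativity(net),
    n_components = igraph::count_components(g)
  )
}
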