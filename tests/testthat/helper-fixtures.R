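# Small deterministic fixtures, built in code.

complete_net <- function(np, na) {
  bipartite_network(matrix(1, np, na))
}

matching_net <- function(s) {
  bipartite_network(diag(s))
}

# community on a complete 2x2 network without parameter noise: every alpha
# equals 1.1 - 0.3/1.03 in the mean-field balance
mean_field_2x2 <- function(rho = 0.1) {
  assemble_community(complete_net(2, 2),
                     meta_parameters(rho = rho, epsilon = 0), seed = 1)
}

# modest random community for integration-heavy tests
small_community <- function(seed = 1, np = 10, na = 10, rho = 0.1,
                            connectance = 0.3, ...) {
  net <- generate_random_network(np, na, connectance, seed = seed)
  assemble_community(net, meta_parameters(rho = rho, ...), seed = seed + 1000)
}
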