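# shared fixtures built in code

# simple one-class construct: `n` copies of the ~33 nm unit of the PAP table
fixture_model <- function(n = 3, initial_lc = 30, k0 = 1 / 0.061,
                          x_beta = 0.074, delta_lc = 33.2, mode = "PAP") {
  protein_model(unfolding_unit("dL33.2", delta_lc, k0, x_beta, count = n),
                initial_contour_length = initial_lc, mode = mode)
}

# heteropolyprotein calibration construct: unit of interest + stable marker
fixture_calibration_model <- function(k0 = 1 / 0.061, x_beta = 0.074,
                                      delta_lc = 33.2, initial_lc = 5) {
  units <- rbind(
    unfolding_unit("dL33.2", delta_lc, k0, x_beta),
    unfolding_unit("marker", delta_lc, 0.1, 0.1)
  )
  protein_model(units, initial_contour_length = initial_lc, mode = "PAP")
}

# weighted path-graph network 1-2-...-n with given weights (default unit)
fixture_path_network <- function(n = 5, weights = rep(1, n - 1)) {
  as_contact_network(
    tibble::tibble(i = 1:(n - 1), j = 2:n, weight = weights),
    n_nodes = n
  )
}

# random connected weighted graph for oracle comparisons
fixture_random_network <- function(n_nodes, edge_prob = 0.3, seed = 1) {
  withr::with_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < edge_prob
    # always keep the chain so the graph is connected
    chain <- pairs[, 2] - pairs[, 1] == 1
    pairs <- pairs[keep | chain, , drop = FALSE]
    as_contact_network(
      tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                     weight = stats::runif(nrow(pairs), 0.1, 2)),
      n_nodes = n_nodes
    )
  })
}

# two-block correlation matrix: within-block rho, across-block zero
fixture_block_correlation <- function(n, block = n %/% 2, rho = 0.9) {
  C <- diag(n)
  b1 <- seq_len(block); b2 <- (block + 1):n
  C[b1, b1] <- rho; C[b2, b2] <- rho
  diag(C) <- 1
  C
}

# igraph view used by oracle computations in tests
oracle_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(network$edges$i, network$edges$j))
  igraph::E(g)$weight <- network$edges$weight
  g
}
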