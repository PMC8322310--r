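test_that("contact edges respect cutoff, occupancy and neighbor exclusion", {
  # 4 residues on a line; residues 1 and 3 oscillate in/out of contact
  n_frames <- 20
  co <- array(0, c(n_frames, 4, 3))
  co[, 2, 1] <- 3.8
  co[, 3, 1] <- 6.5   # 6.5 A from residue 1: inside the 8 A CA proxy cutoff
  co[, 4, 1] <- 30
  # push residue 3 out of range in the last 6 frames (70% occupancy)
  co[15:20, 3, 1] <- 20
  traj <- trajectory_ensemble(co + array(stats::rnorm(length(co), 0, 1e-4),
                                         dim(co)),
                              aligned = TRUE)
  edges_all <- contact_edges(traj, occupancy_threshold = 0.05)
  # pair (1,2) is always in contact but excluded as sequence neighbours
  expect_false(any(edges_all$i == 1 & edges_all$j == 2))
  e13 <- dplyr::filter(edges_all, i == 1, j == 3)
  expect_equal(e13$occupancy, 14 / 20)
  # 70% occupancy < 75% threshold: dropped at the default threshold
  edges <- contact_edges(traj)
  expect_false(any(edges$i == 1 & edges$j == 3))
  # far pair never appears
  expect_false(any(edges_all$i == 1 & edges_all$j == 4))
})

test_that("heavy-atom contacts use the 4.5 A criterion", {
  # two residues whose CAs are 10 A apart but with side-chain atoms 3 A apart
  n_frames <- 12
  ca <- array(0, c(n_frames, 3, 3))
  ca[, 2, 1] <- 10
  ca[, 3, 1] <- 40
  atoms <- array(0, c(n_frames, 5, 3))
  atoms[, 1, 1] <- 0    # CA res1
  atoms[, 2, 1] <- 4    # side chain res1
  atoms[, 3, 1] <- 10   # CA res2
  atoms[, 4, 1] <- 7    # side chain res2 (3 A from res1 side chain)
  atoms[, 5, 1] <- 40   # CA res3
  traj <- trajectory_ensemble(ca, atom_coords = atoms,
                              atom_residue = c(1, 1, 2, 2, 3),
                              aligned = TRUE)
  edges <- contact_edges(traj, occupancy_threshold = 0.5,
                         neighbor_exclusion = 0)
  e12 <- dplyr::filter(edges, i == 1, j == 2)
  expect_equal(e12$occupancy, 1)
  expect_false(any(edges$i == 2 & edges$j == 3))
})

test_that("edge weights are -log|C| and monotone in correlation", {
  C <- matrix(c(1, exp(-1), 0.9, exp(-1), 1, 0.5, 0.9, 0.5, 1), 3, 3)
  edges <- tibble::tibble(i = c(1, 1, 2), j = c(2, 3, 3), occupancy = 1)
  w <- edge_weights(edges, C)
  expect_equal(w$weight[w$i == 1 & w$j == 2], 1)
  expect_equal(w$weight[w$i == 1 & w$j == 3], -log(0.9))
  expect_lt(w$weight[w$i == 1 & w$j == 3], w$weight[w$i == 2 & w$j == 3])

  C0 <- C; C0[1, 2] <- C0[2, 1] <- 0
  expect_warning(w0 <- edge_weights(edges, C0), "zero correlation")
  expect_identical(nrow(w0), 2L)
})

test_that("closeness has its closed-form values on canonical graphs", {
  p5 <- fixture_path_network(5)
  cl <- closeness_centrality(p5)
  expect_equal(cl$closeness[1], 4 / 10) # end node: distances 1+2+3+4
  expect_equal(cl$closeness[3], 4 / 6)  # middle: 2+1+1+2

  # complete graph with unit weights: closeness 1 everywhere
  pairs <- t(utils::combn(4, 2))
  k4 <- as_contact_network(tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                                          weight = 1))
  expect_equal(closeness_centrality(k4)$closeness, rep(1, 4))

  # isolated node gets zero
  iso <- as_contact_network(tibble::tibble(i = 1, j = 2, weight = 1),
                            n_nodes = 3)
  expect_equal(closeness_centrality(iso)$closeness[3], 0)
})

test_that("closeness matches a per-source Dijkstra oracle on random graphs", {
  for (s in 1:5) {
    net <- fixture_random_network(30, seed = 100 + s)
    cl <- closeness_centrality(net)$closeness
    D <- igraph::distances(oracle_igraph(net), algorithm = "dijkstra")
    oracle <- vapply(1:30, function(i) 29 / sum(D[i, -i]), numeric(1))
    expect_equal(cl, oracle, tolerance = 1e-10)
  }
})

test_that("betweenness has its closed-form values on canonical graphs", {
  p5 <- fixture_path_network(5)
  b <- betweenness_centrality(p5)
  expect_equal(b$betweenness[3], 4 / 6, tolerance = 1e-12) # middle of P5
  expect_equal(b$betweenness[1], 0)
  expect_equal(b$betweenness[5], 0)

  # star graph: centre joins every pair
  star <- as_contact_network(tibble::tibble(i = rep(1, 4), j = 2:5,
                                            weight = 1))
  bs <- betweenness_centrality(star)
  expect_equal(bs$betweenness[1], 1)
  expect_true(all(bs$betweenness[-1] == 0))
  expect_true(all(b$betweenness >= 0 & b$betweenness <= 1))
})

test_that("Floyd-Warshall agrees with Dijkstra on 50 random graphs", {
  for (s in 1:50) {
    net <- fixture_random_network(sample(8:20, 1), edge_prob = 0.25,
                                  seed = 200 + s)
    fw <- all_pairs_shortest_paths(net)
    D_oracle <- igraph::distances(oracle_igraph(net), algorithm = "dijkstra")
    expect_equal(fw$dist, unname(D_oracle), tolerance = 1e-10)
  }
})

test_that("Floyd-Warshall distances are metric and paths achieve them", {
  net <- fixture_random_network(15, seed = 33)
  fw <- all_pairs_shortest_paths(net)
  D <- fw$dist
  n <- nrow(D)
  # triangle inequality over all triples
  for (k in 1:n) {
    expect_true(all(D <= outer(D[, k], D[k, ], `+`) + 1e-9))
  }
  # reconstructed paths realize the distances
  wlook <- matrix(Inf, n, n)
  wlook[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
  wlook[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
  for (i in c(1, 5)) for (j in c(10, 15)) {
    pth <- extract_path(fw, i, j)
    len <- sum(wlook[cbind(pth[-length(pth)], pth[-1])])
    expect_equal(len, D[i, j], tolerance = 1e-10)
  }
  # negative weights rejected
  bad <- as_contact_network(tibble::tibble(i = 1, j = 2, weight = 1))
  bad$edges$weight <- -1
  expect_error(all_pairs_shortest_paths(bad), "negative")
})

test_that("suboptimal enumeration matches exhaustive search on small graphs", {
  for (s in 1:10) {
    net <- fixture_random_network(sample(6:12, 1), edge_prob = 0.35,
                                  seed = 300 + s)
    n <- nrow(net$nodes)
    ps <- suboptimal_paths(net, 1, n, offset = 1.0)
    # oracle: all simple paths, filtered by total weight
    g <- oracle_igraph(net)
    wlook <- matrix(Inf, n, n)
    wlook[cbind(net$edges$i, net$edges$j)] <- net$edges$weight
    wlook[cbind(net$edges$j, net$edges$i)] <- net$edges$weight
    all_paths <- igraph::all_simple_paths(g, 1, n)
    lens <- vapply(all_paths, function(p) {
      p <- as.integer(p)
      sum(wlook[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    bound <- min(lens) + 1.0
    keep <- lens <= bound + 1e-9
    oracle_keys <- sort(vapply(all_paths[keep], function(p) {
      paste(as.integer(p), collapse = "-")
    }, character(1)))
    mine_keys <- sort(vapply(ps$paths, paste, character(1), collapse = "-"))
    expect_identical(mine_keys, oracle_keys)
    expect_equal(ps$optimal_length, min(lens), tolerance = 1e-10)
  }
})

test_that("path sets behave across offsets and degenerate cases", {
  net <- fixture_random_network(10, seed = 44)
  p0 <- suboptimal_paths(net, 1, 10, offset = 0)
  expect_gte(length(p0$paths), 1)
  expect_equal(p0$lengths[1], p0$optimal_length)
  # every zero-offset path is optimal
  expect_true(all(abs(p0$lengths - p0$optimal_length) < 1e-9))

  # path count is non-decreasing in the offset
  counts <- vapply(c(0, 0.5, 1, 2),
                   function(o) length(suboptimal_paths(net, 1, 10,
                                                       offset = o)$paths),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))

  # all paths simple, source->sink, within bound
  p2 <- suboptimal_paths(net, 1, 10, offset = 2)
  for (p in p2$paths) {
    expect_identical(p[1], 1L)
    expect_identical(p[length(p)], 10L)
    expect_identical(anyDuplicated(p), 0L)
  }
  expect_true(all(p2$lengths <= p2$optimal_length + 2 + 1e-9))

  # unreachable sink: empty flagged set
  iso <- as_contact_network(tibble::tibble(i = 1, j = 2, weight = 1),
                            n_nodes = 3)
  pu <- suboptimal_paths(iso, 1, 3, offset = 5)
  expect_false(pu$reachable)
  expect_identical(length(pu$paths), 0L)

  # path-count cap raises an informative error
  expect_error(suboptimal_paths(net, 1, 10, offset = 10, max_paths = 2),
               "reduce `offset`")
})

test_that("participation counts paths through each node", {
  net <- fixture_path_network(4)
  ps <- suboptimal_paths(net, 1, 4, offset = 0)
  part <- node_path_participation(ps)
  expect_identical(part$n_paths, rep(1L, 4))

  net2 <- fixture_random_network(10, seed = 55)
  ps2 <- suboptimal_paths(net2, 1, 10, offset = 1.5)
  part2 <- node_path_participation(ps2)
  n_paths <- length(ps2$paths)
  expect_identical(part2$n_paths[part2$node == 1], n_paths)
  expect_identical(part2$n_paths[part2$node == 10], n_paths)
})

test_that("a broad parallel network spreads paths over more nodes than a chain", {
  # both networks have 9 nodes and the same source->sink offset; the "wide"
  # one has three near-degenerate parallel branches, the "narrow" one a
  # single chain route (its remaining nodes are off-pathway spurs)
  wide <- as_contact_network(tibble::tibble(
    i = c(1, 2, 3, 1, 5, 6, 1, 8, 9),
    j = c(2, 3, 4, 5, 6, 4, 8, 9, 4),
    weight = c(1, 1, 1, 1, 1, 1.05, 1, 1.05, 1)
  ), n_nodes = 9)
  narrow <- as_contact_network(tibble::tibble(
    i = c(1, 2, 3, rep(1, 5)),
    j = c(2, 3, 4, 5:9),
    weight = 1
  ), n_nodes = 9)
  pw <- suboptimal_paths(wide, 1, 4, offset = 0.2)
  pn <- suboptimal_paths(narrow, 1, 4, offset = 0.2)
  expect_gt(nrow(node_path_participation(pw)),
            nrow(node_path_participation(pn)))
  expect_gt(length(pw$paths), length(pn$paths))
})

test_that("merging path sets unions coverage and keeps provenance", {
  # 3-armed star of chains converging on a common sink
  arms <- as_contact_network(tibble::tibble(
    i = c(1, 2, 4, 5, 7, 8, 3, 6, 9),
    j = c(2, 3, 5, 6, 8, 9, 10, 10, 10),
    weight = 1
  ), n_nodes = 10)
  s1 <- suboptimal_paths(arms, 1, 10, offset = 0)
  s2 <- suboptimal_paths(arms, 4, 10, offset = 0)
  s3 <- suboptimal_paths(arms, 7, 10, offset = 0)
  merged <- merge_path_sets(s1, s2, s3)
  cover <- node_path_participation(merged)$node
  expect_setequal(cover, 1:10)
  single_covers <- lapply(list(s1, s2, s3), function(s)
    node_path_participation(s)$node)
  for (sc in single_covers) {
    expect_true(all(sc %in% cover))
    expect_gt(length(cover), length(sc))
  }
  expect_identical(sort(unique(merged$provenance)), c(1, 4, 7))

  # merging a set with itself doubles participation, same support
  twice <- merge_path_sets(s1, s1)
  p1 <- node_path_participation(s1)
  pt <- node_path_participation(twice)
  expect_identical(pt$node, p1$node)
  expect_identical(pt$n_paths, 2L * p1$n_paths)

  # mismatched sinks rejected
  s_bad <- suboptimal_paths(arms, 1, 9, offset = 0)
  expect_error(merge_path_sets(s1, s_bad), "same sink")
})

test_that("contact_network pipeline runs end-to-end on a synthetic fold", {
  # correlated two-block chain folded so blocks touch
  C <- fixture_block_correlation(8, block = 4, rho = 0.85)
  base <- rbind(
    cbind(3.8 * (0:3), 0, 0),
    cbind(3.8 * (3:0), 6, 0) # second block folded back near the first
  )
  traj <- generate_correlated_trajectory(8, C, base, n_frames = 400,
                                         fluctuation_sd = 0.6, seed = 12)
  net <- contact_network(traj, align = FALSE)
  expect_s3_class(net, "contact_network")
  expect_gt(nrow(net$edges), 0)
  expect_true(all(net$edges$occupancy >= 0.75))
  expect_true(all(net$edges$weight >= 0))
  expect_true(all(abs(net$edges$j - net$edges$i) > 1))
  # weight consistency with the correlation matrix
  Cm <- correlation_matrix(traj, align = FALSE)
  expect_equal(net$edges$weight,
               -log(abs(Cm[cbind(net$edges$i, net$edges$j)])),
               tolerance = 1e-9)
})
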