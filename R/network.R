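#' Occupancy-filtered contact edges of a trajectory
#'
#' A residue pair is in contact in a frame when any two of their heavy
#' atoms lie within `cutoff` Angstrom; for alpha-carbon-only trajectories
#' (no heavy atoms stored) the CA-CA distance is used instead with a larger
#' default cutoff (8 A), a documented proxy for the heavy-atom criterion.
#' Occupancy is the fraction of frames in contact; an edge is retained when
#' occupancy reaches `occupancy_threshold` and the residues are farther
#' apart in sequence than `neighbor_exclusion` (sequence neighbours give
#' trivial paths and are excluded).
#'
#' @param traj A [trajectory_ensemble()].
#' @param cutoff Contact distance cutoff, Angstrom; defaults to 4.5 with
#'   heavy atoms, 8 for CA-only trajectories.
#' @param occupancy_threshold Minimum fraction of frames in contact.
#' @param neighbor_exclusion Minimum sequence separation `|i - j|` must
#'   exceed this (1 excludes direct neighbours).
#' @return Tibble of retained edges: `i`, `j` (residue indices, `i < j`),
#'   `occupancy`.
#' @export
contact_edges <- function(traj, cutoff = NULL, occupancy_threshold = 0.75,
                          neighbor_exclusion = 1) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  heavy <- !is.null(traj$atom_coords)
  if (is.null(cutoff)) cutoff <- if (heavy) 4.5 else 8
  n_res <- dim(traj$coords)[2]
  n_frames <- dim(traj$coords)[1]

  occ <- matrix(0, n_res, n_res)
  if (heavy) {
    M <- outer(traj$atom_residue, seq_len(n_res), `==`) * 1 # atoms x residues
    for (f in seq_len(n_frames)) {
      D <- as.matrix(stats::dist(traj$atom_coords[f, , ]))
      A <- (D <= cutoff) * 1
      occ <- occ + (crossprod(M, A %*% M) > 0)
    }
  } else {
    for (f in seq_len(n_frames)) {
      D <- as.matrix(stats::dist(traj$coords[f, , ]))
      occ <- occ + (D <= cutoff)
    }
  }
  occ <- occ / n_frames

  pairs <- which(upper.tri(occ), arr.ind = TRUE)
  tibble::tibble(
    i = pairs[, 1], j = pairs[, 2],
    occupancy = occ[pairs]
  ) |>
    dplyr::filter(.data$j - .data$i > neighbor_exclusion,
                  .data$occupancy >= occupancy_threshold)
}

#' Displacement cross-correlation matrix of a trajectory
#'
#' Normalized covariance of the alpha-carbon displacement vectors,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}},}
#' with displacements taken from the mean structure. Frames can first be
#' rigid-body superposed onto the mean structure (two-pass: fit, update
#' mean, refit) to remove overall translation/rotation.
#'
#' @param traj A [trajectory_ensemble()], at least 10 frames.
#' @param align Superpose frames before computing displacements. Skipped
#'   when the trajectory is already flagged aligned.
#' @return Symmetric matrix with unit diagonal, entries in `[-1, 1]`.
#'   Zero-variance residues get 0 off-diagonal entries with a warning.
#' @export
correlation_matrix <- function(traj, align = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  co <- traj$coords
  n_frames <- dim(co)[1]; n_res <- dim(co)[2]
  if (n_frames < 10) stop("need at least 10 frames", call. = FALSE)

  if (align && !traj$aligned) {
    for (pass in 1:2) {
      ref <- apply(co, c(2, 3), mean)
      for (f in seq_len(n_frames)) {
        co[f, , ] <- kabsch_fit(co[f, , ], ref)
      }
    }
  }
  mean_pos <- apply(co, c(2, 3), mean)
  # frames x residues displacement dot products, summed over axes
  num <- matrix(0, n_res, n_res)
  for (ax in 1:3) {
    d <- sweep(co[, , ax], 2, mean_pos[, ax])
    num <- num + crossprod(d) / n_frames
  }
  v <- diag(num)
  zero <- v <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " residue(s) with zero positional variance: ",
            "correlations set to 0", call. = FALSE)
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  pmax(pmin(C, 1), -1)
}

# least-squares rigid-body superposition of `x` onto `ref` (both n x 3)
kabsch_fit <- function(x, ref) {
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  s <- svd(crossprod(xc, rc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(xc %*% t(R), 2, cr, `+`)
}

#' Correlation-weight the contact edges
#'
#' Edge weight `w = -log(|C_ij|)`: strongly correlated contacts get short
#' (cheap) edges, so shortest paths follow chains of correlated residues.
#' Edges with exactly zero correlation would have infinite weight and are
#' dropped with a warning.
#'
#' @param edges Edge tibble from [contact_edges()].
#' @param C Correlation matrix from [correlation_matrix()].
#' @return `edges` with `correlation` and `weight` columns appended.
#' @export
edge_weights <- function(edges, C) {
  stopifnot(all(c("i", "j") %in% names(edges)))
  corr <- C[cbind(edges$i, edges$j)]
  zero <- abs(corr) <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " edge(s) with zero correlation dropped ",
            "(infinite weight)", call. = FALSE)
  }
  edges |>
    dplyr::mutate(correlation = corr, weight = -log(abs(corr))) |>
    dplyr::filter(!zero)
}

#' Build the correlation-weighted residue-interaction network
#'
#' Convenience pipeline: [contact_edges()] then [correlation_matrix()]
#' then [edge_weights()], returning a `contact_network` object holding the
#' node table and the weighted edge list.
#'
#' @param traj A [trajectory_ensemble()].
#' @inheritParams contact_edges
#' @param align Superpose frames before the correlation computation.
#' @return An object of class `contact_network`: list with `nodes`
#'   (residue tibble + `node` index), `edges` (tibble `i`, `j`,
#'   `occupancy`, `correlation`, `weight`) and the construction
#'   `parameters`.
#' @export
contact_network <- function(traj, cutoff = NULL, occupancy_threshold = 0.75,
                            neighbor_exclusion = 1, align = TRUE) {
  edges <- contact_edges(traj, cutoff = cutoff,
                         occupancy_threshold = occupancy_threshold,
                         neighbor_exclusion = neighbor_exclusion)
  C <- correlation_matrix(traj, align = align)
  edges <- edge_weights(edges, C)
  nodes <- dplyr::mutate(traj$residues, node = dplyr::row_number(),
                         .before = 1)
  structure(
    list(nodes = nodes, edges = edges,
         parameters = list(cutoff = cutoff,
                           occupancy_threshold = occupancy_threshold,
                           neighbor_exclusion = neighbor_exclusion,
                           align = align)),
    class = "contact_network"
  )
}

#' Assemble a contact network directly from node and edge tables
#'
#' Lower-level constructor used for fixture graphs and tests: supply the
#' weighted edge list yourself.
#'
#' @param edges Tibble/data frame with columns `i`, `j`, `weight`
#'   (non-negative); `occupancy`/`correlation` optional.
#' @param n_nodes Number of nodes; defaults to `max(i, j)`.
#' @return A `contact_network`.
#' @export
as_contact_network <- function(edges, n_nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("i", "j", "weight") %in% names(edges)))
  if (any(edges$weight < 0)) stop("edge weights must be non-negative",
                                  call. = FALSE)
  if (any(edges$i == edges$j)) stop("self-edges are not allowed", call. = FALSE)
  if (is.null(n_nodes)) n_nodes <- max(edges$i, edges$j)
  nodes <- tibble::tibble(node = seq_len(n_nodes), chain = "A",
                          resid = seq_len(n_nodes), resname = "ALA")
  structure(
    list(nodes = nodes, edges = edges, parameters = list()),
    class = "contact_network"
  )
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# undirected igraph view of a contact_network (internal)
as_igraph_network <- function(network) {
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(network$edges$i, network$edges$j))
  igraph::E(g)$weight <- network$edges$weight
  g
}
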