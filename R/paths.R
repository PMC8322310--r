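#' All-pairs shortest paths by Floyd-Warshall
#'
#' Classic dynamic-programming all-pairs shortest distances on the
#' undirected weighted network, with a next-hop matrix for path
#' reconstruction. Unreachable pairs keep `Inf`. Weights must be
#' non-negative.
#'
#' @param network A `contact_network`.
#' @return An object of class `apsp`: `dist` (n x n), `next_hop` (n x n
#'   integer, `NA` where unreachable).
#' @export
all_pairs_shortest_paths <- function(network) {
  stopifnot(inherits(network, "contact_network"))
  edges <- network$edges
  if (any(edges$weight < 0)) {
    stop("negative edge weights are not allowed", call. = FALSE)
  }
  n <- nrow(network$nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nxt <- matrix(NA_integer_, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$weight[r]
    if (w < D[i, j]) {
      D[i, j] <- w; D[j, i] <- w
      nxt[i, j] <- j; nxt[j, i] <- i
    }
  }
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    through_k <- outer(D[, k], D[k, ], `+`)
    upd <- through_k < D
    if (any(upd)) {
      D[upd] <- through_k[upd]
      nxt[upd] <- matrix(nxt[, k], n, n)[upd]
    }
  }
  structure(list(dist = D, next_hop = nxt), class = "apsp")
}

#' Reconstruct one shortest path from an `apsp` object
#'
#' @param apsp Result of [all_pairs_shortest_paths()].
#' @param from,to Node indices.
#' @return Integer vector of node indices, or `NULL` when unreachable.
#' @export
extract_path <- function(apsp, from, to) {
  stopifnot(inherits(apsp, "apsp"))
  if (!is.finite(apsp$dist[from, to])) return(NULL)
  path <- from
  while (path[length(path)] != to) {
    path <- c(path, apsp$next_hop[path[length(path)], to])
  }
  path
}

#' Closeness centrality on shortest-path distances
#'
#' `c_i = (n_reachable - 1) / sum_j d(i, j)` over the nodes reachable from
#' `i`; isolated nodes get 0. Distances are weighted shortest-path
#' distances from [all_pairs_shortest_paths()].
#'
#' @param network A `contact_network`.
#' @return Tibble `node`, `closeness`.
#' @export
closeness_centrality <- function(network) {
  D <- all_pairs_shortest_paths(network)$dist
  n <- nrow(D)
  cl <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) return(0)
    sum(reach) / sum(d[reach])
  }, numeric(1))
  tibble::tibble(node = seq_len(n), closeness = cl)
}

#' Normalized betweenness centrality
#'
#' Standard shortest-path betweenness with equal splitting among tied
#' shortest paths, endpoints excluded, normalized by `(n-1)(n-2)/2` (the
#' number of node pairs an intermediate could join) so values lie in
#' `[0, 1]`. Computed by Brandes' algorithm via igraph on the weighted
#' graph.
#'
#' @param network A `contact_network`.
#' @return Tibble `node`, `betweenness`.
#' @export
betweenness_centrality <- function(network) {
  g <- as_igraph_network(network)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  tibble::tibble(node = seq_len(nrow(network$nodes)),
                 betweenness = as.numeric(b))
}

#' Enumerate optimal and suboptimal source-to-sink paths
#'
#' All simple paths whose total weight is within `offset` of the shortest
#' source-sink distance, found by depth-first search pruned with the exact
#' remaining-distance bound from [all_pairs_shortest_paths()] (a branch is
#' abandoned as soon as its length plus the shortest remaining distance
#' exceeds the bound). Paths are returned sorted by length, ties in
#' lexicographic node order, so output is deterministic.
#'
#' An alternative node-count filter (`max_nodes`) restricts enumeration to
#' paths of at most that many nodes, for the reading of path spread as a
#' node budget rather than a weight offset; it is off by default.
#'
#' @param network A `contact_network`.
#' @param source,sink Node indices, distinct.
#' @param offset Weight tolerance above the optimal path length (>= 0).
#' @param max_paths Abort with an error if more than this many paths
#'   qualify (advises a smaller offset).
#' @param max_nodes Optional cap on path length in nodes.
#' @return An object of class `path_set`: `source`, `sink`, `paths` (list
#'   of integer node sequences), `lengths`, `optimal_length`, `offset`,
#'   `reachable`.
#' @export
suboptimal_paths <- function(network, source, sink, offset = 0,
                             max_paths = 1e4, max_nodes = NULL) {
  stopifnot(inherits(network, "contact_network"))
  n <- nrow(network$nodes)
  source <- as.integer(source); sink <- as.integer(sink)
  if (source == sink || source < 1 || sink < 1 || source > n || sink > n) {
    stop("`source` and `sink` must be distinct nodes of the network",
         call. = FALSE)
  }
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  apsp <- all_pairs_shortest_paths(network)
  d_opt <- apsp$dist[source, sink]
  if (!is.finite(d_opt)) {
    return(structure(
      list(source = source, sink = sink, paths = list(),
           lengths = numeric(0), optimal_length = Inf, offset = offset,
           reachable = FALSE),
      class = "path_set"
    ))
  }
  bound <- d_opt + offset
  to_sink <- apsp$dist[, sink]

  # adjacency lists in increasing neighbour order -> deterministic DFS
  adj <- vector("list", n)
  wts <- vector("list", n)
  e <- network$edges
  for (r in seq_len(nrow(e))) {
    ei <- as.integer(e$i[r]); ej <- as.integer(e$j[r])
    adj[[ei]] <- c(adj[[ei]], ej)
    wts[[ei]] <- c(wts[[ei]], e$weight[r])
    adj[[ej]] <- c(adj[[ej]], ei)
    wts[[ej]] <- c(wts[[ej]], e$weight[r])
  }
  for (v in seq_len(n)) {
    if (!length(adj[[v]])) next
    o <- order(adj[[v]])
    adj[[v]] <- adj[[v]][o]; wts[[v]] <- wts[[v]][o]
  }

  paths <- vector("list", 256)
  lens <- numeric(256)
  n_found <- 0L
  node_cap <- max_nodes %||% n
  eps <- 1e-9

  on_path <- rep(FALSE, n)
  dfs <- function(v, len, path) {
    if (v == sink) {
      n_found <<- n_found + 1L
      if (n_found > max_paths) {
        stop("more than ", max_paths,
             " qualifying paths; reduce `offset` or raise `max_paths`",
             call. = FALSE)
      }
      if (n_found > length(paths)) {
        length(paths) <<- 2L * length(paths)
        length(lens) <<- 2L * length(lens)
      }
      paths[[n_found]] <<- path
      lens[n_found] <<- len
      return(invisible())
    }
    if (length(path) >= node_cap) return(invisible())
    nb <- adj[[v]]; w <- wts[[v]]
    for (q in seq_along(nb)) {
      u <- nb[q]
      if (on_path[u]) next
      new_len <- len + w[q]
      if (new_len + to_sink[u] > bound + eps) next
      on_path[u] <<- TRUE
      dfs(u, new_len, c(path, u))
      on_path[u] <<- FALSE
    }
    invisible()
  }
  on_path[source] <- TRUE
  dfs(source, 0, source)

  paths <- paths[seq_len(n_found)]
  lens <- lens[seq_len(n_found)]
  key <- vapply(paths, function(p) paste(sprintf("%06d", p), collapse = ","),
                character(1))
  o <- order(lens, key)
  structure(
    list(source = source, sink = sink, paths = paths[o], lengths = lens[o],
         optimal_length = d_opt, offset = offset, reachable = TRUE),
    class = "path_set"
  )
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf(
    "<path_set> %d -> %d: %d path(s), optimal length %.4g, offset %.4g\n",
    x$source, x$sink, length(x$paths), x$optimal_length, x$offset))
  invisible(x)
}

#' Per-node participation counts of a path set
#'
#' How many paths of the set pass through each node; source and sink
#' participate in every path. The participation profile is the working
#' definition of how widely force propagation spreads over the structure.
#'
#' @param path_set A `path_set` (or merged path set).
#' @return Tibble `node`, `n_paths`, sorted by node.
#' @export
node_path_participation <- function(path_set) {
  stopifnot(inherits(path_set, c("path_set", "merged_path_set")))
  paths <- path_set$paths
  if (!length(paths)) {
    return(tibble::tibble(node = integer(), n_paths = integer()))
  }
  counts <- table(unlist(paths))
  tibble::tibble(node = as.integer(names(counts)),
                 n_paths = as.integer(counts)) |>
    dplyr::arrange(.data$node)
}

#' Merge path sets from multiple pulling points onto a common sink
#'
#' Union of the paths of several `path_set`s sharing a sink (multipoint
#' pulling merged into one force-propagation map); per-node participation
#' is summed over sets and per-source provenance is retained.
#'
#' @param ... Two or more `path_set`s with the same sink (or one list of
#'   them).
#' @return An object of class `merged_path_set`: `sink`, `sources`,
#'   `paths`, `lengths`, `provenance` (source of each path).
#' @export
merge_path_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "path_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, logical(1), "path_set")))
  sinks <- vapply(sets, function(s) s$sink, numeric(1))
  if (length(unique(sinks)) != 1) {
    stop("all path sets must share the same sink", call. = FALSE)
  }
  structure(
    list(sink = sinks[1],
         sources = vapply(sets, function(s) s$source, numeric(1)),
         paths = do.call(c, lapply(sets, function(s) s$paths)),
         lengths = do.call(c, lapply(sets, function(s) s$lengths)),
         provenance = rep(vapply(sets, function(s) s$source, numeric(1)),
                          vapply(sets, function(s) length(s$paths), 1L))),
    class = "merged_path_set"
  )
}

#' @export
print.merged_path_set <- function(x, ...) {
  cat(sprintf("<merged_path_set> sources {%s} -> %d: %d path(s)\n",
              paste(x$sources, collapse = ", "), x$sink, length(x$paths)))
  invisible(x)
}
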