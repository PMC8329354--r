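.adj_of <- function(net) {
  if (inherits(net, "scn_network")) net$adjacency
  else {
    a <- as.matrix(net)
    storage.mode(a) <- "integer"
    a
  }
}

#' Clustering coefficient
#'
#' Per-node fraction of a node's neighbor pairs that are themselves
#' connected: `2*T_i / (k_i (k_i - 1))`, 0 for degree < 2. The network value
#' is the unweighted mean over all nodes.
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return List with `nodal` (per-node values) and `mean`.
#' @export
clustering <- function(net) {
  a <- .adj_of(net)
  nodal <- .cpp_clustering(a)
  names(nodal) <- rownames(a)
  list(nodal = nodal, mean = mean(nodal))
}

#' Shortest-path distance matrix
#'
#' Breadth-first-search geodesic distances in edges; unreachable pairs are
#' `Inf`.
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return Numeric distance matrix with zero diagonal.
#' @export
distances_matrix <- function(net) {
  a <- .adj_of(net)
  d <- .cpp_distances(a)
  d <- ifelse(d < 0, Inf, d)
  dimnames(d) <- dimnames(a)
  d
}

#' Characteristic path length
#'
#' Per-node shortest path length is the mean BFS distance to all *reachable*
#' other nodes; `L` is the mean over nodes that can reach at least one other
#' node (unreachable pairs are excluded from the average, the convention
#' needed for possibly disconnected FDR-thresholded networks). An edgeless
#' network has no defined path length: the function returns `NA` with a
#' warning.
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return List with `nodal` (NA where a node reaches no one) and `mean`.
#' @export
path_length <- function(net) {
  d <- distances_matrix(net)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  nodal <- rowMeans(d, na.rm = TRUE)
  nodal[is.nan(nodal)] <- NA_real_
  if (all(is.na(nodal))) {
    warning("path length undefined: network has no edges")
    return(list(nodal = nodal, mean = NA_real_))
  }
  list(nodal = nodal, mean = mean(nodal, na.rm = TRUE))
}

#' Global and nodal efficiency
#'
#' Efficiency is the mean inverse geodesic distance, with `1/Inf = 0` for
#' unreachable pairs (Latora-Marchiori convention): `E_global` averages over
#' all ordered pairs, nodal efficiency over the pairs involving each node.
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return List with `nodal` and `global`.
#' @export
global_efficiency <- function(net) {
  d <- distances_matrix(net)
  inv <- 1 / d
  diag(inv) <- NA
  nodal <- rowMeans(inv, na.rm = TRUE)
  list(nodal = nodal, global = mean(nodal))
}

#' Local efficiency
#'
#' Per-node: the global efficiency of the subgraph induced by the node's
#' neighbors (the node itself excluded); 0 for nodes with fewer than two
#' neighbors. `E_local` is the mean over all nodes.
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return List with `nodal` and `mean`.
#' @export
local_efficiency <- function(net) {
  a <- .adj_of(net)
  nodal <- .cpp_local_efficiency(a)
  names(nodal) <- rownames(a)
  list(nodal = nodal, mean = mean(nodal))
}

#' Betweenness centrality
#'
#' Brandes accumulation of the fraction of all-pairs shortest paths passing
#' through each node, normalized by `(n-1)(n-2)/2` so values lie in [0, 1].
#'
#' @param net an `scn_network` or a binary adjacency matrix.
#' @return List with `raw` and `normalized` per-node vectors.
#' @export
betweenness <- function(net) {
  a <- .adj_of(net)
  raw <- .cpp_betweenness(a)
  names(raw) <- rownames(a)
  n <- nrow(a)
  norm <- if (n > 2) raw / ((n - 1) * (n - 2) / 2) else raw * 0
  list(raw = raw, normalized = norm)
}

#' Degree-preserving random reference networks
#'
#' Generates `n_random` references by Maslov-Sneppen double-edge swaps
#' (10 x |edges| proposals each; swaps creating self-loops or multi-edges
#' are rejected), preserving every node's degree exactly. When no proposal
#' can be accepted (e.g. a complete graph) the references equal the input
#' and the result is flagged.
#'
#' @param net an `scn_network` or a binary adjacency matrix with >= 1 edge.
#' @param n_random number of references (the reference count used for
#'   small-world normalization; default 100).
#' @param seed optional integer seed applied before rewiring.
#' @param swap_factor proposals per edge (default 10).
#' @return List with `C_rand`, `L_rand` (per-reference values),
#'   `n_swaps` (accepted swaps per reference), `flagged` (TRUE when some
#'   reference accepted no swap), and `adjacencies` (the reference
#'   matrices).
#' @export
random_reference <- function(net, n_random = 100, seed = NULL,
                             swap_factor = 10) {
  a <- .adj_of(net)
  m <- sum(a) / 2
  if (m < 1) stop("random references require at least one edge")
  if (n_random < 1) stop("n_random must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  attempts <- as.integer(swap_factor * m)
  C_rand <- L_rand <- n_swaps <- numeric(n_random)
  adjs <- vector("list", n_random)
  for (i in seq_len(n_random)) {
    rw <- .cpp_rewire(a, attempts)
    adjs[[i]] <- rw$adjacency
    n_swaps[i] <- rw$n_swaps
    C_rand[i] <- mean(.cpp_clustering(rw$adjacency))
    L_rand[i] <- suppressWarnings(path_length(rw$adjacency)$mean)
  }
  list(C_rand = C_rand, L_rand = L_rand, n_swaps = n_swaps,
       flagged = any(n_swaps == 0), adjacencies = adjs)
}

#' Small-world indices against matched random references
#'
#' `gamma = C / mean(C_rand)`, `lambda = L / mean(L_rand)`,
#' `sigma = gamma / lambda`, where the reference values are means over
#' `n_random` degree-preserving Maslov-Sneppen rewirings. `sigma > 1`
#' indicates small-world organization. When the references have zero mean
#' clustering the indices are undefined and returned as `NA` with a
#' warning.
#'
#' @inheritParams random_reference
#' @return List with `gamma`, `lambda`, `sigma`, `C`, `L`, `C_rand`,
#'   `L_rand` (reference means) and `flagged`.
#' @export
small_world <- function(net, n_random = 100, seed = NULL, swap_factor = 10) {
  C <- clustering(net)$mean
  L <- path_length(net)$mean
  ref <- random_reference(net, n_random, seed, swap_factor)
  C_rand <- mean(ref$C_rand)
  L_rand <- mean(ref$L_rand)
  if (!is.finite(C_rand) || C_rand == 0) {
    warning("small-world indices undefined: reference clustering is zero")
    return(list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
                C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                flagged = ref$flagged))
  }
  gamma <- C / C_rand
  lambda <- L / L_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, C_rand = C_rand, L_rand = L_rand, flagged = ref$flagged)
}

#' All global and nodal metrics of a binary network
#'
#' Convenience wrapper computing the full metric suite: mean clustering
#' coefficient `C`, characteristic path length `L`, global and local
#' efficiency, small-world `gamma`/`lambda`/`sigma` (when `n_random > 0`),
#' and per-node degree, nodal efficiency and normalized betweenness.
#'
#' @param net an `scn_network` or binary adjacency matrix.
#' @param n_random random references for small-worldness; 0 skips it.
#' @param seed seed for the reference rewiring.
#' @param nodal compute per-node metrics (degree, nodal efficiency,
#'   betweenness)?
#' @return List with `global` (named numeric) and `nodal` (named list of
#'   per-ROI vectors, or `NULL`).
#' @export
network_metrics <- function(net, n_random = 100, seed = NULL, nodal = TRUE) {
  a <- .adj_of(net)
  cl <- clustering(a)
  pl <- suppressWarnings(path_length(a))
  eff <- global_efficiency(a)
  leff <- local_efficiency(a)
  glob <- c(C = cl$mean, L = pl$mean, E_global = eff$global,
            E_local = leff$mean)
  if (n_random > 0) {
    if (sum(a) / 2 >= 1) {
      sw <- suppressWarnings(small_world(a, n_random, seed))
      glob <- c(glob, gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
    } else {
      glob <- c(glob, gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
    }
  }
  nod <- NULL
  if (nodal) {
    nod <- list(degree = rowSums(a),
                nodal_efficiency = eff$nodal,
                betweenness = betweenness(a)$normalized)
  }
  list(global = glob, nodal = nod)
}
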