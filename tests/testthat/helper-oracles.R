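# Brute-force graph oracles, deliberately independent of the package's
# implementations: Floyd-Warshall distances, triple enumeration for
# clustering, dynamic-programming shortest-path counts for betweenness.

adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1L
    a[e[2], e[1]] <- 1L
  }
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

star_graph <- function(n) {
  adj_from_edges(n, lapply(2:n, function(i) c(1, i)))
}

cycle_graph <- function(n) {
  adj_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                      list(c(n, 1))))
}

# Ring lattice on n nodes, each connected to k/2 neighbors per side, with a
# fraction of edges randomly rewired (Watts-Strogatz style construction).
ring_lattice <- function(n, k, p_rewire = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  if (p_rewire > 0) {
    ut <- which(upper.tri(a) & a == 1L)
    rewire <- ut[runif(length(ut)) < p_rewire]
    for (idx in rewire) {
      i <- ((idx - 1) %% n) + 1
      j <- ((idx - 1) %/% n) + 1
      candidates <- which(a[i, ] == 0L & seq_len(n) != i)
      if (length(candidates) == 0) next
      newj <- candidates[sample.int(length(candidates), 1)]
      a[i, j] <- a[j, i] <- 0L
      a[i, newj] <- a[newj, i] <- 1L
    }
  }
  a
}

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_along(nb)) for (y in seq_len(x - 1))
      if (a[nb[x], nb[y]] == 1) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

oracle_path_length <- function(a) {
  d <- oracle_distances(a)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  nodal <- rowMeans(d, na.rm = TRUE)
  nodal <- nodal[!is.nan(nodal)]
  if (length(nodal) == 0) NA_real_ else mean(nodal)
}

oracle_global_efficiency <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- NA
  rowMeans(inv, na.rm = TRUE)
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    mean(oracle_global_efficiency(a[nb, nb, drop = FALSE]))
  }, numeric(1))
}

# Number of shortest s->t paths, by dynamic programming on BFS distances.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  nsp <- function(s, t) {
    if (s == t) return(1)
    if (is.infinite(d[s, t])) return(0)
    preds <- which(a[, t] == 1 & d[s, ] == d[s, t] - 1)
    sum(vapply(preds, function(w) nsp(s, w), numeric(1)))
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(d[s, t])) next
    tot <- nsp(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        bc[v] <- bc[v] + nsp(s, v) * nsp(v, t) / tot
    }
  }
  bc
}

# Benjamini-Hochberg step-up by direct application of the rule.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks) > 0) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

is_connected <- function(a) {
  n <- nrow(a)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier) > 0) {
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    a <- matrix(0L, n, n)
    a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p_edge)
    a <- a + t(a)
    if (sum(a) > 0 && is_connected(a)) return(a)
  }
}

# Small atlas for fixture networks
toy_atlas <- function(n) {
  roi_atlas(sprintf("r%02d", seq_len(n)),
            rep(c("LH", "RH"), length.out = n))
}

# Assemble an scn_covariance object directly from r and p matrices.
make_cov <- function(r, p, n, atlas = toy_atlas(nrow(r))) {
  dimnames(r) <- dimnames(p) <- list(as.character(atlas), as.character(atlas))
  structure(list(r = r, p = p, n = n, atlas = atlas),
            class = "scn_covariance")
}
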