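# Run the full SCN pipeline on one condition's subject-by-ROI matrix and
# return the metric suite. Thresholding is recomputed here on every call so
# the permutation null reflects the data-dependence of the FDR threshold.
# Lean path used inside the permutation loop: numerically identical to
# correlation_matrix() + threshold_fdr() + network_metrics(), without the
# per-call container validation (the inputs are already validated once).
.scn_metrics <- function(X, atlas, q, n_random, seed, nodal) {
  n <- nrow(X)
  p_roi <- ncol(X)
  r <- cor(X)
  rut <- r[upper.tri(r)]
  if (anyNA(rut)) {
    sds <- apply(X, 2, sd)
    stop("zero-variance ROI: ", colnames(X)[which(sds == 0)[1]])
  }
  pvals <- .pearson_p(rut, n)
  keep <- p.adjust(pvals, method = "BH") <= q & rut > 0
  adj <- matrix(0L, p_roi, p_roi)
  adj[upper.tri(adj)] <- as.integer(keep)
  adj <- adj + t(adj)
  ps <- .cpp_path_stats(adj)
  C <- mean(.cpp_clustering(adj))
  glob <- c(C = C, L = ps$L, E_global = ps$E_global,
            E_local = mean(.cpp_local_efficiency(adj)))
  if (n_random > 0) {
    m_edges <- sum(adj) / 2
    if (m_edges >= 1) {
      set.seed(seed)
      rs <- .cpp_ref_stats(adj, as.integer(n_random),
                           as.integer(10 * m_edges))
      gamma <- C / mean(rs$C_rand)
      lambda <- ps$L / mean(rs$L_rand)
      glob <- c(glob, gamma = gamma, lambda = lambda, sigma = gamma / lambda)
    } else {
      glob <- c(glob, gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
    }
  }
  nod <- NULL
  if (nodal) {
    norm <- if (p_roi > 2) (p_roi - 1) * (p_roi - 2) / 2 else 1
    nod <- list(degree = rowSums(adj),
                nodal_efficiency = ps$E_nodal,
                betweenness = .cpp_betweenness(adj) / norm)
  }
  list(global = glob, nodal = nod)
}

.perm_p <- function(null, obs) {
  if (is.na(obs))
    return(c(greater = NA_real_, less = NA_real_, two_sided = NA_real_))
  ok <- !is.na(null)
  k <- sum(ok)
  g <- (1 + sum(null[ok] >= obs)) / (k + 1)
  l <- (1 + sum(null[ok] <= obs)) / (k + 1)
  c(greater = g, less = l, two_sided = min(1, 2 * min(g, l)))
}

#' Paired condition-label permutation test on SCN metrics
#'
#' Tests condition differences in structural covariance network properties
#' with the paired (crossover) permutation scheme: the observed pipeline
#' (correlation, FDR thresholding, graph metrics, including random
#' references when `n_random > 0`) is run once on the true labels; in each
#' of `n_perm` permutations every subject's two condition rows are
#' independently swapped with probability 1/2 and the entire pipeline is
#' re-run, giving a null distribution of the between-condition difference
#' (first condition minus second, i.e. restricted minus full by default).
#'
#' One-sided p-values use the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` (mirrored for the lower
#' side); the two-sided p doubles the smaller tail, capped at 1. Nodal
#' metrics (degree, nodal efficiency, betweenness) are corrected across
#' ROIs by Benjamini-Hochberg at level `q_nodal`.
#'
#' @param tab a `thickness_table` with both conditions for every subject.
#' @param conditions length-2 character: the two condition labels,
#'   difference taken as first minus second.
#' @param n_perm number of permutations (>= 100).
#' @param q FDR level for edge thresholding inside the pipeline.
#' @param q_nodal FDR level for the nodal BH correction across ROIs.
#' @param n_random random references per network for gamma/lambda/sigma;
#'   0 skips small-world indices (much faster).
#' @param nodal compute and test nodal metrics?
#' @param seed master seed (mandatory). Reference-network seeds inside
#'   permutations are derived deterministically from it, so the full result
#'   including null distributions is reproducible bit-for-bit.
#' @param atlas a [roi_atlas()].
#' @return An object of class `scn_permutation`: observed per-condition
#'   metrics, observed differences, null difference matrix
#'   (`n_perm` x metrics), p-values per metric and side, and per-ROI
#'   results with BH decisions when `nodal = TRUE`.
#' @export
permute_conditions <- function(tab, conditions = c("restricted", "full"),
                               n_perm = 1000, q = 0.05, q_nodal = 0.05,
                               n_random = 100, nodal = TRUE, seed,
                               atlas = dk_atlas()) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(attr(tab, "atlas"))) atlas <- attr(tab, "atlas")
  tab <- validate_thickness(tab, atlas, paired = TRUE)
  if (!all(conditions %in% tab$condition))
    stop("conditions not found in table: ",
         paste(setdiff(conditions, tab$condition), collapse = ", "))
  subjects <- unique(tab$subject_id)
  n <- length(subjects)
  rois <- as.character(atlas)
  pick <- function(cond) {
    rows <- tab[tab$condition == cond, ]
    rows <- rows[match(subjects, rows$subject_id), ]
    as.matrix(rows[, rois])
  }
  X1 <- pick(conditions[1])
  X2 <- pick(conditions[2])

  set.seed(seed)
  flips <- matrix(runif(n_perm * n) < 0.5, n_perm, n)
  ref_seeds <- matrix(sample.int(2147483646L, 2 * (n_perm + 1)),
                      ncol = 2)  # row 1 = observed, per-condition seeds

  use_seed <- function(i, k) if (n_random > 0) ref_seeds[i, k] else NULL
  m1 <- .scn_metrics(X1, atlas, q, n_random, use_seed(1, 1), nodal)
  m2 <- .scn_metrics(X2, atlas, q, n_random, use_seed(1, 2), nodal)
  metric_names <- names(m1$global)
  obs_diff <- m1$global - m2$global

  null_glob <- matrix(NA_real_, n_perm, length(metric_names),
                      dimnames = list(NULL, metric_names))
  nodal_names <- if (nodal) names(m1$nodal) else character()
  null_nodal <- lapply(nodal_names, function(nm)
    matrix(NA_real_, n_perm, length(rois), dimnames = list(NULL, rois)))
  names(null_nodal) <- nodal_names

  for (b in seq_len(n_perm)) {
    f <- flips[b, ]
    Xr <- X1; Xr[f, ] <- X2[f, ]
    Xf <- X2; Xf[f, ] <- X1[f, ]
    p1 <- .scn_metrics(Xr, atlas, q, n_random, use_seed(b + 1, 1), nodal)
    p2 <- .scn_metrics(Xf, atlas, q, n_random, use_seed(b + 1, 2), nodal)
    null_glob[b, ] <- p1$global - p2$global
    for (nm in nodal_names)
      null_nodal[[nm]][b, ] <- p1$nodal[[nm]] - p2$nodal[[nm]]
  }

  pvals <- t(vapply(metric_names, function(nm)
    .perm_p(null_glob[, nm], obs_diff[nm]), numeric(3)))
  global_p <- data.frame(metric = metric_names,
                         observed_diff = unname(obs_diff),
                         p_greater = pvals[, "greater"],
                         p_less = pvals[, "less"],
                         p_two_sided = pvals[, "two_sided"],
                         row.names = NULL, stringsAsFactors = FALSE)

  nodal_res <- NULL
  if (nodal) {
    nodal_res <- lapply(nodal_names, function(nm) {
      od <- m1$nodal[[nm]] - m2$nodal[[nm]]
      pv <- t(vapply(seq_along(rois), function(j)
        .perm_p(null_nodal[[nm]][, j], od[j]), numeric(3)))
      p_two <- pv[, "two_sided"]
      p_adj <- p.adjust(p_two, method = "BH")
      data.frame(roi = rois, observed_diff = unname(od),
                 p_greater = pv[, "greater"], p_less = pv[, "less"],
                 p_two_sided = p_two, p_adj = p_adj,
                 significant = p_adj <= q_nodal,
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    names(nodal_res) <- nodal_names
  }

  structure(list(
    conditions = conditions,
    observed = setNames(list(m1$global, m2$global, obs_diff),
                        c(conditions, "diff")),
    global = global_p,
    null_global = null_glob,
    nodal = nodal_res,
    null_nodal = if (nodal) null_nodal else NULL,
    params = list(n_perm = n_perm, q = q, q_nodal = q_nodal,
                  n_random = n_random, seed = seed, n_subjects = n,
                  threshold_recomputed_per_permutation = TRUE)),
    class = "scn_permutation")
}

#' @export
print.scn_permutation <- function(x, digits = 4, ...) {
  cat("Paired SCN permutation test:", x$params$n_subjects, "subjects,",
      x$params$n_perm, "permutations (", x$conditions[1], "-",
      x$conditions[2], ")\n\n")
  print(format(x$global, digits = digits), row.names = FALSE)
  if (!is.null(x$nodal)) {
    for (nm in names(x$nodal)) {
      sig <- x$nodal[[nm]][x$nodal[[nm]]$significant, , drop = FALSE]
      cat("\n", nm, ": ", nrow(sig), " ROI(s) significant after BH at q = ",
          x$params$q_nodal, "\n", sep = "")
      if (nrow(sig) > 0) print(format(sig, digits = digits),
                               row.names = FALSE)
    }
  }
  invisible(x)
}

#' Age-stratified permutation analysis
#'
#' Repeats [permute_conditions()] separately within each `group` label of
#' the table (e.g. young and old adults).
#'
#' @inheritParams permute_conditions
#' @param ... further arguments passed to [permute_conditions()].
#' @return Named list of `scn_permutation` objects, one per group.
#' @export
stratified_analysis <- function(tab, seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  groups <- unique(tab$group)
  res <- lapply(seq_along(groups), function(i) {
    sub <- tab[tab$group == groups[i], ]
    if (length(unique(sub$subject_id)) < 4)
      stop("group '", groups[i], "' has fewer than 4 subjects")
    permute_conditions(sub, seed = seed + i - 1, ...)
  })
  names(res) <- groups
  res
}
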