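# Two-sided p for a Pearson correlation via the exact t transform
# t = r * sqrt((n-2)/(1-r^2)) on n-2 df; |r| = 1 gives p = 0.
.pearson_p <- function(r, n) {
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2))
  p
}

#' Across-subject ROI correlation matrix
#'
#' Builds the structural covariance matrix for one condition: the Pearson
#' correlation of every ROI pair's thickness across subjects, with two-sided
#' p-values from the exact t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x either a `thickness_table` restricted to a single condition
#'   (one row per subject) or a numeric subjects-by-ROI matrix.
#' @param atlas a [roi_atlas()] (ignored when `x` is a thickness table).
#' @return An object of class `scn_covariance`: list with `r` (symmetric,
#'   unit diagonal), `p` (symmetric, `NA` diagonal), `n` (subjects) and the
#'   atlas.
#' @export
correlation_matrix <- function(x, atlas = dk_atlas()) {
  if (is.data.frame(x)) {
    if (length(unique(x$condition)) != 1)
      stop("thickness table must contain a single condition")
    if (anyDuplicated(x$subject_id) > 0)
      stop("one row per subject required")
    if (!is.null(attr(x, "atlas"))) atlas <- attr(x, "atlas")
    x <- as.matrix(x[, as.character(atlas)])
  }
  if (ncol(x) != length(atlas))
    stop("matrix has ", ncol(x), " columns but atlas has ", length(atlas),
         " regions")
  colnames(x) <- as.character(atlas)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 subjects for correlation")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance ROI: ", colnames(x)[which(sds == 0)[1]])
  r <- cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  p <- .pearson_p(r, n)
  diag(p) <- NA_real_
  dimnames(r) <- dimnames(p) <- list(as.character(atlas), as.character(atlas))
  structure(list(r = r, p = p, n = n, atlas = atlas),
            class = "scn_covariance")
}

#' @export
print.scn_covariance <- function(x, ...) {
  cat("SCN covariance:", nrow(x$r), "ROIs, n =", x$n, "subjects\n")
  invisible(x)
}

#' FDR-threshold and binarize a covariance matrix
#'
#' Applies Benjamini-Hochberg step-up control at level `q` to the
#' upper-triangle p-values (each undirected ROI pair is one hypothesis; 2278
#' for the 68-ROI atlas). An edge is kept iff its p-value is BH-significant
#' at `q` AND its correlation is positive; negative correlations are
#' excluded after FDR, so the BH p-value pool is not affected by the sign
#' filter.
#'
#' @param cov an `scn_covariance` from [correlation_matrix()].
#' @param q FDR level in (0, 1).
#' @return An `scn_network` (binary, symmetric, zero diagonal).
#' @export
threshold_fdr <- function(cov, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  ut <- upper.tri(cov$r)
  padj <- p.adjust(cov$p[ut], method = "BH")
  keep <- padj <= q & cov$r[ut] > 0
  adj <- matrix(0L, nrow(cov$r), ncol(cov$r))
  adj[ut] <- as.integer(keep)
  adj <- adj + t(adj)
  binary_network(adj, cov$atlas)
}
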