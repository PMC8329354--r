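#' Group summary for summary-statistic tests
#'
#' @param mean,sd,n group mean, standard deviation and size.
#' @return A `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(mean = mean, sd = sd, n = n), class = "group_summary")
}

#' Two-sample t-test from printed summaries
#'
#' Recomputes a two-tailed two-sample t-test from (mean, SD, n) summaries,
#' as printed in demographics tables. Default is the pooled-variance test
#' on `n_a + n_b - 2` df; `welch = TRUE` gives the Welch-Satterthwaite
#' variant.
#'
#' @param a,b [group_summary()] objects (or lists with mean/sd/n).
#' @param welch use the Welch unequal-variance test instead of pooled?
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t_from_summary <- function(a, b, welch = FALSE) {
  if (a$sd == 0 && b$sd == 0) stop("t undefined: both group SDs are zero")
  if (welch) {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction on 1 df, the test
#' conventionally used for group-by-category demographics counts.
#'
#' @param counts 2x2 matrix of non-negative integer counts with all row and
#'   column margins positive.
#' @return List with `chisq`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined: zero margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, df = 1, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Correlate per-subject thickness change with a behavioral score
#'
#' Pearson correlation (with the same exact t-transform p-value used for
#' the covariance matrices) between per-subject thickness change
#' (restricted minus full, mm) and a behavioral measure.
#'
#' @param delta_thickness,score numeric vectors, one value per subject.
#' @return List with `r`, `n`, `p` (two-sided).
#' @export
behavior_correlation <- function(delta_thickness, score) {
  if (length(delta_thickness) != length(score))
    stop("vectors must have equal length")
  if (length(score) < 4) stop("need at least 4 subjects")
  if (!all(is.finite(delta_thickness)) || !all(is.finite(score)))
    stop("inputs must be finite")
  if (sd(delta_thickness) == 0 || sd(score) == 0)
    stop("correlation undefined: zero variance")
  r <- cor(delta_thickness, score)
  n <- length(score)
  list(r = r, n = n, p = .pearson_p(r, n))
}
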