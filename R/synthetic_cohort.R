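#' Specify a synthetic crossover morphometry cohort
#'
#' Defines the generative model for a two-condition crossover cohort of ROI
#' cortical thickness values: a multivariate normal per condition whose
#' correlation structure is built from block "covariance modules", with an
#' additive latent subject effect shared between a subject's two condition
#' draws (within-subject reliability), optional regional mean thinning under
#' one condition, and optional condition-specific increments of
#' within-module correlation.
#'
#' The per-condition target covariance has diagonal `base_sd^2` and
#' off-diagonal `r * base_sd^2` for ROI pairs inside a module (module
#' correlations and condition increments add where modules overlap). Any
#' resulting pairwise correlation above 0.999, or a target matrix that is
#' not positive semi-definite, is a hard configuration error.
#'
#' @param n_young,n_old subjects per age group.
#' @param conditions two condition labels; the first is the "restricted"
#'   arm by convention.
#' @param atlas a [roi_atlas()].
#' @param base_mean,base_sd baseline thickness mean and between-subject SD,
#'   in mm.
#' @param covariance_modules list of `list(rois =, r =)` entries: ROI labels
#'   (or 1-based indices) and within-module correlation in `[0, 1)`.
#' @param thinning_effects list of `list(roi =, condition =, shift =)`:
#'   subtract `shift` mm from the ROI's mean under that condition.
#' @param covariance_effects list of `list(rois =, condition =, dr =)`:
#'   add `dr` to the within-module correlation under that condition.
#' @param subject_reliability within-subject cross-condition correlation in
#'   `[0, 1)`.
#' @param seed integer seed; mandatory for reproducibility.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [build_target_covariance()]
#' @export
cohort_spec <- function(n_young = 43, n_old = 37,
                        conditions = c("restricted", "full"),
                        atlas = dk_atlas(),
                        base_mean = 2.5, base_sd = 0.25,
                        covariance_modules = list(),
                        thinning_effects = list(),
                        covariance_effects = list(),
                        subject_reliability = 0.5,
                        seed = 1L) {
  stopifnot(length(conditions) == 2, !anyDuplicated(conditions))
  if (n_young + n_old <= 3)
    stop("need more than 3 subjects for correlation analysis")
  if (base_mean <= 0 || base_sd <= 0) stop("base_mean and base_sd must be > 0")
  if (subject_reliability < 0 || subject_reliability >= 1)
    stop("subject_reliability must be in [0, 1)")
  if (is.null(seed) || !is.finite(seed)) stop("seed is mandatory")
  resolve <- function(rois) {
    if (is.numeric(rois)) {
      if (any(rois < 1 | rois > length(atlas))) stop("ROI index out of range")
      return(as.integer(rois))
    }
    idx <- match(rois, as.character(atlas))
    if (anyNA(idx)) stop("unknown ROI label(s): ",
                         paste(rois[is.na(idx)], collapse = ", "))
    idx
  }
  covariance_modules <- lapply(covariance_modules, function(m) {
    if (m$r < 0 || m$r >= 1) stop("module correlation must be in [0, 1)")
    list(rois = resolve(m$rois), r = m$r)
  })
  thinning_effects <- lapply(thinning_effects, function(e) {
    if (!e$condition %in% conditions) stop("unknown condition in thinning effect")
    list(roi = resolve(e$roi), condition = e$condition, shift = e$shift)
  })
  covariance_effects <- lapply(covariance_effects, function(e) {
    if (!e$condition %in% conditions)
      stop("unknown condition in covariance effect")
    list(rois = resolve(e$rois), condition = e$condition, dr = e$dr)
  })
  spec <- structure(list(
    n_young = n_young, n_old = n_old, conditions = conditions, atlas = atlas,
    base_mean = base_mean, base_sd = base_sd,
    covariance_modules = covariance_modules,
    thinning_effects = thinning_effects,
    covariance_effects = covariance_effects,
    subject_reliability = subject_reliability,
    seed = as.integer(seed)), class = "cohort_spec")
  # fail early on an unsatisfiable correlation structure
  for (cond in conditions) build_target_covariance(spec, cond)
  spec
}

#' Default cohort specification
#'
#' The study conditions emulated throughout: 43 young and 37 old subjects,
#' conditions `restricted`/`full`, 68-ROI Desikan-Killiany atlas, baseline
#' thickness 2.5 +/- 0.25 mm, within-subject reliability 0.5, and four
#' bilateral covariance modules (prefrontal, parietal, occipital, temporal)
#' at within-module correlation 0.4, giving the covariance matrix the
#' block-community structure real morphometry shows. No condition effects.
#'
#' @param ... overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(...) {
  pick <- function(regions) {
    as.character(outer(c("lh_", "rh_"), regions, paste0))
  }
  modules <- list(
    list(rois = pick(c("superiorfrontal", "rostralmiddlefrontal",
                       "caudalmiddlefrontal", "parsopercularis",
                       "parstriangularis")), r = 0.4),
    list(rois = pick(c("superiorparietal", "inferiorparietal",
                       "supramarginal", "precuneus", "postcentral")), r = 0.4),
    list(rois = pick(c("lateraloccipital", "cuneus", "pericalcarine",
                       "lingual")), r = 0.4),
    list(rois = pick(c("superiortemporal", "middletemporal",
                       "inferiortemporal", "fusiform")), r = 0.4))
  args <- modifyList(list(covariance_modules = modules), list(...))
  do.call(cohort_spec, args)
}

#' Target ROI covariance for one condition
#'
#' Assembles the condition's target covariance matrix from the spec's
#' modules and condition-specific correlation increments, then checks
#' positive semi-definiteness (smallest eigenvalue >= -1e-10).
#'
#' @param spec a [cohort_spec()].
#' @param condition one of `spec$conditions`.
#' @return Symmetric positive semi-definite matrix (mm^2), labelled by ROI.
#' @export
build_target_covariance <- function(spec, condition) {
  if (!condition %in% spec$conditions) stop("unknown condition: ", condition)
  p <- length(spec$atlas)
  R <- diag(p)
  add_block <- function(R, idx, amount) {
    R[idx, idx] <- R[idx, idx] + amount
    R[cbind(idx, idx)] <- 1
    R
  }
  check_psd <- function(R, what) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      stop(what, " makes the target correlation matrix non-positive ",
           "semi-definite (min eigenvalue ", signif(ev, 4), ")")
  }
  for (i in seq_along(spec$covariance_modules)) {
    m <- spec$covariance_modules[[i]]
    R <- add_block(R, m$rois, m$r)
    if (max(R[m$rois, m$rois][upper.tri(diag(length(m$rois)))]) > 0.999)
      stop("covariance module ", i, " pushes a correlation above 0.999")
    check_psd(R, paste0("covariance module ", i))
  }
  for (i in seq_along(spec$covariance_effects)) {
    e <- spec$covariance_effects[[i]]
    if (e$condition != condition) next
    R <- add_block(R, e$rois, e$dr)
    if (length(e$rois) > 1 &&
        max(R[e$rois, e$rois][upper.tri(diag(length(e$rois)))]) > 0.999)
      stop("covariance effect ", i, " pushes a correlation above 0.999")
    check_psd(R, paste0("covariance effect ", i))
  }
  sigma <- spec$base_sd^2 * R
  dimnames(sigma) <- list(as.character(spec$atlas), as.character(spec$atlas))
  sigma
}

# Matrix square root of a PSD correlation matrix via eigendecomposition.
.psd_factor <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Simulate a paired two-condition cohort
#'
#' Draws one thickness vector per subject and condition from the condition's
#' target multivariate normal. The two draws of a subject share a latent
#' Gaussian subject effect so that the cross-condition correlation of each
#' ROI is approximately `subject_reliability`; conditional on that effect
#' the draws are independent. Mean thinning effects are applied to the
#' stated ROI and condition. Output is bit-identical under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return A `thickness_table` with `2 * (n_young + n_old)` rows (one per
#'   subject and condition), group labels `young`/`old`.
#' @export
simulate_cohort <- function(spec) {
  n <- spec$n_young + spec$n_old
  p <- length(spec$atlas)
  rho <- spec$subject_reliability
  set.seed(spec$seed)
  z_subj <- matrix(rnorm(n * p), n, p)   # shared latent subject effect
  draws <- vector("list", 2)
  for (k in 1:2) {
    cond <- spec$conditions[k]
    sigma <- build_target_covariance(spec, cond)
    L <- .psd_factor(sigma)
    mu <- rep(spec$base_mean, p)
    for (e in spec$thinning_effects)
      if (e$condition == cond) mu[e$roi] <- mu[e$roi] - e$shift
    z_cond <- matrix(rnorm(n * p), n, p)
    z <- sqrt(rho) * z_subj + sqrt(1 - rho) * z_cond
    draws[[k]] <- sweep(z %*% t(L), 2, mu, "+")
  }
  ids <- sprintf("S%03d", seq_len(n))
  groups <- rep(c("young", "old"), c(spec$n_young, spec$n_old))
  tab <- do.call(rbind, lapply(1:2, function(k) {
    d <- as.data.frame(draws[[k]])
    names(d) <- as.character(spec$atlas)
    cbind(data.frame(subject_id = ids, condition = spec$conditions[k],
                     group = groups, stringsAsFactors = FALSE), d)
  }))
  rownames(tab) <- NULL
  validate_thickness(tab, spec$atlas, paired = TRUE)
}
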