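# Config schema: names, types and defaults for run_pipeline(). `input` and
# `synthetic` are mutually exclusive sources of the thickness table.
.config_defaults <- list(q = 0.05, q_nodal = 0.05, n_perm = 1000,
                         n_random = 100, stratify = FALSE,
                         conditions = c("restricted", "full"))

.validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping")
  if (is.null(cfg$seed)) stop("config field 'seed': required (no default)")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config field 'seed': must be an integer")
  cfg <- modifyList(.config_defaults, cfg)
  if (!is.numeric(cfg$q) || cfg$q <= 0 || cfg$q >= 1)
    stop("config field 'q': must be in (0, 1)")
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100)
    stop("config field 'n_perm': must be >= 100")
  if (!is.numeric(cfg$n_random) || cfg$n_random < 0)
    stop("config field 'n_random': must be >= 0")
  if (length(cfg$conditions) != 2)
    stop("config field 'conditions': exactly two labels required")
  has_input <- !is.null(cfg$input)
  has_syn <- !is.null(cfg$synthetic)
  if (has_input == has_syn)
    stop("config: exactly one of 'input' or 'synthetic' is required")
  if (has_syn) {
    s <- cfg$synthetic
    allowed <- c("n_young", "n_old", "base_mean", "base_sd",
                 "subject_reliability", "modules", "thinning",
                 "covariance_effects")
    bad <- setdiff(names(s), allowed)
    if (length(bad))
      stop("config field 'synthetic.", bad[1], "': unknown field")
  }
  cfg
}

.spec_from_config <- function(cfg) {
  s <- cfg$synthetic
  norm_mod <- function(m) list(rois = unlist(m$rois), r = m$r)
  norm_thin <- function(e) list(roi = e$roi, condition = e$condition,
                                shift = e$shift)
  norm_cov <- function(e) list(rois = unlist(e$rois),
                               condition = e$condition, dr = e$dr)
  args <- list(conditions = cfg$conditions, seed = cfg$seed)
  for (f in c("n_young", "n_old", "base_mean", "base_sd",
              "subject_reliability"))
    if (!is.null(s[[f]])) args[[f]] <- s[[f]]
  if (!is.null(s$modules))
    args$covariance_modules <- lapply(s$modules, norm_mod)
  if (!is.null(s$thinning))
    args$thinning_effects <- lapply(s$thinning, norm_thin)
  if (!is.null(s$covariance_effects))
    args$covariance_effects <- lapply(s$covariance_effects, norm_cov)
  if (is.null(s$modules) && is.null(args$covariance_modules))
    do.call(default_cohort_spec, args)
  else
    do.call(cohort_spec, args)
}

.log <- function(...) message("[scnet] ", ...)

#' Run the full SCN pipeline from a config file
#'
#' Orchestrates simulate (or load) -> per-condition covariance -> FDR
#' binarization -> metrics -> paired permutation -> report. The YAML config
#' must name a `seed` and exactly one data source (`input`: a thickness
#' table path, or `synthetic`: a cohort specification); `q`, `q_nodal`,
#' `n_perm`, `n_random`, `conditions` and `stratify` are optional with
#' documented defaults. Outputs written to `out_dir`: per-condition
#' correlation/p matrices and binary networks (TSV), `metrics.json`,
#' `permutation.json`, optional `stratified.json`, and `manifest.json`
#' (config hash, seed, parameters, package version). Re-running with the
#' same config and seed reproduces every output byte-for-byte.
#'
#' @param config_path path to a YAML config file.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the table, networks, metrics and
#'   permutation result.
#' @export
run_pipeline <- function(config_path, out_dir) {
  cfg <- .validate_config(yaml::read_yaml(config_path))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- dk_atlas()
  cfg_hash <- unname(tools::md5sum(config_path))

  if (!is.null(cfg$input)) {
    .log("reading thickness table: ", cfg$input)
    tab <- read_thickness_table(cfg$input, atlas)
  } else {
    .log("simulating synthetic cohort (seed ", cfg$seed, ")")
    spec <- .spec_from_config(cfg)
    tab <- simulate_cohort(spec)
    write_thickness_table(tab, file.path(out_dir, "cohort.tsv"), atlas)
  }
  tab <- validate_thickness(tab, atlas, paired = TRUE)

  nets <- list()
  metrics <- list()
  for (i in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[i]
    .log("building SCN for condition '", cond, "'")
    cov <- correlation_matrix(tab[tab$condition == cond, ], atlas)
    net <- threshold_fdr(cov, cfg$q)
    write_labelled_matrix(cov$r, file.path(out_dir,
                                           paste0("correlation_", cond, ".tsv")))
    write_labelled_matrix(cov$p, file.path(out_dir,
                                           paste0("pvalues_", cond, ".tsv")))
    write_network(net, file.path(out_dir, paste0("network_", cond, ".tsv")))
    m <- network_metrics(net, n_random = cfg$n_random,
                         seed = cfg$seed + i, nodal = TRUE)
    nets[[cond]] <- net
    metrics[[cond]] <- list(global = as.list(m$global),
                            nodal = lapply(m$nodal, as.list),
                            n_edges = sum(net$adjacency) / 2,
                            config_hash = cfg_hash)
  }
  .write_json(metrics, file.path(out_dir, "metrics.json"))

  .log("paired permutation test (", cfg$n_perm, " permutations)")
  perm <- permute_conditions(tab, conditions = cfg$conditions,
                             n_perm = cfg$n_perm, q = cfg$q,
                             q_nodal = cfg$q_nodal,
                             n_random = cfg$n_random, seed = cfg$seed,
                             atlas = atlas)
  .write_json(.perm_report(perm, cfg_hash),
              file.path(out_dir, "permutation.json"))

  strat <- NULL
  if (isTRUE(cfg$stratify)) {
    .log("age-stratified analysis")
    strat <- stratified_analysis(tab, seed = cfg$seed,
                                 conditions = cfg$conditions,
                                 n_perm = cfg$n_perm, q = cfg$q,
                                 q_nodal = cfg$q_nodal,
                                 n_random = cfg$n_random, atlas = atlas)
    .write_json(lapply(strat, .perm_report, cfg_hash = cfg_hash),
                file.path(out_dir, "stratified.json"))
  }

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   q = cfg$q, q_nodal = cfg$q_nodal, n_perm = cfg$n_perm,
                   n_random = cfg$n_random,
                   conditions = as.list(cfg$conditions),
                   stratify = isTRUE(cfg$stratify),
                   threshold_recomputed_per_permutation = TRUE,
                   swap_attempts_per_edge = 10,
                   package = "scnet",
                   version = as.character(packageVersion("scnet")))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  .log("done: outputs in ", out_dir)
  invisible(list(table = tab, networks = nets, metrics = metrics,
                 permutation = perm, stratified = strat))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

.perm_report <- function(perm, cfg_hash) {
  list(conditions = as.list(perm$conditions),
       observed = lapply(perm$observed, as.list),
       global = perm$global,
       nodal = perm$nodal,
       params = perm$params,
       config_hash = cfg_hash)
}

#' Text summary of a permutation result
#'
#' One row per metric: observed value under each condition, difference,
#' two-sided permutation p and (for nodal metrics) the number of
#' BH-significant ROIs.
#'
#' @param perm an `scn_permutation`.
#' @return A data frame.
#' @export
permutation_summary <- function(perm) {
  g <- perm$global
  out <- data.frame(metric = g$metric,
                    perm$observed[[1]][g$metric],
                    perm$observed[[2]][g$metric],
                    difference = g$observed_diff,
                    p_two_sided = g$p_two_sided,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:3] <- perm$conditions
  if (!is.null(perm$nodal)) {
    sig <- vapply(perm$nodal, function(d) sum(d$significant), numeric(1))
    attr(out, "nodal_significant") <- sig
  }
  out
}
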