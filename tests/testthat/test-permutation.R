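# Small paired cohort for permutation unit tests
perm_cohort <- function(seed = 1, n_young = 22, n_old = 18, n_roi = 16,
                        dr = 0, atlas = toy_atlas(n_roi)) {
  eff <- if (dr > 0)
    list(list(rois = 1:6, condition = "restricted", dr = dr))
  else list()
  mod2 <- 7:min(12, n_roi)
  spec <- cohort_spec(n_young = n_young, n_old = n_old, atlas = atlas,
                      covariance_modules = list(list(rois = 1:6, r = 0.15),
                                                list(rois = mod2, r = 0.6)),
                      covariance_effects = eff, seed = seed)
  simulate_cohort(spec)
}

test_that("identical condition tables give zero differences and p >= 0.5", {
  atlas <- toy_atlas(10)
  tab <- perm_cohort(seed = 2, n_roi = 10, atlas = atlas)
  same <- tab
  full_rows <- same$condition == "full"
  ord_r <- match(same$subject_id[full_rows],
                 same$subject_id[same$condition == "restricted"])
  same[full_rows, as.character(atlas)] <-
    same[same$condition == "restricted", as.character(atlas)][ord_r, ]
  res <- permute_conditions(same, n_perm = 100, n_random = 0,
                            nodal = FALSE, seed = 5, atlas = atlas)
  expect_equal(res$global$observed_diff, rep(0, 4))
  expect_true(all(res$global$p_two_sided >= 0.5))
})

test_that("results are reproducible bit-for-bit under a fixed seed", {
  tab <- perm_cohort(seed = 3)
  r1 <- permute_conditions(tab, n_perm = 100, n_random = 5, seed = 17,
                           atlas = toy_atlas(16))
  r2 <- permute_conditions(tab, n_perm = 100, n_random = 5, seed = 17,
                           atlas = toy_atlas(16))
  expect_identical(r1$null_global, r2$null_global)
  expect_identical(r1$global, r2$global)
  expect_identical(r1$nodal, r2$nodal)
})

test_that("p-values respect the add-one estimator bounds", {
  tab <- perm_cohort(seed = 4)
  res <- permute_conditions(tab, n_perm = 100, n_random = 0, seed = 6,
                            atlas = toy_atlas(16))
  ps <- c(res$global$p_greater, res$global$p_less)
  expect_true(all(ps >= 1 / 101))
  expect_true(all(ps <= 1))
  expect_true(all(res$global$p_two_sided <= 1))
  for (nm in names(res$nodal))
    expect_true(all(res$nodal[[nm]]$p_two_sided >= 1 / 101))
})

test_that("swapping condition labels negates differences and mirrors p", {
  tab <- perm_cohort(seed = 7, dr = 0.4)
  a <- permute_conditions(tab, conditions = c("restricted", "full"),
                          n_perm = 100, n_random = 0, nodal = TRUE,
                          seed = 21, atlas = toy_atlas(16))
  b <- permute_conditions(tab, conditions = c("full", "restricted"),
                          n_perm = 100, n_random = 0, nodal = TRUE,
                          seed = 21, atlas = toy_atlas(16))
  expect_equal(a$global$observed_diff, -b$global$observed_diff)
  expect_equal(a$global$p_greater, b$global$p_less)
  expect_equal(a$global$p_less, b$global$p_greater)
  expect_equal(a$nodal$degree$observed_diff, -b$nodal$degree$observed_diff)
})

test_that("unpaired subjects are rejected by name", {
  tab <- perm_cohort(seed = 8)
  broken <- tab[!(tab$subject_id == "S003" & tab$condition == "full"), ]
  expect_error(permute_conditions(broken, n_perm = 100, seed = 1,
                                  atlas = toy_atlas(16)),
               "S003")
  expect_error(permute_conditions(tab, n_perm = 100, atlas = toy_atlas(16)),
               "seed is mandatory")
  expect_error(permute_conditions(tab, n_perm = 50, seed = 1,
                                  atlas = toy_atlas(16)),
               "n_perm")
})

test_that("an injected covariance increase is detected with nodal BH", {
  # one cohort with a strong injected module; smoke-level power check
  tab <- perm_cohort(seed = 9, n_young = 43, n_old = 37, dr = 0.5)
  res <- permute_conditions(tab, n_perm = 200, n_random = 0, seed = 31,
                            atlas = toy_atlas(16))
  expect_lt(res$global$p_two_sided[res$global$metric == "C"], 0.05)
  # the injected module ROIs should dominate nodal-efficiency increases
  ne <- res$nodal$nodal_efficiency
  expect_gt(mean(ne$observed_diff[1:6]), mean(ne$observed_diff[7:16]))
})

test_that("stratified analysis runs per group and validates group size", {
  tab <- perm_cohort(seed = 10, n_young = 12, n_old = 10)
  res <- stratified_analysis(tab, seed = 2, n_perm = 100, n_random = 0,
                             nodal = FALSE, atlas = toy_atlas(16))
  expect_named(res, c("young", "old"))
  expect_s3_class(res$young, "scn_permutation")
  expect_equal(res$young$params$n_subjects, 12)
  expect_equal(res$old$params$n_subjects, 10)

  tiny <- tab[tab$group == "young" | tab$subject_id %in%
                unique(tab$subject_id[tab$group == "old"])[1:2], ]
  expect_error(stratified_analysis(tiny, seed = 2, n_perm = 100,
                                   atlas = toy_atlas(16)),
               "fewer than 4")
})
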