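# Demo pipeline configuration: synthetic 80-subject crossover cohort with
# four bilateral background covariance modules and an injected
# cingulo-insular module whose correlation rises by 0.3 under restriction.
# Run with: run_pipeline(system.file("extdata/demo-config.yaml",
#                                    package = "scnet"), "demo-out")
seed: 7
q: 0.05
q_nodal: 0.05
n_perm: 1000
n_random: 100
stratify: false
conditions: [restricted, full]
synthetic:
  n_young: 43
  n_old: 37
  base_mean: 2.5
  base_sd: 0.25
  subject_reliability: 0.5
  modules:
    - rois: [lh_superiorfrontal, rh_superiorfrontal, lh_rostralmiddlefrontal,
             rh_rostralmiddlefrontal, lh_caudalmiddlefrontal,
             rh_caudalmiddlefrontal, lh_parsopercularis, rh_parsopercularis,
             lh_parstriangularis, rh_parstriangularis]
      r: 0.4
    - rois: [lh_superiorparietal, rh_superiorparietal, lh_inferiorparietal,
             rh_inferiorparietal, lh_supramarginal, rh_supramarginal,
             lh_precuneus, rh_precuneus, lh_postcentral, rh_postcentral]
      r: 0.4
    - rois: [lh_lateraloccipital, rh_lateraloccipital, lh_cuneus, rh_cuneus,
             lh_pericalcarine, rh_pericalcarine, lh_lingual, rh_lingual]
      r: 0.4
    - rois: [lh_superiortemporal, rh_superiortemporal, lh_middletemporal,
             rh_middletemporal, lh_inferiortemporal, rh_inferiortemporal,
             lh_fusiform, rh_fusiform]
      r: 0.4
    - rois: [lh_caudalanteriorcingulate, rh_caudalanteriorcingulate,
             lh_posteriorcingulate, rh_posteriorcingulate,
             lh_rostralanteriorcingulate, rh_rostralanteriorcingulate,
             lh_isthmuscingulate, rh_isthmuscingulate,
             lh_insula, rh_insula]
      r: 0.2
  covariance_effects:
    - rois: [lh_caudalanteriorcingulate, rh_caudalanteriorcingulate,
             lh_posteriorcingulate, rh_posteriorcingulate,
             lh_rostralanteriorcingulate, rh_rostralanteriorcingulate,
             lh_isthmuscingulate, rh_isthmuscingulate,
             lh_insula, rh_insula]
      condition: restricted
      dr: 0.3
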