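# Shared fixtures: a small library screen keeps single-module tests fast;
# the full 2,298-compound screen is built only where a test needs it.

small_screen <- function(n_compounds = 400, subtype = "A4B2", seed = 101,
                         well_cv = 0.05, n_runs = 2,
                         group_sizes = c(A3B4_ONLY = 4, A4B2_ONLY = 3,
                                         A6_ONLY = 2, BOTH_B2 = 4,
                                         ALL_THREE = 3, ARTIFACT = 3)) {
  manifest <- build_manifest(n_compounds)
  truth <- simulate_truth(manifest, group_sizes = group_sizes, seed = seed)
  ctx <- assay_context(subtype)
  sim <- simulate_screen(manifest, truth, ctx,
                         noise_model(well_cv = well_cv, seed = seed + 1),
                         n_runs = n_runs)
  list(manifest = manifest, truth = truth, ctx = ctx, sim = sim)
}

full_screen_manifest <- function() build_manifest(2298)

expect_tibble <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
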