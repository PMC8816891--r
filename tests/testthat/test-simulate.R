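test_that("generation is deterministic given the seed", {
  a <- small_screen(n_compounds = 204, seed = 7)$sim$reads
  b <- small_screen(n_compounds = 204, seed = 7)$sim$reads
  expect_identical(a, b)
  c_ <- small_screen(n_compounds = 204, seed = 8)$sim$reads
  expect_false(identical(a$final, c_$final))
})

test_that("noiseless generation recovers planted inhibition through the pipeline", {
  man <- build_manifest(204)
  truth <- simulate_truth(man, group_sizes = c(A3B4_ONLY = 2, A4B2_ONLY = 2,
                                               A6_ONLY = 1, BOTH_B2 = 2,
                                               ALL_THREE = 2, ARTIFACT = 2),
                          seed = 3)
  ctx <- assay_context("A4B2")
  noiseless <- noise_model(well_cv = 0, plate_scale_sd = 0, seed = 1)
  sim <- simulate_screen(man, truth, ctx, noiseless, n_runs = 1)
  norm <- normalize_plates(subtract_background(sim$reads))
  test_wells <- norm[norm$role == "TEST", ]
  planted <- sim$ground_truth$fluor_inhibition[
    match(test_wells$compound_id, sim$ground_truth$compound_id)]
  # NFS = 1 - planted inhibition exactly in the noiseless limit
  expect_equal(test_wells$nfs, 1 - planted, tolerance = 1e-9)
  # fully inhibited well sits at the zero-control level, inactive at 1
  expect_equal(max(abs(test_wells$nfs[planted == 0] - 1)), 0, tolerance = 1e-9)
})

test_that("realized control CV tracks the nominal well CV", {
  # Monte-Carlo over many plates: pooled per-plate positive-control CV
  # lands within a factor of 2 of the nominal well CV
  man <- build_manifest(204 * 25)
  truth <- simulate_truth(man, seed = 5)
  sim <- simulate_screen(man, truth, assay_context("A3B4"),
                         noise_model(well_cv = 0.05, seed = 13), n_runs = 1)
  qc <- qc_plates(subtract_background(sim$reads))
  expect_equal(nrow(qc), 25)
  expect_gt(mean(qc$cv_pos), 0.05 / 2)
  expect_lt(mean(qc$cv_pos), 0.05 * 2)
})

test_that("default-settings plates land in the expected QC ranges", {
  # Z' in [0.6, 0.95] across simulated plates; S:B above the screening
  # minimum of 4 at every subtype
  for (st in nachr_subtypes) {
    man <- build_manifest(204 * 12)
    truth <- simulate_truth(man, seed = 17)
    sim <- simulate_screen(man, truth, assay_context(st),
                           noise_model(seed = 19), n_runs = 1)
    qc <- qc_plates(subtract_background(sim$reads))
    expect_true(all(qc$z_prime > 0.6 & qc$z_prime < 0.95))
    expect_true(all(qc$sb_ratio > 4))
  }
})

test_that("dose-response generator hits the curve exactly at cv = 0", {
  conc <- dilution_series(100e-6, 3, 12)
  expect_equal(conc[12], 100e-6 / 3^11)
  d <- simulate_dose_response(0, 100, 1e-7, 1, conc, reps = 2, cv = 0)
  mu <- 100 / (1 + (1e-7 / d$conc_M))
  expect_equal(d$response, mu)
  expect_error(simulate_dose_response(0, 100, 1e-7, 1, c(-1e-6, 1e-6)),
               "positive")
  # seeded determinism
  d1 <- simulate_dose_response(0, 100, 1e-7, 1, conc, reps = 4, cv = 0.05, seed = 9)
  d2 <- simulate_dose_response(0, 100, 1e-7, 1, conc, reps = 4, cv = 0.05, seed = 9)
  expect_identical(d1, d2)
})

test_that("efflux generator produces exact inhibition in the noiseless limit", {
  man <- build_manifest(50)
  truth <- simulate_truth(man, group_sizes = c(A3B4_ONLY = 3, A4B2_ONLY = 0,
                                               A6_ONLY = 0, BOTH_B2 = 0,
                                               ALL_THREE = 2, ARTIFACT = 2),
                          seed = 23)
  noiseless <- noise_model(well_cv = 0, seed = 1)
  ef <- simulate_efflux(man$compound_id[1:20], truth, "A3B4", noiseless)
  val <- efflux_validation(ef)
  planted <- truth$truth[truth$truth$subtype == "A3B4", ]
  expected <- 100 * planted$true_inhibition[
    match(val$compounds$compound_id, planted$compound_id)]
  expect_equal(val$compounds$mean_pct_inhibition, unname(expected),
               tolerance = 1e-9)
  # artifacts (fluorescence-only) show zero channel inhibition
  artifact_ids <- truth$groups$compound_id[truth$groups$group == "ARTIFACT"]
  got <- val$compounds$mean_pct_inhibition[
    val$compounds$compound_id %in% artifact_ids]
  expect_equal(got, rep(0, length(got)), tolerance = 1e-9)
})

test_that("edge bias only distorts border wells", {
  man <- build_manifest(204)
  truth <- simulate_truth(man, seed = 3)
  ctx <- assay_context("A4B2")
  base <- simulate_screen(man, truth, ctx,
                          noise_model(well_cv = 0, plate_scale_sd = 0,
                                      edge_bias = 0, seed = 1), n_runs = 1)
  biased <- simulate_screen(man, truth, ctx,
                            noise_model(well_cv = 0, plate_scale_sd = 0,
                                        edge_bias = 0.2, seed = 1), n_runs = 1)
  edge <- base$reads$role == "EDGE_EXCLUDED"
  expect_equal(biased$reads$final[!edge], base$reads$final[!edge])
  expect_false(any(biased$reads$final[edge] == base$reads$final[edge]))
})
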