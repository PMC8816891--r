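test_that("coefficient of variation matches hand arithmetic and errors cleanly", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(90, 100, 110)), 0.1)  # sample SD 10, mean 100
  expect_error(coefficient_of_variation(c(0, 0, 0)), "zero-mean")
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("CV is scale-invariant", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(12, mean = 100, sd = 7)
    c_ <- runif(1, 0.1, 50)
    expect_equal(coefficient_of_variation(c_ * x),
                 coefficient_of_variation(x), tolerance = 1e-12)
  }
})

test_that("signal-to-background is the ratio of control means", {
  expect_equal(signal_to_background(c(110, 130), c(1, 3)), 60)
  expect_equal(signal_to_background(c(7, 9), c(7, 9)), 1)
  expect_error(signal_to_background(c(1, 2), c(-1, 1)), "zero")
  expect_error(signal_to_background(numeric(0), c(1)), "non-empty")
})

test_that("z_prime matches its formula and boundary behavior", {
  expect_equal(z_prime(rep(100, 4), rep(3, 4)), 1)  # zero variance limit
  # means 100/0, sds 5/2: 1 - 3*7/100
  pos <- c(95, 100, 105); pos <- pos / sd(pos) * 5
  pos <- pos - mean(pos) + 100
  zero <- c(-2, 0, 2); zero <- zero / sd(zero) * 2
  expect_equal(z_prime(pos, zero), 1 - 3 * 7 / 100)
  expect_error(z_prime(c(5, 7), c(7, 5)), "equal")
  expect_error(z_prime(5, c(1, 2)), "at least 2")
})

test_that("z_prime is invariant under common affine rescaling and decreasing in SD", {
  set.seed(21)
  for (i in 1:20) {
    pos <- rnorm(12, 1000, 30)
    zero <- rnorm(12, 50, 10)
    a <- runif(1, 0.5, 10); b <- runif(1, -20, 20)
    expect_equal(z_prime(a * pos + b, a * zero + b), z_prime(pos, zero),
                 tolerance = 1e-10)
    # inflating one control's spread strictly lowers Z'
    wider <- mean(pos) + (pos - mean(pos)) * 2
    expect_lt(z_prime(wider, zero), z_prime(pos, zero))
  }
})

test_that("positional bias flags a doubled column and passes clean plates", {
  lay <- default_layout()
  plate <- lay
  plate$nfs <- 1
  bias <- suppressWarnings(positional_bias(plate))
  expect_true(all(bias$bias == 0))
  expect_false(any(bias$flagged))

  set.seed(5)
  plate$nfs <- rnorm(384, 1, 0.05)
  plate$nfs[plate$col == 10 & plate$role == "TEST"] <- plate$nfs[plate$col == 10 & plate$role == "TEST"] * 2
  bias <- positional_bias(plate, flag_threshold = 3)
  flagged_cols <- bias$index[bias$axis == "col" & bias$flagged]
  expect_true(10 %in% flagged_cols)
  clean_rows <- bias[bias$axis == "row", ]
  expect_true(all(abs(clean_rows$bias) < 3 | clean_rows$flagged))
})

test_that("no positional flags on the default simulated plate", {
  scr <- small_screen(n_compounds = 204, n_runs = 1)
  net <- subtract_background(scr$sim$reads)
  norm <- normalize_plates(net)
  p1 <- norm[norm$plate_id == norm$plate_id[1], ]
  bias <- positional_bias(p1, flag_threshold = 3)
  expect_false(any(bias$flagged))
})

test_that("robust outlier removal drops gross outliers, never clean data", {
  res <- remove_control_outliers(c(100, 101, 99, 100, 500), k = 3)
  expect_equal(res$removed, 5L)
  expect_equal(res$retained, c(100, 101, 99, 100))

  expect_equal(remove_control_outliers(rep(7, 12))$removed, integer(0))
  expect_warning(res3 <- remove_control_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(res3$removed, integer(0))

  set.seed(31)
  n_removed <- vapply(1:50, function(i) {
    length(remove_control_outliers(rnorm(12), k = 5)$removed)
  }, numeric(1))
  expect_lt(mean(n_removed > 0), 0.1)  # clean Gaussian rarely trimmed at k=5

  # removal is capped at 25% of the series
  x <- c(rep(100, 8), rep(1e5, 4))
  expect_lte(length(remove_control_outliers(x, k = 1)$removed), 3)
})

test_that("QC gate uses strict thresholds and is monotone", {
  rep_ok <- tibble::tibble(cv_pos = 0.05, sb_ratio = 60, z_prime = 0.8)
  expect_true(gate_plate(rep_ok))
  expect_false(gate_plate(tibble::tibble(cv_pos = 0.05, sb_ratio = 60, z_prime = 0.4)))
  expect_false(gate_plate(tibble::tibble(cv_pos = 0.10, sb_ratio = 60, z_prime = 0.8)))
  expect_false(gate_plate(tibble::tibble(cv_pos = 0.05, sb_ratio = 4, z_prime = 0.8)))

  # improving any metric never flips pass -> fail
  set.seed(41)
  for (i in 1:50) {
    r <- tibble::tibble(cv_pos = runif(1, 0, 0.2), sb_ratio = runif(1, 1, 100),
                        z_prime = runif(1, -0.5, 1))
    better <- tibble::tibble(cv_pos = r$cv_pos * 0.9, sb_ratio = r$sb_ratio * 1.1,
                             z_prime = r$z_prime + 0.01)
    expect_true(!gate_plate(r) || gate_plate(better))
  }
})

test_that("qc_plates reports per-plate metrics on simulated data", {
  scr <- small_screen(n_compounds = 408, n_runs = 1)
  net <- subtract_background(scr$sim$reads)
  qc <- qc_plates(net)
  expect_tibble(qc, c("plate_id", "cv_pos", "cv_zero", "sb_ratio", "z_prime",
                      "passed"))
  expect_equal(nrow(qc), 2)
  expect_true(all(qc$passed))
  expect_true(all(qc$sb_ratio > 4))
  expect_true(all(qc$z_prime < 1))
})
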