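test_that("noiseless approach segments obey the contact model exactly", {
  p <- quiet_preset(load_range_nN = c(6, 6))
  cv <- generate_force_curve(10e3, p, seed = 3)
  z0 <- attr(cv, "truth")$contact_z_nm
  app <- curve_force(cv, "approach")
  delta <- (app$z_nm - z0) - app$deflection_nm
  sel <- delta > 1  # in contact
  expected <- hertz_force(delta[sel], 10e3, R_m = 3e-6, nu = 0.5)
  expect_lt(max(abs(app$force_pN[sel] - expected) / expected), 1e-9)
  # spot value: the model at 100 nm indentation
  i <- which.min(abs(delta - 100))
  expect_equal(app$force_pN[i], hertz_force(delta[i], 10e3, 3e-6), tolerance = 1e-12)
})

test_that("generators are pure functions of (parameters, seed)", {
  p <- mechanical_preset("ctc_metastatic")
  a <- generate_force_curve(6.2e3, p, seed = 9)
  b <- generate_force_curve(6.2e3, p, seed = 9)
  expect_equal(a$approach, b$approach)
  expect_equal(a$retraction, b$retraction)
  c2 <- generate_force_curve(6.2e3, p, seed = 10)
  expect_false(isTRUE(all.equal(a$approach$deflection_nm,
                                c2$approach$deflection_nm)))

  m1 <- generate_force_volume(p, seed = 4)
  m2 <- generate_force_volume(p, seed = 4)
  expect_equal(ctcforce:::fv_samples(m1), ctcforce:::fv_samples(m2))

  i1 <- generate_fluorescence_image(5, 2, noise_sd = 1, seed = 2)
  i2 <- generate_fluorescence_image(5, 2, noise_sd = 1, seed = 2)
  expect_identical(i1$pixels, i2$pixels)
})

test_that("stiff-cell indentations under 7-12 nN loads span the expected band", {
  for (load in c(7, 9, 12)) {
    cv <- generate_force_curve(23.9e3, quiet_preset(load_range_nN = c(load, load)),
                               seed = 1)
    dmax <- attr(cv, "truth")$delta_max_nm
    expect_gt(dmax, 200)
    expect_lt(dmax, 400)
  }
})

test_that("grid geometry follows the preset", {
  m <- generate_force_volume(mechanical_preset("ctc_metastatic"), seed = 1)
  expect_equal(c(m$n_rows, m$n_cols), c(8L, 8L))
  expect_length(m$curves, 64)
  expect_equal(m$pixel_size, 0.156)

  mp <- generate_force_volume(mechanical_preset("pc3"), seed = 1)
  expect_length(mp$curves, 16)
  expect_equal(mp$pixel_size, 0.625)
})

test_that("cell populations draw independent cells consistently", {
  p <- mechanical_preset("ctc_localized")
  pop <- generate_cell_population(p, 3, seed = 21)
  expect_length(pop, 3)
  expect_equal(sum(vapply(pop, function(m) length(m$curves), integer(1))), 192)

  expect_error(generate_cell_population(p, 0, seed = 1), "argument error")

  # n_cells = 1 is one force-volume call with the derived sub-seed
  pop1 <- generate_cell_population(p, 1, seed = 33)
  sub <- withr::with_seed(33L, sample.int(.Machine$integer.max - 1L, 1))
  direct <- generate_force_volume(p, sub, label = "cell_01")
  expect_equal(ctcforce:::fv_samples(pop1[[1]]), ctcforce:::fv_samples(direct))
})

test_that("cell-level modulus draws average to the preset mean", {
  # law of large numbers on the generating values, 200 single-pixel cells
  p <- mechanical_preset("ctc_metastatic", grid = c(1L, 1L))
  pop <- generate_cell_population(p, 200, seed = 77)
  e <- vapply(pop, function(m) attr(m, "truth")$E_cell_Pa, numeric(1))
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - p$E_mean_Pa), 3 * se)
})

test_that("limited piezo travel is reported as an error", {
  p <- quiet_preset(load_range_nN = c(12, 12), max_z_travel_nm = 400)
  expect_error(generate_force_curve(6.2e3, p, seed = 1), "travel exceeded")
})

test_that("synthetic fluorescence images have the requested contrast", {
  msk <- matrix(FALSE, 32, 32); msk[11:20, 11:20] <- TRUE
  img <- generate_fluorescence_image(5, 2, sample_mask = msk, noise_sd = 0, seed = 1)
  expect_equal(corrected_total_fluorescence(img), 300)  # 100 px * (5 - 2)

  flat <- generate_fluorescence_image(2, 2, sample_mask = msk, noise_sd = 0, seed = 1)
  expect_equal(corrected_total_fluorescence(flat), 0)

  overlap <- matrix(TRUE, 32, 32)
  expect_error(
    generate_fluorescence_image(5, 2, sample_mask = overlap,
                                background_mask = overlap, seed = 1),
    "overlapping masks"
  )
  expect_error(generate_fluorescence_image(1, 2, seed = 1), "argument error")
})

test_that("capture experiments follow the binomial/Poisson model", {
  all_in <- generate_capture_experiment(1, 1000, 50, seed = 1)
  expect_equal(all_in$n_captured, 1000L)
  none <- generate_capture_experiment(0, 1000, 50, seed = 1)
  expect_equal(none$n_captured, 0L)

  eff <- vapply(1:500, function(s) {
    e <- generate_capture_experiment(0.895, 1000, 50, seed = s)
    capture_efficiency(e$n_captured, e$n_spiked)
  }, numeric(1))
  expect_lt(abs(mean(eff) - 89.5), 1)  # binomial mean, within 1%
})
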