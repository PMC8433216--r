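test_that("baseline estimation recovers offset and tilt", {
  z <- seq(0, 500, by = 2)
  flat <- estimate_baseline(z, rep(3, length(z)))
  expect_equal(flat$offset_pN, 3)
  expect_equal(flat$slope_pN_per_um, 0)

  tilted <- estimate_baseline(z, 1 + 2 * z / 1000, baseline_fraction = 0.5)
  expect_equal(tilted$slope_pN_per_um, 2, tolerance = 0.01)
  expect_equal(tilted$offset_pN, 1, tolerance = 0.01)

  noise <- withr::with_seed(8, rnorm(length(z), 0, 5))
  nb <- estimate_baseline(z, noise, baseline_fraction = 0.5)
  m <- floor(length(z) * 0.5)
  expect_lt(abs(nb$offset_pN), 3 * 5 / sqrt(m) * 2)  # ~3 SE of the mean, slack for tilt df

  expect_error(estimate_baseline(1:10, rnorm(10)), "segment too short")
})

test_that("contact point is found at the true contact", {
  cv <- generate_force_curve(23.9e3, quiet_preset(), seed = 2)
  z0 <- attr(cv, "truth")$contact_z_nm
  expect_lt(abs(detect_contact_point(cv) - z0), 2)  # one sample spacing

  expect_error(detect_contact_point(baseline_only_curve()), "no contact detected")

  p <- mechanical_preset("ctc_localized")  # 5 pN RMS noise
  err <- vapply(1:100, function(s) {
    cv <- generate_force_curve(23.9e3, p, seed = s)
    abs(detect_contact_point(cv) - attr(cv, "truth")$contact_z_nm)
  }, numeric(1))
  expect_lt(median(err), 10)
})

test_that("indentation follows its definition", {
  cv <- generate_force_curve(10e3, quiet_preset(), seed = 6)
  z0 <- detect_contact_point(cv)
  ind <- compute_indentation(cv, z0)
  app <- curve_force(cv, "approach")
  at_contact <- which.min(abs(app$z_nm - z0))
  expect_lt(ind$delta_nm[at_contact], 1)
  expect_lt(abs(ind$force_pN[at_contact]), 1)

  sel <- ind$delta_nm > 1
  expected <- hertz_force(ind$delta_nm[sel], 10e3, 3e-6)
  expect_lt(max(abs(ind$force_pN[sel] - expected) / expected), 1e-6)

  # rigid surface: deflection tracks z one-to-one, so indentation is zero
  z <- seq(0, 400, by = 2); z0r <- 200
  d <- pmax(z - z0r, 0)
  rigid <- force_curve(data.frame(z_nm = z, deflection_nm = d),
                       data.frame(z_nm = rev(z), deflection_nm = rev(d)))
  indr <- compute_indentation(rigid, z0r)
  expect_equal(max(abs(indr$delta_nm)), 0)
  expect_equal(measure_deformation(indr), 0)
})

test_that("the Hertz fit recovers the generating modulus", {
  cv <- generate_force_curve(10e3, quiet_preset(), seed = 4)
  ind <- compute_indentation(cv, detect_contact_point(cv))
  fit <- fit_hertz(ind, R_m = 3e-6, analysis_config(fit_range_nm = c(100, 200)))
  expect_lt(abs(fit$E_Pa - 10e3) / 10e3, 1e-3)
  expect_gt(fit$r_squared, 0.999)

  expect_error(
    fit_hertz(tibble::tibble(delta_nm = rep(0, 50), force_pN = rep(0, 50)), 3e-6),
    "fit range empty"
  )
  down <- tibble::tibble(delta_nm = seq(100, 200, length.out = 20),
                         force_pN = -seq(100, 200, length.out = 20)^1.5)
  expect_error(fit_hertz(down, 3e-6), "non-physical fit")

  td <- tidy(fit); gl <- glance(fit)
  expect_equal(td$estimate[td$term == "E_Pa"], fit$E_Pa)
  expect_equal(gl$r.squared, fit$r_squared)
})

test_that("deformation equals the closed-form model inversion", {
  cv <- generate_force_curve(23.9e3, quiet_preset(load_range_nN = c(6, 6)), seed = 1)
  ind <- compute_indentation(cv, detect_contact_point(cv))
  d_expected <- hertz_indentation(6000, 23.9e3, 3e-6)  # ~188 nm
  expect_equal(measure_deformation(ind), d_expected, tolerance = 1e-3)
})

test_that("adhesion events follow the strict neighbor-minimum rule", {
  base <- rep(0, 120)
  f <- base
  f[c(20, 45, 70)] <- c(-50, -30, -15)
  ev <- detect_adhesion_events(f)
  expect_equal(ev$sample_index, c(20L, 45L, 70L))
  expect_equal(ev$force_magnitude_pN, c(50, 30, 15))

  f8 <- base; f8[30] <- -8
  expect_equal(nrow(detect_adhesion_events(f8)), 0)  # below the 10 pN cutoff

  expect_equal(nrow(detect_adhesion_events(abs(rnorm(60)))), 0)  # never below zero

  expect_error(detect_adhesion_events(rep(0, 9)), "segment too short")

  # ties disqualify: a two-sample flat-bottom dip has no strict minimum
  ft <- base; ft[c(40, 41)] <- -60
  expect_equal(nrow(detect_adhesion_events(ft)), 0)
})

test_that("a curve built with seven dips yields seven events", {
  p <- mechanical_preset("ctc_localized", noise_rms_pN = 0,
                         baseline_slope_pN_per_um = 0,
                         adhesion_event_count_range = c(7L, 7L))
  cv <- generate_force_curve(23.9e3, p, seed = 12)
  res <- analyze_force_curve(cv)
  expect_equal(res$n_events, 7L)
  expect_equal(res$max_adhesion_pN, max(attr(cv, "truth")$dip_depths_pN),
               tolerance = 1e-6)
})

test_that("work of detachment matches hand-computed areas", {
  # triangular dip: 100 pN deep, 200 nm base -> 1/2 * 100 * 200 pN nm = 10 aJ
  s <- seq(0, 300, by = 5)
  f <- -pmax(0, 100 - abs(s - 100))
  expect_equal(compute_work_of_detachment(s, f), 10, tolerance = 1e-12)

  # rectangular dip with vertical edges: 50 pN x 100 nm = 5 aJ
  sr <- c(0, 50, 100, 100, 150, 200, 200, 250, 300)
  fr <- c(0, 0, 0, -50, -50, -50, 0, 0, 0)
  expect_equal(compute_work_of_detachment(sr, fr), 5, tolerance = 1e-12)

  expect_equal(compute_work_of_detachment(s, abs(f)), 0)  # nothing below zero
})

test_that("QC rejects unclear curves with a recorded reason", {
  clean <- generate_force_curve(23.9e3, mechanical_preset("ctc_localized"), seed = 3)
  qc <- qc_curve(clean)
  expect_true(qc$qc_pass)
  expect_equal(qc$qc_reason, "ok")

  qc2 <- qc_curve(baseline_only_curve())
  expect_false(qc2$qc_pass)
  expect_equal(qc2$qc_reason, "no contact detected")

  z <- seq(0, 400, by = 2)
  shuffle <- withr::with_seed(5, sample(length(z)))
  bad <- force_curve(
    data.frame(z_nm = z[shuffle], deflection_nm = rep(0, length(z))),
    data.frame(z_nm = rev(z), deflection_nm = rep(0, length(z))),
    validate = FALSE
  )
  qc3 <- qc_curve(bad)
  expect_false(qc3$qc_pass)
  expect_equal(qc3$qc_reason, "malformed segment")
})

test_that("force-volume analysis records per-pixel failures without raising", {
  m <- generate_force_volume(quiet_preset("ctc_localized",
                                          adhesion_event_count_range = c(2L, 5L)),
                             seed = 14)
  res <- analyze_force_volume(m, analysis_config(fit_range_nm = c(100, 200)))
  expect_equal(nrow(res), 64)
  expect_equal(sum(res$qc_pass), 64)

  m$curves[[5]] <- baseline_only_curve()
  m$curves[[20]] <- baseline_only_curve()
  m$curves[[63]] <- baseline_only_curve()
  res2 <- analyze_force_volume(m, analysis_config(fit_range_nm = c(100, 200)))
  expect_equal(sum(!res2$qc_pass), 3)
  expect_true(all(is.na(res2$E_Pa[!res2$qc_pass])))
  expect_true(all(res2$qc_reason[!res2$qc_pass] == "no contact detected"))
})
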