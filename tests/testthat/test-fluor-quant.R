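make_img <- function(px, seed_mask = NULL) {
  sm <- matrix(FALSE, nrow(px), ncol(px)); sm[3:12, 3:12] <- TRUE
  bm <- matrix(FALSE, nrow(px), ncol(px)); bm[1, ] <- TRUE
  fluor_image(px, sm, bm)
}

test_that("mean/SD transfer matches reference moments and is idempotent", {
  px <- withr::with_seed(4, matrix(rnorm(400, 10, 2), 20, 20))
  ref_px <- withr::with_seed(5, matrix(rnorm(400, 20, 4), 20, 20))
  img <- make_img(px); ref <- make_img(ref_px)

  ident <- transfer_mean_sd(img, img)
  expect_equal(ident$pixels, img$pixels, tolerance = 1e-12)

  out <- transfer_mean_sd(img, ref)
  expect_equal(mean(out$pixels), mean(ref$pixels), tolerance = 1e-12)
  expect_equal(sd(out$pixels), sd(ref$pixels), tolerance = 1e-12)

  twice <- transfer_mean_sd(out, ref)
  expect_equal(twice$pixels, out$pixels, tolerance = 1e-12)

  flat <- make_img(matrix(3, 20, 20))
  expect_error(transfer_mean_sd(flat, ref), "degenerate input")
})

test_that("integrated density equals area times mean gray value", {
  px <- matrix(0, 20, 20); px[3:12, 3:12] <- 5
  img <- make_img(px)
  expect_equal(integrated_density(img), 500)  # 100 px x MGV 5

  one <- matrix(0, 20, 20); one[5, 5] <- 42
  sm <- matrix(FALSE, 20, 20); sm[5, 5] <- TRUE
  bm <- matrix(FALSE, 20, 20); bm[1, ] <- TRUE
  expect_equal(integrated_density(fluor_image(one, sm, bm)), 42)

  rnd <- make_img(withr::with_seed(6, matrix(runif(400), 20, 20)))
  expect_equal(integrated_density(rnd), sum(rnd$pixels[rnd$sample_mask]))
})

test_that("corrected total fluorescence subtracts the scaled background", {
  uni <- make_img(matrix(7, 20, 20))
  expect_equal(corrected_total_fluorescence(uni), 0)

  px <- matrix(2, 20, 20); px[3:12, 3:12] <- 5
  img <- make_img(px)
  expect_equal(corrected_total_fluorescence(img), 300)  # 100 x (5 - 2)

  gen <- generate_fluorescence_image(
    5, 2, dim = c(20L, 20L),
    sample_mask = img$sample_mask, background_mask = img$background_mask,
    noise_sd = 0, seed = 1
  )
  expect_equal(corrected_total_fluorescence(gen), 300)

  tab <- ctf_table(img)
  expect_equal(tab$area_px, 100)
  expect_equal(tab$int_den, 500)
  expect_equal(tab$ctf, 300)
})

test_that("CTF is shift-invariant and scales linearly", {
  px <- withr::with_seed(7, matrix(runif(400, 1, 9), 20, 20))
  img <- make_img(px)
  base <- corrected_total_fluorescence(img)

  shifted <- make_img(px + 123.4)
  expect_equal(corrected_total_fluorescence(shifted), base, tolerance = 1e-9)

  scaled <- make_img(px * 3.5)
  expect_equal(corrected_total_fluorescence(scaled), 3.5 * base, tolerance = 1e-12)
})

test_that("saturation summary finds the plateau concentration", {
  conc <- c(0.5, 5, 10, 20, 40)
  ctf <- 1000 * conc / (1 + conc)  # one-site binding, K = 1
  s <- saturation_summary(conc, ctf)
  expect_equal(s$K_ug_ml, 1, tolerance = 1e-6)
  # closed form: c/(K+c) >= 0.95 iff c >= 19, so the smallest tested is 20
  expect_equal(s$saturating_concentration, 20)

  flat <- saturation_summary(conc, rep(800, 5))
  expect_lt(flat$K_ug_ml, 1e-3)
  expect_equal(flat$saturating_concentration, 0.5)

  expect_error(saturation_summary(c(1, 2, 5), c(10, 20, 30)), "insufficient points")
  expect_warning(saturation_summary(conc, c(1000, 800, 600, 400, 200)),
                 "non-monotone")
})
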