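test_that("constructors enforce the structural invariants", {
  expect_error(cantilever_spec(spring_constant = 0), "positive")
  expect_error(cantilever_spec(tip_radius = -1e-6), "positive")

  z <- seq(0, 30, by = 2)
  seg <- data.frame(z_nm = z, deflection_nm = rep(0, length(z)))
  short <- seg[1:10, ]
  expect_error(force_curve(short, seg[rev(seq_len(nrow(seg))), ]),
               "fewer than 16 samples")
  shuffled <- seg[withr::with_seed(1, sample(nrow(seg))), ]
  expect_error(force_curve(shuffled, seg[rev(seq_len(nrow(seg))), ]),
               "not strictly monotone")
  bad <- seg; bad$deflection_nm[3] <- NaN
  expect_error(force_curve(bad, seg[rev(seq_len(nrow(seg))), ]),
               "non-finite")

  expect_error(force_volume_map(list(), 0, 0, 0.156), "empty map")
})

test_that("force is derived from deflection via the spring constant", {
  for (seed in 1:5) {
    k <- withr::with_seed(seed, runif(1, 0.01, 0.5))
    cv <- generate_force_curve(10e3, quiet_preset(cantilever = cantilever_spec(k)),
                               seed = seed)
    app <- curve_force(cv, "approach")
    expect_equal(app$force_pN, k * app$deflection_nm * 1000)
  }
})

test_that("container round trip preserves samples and metadata exactly", {
  m <- generate_force_volume(mechanical_preset("ctc_localized"), seed = 11,
                             label = "cell_rt")
  path <- withr::local_tempdir()
  write_curve_container(m, file.path(path, "c"))
  m2 <- read_curve_container(file.path(path, "c"))

  s1 <- ctcforce:::fv_samples(m)
  s2 <- ctcforce:::fv_samples(m2)
  expect_identical(dim(s1), dim(s2))
  expect_equal(max(abs(s1$z_nm - s2$z_nm)), 0)
  expect_equal(max(abs(s1$deflection_nm - s2$deflection_nm)), 0)
  expect_equal(m2$n_rows, m$n_rows)
  expect_equal(m2$pixel_size, m$pixel_size)
  expect_equal(m2$cantilever$spring_constant, m$cantilever$spring_constant)
  expect_equal(m2$cantilever$tip_radius, m$cantilever$tip_radius)
  expect_equal(m2$label, m$label)
  expect_equal(fv_curve(m2, 3, 5)$label, fv_curve(m, 3, 5)$label)
})

test_that("writes are byte-stable and produce one table per pixel", {
  m <- generate_force_volume(mechanical_preset("pc3"), seed = 5)
  root <- withr::local_tempdir()
  write_curve_container(m, file.path(root, "a"))
  write_curve_container(m, file.path(root, "b"))

  fa <- sort(list.files(file.path(root, "a")))
  expect_length(grep("^curve_.*tsv$", fa), 16)  # 4 x 4 grid
  expect_true("metadata.yaml" %in% fa)
  for (f in fa) {
    expect_identical(readBin(file.path(root, "a", f), "raw", 1e6),
                     readBin(file.path(root, "b", f), "raw", 1e6))
  }
})

test_that("container reader rejects missing metadata and units", {
  m <- generate_force_volume(mechanical_preset("pc3"), seed = 5)
  root <- withr::local_tempdir()

  expect_error(read_curve_container(file.path(root, "nothing")), "metadata error")

  p1 <- file.path(root, "no_units")
  write_curve_container(m, p1)
  meta <- yaml::read_yaml(file.path(p1, "metadata.yaml"))
  meta$units <- NULL
  yaml::write_yaml(meta, file.path(p1, "metadata.yaml"))
  expect_error(read_curve_container(p1), "unit error")

  p2 <- file.path(root, "no_spring")
  write_curve_container(m, p2)
  meta <- yaml::read_yaml(file.path(p2, "metadata.yaml"))
  meta$cantilever$spring_constant_N_per_m <- NULL
  yaml::write_yaml(meta, file.path(p2, "metadata.yaml"))
  expect_error(read_curve_container(p2), "metadata error")
})
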