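ax200 <- default_axis()
wl200 <- ax200$wavelengths_nm

test_that("denoising preserves the DC component and rejects non-uniform grids", {
  cube <- spectral_cube(array(rep(5, 200), c(1, 1, 200)), ax200)
  out <- denoise_cube(cube, filter_spec())
  expect_lt(max(abs(out$values - 5)) / 5, 1e-9)

  irr <- spectral_axis(c(seq(500, 519), seq(525, length.out = 180, by = 1)))
  cube2 <- spectral_cube(array(1, c(1, 1, 200)), irr)
  expect_error(denoise_cube(cube2), "resample")
})

test_that("zero-phase Butterworth attenuates by |H|^2: 1/2 at cutoff, ~1 in passband", {
  co <- 0.08
  for (case in list(list(f = co, gain = 0.5, tol = 0.02),
                    list(f = co / 10, gain = 1.0, tol = 0.01))) {
    s <- 0.5 + 0.2 * sin(2 * pi * case$f * (wl200 - wl200[1]))
    cube <- spectral_cube(array(s, c(1, 1, 200)), ax200)
    out <- denoise_cube(cube, filter_spec(order = 6, cutoff = co))
    interior <- 41:160
    amp <- (max(out$values[1, 1, interior]) -
              min(out$values[1, 1, interior])) / 2
    expect_equal(amp / 0.2, case$gain, tolerance = case$tol)
  }
})

test_that("cutoff at or above Nyquist is rejected", {
  cube <- spectral_cube(array(1, c(1, 1, 200)), ax200)
  expect_error(denoise_cube(cube, filter_spec(cutoff = 0.5)), "Nyquist")
})

test_that("baseline removal subtracts the least-squares polynomial exactly", {
  ramp <- 2 + 0.01 * (wl200 - 500)
  cube <- spectral_cube(array(ramp, c(1, 1, 200)), ax200)
  out <- remove_baseline(cube, 1L)
  expect_lt(max(abs(out$values)), 1e-9)

  # 20 whole periods, centred: exactly orthogonal to intercept and slope
  sine <- 0.3 * cos(2 * pi * 0.1 * (wl200 - 599.5))
  cube2 <- spectral_cube(array(pmax(ramp + sine, 0), c(1, 1, 200)), ax200)
  out2 <- remove_baseline(cube2, 1L)
  expect_lt(sqrt(mean((out2$values[1, 1, ] - sine)^2)) / sqrt(mean(sine^2)),
            0.01)

  out0 <- remove_baseline(random_cube(), 0L)
  expect_lt(max(abs(apply(out0$values, c(1, 2), mean))), 1e-12)
})

test_that("Sigma of a clean sinusoid is a/sqrt(2); a noise floor restores it under noise", {
  n <- 200
  a <- 0.2
  s <- 0.5 + a * sin(2 * pi * 0.02 * (wl200 - 500))  # 4 whole periods in band
  cube <- spectral_cube(array(s, c(1, 1, n)), ax200)
  sm <- compute_sigma_map(cube, filter = filter_spec(), poly_order = 0L)
  expect_equal(sm$values[1, 1], a / sqrt(2), tolerance = 0.01)

  expect_equal(compute_sigma_map(spectral_cube(array(3, c(2, 3, n)), ax200),
                                 filter = NULL)$values,
               matrix(0, 2, 3))

  eta <- 0.05
  set.seed(7)
  vals <- array(rep(s, each = 100), c(100, 1, n)) +
    array(rnorm(100 * n, sd = eta), c(100, 1, n))
  cube3 <- spectral_cube(pmax(vals, 0), ax200)
  sm3 <- compute_sigma_map(cube3, filter = NULL, poly_order = 0L,
                           noise_floor = eta^2)
  expect_equal(mean(sm3$values), a / sqrt(2), tolerance = 0.05)
})

test_that("Sigma is invariant to added baselines and scales linearly with the cube", {
  cube <- random_cube(seed = 5, axis = spectral_axis(seq(500, 699)))
  s0 <- compute_sigma_map(cube, poly_order = 1L)$values
  wl <- cube$axis$wavelengths_nm
  shifted <- cube
  shifted$values <- sweep(cube$values, 3L, 4 + 0.02 * (wl - 500), `+`)
  expect_equal(compute_sigma_map(shifted, poly_order = 1L)$values, s0,
               tolerance = 1e-6)

  scaled <- cube
  scaled$values <- cube$values * 3.7
  expect_equal(compute_sigma_map(scaled, poly_order = 1L)$values, 3.7 * s0,
               tolerance = 1e-9)
})

test_that("axes shorter than 8 samples are rejected for variance analysis", {
  expect_error(spectral_axis(seq(500, 506)), "at least 8")
})

test_that("sigma_to_ld follows both conventions and their scalings", {
  sm <- structure(list(values = matrix(2, 3, 3), provenance = list()),
                  class = "sigma_map")
  ax <- small_axis()
  kbar <- ax$center_wavenumber
  ld_v <- sigma_to_ld(sm, 2, ax, "variance")
  expect_equal(ld_v$values[1, 1], 4 / (kbar^2 * 2000))
  ld_l <- sigma_to_ld(sm, 2, ax, "linear")
  expect_equal(ld_l$values[1, 1], 2 / 2000)

  # zero Sigma -> zero L_d
  sm0 <- structure(list(values = matrix(0, 2, 2), provenance = list()),
                   class = "sigma_map")
  expect_true(all(sigma_to_ld(sm0, 1, ax, "variance")$values == 0))
  expect_true(all(sigma_to_ld(sm0, 1, ax, "linear")$values == 0))

  # thickness doubling halves L_d in both conventions
  expect_equal(sigma_to_ld(sm, 4, ax, "variance")$values,
               ld_v$values / 2)
  expect_equal(sigma_to_ld(sm, 4, ax, "linear")$values,
               ld_l$values / 2)

  # Sigma doubling: x4 under variance, x2 under linear
  sm2 <- structure(list(values = matrix(4, 3, 3), provenance = list()),
                   class = "sigma_map")
  expect_equal(sigma_to_ld(sm2, 2, ax, "variance")$values, 4 * ld_v$values)
  expect_equal(sigma_to_ld(sm2, 2, ax, "linear")$values, 2 * ld_l$values)

  # thickness map with bad pixels errors with a count
  thick <- matrix(2, 3, 3)
  thick[1, 1] <- 0
  thick[2, 2] <- -1
  expect_error(sigma_to_ld(sm, thick, ax), "2 pixel")
})

test_that("mean_ld averages over masks and rejects empty masks", {
  ld <- structure(list(values = matrix(1:4, 2, 2)), class = "ld_map")
  expect_equal(mean_ld(ld), 2.5)
  expect_equal(mean_ld(structure(list(values = matrix(7, 5, 5)),
                                 class = "ld_map")), 7)
  cb <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(mean_ld(structure(list(values = cb), class = "ld_map"),
                       mask = cb > 0), 3)
  expect_error(mean_ld(ld, mask = matrix(FALSE, 2, 2)), "no pixels")
})

test_that("analysis maps roundtrip through float TIFF with provenance", {
  dir <- withr::local_tempdir()
  cube <- random_cube(seed = 9)
  sm <- compute_sigma_map(cube, poly_order = 1L)
  ld <- sigma_to_ld(sm, 2, cube$axis, "variance", calibration = 19.3)
  p <- file.path(dir, "ld.tif")
  write_map(ld, p)
  back <- read_map(p)
  expect_lt(max(abs(back$values - ld$values)),
            2^-31 * max(1, max(ld$values)))
  expect_equal(back$convention, "variance")
  expect_equal(back$calibration_constant, 19.3)
  expect_equal(back$provenance$poly_order, 1L)
})
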