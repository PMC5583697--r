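ax <- default_axis()

test_that("density maps to refractive index linearly through alpha", {
  expect_equal(density_to_ri(0), 1.333)
  expect_equal(density_to_ri(1.0), 1.513)
  rho <- c(0.1, 0.5, 1.2)
  expect_equal(density_to_ri(2 * rho) - 1.333,
               2 * (density_to_ri(rho) - 1.333), tolerance = 1e-12)
  m <- refractive_model(n_water = 1.334, alpha_ml_per_g = 0.2)
  expect_equal(density_to_ri(0.5, m), 1.434)
  expect_error(refractive_model(alpha_ml_per_g = 0))
})

test_that("Gaussian-correlated profiles hit their target SD and correlation length", {
  expect_true(all(gaussian_correlated_profile(0, 40, 2000)$delta_n == 0))
  set.seed(17)
  prof <- replicate(200, gaussian_correlated_profile(0.02, 40, 2000)$delta_n)
  expect_equal(sd(as.vector(prof)), 0.02, tolerance = 0.05)
  acf_mean <- rowMeans(apply(prof, 2, function(x) {
    a <- acf(x, lag.max = 30, plot = FALSE, demean = FALSE)$acf[, 1, 1]
    a / a[1]
  }))
  dz <- 10  # min(40/4, 10)
  cross <- approx(acf_mean, (0:30) * dz, xout = exp(-1))$y
  expect_equal(cross, 40, tolerance = 0.15)

  expect_error(gaussian_correlated_profile(0.02, 40, 2000, dz_nm = 15),
               "coarse")
  p1 <- gaussian_correlated_profile(0.02, 40, 2000, seed = 4)
  p2 <- gaussian_correlated_profile(0.02, 40, 2000, seed = 4)
  expect_identical(p1$delta_n, p2$delta_n)
})

test_that("transfer-matrix reflectance matches the Airy closed form", {
  med <- layered_medium(rep(0, 200), 10, n0 = 1.4, n_ambient = 1,
                        n_substrate = 1.6)
  R <- transfer_matrix_reflectance(med, ax)
  Ra <- airy_reflectance(1, 1.4, 1.6, 2000, ax$wavelengths_nm)
  expect_lt(max(abs(R - Ra) / Ra), 1e-10)

  # half-wave film on an index-matched substrate: bare-interface Fresnel
  lam0 <- 600
  med2 <- layered_medium(rep(0, 50), lam0 / (2 * 1.5) / 50, n0 = 1.5,
                         n_ambient = 1, n_substrate = 1.5)
  R2 <- transfer_matrix_reflectance(med2, spectral_axis(seq(593, 607, by = 1)))
  expect_equal(R2[8], ((1 - 1.5) / (1 + 1.5))^2, tolerance = 1e-10)

  # fully index-matched stack reflects nothing
  med3 <- layered_medium(rep(0, 100), 10, n0 = 1.38, n_ambient = 1.38,
                         n_substrate = 1.38)
  expect_lt(max(transfer_matrix_reflectance(med3, ax)), 1e-20)
})

test_that("the solver conserves energy and rejects non-physical media", {
  m <- gaussian_correlated_profile(0.05, 30, 3000, seed = 7)
  rt <- transfer_matrix_reflectance(m, ax, transmission = TRUE)
  expect_lt(max(abs(rt$R + rt$T - 1)), 1e-10)
  expect_true(all(rt$R >= 0 & rt$R <= 1))
  expect_error(layered_medium(c(0, -2), 10, n0 = 1.38), "non-physical")
})

test_that("ensembles are seed-deterministic and vanish without disorder", {
  e0 <- simulate_pws_ensemble(0, 30, 2000, ax, n_realizations = 5, seed = 1)
  expect_lt(e0$mean_sigma2, 1e-12)
  e1 <- simulate_pws_ensemble(0.02, 30, 2000, ax, n_realizations = 10,
                              seed = 42)
  e2 <- simulate_pws_ensemble(0.02, 30, 2000, ax, n_realizations = 10,
                              seed = 42)
  expect_identical(e1$spectra, e2$spectra)
  expect_identical(e1$sigma, e2$sigma)
  expect_warning(simulate_pws_ensemble(0.2, 30, 5000, ax,
                                       n_realizations = 2, seed = 1),
                 "weak-scattering")
})

test_that("calibration recovers itself and rejects degenerate grids", {
  grid <- expand.grid(sigma_n = c(0.01, 0.03), corr_len_nm = c(20, 30))
  cal <- calibrate_ld(grid, ax, "variance", n_realizations = 60, seed = 60)
  expect_gt(cal$r_squared, 0.9)
  # applying the constant and re-fitting is idempotent: second constant ~ 1
  tab <- cal$table
  c2 <- sum(tab$target * (cal$constant * tab$measured)) /
    sum((cal$constant * tab$measured)^2)
  expect_equal(c2, 1, tolerance = 0.05)
  expect_error(calibrate_ld(data.frame(sigma_n = 0.02, corr_len_nm = 20),
                            ax), "degenerate")
})

test_that("phantoms are deterministic with exactly the requested nuclei", {
  sp <- phantom_spec(dim_px = c(72L, 72L), n_nuclei = 4L, seed = 9L)
  axs <- small_axis(16)
  ph1 <- make_phantom_cube(sp, axs)
  expect_equal(max(ph1$mask$labels), 4L)
  expect_equal(length(unique(as.vector(ph1$mask$labels))), 5L)
  ph2 <- make_phantom_cube(sp, axs)
  expect_identical(ph1$cube$values, ph2$cube$values)
  expect_identical(ph1$mask$labels, ph2$mask$labels)
  expect_identical(ph1$transmission, ph2$transmission)

  over <- phantom_spec(dim_px = c(72L, 72L), n_nuclei = 2L,
                       centers = rbind(c(30, 30), c(32, 33)), seed = 1L)
  expect_error(make_phantom_cube(over, axs), "overlap")
})

test_that("phantom nuclei with doubled sigma_n carry higher measured L_d", {
  axs <- small_axis(64)
  wins <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    ph <- make_phantom_cube(phantom_spec(dim_px = c(64L, 64L), n_nuclei = 2L,
                                         nucleus_radius_um = 3,
                                         seed = 300L + s),
                            axs)
    sm <- compute_sigma_map(ph$cube, poly_order = 1L)
    ld <- sigma_to_ld(sm, 2, axs, "variance")
    nuc <- mean_ld(ld, ph$mask$labels > 0)
    cyt <- mean_ld(ld, ph$mask$labels == 0)
    if (nuc > cyt) wins <- wins + 1L
  }
  expect_gte(wins / n_seeds, 0.95)
})

test_that("synthetic cohorts are deterministic with the documented columns", {
  co1 <- make_cohort(5, c(a = 1, b = 2), 0.3, seed = 8, cellular_slope = 0.8,
                     cellular_noise_sd = 0.1)
  co2 <- make_cohort(5, c(a = 1, b = 2), 0.3, seed = 8, cellular_slope = 0.8,
                     cellular_noise_sd = 0.1)
  expect_identical(co1, co2)
  expect_s3_class(co1, "patient_summary")
  expect_equal(nrow(co1), 10L)
  expect_equal(as.integer(table(co1$group)[c("a", "b")]), c(5L, 5L))
  expect_true(all(is.finite(co1$mean_cellular_ld)))
})
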