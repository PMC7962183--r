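test_that("band_integrate handles simple closed-form spectra", {
  flat <- spectral_curve(c(400, 700), c(1, 1))
  expect_equal(band_integrate(flat, 400, 700), 300)
  # triangle peaking at 1 over [290, 330]: area 0.5 * 40 * 1 = 20
  tri <- spectral_curve(c(290, 310, 330), c(0, 1, 0))
  expect_equal(band_integrate(tri, 280, 400), 20)
  # sub-band additivity is exact
  expect_equal(
    band_integrate(tri, 280, 315) + band_integrate(tri, 315, 400),
    band_integrate(tri, 280, 400)
  )
  expect_warning(out <- band_integrate(tri, 500, 600), "overlap")
  expect_equal(out, 0)
})

test_that("band_integrate matches a fine-grid Riemann oracle on rough curves", {
  set.seed(42)
  lam <- sort(runif(200, 300, 800))
  lam <- lam[c(TRUE, diff(lam) > 1e-6)]
  curve <- spectral_curve(lam, rexp(length(lam)))
  # oracle: midpoint Riemann sum of the interpolant on 10^4 points
  grid <- seq(400, 700, length.out = 1e4 + 1)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  oracle <- sum(eval_spectrum(curve, mid) * diff(grid))
  expect_equal(band_integrate(curve, 400, 700), oracle, tolerance = 1e-3)
})

test_that("PPFD conversion matches the photon-energy closed form", {
  # 1 W m^-2 monochromatic at 600 nm -> 5.02 umol m^-2 s^-1
  mono <- spectral_curve(c(599.5, 600, 600.5), c(0, 2, 0)) # integral = 1 W
  expect_equal(irradiance_to_ppfd(mono), 5.0155, tolerance = 1e-3)
  # outside the PAR band the photon flux is masked to zero
  uv <- spectral_curve(c(299.5, 300, 300.5), c(0, 2, 0))
  expect_equal(irradiance_to_ppfd(uv), 0)
  # linearity
  mono2 <- spectral_curve(c(599.5, 600, 600.5), c(0, 4, 0))
  expect_equal(irradiance_to_ppfd(mono2), 2 * irradiance_to_ppfd(mono))
})

test_that("daily dose arithmetic and validation", {
  expect_identical(daily_dose(1.0, 12), 43.2)
  expect_identical(daily_dose(0, 12), 0)
  # 0.70 W m^-2 over 12 h: 30.24 kJ (a rounded-mean report would differ)
  expect_equal(daily_dose(0.70, 12), 30.24)
  expect_error(daily_dose(-1, 12), "nonnegative")
  expect_error(daily_dose(1, 25), "\\[0, 24\\]")
})

test_that("action spectra must be normalized at the stated wavelength", {
  gp <- gpas_action_spectrum()
  expect_equal(eval_spectrum(gp, 300), 1, tolerance = 1e-9)
  # monotone decreasing through the UV-B and zero beyond the cutoff
  expect_gt(eval_spectrum(gp, 290), eval_spectrum(gp, 305))
  expect_equal(eval_spectrum(gp, 350), 0)
  bad <- spectral_curve(c(280, 400), c(2, 2))
  expect_error(action_spectrum(bad), "not normalized")
})

test_that("weighting identities: flat action and normalization-wavelength source", {
  spd <- spd_uvb_led(1.0)
  flat <- action_spectrum(spectral_curve(c(200, 900), c(1, 1)))
  rep_flat <- biologically_effective(spd, flat, 12)
  expect_equal(
    rep_flat$weighted[["total_be"]], rep_flat$unweighted[["uv_total"]],
    tolerance = 1e-10
  )
  expect_equal(rep_flat$unweighted[["uv_total"]], 43.2, tolerance = 1e-9)
  # monochromatic source at 300 nm: weighted dose = unweighted dose
  mono <- spectral_curve(c(299.9, 300, 300.1), c(0, 10, 0))
  rep_mono <- biologically_effective(mono, gpas_action_spectrum(), 12)
  expect_equal(
    rep_mono$weighted[["total_be"]], rep_mono$unweighted[["uv_total"]],
    tolerance = 1e-3
  )
})

test_that("weighted UV-B/UV-A partition matches a fine-grid quadrature oracle", {
  spd <- spd_uvb_led(1.0)
  gp <- gpas_action_spectrum()
  rep <- biologically_effective(spd, gp, 12)
  grid <- seq(280, 400, length.out = 2e5 + 1)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  w <- eval_spectrum(spd, mid) * eval_spectrum(gp, mid)
  oracle_b <- sum(w[mid <= 315] * diff(grid)[mid <= 315]) * 12 * 3.6
  oracle_a <- sum(w[mid > 315] * diff(grid)[mid > 315]) * 12 * 3.6
  expect_equal(rep$weighted[["uvb_be"]], oracle_b, tolerance = 1e-3)
  expect_equal(rep$weighted[["uva_be"]], oracle_a, tolerance = 1e-3)
  expect_equal(
    rep$weighted[["total_be"]],
    sum(rep$weighted[c("uvc_be", "uvb_be", "uva_be")])
  )
  # weighted <= unweighted whenever the action spectrum is <= 1
  expect_lte(rep$weighted[["total_be"]], rep$unweighted[["uv_total"]])
})

test_that("dose monotonicity: raising the spectrum never lowers any dose", {
  set.seed(1)
  lam <- seq(280, 400, by = 2)
  v <- runif(length(lam))
  gp <- gpas_action_spectrum()
  base <- biologically_effective(spectral_curve(lam, v), gp, 12)
  for (k in c(5, 20, 45)) {
    v2 <- v
    v2[k] <- v2[k] + 0.5
    up <- biologically_effective(spectral_curve(lam, v2), gp, 12)
    expect_true(all(up$unweighted >= base$unweighted - 1e-12))
    expect_true(all(up$weighted >= base$weighted - 1e-12))
  }
})

test_that("spectrum CSV reader round-trips a curve", {
  path <- withr::local_tempfile(fileext = ".csv")
  lam <- seq(280, 400, by = 5)
  utils::write.csv(
    data.frame(wavelength_nm = lam, value = exp(-(lam - 310)^2 / 50)),
    path, row.names = FALSE
  )
  cv <- read_spectrum_csv(path)
  expect_s3_class(cv, "spectral_curve")
  expect_equal(eval_spectrum(cv, 310), 1)
})
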