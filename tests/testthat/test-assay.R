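test_that("DPPH radical scavenging follows the blank-ratio formula", {
  expect_equal(as.numeric(dpph_rsa(1.0, 1.0)), 0)
  expect_equal(as.numeric(dpph_rsa(1.0, 0)), 100)
  expect_equal(as.numeric(dpph_rsa(1.000, 0.333)), 66.7)
  expect_error(dpph_rsa(0, 0.5), "domain error")
  expect_error(dpph_rsa(1, -0.1), "domain error")
  # clipping is flagged, not silent
  over <- dpph_rsa(0.5, 0.8)
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "clipped"))
})

test_that("quantify scales inverse prediction by volume, dilution, mass", {
  curve <- calibration_curve(c(0, 1, 2, 3), c(0, 1, 2, 3)) # identity line
  # absorbance 0.5, 0.05 g, 1 mL, dilution 1 -> 0.5 * 1 * 1 / 0.05 = 10
  expect_equal(as.numeric(quantify(0.5, curve, mass_g = 0.05)), 10)
  expect_equal(
    as.numeric(quantify(0.5, curve, mass_g = 0.05, dilution = 2)), 20
  )
  expect_true(attr(quantify(9, curve, mass_g = 0.05), "extrapolated"))
})

test_that("spiked concentrations are recovered through a synthetic curve", {
  set.seed(11)
  conc <- c(0, 25, 50, 100, 200)
  slope <- 0.004
  intercept <- 0.02
  curve <- calibration_curve(conc, intercept + slope * conc)
  spike <- 120 # mg/L in the extract
  a <- intercept + slope * spike
  got <- as.numeric(quantify(a, curve, mass_g = 0.05, volume_ml = 1))
  # conc (mg/mL) * 1 mL / 0.05 g: recovery of the spiked level
  expect_equal(got, spike / 0.05 * 1, tolerance = 1e-9)
  expect_error(calibration_curve(c(0, 1, 2), c(2, 1, 0)), "slope")
})

test_that("the default design emits the 29 + 27 record structure", {
  d <- synth_assays(seed = 1)
  expect_s3_class(d, "assay_records")
  expect_equal(nrow(d), 56)
  expect_equal(sum(d$treatment == "control"), 29)
  expect_equal(sum(d$treatment == "+UV-B"), 27)
  expect_true(all(d$uvi[d$treatment == "control"] == 0))
  expect_true(all(d$uvi[d$treatment == "+UV-B"] > 0))
  expect_true(all(d$rsa >= 0 & d$rsa <= 100))
  expect_true(all(d$tfc >= 0 & d$tpc >= 0))
})

test_that("noiseless generation makes the coefficients exactly identifiable", {
  co <- default_assay_coefficients()
  co$sigma[] <- 0
  co$rho_tfc_tpc <- 0
  d <- synth_assays(coefficients = co, uvi_jitter = 0, seed = 2)
  fit <- fit_regression(d, "tfc")
  expect_equal(unname(fit$coefficients["lo"]), unname(co$tfc["lo"]),
    tolerance = 1e-9
  )
  expect_equal(unname(fit$coefficients["uvi"]), unname(co$tfc["uvi"]),
    tolerance = 1e-9
  )
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("a null UV effect leaves treatments indistinguishable at equal leaf order", {
  co <- default_assay_coefficients()
  co$sigma[] <- 0
  co$rho_tfc_tpc <- 0
  co$tfc["uvi"] <- 0
  d <- synth_assays(coefficients = co, uvi_jitter = 0, seed = 3)
  m <- merge(
    d[d$treatment == "control", c("leaf_order", "tfc")],
    d[d$treatment == "+UV-B", c("leaf_order", "tfc")],
    by = "leaf_order"
  )
  expect_equal(m$tfc.x, m$tfc.y, tolerance = 1e-12)
})

test_that("generated TFC-TPC correlation sits near its configured target", {
  rs <- vapply(1:20, function(seed) {
    d <- synth_assays(seed = seed)
    pearson(d$tfc, d$tpc)$r
  }, 0)
  expect_lt(abs(mean(rs) - 0.73), 0.1)
  expect_true(all(rs > 0.5 & rs < 0.95))
})

test_that("coefficient estimates are unbiased across replicates", {
  co <- default_assay_coefficients()
  est <- vapply(1:200, function(seed) {
    d <- synth_assays(seed = seed)
    stats::coef(stats::lm(tfc ~ leaf_order + uvi, data = d))[c(2, 3)]
  }, c(lo = 0, uvi = 0))
  for (term in c("lo", "uvi")) {
    bias <- mean(est[term, ]) - co$tfc[[term]]
    se <- stats::sd(est[term, ]) / sqrt(ncol(est))
    expect_lt(abs(bias), 3 * se)
  }
})

test_that("tally-driven doses pass through the action-spectrum weighting", {
  scn <- add_plant(
    build_chamber(chamber_layout(wall_height = 0)),
    build_rosette(rosette_spec(n_leaves = 4, triangles_per_leaf = 100))
  )
  tl <- trace(scn, n_rays = 2e4, bands = "UV", seed = 8)
  uvi_w <- uvi_from_tally(tl)
  uvi_raw <- uvi_from_tally(tl, spd = NULL)
  expect_length(uvi_w, 4)
  expect_true(all(uvi_w < uvi_raw)) # weighting shrinks the dose
  d <- synth_assays(uvi = tl, seed = 4)
  expect_true(all(d$uvi[d$treatment == "+UV-B"] > 0))
})
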