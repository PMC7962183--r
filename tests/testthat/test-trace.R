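uv_point_emitter <- function(z = 200, power = 1, half_angle = 90) {
  emitter(c(0, 0, z), c(0, 0, -1), power = c(UV = power), half_angle = half_angle)
}

test_that("emission polar angles follow the truncated-cosine law", {
  set.seed(101)
  em <- uv_point_emitter(half_angle = 90)
  s <- sample_emission(em, 1e5)
  # P(theta <= 60 deg) = sin^2(60) = 0.75 for the full cosine law
  p60 <- mean(s$theta_deg <= 60)
  expect_lt(abs(p60 - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  # truncation at 60 degrees is hard
  set.seed(102)
  s60 <- sample_emission(uv_point_emitter(half_angle = 60), 1e4)
  expect_lte(max(s60$theta_deg), 60 + 1e-9)
  # fixed seed reproduces the ray stream exactly
  set.seed(7)
  a <- sample_emission(em, 100)
  set.seed(7)
  b <- sample_emission(em, 100)
  expect_identical(a, b)
})

test_that("sampled directions are unit length and origins cover panels", {
  set.seed(5)
  panel <- emitter(c(0, 0, 100), c(0, 0, -1), power = c(PAR = 2),
                   size = c(200, 100))
  s <- sample_emission(panel, 5000)
  expect_equal(rowSums(s$direction^2), rep(1, 5000), tolerance = 1e-12)
  expect_lte(max(abs(s$origin[, 1])), 100)
  expect_lte(max(abs(s$origin[, 2])), 50)
  # weight = power / n
  expect_equal(s$weight, 2 / 5000)
})

test_that("BVH intersection equals the brute-force oracle", {
  m <- icosphere(10, 2) # 320 faces
  rays <- random_rays(1000, r = 50, seed = 3)
  bvh <- intersect_rays(m, rays$origins, rays$dirs, method = "bvh")
  brute <- intersect_rays(m, rays$origins, rays$dirs, method = "brute")
  expect_identical(bvh$face, brute$face)
  expect_identical(bvh$t, brute$t)
  expect_gt(sum(!is.na(bvh$face)), 500) # the bundle does hit the sphere
})

test_that("axis-aligned ray hits the unit square at the expected point", {
  m <- rect_mesh(c(-0.5, -0.5, 0), c(1, 0, 0), c(0, 1, 0))
  hit <- intersect_rays(m, c(0, 0, 5), c(0, 0, -1))
  expect_false(is.na(hit$face))
  expect_equal(hit$t, 5)
  # pointing away: miss
  miss <- intersect_rays(m, c(0, 0, 5), c(0, 0, 1))
  expect_true(is.na(miss$face))
})

test_that("surface interaction outcomes follow the R/T/A probabilities", {
  s <- surface_interaction(c(0, 0, 1), c(0, 0, -1), R = 0, T = 0,
                           n = 1000, seed = 1)
  expect_true(all(s$outcome == "absorb"))
  s2 <- surface_interaction(c(0, 0, 1), c(0, 0, -1), R = 0.5, T = 0.5,
                            n = 1e5, seed = 2)
  fr <- mean(s2$outcome == "reflect")
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(
    surface_interaction(c(0, 0, 1), c(0, 0, -1), R = 0.8, T = 0.4, n = 1),
    "optics validation"
  )
})

test_that("pure reflection scatters cosine-weighted into the upper hemisphere", {
  s <- surface_interaction(c(0, 0, 1), c(0.3, 0.2, -0.93), R = 1, T = 0,
                           n = 2e4, seed = 4)
  expect_true(all(s$outcome == "reflect"))
  ct <- s$direction[, 3]
  expect_gt(min(ct), 0) # all upward
  # cos(theta) of a cosine-weighted direction has CDF t^2 on [0, 1]
  ks <- suppressWarnings(stats::ks.test(ct, function(t) t^2))
  expect_gt(ks$p.value, 0.001)
})

test_that("a black floor absorbs every emitted ray", {
  # truncated cone (60 deg): every ray reaches the floor within its extent
  scn <- floor_scene(R = 0, T = 0, emitters = list(uv_point_emitter(half_angle = 60)))
  tl <- trace(scn, n_rays = 2e4, seed = 9)
  expect_equal(tl$tally$absorbed_w, 1.0, tolerance = 1e-12)
  expect_equal(tl$balance$UV$escaped, 0)
  expect_lte(energy_balance_error(tl)[["UV"]], 1e-12)
})

test_that("energy is conserved on reflective multi-bounce scenes", {
  scn <- add_plant(build_chamber(), build_rosette(rosette_spec(
    triangles_per_leaf = 120
  )))
  tl <- trace(scn, n_rays = 5e4, bands = c("PAR", "UV"), seed = 21)
  expect_true(all(energy_balance_error(tl) <= 1e-12))
  b <- tl$balance$UV
  expect_gt(b$escaped, 0) # open chamber: some rays leave
  expect_gte(b$terminated, 0)
})

test_that("on-axis irradiance of a cosine point source matches P/(pi d^2)", {
  d <- 200
  p <- 2.5
  scn <- patch_scene(side = 10, z = 0, emitters = list(
    uv_point_emitter(z = d, power = p, half_angle = 90)
  ))
  tl <- trace(scn, n_rays = 2e5, n_batches = 20, seed = 33)
  analytic <- p / (pi * (d / 1000)^2)
  got <- tl$tally$irradiance_w_m2[1]
  se <- tl$tally$stderr_w[1] / (tl$tally$area_cm2[1] * 1e-4)
  expect_lt(abs(got - analytic), 3 * se)
  expect_lt(se / got, 0.1) # the estimate is actually informative
})

test_that("mirror-symmetric leaves intercept equal flux", {
  h <- 4
  mk_leaf <- function(x0) rect_mesh(c(x0, -15, 50), c(30, 0, 0), c(0, 30, 0))
  m <- rosetrace:::merge_meshes(mk_leaf(20), mk_leaf(-50))
  groups <- data.frame(
    group = 1:2, kind = "leaf", leaf_order = 1:2,
    optics_id = "leaf", stringsAsFactors = FALSE
  )
  scn <- scene(m, groups, list(leaf = optical_props(UV = c(R = 0.1, T = 0.05))),
    list(uv_point_emitter(z = 300)))
  tl <- trace(scn, n_rays = 2e5, n_batches = 20, seed = 12)
  dif <- abs(diff(tl$tally$absorbed_w))
  sig <- sqrt(sum(tl$tally$stderr_w^2))
  expect_lt(dif, 3 * sig)
})

test_that("Monte-Carlo stderr scales as 1/sqrt(n)", {
  scn <- patch_scene(side = 60, z = 0, emitters = list(uv_point_emitter(z = 150)))
  ses <- vapply(c(1e4, 1e5), function(n) {
    tl <- trace(scn, n_rays = n, n_batches = 10, seed = 77)
    tl$tally$stderr_w[1]
  }, 0)
  ratio <- ses[1] / ses[2]
  expect_gt(ratio, sqrt(10) / 1.5)
  expect_lt(ratio, sqrt(10) * 1.5)
})

test_that("tally is invariant to mesh refinement within MC error", {
  run <- function(tpl) {
    scn <- add_plant(build_chamber(chamber_layout(wall_height = 0)),
      build_rosette(rosette_spec(n_leaves = 5, triangles_per_leaf = tpl)))
    trace(scn, n_rays = 1e5, bands = "UV", n_batches = 20, seed = 50)
  }
  a <- leaf_interception(run(150), "UV")
  b <- leaf_interception(run(300), "UV")
  comb <- sqrt(a$stderr_w^2 + b$stderr_w^2)
  expect_true(all(abs(a$absorbed_w - b$absorbed_w) < 3.5 * comb))
})

test_that("tracing is deterministic and linear in emitter power", {
  scn <- patch_scene(side = 40, emitters = list(uv_point_emitter(power = 1)))
  t1 <- trace(scn, n_rays = 5e4, seed = 31)
  t1b <- trace(scn, n_rays = 5e4, seed = 31)
  expect_identical(t1$tally$absorbed_w, t1b$tally$absorbed_w)
  scn2 <- patch_scene(side = 40, emitters = list(uv_point_emitter(power = 3)))
  t3 <- trace(scn2, n_rays = 5e4, seed = 31)
  expect_equal(t3$tally$absorbed_w, 3 * t1$tally$absorbed_w, tolerance = 1e-12)
})

test_that("calibration rescales emitters by target over pilot reading", {
  scn <- floor_scene(R = 0.3, T = 0, emitters = list(uv_point_emitter(z = 250)),
    sensors = list(virtual_sensor(c(0, 0, 1), radius = 60)))
  cal <- calibrate_power(scn, target_w_m2 = 1.0, band = "UV",
                         n_rays = 2e5, seed = 61)
  expect_equal(cal$scale, 1.0 / cal$pilot_reading)
  re <- trace(cal$scene, n_rays = 4e5, bands = "UV", seed = 62)
  expect_equal(re$sensor$UV[1], 1.0, tolerance = 0.05)
  # unlit sensor is a calibration error
  dark <- floor_scene(R = 0, T = 0, emitters = list(uv_point_emitter(z = 250)),
    sensors = list(virtual_sensor(c(2000, 2000, 1), radius = 10)))
  expect_error(calibrate_power(dark, 1, "UV", n_rays = 1e4), "calibration error")
})
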