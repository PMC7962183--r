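test_that("noiseless traces yield the plateau signals exactly", {
  tr <- simulate_trace(f_o = 0.2, f_m = 1.0, f_prime = 0.45, f_m_prime = 0.7,
                       sigma = 0, seed = 1)
  s <- extract_signals(tr)
  expect_equal(s$f_o, 0.2)
  expect_equal(s$f_m, 1.0)
  expect_equal(s$f_prime, 0.45)
  expect_equal(s$f_m_prime, 0.7)
})

test_that("noisy extraction recovers plateaus within 3 sigma/sqrt(n)", {
  sig <- 0.005
  tr <- simulate_trace(0.2, 1.0, 0.45, 0.7, sigma = sig, seed = 42)
  s <- extract_signals(tr)
  n_ml <- sum(tr$phase == "dark_ml")
  expect_lt(abs(s$f_o - 0.2), 3 * sig / sqrt(n_ml))
  # plateau means use about half the pulse window
  n_pl <- sum(tr$phase == "dark_pulse") / 2
  expect_lt(abs(s$f_m - 1.0), 3 * sig / sqrt(n_pl))
})

test_that("quenching ratios follow their defining equations", {
  q <- quench_params(f_o = 0.22, f_m = 1.00, f_prime = 0.40, f_m_prime = 0.80)
  expect_equal(q$fv_fm, 0.78)          # (1 - 0.22)/1
  expect_equal(q$npq, 0.25)            # (1 - 0.8)/0.8
  expect_equal(q$phi_psii, 0.5)        # (0.8 - 0.4)/0.8
  # PSII operating efficiency example: F' = 0.39, Fm' = 1.0 -> 0.61
  q2 <- quench_params(0.2, 1.2, 0.39, 1.0)
  expect_equal(q2$phi_psii, 0.61)
  # no quenching when Fm' = Fm
  expect_equal(quench_params(0.2, 1.0, 0.4, 1.0)$npq, 0)
  expect_error(quench_params(0.2, 0.1, 0.4, 1.0), "f_m must be >= f_o")
  expect_error(quench_params(0, 1, 0.4, 1), "positive")
})

test_that("simulate -> extract -> quench round-trips exactly at sigma = 0", {
  for (p in list(c(0.2, 1.0, 0.45, 0.70), c(0.15, 0.9, 0.30, 0.55))) {
    tr <- simulate_trace(p[1], p[2], p[3], p[4], sigma = 0, seed = 3)
    q <- quench_analysis(tr)
    truth <- quench_params(p[1], p[2], p[3], p[4])
    expect_equal(q$fv_fm, truth$fv_fm, tolerance = 1e-12)
    expect_equal(q$npq, truth$npq, tolerance = 1e-12)
    expect_equal(q$phi_psii, truth$phi_psii, tolerance = 1e-12)
  }
})

test_that("recovered NPQ is unbiased over noisy replicates", {
  truth <- quench_params(0.2, 1.0, 0.45, 0.70)
  npq <- vapply(1:100, function(seed) {
    quench_analysis(simulate_trace(0.2, 1.0, 0.45, 0.70,
      sigma = 0.01, seed = seed
    ))$npq
  }, 0)
  se <- stats::sd(npq) / sqrt(length(npq))
  expect_lt(abs(mean(npq) - truth$npq), 3 * se)
})

test_that("quench parameters are invariant to trace rescaling", {
  tr <- simulate_trace(0.2, 1.0, 0.45, 0.7, sigma = 0.004, seed = 9)
  q1 <- quench_analysis(tr)
  tr2 <- tr
  tr2$f <- tr2$f * 37.5
  q2 <- quench_analysis(tr2)
  expect_equal(q2$fv_fm, q1$fv_fm, tolerance = 1e-12)
  expect_equal(q2$npq, q1$npq, tolerance = 1e-12)
  expect_equal(q2$phi_psii, q1$phi_psii, tolerance = 1e-12)
})

test_that("protocol violations are reported by phase name", {
  tr <- simulate_trace(0.2, 1.0, 0.45, 0.7, sigma = 0, seed = 1)
  expect_error(extract_signals(tr[tr$phase != "actinic", ]), "actinic")
  expect_error(extract_signals(tr[tr$phase != "dark_ml", ]),
               "dark measuring-light")
  expect_error(
    extract_signals(tr[!grepl("light_pulse", tr$phase), ]),
    "light_pulse"
  )
  expect_error(simulate_trace(0.2, 1.0, 0.45, 0.7, sigma = -1), "nonnegative")
  expect_error(simulate_trace(1.2, 1.0, 0.45, 0.7), "f_m >= f_o")
})
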