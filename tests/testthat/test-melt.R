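test_that("melt_curve validates and converts units", {
  mc <- melt_curve(seq(5, 90, by = 5), rnorm(18), unit = "C")
  expect_equal(mc$temperature_K[1], 278.15)
  expect_error(melt_curve(1:5, 1:5), "at least 10")
  expect_error(melt_curve(c(seq(278, 296, 2), 295), rnorm(11)),
               "strictly increasing")
  expect_error(melt_curve(seq(5, 90, 5), rnorm(18)), "unit")
})

test_that("baseline OLS recovers exact generating lines", {
  T_K <- seq(278, 363, by = 0.5)
  y <- ifelse(T_K < 300, -21560 + 20 * T_K, -5390 + 5 * T_K)
  curve <- melt_curve(T_K, y)
  bl <- fit_baselines(curve, c(278, 295), c(320, 363))
  expect_equal(bl$y_N, -21560, tolerance = 1e-9)
  expect_equal(bl$m_N, 20, tolerance = 1e-9)
  expect_equal(bl$y_U, -5390, tolerance = 1e-9)
  expect_equal(bl$m_U, 5, tolerance = 1e-9)
})

test_that("flat noisy baselines give slopes within 3 standard errors of zero", {
  set.seed(11)
  T_K <- seq(278, 363, by = 0.5)
  y <- ifelse(T_K < 310, -16000, -4000) + rnorm(length(T_K), 0, 150)
  bl <- fit_baselines(melt_curve(T_K, y), c(278, 295), c(330, 363))
  expect_lt(abs(bl$m_N / bl$se_N[2]), 3)
  expect_lt(abs(bl$m_U / bl$se_U[2]), 3)
})

test_that("baseline windows must be ordered and populated", {
  curve <- melt_curve(seq(278, 363, 0.5),
                      rnorm(length(seq(278, 363, 0.5))))
  expect_error(fit_baselines(curve, c(340, 360), c(280, 300)),
               "below the unfolded window")
  expect_error(fit_baselines(curve, c(270, 271), c(330, 363)),
               "insufficient data")
})

test_that("fraction unfolded interpolates between the baselines", {
  T_K <- seq(278, 363, by = 1)
  bl <- structure(list(y_N = -16000, m_N = 0, y_U = -4000, m_U = 0),
                  class = "baseline_model")
  # signal exactly midway -> fU = 0.5
  curve <- melt_curve(T_K, rep(-10000, length(T_K)))
  fU <- unfolded_fraction(curve, bl)
  expect_equal(fU$fU, rep(0.5, length(T_K)))
  # signal on the native line -> clipped to eps
  curve2 <- melt_curve(T_K, rep(-16000, length(T_K)))
  fU2 <- unfolded_fraction(curve2, bl)
  expect_equal(unique(fU2$fU), 1e-4)
  expect_true(all(fU2$clipped))
  expect_equal(attr(fU2, "n_clipped"), length(T_K))
})

test_that("sloped-baseline construction inverts exactly", {
  # forward-construct Y0 for fU = 0.25 at T = 300 with sloped baselines
  T_K <- seq(278, 363, by = 1)
  bN <- -16000 + 20 * (T_K - 278)
  bU <- -4000 + 5 * (T_K - 278)
  fU_true <- 0.25
  y <- (1 - fU_true) * bN + fU_true * bU
  bl <- structure(list(y_N = -16000 - 20 * 278, m_N = 20,
                       y_U = -4000 - 5 * 278, m_U = 5),
                  class = "baseline_model")
  fU <- unfolded_fraction(melt_curve(T_K, y), bl)
  expect_equal(fU$fU[T_K == 300], 0.25, tolerance = 1e-12)
})

test_that("crossing baselines are rejected as degenerate", {
  T_K <- seq(278, 363, by = 1)
  bl <- structure(list(y_N = -16000 - 200 * 278, m_N = 200,
                       y_U = -4000, m_U = 0),
                  class = "baseline_model")
  expect_error(unfolded_fraction(melt_curve(T_K, rep(-8000, length(T_K))),
                                 bl),
               "degenerate")
})

test_that("free-energy conversion matches hand arithmetic", {
  # fU = 0.5 -> dG = 0 at any temperature
  fU <- data.frame(temperature_K = c(295, 300, 310), fU = 0.5,
                   clipped = FALSE)
  st <- free_energy_series(fU, window_K = c(288, 334))
  expect_equal(st$dG_kJ_mol, rep(0, 3))
  # fU = e/(1+e) at 300 K -> K = e, dG = -R*300
  fU2 <- data.frame(temperature_K = 300, fU = exp(1) / (1 + exp(1)),
                    clipped = FALSE)
  st2 <- free_energy_series(fU2, window_K = c(288, 334))
  expect_equal(st2$dG_kJ_mol, -8.314e-3 * 300, tolerance = 1e-10)
  expect_equal(st2$dG_kJ_mol, -2.494, tolerance = 1e-3)
  # fU = 0.269 at 298 K -> K = 0.368, dG = -RT ln K = +2.47 kJ/mol
  fU3 <- data.frame(temperature_K = 298, fU = 0.269, clipped = FALSE)
  st3 <- free_energy_series(fU3, window_K = c(288, 334))
  expect_equal(st3$dG_kJ_mol,
               -8.314e-3 * 298 * log(0.269 / (1 - 0.269)),
               tolerance = 1e-10)
  expect_equal(st3$dG_kJ_mol, 2.47, tolerance = 5e-3)
})

test_that("clipped points and out-of-window points are excluded", {
  fU <- data.frame(temperature_K = c(280, 290, 300, 350),
                   fU = c(1e-4, 0.3, 0.6, 1 - 1e-4),
                   clipped = c(TRUE, FALSE, FALSE, TRUE))
  st <- free_energy_series(fU, window_K = c(288, 334))
  expect_equal(st$temperature_K, c(290, 300))
  expect_error(free_energy_series(fU, window_K = c(400, 410)),
               "insufficient data")
})

test_that("melt curve CSV round trip preserves the data", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  mc <- gen_melt_curve(melt_generator(noise_sigma = 0))
  write_melt_curve(mc, tmp)
  back <- read_melt_curve(tmp)
  expect_equal(back$temperature_K, mc$temperature_K)
  expect_equal(back$signal, mc$signal, tolerance = 1e-12)
})
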