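test_that("mean residue ellipticity conversion follows the 1/(10 C l N) rule", {
  wl <- seq(200, 250, by = 1)
  # zero signal stays zero
  s0 <- cd_spectrum(wl, rep(0, length(wl)), 1e-5, 0.1, 349)
  expect_true(all(to_mre(s0)$mre_deg_cm2_dmol == 0))
  # hand arithmetic: -33 mdeg, C = 1e-5 M, l = 0.1 cm, N = 349
  s1 <- cd_spectrum(c(208, 222), c(-33, -33), 1e-5, 0.1, 349)
  expect_equal(to_mre(s1)$mre_deg_cm2_dmol,
               rep(-33 / (10 * 1e-5 * 0.1 * 349), 2))
  expect_equal(to_mre(s1)$mre_deg_cm2_dmol[1], -9455.6, tolerance = 1e-4)
})

test_that("conversion is linear in signal and inverse in each metadata factor", {
  set.seed(4)
  wl <- seq(195, 250, by = 0.5)
  theta <- rnorm(length(wl), -20, 10)
  base <- to_mre(cd_spectrum(wl, theta, 2e-5, 0.2, 120))$mre_deg_cm2_dmol
  expect_equal(to_mre(cd_spectrum(wl, 3 * theta, 2e-5, 0.2,
                                  120))$mre_deg_cm2_dmol, 3 * base)
  expect_equal(to_mre(cd_spectrum(wl, theta, 4e-5, 0.2,
                                  120))$mre_deg_cm2_dmol, base / 2)
  expect_equal(to_mre(cd_spectrum(wl, theta, 2e-5, 0.4,
                                  120))$mre_deg_cm2_dmol, base / 2)
  expect_equal(to_mre(cd_spectrum(wl, theta, 2e-5, 0.2,
                                  240))$mre_deg_cm2_dmol, base / 2)
})

test_that("invalid spectra and metadata are rejected", {
  wl <- seq(200, 250, 1)
  expect_error(cd_spectrum(wl, rep(0, 10), 1e-5, 0.1, 100), "equal length")
  expect_error(cd_spectrum(rev(wl), rep(0, length(wl)), 1e-5, 0.1, 100),
               "increasing")
  expect_error(cd_spectrum(c(100, 200), c(0, 0), 1e-5, 0.1, 100),
               "185")
  expect_error(cd_spectrum(wl, rep(0, length(wl)), -1e-5, 0.1, 100),
               "invalid metadata")
  expect_error(cd_spectrum(wl, rep(0, length(wl)), 1e-5, 0, 100),
               "invalid metadata")
})

test_that("222/208 ratio classifies against the helix and coiled-coil anchors", {
  mk <- function(m222, m208) {
    # linear spectrum through the two anchor wavelengths
    wl <- seq(200, 230, by = 0.5)
    mre <- approx(c(208, 222), c(m208, m222), xout = wl, rule = 2)$y
    structure(list(wavelength_nm = wl, mre_deg_cm2_dmol = mre),
              class = "mre_spectrum")
  }
  expect_equal(ratio_222_208(mk(-20000, -20000))$ratio_222_208, 1)
  # the printed coiled-coil anchor value classifies coiled-coil-like
  expect_identical(ratio_222_208(mk(-1.03e4, -1e4))$classification,
                   "coiled_coil_like")
  # the printed pure-helix anchor value classifies helix-like
  expect_identical(ratio_222_208(mk(-0.83e4, -1e4))$classification,
                   "helix_like")
  expect_identical(ratio_222_208(mk(-0.93e4, -1e4))$classification,
                   "intermediate")
  # positive scaling of the whole spectrum leaves the ratio unchanged
  set.seed(8)
  for (k in runif(5, 0.1, 40)) {
    expect_equal(ratio_222_208(mk(-0.9e4 * k, -1e4 * k))$ratio_222_208,
                 0.9, tolerance = 1e-12)
  }
})

test_that("ratio errors on missing coverage or vanishing 208 signal", {
  short <- structure(list(wavelength_nm = seq(215, 230, 0.5),
                          mre_deg_cm2_dmol = rep(-1e4, 31)),
                     class = "mre_spectrum")
  expect_error(ratio_222_208(short), "outside")
  zero <- structure(list(wavelength_nm = seq(200, 230, 0.5),
                         mre_deg_cm2_dmol = rep(0, 61)),
                    class = "mre_spectrum")
  expect_error(ratio_222_208(zero), "undefined ratio")
})

test_that("chain-length helix formula reproduces hand-computed fractions", {
  # observed equal to the full-helix prediction -> fraction 1
  full <- -40000 * (1 - 4.6 / 349)
  expect_equal(helix_fraction_chain_length(full, 349)$fraction, 1)
  expect_equal(helix_fraction_chain_length(0, 349)$fraction, 0)
  # the stalk heterodimer's measured [Theta]222
  expect_equal(helix_fraction_chain_length(-16770.5, 349)$fraction,
               16770.5 / 39472.8, tolerance = 1e-5)
  expect_equal(helix_fraction_chain_length(-16770.5, 349)$fraction,
               0.425, tolerance = 1e-3)
  expect_warning(out <- helix_fraction_chain_length(500, 349), "positive")
  expect_equal(out$fraction, 0)
  # monotone in |signal| for fixed chain length
  f <- sapply(seq(0, -39000, by = -1000), function(m)
    helix_fraction_chain_length(m, 349)$fraction)
  expect_true(all(diff(f) > 0))
})

test_that("basis deconvolution recovers exact mixtures to < 1e-8", {
  basis <- cd_basis_spectra()
  for (hf in c(0, 0.25, 0.5, 1)) {
    sp <- gen_cd_spectrum(hf, coil_frac = 1 - hf, noise_sigma_mdeg = 0)
    est <- helix_fraction_basis(to_mre(sp), basis)
    expect_equal(est$fraction, hf, tolerance = 1e-8)
  }
  # three-component mixture
  sp3 <- gen_cd_spectrum(0.3, coil_frac = 0.2, noise_sigma_mdeg = 0)
  est3 <- helix_fraction_basis(to_mre(sp3))
  expect_equal(unname(est3$coefficients), c(0.3, 0.5, 0.2),
               tolerance = 1e-8)
})

test_that("basis deconvolution tolerates noise at the 1% level", {
  # sigma = 1% of the raw-signal range, fixed seed
  clean <- gen_cd_spectrum(0.3, coil_frac = 0.7, noise_sigma_mdeg = 0)
  sigma <- 0.01 * diff(range(clean$ellipticity_mdeg))
  sp <- gen_cd_spectrum(0.3, coil_frac = 0.7, noise_sigma_mdeg = sigma,
                        seed = 21)
  est <- helix_fraction_basis(to_mre(sp))
  expect_equal(est$fraction, 0.30, tolerance = 0.02 / 0.30)
})

test_that("deconvolution needs at least two overlapping basis spectra", {
  sp <- gen_cd_spectrum(0.5, coil_frac = 0.5)
  expect_error(helix_fraction_basis(to_mre(sp),
                                    cd_basis_spectra()["helix"]),
               "at least 2")
})

test_that("cd_report bundles the spectrum metrics", {
  sp <- gen_cd_spectrum(0.6, coil_frac = 0.4)
  rep <- cd_report(sp)
  expect_named(rep, c("mre222", "mre208", "ratio", "classification",
                      "helix_fraction_by_method"))
  expect_equal(rep$helix_fraction_by_method$basis_deconvolution, 0.6,
               tolerance = 1e-6)
})

test_that("CD spectrum CSV round trip preserves the data", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  sp <- gen_cd_spectrum(0.5, coil_frac = 0.5)
  write_cd_spectrum(sp, tmp)
  back <- read_cd_spectrum(tmp, sp$concentration_molar, sp$path_cm,
                           sp$n_residues)
  expect_equal(back$ellipticity_mdeg, sp$ellipticity_mdeg,
               tolerance = 1e-10)
})
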