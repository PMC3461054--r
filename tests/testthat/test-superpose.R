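test_that("superposition is exact for identical and rigidly moved frames", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  y <- apply_rigid(x)
  out <- kabsch_superpose(x, y)
  expect_lt(out$rmsd, 1e-8)
  expect_equal(det(out$rotation), 1, tolerance = 1e-10)
  expect_equal(out$coords, x, tolerance = 1e-8)
  expect_error(kabsch_superpose(x[1:2, ], y[1:2, ]), "underdetermined")
})

test_that("SVD superposition matches brute-force rotational search on small toys", {
  set.seed(42)
  for (rep in 1:3) {
    a <- matrix(rnorm(18, sd = 2), ncol = 3)
    b <- matrix(rnorm(18, sd = 2), ncol = 3)
    fast <- kabsch_superpose(a, b)$rmsd
    slow <- rmsd_bruteforce(a, b)
    expect_lt(abs(fast - slow), 1e-3)
    expect_lte(fast, slow + 1e-9)  # closed form can never be worse
  }
})

test_that("SVD superposition agrees with the bio3d reference implementation", {
  set.seed(7)
  a <- matrix(rnorm(45, sd = 3), ncol = 3)
  b <- matrix(rnorm(45, sd = 3), ncol = 3)
  ours <- kabsch_superpose(a, b)
  fitted <- bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)),
                           fixed.inds = 1:45, mobile.inds = 1:45)
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("per-frame RMSD series is zero for rigid-motion-only ensembles", {
  base <- gen_ideal_helix(20)
  x0 <- frame_coords(base)
  coords <- array(0, dim = c(20, 3, 3))
  coords[, , 1] <- x0
  coords[, , 2] <- x0
  coords[, , 3] <- apply_rigid(x0)
  ens <- structure_ensemble(base$atoms, coords)
  r <- rmsd_series(ens, selection = "calpha")
  expect_equal(r, c(0, 0, 0), tolerance = 1e-8)
  # nm conversion is a factor of ten
  ens2 <- perturb_ensemble(base, sigma = 0.5, n_frames = 5, seed = 2)
  expect_equal(rmsd_series(ens2, "calpha"),
               10 * rmsd_series(ens2, "calpha", unit = "nm"))
})

test_that("mean RMSD from the perturbation generator matches its expectation", {
  # after superposition of n-atom frames, E[RMSD^2] ~ 3 sigma^2 (1 - ~7/(3n))
  base <- gen_ideal_helix(60)
  sigma <- 0.4
  r <- sapply(1:50, function(s) {
    ens <- perturb_ensemble(base, sigma, n_frames = 2, seed = s)
    rmsd_series(ens, "calpha")[2]
  })
  # both frames displaced independently: pair variance doubles
  expected <- sigma * sqrt(3) * sqrt(2)
  expect_equal(mean(r), expected, tolerance = 0.1)
})

test_that("RMSF recovers a planted per-residue fluctuation profile", {
  n <- 100
  base <- gen_ideal_helix(n)
  sigma <- seq(0.2, 1.2, length.out = n)
  ens <- perturb_ensemble(base, sigma, n_frames = 500, seed = 31)
  prof <- rmsf(ens)
  rel_err <- abs(prof$rmsf - sigma * sqrt(3)) / (sigma * sqrt(3))
  # profile-level recovery; the max over 100 residues carries both
  # sampling noise and the alignment-noise floor at the low-sigma end
  expect_lt(mean(rel_err), 0.10)
  expect_lt(max(rel_err), 0.15)
  # static ensemble: zero everywhere; single frame: undefined
  ens0 <- perturb_ensemble(base, 0, n_frames = 10, seed = 1)
  expect_true(all(rmsf(ens0)$rmsf == 0))
  one <- structure_ensemble(base$atoms, frame_coords(base))
  expect_error(rmsf(one), "single frame")
})

test_that("global rigid motions do not change RMSF", {
  base <- gen_ideal_helix(40)
  sigma <- rep(0.5, 40)
  a <- rmsf(perturb_ensemble(base, sigma, n_frames = 200, seed = 5))
  b <- rmsf(perturb_ensemble(base, sigma, n_frames = 200, seed = 5,
                             rigid_motion = TRUE))
  expect_equal(a$rmsf, b$rmsf, tolerance = 1e-8)
})

test_that("radius of gyration matches symmetry and brute-force sums", {
  # two equal-mass points 2 A apart -> Rg = 1 A = 0.1 nm
  two <- structure_ensemble(
    data.frame(chain = "A", resno = 1:2, resid = "ALA", elety = "CA",
               element = "C"),
    matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(radius_of_gyration(two), 0.1, tolerance = 1e-12)
  # translation invariance
  two_shift <- structure_ensemble(two$atoms, frame_coords(two) + 100)
  expect_equal(radius_of_gyration(two_shift), 0.1, tolerance = 1e-9)
  # random cloud against direct summation with element masses
  set.seed(12)
  n <- 100
  els <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  atoms <- data.frame(chain = "A", resno = seq_len(n), resid = "ALA",
                      elety = "X", element = els)
  xyz <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
  ens <- structure_ensemble(atoms, xyz)
  mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)[els]
  com <- colSums(xyz * mass) / sum(mass)
  oracle <- sqrt(sum(mass * rowSums(sweep(xyz, 2, com)^2)) / sum(mass))
  expect_equal(radius_of_gyration(ens, unit = "angstrom"), oracle,
               tolerance = 1e-10)
})
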