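# Independent oracles and fixture builders used across the suite.

# Brute-force rigid superposition: minimise RMSD over rotations by
# Nelder-Mead on Euler angles from many seeded random starts. Slow and
# independent of the SVD route.
euler_rotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

rmsd_bruteforce <- function(reference, mobile, n_starts = 40) {
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  obj <- function(p) {
    R <- euler_rotation(p[1], p[2], p[3])
    sqrt(mean(rowSums((B %*% t(R) - A)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3))
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    if (o$value < best) best <- o$value
  }
  best
}

# Analytic accessible area of two intersecting spheres of (expanded)
# radii r1, r2 at centre distance d (d < r1 + r2).
two_sphere_area <- function(r1, r2, d) {
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  (4 * pi * r1^2 - 2 * pi * r1 * h1) + (4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# Random rigid motion applied to one frame of coordinates.
apply_rigid <- function(xyz, angle = 1.1, axis = c(0, 0, 1),
                        shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, `+`)
}

# Minimal two-residue fixture with named side-chain atoms at controlled
# separation (for salt-bridge / contact construction).
two_residue_frame <- function(res1 = "GLU", atom1 = "OE1",
                              res2 = "LYS", atom2 = "NZ",
                              chain1 = "A", chain2 = "B",
                              separation = 3.5) {
  atoms <- data.frame(chain = c(chain1, chain2), resno = c(10L, 20L),
                      resid = c(res1, res2), elety = c(atom1, atom2),
                      element = substr(c(atom1, atom2), 1, 1),
                      stringsAsFactors = FALSE)
  xyz <- matrix(c(0, 0, 0, separation, 0, 0), 2, 3, byrow = TRUE)
  structure_ensemble(atoms, xyz)
}

# Helix-coil-helix chain: two ideal 20-residue helices separated by a
# 10-residue extended stretch, with large displacements between
# segments so no junction geometry is accidentally helical.
helix_coil_helix <- function() {
  h1 <- frame_coords(gen_ideal_helix(20))
  coil <- cbind(60 + 3.5 * (0:9), 0, 0)
  h2 <- sweep(frame_coords(gen_ideal_helix(20)), 2, c(150, 0, 0), `+`)
  xyz <- rbind(h1, coil, h2)
  atoms <- data.frame(chain = "A", resno = 1:50, resid = "ALA",
                      elety = "CA", element = "C",
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, xyz)
}
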