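#' Two-state melt-curve generator
#'
#' Bundles the ground-truth thermodynamic parameters, linear baselines,
#' temperature grid and noise level for forward simulation of a thermal
#' melt with [gen_melt_curve()]. Defaults are the fitted parameters of
#' the His-tagged KLP64D/68D stalk heterodimer (midpoint 297.6 K,
#' enthalpy 102.1 kJ/mol, heat capacity change implied by a maximum
#' stability temperature of 161.7 K) on a 278-363 K grid at 0.5 K pitch,
#' with baselines in mean-residue-ellipticity-like units.
#'
#' Baselines are parameterised relative to the grid start:
#' `native(T) = native[1] + native[2] * (T - T0)`, and likewise for
#' `unfolded`, with `T0` the first grid temperature.
#'
#' @param Tm_K,dHm_kJ_mol,dCp_kJ_mol_K ground-truth two-state
#'   thermodynamics.
#' @param native,unfolded baseline `c(intercept, slope)` pairs (signal
#'   units, signal per K).
#' @param T_grid_K temperature grid, Kelvin.
#' @param noise_sigma additive Gaussian noise sd on the observable,
#'   signal units.
#' @param seed integer seed; the generator is seed-deterministic.
#' @return object of class `melt_generator`.
#' @export
melt_generator <- function(Tm_K = 297.6, dHm_kJ_mol = 102.1,
                           dCp_kJ_mol_K = dcp_from_ts(297.6, 102.1, 161.7),
                           native = c(-16000, 20),
                           unfolded = c(-4000, 5),
                           T_grid_K = seq(278, 363, by = 0.5),
                           noise_sigma = 0, seed = 1L) {
  stopifnot(noise_sigma >= 0, length(T_grid_K) >= 10,
            all(diff(T_grid_K) > 0))
  structure(list(Tm_K = Tm_K, dHm_kJ_mol = dHm_kJ_mol,
                 dCp_kJ_mol_K = dCp_kJ_mol_K, native = native,
                 unfolded = unfolded, T_grid_K = T_grid_K,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "melt_generator")
}

#' Simulate a melt curve from a two-state generator
#'
#' Forward model: \eqn{Y_0(T) = (1-f_U) b_N(T) + f_U b_U(T) + \epsilon}
#' with \eqn{f_U = K/(1+K)}, \eqn{K = \exp(-\Delta G(T)/(RT))} and
#' \eqn{\Delta G} the Gibbs-Helmholtz stability curve of the generator's
#' parameters.
#'
#' @param gen a [melt_generator()].
#' @return a [melt_curve()].
#' @examples
#' mc <- gen_melt_curve(melt_generator(noise_sigma = 0))
#' @export
gen_melt_curve <- function(gen) {
  stopifnot(inherits(gen, "melt_generator"))
  T_K <- gen$T_grid_K
  if (gen$Tm_K < min(T_K) || gen$Tm_K > max(T_K))
    warning("Tm (", gen$Tm_K, " K) lies outside the temperature grid; ",
            "downstream fits will fail by design")
  T0 <- T_K[1]
  bN <- gen$native[1] + gen$native[2] * (T_K - T0)
  bU <- gen$unfolded[1] + gen$unfolded[2] * (T_K - T0)
  fU <- two_state_fraction(T_K, gen$Tm_K, gen$dHm_kJ_mol, gen$dCp_kJ_mol_K)
  y <- (1 - fU) * bN + fU * bU
  if (gen$noise_sigma > 0) {
    set.seed(gen$seed)
    y <- y + stats::rnorm(length(y), 0, gen$noise_sigma)
  }
  melt_curve(T_K, y)
}

#' Simulate a CD spectrum as a basis mixture
#'
#' Builds a mean-residue spectrum as `helix_frac * helix +
#' sheet_frac * sheet + coil_frac * coil` on the basis grid (any
#' unassigned remainder goes to the last basis component), back-converts
#' it to raw millidegrees using the supplied sample metadata, and adds
#' seeded Gaussian noise.
#'
#' @param helix_frac,coil_frac mixture fractions in \[0, 1\] with sum
#'   <= 1; the remainder is assigned to the sheet component.
#' @param basis named basis list as for [helix_fraction_basis()].
#' @param noise_sigma_mdeg Gaussian noise sd on the raw signal, mdeg.
#' @param seed integer seed.
#' @param concentration_molar,path_cm,n_residues,temperature_K sample
#'   metadata for the raw-signal back-conversion.
#' @return a [cd_spectrum()].
#' @export
gen_cd_spectrum <- function(helix_frac, coil_frac = 0,
                            basis = cd_basis_spectra(),
                            noise_sigma_mdeg = 0, seed = 1L,
                            concentration_molar = 1e-5, path_cm = 0.1,
                            n_residues = 349, temperature_K = 278) {
  if (helix_frac < 0 || coil_frac < 0)
    stop("mixture fractions must be non-negative")
  if (helix_frac + coil_frac > 1 + 1e-12)
    stop("mixture fractions must sum to at most 1")
  if (!all(c("helix", "coil") %in% names(basis)))
    stop("basis must provide 'helix' and 'coil' components")
  sheet_frac <- 1 - helix_frac - coil_frac
  wl <- basis$helix$wavelength_nm
  mre <- helix_frac * basis$helix$mre_deg_cm2_dmol +
    coil_frac * stats::approx(basis$coil$wavelength_nm,
                              basis$coil$mre_deg_cm2_dmol, xout = wl,
                              ties = mean)$y
  if ("sheet" %in% names(basis) && sheet_frac > 0)
    mre <- mre + sheet_frac *
      stats::approx(basis$sheet$wavelength_nm,
                    basis$sheet$mre_deg_cm2_dmol, xout = wl,
                    ties = mean)$y
  theta <- mre * 10 * concentration_molar * path_cm * n_residues
  if (noise_sigma_mdeg > 0) {
    set.seed(seed)
    theta <- theta + stats::rnorm(length(theta), 0, noise_sigma_mdeg)
  }
  cd_spectrum(wl, theta, concentration_molar, path_cm, n_residues,
              temperature_K)
}

#' Ideal alpha-helix C-alpha trace
#'
#' Regular helix with the canonical alpha-helical parameters: 1.5 A rise
#' and 100 degrees twist per residue on a 2.3 A radius, giving a
#' consecutive C-alpha spacing of ~3.8 A. Positive control for the
#' geometric helicity operator.
#'
#' @param n_residues number of residues (>= 5).
#' @param rise rise per residue, Angstrom.
#' @param twist_deg twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param chain chain id.
#' @param resid residue name used for all residues.
#' @return a one-frame [structure_ensemble()] of CA atoms.
#' @export
gen_ideal_helix <- function(n_residues, rise = 1.5, twist_deg = 100,
                            radius = 2.3, chain = "A", resid = "ALA") {
  stopifnot(n_residues >= 5)
  i <- seq_len(n_residues) - 1
  th <- i * twist_deg * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), rise * i)
  atoms <- data.frame(chain = chain, resno = seq_len(n_residues),
                      resid = resid, elety = "CA", element = "C",
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, xyz)
}

#' Extended (fully stretched) C-alpha trace
#'
#' Collinear C-alpha placement at a given spacing; negative control for
#' the helicity operator.
#'
#' @param n_residues number of residues.
#' @param spacing consecutive C-alpha distance, Angstrom (default 3.5).
#' @param chain chain id.
#' @param origin translation applied to the chain.
#' @return a one-frame [structure_ensemble()] of CA atoms.
#' @export
gen_extended_chain <- function(n_residues, spacing = 3.5, chain = "A",
                               origin = c(0, 0, 0)) {
  i <- seq_len(n_residues) - 1
  xyz <- cbind(spacing * i + origin[1], origin[2] + 0 * i,
               origin[3] + 0 * i)
  atoms <- data.frame(chain = chain, resno = seq_len(n_residues),
                      resid = "ALA", elety = "CA", element = "C",
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, xyz)
}

#' Crick-parameterised two-chain coiled-coil C-alpha model
#'
#' Two alpha-helical C-alpha traces wound about a common superhelical
#' axis: each residue sits on a minor helix (radius `r1`, 4*pi/7 radians
#' per residue so the seam repeats with the heptad period) carried along
#' a left-handed major helix of radius `R0` and pitch `pitch`. Chains A
#' and B are offset by `phase_offset_deg` about the axis. Positive
#' control for interchain metrics.
#'
#' @param n_residues residues per chain (>= 14).
#' @param R0 superhelix radius, Angstrom (default 4.9).
#' @param pitch superhelical pitch, Angstrom (default 140).
#' @param r1 minor-helix radius, Angstrom.
#' @param rise rise per residue along the superhelical axis, Angstrom.
#' @param phase_offset_deg angular offset of chain B (default 180).
#' @return a one-frame [structure_ensemble()] with chains A and B.
#' @export
gen_coiled_coil <- function(n_residues, R0 = 4.9, pitch = 140, r1 = 2.3,
                            rise = 1.5, phase_offset_deg = 180) {
  stopifnot(n_residues >= 14)
  omega1 <- 4 * pi / 7          # minor-helix phase per residue
  build_chain <- function(Phi0, chain) {
    i <- seq_len(n_residues) - 1
    z <- rise * i
    Om <- -2 * pi * z / pitch + Phi0   # left-handed supercoil
    axis <- cbind(R0 * cos(Om), R0 * sin(Om), z)
    ## local frame: radial normal, and binormal ~ tangent x normal
    tx <- cbind(R0 * (2 * pi / pitch) * sin(Om),
                -R0 * (2 * pi / pitch) * cos(Om),
                rep(1, length(z)))
    tx <- tx / sqrt(rowSums(tx^2))
    nx <- cbind(cos(Om), sin(Om), rep(0, length(z)))
    bx <- cbind(tx[, 2] * nx[, 3] - tx[, 3] * nx[, 2],
                tx[, 3] * nx[, 1] - tx[, 1] * nx[, 3],
                tx[, 1] * nx[, 2] - tx[, 2] * nx[, 1])
    th <- omega1 * i
    xyz <- axis + r1 * (cos(th) * nx + sin(th) * bx)
    atoms <- data.frame(chain = chain, resno = seq_len(n_residues),
                        resid = "ALA", elety = "CA", element = "C",
                        stringsAsFactors = FALSE)
    list(atoms = atoms, xyz = xyz)
  }
  a <- build_chain(0, "A")
  b <- build_chain(phase_offset_deg * pi / 180, "B")
  structure_ensemble(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz))
}

#' Seeded heptad-periodic sequence with planted charged core residues
#'
#' Generates a coiled-coil-like sequence: hydrophobic residues (L, I, V,
#' M) at the `a` and `d` positions, charged/polar residues elsewhere,
#' with charged substitutions (from D, E, K, R) planted at the requested
#' a/d sites — the "atypical heptads" of weak coiled coils. Returns the
#' ground-truth register alongside the sequence.
#'
#' @param n_heptads number of heptads.
#' @param charged_ad_positions integer residue indices (1-based within
#'   the sequence) to carry a planted charged residue; each must be an
#'   `a` or `d` position under the generated register.
#' @param phase register letter of the first residue, default `"a"`.
#' @param seed integer seed.
#' @param id sequence id.
#' @param numbering_offset full-protein number of the first residue.
#' @return list with `seq` (a [protein_sequence()]), `register`
#'   (character vector), `blocks` (the single generating block) and
#'   `charged_ad_positions`.
#' @export
gen_heptad_sequence <- function(n_heptads, charged_ad_positions = integer(),
                                phase = "a", seed = 1L, id = "synthetic",
                                numbering_offset = 1) {
  set.seed(seed)
  n <- 7L * n_heptads
  p0 <- match(tolower(phase), letters[1:7])
  if (is.na(p0)) stop("phase must be a..g")
  register <- letters[1:7][((seq_len(n) - 1 + p0 - 1) %% 7) + 1]
  core <- register %in% c("a", "d")
  res <- character(n)
  res[core] <- sample(c("L", "I", "V", "M"), sum(core), replace = TRUE)
  res[!core] <- sample(c("E", "K", "Q", "N", "R", "D", "S", "T", "A"),
                       sum(!core), replace = TRUE)
  charged_ad_positions <- as.integer(charged_ad_positions)
  if (length(charged_ad_positions)) {
    if (any(charged_ad_positions < 1 | charged_ad_positions > n))
      stop("planted positions outside the sequence")
    if (!all(core[charged_ad_positions]))
      stop("planted positions must be a/d sites under the register; ",
           "offenders: ",
           paste(charged_ad_positions[!core[charged_ad_positions]],
                 collapse = ", "))
    res[charged_ad_positions] <- sample(c("D", "E", "K", "R"),
                                        length(charged_ad_positions),
                                        replace = TRUE)
  }
  seq <- protein_sequence(id, paste(res, collapse = ""),
                          numbering_offset = numbering_offset)
  list(seq = seq, register = register,
       blocks = data.frame(start = numbering_offset,
                           end = numbering_offset + n - 1L,
                           phase = phase),
       charged_ad_positions = charged_ad_positions)
}

## Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Perturbed-ensemble generator
#'
#' Builds a synthetic conformational ensemble from a base structure:
#' each frame adds independent isotropic Gaussian displacements with a
#' prescribed per-residue standard deviation (per coordinate), plus an
#' optional random global rigid motion. Ground truth for RMSF/RMSD
#' recovery: the expected RMSF of residue `i` is \eqn{\sigma_i \sqrt 3}.
#'
#' @param base a one-frame [structure_ensemble()] (the first frame is
#'   used if several are present).
#' @param sigma per-residue displacement sd in Angstrom: a scalar or a
#'   vector matching the base structure's residues (in
#'   chain-then-residue order).
#' @param n_frames number of frames to generate.
#' @param seed integer seed; the generator is seed-deterministic.
#' @param rigid_motion add a random global rotation + translation to
#'   every frame (default `FALSE`).
#' @param translation_scale sd of the random rigid translation, Angstrom.
#' @return a [structure_ensemble()] with `n_frames` frames.
#' @export
perturb_ensemble <- function(base, sigma, n_frames = 100, seed = 1L,
                             rigid_motion = FALSE,
                             translation_scale = 5) {
  stopifnot(all(sigma >= 0), n_frames >= 1)
  at <- base$atoms
  x0 <- frame_coords(base, 1)
  if (is.null(dim(x0))) x0 <- matrix(x0, ncol = 3)
  reskey <- paste(at$chain, at$resno)
  resids <- unique(reskey)
  sigma <- rep_len(sigma, length(resids))
  sig_atom <- sigma[match(reskey, resids)]
  set.seed(seed)
  ## all displacement noise is drawn before any rigid-motion draws, so a
  ## given seed produces identical internal displacements whether or not
  ## rigid motions are added (the invariance tests rely on this)
  coords <- array(NA_real_, dim = c(nrow(at), 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- x0 +
      matrix(stats::rnorm(3 * nrow(at), 0, sig_atom), ncol = 3)
  if (rigid_motion) {
    for (f in seq_len(n_frames)) {
      R <- random_rotation()
      xf <- coords[, , f] %*% t(R)
      coords[, , f] <- sweep(xf, 2,
                             stats::rnorm(3, 0, translation_scale), `+`)
    }
  }
  structure_ensemble(at, coords)
}
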