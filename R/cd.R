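#' Construct a far-UV CD spectrum
#'
#' Raw circular-dichroism signal (millidegrees) against wavelength, with
#' the sample metadata needed to normalise to mean residue molar
#' ellipticity: molar concentration, cuvette path length and residue
#' count.
#'
#' @param wavelength_nm strictly increasing wavelengths in nm, within
#'   \[185, 300\].
#' @param ellipticity_mdeg observed ellipticity in millidegrees.
#' @param concentration_molar protein concentration, mol/L.
#' @param path_cm cuvette path length, cm.
#' @param n_residues number of amino-acid residues in the species in
#'   solution (per complex for an intact dimer).
#' @param temperature_K acquisition temperature, K (metadata only).
#' @return an object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelength_nm, ellipticity_mdeg,
                        concentration_molar, path_cm, n_residues,
                        temperature_K = 278) {
  if (length(wavelength_nm) != length(ellipticity_mdeg))
    stop("wavelength and ellipticity must have equal length")
  if (length(wavelength_nm) < 2)
    stop("spectrum needs at least 2 points")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(wavelength_nm < 185 | wavelength_nm > 300))
    stop("wavelengths must lie within [185, 300] nm")
  if (!isTRUE(concentration_molar > 0) || !isTRUE(path_cm > 0) ||
      !isTRUE(n_residues > 0))
    stop("invalid metadata: concentration, path length and residue ",
         "count must all be positive")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 ellipticity_mdeg = as.numeric(ellipticity_mdeg),
                 concentration_molar = concentration_molar,
                 path_cm = path_cm,
                 n_residues = as.integer(n_residues),
                 temperature_K = temperature_K),
            class = "cd_spectrum")
}

#' Convert raw ellipticity to mean residue molar ellipticity
#'
#' Normalises the raw signal per residue, per mole, per centimetre of
#' path: \deqn{[\Theta] = \frac{\theta_{mdeg}}{10 \, C \, l \, N}} with
#' `C` in mol/L, `l` in cm and `N` residues, giving units of
#' deg cm^2 dmol^-1.
#'
#' @param spectrum a [cd_spectrum()].
#' @return an object of class `mre_spectrum`: list with `wavelength_nm`
#'   and `mre_deg_cm2_dmol`.
#' @examples
#' s <- cd_spectrum(c(208, 222), c(-33, -33), 1e-5, 0.1, 349)
#' to_mre(s)$mre_deg_cm2_dmol
#' @export
to_mre <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  denom <- 10 * spectrum$concentration_molar * spectrum$path_cm *
    spectrum$n_residues
  structure(list(wavelength_nm = spectrum$wavelength_nm,
                 mre_deg_cm2_dmol = spectrum$ellipticity_mdeg / denom),
            class = "mre_spectrum")
}

## Linear interpolation of [Theta] at a wavelength, with a range check.
mre_at <- function(mre, wavelength_nm) {
  wl <- mre$wavelength_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop("wavelength ", wavelength_nm, " nm outside spectrum range [",
         min(wl), ", ", max(wl), "]")
  stats::approx(wl, mre$mre_deg_cm2_dmol, xout = wavelength_nm,
                ties = mean)$y
}

#' Coiled-coil index from the 222/208 nm ellipticity ratio
#'
#' The ratio of mean residue ellipticities at the two helical minima,
#' \eqn{[\Theta]_{222}/[\Theta]_{208}}, distinguishes isolated
#' alpha-helices (typical value 0.83) from two-stranded coiled coils
#' (typical value 1.03). Classification uses a dead-band around the
#' midpoint of the anchors: at or above `band[2]` the spectrum is called
#' `coiled_coil_like`, at or below `band[1]` `helix_like`, otherwise
#' `intermediate`.
#'
#' @param mre an `mre_spectrum` from [to_mre()].
#' @param anchors reference ratios `c(helix, coiled_coil)`, default
#'   `c(0.83, 1.03)`.
#' @param band classification dead-band, default `c(0.88, 0.98)`.
#' @return list with `ratio_222_208`, `mre222`, `mre208`,
#'   `classification` and the anchors used.
#' @export
ratio_222_208 <- function(mre, anchors = c(0.83, 1.03),
                          band = c(0.88, 0.98)) {
  m222 <- mre_at(mre, 222)
  m208 <- mre_at(mre, 208)
  if (abs(m208) < 1e-12)
    stop("undefined ratio: [Theta]208 is (numerically) zero")
  r <- m222 / m208
  cls <- if (r >= band[2]) "coiled_coil_like"
         else if (r <= band[1]) "helix_like"
         else "intermediate"
  list(ratio_222_208 = r, mre222 = m222, mre208 = m208,
       classification = cls, anchors = anchors, band = band)
}

#' Helix fraction from the chain-length formula
#'
#' Estimates fractional helicity by comparing the observed
#' \eqn{[\Theta]_{222}} with the value expected for a fully helical chain
#' of `n` residues, \eqn{[\Theta]_{222}^{max} = -40000 (1 - 4.6/n)}
#' (the chain-length dependence of the per-residue helix signal). The
#' fraction is clipped to \[0, 1\].
#'
#' @param mre222 observed mean residue ellipticity at 222 nm,
#'   deg cm^2 dmol^-1 (negative for helical content).
#' @param n_residues chain length used for the end-effect correction;
#'   must exceed 5.
#' @return list with `fraction` and `method = "chain_length_formula"`.
#' @examples
#' helix_fraction_chain_length(-16770.5, 349)
#' @export
helix_fraction_chain_length <- function(mre222, n_residues) {
  stopifnot(n_residues > 5)
  if (mre222 > 0) {
    warning("positive [Theta]222 implies no helical signal; fraction 0")
    return(list(fraction = 0, method = "chain_length_formula"))
  }
  pred <- -40000 * (1 - 4.6 / n_residues)
  list(fraction = min(max(mre222 / pred, 0), 1),
       method = "chain_length_formula")
}

#' Helix fraction by basis-spectrum deconvolution
#'
#' Decomposes a mean-residue spectrum as a non-negative mixture of
#' reference secondary-structure basis spectra (helix, sheet, coil, ...)
#' by non-negative least squares, normalises the coefficients to sum to
#' one, and reports the helix coefficient as the helix fraction. The
#' basis is interpolated onto the query wavelength grid over their common
#' range.
#'
#' @param mre an `mre_spectrum` from [to_mre()].
#' @param basis named list of basis spectra, each a list/data frame with
#'   `wavelength_nm` and `mre_deg_cm2_dmol`; must contain an element
#'   named `helix`. Default [cd_basis_spectra()], a generic synthetic
#'   basis shipped with the package.
#' @return list with `fraction`, `coefficients` (normalised, named) and
#'   `method = "basis_deconvolution"`.
#' @export
helix_fraction_basis <- function(mre, basis = cd_basis_spectra()) {
  if (length(basis) < 2)
    stop("need at least 2 basis spectra for deconvolution")
  if (!"helix" %in% names(basis))
    stop("basis must contain a spectrum named 'helix'")
  lo <- max(sapply(basis, function(b) min(b$wavelength_nm)),
            min(mre$wavelength_nm))
  hi <- min(sapply(basis, function(b) max(b$wavelength_nm)),
            max(mre$wavelength_nm))
  if (hi <= lo) stop("basis and query wavelength ranges do not overlap")
  keep <- mre$wavelength_nm >= lo & mre$wavelength_nm <= hi
  wl <- mre$wavelength_nm[keep]
  y <- mre$mre_deg_cm2_dmol[keep]
  A <- sapply(basis, function(b)
    stats::approx(b$wavelength_nm, b$mre_deg_cm2_dmol, xout = wl,
                  ties = mean)$y)
  coefs <- nnls_lawson_hanson(A, y)
  names(coefs) <- names(basis)
  total <- sum(coefs)
  norm <- if (total > 0) coefs / total else coefs
  list(fraction = unname(norm["helix"]), coefficients = norm,
       method = "basis_deconvolution")
}

## Lawson-Hanson active-set non-negative least squares:
## argmin_{x >= 0} ||A x - y||. Small and exact for the few-component
## basis systems used here.
nnls_lawson_hanson <- function(A, y, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * norm(A, "F") * n
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, y - A %*% x)
  iter <- 0; max_iter <- 30 * n
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), y)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      if (!any(passive)) { s <- numeric(n); break }
    }
    x <- s
    w <- crossprod(A, y - A %*% x)
  }
  pmax(x, 0)
}

#' Generic synthetic secondary-structure CD basis
#'
#' A small helix/sheet/coil reference set built from analytic band shapes
#' with the canonical far-UV features: the helix basis has the strong
#' positive band near 192 nm and the double minima at 208 and 222 nm; the
#' sheet basis a positive band near 196 nm and a single minimum near
#' 218 nm; the coil basis a deep minimum near 198 nm. These are
#' synthetic, generic shapes intended for mixture tests and rough
#' deconvolution, not a replacement for instrument-calibrated reference
#' sets.
#'
#' @param wavelength_nm wavelength grid, default 190-260 nm at 0.5 nm.
#' @return named list of basis spectra (`helix`, `sheet`, `coil`), each
#'   with `wavelength_nm` and `mre_deg_cm2_dmol`.
#' @export
cd_basis_spectra <- function(wavelength_nm = seq(190, 260, by = 0.5)) {
  g <- function(center, width, amp)
    amp * exp(-0.5 * ((wavelength_nm - center) / width)^2)
  make <- function(y) list(wavelength_nm = wavelength_nm,
                           mre_deg_cm2_dmol = y)
  list(
    helix = make(g(191, 5.5, 72000) + g(208, 6.0, -34000) +
                   g(222, 7.5, -35000)),
    sheet = make(g(196, 5.5, 32000) + g(218, 8.0, -14000)),
    coil = make(g(198, 6.5, -42000) + g(220, 12, 2500))
  )
}

#' Read a CD spectrum from a delimited file
#'
#' Expects header columns `wavelength_nm` and `ellipticity_mdeg` (CSV or
#' TSV, autodetected); sample metadata is supplied as arguments.
#'
#' @param path file path.
#' @inheritParams cd_spectrum
#' @return a [cd_spectrum()].
#' @export
read_cd_spectrum <- function(path, concentration_molar, path_cm,
                             n_residues, temperature_K = 278) {
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("wavelength_nm", "ellipticity_mdeg")
  if (!all(need %in% names(df)))
    stop("CD file must have columns 'wavelength_nm' and ",
         "'ellipticity_mdeg'; found: ", paste(names(df), collapse = ", "))
  cd_spectrum(df$wavelength_nm, df$ellipticity_mdeg, concentration_molar,
              path_cm, n_residues, temperature_K)
}

#' Write a CD spectrum to CSV
#' @param spectrum a [cd_spectrum()].
#' @param path output file path.
#' @export
write_cd_spectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelength_nm,
               ellipticity_mdeg = spectrum$ellipticity_mdeg),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full CD report for one spectrum
#'
#' Bundles mean-residue conversion, the 222/208 coiled-coil index and
#' both helix-content estimates into one list, suitable for JSON export.
#'
#' @param spectrum a [cd_spectrum()].
#' @param basis basis set for [helix_fraction_basis()].
#' @inheritParams ratio_222_208
#' @return list with `mre222`, `mre208`, `ratio`, `classification` and
#'   `helix_fraction_by_method`.
#' @export
cd_report <- function(spectrum, basis = cd_basis_spectra(),
                      anchors = c(0.83, 1.03), band = c(0.88, 0.98)) {
  mre <- to_mre(spectrum)
  rat <- ratio_222_208(mre, anchors = anchors, band = band)
  hf_cl <- helix_fraction_chain_length(rat$mre222, spectrum$n_residues)
  hf_bd <- tryCatch(helix_fraction_basis(mre, basis),
                    error = function(e) list(fraction = NA_real_))
  list(mre222 = rat$mre222, mre208 = rat$mre208,
       ratio = rat$ratio_222_208, classification = rat$classification,
       helix_fraction_by_method = list(
         chain_length_formula = hf_cl$fraction,
         basis_deconvolution = hf_bd$fraction))
}
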