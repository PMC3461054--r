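#' Construct a thermal melt curve
#'
#' A melt curve is the unfolding observable: mean residue molar ellipticity
#' (or any linear reporter of the folded population) recorded against
#' temperature at a fixed wavelength, conventionally 222 nm where the
#' helical CD signal is strongest.
#'
#' @param temperature temperatures, strictly increasing. Interpreted
#'   according to `unit` and stored in Kelvin.
#' @param signal observed signal at each temperature (Y0).
#' @param wavelength_nm monitored wavelength, default 222.
#' @param unit `"K"` or `"C"`; Celsius input is converted to Kelvin.
#' @return an object of class `melt_curve`: a data frame with columns
#'   `temperature_K` and `signal`, plus a `wavelength_nm` attribute.
#' @examples
#' mc <- melt_curve(seq(5, 90, by = 5), rnorm(18), unit = "C")
#' range(mc$temperature_K)
#' @export
melt_curve <- function(temperature, signal, wavelength_nm = 222,
                       unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature <- temperature + 273.15
  if (length(temperature) != length(signal))
    stop("temperature and signal must have equal length")
  if (length(temperature) < 10)
    stop("melt curve needs at least 10 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(temperature <= 250 | temperature >= 400))
    stop("temperatures must lie in (250, 400) K; check the unit flag")
  out <- data.frame(temperature_K = as.numeric(temperature),
                    signal = as.numeric(signal))
  attr(out, "wavelength_nm") <- wavelength_nm
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Read a melt curve from a delimited file
#'
#' Expects header columns `temperature` and `signal` (CSV or TSV,
#' autodetected from the header line).
#'
#' @param path file path.
#' @inheritParams melt_curve
#' @return a [melt_curve()].
#' @export
read_melt_curve <- function(path, unit = c("K", "C"), wavelength_nm = 222) {
  unit <- match.arg(unit)
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("temperature", "signal")
  if (!all(need %in% names(df)))
    stop("melt file must have columns 'temperature' and 'signal'; found: ",
         paste(names(df), collapse = ", "))
  melt_curve(df$temperature, df$signal, wavelength_nm = wavelength_nm,
             unit = unit)
}

#' Write a melt curve to CSV
#'
#' Columns `temperature` (Kelvin) and `signal`, matching [read_melt_curve()].
#'
#' @param curve a [melt_curve()].
#' @param path output file path.
#' @export
write_melt_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(temperature = curve$temperature_K, signal = curve$signal),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit linear native and unfolded baselines
#'
#' Ordinary least-squares lines through the points of a melt curve falling
#' inside the native (pre-transition) and unfolded (post-transition)
#' temperature windows. The baselines model the temperature dependence of
#' the folded-state and unfolded-state signals outside the transition.
#'
#' @param curve a [melt_curve()].
#' @param native_window_K numeric length-2, Kelvin interval of purely
#'   native signal. Default: the lowest 10 K of the data.
#' @param unfolded_window_K Kelvin interval of purely unfolded signal.
#'   Default: the highest 15 K of the data.
#' @return an object of class `baseline_model` with intercepts `y_N`,
#'   `y_U`, slopes `m_N`, `m_U` (signal per Kelvin, absolute temperature)
#'   and the windows used.
#' @export
fit_baselines <- function(curve, native_window_K = NULL,
                          unfolded_window_K = NULL) {
  T_K <- curve$temperature_K
  if (is.null(native_window_K))
    native_window_K <- c(min(T_K), min(T_K) + 10)
  if (is.null(unfolded_window_K))
    unfolded_window_K <- c(max(T_K) - 15, max(T_K))
  native_window_K <- sort(as.numeric(native_window_K))
  unfolded_window_K <- sort(as.numeric(unfolded_window_K))
  if (native_window_K[2] > unfolded_window_K[1])
    stop("native window must lie entirely below the unfolded window")

  in_n <- T_K >= native_window_K[1] & T_K <= native_window_K[2]
  in_u <- T_K >= unfolded_window_K[1] & T_K <= unfolded_window_K[2]
  if (sum(in_n) < 3)
    stop("insufficient data: native window [", native_window_K[1], ", ",
         native_window_K[2], "] K contains ", sum(in_n), " points (need 3)")
  if (sum(in_u) < 3)
    stop("insufficient data: unfolded window [", unfolded_window_K[1], ", ",
         unfolded_window_K[2], "] K contains ", sum(in_u), " points (need 3)")

  fn <- stats::lm(signal ~ temperature_K, data = curve[in_n, ])
  fu <- stats::lm(signal ~ temperature_K, data = curve[in_u, ])
  out <- list(
    y_N = unname(stats::coef(fn)[1]), m_N = unname(stats::coef(fn)[2]),
    y_U = unname(stats::coef(fu)[1]), m_U = unname(stats::coef(fu)[2]),
    se_N = suppressWarnings(summary(fn)$coefficients[, "Std. Error"]),
    se_U = suppressWarnings(summary(fu)$coefficients[, "Std. Error"]),
    native_window_K = native_window_K,
    unfolded_window_K = unfolded_window_K,
    n_native = sum(in_n), n_unfolded = sum(in_u))
  class(out) <- "baseline_model"
  out
}

#' @export
print.baseline_model <- function(x, ...) {
  cat("Two-state melt baselines (signal = intercept + slope * T[K])\n")
  cat(sprintf("  native  : %10.4g + %10.4g * T  (%d pts in [%.1f, %.1f] K)\n",
              x$y_N, x$m_N, x$n_native,
              x$native_window_K[1], x$native_window_K[2]))
  cat(sprintf("  unfolded: %10.4g + %10.4g * T  (%d pts in [%.1f, %.1f] K)\n",
              x$y_U, x$m_U, x$n_unfolded,
              x$unfolded_window_K[1], x$unfolded_window_K[2]))
  invisible(x)
}

#' Fraction unfolded from baseline-corrected signal
#'
#' For each temperature the unfolded fraction is the position of the
#' observed signal between the extrapolated native and unfolded baselines:
#' \deqn{f_U(T) = \frac{Y_0 - (y_N + m_N T)}{(y_U + m_U T) - (y_N + m_N T)}}
#' Values are clipped into `[eps, 1 - eps]` before any logarithm is taken
#' downstream; clipped points are flagged so the stability-curve fit can
#' exclude them.
#'
#' @param curve a [melt_curve()].
#' @param baselines a `baseline_model` from [fit_baselines()].
#' @param eps clip bound, default `1e-4`.
#' @return data frame with columns `temperature_K`, `fU` (clipped),
#'   `fU_raw`, and logical `clipped`; the clip count is in attribute
#'   `n_clipped`.
#' @export
unfolded_fraction <- function(curve, baselines, eps = 1e-4) {
  T_K <- curve$temperature_K
  bN <- baselines$y_N + baselines$m_N * T_K
  bU <- baselines$y_U + baselines$m_U * T_K
  sep <- bU - bN
  if (any(sign(sep) != sign(sep[1])) || any(sep == 0))
    stop("degenerate baselines: native and unfolded lines cross inside ",
         "the data range")
  fU_raw <- (curve$signal - bN) / sep
  fU <- pmin(pmax(fU_raw, eps), 1 - eps)
  out <- data.frame(temperature_K = T_K, fU = fU, fU_raw = fU_raw,
                    clipped = fU != fU_raw)
  attr(out, "n_clipped") <- sum(out$clipped)
  out
}

#' Free energy of unfolding across the transition window
#'
#' Converts unfolded fractions to an apparent equilibrium constant
#' \eqn{K = f_U/(1-f_U)} and a free energy \eqn{\Delta G = -RT\ln K}
#' (R = 8.314e-3 kJ/mol/K), restricted to the configured transition
#' window. Points clipped by [unfolded_fraction()] are dropped: their
#' logit is dominated by baseline noise, not by the transition.
#'
#' @param fU data frame from [unfolded_fraction()] (columns
#'   `temperature_K`, `fU`, optionally `clipped`).
#' @param window_K transition window in Kelvin, default `c(288, 334)`.
#' @param drop_clipped drop clipped points (default `TRUE`).
#' @return an object of class `stability_curve`: data frame with columns
#'   `temperature_K`, `dG_kJ_mol`, `fU` and `weight`
#'   (\eqn{(f_U(1-f_U))^2}, the inverse-variance weight for constant
#'   signal noise).
#' @export
free_energy_series <- function(fU, window_K = c(288, 334),
                               drop_clipped = TRUE) {
  keep <- fU$temperature_K >= window_K[1] & fU$temperature_K <= window_K[2]
  if (drop_clipped && !is.null(fU$clipped)) keep <- keep & !fU$clipped
  if (!any(keep))
    stop("insufficient data: no usable points inside the transition ",
         "window [", window_K[1], ", ", window_K[2], "] K")
  T_K <- fU$temperature_K[keep]
  f <- fU$fU[keep]
  K <- f / (1 - f)
  out <- data.frame(temperature_K = T_K,
                    dG_kJ_mol = -R_GAS * T_K * log(K),
                    fU = f,
                    weight = (f * (1 - f))^2)
  attr(out, "window_K") <- window_K
  class(out) <- c("stability_curve", "data.frame")
  out
}
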