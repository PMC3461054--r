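#' @keywords internal
"_PACKAGE"

## Gas constant in kJ mol^-1 K^-1; all free energies in kJ/mol, all
## temperatures in Kelvin throughout the package.
R_GAS <- 8.314e-3

#' Gibbs-Helmholtz stability curve
#'
#' Free energy of unfolding as a function of temperature for a two-state
#' transition with midpoint `Tm_K`, van't Hoff enthalpy `dHm_kJ_mol` at the
#' midpoint and a temperature-independent heat capacity change
#' `dCp_kJ_mol_K`:
#' \deqn{\Delta G(T) = \Delta H_m (1 - T/T_m) +
#'   \Delta C_p [(T - T_m) - T \ln(T/T_m)]}
#' By construction \eqn{\Delta G(T_m) = 0}; with \eqn{\Delta C_p > 0} the
#' curve is concave with a single maximum at the temperature of maximum
#' conformational stability (see [ts_from_params()]).
#'
#' @param T_K temperature(s), Kelvin; must be positive.
#' @param Tm_K transition midpoint temperature, K.
#' @param dHm_kJ_mol enthalpy change of unfolding at the midpoint, kJ/mol.
#' @param dCp_kJ_mol_K heat capacity change of unfolding, kJ/mol/K.
#' @return free energy of unfolding at `T_K`, kJ/mol.
#' @examples
#' gibbs_helmholtz(295, Tm_K = 297.6, dHm_kJ_mol = 102.1, dCp_kJ_mol_K = 0.56)
#' @export
gibbs_helmholtz <- function(T_K, Tm_K, dHm_kJ_mol, dCp_kJ_mol_K = 0) {
  stopifnot(all(T_K > 0), Tm_K > 0)
  dHm_kJ_mol * (1 - T_K / Tm_K) +
    dCp_kJ_mol_K * ((T_K - Tm_K) - T_K * log(T_K / Tm_K))
}

#' Temperature of maximum conformational stability
#'
#' Stationary point of the Gibbs-Helmholtz stability curve,
#' \eqn{T_s = T_m \exp(-\Delta H_m / (\Delta C_p T_m))}. Undefined (returns
#' `NA`) when `dCp_kJ_mol_K <= 0`, in which case the stability curve is a
#' straight van't Hoff line with no interior maximum.
#'
#' @inheritParams gibbs_helmholtz
#' @return `Ts` in Kelvin, or `NA_real_` when `dCp_kJ_mol_K <= 0`.
#' @examples
#' ts_from_params(297.6, 102.1, 0.5625) # ~161.7 K
#' @export
ts_from_params <- function(Tm_K, dHm_kJ_mol, dCp_kJ_mol_K) {
  stopifnot(Tm_K > 0)
  if (!is.finite(dCp_kJ_mol_K) || dCp_kJ_mol_K <= 0) return(NA_real_)
  Tm_K * exp(-dHm_kJ_mol / (dCp_kJ_mol_K * Tm_K))
}

#' Heat capacity change implied by a maximum-stability temperature
#'
#' Inverts the stationarity relation of the stability curve: given the
#' midpoint `Tm_K`, enthalpy `dHm_kJ_mol` and the temperature of maximum
#' stability `Ts_K`, returns the `dCp` for which the Gibbs-Helmholtz curve
#' is stationary at `Ts_K`:
#' \deqn{\Delta C_p = -\Delta H_m / (T_m \ln(T_s/T_m))}
#' Useful for checking internal consistency of reported thermodynamic
#' tables, where `Ts` is printed but `dCp` is not.
#'
#' @inheritParams gibbs_helmholtz
#' @param Ts_K temperature of maximum conformational stability, K; must lie
#'   below `Tm_K`.
#' @return `dCp` in kJ/mol/K.
#' @examples
#' dcp_from_ts(297.6, 102.1, 161.7)
#' @export
dcp_from_ts <- function(Tm_K, dHm_kJ_mol, Ts_K) {
  stopifnot(Tm_K > 0, Ts_K > 0)
  if (Ts_K >= Tm_K)
    stop("Ts must lie below Tm for a positive heat capacity change")
  -dHm_kJ_mol / (Tm_K * log(Ts_K / Tm_K))
}

#' Equilibrium unfolded fraction of the two-state model
#'
#' Forward two-state population: \eqn{K(T) = \exp(-\Delta G(T)/(RT))},
#' \eqn{f_U = K/(1+K)}. This is the generating model inverted by the melt
#' analysis.
#'
#' @inheritParams gibbs_helmholtz
#' @return unfolded fraction in (0, 1).
#' @export
two_state_fraction <- function(T_K, Tm_K, dHm_kJ_mol, dCp_kJ_mol_K = 0) {
  dG <- gibbs_helmholtz(T_K, Tm_K, dHm_kJ_mol, dCp_kJ_mol_K)
  K <- exp(-dG / (R_GAS * T_K))
  K / (1 + K)
}

#' Fit the Gibbs-Helmholtz equation to a stability curve
#'
#' Least-squares fit of \eqn{\Delta G(T)} over `(Tm, dHm, dCp >= 0)` to a
#' set of free-energy points, typically produced by [free_energy_series()].
#' Uses Levenberg-Marquardt ([minpack.lm::nlsLM()]) with deterministic
#' starts: `Tm0` at the interpolated zero crossing of the points, `dHm0`
#' from the van't Hoff slope of \eqn{\ln K} vs \eqn{1/T} over the central
#' part of the transition, `dCp0 = 0.5` kJ/mol/K. A small number of
#' fallback restarts around these starts is attempted before failing.
#'
#' @param stability data frame with columns `temperature_K` and
#'   `dG_kJ_mol` (a `stability_curve` as returned by
#'   [free_energy_series()]); an optional `weight` column is honoured.
#' @param init optional named list overriding any of `Tm`, `dHm`, `dCp`
#'   starting values.
#' @param fix_dcp_zero logical; fit the straight van't Hoff line
#'   (`dCp = 0`) instead of floating `dCp`.
#' @param weights `"variance"` (default) weights each point by
#'   \eqn{(f_U(1-f_U))^2}, the inverse-variance weight implied by constant
#'   noise on the melt observable propagated through the logit transform
#'   (requires a `fU` or `weight` column; falls back to unweighted
#'   otherwise); `"none"` for ordinary least squares.
#' @return a list with components `Tm_K`, `dHm_kJ_mol`, `dCp_kJ_mol_K`,
#'   `Ts_K`, standard errors (`se`), residual standard deviation
#'   (`sigma`), convergence info and the underlying `nls` fit.
#' @export
fit_gibbs_helmholtz <- function(stability, init = NULL,
                                fix_dcp_zero = FALSE,
                                weights = c("variance", "none")) {
  weights <- match.arg(weights)
  T_K <- stability$temperature_K
  dG <- stability$dG_kJ_mol
  keep <- is.finite(T_K) & is.finite(dG)
  T_K <- T_K[keep]; dG <- dG[keep]
  if (length(T_K) < 6)
    stop("insufficient data: need >= 6 finite free-energy points, got ",
         length(T_K))
  if (min(dG) > 0 || max(dG) < 0)
    stop("insufficient data: free-energy points must span the zero ",
         "crossing (all points have one sign)")

  w <- rep(1, length(T_K))
  if (weights == "variance") {
    if (!is.null(stability$weight)) {
      w <- stability$weight[keep]
    } else if (!is.null(stability$fU)) {
      fU <- stability$fU[keep]
      w <- (fU * (1 - fU))^2
    }
    w[!is.finite(w) | w < 0] <- 0
  }

  start <- gh_start_values(T_K, dG)
  if (!is.null(init)) start[names(init)] <- unlist(init)

  dat <- data.frame(T_K = T_K, dG = dG)
  do_fit <- function(st) {
    if (fix_dcp_zero) {
      minpack.lm::nlsLM(
        dG ~ dHm * (1 - T_K / Tm), data = dat,
        start = list(Tm = st$Tm, dHm = st$dHm), weights = w,
        lower = c(Tm = 200, dHm = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        dG ~ dHm * (1 - T_K / Tm) + dCp * ((T_K - Tm) - T_K * log(T_K / Tm)),
        data = dat,
        start = list(Tm = st$Tm, dHm = st$dHm, dCp = st$dCp), weights = w,
        lower = c(Tm = 200, dHm = -Inf, dCp = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }

  fit <- NULL; last_err <- NULL
  for (jitter in list(c(0, 1), c(2, 1.2), c(-2, 0.8))) {
    st <- list(Tm = start$Tm + jitter[1], dHm = start$dHm * jitter[2],
               dCp = start$dCp)
    fit <- tryCatch(do_fit(st), error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Gibbs-Helmholtz fit failed to converge: ",
         conditionMessage(last_err))

  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  dCp <- if (fix_dcp_zero) 0 else unname(cf["dCp"])
  out <- list(
    Tm_K = unname(cf["Tm"]),
    dHm_kJ_mol = unname(cf["dHm"]),
    dCp_kJ_mol_K = dCp,
    Ts_K = ts_from_params(unname(cf["Tm"]), unname(cf["dHm"]), dCp),
    se = c(Tm_K = unname(se["Tm"]), dHm_kJ_mol = unname(se["dHm"]),
           dCp_kJ_mol_K = if (fix_dcp_zero) 0 else unname(se["dCp"])),
    sigma = summary(fit)$sigma,
    n = length(T_K),
    convInfo = fit$convInfo,
    fit = fit)
  class(out) <- "gh_fit"
  out
}

## Deterministic starting values: Tm from the interpolated dG zero
## crossing, dHm from the van't Hoff slope of ln K vs 1/T over the central
## 20% of the transition, dCp = 0.5 kJ/mol/K.
gh_start_values <- function(T_K, dG) {
  ord <- order(T_K)
  T_K <- T_K[ord]; dG <- dG[ord]
  sgn <- sign(dG)
  cross <- which(diff(sgn) != 0)[1]
  Tm0 <- if (is.na(cross)) {
    stats::approx(dG, T_K, xout = 0, ties = mean)$y
  } else {
    i <- cross
    T_K[i] + (0 - dG[i]) * (T_K[i + 1] - T_K[i]) / (dG[i + 1] - dG[i])
  }
  if (!is.finite(Tm0)) Tm0 <- stats::median(T_K)

  lnK <- -dG / (R_GAS * T_K)
  central <- abs(T_K - Tm0) <= 0.1 * diff(range(T_K))
  if (sum(central) < 3) central <- rep(TRUE, length(T_K))
  vh <- stats::lm(lnK[central] ~ I(1 / T_K[central]))
  ## ln K = -dHm/R * 1/T + dSm/R  =>  slope = -dHm/R
  dHm0 <- -unname(stats::coef(vh)[2]) * R_GAS
  if (!is.finite(dHm0) || dHm0 <= 0) dHm0 <- 100
  list(Tm = Tm0, dHm = dHm0, dCp = 0.5)
}

#' @export
print.gh_fit <- function(x, ...) {
  cat("Gibbs-Helmholtz stability-curve fit\n")
  cat(sprintf("  Tm  = %8.2f K   (se %.3g)\n", x$Tm_K, x$se["Tm_K"]))
  cat(sprintf("  dHm = %8.2f kJ/mol (se %.3g)\n",
              x$dHm_kJ_mol, x$se["dHm_kJ_mol"]))
  cat(sprintf("  dCp = %8.4f kJ/mol/K (se %.3g)\n",
              x$dCp_kJ_mol_K, x$se["dCp_kJ_mol_K"]))
  if (is.finite(x$Ts_K))
    cat(sprintf("  Ts  = %8.2f K (maximum stability)\n", x$Ts_K))
  cat(sprintf("  residual sd %.4g on %d points\n", x$sigma, x$n))
  invisible(x)
}
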