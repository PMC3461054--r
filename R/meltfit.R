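#' Fit the apparent two-state thermal-unfolding model to a melt curve
#'
#' `meltfit()` is the package's central model-fitting function. It chains
#' the stages of the classical stability-curve analysis of a thermal
#' denaturation experiment:
#' \enumerate{
#'   \item linear native and unfolded baselines by ordinary least squares
#'     ([fit_baselines()]);
#'   \item fraction unfolded \eqn{f_U(T)} by baseline interpolation
#'     ([unfolded_fraction()]);
#'   \item apparent equilibrium constant and free energy
#'     \eqn{\Delta G = -RT \ln(f_U/(1-f_U))} inside the transition window
#'     ([free_energy_series()]);
#'   \item non-linear Gibbs-Helmholtz fit for
#'     \eqn{(T_m, \Delta H_m, \Delta C_p)} ([fit_gibbs_helmholtz()]);
#'   \item derived quantities: the temperature of maximum stability
#'     \eqn{T_s} and \eqn{\Delta G} at a reference temperature.
#' }
#'
#' @param curve a [melt_curve()].
#' @param transition_window_K Kelvin interval of the unfolding transition
#'   used for the stability-curve fit; default `c(288, 334)`.
#' @param native_window_K,unfolded_window_K baseline windows, passed to
#'   [fit_baselines()] (defaults: lowest 10 K / highest 15 K of the data).
#' @param Tref_K reference temperature for the reported free energy of
#'   unfolding, default 295 K.
#' @param eps clip bound for \eqn{f_U}, default `1e-4`.
#' @param method `"global"` (default) or `"staged"`. The staged method
#'   is the literal chain above: baselines are fixed at their windowed
#'   OLS estimates and only the stability curve is fit. The global
#'   method uses the staged estimates to initialise a joint
#'   Levenberg-Marquardt fit of all seven parameters (two baselines plus
#'   \eqn{T_m, \Delta H_m, \Delta C_p}) directly to the observable
#'   \eqn{Y_0(T) = (1-f_U) b_N(T) + f_U b_U(T)}. For marginally stable
#'   proteins the pre-transition window is never purely native (the
#'   unfolded fraction is already appreciable at the lowest
#'   temperatures), which contaminates fixed windowed baselines; the
#'   joint fit resolves this and is exact on noise-free two-state data.
#'   The fraction-unfolded and free-energy series reported in the object
#'   are recomputed from the final baselines either way.
#' @param weights weighting scheme for the stability-curve fit, see
#'   [fit_gibbs_helmholtz()] (staged stability fit only; the global fit
#'   works on the homoscedastic observable).
#' @param fix_dcp_zero force \eqn{\Delta C_p = 0} (straight van't Hoff
#'   stability line).
#' @return an object of class `meltfit` with components `curve`,
#'   `baselines`, `fU`, `stability`, `gh` (the Gibbs-Helmholtz fit),
#'   `params` (named vector: `Tm_K`, `dHm_kJ_mol`, `dCp_kJ_mol_K`, `Ts_K`,
#'   `dG_ref_kJ_mol`), `se`, `Tref_K`, and QC counts. Supported methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' gen <- melt_generator(Tm_K = 297.6, dHm_kJ_mol = 102.1,
#'                       dCp_kJ_mol_K = 0.56, noise_sigma = 0)
#' fit <- meltfit(gen_melt_curve(gen))
#' coef(fit)
#' @seealso [gen_melt_curve()] for the matching forward generator.
#' @export
meltfit <- function(curve,
                    transition_window_K = c(288, 334),
                    native_window_K = NULL,
                    unfolded_window_K = NULL,
                    Tref_K = 295,
                    eps = 1e-4,
                    method = c("global", "staged"),
                    weights = c("variance", "none"),
                    fix_dcp_zero = FALSE) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  if (!inherits(curve, "melt_curve"))
    curve <- melt_curve(curve$temperature_K, curve$signal)

  bl <- fit_baselines(curve, native_window_K, unfolded_window_K)

  if (method == "staged") {
    fU <- unfolded_fraction(curve, bl, eps = eps)
    st <- free_energy_series(fU, window_K = transition_window_K)
    gh <- fit_gibbs_helmholtz(st, weights = weights,
                              fix_dcp_zero = fix_dcp_zero)
    se <- gh$se
  } else {
    glob <- fit_melt_global(curve, bl, fix_dcp_zero = fix_dcp_zero)
    bl <- glob$baselines
    gh <- glob
    se <- glob$se
    fU <- unfolded_fraction(curve, bl, eps = eps)
    st <- free_energy_series(fU, window_K = transition_window_K)
  }

  params <- c(Tm_K = gh$Tm_K,
              dHm_kJ_mol = gh$dHm_kJ_mol,
              dCp_kJ_mol_K = gh$dCp_kJ_mol_K,
              Ts_K = gh$Ts_K,
              dG_ref_kJ_mol = gibbs_helmholtz(Tref_K, gh$Tm_K,
                                              gh$dHm_kJ_mol,
                                              gh$dCp_kJ_mol_K))
  out <- list(curve = curve, baselines = bl, fU = fU, stability = st,
              gh = gh, params = params, se = se, Tref_K = Tref_K,
              transition_window_K = transition_window_K,
              n_clipped = attr(fU, "n_clipped"),
              n_fit = if (method == "staged") gh$n else nrow(st),
              method = method, weights = weights,
              call = match.call())
  class(out) <- "meltfit"
  out
}

## Joint fit of baselines + thermodynamics to the raw observable.
## Initialised from the windowed baselines; Tm0 at the crossing of the
## raw baseline-interpolated fraction through 0.5, dHm0 from a central
## van't Hoff slope, dCp0 = 0.5 kJ/mol/K.
fit_melt_global <- function(curve, bl, fix_dcp_zero = FALSE) {
  T_K <- curve$temperature_K
  y <- curve$signal

  ## Tm start: peak of the smoothed derivative of the observable (the
  ## transition slope dwarfs the baseline slopes there).
  Tm0 <- tryCatch({
    ss <- stats::smooth.spline(T_K, y)
    dy <- stats::predict(ss, T_K, deriv = 1)$y
    inner <- T_K > stats::quantile(T_K, 0.05) &
      T_K < stats::quantile(T_K, 0.95)
    T_K[inner][which.max(abs(dy[inner]))]
  }, error = function(e) stats::median(T_K))

  dat <- data.frame(T_K = T_K, y = y)
  model <- function(T_K, yN, mN, yU, mU, Tm, dHm, dCp) {
    fU <- two_state_fraction(T_K, Tm, dHm, dCp)
    (1 - fU) * (yN + mN * T_K) + fU * (yU + mU * T_K)
  }

  ## Baseline slopes are bounded at 1% of the transition amplitude per
  ## Kelvin: CD melt baselines drift gently, and without a bound the
  ## least-squares problem for a marginally stable protein (no native
  ## plateau in the data) develops a degenerate valley in which a steep
  ## "baseline" absorbs the transition.
  amp <- abs((bl$y_U + bl$m_U * mean(T_K)) -
               (bl$y_N + bl$m_N * mean(T_K)))
  smax <- 0.01 * amp

  ## Deterministic multistart: the windowed native baseline is biased
  ## for marginally stable proteins (the "native" window already holds
  ## partly unfolded protein), so also try a native line through the
  ## coldest point parallel to the unfolded slope; cross with a small
  ## grid of enthalpy starts and keep the lowest-deviance admissible
  ## fit.
  clamp <- function(v) min(max(v, -smax), smax)
  native_starts <- list(
    c(yN = y[1] - clamp(bl$m_N) * T_K[1], mN = clamp(bl$m_N)),
    c(yN = y[1] - clamp(bl$m_U) * T_K[1], mN = clamp(bl$m_U)))
  dHm_starts <- c(50, 100, 200)

  best <- NULL; best_dev <- Inf; last_err <- NULL
  for (ns in native_starts) for (dHm0 in dHm_starts) {
    start <- list(yN = unname(ns["yN"]), mN = unname(ns["mN"]),
                  yU = bl$y_U, mU = clamp(bl$m_U), Tm = Tm0, dHm = dHm0)
    fit <- tryCatch({
      if (fix_dcp_zero) {
        minpack.lm::nlsLM(
          y ~ model(T_K, yN, mN, yU, mU, Tm, dHm, 0), data = dat,
          start = start,
          lower = c(-Inf, -smax, -Inf, -smax, 200, -Inf),
          upper = c(Inf, smax, Inf, smax, Inf, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(
          y ~ model(T_K, yN, mN, yU, mU, Tm, dHm, dCp), data = dat,
          start = c(start, list(dCp = 0.5)),
          lower = c(-Inf, -smax, -Inf, -smax, 200, -Inf, 0),
          upper = c(Inf, smax, Inf, smax, Inf, Inf, Inf),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) { last_err <<- e; NULL })
    if (!is.null(fit)) {
      cfi <- stats::coef(fit)
      ## admissibility: baselines must not cross inside the data range
      ## (there the "transition" is absorbed by a baseline), and the
      ## fitted transition must actually be bracketed by the data
      sep <- (cfi["yU"] + cfi["mU"] * T_K) - (cfi["yN"] + cfi["mN"] * T_K)
      if (any(sign(sep) != sign(sep[1])) || any(sep == 0)) next
      fU_fit <- two_state_fraction(T_K, cfi["Tm"], cfi["dHm"],
                                   if (fix_dcp_zero) 0 else cfi["dCp"])
      if (fU_fit[1] > 0.4 || fU_fit[length(fU_fit)] < 0.6) next
      dev <- sum(stats::residuals(fit)^2)
      if (dev < best_dev) { best <- fit; best_dev <- dev }
    }
  }
  if (is.null(best))
    stop("global melt fit failed: no admissible optimum found",
         if (!is.null(last_err))
           paste0(" (last optimiser error: ",
                  conditionMessage(last_err), ")"))
  fit <- best
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  dCp <- if (fix_dcp_zero) 0 else unname(cf["dCp"])
  bl_fit <- bl
  bl_fit$y_N <- unname(cf["yN"]); bl_fit$m_N <- unname(cf["mN"])
  bl_fit$y_U <- unname(cf["yU"]); bl_fit$m_U <- unname(cf["mU"])
  list(Tm_K = unname(cf["Tm"]), dHm_kJ_mol = unname(cf["dHm"]),
       dCp_kJ_mol_K = dCp,
       Ts_K = ts_from_params(unname(cf["Tm"]), unname(cf["dHm"]), dCp),
       se = c(Tm_K = unname(se["Tm"]), dHm_kJ_mol = unname(se["dHm"]),
              dCp_kJ_mol_K = if (fix_dcp_zero) 0 else unname(se["dCp"])),
       sigma = summary(fit)$sigma, baselines = bl_fit,
       convInfo = fit$convInfo, fit = fit)
}

#' @export
print.meltfit <- function(x, digits = 4, ...) {
  cat("Two-state thermal unfolding fit (Gibbs-Helmholtz stability curve)\n")
  cat(sprintf("  Tm  = %.*g K,  dHm = %.*g kJ/mol,  dCp = %.*g kJ/mol/K\n",
              digits, x$params["Tm_K"], digits, x$params["dHm_kJ_mol"],
              digits, x$params["dCp_kJ_mol_K"]))
  if (is.finite(x$params["Ts_K"]))
    cat(sprintf("  Ts  = %.*g K (maximum stability),  dG(%g K) = %.*g kJ/mol\n",
                digits, x$params["Ts_K"], x$Tref_K,
                digits, x$params["dG_ref_kJ_mol"]))
  cat(sprintf("  stability fit: %d points in [%.0f, %.0f] K, %d clipped\n",
              x$n_fit, x$transition_window_K[1], x$transition_window_K[2],
              x$n_clipped))
  invisible(x)
}

#' @export
coef.meltfit <- function(object, ...) object$params

#' @export
summary.meltfit <- function(object, ...) {
  structure(list(params = object$params, se = object$se,
                 baselines = object$baselines,
                 sigma = object$gh$sigma, n_fit = object$n_fit,
                 n_clipped = object$n_clipped, Tref_K = object$Tref_K,
                 transition_window_K = object$transition_window_K,
                 method = object$method),
            class = "summary.meltfit")
}

#' @export
print.summary.meltfit <- function(x, ...) {
  cat("Two-state thermal unfolding: parameter estimates\n\n")
  tab <- data.frame(
    estimate = x$params[c("Tm_K", "dHm_kJ_mol", "dCp_kJ_mol_K")],
    std.error = x$se[c("Tm_K", "dHm_kJ_mol", "dCp_kJ_mol_K")])
  print(round(tab, 4))
  cat(sprintf("\nDerived: Ts = %.2f K, dG(%g K) = %.3f kJ/mol\n",
              x$params["Ts_K"], x$Tref_K, x$params["dG_ref_kJ_mol"]))
  cat(sprintf("Stability fit: %d points in [%.0f, %.0f] K (%d clipped), ",
              x$n_fit, x$transition_window_K[1], x$transition_window_K[2],
              x$n_clipped))
  cat(sprintf("residual sd %.4g %s\n", x$sigma,
              if (identical(x$method, "staged")) "kJ/mol"
              else "(signal units)"))
  print(x$baselines)
  invisible(x)
}

#' Predict free energy of unfolding, unfolded fraction or signal
#'
#' @param object a [meltfit()] object.
#' @param newdata optional numeric vector of temperatures (K); defaults to
#'   the fitted curve's temperatures.
#' @param type `"dG"` (free energy, kJ/mol), `"fU"` (unfolded fraction) or
#'   `"signal"` (reconstructed observable using the fitted baselines).
#' @param ... unused.
#' @export
predict.meltfit <- function(object, newdata = NULL,
                            type = c("dG", "fU", "signal"), ...) {
  type <- match.arg(type)
  T_K <- if (is.null(newdata)) object$curve$temperature_K else
    as.numeric(newdata)
  p <- object$params
  dG <- gibbs_helmholtz(T_K, p["Tm_K"], p["dHm_kJ_mol"], p["dCp_kJ_mol_K"])
  if (type == "dG") return(unname(dG))
  K <- exp(-dG / (R_GAS * T_K))
  fU <- K / (1 + K)
  if (type == "fU") return(unname(fU))
  bl <- object$baselines
  bN <- bl$y_N + bl$m_N * T_K
  bU <- bl$y_U + bl$m_U * T_K
  unname((1 - fU) * bN + fU * bU)
}

#' @export
fitted.meltfit <- function(object, ...) predict(object, type = "signal")

#' @export
residuals.meltfit <- function(object, type = c("signal", "dG"), ...) {
  type <- match.arg(type)
  if (type == "signal")
    return(object$curve$signal - fitted(object))
  object$stability$dG_kJ_mol -
    predict(object, object$stability$temperature_K, type = "dG")
}

#' Simulate replicate melt curves from a fitted unfolding model
#'
#' Draws `nsim` new melt curves on the fitted curve's temperature grid
#' from the fitted two-state model and baselines, with Gaussian noise of
#' standard deviation equal to the observed root-mean-square signal
#' residual.
#'
#' @param object a [meltfit()] object.
#' @param nsim number of replicate curves.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of [melt_curve()] objects.
#' @export
simulate.meltfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  T_K <- object$curve$temperature_K
  mu <- fitted(object)
  sdres <- stats::sd(residuals(object))
  lapply(seq_len(nsim), function(i)
    melt_curve(T_K, mu + stats::rnorm(length(mu), 0, sdres),
               wavelength_nm = attr(object$curve, "wavelength_nm")))
}

#' Plot a fitted thermal-unfolding analysis
#'
#' Two panels: the melt curve with fitted baselines and reconstructed
#' two-state signal, and the stability curve (free-energy points with the
#' fitted Gibbs-Helmholtz line).
#'
#' @param x a [meltfit()] object.
#' @param which which panels to draw (subset of `1:2`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.meltfit <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  T_K <- x$curve$temperature_K
  if (1 %in% which) {
    graphics::plot(T_K, x$curve$signal, pch = 16, cex = 0.4,
                   xlab = "Temperature (K)", ylab = "Signal", ...)
    graphics::abline(x$baselines$y_N, x$baselines$m_N, lty = 2, col = 4)
    graphics::abline(x$baselines$y_U, x$baselines$m_U, lty = 2, col = 2)
    graphics::lines(T_K, fitted(x), col = "darkgreen", lwd = 2)
  }
  if (2 %in% which) {
    graphics::plot(x$stability$temperature_K, x$stability$dG_kJ_mol,
                   pch = 16, cex = 0.5, xlab = "Temperature (K)",
                   ylab = expression(Delta * G ~ "(kJ/mol)"), ...)
    Tg <- seq(min(x$stability$temperature_K),
              max(x$stability$temperature_K), length.out = 200)
    graphics::lines(Tg, predict(x, Tg, type = "dG"), col = 2, lwd = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
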