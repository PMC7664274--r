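# Two-parameter Boltzmann fits for channel activation / availability curves.

#' Fit a Boltzmann function to a voltage-dependence curve
#'
#' Fits the two-state Boltzmann sigmoid used to describe voltage-dependent
#' channel gating. For `direction = "activation"` the model is
#' \deqn{y = A / (1 + \exp((V_{1/2} - V)/k))}
#' (rising with voltage); for `direction = "inactivation"` it is
#' \deqn{y = A / (1 + \exp((V - V_{1/2})/k))}
#' (falling with voltage). Fitting is nonlinear least squares
#' (Levenberg-Marquardt). Starting values: amplitude = max(|y|), V1/2 = the
#' voltage whose y is closest to half amplitude, k = 5 mV.
#'
#' @param voltage Voltages (mV), at least 5 points spanning the transition.
#' @param y Response values (normalized permeability or availability).
#' @param direction `"activation"` or `"inactivation"`; fixes the sign
#'   convention so the slope factor k is always positive.
#' @param fit_amplitude Fit the amplitude A (default) or fix it at 1.
#' @return Object of class `boltzmann_fit`: list with `v_half` (mV), `k`
#'   (mV, > 0), `amplitude`, `direction`, `residual` (RMS), `converged`.
#' @examples
#' v <- seq(-80, 20, by = 10)
#' y <- 1 / (1 + exp((-35.45 - v) / 6.47))
#' fit_boltzmann(v, y, "activation")
#' @export
fit_boltzmann <- function(voltage, y, direction = c("activation", "inactivation"),
                          fit_amplitude = TRUE) {
  direction <- match.arg(direction)
  ok <- is.finite(voltage) & is.finite(y)
  voltage <- voltage[ok]; y <- y[ok]
  if (length(voltage) < 5)
    stop("fit_boltzmann: need at least 5 finite points spanning the transition")
  if (sd(y) < 1e-12 * max(abs(y), 1))
    stop("fit_boltzmann: response is flat; no transition to fit")
  sgn <- if (direction == "activation") -1 else 1
  a0 <- max(abs(y))
  v0 <- voltage[which.min(abs(y - a0 / 2))]
  dat <- data.frame(v = voltage, y = y)
  fit <- tryCatch(
    if (fit_amplitude) {
      minpack.lm::nlsLM(
        y ~ A / (1 + exp(sgn * (v - vh) / k)), data = dat,
        start = list(A = a0, vh = v0, k = 5),
        lower = c(A = 0, vh = -Inf, k = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ 1 / (1 + exp(sgn * (v - vh) / k)), data = dat,
        start = list(vh = v0, k = 5),
        lower = c(vh = -Inf, k = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e)
      stop("fit_boltzmann: fit did not converge (", conditionMessage(e),
           "); check that the data follow the requested direction",
           call. = FALSE))
  cf <- coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  if (!isTRUE(conv))
    stop("fit_boltzmann: Levenberg-Marquardt did not converge")
  structure(
    list(v_half = unname(cf["vh"]), k = unname(cf["k"]),
         amplitude = if (fit_amplitude) unname(cf["A"]) else 1,
         direction = direction,
         residual = sqrt(mean(residuals(fit)^2)),
         converged = TRUE),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit: V1/2 = %.2f mV, k = %.2f mV, A = %.3f (RMS %.2g)\n",
              x$direction, x$v_half, x$k, x$amplitude, x$residual))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
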