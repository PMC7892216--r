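#' Two-stage power-law calibration of dose against red-channel NOD
#'
#' Fits the conventional red-channel calibration curve
#' \deqn{D = a \cdot \mathrm{NOD} + b \cdot \mathrm{NOD}^c}
#' in two stages. Stage 1 is a bounded nonlinear least-squares fit with `a`
#' and `b` free and the exponent constrained to \eqn{1 \le c \le 3}, started
#' from a linear pre-fit of dose on NOD and multi-started over several
#' exponent guesses to avoid local minima. The stage-1 exponent is then
#' rounded to the nearest tenth and held fixed while `a` and `b` are refitted
#' (a linear problem, warm-started at their stage-1 values). The returned
#' object carries the stage-2 parameters.
#'
#' @param nod red-channel net optical densities (non-negative, not all equal).
#' @param dose delivered doses in cGy, same length as `nod`.
#' @param c_bounds lower/upper bound on the exponent in stage 1.
#' @param c_starts stage-1 multi-start values for the exponent.
#' @return an object of class `power_fit` with elements `a`, `b`, `c`
#'   (stage-2 values), `stage1` (unrounded stage-1 parameters),
#'   `rms_residual` (cGy, stage 2), `rms_residual_stage1` and `n`.
#' @seealso [predict.power_fit()], [percent_error()]
#' @examples
#' nod <- seq(0.05, 0.6, by = 0.05)
#' dose <- 120 * nod + 800 * nod^2.3
#' fit_power_nod(nod, dose)
#' @export
fit_power_nod <- function(nod, dose, c_bounds = c(1, 3), c_starts = c(1.5, 2, 2.5)) {
  nod <- as.numeric(nod)
  dose <- as.numeric(dose)
  if (length(nod) != length(dose)) stop_input("nod and dose must have the same length")
  keep <- is.finite(nod) & is.finite(dose)
  nod <- nod[keep]; dose <- dose[keep]
  if (length(nod) < 4L) stop_input("at least 4 samples are required for the power fit")
  if (any(nod < 0)) stop_input("nod values must be non-negative")
  if (diff(range(nod)) <= 0) stop_input("degenerate data: all nod values are equal")

  df <- data.frame(nod = nod, dose = dose)
  # linear pre-fit for starting values of a and b
  pre <- stats::lm(dose ~ 0 + nod + I(nod^2), data = df)
  a0 <- unname(stats::coef(pre)[1L])
  b0 <- unname(stats::coef(pre)[2L])
  if (!is.finite(a0)) a0 <- max(dose) / max(nod)
  if (!is.finite(b0)) b0 <- 0
  # a vanishing power-term start makes the exponent gradient singular
  if (abs(b0) < 1e-4 * max(abs(dose))) b0 <- 1e-4 * max(abs(dose))

  best <- NULL
  for (c0 in c_starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        dose ~ a * nod + b * nod^c, data = df,
        start = list(a = a0, b = b0, c = c0),
        lower = c(-Inf, -Inf, c_bounds[1L]),
        upper = c(Inf, Inf, c_bounds[2L]),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  if (is.null(best)) stop("power fit failed to converge from all starting exponents")

  p1 <- as.list(stats::coef(best$fit))
  rms1 <- sqrt(best$rss / length(nod))

  # stage 2: exponent fixed at the rounded stage-1 value -> linear in a, b
  c2 <- round(p1$c, 1)
  if (abs(c2 - 1) < 1e-9) {
    # the rounded exponent collapses both terms onto nod: purely linear model
    ls2 <- stats::lm.fit(cbind(nod = nod), dose)
    a2 <- unname(ls2$coefficients[1L]); b2 <- 0
  } else {
    X <- cbind(nod = nod, nodc = nod^c2)
    ls2 <- stats::lm.fit(X, dose)
    a2 <- unname(ls2$coefficients[1L])
    b2 <- unname(ls2$coefficients[2L])
  }
  if (any(!is.finite(c(a2, b2)))) stop("stage-2 refit is rank deficient")
  rms2 <- sqrt(mean(ls2$residuals^2))

  structure(list(
    a = a2, b = b2, c = c2,
    stage1 = list(a = p1$a, b = p1$b, c = p1$c),
    rms_residual = rms2,
    rms_residual_stage1 = rms1,
    n = length(nod)
  ), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Red-channel NOD power calibration (two-stage)\n")
  cat(sprintf("  D(nod) = %.6g * nod + %.6g * nod^%.1f\n", x$a, x$b, x$c))
  cat(sprintf("  stage-1 exponent %.4f, rounded to %.1f\n", x$stage1$c, x$c))
  cat(sprintf("  rms residual %.4g cGy on %d samples\n", x$rms_residual, x$n))
  invisible(x)
}

#' @export
coef.power_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' Evaluate a power-law calibration at given NOD values
#'
#' @param object a [fit_power_nod()] fit.
#' @param nod net optical densities (non-negative).
#' @param ... unused.
#' @return calculated dose(s) in cGy, `a * nod + b * nod^c`.
#' @export
predict.power_fit <- function(object, nod, ...) {
  nod <- as.numeric(nod)
  if (any(nod < 0, na.rm = TRUE)) stop_input("nod must be non-negative")
  object$a * nod + object$b * nod^object$c
}

#' @export
summary.power_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.power_fit")
}

#' @export
print.summary.power_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  stage-1 parameters: a = %.6g, b = %.6g, c = %.4f (rms %.4g cGy)\n",
              x$fit$stage1$a, x$fit$stage1$b, x$fit$stage1$c, x$fit$rms_residual_stage1))
  invisible(x)
}
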