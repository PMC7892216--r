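#' Cubic intralot refit of network dose estimates
#'
#' For a film lot outside the training lot, the network's dose estimate H is
#' systematically offset by the lot's sensitivity difference. A single
#' calibration session of the new lot is used to fit the cubic correction
#' \deqn{D_{rfit} = e H^3 + f H^2 + g H + k}
#' by ordinary least squares of delivered dose on H. The polynomial is only
#' trusted over the H range of the fit samples; evaluations outside it are
#' flagged as extrapolation (cubics diverge).
#'
#' @param H network dose estimates (cGy) for the new lot's calibration
#'   session; at least 4 distinct values.
#' @param dose delivered doses (cGy), spanning a nonzero range.
#' @param source_lot optional lot label stored with the fit.
#' @return an object of class `dose_refit` with coefficients `e`, `f`, `g`,
#'   `k`, the fitted `h_range`, `rms_residual` (cGy) and `n`.
#' @seealso [predict.dose_refit()], [run_intralot_test()]
#' @export
fit_dose_refit <- function(H, dose, source_lot = NULL) {
  H <- as.numeric(H); dose <- as.numeric(dose)
  if (length(H) != length(dose)) stop_input("H and dose must have the same length")
  if (length(H) < 4L || length(unique(H)) < 4L) {
    stop_input("the cubic refit needs at least 4 distinct H samples")
  }
  if (diff(range(dose)) <= 0) stop_input("refit samples must span a nonzero dose range")
  fit <- stats::lm(dose ~ H + I(H^2) + I(H^3))
  cf <- unname(stats::coef(fit))
  if (any(!is.finite(cf))) stop_input("rank-deficient refit design")
  structure(list(e = cf[4L], f = cf[3L], g = cf[2L], k = cf[1L],
                 h_range = range(H),
                 rms_residual = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(H),
                 source_lot = source_lot),
            class = "dose_refit")
}

#' @export
print.dose_refit <- function(x, ...) {
  cat("Cubic intralot refit",
      if (!is.null(x$source_lot)) sprintf("(lot %s)", x$source_lot), "\n")
  cat(sprintf("  D = %.4g H^3 + %.4g H^2 + %.4g H + %.4g\n", x$e, x$f, x$g, x$k))
  cat(sprintf("  fitted on %d samples, H in [%.1f, %.1f] cGy, rms %.3g cGy\n",
              x$n, x$h_range[1L], x$h_range[2L], x$rms_residual))
  invisible(x)
}

#' @export
coef.dose_refit <- function(object, ...) {
  c(e = object$e, f = object$f, g = object$g, k = object$k)
}

#' Apply a cubic refit to network dose estimates
#'
#' @param object a [fit_dose_refit()] fit.
#' @param H network dose estimate(s), cGy.
#' @param ... unused.
#' @return refit dose(s) in cGy, with a logical attribute `extrapolated`
#'   marking values of `H` outside the fitted range.
#' @export
predict.dose_refit <- function(object, H, ...) {
  H <- as.numeric(H)
  out <- object$e * H^3 + object$f * H^2 + object$g * H + object$k
  attr(out, "extrapolated") <- H < object$h_range[1L] | H > object$h_range[2L]
  out
}

#' Error statistics between calculated and delivered doses
#'
#' Builds the standard verification report: per-sample signed percentage
#' errors, their maximum and mean absolute values, and the cGy-scale mean
#' squared error (with its square root) and mean absolute error.
#'
#' @param calculated calculated doses (cGy): H, refit doses, or a
#'   conventional-calibration estimate.
#' @param delivered delivered doses (cGy), > 0.
#' @param label optional report label.
#' @param extrapolated optional logical vector marking samples evaluated
#'   outside a refit's fitted range.
#' @return an object of class `dose_error_report`: list with `per_sample`
#'   (data.frame of `delivered_cGy`, `calculated_cGy`, `percent_error`),
#'   `max_abs_pct`, `mean_abs_pct`, `mse`, `rmse`, `mae`, `n` and
#'   `n_extrapolated`.
#' @export
dose_error_report <- function(calculated, delivered, label = NULL,
                              extrapolated = NULL) {
  if (!length(delivered)) stop_input("empty test set")
  pe <- percent_error(calculated, delivered)
  per <- data.frame(delivered_cGy = delivered, calculated_cGy = as.numeric(calculated),
                    percent_error = pe)
  if (!is.null(extrapolated)) per$extrapolated <- extrapolated
  d <- as.numeric(calculated) - delivered
  structure(list(per_sample = per,
                 max_abs_pct = max(abs(pe)),
                 mean_abs_pct = mean(abs(pe)),
                 mse = mean(d^2),
                 rmse = sqrt(mean(d^2)),
                 mae = mean(abs(d)),
                 n = length(delivered),
                 n_extrapolated = if (is.null(extrapolated)) 0L else sum(extrapolated),
                 label = label),
            class = "dose_error_report")
}

#' @export
print.dose_error_report <- function(x, ...) {
  cat("Dose verification report", if (!is.null(x$label)) paste0("(", x$label, ")"), "\n")
  cat(sprintf("  n = %d samples%s\n", x$n,
              if (x$n_extrapolated > 0) sprintf(" (%d beyond the refit range)", x$n_extrapolated) else ""))
  cat(sprintf("  percent error: max |E| = %.2f %%, mean |E| = %.2f %%\n",
              x$max_abs_pct, x$mean_abs_pct))
  cat(sprintf("  dose scale:    MSE = %.2f cGy^2 (rmse %.2f cGy), MAE = %.2f cGy\n",
              x$mse, x$rmse, x$mae))
  invisible(x)
}

#' @export
as.data.frame.dose_error_report <- function(x, ...) x$per_sample

#' Aging-effect verification of a trained network
#'
#' Tests the trained network on later-shelf-age samples of its own training
#' lot. No refit is applied — test lot and training lot are the same — so the
#' calculated dose is the network output H itself.
#'
#' @param model a fitted [hnn_fit()] model.
#' @param test sample table of the later-age verification session.
#' @param dose_col delivered-dose column name.
#' @return a [dose_error_report()].
#' @export
run_aging_test <- function(model, test, dose_col = "dose_cGy") {
  if (!nrow(test)) stop_input("empty test set")
  H <- predict(model, test)
  dose_error_report(H, as.numeric(test[[dose_col]]), label = "aging effect (H vs delivered)")
}

#' Intralot verification of a trained network on a new film lot
#'
#' Fits the cubic refit on the new lot's first calibration session
#' (network estimate H against delivered dose), applies it to the lot's
#' later sessions, and reports the error statistics of the refit doses.
#'
#' @param model a fitted [hnn_fit()] model.
#' @param refit_samples sample table of the new lot's first calibration.
#' @param test sample table of the same lot's later sessions.
#' @param dose_col delivered-dose column name.
#' @return a [dose_error_report()] with the fitted `dose_refit` attached as
#'   attribute `refit`.
#' @export
run_intralot_test <- function(model, refit_samples, test, dose_col = "dose_cGy") {
  if (!nrow(test)) stop_input("empty test set")
  h_cal <- predict(model, refit_samples)
  rf <- fit_dose_refit(h_cal, as.numeric(refit_samples[[dose_col]]),
                       source_lot = if ("lot_id" %in% names(refit_samples))
                         as.character(refit_samples$lot_id[1L]) else NULL)
  h_test <- predict(model, test)
  d_rd <- predict(rf, h_test)
  rep <- dose_error_report(d_rd, as.numeric(test[[dose_col]]),
                           label = sprintf("intralot (lot %s, cubic refit)",
                                           rf$source_lot %||% "?"),
                           extrapolated = attr(d_rd, "extrapolated"))
  attr(rep, "refit") <- rf
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
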