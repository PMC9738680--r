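# Evaluation metrics for predicted-vs-ground-truth heart-rate series.
#
# All metrics derive from the per-sample error E_i = P_i - GT_i:
#   ME   = mean(E)
#   SD   = sqrt(mean((E - ME)^2))          (population form, 1/n)
#   RMSE = sqrt(mean(E^2))
#   MAPE = 100 * mean(|E| / GT)            (reported in percent)
#   rho  = Pearson correlation of P and GT
# The population SD gives the exact identity RMSE^2 = ME^2 + SD^2.

#' Compute the evaluation metrics for a prediction / ground-truth pair
#'
#' @param P numeric vector of predictions
#' @param GT numeric vector of ground-truth values (same length, nonzero for
#'   MAPE)
#' @return object of class `metrics_report`: list with `ME`, `SD`, `RMSE`,
#'   `MAPE` (percent), `rho`, `n`
#' @export
compute_metrics <- function(P, GT) {
  if (length(P) != length(GT)) stop_cfg("P and GT differ in length")
  n <- length(P)
  if (n < 2) stop_cfg("need at least 2 pairs")
  if (any(!is.finite(P)) || any(!is.finite(GT)))
    stop_cfg("non-finite values in input")
  if (any(GT == 0)) stop_cfg("MAPE undefined: ground truth contains zeros")
  if (stats::sd(P) == 0 || stats::sd(GT) == 0)
    stop_cfg("correlation undefined for a constant series")
  E <- P - GT
  ME <- mean(E)
  SD <- sqrt(mean((E - ME)^2))
  RMSE <- sqrt(mean(E * E))
  MAPE <- 100 * mean(abs(E) / GT)
  rho <- stats::cor(P, GT)
  structure(list(ME = ME, SD = SD, RMSE = RMSE, MAPE = MAPE, rho = rho,
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%10s %14s %8s %8s %8s\n",
              "ME", "Standard Dev.", "RMSE", "MAPE", "rho"))
  cat(sprintf("%10.3f %14.3f %8.3f %8.3f %8.3f\n",
              x$ME, x$SD, x$RMSE, x$MAPE, x$rho))
  cat(sprintf("(n = %d pairs; MAPE in percent)\n", x$n))
  invisible(x)
}

#' @export
as.list.metrics_report <- function(x, ...) unclass(x)
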