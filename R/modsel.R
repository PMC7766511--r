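#' Deviance information criterion
#'
#' \eqn{DIC = D(\bar\theta) + 2 p_D} with
#' \eqn{p_D = \bar D - D(\bar\theta)}: the mean of the per-cycle
#' conditional deviances minus the deviance at the posterior means of all
#' parameters. A negative effective-parameter count is reported with a
#' warning flag rather than clipped.
#'
#' @param fit an `rrm_fit` (or any list with a `draws$deviance` trace and
#'   `D_at_mean`).
#' @param label optional model label.
#' @return Tibble with `model`, `D_bar`, `D_at_mean`, `pD`, `DIC`,
#'   `pD_negative`.
#' @export
dic <- function(fit, label = NULL) {
  dev <- fit$draws$deviance
  if (is.null(dev) || !length(dev)) stop("fit carries no deviance trace")
  D_bar <- mean(dev)
  pD <- D_bar - fit$D_at_mean
  tibble::tibble(
    model = label %||% "model",
    D_bar = D_bar,
    D_at_mean = fit$D_at_mean,
    pD = pD,
    DIC = fit$D_at_mean + 2 * pD,
    pD_negative = pD < 0
  )
}

#' Posterior model probabilities from DIC values
#'
#' \eqn{PMP_s = \exp(-\Delta_s/2) / \sum_r \exp(-\Delta_r/2)} with
#' \eqn{\Delta_s = DIC_s - \min(DIC)}; computed after subtracting the
#' minimum so that large DIC differences cannot overflow. The lowest-DIC
#' model always receives the highest probability.
#'
#' @param dic_values numeric vector of DIC values (>= 2 models), optionally
#'   named.
#' @return Named numeric probability vector summing to 1.
#' @export
#' @examples
#' pmp(c(homogeneous = 0, heterogeneous = 2))
pmp <- function(dic_values) {
  if (length(dic_values) < 2) stop("need at least two models")
  if (any(!is.finite(dic_values))) stop("non-finite DIC value(s)")
  delta <- dic_values - min(dic_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Model-comparison report
#'
#' @param fits named list of `rrm_fit` objects fitted to the same data.
#' @return Tibble (model, DIC, pD, PMP), ordered by DIC.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  scores <- purrr::imap(fits, ~ dic(.x, .y)) |> dplyr::bind_rows()
  scores$PMP <- as.numeric(pmp(stats::setNames(scores$DIC, scores$model)))
  dplyr::arrange(scores, .data$DIC)
}

# Spectral density of a chain at frequency zero, via an AR fit (the
# estimator used by the standard Bayesian output analysis packages).
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1, 30))
  if (!length(fit$ar)) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the means of the first `frac_a` and last `frac_b` segments of
#' a chain, standardized by spectral-density-at-zero standard errors:
#' asymptotically standard normal for a stationary chain.
#'
#' @param chain numeric sample sequence (length >= 20).
#' @param frac_a,frac_b fractions for the early and late segment (defaults
#'   0.1 and 0.5).
#' @return The z statistic (single number).
#' @export
geweke_z <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 20) stop("chain too short for the Geweke diagnostic")
  if (stats::var(chain) == 0) stop("zero-variance chain")
  a <- chain[seq_len(max(2, floor(frac_a * n)))]
  b <- chain[seq.int(n - max(2, floor(frac_b * n)) + 1, n)]
  va <- spectrum0_ar(a) / length(a)
  vb <- spectrum0_ar(b) / length(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}
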