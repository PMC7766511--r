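#' Plot age-wise heritability curves
#'
#' One line per trait with the 95% credible band, from the per-draw
#' posterior of \eqn{h^2_j}.
#'
#' @param genpar result of [genetic_parameters()].
#' @return A ggplot object.
#' @export
plot_heritability <- function(genpar) {
  ggplot2::ggplot(genpar$h2,
                  ggplot2::aes(x = .data$age, y = .data$mean,
                               colour = .data$trait, fill = .data$trait)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = expression(h^2),
                  title = "Age-wise heritability") +
    ggplot2::theme_minimal()
}

#' Plot a genetic correlation matrix over ages
#'
#' @param corr correlation matrix from [genetic_parameters()] or
#'   [correlation_block()].
#' @return A ggplot tile map.
#' @export
plot_correlations <- function(corr) {
  df <- tibble::tibble(
    row = rep(rownames(corr), times = ncol(corr)),
    col = rep(colnames(corr), each = nrow(corr)),
    r = as.numeric(corr)
  )
  df$row <- factor(df$row, levels = rownames(corr))
  df$col <- factor(df$col, levels = colnames(corr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Trace plot of retained variance-component draws
#'
#' @param fit an `rrm_fit`.
#' @param element which diagonal coefficient to trace (default 1).
#' @return A ggplot object.
#' @export
plot_trace <- function(fit, element = 1) {
  stopifnot(inherits(fit, "rrm_fit"))
  n <- fit$n_retained
  df <- dplyr::bind_rows(
    tibble::tibble(iter = seq_len(n), value = fit$draws$G0[element, element, ],
                   block = "G0"),
    tibble::tibble(iter = seq_len(n), value = fit$draws$Rq[element, element, ],
                   block = "Rq"),
    tibble::tibble(iter = seq_len(n), value = fit$draws$Rp[element, element, ],
                   block = "Rp")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~block, scales = "free_y") +
    ggplot2::labs(x = "Retained draw", y = "Value") +
    ggplot2::theme_minimal()
}

#' @param object an `rrm_fit`; `...` passed to [plot_trace()].
#' @param ... see `object`.
#' @method autoplot rrm_fit
#' @export
autoplot.rrm_fit <- function(object, ...) plot_trace(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
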