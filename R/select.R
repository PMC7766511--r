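#' Breeding values over ages
#'
#' \eqn{EBV_i = T \hat a_i}: the covariate matrix maps an animal's
#' regression-coefficient estimates to breeding values at every age of the
#' grid.
#'
#' @param a_hat coefficient vector (length `ncol(T)`) or matrix (animals x
#'   coefficients).
#' @param T covariate matrix from [legendre_T()].
#' @return Numeric vector (or matrix, animals x ages) of EBVs.
#' @export
ebv_by_age <- function(a_hat, T = legendre_T(4)) {
  if (is.matrix(a_hat)) {
    if (ncol(a_hat) != ncol(T)) stop("coefficient dimension mismatch")
    out <- a_hat %*% t(T)
    colnames(out) <- rownames(T)
    return(out)
  }
  if (length(a_hat) != ncol(T)) stop("coefficient dimension mismatch")
  stats::setNames(as.numeric(T %*% a_hat), rownames(T))
}

#' Relative breeding values
#'
#' Standardizes EBVs at one age to the customary proof scale with mean 100
#' and standard deviation 5 (sample SD, n - 1 denominator).
#'
#' @param ebv numeric EBV vector over sires (>= 2 values, non-constant).
#' @return Numeric RBV vector with mean exactly 100 and SD exactly 5.
#' @export
#' @examples
#' rbv(c(-1, 0, 1))  # 95, 100, 105
rbv <- function(ebv) {
  if (length(ebv) < 2) stop("need at least two sires")
  s <- stats::sd(ebv)
  if (s == 0) stop("zero dispersion in EBVs")
  100 + 5 * (ebv - mean(ebv)) / s
}

#' Per-sire EBV table from a fitted model
#'
#' Links each sire's posterior-mean additive coefficients to its EBV at
#' every age, for one trait of the fit, and counts daughters with records.
#'
#' @param fit an `rrm_fit`.
#' @param trait trait name (default the first).
#' @return Long tibble: `sire_id`, `n_daughters`, `age`, `ebv`.
#' @export
sire_ebv_table <- function(fit, trait = NULL) {
  stopifnot(inherits(fit, "rrm_fit"))
  design <- fit$design
  trait <- trait %||% design$traits[1]
  t_i <- match(trait, design$traits)
  if (is.na(t_i)) stop("unknown trait: ", trait)
  k1 <- ncol(design$T)
  cols <- (t_i - 1) * k1 + seq_len(k1)
  ped <- fit$pedigree
  cows <- unique(design$cow_id)
  sires <- ped$sire[match(cows, ped$animal)]
  counts <- table(sires[!is.na(sires)])
  sire_ids <- names(counts)
  a_hat <- fit$means$a[sire_ids, cols, drop = FALSE]
  ebv <- ebv_by_age(a_hat, design$T)
  tibble::tibble(
    sire_id = rep(sire_ids, times = ncol(ebv)),
    n_daughters = rep(as.integer(counts), times = ncol(ebv)),
    age = rep(as.integer(colnames(ebv)), each = length(sire_ids)),
    ebv = as.numeric(ebv)
  ) |> dplyr::arrange(.data$sire_id, .data$age)
}

#' Top fraction of eligible sires
#'
#' Filters to sires with strictly more than `min_daughters` daughters with
#' records, ranks by EBV at the selection age (descending, ties broken by
#' sire id for determinism) and returns the top `ceiling(fraction * n)`
#' ids.
#'
#' @param sire_table long tibble from [sire_ebv_table()] (columns
#'   `sire_id`, `n_daughters`, `age`, `ebv`).
#' @param fraction selected fraction in (0, 1\]; the customary choices are
#'   0.01 and 0.10.
#' @param age_at_selection age (years) whose EBV ranks the sires.
#' @param min_daughters eligibility cut: daughters must exceed this count.
#' @return Character vector of selected sire ids, in rank order.
#' @export
top_fraction <- function(sire_table, fraction, age_at_selection,
                         min_daughters = 5) {
  stopifnot(fraction > 0, fraction <= 1)
  elig <- sire_table |>
    dplyr::filter(.data$n_daughters > min_daughters,
                  .data$age == age_at_selection)
  if (!nrow(elig)) stop("no eligible sires")
  elig <- dplyr::arrange(elig, dplyr::desc(.data$ebv), .data$sire_id)
  elig$sire_id[seq_len(ceiling(fraction * nrow(elig)))]
}

#' Percentage of commonly selected sires
#'
#' @param set_a,set_b equal-size id sets selected from the same eligible
#'   pool (e.g. under two longevity definitions).
#' @return Percentage overlap, `100 |A intersect B| / |A|`.
#' @export
common_selected <- function(set_a, set_b) {
  if (length(set_a) != length(set_b)) {
    stop("selected sets differ in size (", length(set_a), " vs ",
         length(set_b), ")")
  }
  100 * length(intersect(set_a, set_b)) / length(set_a)
}

#' Observed daughter longevity metrics per sire
#'
#' For each sire: daughters' average culling age and the proportion of
#' daughters whose completed-years culling age reaches 6, 9 and 12 years.
#'
#' @param records QC-passed life-history tibble with a `sire_id` column
#'   (or supply `pedigree` for the linkage).
#' @param pedigree optional pedigree tibble used to look up each cow's
#'   sire when `records` lacks `sire_id`.
#' @return Tibble: `sire_id`, `n_daughters`, `avg_culling_age`, `alive_6`,
#'   `alive_9`, `alive_12`.
#' @export
observed_daughter_metrics <- function(records, pedigree = NULL) {
  records <- tibble::as_tibble(records)
  if (!"sire_id" %in% names(records)) {
    if (is.null(pedigree)) stop("records lack sire_id and no pedigree given")
    ped <- normalize_pedigree(pedigree)
    records$sire_id <- ped$sire[match(records$cow_id, ped$animal)]
  }
  records |>
    dplyr::filter(!is.na(.data$sire_id)) |>
    dplyr::group_by(sire_id = .data$sire_id) |>
    dplyr::summarise(
      n_daughters = dplyr::n(),
      avg_culling_age = mean(.data$culling_age),
      alive_6 = mean(floor(.data$culling_age) >= 6),
      alive_9 = mean(floor(.data$culling_age) >= 9),
      alive_12 = mean(floor(.data$culling_age) >= 12),
      .groups = "drop"
    )
}

#' Expected daughter longevity regression
#'
#' Ordinary least squares of an observed daughter metric on the sires'
#' relative breeding values: \eqn{EDL = b_0 + b_1 RBV}. Because OLS passes
#' through the mean, the EDL predicted at RBV = 100 equals the
#' eligible-sire mean of the metric.
#'
#' @param rbv RBV vector over sires (>= 3, non-constant).
#' @param metric observed daughter metric per sire, same order.
#' @param label metric label stored with the model.
#' @param age_at_selection age whose RBV was used, stored with the model.
#' @return An `edl_model` list with `b0`, `b1`, `label`,
#'   `age_at_selection` and the underlying `lm` fit.
#' @export
fit_edl <- function(rbv, metric, label = "metric", age_at_selection = NA) {
  if (length(rbv) < 3) stop("need at least three sires")
  if (stats::sd(rbv) == 0) stop("zero dispersion in RBV")
  fit <- stats::lm(metric ~ rbv)
  b <- stats::coef(fit)
  if (any(!is.finite(b))) stop("singular EDL regression")
  structure(list(b0 = unname(b[1]), b1 = unname(b[2]), label = label,
                 age_at_selection = age_at_selection, lm = fit),
            class = "edl_model")
}

#' @export
print.edl_model <- function(x, ...) {
  cat("<edl_model>", x$label, ": EDL =", signif(x$b0, 5), "+",
      signif(x$b1, 5), "x RBV\n")
  invisible(x)
}

#' @rdname fit_edl
#' @param x an `edl_model`.
#' @param ... unused.
#' @method tidy edl_model
#' @export
tidy.edl_model <- function(x, ...) {
  tibble::tibble(term = c("b0", "b1"), estimate = c(x$b0, x$b1),
                 metric = x$label, age_at_selection = x$age_at_selection)
}

#' @rdname fit_edl
#' @param object an `edl_model`.
#' @param newdata optional tibble/vector of RBVs to predict at.
#' @export
predict.edl_model <- function(object, newdata, ...) {
  object$b0 + object$b1 * as.numeric(newdata)
}

#' Prediction accuracy
#'
#' Sample Pearson correlation between the expected and the observed
#' daughter longevity.
#'
#' @param predicted,observed numeric vectors (>= 3 pairs, both
#'   non-constant).
#' @return Pearson r.
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3) {
    stop("need at least three matched pairs")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in predicted or observed values")
  }
  stats::cor(predicted, observed)
}

#' Top-versus-bottom comparison report
#'
#' Mean (+/- SE) of a metric for the top and bottom selected fractions and
#' the percent difference `100 * (top - bottom) / top`.
#'
#' @param sire_table tibble from [sire_ebv_table()].
#' @param metrics tibble from [observed_daughter_metrics()].
#' @param metric column of `metrics` to compare.
#' @param fraction,age_at_selection,min_daughters see [top_fraction()].
#' @return One-row tibble with top/bottom means, SEs and `dif_pct`.
#' @export
top_bottom_comparison <- function(sire_table, metrics, metric = "avg_culling_age",
                                  fraction = 0.1, age_at_selection = 4,
                                  min_daughters = 5) {
  top <- top_fraction(sire_table, fraction, age_at_selection, min_daughters)
  flipped <- dplyr::mutate(sire_table, ebv = -.data$ebv)
  bottom <- top_fraction(flipped, fraction, age_at_selection, min_daughters)
  mtop <- metrics[[metric]][match(top, metrics$sire_id)]
  mbot <- metrics[[metric]][match(bottom, metrics$sire_id)]
  se <- function(x) stats::sd(x) / sqrt(length(x))
  tibble::tibble(
    metric = metric, fraction = fraction,
    top_mean = mean(mtop, na.rm = TRUE), top_se = se(mtop[!is.na(mtop)]),
    bottom_mean = mean(mbot, na.rm = TRUE),
    bottom_se = se(mbot[!is.na(mbot)]),
    dif_pct = 100 * (mean(mtop, na.rm = TRUE) - mean(mbot, na.rm = TRUE)) /
      mean(mtop, na.rm = TRUE)
  )
}
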