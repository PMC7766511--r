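#' Age-wise covariance matrices from coefficient covariances
#'
#' Applies the covariance-function congruence transform per effect:
#' herd-year-season \eqn{\phi = T R_q T'}, additive \eqn{\Sigma = T G_0 T'}
#' and permanent environment \eqn{\theta = T R_p T'}. For multiple-trait
#' fits `T` is the block-diagonal expanded covariate matrix and the
#' results are `(14 n_traits)`-square block matrices.
#'
#' @param G0,Rq,Rp coefficient covariance matrices (any may be `NULL`).
#' @param T covariate matrix from [legendre_T()] (possibly
#'   [expand_multitrait()]-expanded).
#' @param residual residual variance vector (14 per trait) or scalar,
#'   passed through.
#' @return List with `additive`, `hys`, `pe` age-covariance matrices and
#'   `residual`.
#' @export
age_covariances <- function(G0 = NULL, Rq = NULL, Rp = NULL,
                            T = legendre_T(4), residual = NULL) {
  congr <- function(M) {
    if (is.null(M)) return(NULL)
    if (ncol(T) != nrow(M)) {
      stop("dimension mismatch: T has ", ncol(T), " columns but the ",
           "coefficient matrix is ", nrow(M), "-square")
    }
    T %*% M %*% t(T)
  }
  list(additive = congr(G0), hys = congr(Rq), pe = congr(Rp),
       residual = residual)
}

#' Age-wise heritabilities
#'
#' \eqn{h^2_j = \sigma^2_{a_j} / (\sigma^2_{a_j} + \sigma^2_{q_j} +
#' \sigma^2_{p_j} + \sigma^2_{e_j})} from the diagonals of the age
#' covariance matrices.
#'
#' @param cov list from [age_covariances()] with non-null `additive`,
#'   `hys`, `pe` and `residual`.
#' @return Numeric vector of heritabilities, one per age row of the
#'   covariance matrices.
#' @export
heritability_by_age <- function(cov) {
  va <- diag(cov$additive)
  vq <- diag(cov$hys)
  vp <- diag(cov$pe)
  ve <- rep_len(cov$residual, length(va))
  total <- va + vq + vp + ve
  if (any(total <= 0)) {
    stop("zero total variance at age index ", which(total <= 0)[1])
  }
  as.numeric(va / total)
}

#' Genetic correlation matrix over ages (and traits)
#'
#' \eqn{r_{jj'} = \sigma_{a_{jj'}} / \sqrt{\sigma^2_{a_j}
#' \sigma^2_{a_{j'}}}}; the same formula serves within-trait age pairs and
#' the between-trait blocks of a multi-trait additive covariance matrix.
#'
#' @param Sigma additive age-covariance matrix (positive diagonal).
#' @return Correlation matrix of the same dimension.
#' @export
genetic_correlations <- function(Sigma) {
  d <- diag(Sigma)
  if (any(d <= 0)) {
    stop("non-positive additive variance at index ", which(d <= 0)[1])
  }
  stats::cov2cor(Sigma)
}

#' Average a correlation matrix over an age window
#'
#' Within-trait averages use the strictly-upper-triangle entries of a
#' square block restricted to the window (the diagonal is excluded);
#' between-trait averages use all window-restricted entries of a
#' rectangular block. The window `"3-12"` keeps ages 3 to 12 inclusive.
#'
#' @param mat correlation (sub)matrix whose rows/columns are the ages of
#'   `ages`.
#' @param ages ages labelling the rows (and columns), default the full
#'   grid.
#' @param age_window `"all"` or `"3-12"`.
#' @param mode `"within_offdiag"` (square, strict upper triangle) or
#'   `"between_all"` (all entries).
#' @return Tibble with `mean`, `se` (standard error of the averaged
#'   entries) and `n_entries`.
#' @export
average_correlation <- function(mat, ages = age_grid(),
                                age_window = c("all", "3-12"),
                                mode = c("within_offdiag", "between_all")) {
  age_window <- match.arg(age_window)
  mode <- match.arg(mode)
  if (mode == "within_offdiag" && nrow(mat) != ncol(mat)) {
    stop("within-trait mode needs a square block")
  }
  if (nrow(mat) != length(ages) || ncol(mat) != length(ages)) {
    stop("matrix dimension does not match the age labels")
  }
  keep <- if (age_window == "all") rep(TRUE, length(ages)) else
    ages >= 3 & ages <= 12
  if (!any(keep)) stop("empty age window")
  sub <- mat[keep, keep, drop = FALSE]
  vals <- if (mode == "within_offdiag") sub[upper.tri(sub)] else
    as.numeric(sub)
  if (!length(vals)) stop("empty age window")
  tibble::tibble(
    mean = mean(vals),
    se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
    n_entries = length(vals)
  )
}

#' Posterior genetic parameters of a fitted RRM
#'
#' Applies the age-covariance transform and the heritability and
#' correlation formulas to every retained draw, then summarizes: the
#' posterior standard errors of derived quantities come from the per-draw
#' transformation, not a delta method.
#'
#' @param fit an `rrm_fit`.
#' @return List with `h2` (tibble: trait, age, mean, se, lower, upper),
#'   `correlation` (posterior-mean additive correlation matrix over all
#'   trait-age combinations) and `age_cov` (posterior-mean age
#'   covariances).
#' @export
genetic_parameters <- function(fit) {
  stopifnot(inherits(fit, "rrm_fit"))
  design <- fit$design
  Tm <- design$T_multi
  ages <- age_grid()
  n_traits <- length(design$traits)
  n_age <- length(ages)
  n_draw <- fit$n_retained
  het <- design$spec$residual_structure == "heterogeneous_by_age"

  h2_draws <- matrix(NA_real_, n_draw, n_age * n_traits)
  corr_sum <- matrix(0, n_age * n_traits, n_age * n_traits)
  for (s in seq_len(n_draw)) {
    Sig <- Tm %*% fit$draws$G0[, , s] %*% t(Tm)
    Phi <- Tm %*% fit$draws$Rq[, , s] %*% t(Tm)
    The <- Tm %*% fit$draws$Rp[, , s] %*% t(Tm)
    sig2 <- fit$draws$sigma2[s, ]
    ve <- if (het) as.numeric(sig2) else rep(as.numeric(sig2), each = n_age)
    h2_draws[s, ] <- diag(Sig) / (diag(Sig) + diag(Phi) + diag(The) + ve)
    corr_sum <- corr_sum + stats::cov2cor(Sig)
  }
  labels <- paste0(rep(design$traits, each = n_age), "_",
                   rep(ages, times = n_traits))
  corr <- corr_sum / n_draw
  dimnames(corr) <- list(labels, labels)

  h2 <- tibble::tibble(
    trait = rep(design$traits, each = n_age),
    age = rep(ages, times = n_traits),
    mean = colMeans(h2_draws),
    se = apply(h2_draws, 2, stats::sd),
    lower = apply(h2_draws, 2, stats::quantile, probs = 0.025),
    upper = apply(h2_draws, 2, stats::quantile, probs = 0.975)
  )
  mean_cov <- age_covariances(G0 = fit$means$G0, Rq = fit$means$Rq,
                              Rp = fit$means$Rp, T = Tm,
                              residual = fit$means$sigma2)
  list(h2 = h2, correlation = corr, age_cov = mean_cov)
}

#' Extract a trait-pair block of a multi-trait correlation matrix
#'
#' @param corr labelled correlation matrix from [genetic_parameters()].
#' @param trait_a,trait_b trait names.
#' @return The 14 x 14 between-trait (or within-trait) block.
#' @export
correlation_block <- function(corr, trait_a, trait_b) {
  ra <- grepl(paste0("^", trait_a, "_"), rownames(corr))
  cb <- grepl(paste0("^", trait_b, "_"), colnames(corr))
  if (!any(ra) || !any(cb)) stop("trait not present in correlation matrix")
  corr[ra, cb, drop = FALSE]
}
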