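#' Age grid for yearly longevity records
#'
#' Longevity indicators are recorded once per year of age, from 2 to 15
#' years inclusive (14 age classes). All covariance-function machinery in
#' the package works on this grid unless another is supplied.
#'
#' @param min_age,max_age integer bounds of the grid in whole years.
#' @return Integer vector of ages.
#' @export
age_grid <- function(min_age = 2L, max_age = 15L) {
  stopifnot(max_age > min_age)
  seq.int(min_age, max_age)
}

#' Map an age onto the standardized polynomial domain
#'
#' Ages are mapped affinely onto \eqn{[-1, 1]}: the youngest age of the grid
#' goes to -1, the oldest to +1.
#'
#' @param age numeric age(s) in years.
#' @param grid age grid as returned by [age_grid()].
#' @return Numeric vector in \eqn{[-1, 1]}.
#' @export
#' @examples
#' standardize_age(c(2, 8.5, 15))
standardize_age <- function(age, grid = age_grid()) {
  lo <- min(grid)
  hi <- max(grid)
  if (any(age < lo | age > hi)) {
    stop("age outside the grid [", lo, ", ", hi, "]: ",
         paste(age[age < lo | age > hi], collapse = ", "))
  }
  -1 + 2 * (age - lo) / (hi - lo)
}

#' Legendre covariate matrix over the age grid
#'
#' Builds the matrix of Legendre polynomial covariates used for all random
#' regressions: row j holds the polynomial values at the standardized age
#' x_j, columns correspond to polynomial degrees 0..order. By default the
#' normalized (covariance-function) form
#' \eqn{\phi_n(x) = \sqrt{(2n+1)/2}\, P_n(x)} is used; `normalized = FALSE`
#' gives the raw \eqn{P_n}.
#'
#' An RRM of "order k" carries k+1 random regression coefficients per
#' effect level (LEG4 = 5 coefficients).
#'
#' @param order polynomial order (degree of the highest term); 2, 3 and 4
#'   are the orders used for longevity evaluation.
#' @param grid age grid, default [age_grid()].
#' @param normalized use the orthonormal-weight scaling (default TRUE).
#' @return Numeric matrix, `length(grid)` x `(order + 1)`, with age row
#'   names and column names `phi0..phiK`.
#' @export
#' @examples
#' T4 <- legendre_T(4)
#' dim(T4)  # 14 x 5
legendre_T <- function(order, grid = age_grid(), normalized = TRUE) {
  stopifnot(order >= 0, length(grid) >= 2)
  x <- standardize_age(grid, grid)
  P <- matrix(0, length(x), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (n in 1:(order - 1)) {
      # three-term recurrence: (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
      P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
    }
  }
  if (normalized) {
    P <- sweep(P, 2, sqrt((2 * seq(0, order) + 1) / 2), `*`)
  }
  dimnames(P) <- list(age = as.character(grid),
                      paste0("phi", seq(0, order)))
  P
}

#' Expand a covariate matrix for multiple-trait analyses
#'
#' Multiple-trait random regression models stack the per-trait covariate
#' matrices block-diagonally, so the coefficient vector of one effect level
#' carries `n_traits` blocks of `order + 1` coefficients.
#'
#' @param T single-trait covariate matrix from [legendre_T()].
#' @param n_traits number of traits (>= 1).
#' @return Block-diagonal matrix of dimension
#'   `(nrow(T) * n_traits) x (ncol(T) * n_traits)`.
#' @export
expand_multitrait <- function(T, n_traits) {
  stopifnot(is.matrix(T), n_traits >= 1)
  if (n_traits == 1) return(T)
  out <- matrix(0, nrow(T) * n_traits, ncol(T) * n_traits)
  for (t in seq_len(n_traits)) {
    ri <- (t - 1) * nrow(T) + seq_len(nrow(T))
    ci <- (t - 1) * ncol(T) + seq_len(ncol(T))
    out[ri, ci] <- T
  }
  rownames(out) <- rep(rownames(T), n_traits)
  colnames(out) <- paste0("t", rep(seq_len(n_traits), each = ncol(T)), "_",
                          rep(colnames(T), n_traits))
  out
}
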