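#' Random regression model specification
#'
#' Describes a single- or multiple-trait Bayesian linear RRM: the Legendre
#' order shared by all regressions, the residual structure (one variance
#' per yearly age class, or a single variance), and the prior
#' hyperparameters. Priors are weakly informative: coefficient covariance
#' matrices carry inverted-Wishart priors IW(`nu`, V) whose scale V is a
#' basis-scaled identity sized so each effect accounts for a share of the
#' phenotypic variance (defaults: herd-year-season 0.1, additive 0.3,
#' permanent environment 0.2), the residual a scaled inverse chi-square
#' with `nu_e` degrees of freedom and scale 0.4 of the phenotypic
#' variance, and fixed effects a vague Gaussian prior with variance
#' `sigma_b` (1e10).
#'
#' @param order Legendre polynomial order (2, 3 or 4 are the tested ones).
#' @param residual_structure `"heterogeneous_by_age"` (14 classes per
#'   trait) or `"homogeneous"` (one class per trait).
#' @param nu inverted-Wishart prior degrees of freedom.
#' @param prior_shares named shares of phenotypic variance for `q`, `a`,
#'   `p` prior scales.
#' @param nu_e,residual_share residual prior df and phenotypic-variance
#'   share.
#' @param sigma_b fixed-effect prior variance.
#' @return An `rrm_spec` list.
#' @export
rrm_spec <- function(order = 4,
                     residual_structure = c("heterogeneous_by_age",
                                            "homogeneous"),
                     nu = 3,
                     prior_shares = c(q = 0.1, a = 0.3, p = 0.2),
                     nu_e = 3,
                     residual_share = 0.4,
                     sigma_b = 1e10) {
  residual_structure <- match.arg(residual_structure)
  stopifnot(order >= 0, nu > 0, nu_e > 0,
            all(c("q", "a", "p") %in% names(prior_shares)))
  structure(list(order = order, residual_structure = residual_structure,
                 nu = nu, prior_shares = prior_shares, nu_e = nu_e,
                 residual_share = residual_share, sigma_b = sigma_b),
            class = "rrm_spec")
}

#' MCMC chain configuration
#'
#' Desk-scale defaults (20,000 cycles, 10,000 burn-in, thinning 10) suit
#' simulated data; production evaluations of large national datasets use
#' far longer chains (e.g. 500,000 / 250,000 / 10), available by setting
#' the fields.
#'
#' @param length total Gibbs cycles.
#' @param burn_in discarded cycles (must be < `length`).
#' @param thin sampling interval (>= 1).
#' @param seed integer seed; two runs with the same seed give identical
#'   retained draws.
#' @return A `chain_config` list.
#' @export
chain_config <- function(length = 20000, burn_in = 10000, thin = 10,
                         seed = 1L) {
  if (burn_in >= length) stop("burn_in must be smaller than chain length")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(length = as.integer(length), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "chain_config")
}

panel_values <- function(x) {
  if (inherits(x, "longevity_panel")) {
    tidy(x)[, c("cow_id", "age", "code")] |>
      dplyr::rename(value = "code")
  } else {
    x <- tibble::as_tibble(x)
    if ("y" %in% names(x)) x <- dplyr::rename(x, value = "y")
    if ("code" %in% names(x)) x <- dplyr::rename(x, value = "code")
    stopifnot(all(c("cow_id", "age", "value") %in% names(x)))
    x[, c("cow_id", "age", "value")]
  }
}

#' Build design structures for the RRM
#'
#' Turns one or more trait panels plus the cow metadata into the
#' observation-level structures the Gibbs sampler consumes: one row per
#' non-missing (cow, age, trait) cell, each mapped to its cow, its
#' herd-year-season level (herd x birth year x season), its year-season
#' fixed regression level, its embryo-transfer indicator, and its residual
#' class. Covariate rows are the Legendre covariates of the observation's
#' age placed in the trait's coefficient block.
#'
#' @param panels a `longevity_panel`, a long tibble with `cow_id`, `age`
#'   and `value` (or `code` / `y`) columns, or a named list of such
#'   objects, one per trait.
#' @param records cow metadata tibble: `cow_id`, `herd_id`,
#'   `birth_year_season`, `embryo_transfer` (and `birth_date` if the
#'   year-season label must be derived).
#' @param spec an [rrm_spec()].
#' @return An `rrm_design` list; its `n_obs`, `traits` and level tables are
#'   user-visible, the index vectors feed [gibbs_fit()].
#' @export
build_design <- function(panels, records, spec = rrm_spec()) {
  stopifnot(inherits(spec, "rrm_spec"))
  records <- tibble::as_tibble(records)
  if (!"birth_year_season" %in% names(records)) {
    records$birth_year_season <- birth_year_season(records$birth_date)
  }
  if (!"embryo_transfer" %in% names(records)) {
    records$embryo_transfer <- FALSE
  }
  if (!is.list(panels) || inherits(panels, c("longevity_panel",
                                             "data.frame"))) {
    panels <- list(trait1 = panels)
  }
  if (is.null(names(panels)) || any(names(panels) == "")) {
    names(panels) <- paste0("trait", seq_along(panels))
  }
  traits <- names(panels)
  long <- purrr::imap(panels, function(x, nm) {
    out <- panel_values(x)
    out$trait <- nm
    out
  }) |> dplyr::bind_rows()
  long <- long[!is.na(long$value), , drop = FALSE]
  if (!nrow(long)) stop("no non-missing observations")

  meta_cols <- c("cow_id", "herd_id", "birth_year_season", "embryo_transfer")
  missing_meta <- setdiff(unique(long$cow_id), records$cow_id)
  if (length(missing_meta)) {
    stop("cow(s) without metadata records: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  long <- dplyr::left_join(long, records[, meta_cols], by = "cow_id")
  if (anyNA(long$herd_id)) {
    stop("cow(s) without a herd-year-season label: ",
         paste(utils::head(unique(long$cow_id[is.na(long$herd_id)]), 5),
               collapse = ", "))
  }
  long$hys <- paste0(long$herd_id, "_", long$birth_year_season)
  long$trait_i <- match(long$trait, traits)
  ages <- age_grid()
  long$age_i <- match(long$age, ages)
  if (anyNA(long$age_i)) stop("observation age outside the 2-15 grid")

  T1 <- legendre_T(spec$order)
  k1 <- ncol(T1)
  n_traits <- length(traits)
  Tobs <- matrix(0, nrow(long), k1 * n_traits)
  for (t in seq_len(n_traits)) {
    rows <- which(long$trait_i == t)
    Tobs[rows, (t - 1) * k1 + seq_len(k1)] <- T1[long$age_i[rows], ,
                                                 drop = FALSE]
  }

  hys_levels <- sort(unique(long$hys))
  ys_levels <- sort(unique(long$birth_year_season))
  n_age <- length(ages)
  if (spec$residual_structure == "heterogeneous_by_age") {
    class_i <- (long$trait_i - 1L) * n_age + long$age_i
    class_labels <- paste0(rep(traits, each = n_age), "_age",
                           rep(ages, times = n_traits))
  } else {
    class_i <- long$trait_i
    class_labels <- traits
  }

  structure(list(
    y = as.numeric(long$value),
    Tobs = Tobs,
    cow_id = long$cow_id,
    hys_i = match(long$hys, hys_levels),
    ys_i = match(long$birth_year_season, ys_levels),
    trait_i = long$trait_i,
    et = as.numeric(long$embryo_transfer),
    class_i = as.integer(class_i),
    hys_levels = hys_levels, ys_levels = ys_levels,
    class_labels = class_labels,
    traits = traits, n_obs = nrow(long),
    T = T1, T_multi = expand_multitrait(T1, n_traits),
    spec = spec
  ), class = "rrm_design")
}

#' @export
print.rrm_design <- function(x, ...) {
  cat("<rrm_design>", x$n_obs, "observations,", length(unique(x$cow_id)),
      "cows,", length(x$traits), "trait(s), order", x$spec$order, "\n")
  invisible(x)
}

#' Fit the random regression animal model by Gibbs sampling
#'
#' Samples all location effects block-by-block from their Gaussian full
#' conditionals (the additive block uses \eqn{G_0^{-1} \otimes A^{-1}}),
#' the coefficient covariance matrices from inverted-Wishart conditionals,
#' and each residual class variance from its scaled inverse chi-square
#' conditional. The conditional Gaussian deviance is recorded at every
#' retained cycle for DIC computation.
#'
#' @param design an [build_design()] result.
#' @param pedigree pedigree tibble covering (at least) all cows with
#'   records; pruned/sorted internally and used to build the sparse
#'   A-inverse.
#' @param chain a [chain_config()].
#' @param fix_variances keep all (co)variance components at their
#'   starting values and sample only location effects (used for
#'   generalized least-squares cross-checks).
#' @param fix_covariances keep only the coefficient covariance matrices
#'   fixed while the residual classes are still sampled (used for
#'   conjugate closed-form cross-checks).
#' @param start optional named list of starting values (`G0`, `Rq`, `Rp`,
#'   `sigma2`); defaults are the prior scales.
#' @return An `rrm_fit` object: retained draws of `G0`, `Rq`, `Rp`,
#'   residual variances and the embryo-transfer contrast; posterior means
#'   of all location effects; the deviance trace and deviance at the
#'   posterior means; and the design/chain metadata.
#' @export
gibbs_fit <- function(design, pedigree, chain = chain_config(),
                      fix_variances = FALSE, fix_covariances = FALSE,
                      start = NULL) {
  stopifnot(inherits(design, "rrm_design"), inherits(chain, "chain_config"))
  ped <- sort_pedigree(pedigree)
  cows <- unique(design$cow_id)
  missing_cows <- setdiff(cows, ped$animal)
  if (length(missing_cows)) {
    stop("cow(s) with records missing from pedigree: ",
         paste(utils::head(missing_cows, 5), collapse = ", "))
  }
  Ainv <- build_A_inverse(ped)
  Ainv_gen <- methods::as(Ainv, "generalMatrix")
  cow_i <- match(design$cow_id, ped$animal)

  spec <- design$spec
  k <- ncol(design$Tobs)
  varP <- stats::var(design$y)
  # basis-scaled identity: mean_j t_j' (c I) t_j = share * varP
  basis_scale <- mean(rowSums(design$T^2))
  Vmat <- function(share) diag(share * varP / basis_scale, k)
  Vq <- Vmat(spec$prior_shares["q"])
  Vg <- Vmat(spec$prior_shares["a"])
  Vp <- Vmat(spec$prior_shares["p"])
  n_class <- length(design$class_labels)
  s2e_prior <- rep(spec$residual_share * varP, n_class)

  start <- start %||% list()
  G0_init <- start$G0 %||% Vg
  Rq_init <- start$Rq %||% Vq
  Rp_init <- start$Rp %||% Vp
  sigma2_init <- start$sigma2 %||% s2e_prior
  if (length(sigma2_init) == 1) sigma2_init <- rep(sigma2_init, n_class)

  res <- gibbs_rrm(
    y = design$y, Tobs = design$Tobs,
    obs_cow = cow_i - 1L, obs_hys = design$hys_i - 1L,
    obs_ys = design$ys_i - 1L, obs_trait = design$trait_i - 1L,
    obs_et = design$et, obs_class = design$class_i - 1L,
    Ainv = Ainv_gen, n_traits = length(design$traits),
    Vq = Vq, Vg = Vg, Vp = Vp,
    nu = spec$nu, nu_e = spec$nu_e, s2e_prior = s2e_prior,
    sigma_b = spec$sigma_b,
    n_iter = chain$length, burn_in = chain$burn_in, thin = chain$thin,
    seed = chain$seed,
    fix_covariances = fix_variances || fix_covariances,
    fix_residual = fix_variances,
    G0_init = G0_init, Rq_init = Rq_init, Rp_init = Rp_init,
    sigma2_init = sigma2_init
  )
  dimnames(res$sigma2) <- list(NULL, design$class_labels)
  rownames(res$a_mean) <- ped$animal
  rownames(res$p_mean) <- ped$animal
  rownames(res$q_mean) <- design$hys_levels
  rownames(res$b_ys_mean) <- design$ys_levels

  structure(list(
    draws = list(G0 = res$G0, Rq = res$Rq, Rp = res$Rp,
                 sigma2 = res$sigma2, b_et = res$b_et, b_ys = res$b_ys,
                 deviance = as.numeric(res$deviance)),
    means = list(G0 = (res$G0_mean + t(res$G0_mean)) / 2,
                 Rq = (res$Rq_mean + t(res$Rq_mean)) / 2,
                 Rp = (res$Rp_mean + t(res$Rp_mean)) / 2,
                 sigma2 = stats::setNames(as.numeric(res$sigma2_mean),
                                          design$class_labels),
                 a = res$a_mean, p = res$p_mean, q = res$q_mean,
                 b_ys = res$b_ys_mean,
                 b_et = as.numeric(res$b_et_mean)),
    D_at_mean = res$D_at_mean,
    n_retained = res$n_retained,
    design = design, chain = chain, pedigree = ped,
    fix_variances = fix_variances
  ), class = "rrm_fit")
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat("<rrm_fit>", length(x$design$traits), "trait(s), order",
      x$design$spec$order, "-", x$n_retained, "retained draws\n")
  cat("  residual structure:", x$design$spec$residual_structure, "\n")
  invisible(x)
}

#' Posterior summaries of the variance components
#'
#' Elementwise posterior means and equal-tail 95% credible intervals for
#' every coefficient covariance element and residual class variance.
#' Covariance means are re-symmetrized.
#'
#' @param fit an `rrm_fit`.
#' @param level credible-interval mass (default 0.95).
#' @return Tibble with `block`, `row`, `col`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rrm_fit"))
  if (fit$n_retained < 2) stop("need at least 2 retained draws")
  al <- (1 - level) / 2
  summarize_cube <- function(cube, block) {
    k <- dim(cube)[1]
    purrr::map_dfr(seq_len(k), function(i) {
      purrr::map_dfr(seq_len(k), function(j) {
        x <- (cube[i, j, ] + cube[j, i, ]) / 2
        tibble::tibble(block = block, row = i, col = j, mean = mean(x),
                       lower = stats::quantile(x, al, names = FALSE),
                       upper = stats::quantile(x, 1 - al, names = FALSE))
      })
    })
  }
  res <- dplyr::bind_rows(
    summarize_cube(fit$draws$G0, "G0"),
    summarize_cube(fit$draws$Rq, "Rq"),
    summarize_cube(fit$draws$Rp, "Rp")
  )
  sig <- fit$draws$sigma2
  res_sig <- purrr::map_dfr(seq_len(ncol(sig)), function(j) {
    tibble::tibble(block = "sigma2_e", row = j, col = j,
                   mean = mean(sig[, j]),
                   lower = stats::quantile(sig[, j], al, names = FALSE),
                   upper = stats::quantile(sig[, j], 1 - al, names = FALSE))
  })
  dplyr::bind_rows(res, res_sig)
}

#' @rdname posterior_summary
#' @param x an `rrm_fit`.
#' @param ... unused.
#' @method tidy rrm_fit
#' @export
tidy.rrm_fit <- function(x, ...) posterior_summary(x, ...)

#' One-row model overview
#'
#' @param x an `rrm_fit`.
#' @param ... unused.
#' @return Tibble with observation counts, DIC components and chain info.
#' @method glance rrm_fit
#' @export
glance.rrm_fit <- function(x, ...) {
  sc <- dic(x)
  tibble::tibble(
    n_obs = x$design$n_obs,
    n_cows = length(unique(x$design$cow_id)),
    n_traits = length(x$design$traits),
    order = x$design$spec$order,
    residual_structure = x$design$spec$residual_structure,
    n_retained = x$n_retained,
    D_bar = sc$D_bar, D_at_mean = sc$D_at_mean, pD = sc$pD, DIC = sc$DIC
  )
}
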