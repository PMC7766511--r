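#' Simulation configuration for synthetic longevity data
#'
#' Defines the data-generating conditions for a pedigreed cattle population
#' with random-regression structure: per-animal additive (`true_G0`) and
#' permanent-environment (`true_Rp`) coefficient covariances, a
#' herd-year-season coefficient covariance (`true_Rq`), and residual
#' variances per yearly age class. Additive coefficients are correlated
#' through the pedigree (founder draws plus Mendelian sampling), so
#' `Var(a) = true_G0 (x) A` by construction.
#'
#' Defaults emulate a small beef-cattle evaluation: a quadratic (LEG2)
#' coefficient basis, moderate heritability, and the culling-reason mix
#' observed in large North American Angus data (about 25% natural death,
#' 4% structural, 1% disease, 26% fertility, 10% performance, 34%
#' miscellaneous).
#'
#' @param n_founders number of founder animals (alternating sex).
#' @param n_generations number of descendant generations.
#' @param offspring_per_mating offspring per mating.
#' @param n_herds number of herds; females are assigned a herd at random.
#' @param sire_ratio proportion of available males actually used as sires
#'   (bulls serve many cows; default 0.2).
#' @param years span of birth years (founders at the start).
#' @param seasons_per_year calving/birth seasons per year (2: Jan–Jun,
#'   Jul–Dec).
#' @param true_G0,true_Rp,true_Rq symmetric PSD coefficient covariance
#'   matrices of equal dimension (Legendre order + 1).
#' @param true_residual residual variance: scalar or vector of 14 age-class
#'   variances.
#' @param mode `"binary"` emits culling/calving events through a latent
#'   threshold; `"gaussian"` emits the continuous latent response directly
#'   (used for exact parameter-recovery checks).
#' @param culling_reason_probs probability over the six specific
#'   culling-reason groups (must sum to 1).
#' @param cull_threshold latent value below which the cow is culled that
#'   year (binary mode).
#' @param b_et true embryo-transfer contrast; `et_prob` the proportion of
#'   ET-born cows.
#' @param et_prob see `b_et`.
#' @param ys_sd standard deviation of the true year-season fixed regression
#'   coefficients.
#' @param reason_coupling in \[0, 1\]: probability that a cow's culling
#'   reason is dictated by the rank of her additive level rather than drawn
#'   independently.
#' @param seed integer seed; fully determines all simulator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 40,
                       n_generations = 3,
                       offspring_per_mating = 2,
                       n_herds = 5,
                       sire_ratio = 0.2,
                       years = c(1990, 2005),
                       seasons_per_year = 2,
                       true_G0 = diag(0.25, 3),
                       true_Rp = diag(0.25, 3),
                       true_Rq = diag(0.10, 3),
                       true_residual = 0.4,
                       mode = c("binary", "gaussian"),
                       culling_reason_probs = c(
                         natural_death = 0.25, structural_problems = 0.04,
                         disease = 0.01, fertility = 0.26,
                         performance = 0.10, miscellaneous = 0.34),
                       cull_threshold = -1.0,
                       b_et = 0.2,
                       et_prob = 0.05,
                       ys_sd = 0.1,
                       reason_coupling = 0,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1,
            n_herds >= 1, length(years) == 2, years[2] >= years[1],
            sire_ratio > 0, sire_ratio <= 1)
  for (nm in c("true_G0", "true_Rp", "true_Rq")) {
    M <- get(nm)
    if (!isSymmetric(unname(M), tol = 1e-8)) {
      stop(nm, " must be symmetric")
    }
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop(nm, " is not positive semi-definite")
    }
  }
  k <- nrow(true_G0)
  stopifnot(nrow(true_Rp) == k, nrow(true_Rq) == k)
  if (!length(true_residual) %in% c(1L, 14L) || any(true_residual < 0)) {
    stop("true_residual must be a non-negative scalar or vector of 14")
  }
  if (abs(sum(culling_reason_probs) - 1) > 1e-12) {
    stop("culling_reason_probs must sum to 1")
  }
  structure(
    list(n_founders = n_founders, n_generations = n_generations,
         offspring_per_mating = offspring_per_mating, n_herds = n_herds,
         sire_ratio = sire_ratio,
         years = years, seasons_per_year = seasons_per_year,
         true_G0 = true_G0, true_Rp = true_Rp, true_Rq = true_Rq,
         true_residual = true_residual, mode = mode,
         culling_reason_probs = culling_reason_probs,
         cull_threshold = cull_threshold, b_et = b_et, et_prob = et_prob,
         ys_sd = ys_sd, reason_coupling = reason_coupling,
         order = k - 1L, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a multi-generation pedigree
#'
#' Founders alternate sex. At each generation every female born in an
#' earlier generation is mated once to one of the service sires (the first
#' `sire_ratio` share of available males, cycled) and produces
#' `offspring_per_mating` offspring of alternating sex.
#' The result is topologically ordered; the mating structure is
#' deterministic given the configuration, while herd assignment of females
#' is seeded.
#'
#' @param cfg a [sim_config()].
#' @return Pedigree tibble with columns `animal`, `sire`, `dam`, `sex`,
#'   `generation`, `birth_year`, `birth_season` and `herd_id` (females).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gen_gap <- max(1, floor(diff(cfg$years) / max(1, cfg$n_generations)))
  make_rows <- function(ids, sire, dam, gen) {
    tibble::tibble(
      animal = ids, sire = sire, dam = dam,
      sex = rep_len(c("M", "F"), length(ids)),
      generation = gen,
      birth_year = min(cfg$years[1] + gen * gen_gap, cfg$years[2]),
      birth_season = rep_len(paste0("S", seq_len(cfg$seasons_per_year)),
                             length(ids))
    )
  }
  ped <- make_rows(sprintf("A%05d", seq_len(cfg$n_founders)),
                   NA_character_, NA_character_, 0L)
  next_id <- cfg$n_founders + 1L
  for (g in seq_len(cfg$n_generations)) {
    males <- ped$animal[ped$sex == "M"]
    females <- ped$animal[ped$sex == "F"]
    if (!length(males) || !length(females)) {
      stop("infeasible mating structure: generation ", g,
           " has a single sex available")
    }
    in_service <- males[seq_len(max(1, ceiling(length(males) *
                                                 cfg$sire_ratio)))]
    sires <- rep_len(in_service, length(females))
    ids <- sprintf("A%05d",
                   seq(next_id,
                       length.out = length(females) * cfg$offspring_per_mating))
    next_id <- next_id + length(ids)
    ped <- dplyr::bind_rows(
      ped,
      make_rows(ids,
                rep(sires, each = cfg$offspring_per_mating),
                rep(females, each = cfg$offspring_per_mating), g)
    )
  }
  ped$herd_id <- ifelse(ped$sex == "F",
                        paste0("H", sample.int(cfg$n_herds, nrow(ped),
                                               replace = TRUE)),
                        NA_character_)
  ped
}

matrix_sqrt <- function(M, name = "covariance") {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop(name, " is not positive semi-definite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
}

#' Simulate true breeding values and environmental effects
#'
#' Draws founder additive coefficient vectors from `N(0, true_G0)` and
#' non-founder vectors as the parent average plus a Mendelian-sampling
#' deviation with covariance \eqn{(0.5 - 0.25 (F_s + F_d))\,G_0}, so the
#' additive coefficients have covariance `true_G0 (x) A`. Permanent
#' environmental vectors are iid `N(0, true_Rp)` per animal and
#' herd-year-season vectors iid `N(0, true_Rq)` per level.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param cfg the [sim_config()].
#' @return List with matrices `a` (animals x k), `p` (animals x k), `q`
#'   (herd-year-season levels x k), fixed effects (`b_et`, `ys`: levels x k)
#'   and the inbreeding vector `F`.
#' @export
simulate_true_values <- function(ped, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ped <- sort_pedigree(ped)
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  k <- cfg$order + 1L
  F <- inbreeding_coefficients(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  L0 <- matrix_sqrt(cfg$true_G0, "true_G0")
  a <- matrix(0, n, k, dimnames = list(ped$animal, NULL))
  z <- matrix(stats::rnorm(n * k), n, k)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      a[i, ] <- L0 %*% z[i, ]
    } else {
      pa <- 0.5 * ((if (!is.na(s)) a[s, ] else 0) +
                   (if (!is.na(d)) a[d, ] else 0))
      Fs <- if (!is.na(s)) F[s] else -1
      Fd <- if (!is.na(d)) F[d] else -1
      mend <- 0.5 - 0.25 * (Fs + Fd)
      a[i, ] <- pa + sqrt(mend) * (L0 %*% z[i, ])
    }
  }
  p <- matrix(stats::rnorm(n * k), n, k) %*% t(matrix_sqrt(cfg$true_Rp, "true_Rp"))
  rownames(p) <- ped$animal
  # herd-year-season levels for all females (the cows that can get records)
  fem <- ped[ped$sex == "F", , drop = FALSE]
  hys_levels <- sort(unique(paste0(fem$herd_id, "_", fem$birth_year, "_",
                                   fem$birth_season)))
  q <- matrix(stats::rnorm(length(hys_levels) * k), length(hys_levels), k) %*%
    t(matrix_sqrt(cfg$true_Rq, "true_Rq"))
  rownames(q) <- hys_levels
  ys_levels <- sort(unique(paste0(fem$birth_year, "_", fem$birth_season)))
  ys <- matrix(stats::rnorm(length(ys_levels) * k, sd = cfg$ys_sd),
               length(ys_levels), k)
  rownames(ys) <- ys_levels
  list(a = a, p = p, q = q, b_et = cfg$b_et, ys = ys, F = F, ped = ped)
}

#' Simulate cow life histories
#'
#' For every female, a latent response is generated at each age of the
#' grid: \eqn{y_{ij} = x_{ij}'b + t_j'q_h + t_j'a_i + t_j'p_i + e_{ij}}.
#' In `gaussian` mode the latent values are returned directly (the exact
#' linear-model data used for parameter-recovery checks). In `binary` mode
#' the cow is culled at the first age whose latent value falls below
#' `cfg$cull_threshold` (culling age uniform within that year), a culling
#' reason is drawn from `culling_reason_probs`, the first calving age is
#' uniform on 19–30 months, and later calvings occur at alive ages with
#' probability `plogis(1.5 + y)`.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param tv true values from [simulate_true_values()].
#' @param cfg the [sim_config()].
#' @param inject_qc_violations also emit a handful of records violating the
#'   quality-control rules (pre-1990 births, out-of-window first calvings),
#'   to exercise QC.
#' @return A `life_histories` list: `records` (life-history tibble, see
#'   [life_history]), `responses` (long tibble `cow_id`, `age`, `y`;
#'   gaussian mode only) and `mode`.
#' @export
simulate_life_histories <- function(ped, tv, cfg,
                                    inject_qc_violations = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  ped <- tv$ped
  ages <- age_grid()
  T <- legendre_T(cfg$order)
  fem <- ped[ped$sex == "F", , drop = FALSE]
  n <- nrow(fem)
  if (!n) stop("no females in the pedigree")
  hys <- paste0(fem$herd_id, "_", fem$birth_year, "_", fem$birth_season)
  ysl <- paste0(fem$birth_year, "_", fem$birth_season)
  et <- stats::runif(n) < cfg$et_prob
  sig_e <- if (length(cfg$true_residual) == 1) {
    rep(cfg$true_residual, length(ages))
  } else cfg$true_residual
  # latent responses, cows x ages
  curve <- (tv$a[fem$animal, , drop = FALSE] +
            tv$p[fem$animal, , drop = FALSE] +
            tv$q[hys, , drop = FALSE]) %*% t(T)
  fixed <- et * cfg$b_et + tv$ys[ysl, , drop = FALSE] %*% t(T)
  e <- matrix(stats::rnorm(n * length(ages)), n, length(ages)) %*%
    diag(sqrt(sig_e), length(ages))
  y <- curve + fixed + e
  dimnames(y) <- list(fem$animal, ages)

  birth_date <- as.Date(paste0(
    fem$birth_year, ifelse(fem$birth_season == "S1", "-03-15", "-09-15")))
  base <- tibble::tibble(
    cow_id = fem$animal, sire_id = fem$sire, herd_id = fem$herd_id,
    birth_date = birth_date, embryo_transfer = et,
    birth_year_season = paste0(fem$birth_year, "_", fem$birth_season)
  )

  if (cfg$mode == "gaussian") {
    responses <- tibble::tibble(
      cow_id = rep(fem$animal, each = length(ages)),
      age = rep(ages, times = n),
      y = as.numeric(t(y))
    )
    records <- base
    return(structure(list(records = records, responses = responses,
                          mode = "gaussian"),
                     class = "life_histories"))
  }

  below <- y < cfg$cull_threshold
  first_cull <- apply(below, 1, function(r) {
    w <- which(r)
    if (length(w)) ages[w[1]] else max(ages)
  })
  culling_age <- unname(first_cull) + stats::runif(n)
  # drawn within the 19-29 month range so the first calving always maps to
  # the age-2 slot and never postdates an age-2 culling
  first_calving <- round(stats::runif(n, 19, 29.4))
  reason_codes <- list(
    natural_death = "died_unknown", structural_problems = "feet_conformation",
    disease = "illness_disease", fertility = "fertility",
    performance = "productivity", miscellaneous = "miscellaneous")
  groups <- names(cfg$culling_reason_probs)
  drawn <- sample(groups, n, replace = TRUE, prob = cfg$culling_reason_probs)
  if (cfg$reason_coupling > 0) {
    # couple the reason to the rank of the cow's mean additive level
    couple <- stats::runif(n) < cfg$reason_coupling
    rk <- rank(rowMeans(tv$a[fem$animal, , drop = FALSE] %*% t(T)),
               ties.method = "first")
    cut <- cumsum(cfg$culling_reason_probs)
    drawn[couple] <- groups[findInterval(rk[couple] / (n + 1), c(0, cut),
                                         rightmost.closed = TRUE)]
  }
  reason <- unlist(reason_codes[drawn], use.names = FALSE)

  calv_prob <- stats::plogis(1.5 + y)
  calvings <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- first_calving[i]
    for (j in ages[-1]) {
      if (j > floor(culling_age[i])) break
      if (stats::runif(1) < calv_prob[i, as.character(j)]) {
        ca <- c(ca, 12L * j + sample(-2:2, 1))
      }
    }
    calvings[[i]] <- sort(unique(ca))
  }
  records <- base
  records$first_calving_age <- first_calving
  records$calving_ages <- calvings
  records$culling_age <- culling_age
  records$culling_reason <- reason

  if (inject_qc_violations) {
    bad <- records[seq_len(min(3, nrow(records))), ]
    bad$cow_id <- paste0(bad$cow_id, "_qc")
    bad$birth_date <- as.Date("1985-05-01")
    bad2 <- records[seq_len(min(2, nrow(records))), ]
    bad2$cow_id <- paste0(bad2$cow_id, "_fc")
    bad2$first_calving_age <- 35
    records <- dplyr::bind_rows(records, bad, bad2)
  }
  structure(list(records = records, responses = NULL, mode = "binary"),
            class = "life_histories")
}

#' Write simulated pedigree and records as delimited text
#'
#' @param ped pedigree tibble.
#' @param lh `life_histories` object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(ped, lh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE)
  rec <- lh$records
  if ("calving_ages" %in% names(rec)) {
    rec$calving_ages <- vapply(rec$calving_ages, paste, character(1),
                               collapse = ";")
  }
  utils::write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(lh$responses)) {
    utils::write.csv(lh$responses, file.path(dir, "responses.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read life-history records written by [write_simulation()]
#'
#' @param path records.csv path.
#' @return Life-history tibble with a parsed `calving_ages` list-column.
#' @export
read_life_histories <- function(path) {
  rec <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  rec$birth_date <- as.Date(rec$birth_date)
  if ("calving_ages" %in% names(rec)) {
    rec$calving_ages <- lapply(strsplit(as.character(rec$calving_ages), ";"),
                               as.numeric)
  }
  rec
}
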