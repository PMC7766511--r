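test_that("smallest trio pedigree and determinism", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    offspring_per_mating = 1, seed = 9)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3)
  expect_setequal(c(ped$sire[3], ped$dam[3]), ped$animal[1:2])
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
})

test_that("generation sizes match direct enumeration of the mating rule", {
  cfg <- sim_config(n_founders = 20, n_generations = 3,
                    offspring_per_mating = 2, seed = 1)
  ped <- simulate_pedigree(cfg)
  # oracle: every female born so far is mated once per generation,
  # each mating yields offspring_per_mating calves of alternating sex
  sizes <- 20
  females <- 10
  for (g in 1:3) {
    born <- females * 2
    sizes <- c(sizes, born)
    females <- females + born / 2
  }
  expect_equal(unname(table(ped$generation)), sizes, ignore_attr = TRUE)
  expect_equal(sizes, c(20, 20, 40, 80))
})

test_that("degenerate and Monte-Carlo checks on true values", {
  cfg0 <- sim_config(n_founders = 10, n_generations = 1,
                     true_G0 = matrix(0, 3, 3), seed = 2)
  ped0 <- simulate_pedigree(cfg0)
  tv0 <- simulate_true_values(ped0, cfg0)
  expect_true(all(tv0$a == 0))

  # founder draws have the configured covariance
  cfgI <- sim_config(n_founders = 5000, n_generations = 1,
                     true_G0 = diag(3), seed = 3)
  pedI <- simulate_pedigree(cfgI)
  tvI <- simulate_true_values(pedI, cfgI)
  founders <- pedI$animal[pedI$generation == 0]
  S <- stats::cov(tvI$a[founders, ])
  expect_lt(max(abs(S - diag(3))), 0.1)

  # non-PSD covariance is rejected by name
  bad <- diag(3); bad[1, 1] <- -1
  expect_error(sim_config(n_founders = 4, true_G0 = bad),
               "true_G0")
})

test_that("full-sib coefficient correlation is about one half", {
  # 1500 independent full-sib pairs from unrelated parents
  n_fam <- 1500
  ped <- tibble::tibble(
    animal = c(sprintf("s%04d", 1:n_fam), sprintf("d%04d", 1:n_fam),
               sprintf("x%04d", 1:n_fam), sprintf("y%04d", 1:n_fam)),
    sire = c(rep(NA, 2 * n_fam), sprintf("s%04d", 1:n_fam),
             sprintf("s%04d", 1:n_fam)),
    dam = c(rep(NA, 2 * n_fam), sprintf("d%04d", 1:n_fam),
            sprintf("d%04d", 1:n_fam)),
    sex = "F", herd_id = "H1", birth_year = 1995, birth_season = "S1"
  )
  cfg <- sim_config(n_founders = 4, true_G0 = diag(1, 3), seed = 11)
  tv <- simulate_true_values(ped, cfg)
  r <- stats::cor(tv$a[sprintf("x%04d", 1:n_fam), 1],
                  tv$a[sprintf("y%04d", 1:n_fam), 1])
  expect_equal(r, 0.5, tolerance = 0.15)
})

test_that("culling threshold limits behave as expected", {
  cfg_lo <- sim_config(n_founders = 30, n_generations = 1,
                       cull_threshold = -Inf, seed = 4)
  ped <- simulate_pedigree(cfg_lo)
  tv <- simulate_true_values(ped, cfg_lo)
  lh <- simulate_life_histories(ped, tv, cfg_lo)
  expect_true(all(lh$records$culling_age >= 15))

  cfg_hi <- sim_config(n_founders = 30, n_generations = 1,
                       cull_threshold = Inf, seed = 4)
  tv2 <- simulate_true_values(ped, cfg_hi)
  lh2 <- simulate_life_histories(ped, tv2, cfg_hi)
  expect_true(all(floor(lh2$records$culling_age) == 2))
})

test_that("noise-free constant basis returns the additive level exactly", {
  cfg <- sim_config(n_founders = 20, n_generations = 1,
                    true_G0 = diag(1, 1), true_Rp = diag(0, 1),
                    true_Rq = diag(0, 1), true_residual = 0,
                    ys_sd = 0, et_prob = 0, mode = "gaussian", seed = 6)
  ped <- simulate_pedigree(cfg)
  tv <- simulate_true_values(ped, cfg)
  lh <- simulate_life_histories(ped, tv, cfg)
  wide <- tidyr::pivot_wider(lh$responses, names_from = "age",
                             values_from = "y")
  y <- as.matrix(wide[, -1])
  expect_equal(apply(y, 1, stats::sd), rep(0, nrow(y)), tolerance = 1e-12)
  expect_equal(unname(y[, 1]),
               unname(tv$a[wide$cow_id, 1] * sqrt(1 / 2)),
               tolerance = 1e-12)
})

test_that("simulated age-wise variance matches the model arithmetic", {
  cfg <- constant_h2_config(n_founders = 3000, seed = 8)
  ped <- simulate_pedigree(cfg)
  tv <- simulate_true_values(ped, cfg)
  lh <- simulate_life_histories(ped, tv, cfg)
  Tm <- legendre_T(cfg$order)
  Ctot <- cfg$true_G0 + cfg$true_Rp + cfg$true_Rq
  expected <- diag(Tm %*% Ctot %*% t(Tm)) + cfg$true_residual
  observed <- lh$responses |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(v = stats::var(.data$y)) |>
    dplyr::pull(.data$v)
  # herd-year-season truth is shared within herd, inflating the naive
  # Monte-Carlo error; accept 15% relative deviation
  expect_lt(max(abs(observed - expected) / expected), 0.15)
})

test_that("binary panels stay within the code alphabet, 14 slots per cow", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, seed = 10)
  ped <- simulate_pedigree(cfg)
  tv <- simulate_true_values(ped, cfg)
  lh <- simulate_life_histories(ped, tv, cfg, inject_qc_violations = TRUE)
  qc <- apply_quality_control(lh$records)
  expect_gt(sum(qc$report$n[qc$report$rule %in%
                              c("birth_year", "first_calving_age")]), 0)
  panel <- build_longevity_panel(qc$records, "FLb")
  expect_equal(ncol(panel$codes), 14)
  expect_true(all(panel$codes %in% c(0L, 1L, NA_integer_)))
  long <- tidy(panel)
  expect_equal(nrow(long), nrow(qc$records) * 14)
})

test_that("life histories are reproducible and writable", {
  cfg <- sim_config(n_founders = 16, n_generations = 1, seed = 12)
  ped <- simulate_pedigree(cfg)
  tv <- simulate_true_values(ped, cfg)
  lh1 <- simulate_life_histories(ped, tv, cfg)
  lh2 <- simulate_life_histories(ped, tv, cfg)
  expect_identical(lh1$records, lh2$records)
  dir <- withr::local_tempdir()
  write_simulation(ped, lh1, dir)
  back <- read_life_histories(file.path(dir, "records.csv"))
  expect_equal(back$culling_age, lh1$records$culling_age)
  expect_equal(back$calving_ages, lh1$records$calving_ages)
})
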