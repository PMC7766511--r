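small_sim <- function(seed = 21, mode = "gaussian", n_founders = 40) {
  cfg <- sim_config(n_founders = n_founders, n_generations = 1, seed = seed,
                    mode = mode)
  ped <- simulate_pedigree(cfg)
  tv <- simulate_true_values(ped, cfg)
  lh <- simulate_life_histories(ped, tv, cfg)
  list(cfg = cfg, ped = ped, tv = tv, lh = lh)
}

test_that("design construction counts observations and covariates", {
  recs <- dplyr::bind_rows(make_record("c1", 8, c(24, 36)),
                           make_record("c2", 5, 24),
                           make_record("c3", 12, c(24, 48, 60)))
  spec <- rrm_spec(order = 4, residual_structure = "homogeneous")
  tl <- build_longevity_panel(recs, "TL")
  des <- build_design(tl, recs, spec)
  expect_equal(des$n_obs, 42)  # 3 cows x 14 ages
  expect_true(all(rowSums(des$Tobs != 0) == 5))

  flb <- build_longevity_panel(recs, "FLb")
  n_missing <- sum(is.na(flb$codes))
  des_b <- build_design(flb, recs, spec)
  expect_equal(des_b$n_obs, 42 - n_missing)
  expect_gt(n_missing, 0)

  # heterogeneous residual structure indexes one class per age
  des_h <- build_design(tl, recs, rrm_spec(order = 2))
  expect_equal(length(des_h$class_labels), 14)
  expect_equal(unname(table(des_h$class_i)), rep(3L, 14), ignore_attr = TRUE)
})

test_that("multi-trait design places covariates in the trait block", {
  recs <- dplyr::bind_rows(make_record("c1", 8, c(24, 36)),
                           make_record("c2", 5, 24))
  spec <- rrm_spec(order = 2, residual_structure = "homogeneous")
  des <- build_design(list(TL = build_longevity_panel(recs, "TL"),
                           FLa = build_longevity_panel(recs, "FLa")),
                      recs, spec)
  expect_equal(des$n_obs, 56)
  expect_equal(ncol(des$Tobs), 6)
  t1 <- des$trait_i == 1
  expect_true(all(des$Tobs[t1, 4:6] == 0))
  expect_true(all(des$Tobs[!t1, 1:3] == 0))
  expect_equal(length(des$class_labels), 2)
})

test_that("same seed reproduces retained draws exactly", {
  s <- small_sim()
  des <- build_design(s$lh$responses, s$lh$records,
                      rrm_spec(order = 2, residual_structure = "homogeneous"))
  ch <- chain_config(length = 600, burn_in = 300, thin = 3, seed = 5)
  f1 <- gibbs_fit(des, s$ped, ch)
  f2 <- gibbs_fit(des, s$ped, ch)
  expect_identical(f1$draws, f2$draws)
  expect_equal(f1$n_retained, 100)
})

test_that("chain configuration is validated before any computation", {
  expect_error(chain_config(length = 100, burn_in = 100), "burn_in")
  expect_error(chain_config(thin = 0), "thin")
})

test_that("fixed-variance posterior means solve the mixed-model equations", {
  s <- small_sim(seed = 31)
  spec <- rrm_spec(order = 2, residual_structure = "homogeneous")
  des <- build_design(s$lh$responses, s$lh$records, spec)
  start <- list(G0 = s$cfg$true_G0, Rq = s$cfg$true_Rq,
                Rp = s$cfg$true_Rp, sigma2 = s$cfg$true_residual)
  fit <- gibbs_fit(des, s$ped, chain_config(length = 6000, burn_in = 1000,
                                            thin = 1, seed = 7),
                   fix_variances = TRUE, start = start)

  # oracle: direct sparse solve of the MME at the same fixed variances
  gls <- mme_solve(des, fit$pedigree, start)

  # compare the fixed effects within Monte-Carlo error (spectral SEs)
  draws_ys <- fit$draws$b_ys
  for (j in seq_len(ncol(draws_ys))) {
    se <- sqrt(herdlife:::spectrum0_ar(draws_ys[, j]) / nrow(draws_ys))
    expect_lt(abs(mean(draws_ys[, j]) - gls$ys[j]), 3 * se + 1e-8)
  }
  se_et <- sqrt(herdlife:::spectrum0_ar(fit$draws$b_et[, 1]) /
                  nrow(fit$draws$b_et))
  expect_lt(abs(mean(fit$draws$b_et[, 1]) - gls$et), 3 * se_et + 1e-8)
})

test_that("posterior summaries behave on constant and two-draw chains", {
  s <- small_sim(seed = 41, n_founders = 20)
  des <- build_design(s$lh$responses, s$lh$records,
                      rrm_spec(order = 2, residual_structure = "homogeneous"))
  fit <- gibbs_fit(des, s$ped, chain_config(length = 300, burn_in = 100,
                                            thin = 2, seed = 3))
  ps <- posterior_summary(fit)
  expect_true(all(c("G0", "Rq", "Rp", "sigma2_e") %in% ps$block))
  expect_true(all(ps$lower <= ps$mean & ps$mean <= ps$upper))

  # constant chain: mean equals the constant and zero-width intervals
  const <- fit
  const$draws$G0 <- array(2, dim = c(1, 1, 5))
  const$draws$Rq <- array(1, dim = c(1, 1, 5))
  const$draws$Rp <- array(1, dim = c(1, 1, 5))
  const$draws$sigma2 <- matrix(3, 5, 1)
  const$n_retained <- 5
  cs <- posterior_summary(const)
  g0 <- cs[cs$block == "G0", ]
  expect_equal(g0$mean, 2)
  expect_equal(g0$upper - g0$lower, 0)
})

test_that("inverse-Wishart sampler matches the analytic mean", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  df <- 10
  draws <- herdlife:::draw_inv_wishart(10000, df, S, seed = 99)
  m <- apply(draws, c(1, 2), mean)
  expect_equal(m, S / (df - 2 - 1), tolerance = 0.05)
})
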