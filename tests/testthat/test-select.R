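test_that("EBVs are the basis image of the coefficients", {
  Tm <- legendre_T(4)
  expect_equal(unname(ebv_by_age(rep(0, 5), Tm)), rep(0, 14))
  e <- ebv_by_age(c(3, 0, 0, 0, 0), Tm)
  expect_equal(unname(e), rep(3 * sqrt(1 / 2), 14))
  a1 <- rnorm(5); a2 <- rnorm(5)
  expect_equal(ebv_by_age(a1 + a2, Tm), ebv_by_age(a1, Tm) + ebv_by_age(a2, Tm))
  expect_error(ebv_by_age(1:3, Tm), "dimension")
})

test_that("RBV standardization hits mean 100 and SD 5 exactly", {
  expect_equal(unname(rbv(c(-1, 0, 1))), c(95, 100, 105))
  set.seed(8)
  x <- rnorm(50, sd = 3)
  r <- rbv(x)
  expect_equal(mean(r), 100)
  expect_equal(sd(r), 5)
  # affine invariance of the standardized result
  expect_equal(rbv(2 * x + 7), r)
  expect_error(rbv(rep(1, 4)), "zero dispersion")
  expect_error(rbv(3), "two sires")
})

test_that("top-fraction selection sizes, filtering and tie-breaking", {
  st <- tibble::tibble(sire_id = sprintf("S%03d", 1:100),
                       n_daughters = rep(c(4, 20), 50),
                       age = 4, ebv = rev(seq_len(100)))
  # only the 50 sires with > 5 daughters are eligible
  top <- top_fraction(st, 0.10, age_at_selection = 4)
  expect_equal(length(top), 5)
  expect_equal(top, c("S002", "S004", "S006", "S008", "S010"))

  big <- tibble::tibble(sire_id = sprintf("S%04d", 1:523),
                        n_daughters = 10, age = 4, ebv = rnorm(523))
  expect_equal(length(top_fraction(big, 0.01, 4)), 6)  # ceiling(5.23)

  ties <- tibble::tibble(sire_id = c("b", "a", "c"), n_daughters = 10,
                         age = 4, ebv = 1)
  expect_equal(top_fraction(ties, 2 / 3, 4), c("a", "b"))
  expect_error(top_fraction(ties[ties$n_daughters > 99, ], 0.1, 4),
               "eligible")
})

test_that("commonly-selected percentages count overlap", {
  expect_equal(common_selected(letters[1:10], letters[1:10]), 100)
  expect_equal(common_selected(letters[1:10], letters[11:20]), 0)
  expect_equal(common_selected(letters[1:10], letters[4:13]), 70)
  expect_error(common_selected(letters[1:3], letters[1:4]), "size")
})

test_that("observed daughter metrics count completed years", {
  recs <- dplyr::bind_rows(
    make_record("d1", 5.9, sire = "S1"),
    make_record("d2", 7.2, sire = "S1"),
    make_record("d3", 13.0, sire = "S2"),
    make_record("d4", 13.9, sire = "S2")
  )
  m <- observed_daughter_metrics(recs)
  s1 <- m[m$sire_id == "S1", ]
  expect_equal(s1$avg_culling_age, 6.55)
  expect_equal(s1$alive_6, 0.5)
  s2 <- m[m$sire_id == "S2", ]
  expect_equal(c(s2$alive_6, s2$alive_9, s2$alive_12), c(1, 1, 1))
  expect_true(all(m$alive_6 >= m$alive_9 & m$alive_9 >= m$alive_12))

  # linkage through a pedigree when records lack the sire column
  ped <- tibble::tibble(animal = c("S1", "d1", "d2"),
                        sire = c(NA, "S1", "S1"), dam = NA)
  m2 <- observed_daughter_metrics(recs[1:2, names(recs) != "sire_id"], ped)
  expect_equal(m2$n_daughters, 2)
})

test_that("EDL regression recovers exact linear relationships", {
  r <- c(95, 100, 105)
  m <- fit_edl(r, 2 + 0.1 * r)
  expect_equal(c(m$b0, m$b1), c(2, 0.1))
  m2 <- fit_edl(r, c(5, 6, 7))
  expect_equal(c(m2$b0, m2$b1), c(-14, 0.2))
  const <- fit_edl(r, rep(4.2, 3))
  expect_equal(c(const$b0, const$b1), c(4.2, 0))
  # OLS through the mean: prediction at RBV = 100 is the metric mean
  set.seed(5)
  rr <- rbv(rnorm(20)); mm <- rnorm(20, 8)
  expect_equal(predict(fit_edl(rr, mm), 100), mean(mm))
  expect_error(fit_edl(rep(100, 5), 1:5), "zero dispersion")
})

test_that("prediction accuracy is the sample Pearson correlation", {
  expect_equal(prediction_accuracy(1:5, 1:5), 1)
  expect_equal(prediction_accuracy(1:5, -(1:5)), -1)
  expect_equal(prediction_accuracy(c(1, 2, 3), c(2, 2, 4)), 0.866,
               tolerance = 1e-3)
  expect_error(prediction_accuracy(1:5, rep(2, 5)), "zero variance")
})

test_that("accuracy grows with daughter count on synthetic sires", {
  acc_for_n <- function(n_daughters, seed) {
    set.seed(seed)
    n_sires <- 60
    bv <- rnorm(n_sires)
    # EBV from one daughter crop, observed longevity from an independent one
    ebv_hat <- bv / 2 + rnorm(n_sires, sd = 2 / sqrt(n_daughters))
    observed <- bv / 2 + rnorm(n_sires, sd = 2 / sqrt(30))
    edl <- fit_edl(rbv(ebv_hat), observed)
    prediction_accuracy(predict(edl, rbv(ebv_hat)), observed)
  }
  acc <- vapply(c(5, 20, 100), function(n) {
    mean(vapply(1:30, function(s) acc_for_n(n, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("top-bottom comparison uses the top mean as denominator", {
  st <- tibble::tibble(sire_id = sprintf("S%02d", 1:20), n_daughters = 10,
                       age = 4, ebv = 1:20)
  metrics <- tibble::tibble(sire_id = st$sire_id,
                            avg_culling_age = 4 + 0.2 * (1:20))
  cmp <- top_bottom_comparison(st, metrics, fraction = 0.25)
  expect_equal(cmp$top_mean, mean(4 + 0.2 * c(20, 19, 18, 17, 16)))
  expect_equal(cmp$bottom_mean, mean(4 + 0.2 * (1:5)))
  expect_equal(cmp$dif_pct,
               100 * (cmp$top_mean - cmp$bottom_mean) / cmp$top_mean)
})
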