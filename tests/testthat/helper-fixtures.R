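# Builders for small in-code fixtures used across the suite.

make_record <- function(cow_id, culling_age,
                        calvings_months = 24,
                        first_calving = calvings_months[1],
                        birth = as.Date("1995-03-01"),
                        herd = "H1", reason = "fertility",
                        sire = NA_character_, et = FALSE) {
  tibble::tibble(
    cow_id = cow_id, sire_id = sire, herd_id = herd, birth_date = birth,
    first_calving_age = first_calving,
    calving_ages = list(calvings_months),
    culling_age = culling_age, culling_reason = reason,
    embryo_transfer = et
  )
}

# random but valid pedigree: parents drawn from earlier animals or unknown
random_pedigree <- function(n, seed, p_known = 0.7) {
  set.seed(seed)
  animal <- sprintf("R%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  for (i in seq_len(n)) {
    if (i < 3) next
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males) && stats::runif(1) < p_known) {
      sire[i] <- animal[males[sample.int(length(males), 1)]]
    }
    if (length(females) && stats::runif(1) < p_known) {
      dam[i] <- animal[females[sample.int(length(females), 1)]]
    }
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam, sex = sex)
}

# gaussian-mode simulation with constant true heritability across ages:
# G0, Rq, Rp scaled identities and residual proportional to the squared
# basis row norms make every variance component share the same age curve.
constant_h2_config <- function(n_founders, n_generations = 1, seed = 1,
                               g = 0.3, q = 0.1, p = 0.2, e = 0.4,
                               order = 2) {
  Tm <- legendre_T(order)
  norms <- rowSums(Tm^2)
  sim_config(
    n_founders = n_founders, n_generations = n_generations,
    offspring_per_mating = 2, n_herds = 4,
    true_G0 = diag(g / mean(norms), order + 1),
    true_Rp = diag(p / mean(norms), order + 1),
    true_Rq = diag(q / mean(norms), order + 1),
    true_residual = e * norms / mean(norms),
    mode = "gaussian", seed = seed
  )
}

true_h2_curve <- function(cfg) {
  Tm <- legendre_T(cfg$order)
  va <- diag(Tm %*% cfg$true_G0 %*% t(Tm))
  vq <- diag(Tm %*% cfg$true_Rq %*% t(Tm))
  vp <- diag(Tm %*% cfg$true_Rp %*% t(Tm))
  ve <- rep_len(cfg$true_residual, nrow(Tm))
  va / (va + vq + vp + ve)
}
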