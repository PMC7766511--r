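#' Pedigree utilities for the animal model
#'
#' A pedigree is a tibble with columns `animal`, `sire`, `dam` (character or
#' integer ids; `NA` or `"0"` for unknown parents) and optionally
#' `birth_year` and `sex`. All functions topologically sort internally so
#' parents precede offspring.
#'
#' @name pedigree
NULL

normalize_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ped$animal <- as.character(ped$animal)
  fix_unknown <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x %in% c("0", "")] <- NA_character_
    x
  }
  ped$sire <- fix_unknown(ped$sire)
  ped$dam <- fix_unknown(ped$dam)
  if (anyDuplicated(ped$animal)) {
    stop("duplicated animal ids in pedigree: ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  }
  # parents appearing only as parents become founders
  only_parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(only_parents)) {
    ped <- dplyr::bind_rows(
      tibble::tibble(animal = only_parents, sire = NA_character_,
                     dam = NA_character_),
      ped
    )
  }
  ped
}

#' Topologically sort a pedigree
#'
#' Orders animals so every parent precedes its offspring; errors on cycles
#' (an animal that is its own ancestor).
#'
#' @param ped pedigree tibble (see [pedigree]).
#' @return The sorted tibble.
#' @export
sort_pedigree <- function(ped) {
  ped <- normalize_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  depth <- rep(NA_integer_, n)
  pending <- seq_len(n)
  while (length(pending)) {
    ready <- vapply(pending, function(j) {
      par <- c(si[j], di[j])
      par <- par[!is.na(par)]
      !length(par) || !anyNA(depth[par])
    }, logical(1))
    if (!any(ready)) {
      stop("pedigree cycle detected involving animal(s): ",
           paste(utils::head(ped$animal[pending], 5), collapse = ", "))
    }
    for (j in pending[ready]) {
      par <- c(si[j], di[j])
      par <- par[!is.na(par)]
      depth[j] <- if (length(par)) max(depth[par]) + 1L else 0L
    }
    pending <- pending[!ready]
  }
  ped[order(depth, seq_len(n)), , drop = FALSE]
}

#' Prune a pedigree to ancestors of phenotyped animals
#'
#' Keeps the phenotyped animals plus their ancestors up to
#' `max_generations` back (generation distance = shortest path to any
#' phenotyped descendant). Parents of animals at the generation limit are
#' set to unknown, so the result is closed under parenthood.
#'
#' @param ped pedigree tibble.
#' @param phenotyped_ids ids of animals with records; must all be present.
#' @param max_generations generations of ancestors to retain (default 10).
#' @return Pruned, topologically sorted pedigree tibble.
#' @export
prune_pedigree <- function(ped, phenotyped_ids, max_generations = 10) {
  ped <- sort_pedigree(ped)
  phenotyped_ids <- as.character(phenotyped_ids)
  missing_ids <- setdiff(phenotyped_ids, ped$animal)
  if (length(missing_ids)) {
    stop("phenotyped animals absent from pedigree: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  gen <- rep(Inf, nrow(ped))
  gen[idx[phenotyped_ids]] <- 0
  frontier <- idx[phenotyped_ids]
  g <- 0
  while (length(frontier) && g < max_generations) {
    par <- c(si[frontier], di[frontier])
    par <- unique(par[!is.na(par)])
    newly <- par[gen[par] > g + 1]
    gen[newly] <- g + 1
    frontier <- newly
    g <- g + 1
  }
  keep <- which(is.finite(gen))
  out <- ped[keep, , drop = FALSE]
  # drop parent links pointing outside the kept set
  out$sire[!(out$sire %in% out$animal)] <- NA_character_
  out$dam[!(out$dam %in% out$animal)] <- NA_character_
  sort_pedigree(out)
}

#' Inbreeding coefficients
#'
#' Computes the inbreeding coefficient F of every animal with the
#' Meuwissen–Luo recursion on the Cholesky representation of the additive
#' relationship matrix. Founders (unknown parents) get F = 0.
#'
#' @param ped pedigree tibble; sorted internally.
#' @return Named numeric vector of F, in the sorted pedigree's order.
#' @export
inbreeding_coefficients <- function(ped) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); si[is.na(si)] <- 0L
  di <- unname(idx[ped$dam]);  di[is.na(di)] <- 0L
  F <- meuwissen_luo_F(si, di)
  stats::setNames(F, ped$animal)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes at most nine
#' entries involving itself and its known parents, weighted by the inverse
#' Mendelian-sampling variance
#' \eqn{d_i = 1/(0.5 - 0.25 (F_s + F_d))} (both parents known),
#' \eqn{1/(0.75 - 0.25 F_p)} (one known) or 1 (founder).
#'
#' @param ped pedigree tibble; sorted internally.
#' @param F optional inbreeding coefficients matching the sorted pedigree;
#'   computed if missing.
#' @return A symmetric sparse [Matrix::dsCMatrix] with animal-id dimnames,
#'   in sorted pedigree order.
#' @export
build_A_inverse <- function(ped, F = NULL) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  if (is.null(F)) F <- inbreeding_coefficients(ped)
  stopifnot(length(F) == n)
  F <- unname(F)
  Fs <- ifelse(is.na(si), 0, F[si])
  Fd <- ifelse(is.na(di), 0, F[di])
  d <- ifelse(!is.na(si) & !is.na(di), 1 / (0.5 - 0.25 * (Fs + Fd)),
       ifelse(!is.na(si) | !is.na(di), 1 / (0.75 - 0.25 * (Fs + Fd)), 1))
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, pmin(i, j)); jj <<- c(jj, pmax(i, j)); xx <<- c(xx, v)
  }
  anim <- seq_len(n)
  add(anim, anim, d)
  has_s <- !is.na(si); has_d <- !is.na(di)
  add(anim[has_s], si[has_s], -d[has_s] / 2)
  add(anim[has_d], di[has_d], -d[has_d] / 2)
  add(si[has_s], si[has_s], d[has_s] / 4)
  add(di[has_d], di[has_d], d[has_d] / 4)
  both <- has_s & has_d
  add(si[both], di[both], d[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = TRUE)
  dimnames(Ainv) <- list(ped$animal, ped$animal)
  Ainv
}

#' Dense additive relationship matrix by the tabular method
#'
#' Brute-force oracle for small pedigrees: a_ii = 1 + F_i with F_i half the
#' parents' relationship, a_ij the average relationship of j with i's
#' parents.
#'
#' @param ped pedigree tibble; sorted internally.
#' @param max_animals size guard (dense \eqn{O(n^2)} construction).
#' @return Dense symmetric numeric matrix with animal-id dimnames.
#' @export
relationship_matrix_bruteforce <- function(ped, max_animals = 2000) {
  ped <- sort_pedigree(ped)
  n <- nrow(ped)
  if (n > max_animals) {
    stop("pedigree too large for the dense tabular method (", n, " > ",
         max_animals, " animals)")
  }
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                    (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- A[i, j] <- aij
    }
  }
  A
}
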