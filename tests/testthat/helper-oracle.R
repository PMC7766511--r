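# Direct sparse mixed-model-equation solve at fixed variance components:
# the generalized-least-squares oracle for the location effects.
# Column layout: [ys blocks | et | q blocks | a blocks | p blocks].
mme_solve <- function(des, ped, start) {
  ped <- sort_pedigree(ped)
  k <- ncol(des$T)
  n_anim <- nrow(ped)
  n_hys <- length(des$hys_levels)
  n_ys <- length(des$ys_levels)
  cow_i <- match(des$cow_id, ped$animal)
  off_et <- n_ys * k
  off_q <- off_et + 1
  off_a <- off_q + n_hys * k
  off_p <- off_a + n_anim * k
  ncoef <- off_p + n_anim * k
  n_obs <- des$n_obs
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(rows, cols, vals) {
    ii <<- c(ii, rows); jj <<- c(jj, cols); xx <<- c(xx, vals)
  }
  for (m in seq_len(k)) {
    add(seq_len(n_obs), (des$ys_i - 1) * k + m, des$Tobs[, m])
    add(seq_len(n_obs), off_q + (des$hys_i - 1) * k + m, des$Tobs[, m])
    add(seq_len(n_obs), off_a + (cow_i - 1) * k + m, des$Tobs[, m])
    add(seq_len(n_obs), off_p + (cow_i - 1) * k + m, des$Tobs[, m])
  }
  add(seq_len(n_obs), rep(off_et + 1, n_obs), des$et)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_obs, ncoef))
  prior <- Matrix::bdiag(c(
    rep(list(diag(1e-10, k)), n_ys), list(matrix(1e-10)),
    rep(list(solve(start$Rq)), n_hys),
    list(Matrix::kronecker(build_A_inverse(ped), solve(start$G0))),
    rep(list(solve(start$Rp)), n_anim)
  ))
  sig2 <- start$sigma2[1]
  lhs <- Matrix::crossprod(W) / sig2 + prior
  rhs <- Matrix::crossprod(W, des$y) / sig2
  sol <- as.numeric(Matrix::solve(lhs, rhs))
  list(ys = sol[seq_len(n_ys * k)], et = sol[off_et + 1], all = sol)
}
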