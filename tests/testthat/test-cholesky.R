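test_that("an exactly low-rank tensor is recovered at its true rank", {
  set.seed(7)
  n <- 4; k <- 3
  L <- matrix(rnorm(n^2 * k), n^2, k)
  ## symmetrize each factor so the tensor has the full permutational symmetry
  for (j in 1:k) {
    M <- matrix(L[, j], n, n); L[, j] <- as.numeric((M + t(M)) / 2)
  }
  eri <- array(tcrossprod(L), rep(n, 4))
  cf <- cholesky_decompose(eri, threshold = 1e-10)
  expect_equal(cf$rank, k)
  expect_lt(max(abs(cholesky_reconstruct(cf) - eri)), 1e-9)
})

test_that("threshold above the largest diagonal gives rank zero", {
  eri <- ao_h2_sto3g()$eri
  cf <- cholesky_decompose(eri, threshold = 10)
  expect_equal(cf$rank, 0L)
})

test_that("reconstruction error is bounded by the threshold", {
  for (tau in c(1e-3, 1e-5, 1e-8)) {
    cf <- cholesky_decompose(ao_lih_sto3g()$eri, threshold = tau)
    err <- abs(cholesky_reconstruct(cf) - ao_lih_sto3g()$eri)
    expect_lt(max(err), tau * 1.01)
  }
})

test_that("Cholesky and dense MO paths give the same integrals", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  mi_dense <- transform_to_mo(ao, scf$mocoeffs)
  cf <- cholesky_decompose(ao$eri, threshold = 1e-7)
  mi_chol <- transform_to_mo(ao, scf$mocoeffs, chol = cf)
  expect_lt(max(abs(paircc:::mo_eri_full(mi_chol) - mi_dense$eri)), 1e-6)
  ## downstream energies agree within the decomposition threshold
  p1 <- solve_pccd(mi_dense, 4)
  p2 <- solve_pccd(mi_chol, 4)
  expect_equal(p1$energy, p2$energy, tolerance = 1e-6)
})

test_that("a non-PSD matrix is refused", {
  eri <- array(0, rep(2, 4))
  eri[1, 1, 1, 1] <- -1
  expect_error(cholesky_decompose(eri, 1e-6), "positive semidefinite")
})
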