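test_that("MO coefficients are overlap-orthonormal and partition the space", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  C <- scf$mocoeffs$C
  expect_lt(max(abs(crossprod(C, ao$S %*% C) - diag(ncol(C)))), 1e-10)
  mc <- mo_coefficients(C, 4, frozen_core = 1L)
  expect_identical(sort(c(mc$frozen_core, mc$occupied_pairs, mc$virtuals)),
                   seq_len(ncol(C)))
  expect_equal(2 * (length(mc$frozen_core) + length(mc$occupied_pairs)), 4)
})

test_that("transforming with the identity leaves integrals unchanged", {
  set.seed(12)
  ao <- ao_h2_sto3g()
  mi <- transform_to_mo(ao, diag(ao$nbf))
  expect_equal(mi$h, ao$Hcore, tolerance = 1e-12)
  expect_equal(mi$eri, ao$eri, tolerance = 1e-12)
})

test_that("SCF energy is invariant under rotations inside occ/virt blocks", {
  set.seed(21)
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  C <- scf$mocoeffs$C
  nocc <- 2
  rot <- function(n) { q <- qr.Q(qr(matrix(rnorm(n^2), n))); q }
  C2 <- C
  C2[, 1:nocc] <- C[, 1:nocc] %*% rot(nocc)
  C2[, (nocc + 1):ncol(C)] <- C[, (nocc + 1):ncol(C)] %*% rot(ncol(C) - nocc)
  ## energy re-derived from the rotated occupied density
  D <- 2 * tcrossprod(C2[, 1:nocc])
  jk <- paircc:::fock_jk(D, ao$eri, NULL)
  E <- 0.5 * sum(D * (2 * ao$Hcore + jk$J - 0.5 * jk$K)) + ao$enuc
  expect_equal(E, scf$E_total, tolerance = 1e-10)
})

test_that("empty frozen set is the identity operation", {
  res <- mi_for(ao_lih_sto3g())
  expect_identical(fold_frozen_core(res$mi, integer(0)), res$mi)
})

test_that("freezing the Li 1s reproduces the core-constrained FCI", {
  res <- mi_for(ao_lih_sto3g())
  mi_act <- fold_frozen_core(res$mi, 1L)
  e_act <- dense_fci(mi_act, 2)$energy
  ## independent reference: diagonalize the full Hamiltonian restricted to
  ## determinants with the core orbital doubly occupied
  space <- paircc:::det_space(res$mi$n_orb, 4, "all")
  H <- paircc:::ci_hamiltonian(space, res$mi)
  core_occ <- vapply(seq_len(space$ndet), function(d) {
    ma <- space$strings[space$dets[d, 1]]
    mb <- space$strings[space$dets[d, 2]]
    bitwAnd(ma, 1L) == 1L && bitwAnd(mb, 1L) == 1L
  }, logical(1))
  Hc <- H[core_occ, core_occ]
  e_constrained <- min(eigen(Hc, symmetric = TRUE, only.values = TRUE)$values) +
    res$mi$core_energy
  expect_equal(e_act, e_constrained, tolerance = 1e-8)
})

test_that("frozen-core dipole bookkeeping adds back 2 sum d_cc", {
  res <- mi_for(ao_lih_sto3g())
  mi_act <- fold_frozen_core(res$mi, 1L)
  for (ax in 1:3) {
    expect_equal(mi_act$frozen_dipole[ax],
                 -2 * res$mi$dipole[[ax]][1, 1], tolerance = 1e-10)
  }
})

test_that("frozen set overlapping declared active pairs is refused", {
  expect_error(mo_coefficients(diag(4), 4, frozen_core = 3L), "doubly occupied")
})
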