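test_that("orbital gradient matches finite differences of the energy", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  env <- paircc:::freeze_core_env(ao, scf$mocoeffs$C, 0)
  C0 <- scf$mocoeffs$C
  mi0 <- paircc:::active_space_ints(ao, env, C0)
  p0 <- solve_pccd_lambda(solve_pccd(mi0, 4), mi0)
  g <- orbital_gradient(mi0, p0)
  efun <- function(K) {
    C <- C0 %*% paircc:::expm_antisym(K)
    solve_pccd(paircc:::active_space_ints(ao, env, C), 4)$energy
  }
  h <- 1e-5
  n <- ncol(C0)
  for (pq in list(c(1, 2), c(2, 4), c(3, 6), c(1, 5))) {
    K <- matrix(0, n, n)
    K[pq[1], pq[2]] <- h; K[pq[2], pq[1]] <- -h
    gnum <- (efun(K) - efun(-K)) / (2 * h)
    expect_equal(g[pq[1], pq[2]], gnum, tolerance = 1e-6)
  }
})

test_that("oo-pCCD reaches FCI for a two-electron system", {
  ao <- ao_h2_ccpvdz()
  scf <- solve_rhf(ao)
  oo <- solve_oopccd(ao, scf, nfrozen = 0)
  fci <- dense_fci(transform_to_mo(ao, scf$mocoeffs), 2)
  expect_equal(oo$energy, fci$energy, tolerance = 1e-7)
})

test_that("already-optimal orbitals are a fixed point", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  oo1 <- solve_oopccd(ao, scf, nfrozen = 0)
  oo2 <- solve_oopccd(ao, oo1$mocoeffs$C, nfrozen = 0)
  expect_equal(oo2$energy, oo1$energy, tolerance = 1e-10)
})

test_that("orbital optimization lowers the energy below canonical pCCD", {
  res <- mi_for(ao_lih_sto3g())
  p_can <- solve_pccd(res$mi, 4)
  oo <- solve_oopccd(ao_lih_sto3g(), res$scf, nfrozen = 0)
  expect_lt(oo$energy, p_can$energy)
  ## accepted steps never increase the energy
  expect_true(all(diff(oo$energy_trace) <= 1e-12))
})

test_that("relaxed reference density equals the FCI density for H2", {
  ao <- ao_h2_ccpvdz()
  scf <- solve_rhf(ao)
  oo <- solve_oopccd(ao, scf, nfrozen = 0, conv_grad = 1e-7,
                     conv_e = 1e-12, max_iter = 500)
  g <- relaxed_reference_rdm(oo, tol = 1e-4)
  ## compare against dense FCI in the optimized orbital basis
  fci <- dense_fci(oo$mi, 2)
  expect_lt(max(abs(g$gamma - fci_rdm1(fci))), 1e-6)
})

test_that("homonuclear oo-pCCD dipole vanishes by symmetry", {
  ao <- ao_h2_sto3g()
  scf <- solve_rhf(ao)
  oo <- solve_oopccd(ao, scf, nfrozen = 0)
  mu <- electronic_dipole(relaxed_reference_rdm(oo, tol = 1e-4), oo$mi) +
    nuclear_dipole(ao$molecule)
  expect_lt(max(abs(au_to_debye(mu))), 1e-8)
})

test_that("an unconverged result refuses to hand out the relaxed density", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  oo <- solve_oopccd(ao, scf, nfrozen = 0, max_iter = 1)
  expect_error(relaxed_reference_rdm(oo, tol = 1e-12), "gradient")
})
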