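test_that("RHF energy equals the reference-determinant expectation value", {
  res <- mi_for(ao_h2_sto3g())
  space <- paircc:::det_space(2, 2, "all")
  H <- paircc:::ci_hamiltonian(space, res$mi)
  iref <- paircc:::ref_det_index(space)
  expect_equal(res$scf$E_total, H[iref, iref] + res$mi$core_energy,
               tolerance = 1e-10)
})

test_that("helium SCF energy respects the variational bounds", {
  ao <- build_from_backend(molecule("He", matrix(0, 1, 3)), "cc-pvdz")
  e <- solve_rhf(ao)$E_total
  expect_lt(e, -2.75)
  expect_gt(e, -2.9037) # exact nonrelativistic ground state
})

test_that("converged SCF satisfies the commutator condition", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  jk <- paircc:::fock_jk(scf$density, ao$eri, NULL)
  F <- ao$Hcore + jk$J - 0.5 * jk$K
  err <- F %*% scf$density %*% ao$S - ao$S %*% scf$density %*% F
  expect_lt(max(abs(err)), 1e-7)
})

test_that("RHF dipole matches the finite-difference field derivative", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  mu_resp <- -sum(scf$density * ao$dipole$z)
  eps <- 1e-4
  ep <- solve_rhf(paircc:::apply_field(ao, "z", eps))$E_total
  em <- solve_rhf(paircc:::apply_field(ao, "z", -eps))$E_total
  expect_equal(mu_resp, -(ep - em) / (2 * eps), tolerance = 1e-6)
})

test_that("Pipek-Mezey localization ascends and preserves the energy", {
  ao <- fixture_ao("h2o_sto3g", function()
    build_from_backend(
      molecule(c("O", "H", "H"),
               rbind(c(0, 0, 0), c(0.757, 0.586, 0), c(-0.757, 0.586, 0))),
      "sto-3g"))
  scf <- solve_rhf(ao)
  ao_atom <- rep(vapply(ao$shells, `[[`, 0L, "atom"),
                 2L * vapply(ao$shells, `[[`, 0L, "l") + 1L)
  pm <- pipek_mezey_localize(scf$mocoeffs$C, ao$S, ao_atom, block = 2:5)
  expect_true(all(diff(pm$trace) > -1e-10)) # monotone ascent
  ## localized orbitals stay orthonormal and give the same SCF energy
  C <- pm$C
  expect_lt(max(abs(crossprod(C, ao$S %*% C) - diag(ncol(C)))), 1e-9)
  D <- 2 * tcrossprod(C[, 1:5])
  jk <- paircc:::fock_jk(D, ao$eri, NULL)
  E <- 0.5 * sum(D * (2 * ao$Hcore + jk$J - 0.5 * jk$K)) + ao$enuc
  expect_equal(E, scf$E_total, tolerance = 1e-10)
})

test_that("a single-orbital block is left unchanged by localization", {
  ao <- ao_lih_sto3g()
  scf <- solve_rhf(ao)
  ao_atom <- rep(vapply(ao$shells, `[[`, 0L, "atom"),
                 2L * vapply(ao$shells, `[[`, 0L, "l") + 1L)
  pm <- pipek_mezey_localize(scf$mocoeffs$C, ao$S, ao_atom, block = 2L)
  expect_identical(pm$C, scf$mocoeffs$C)
})
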