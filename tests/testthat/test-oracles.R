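test_that("H2 FCI matches the hand-built two-determinant secular problem", {
  res <- mi_for(ao_h2_sto3g())
  mi <- res$mi
  ## closed-shell dets |1 1bar> and |2 2bar>
  e11 <- 2 * mi$h[1, 1] + mi$eri[1, 1, 1, 1]
  e22 <- 2 * mi$h[2, 2] + mi$eri[2, 2, 2, 2]
  k12 <- mi$eri[1, 2, 1, 2]
  ## the two open-shell singlet/triplet dets decouple from the ground state
  ## only through K; the seniority-zero 2x2 block is exact here because the
  ## singlet combination of open-shell dets has different (u) symmetry
  e2x2 <- min(eigen(rbind(c(e11, k12), c(k12, e22)),
                    symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(dense_fci(mi, 2)$energy, e2x2 + mi$core_energy,
               tolerance = 1e-10)
})

test_that("a one-electron Hamiltonian gives the orbital-sum energy", {
  mi <- mo_integral_set(h = diag(c(-3, -1, 2)), eri = array(0, rep(3, 4)),
                        core_energy = 0.25)
  expect_equal(dense_fci(mi, 4)$energy, 2 * (-3) + 2 * (-1) + 0.25,
               tolerance = 1e-12)
})

test_that("seniority filter is exact for two electrons in natural orbitals", {
  res <- mi_for(ao_h2_sto3g())
  e_all <- dense_fci(res$mi, 2)$energy
  ## H2 minimal-basis canonical orbitals are the natural orbitals by symmetry
  e_sz <- dense_fci(res$mi, 2, "seniority-zero")$energy
  expect_equal(e_sz, e_all, tolerance = 1e-10)
})

test_that("FCI energy is invariant under orbital rotations", {
  set.seed(42)
  res <- mi_for(ao_lih_sto3g())
  e0 <- dense_fci(res$mi, 4)$energy
  n <- res$mi$n_orb
  U <- qr.Q(qr(matrix(rnorm(n^2), n)))
  hU <- crossprod(U, res$mi$h %*% U)
  eU <- transform_eri_index(res$mi$eri, t(U))
  miU <- mo_integral_set((hU + t(hU)) / 2, eri = eU,
                         core_energy = res$mi$core_energy)
  expect_equal(dense_fci(miU, 4)$energy, e0, tolerance = 1e-9)
})

test_that("pairing generator is deterministic and trivial at G = 0", {
  h1 <- make_pairing_hamiltonian(c(0, 1, 2, 3), 0.3, seed = 5, jitter = 0.05)
  h2 <- make_pairing_hamiltonian(c(0, 1, 2, 3), 0.3, seed = 5, jitter = 0.05)
  expect_identical(h1$h, h2$h)
  expect_identical(h1$eri, h2$eri)
  p <- solve_pccd(make_pairing_hamiltonian(c(0, 1, 2, 3), 0), 4)
  expect_equal(p$E_corr, 0, tolerance = 1e-12)
})

test_that("projected residual grows linearly for small perturbations", {
  hm <- make_pairing_hamiltonian(c(0, 0.7, 1.9, 2.8), 0.2)
  p <- solve_pccd(hm, 4)
  set.seed(9)
  d <- matrix(rnorm(length(p$t)), nrow(p$t))
  r1 <- projected_residual_check(p$t + 1e-5 * d, hm, 4)$max
  r2 <- projected_residual_check(p$t + 2e-5 * d, hm, 4)$max
  expect_equal(r2 / r1, 2, tolerance = 0.01)
  ## zero Hamiltonian: zero residual for any amplitudes
  hz <- mo_integral_set(h = matrix(0, 4, 4), eri = array(0, rep(4, 4)),
                        core_energy = 0)
  expect_equal(projected_residual_check(p$t, hz, 4)$max, 0)
})

test_that("DOCI and pCCD agree closely on the pairing model", {
  hm <- make_pairing_hamiltonian(c(0, 1, 2, 3), 0.15)
  e_doci <- dense_fci(hm, 4, "seniority-zero")$energy
  e_pccd <- solve_pccd(hm, 4)$energy
  expect_equal(e_pccd, e_doci, tolerance = 1e-4)
})

test_that("determinant spaces have the closed-form binomial dimension", {
  sp <- paircc:::det_space(5, 4, "all")
  expect_equal(sp$ndet, choose(5, 2)^2)
  sz <- paircc:::det_space(5, 4, "seniority-zero")
  expect_equal(sz$ndet, choose(5, 2))
  expect_error(paircc:::det_space(20, 10), "too large")
})
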