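test_that("H2/STO-3G integrals reproduce the classic published values", {
  ao <- ao_h2_sto3g()
  ## reference values from the standard minimal-basis H2 worked example
  expect_equal(ao$S[1, 2], 0.6593, tolerance = 1e-4)
  expect_equal(ao$kinetic[1, 1], 0.7600, tolerance = 1e-4)
  expect_equal(ao$kinetic[1, 2], 0.2365, tolerance = 5e-4)
  expect_equal(ao$eri[1, 1, 1, 1], 0.7746, tolerance = 1e-4)
  expect_equal(ao$eri[1, 1, 2, 2], 0.5697, tolerance = 1e-4)
  expect_equal(ao$eri[2, 1, 1, 1], 0.4441, tolerance = 1e-4)
  expect_equal(ao$eri[2, 1, 2, 1], 0.2970, tolerance = 1e-4)
  expect_equal(ao$enuc, 1 / 1.4)
})

test_that("nuclear repulsion of a diatomic is Z1 Z2 / r", {
  r <- 1.09
  mol <- diatomic("N", "N", r)
  expect_equal(nuclear_repulsion(mol), 49 / (r * 1.8897261246),
               tolerance = 1e-9)
})

test_that("SCF energy is invariant under rigid rotation (s/p/d/f shells)", {
  toy <- list(
    H = list(list(l = 0L, exps = c(1.3, 0.3), coefs = c(0.5, 0.6)),
             list(l = 1L, exps = 0.8, coefs = 1),
             list(l = 2L, exps = 0.9, coefs = 1)),
    F = list(list(l = 0L, exps = c(2.0, 0.5), coefs = c(0.4, 0.7)),
             list(l = 1L, exps = c(1.1, 0.35), coefs = c(0.6, 0.5)),
             list(l = 2L, exps = 0.7, coefs = 1),
             list(l = 3L, exps = 1.2, coefs = 1)))
  attr(toy, "name") <- "toy"
  xyz <- rbind(c(0.1, -0.2, 0.3), c(0.8, 0.5, -0.4))
  th <- 0.7; R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  th2 <- 0.4; R2 <- rbind(c(1, 0, 0), c(0, cos(th2), -sin(th2)), c(0, sin(th2), cos(th2)))
  e1 <- solve_rhf(build_from_backend(molecule(c("H", "F"), xyz, unit = "bohr"), toy))$E_total
  e2 <- solve_rhf(build_from_backend(molecule(c("H", "F"), xyz %*% t(R2 %*% R3),
                                              unit = "bohr"), toy))$E_total
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("rigid translation leaves the energy invariant and shifts the dipole", {
  ao1 <- ao_lih_sto3g()
  shift <- c(0.3, -0.2, 0.5) # bohr
  mol2 <- molecule(c("Li", "H"),
                   ao_lih_sto3g()$molecule$coords +
                     matrix(shift, 2, 3, byrow = TRUE), unit = "bohr")
  ao2 <- build_from_backend(mol2, "sto-3g")
  scf1 <- solve_rhf(ao1); scf2 <- solve_rhf(ao2)
  expect_equal(scf1$E_total, scf2$E_total, tolerance = 1e-9)
  mu1 <- vapply(ao1$dipole, function(d) -sum(scf1$density * d), 0) +
    nuclear_dipole(ao1$molecule)
  mu2 <- vapply(ao2$dipole, function(d) -sum(scf2$density * d), 0) +
    nuclear_dipole(mol2)
  ## neutral molecule: total dipole unchanged by translation
  expect_equal(mu1, mu2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-electron tensor has 8-fold permutational symmetry", {
  e <- ao_lih_sto3g()$eri
  expect_lt(max(abs(e - aperm(e, c(2, 1, 3, 4)))), 1e-12)
  expect_lt(max(abs(e - aperm(e, c(1, 2, 4, 3)))), 1e-12)
  expect_lt(max(abs(e - aperm(e, c(3, 4, 1, 2)))), 1e-12)
})

test_that("overlap is positive definite and AO normalization is exact", {
  ao <- ao_lih_sto3g()
  expect_true(all(eigen(ao$S, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_equal(diag(ao$S), rep(1, ao$nbf), tolerance = 1e-12)
})

test_that("unknown basis or element raises a configuration error", {
  expect_error(build_from_backend(diatomic("H", "H", 0.7), "no-such-basis"),
               "not found")
  expect_error(build_from_backend(diatomic("Ne", "Ne", 3.0), "aug-cc-pvtz"),
               "no entry for element")
})

test_that("embedding potential: zero is identity, overlap shift is a gauge", {
  ao <- ao_h2_sto3g()
  scf0 <- solve_rhf(ao)
  ao0 <- add_embedding_potential(ao, matrix(0, ao$nbf, ao$nbf))
  expect_equal(solve_rhf(ao0)$E_total, scf0$E_total, tolerance = 1e-12)
  eps <- 0.05
  aoS <- add_embedding_potential(ao, eps * ao$S)
  scfS <- solve_rhf(aoS)
  expect_equal(scfS$E_total, scf0$E_total + eps * 2, tolerance = 1e-9)
  mu0 <- vapply(ao$dipole, function(d) -sum(scf0$density * d), 0)
  muS <- vapply(aoS$dipole, function(d) -sum(scfS$density * d), 0)
  expect_equal(mu0, muS, tolerance = 1e-8)
  expect_error(add_embedding_potential(ao, matrix(1:4, 2, 2) + 0.5),
               "symmetric")
})
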