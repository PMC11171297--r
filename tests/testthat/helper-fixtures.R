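## Shared fixtures: small molecules with cached integrals and random
## model Hamiltonians.  Everything is generated in code; cached per test
## session to keep the suite fast.

fixture_cache <- new.env(parent = emptyenv())

fixture_ao <- function(key, builder) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- builder()
  fixture_cache[[key]]
}

ao_h2_sto3g <- function(r = 1.4) {
  fixture_ao(paste0("h2_sto3g_", r), function()
    build_from_backend(diatomic("H", "H", r, unit = "bohr"), "sto-3g"))
}

ao_lih_sto3g <- function() {
  fixture_ao("lih_sto3g", function()
    build_from_backend(diatomic("Li", "H", 1.6), "sto-3g"))
}

ao_heh_sto3g <- function() {
  fixture_ao("heh_sto3g", function()
    build_from_backend(diatomic("He", "H", 0.772, charge = 1), "sto-3g"))
}

ao_h2_ccpvdz <- function(r = 0.74) {
  fixture_ao(paste0("h2_ccpvdz_", r), function()
    build_from_backend(diatomic("H", "H", r), "cc-pvdz"))
}

ao_lih_ccpvdz <- function() {
  fixture_ao("lih_ccpvdz", function()
    build_from_backend(diatomic("Li", "H", 1.595), "cc-pvdz"))
}

## canonical-orbital active-space MO integrals for a fixture
mi_for <- function(ao, nfrozen = 0) {
  scf <- solve_rhf(ao)
  mi <- transform_to_mo(ao, scf$mocoeffs)
  if (nfrozen > 0) mi <- fold_frozen_core(mi, seq_len(nfrozen))
  list(scf = scf, mi = mi)
}

## random two-electron tensor with full 8-fold permutational symmetry
random_sym_eri <- function(n) {
  e <- array(rnorm(n^4), rep(n, 4))
  e <- (e + aperm(e, c(2, 1, 3, 4)) + aperm(e, c(1, 2, 4, 3)) +
        aperm(e, c(2, 1, 4, 3)) + aperm(e, c(3, 4, 1, 2)) +
        aperm(e, c(4, 3, 1, 2)) + aperm(e, c(3, 4, 2, 1)) +
        aperm(e, c(4, 3, 2, 1))) / 8
  e
}

random_mi <- function(n, hscale = 1, vscale = 1) {
  h <- matrix(rnorm(n^2), n); h <- (h + t(h)) / 2 * hscale
  mo_integral_set(h, eri = random_sym_eri(n) * vscale, core_energy = 0)
}

## random pair-excluded symmetric doubles amplitudes
random_t2 <- function(no, nv, scale = 0.2) {
  t2 <- array(rnorm(no^2 * nv^2), c(no, no, nv, nv)) * scale
  paircc:::zero_pair((t2 + aperm(t2, c(2, 1, 4, 3))) / 2)
}

## H4 chain in a minimal basis (4 orbitals, 4 electrons)
ao_h4_sto3g <- function() {
  fixture_ao("h4_sto3g", function()
    build_from_backend(
      molecule(rep("H", 4),
               cbind(0, 0, c(0, 0.95, 1.9, 2.85))), "sto-3g"))
}

## FCI one-particle density for a converged dense_fci result
fci_rdm1 <- function(fci) {
  n <- fci$space$norb
  g <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    g[p, q] <- sum(fci$civec * paircc:::apply_Epq(fci$space, fci$civec, p, q))
  }
  g
}
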