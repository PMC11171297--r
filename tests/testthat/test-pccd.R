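test_that("residual at t = 0 is the pair-exchange integral", {
  res <- mi_for(ao_lih_sto3g())
  no <- 2; nv <- res$mi$n_orb - no
  r0 <- pccd_residual(matrix(0, no, nv), res$mi, 4)
  K <- matrix(0, no, nv)
  for (i in 1:no) for (a in 1:nv) K[i, a] <- res$mi$eri[i, no + a, i, no + a]
  expect_equal(r0, K, tolerance = 1e-12)
  ## and the oracle gives the same matrix elements
  orc <- projected_residual_check(matrix(0, no, nv), res$mi, 4)
  expect_equal(orc$residual, K, tolerance = 1e-12)
})

test_that("exact FCI pair ratios are a root for a two-electron system", {
  res <- mi_for(ao_h2_sto3g())
  fci <- dense_fci(res$mi, 2)
  ## CI coefficients of |1 1bar> and |2 2bar>
  space <- fci$space
  idx0 <- paircc:::ref_det_index(space)
  v2 <- paircc:::apply_pair(space, replace(numeric(space$ndet), idx0, 1), 1, 2)
  c2 <- sum(v2 * fci$civec)
  t_exact <- matrix(c2 / fci$civec[idx0], 1, 1)
  r <- pccd_residual(t_exact, res$mi, 2)
  expect_lt(max(abs(r)), 1e-10)
})

test_that("with zero two-electron integrals the residual vanishes at t = 0", {
  mi <- mo_integral_set(h = diag(c(-2, -1, 0.5)), eri = array(0, rep(3, 4)),
                        core_energy = 0)
  expect_equal(pccd_residual(matrix(0, 1, 2), mi, 2), matrix(0, 1, 2))
})

test_that("pCCD equals FCI for two electrons and the oracle certifies it", {
  res <- mi_for(ao_h2_sto3g())
  p <- solve_pccd(res$mi, 2)
  expect_equal(p$energy, dense_fci(res$mi, 2)$energy, tolerance = 1e-9)
  expect_lt(projected_residual_check(p$t, res$mi, 2)$max, 1e-8)
  expect_lt(p$E_corr, 0)
})

test_that("weak-coupling pairing model reproduces perturbation theory", {
  G <- 1e-4
  lev <- c(0, 1, 2, 3)
  hm <- make_pairing_hamiltonian(lev, G)
  p <- solve_pccd(hm, 4)
  e2 <- -sum(outer(lev[1:2], lev[3:4], function(i, a) G^2 / (2 * a - 2 * i)))
  expect_equal(p$E_corr, e2, tolerance = 1e-3)
})

test_that("converged amplitudes satisfy the brute-force projections", {
  for (fix in list(list(mi_for(ao_h4_sto3g())$mi, 4),
                   list(mi_for(ao_lih_sto3g())$mi, 4))) {
    p <- solve_pccd(fix[[1]], fix[[2]])
    expect_lt(projected_residual_check(p$t, fix[[1]], fix[[2]])$max, 1e-8)
  }
})

test_that("pair Lambda equations give the FCI natural occupations", {
  res <- mi_for(ao_h2_sto3g())
  p <- solve_pccd_lambda(solve_pccd(res$mi, 2), res$mi)
  g <- pccd_response_1rdm(p)
  fci <- dense_fci(res$mi, 2)
  expect_equal(diag(g$gamma), diag(fci_rdm1(fci)), tolerance = 1e-7)
  ## seniority-zero structure: strictly diagonal
  expect_equal(g$gamma, diag(diag(g$gamma)), tolerance = 1e-12)
})

test_that("zero coupling gives zero Lambda", {
  mi <- mo_integral_set(h = diag(c(-2, -1, 0.5)), eri = array(0, rep(3, 4)),
                        core_energy = 0)
  p <- solve_pccd_lambda(solve_pccd(mi, 2), mi)
  expect_equal(p$lam, matrix(0, 1, 2))
})

test_that("response 1-RDM has exact trace and reference limit", {
  res <- mi_for(ao_lih_sto3g())
  p <- solve_pccd_lambda(solve_pccd(res$mi, 4), res$mi)
  g <- pccd_response_1rdm(p)
  expect_equal(sum(diag(g$gamma)), 4, tolerance = 1e-10)
  p0 <- p; p0$t <- 0 * p0$t; p0$lam <- 0 * p0$lam
  g0 <- pccd_response_1rdm(p0)
  expect_equal(diag(g0$gamma), c(2, 2, 0, 0, 0, 0))
})

test_that("response 2-RDM blocks reconstruct the energy and the HF limit", {
  res <- mi_for(ao_lih_sto3g())
  p <- solve_pccd_lambda(solve_pccd(res$mi, 4), res$mi)
  r2 <- pccd_response_2rdm(p)
  expect_equal(paircc:::pccd_energy_from_rdm(r2, res$mi), p$energy,
               tolerance = 1e-9)
  p0 <- p; p0$t <- 0 * p0$t; p0$lam <- 0 * p0$lam
  r20 <- pccd_response_2rdm(p0)
  no <- 2
  expect_equal(r20$nn[1:no, 1:no], matrix(1, no, no))
  expect_equal(diag(r20$pair)[1:no], rep(1, no))
  expect_true(all(r20$nn[-(1:no), -(1:no)] == 0))
})

test_that("two-electron 2-RDM blocks match dense FCI", {
  res <- mi_for(ao_h2_sto3g())
  p <- solve_pccd_lambda(solve_pccd(res$mi, 2), res$mi)
  r2 <- pccd_response_2rdm(p)
  fci <- dense_fci(res$mi, 2)
  space <- fci$space
  for (pp in 1:2) for (qq in 1:2) {
    ## <b_p^+ b_q> = <psi| P+_p P_q |psi>; apply_pair moves the pair q -> p
    bpq <- sum(fci$civec * paircc:::apply_pair(space, fci$civec, qq, pp))
    expect_equal(r2$pair[pp, qq], bpq, tolerance = 1e-7)
  }
})

test_that("noninteracting fragments have additive correlation energy", {
  res <- mi_for(ao_h2_sto3g())
  mi <- res$mi; n <- mi$n_orb
  h2 <- matrix(0, 2 * n, 2 * n); e2 <- array(0, rep(2 * n, 4))
  h2[1:n, 1:n] <- mi$h; h2[n + 1:n, n + 1:n] <- mi$h
  e2[1:n, 1:n, 1:n, 1:n] <- mi$eri
  e2[n + 1:n, n + 1:n, n + 1:n, n + 1:n] <- mi$eri
  ord <- c(1, n + 1, 2:n, n + 2:n)
  mi2 <- mo_integral_set(h2[ord, ord], eri = e2[ord, ord, ord, ord],
                         core_energy = 2 * mi$core_energy)
  p1 <- solve_pccd(mi, 2)
  p2 <- solve_pccd(mi2, 4)
  expect_equal(p2$E_corr, 2 * p1$E_corr, tolerance = 1e-9)
})
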