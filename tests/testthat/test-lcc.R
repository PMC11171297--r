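## The linearized-CC equations are certified against the exact
## determinant-space map (lcc_det_residual): arbitrary amplitudes, random
## Hamiltonians, both variants, residuals and energies.

test_that("production residuals equal the determinant-space map", {
  set.seed(31)
  no <- 2; nv <- 3; norb <- no + nv
  for (rep in 1:2) {
    mi <- random_mi(norb)
    tp <- matrix(rnorm(no * nv), no, nv) * 0.3
    t1 <- matrix(rnorm(no * nv), no, nv) * 0.2
    t2 <- random_t2(no, nv)
    orc <- paircc:::lcc_det_residual(t1, t2, tp, mi, 2 * no)
    prod_sd <- lcc_residual(list(t1 = t1, t2 = t2), tp, mi, 2 * no, "lccsd")
    expect_lt(max(abs(prod_sd$r1 - orc$r1)), 1e-10)
    expect_lt(max(abs(prod_sd$r2 - orc$r2)), 1e-10)
    orc_d <- paircc:::lcc_det_residual(NULL, t2, tp, mi, 2 * no)
    prod_d <- lcc_residual(list(t2 = t2), tp, mi, 2 * no, "lccd")
    expect_lt(max(abs(prod_d$r2 - orc_d$r2)), 1e-10)
    ## energy functional agrees too
    sys <- paircc:::lcc_system(mi, 2 * no, tp, "lccsd")
    expect_equal(paircc:::lcc_energy(sys, t1, t2), orc$E_lcc, tolerance = 1e-10)
  }
})

test_that("the residual is affine in the correction amplitudes", {
  set.seed(32)
  no <- 2; nv <- 2
  mi <- random_mi(no + nv)
  tp <- matrix(rnorm(no * nv), no, nv) * 0.3
  tA <- random_t2(no, nv); tB <- random_t2(no, nv)
  al <- 0.37
  rA <- lcc_residual(list(t2 = tA), tp, mi, 2 * no, "lccd")$r2
  rB <- lcc_residual(list(t2 = tB), tp, mi, 2 * no, "lccd")$r2
  rM <- lcc_residual(list(t2 = al * tA + (1 - al) * tB), tp, mi, 2 * no,
                     "lccd")$r2
  expect_lt(max(abs(rM - (al * rA + (1 - al) * rB))), 1e-10)
})

test_that("pair-channel rows are excluded everywhere", {
  set.seed(33)
  no <- 2; nv <- 2
  mi <- random_mi(no + nv)
  tp <- matrix(rnorm(no * nv), no, nv) * 0.3
  lc <- solve_lcc_lambda(solve_lcc(tp, mi, 2 * no, "lccsd"))
  r <- lcc_residual(list(t1 = lc$t1, t2 = lc$t2), tp, mi, 2 * no, "lccsd")
  for (i in 1:no) for (a in 1:nv) {
    expect_identical(lc$t2[i, i, a, a], 0)
    expect_identical(lc$l2[i, i, a, a], 0)
    expect_identical(r$r2[i, i, a, a], 0)
  }
  ## rows with i = j, a != b and i != j, a = b are genuinely included
  expect_gt(max(abs(lc$t2[1, 1, 1, 2])), 0)
})

test_that("with tp = 0 the solve matches an independent dense linear solve", {
  set.seed(34)
  no <- 2; nv <- 2
  mi <- random_mi(no + nv, vscale = 0.3)
  tp0 <- matrix(0, no, nv)
  lc <- solve_lcc(tp0, mi, 2 * no, "lccsd", tol = 1e-10)
  ## dense system assembled from the determinant-space map by unit probes
  nt1 <- no * nv
  pack <- function(t1, t2) c(as.numeric(t1), as.numeric(t2))
  z1 <- matrix(0, no, nv); z2 <- array(0, c(no, no, nv, nv))
  b <- paircc:::lcc_det_residual(z1, z2, tp0, mi, 2 * no)
  bvec <- pack(b$r1, b$r2)
  keep <- c(rep(TRUE, nt1), as.logical({m <- array(TRUE, c(no, no, nv, nv));
    for (i in 1:no) for (a in 1:nv) m[i, i, a, a] <- FALSE; m}))
  nfull <- length(bvec)
  A <- matrix(0, nfull, nfull)
  for (k in which(keep)) {
    u <- numeric(nfull); u[k] <- 1
    u1 <- matrix(u[1:nt1], no, nv)
    u2 <- array(u[-(1:nt1)], c(no, no, nv, nv))
    ## symmetrize the probe like a genuine amplitude
    u2 <- (u2 + aperm(u2, c(2, 1, 4, 3))) / 2
    r <- paircc:::lcc_det_residual(u1, u2, tp0, mi, 2 * no)
    A[, k] <- pack(r$r1, r$r2) - bvec
  }
  Ak <- A[keep, keep]
  sv <- svd(Ak)
  pos <- sv$d > 1e-10 * sv$d[1]
  x <- sv$v[, pos] %*% (crossprod(sv$u[, pos], -bvec[keep]) / sv$d[pos])
  sol <- numeric(nfull); sol[keep] <- x
  s1 <- matrix(sol[1:nt1], no, nv)
  s2 <- array(sol[-(1:nt1)], c(no, no, nv, nv))
  s2 <- (s2 + aperm(s2, c(2, 1, 4, 3))) / 2
  sys <- paircc:::lcc_system(mi, 2 * no, tp0, "lccsd")
  expect_equal(paircc:::lcc_energy(sys, s1, s2),
               lc$E_lcc, tolerance = 1e-9)
})

test_that("forcing t1 = 0 in the LCCSD equations reproduces LCCD", {
  set.seed(35)
  no <- 2; nv <- 3
  mi <- random_mi(no + nv)
  tp <- matrix(rnorm(no * nv), no, nv) * 0.3
  t2 <- random_t2(no, nv)
  r_sd <- lcc_residual(list(t1 = matrix(0, no, nv), t2 = t2), tp, mi,
                       2 * no, "lccsd")
  r_d <- lcc_residual(list(t2 = t2), tp, mi, 2 * no, "lccd")
  expect_equal(r_sd$r2, r_d$r2, tolerance = 1e-12)
})

test_that("the correction energy is additive over noninteracting fragments", {
  res <- mi_for(ao_h2_sto3g())
  mi <- res$mi; n <- mi$n_orb
  h2 <- matrix(0, 2 * n, 2 * n); e2 <- array(0, rep(2 * n, 4))
  h2[1:n, 1:n] <- mi$h; h2[n + 1:n, n + 1:n] <- mi$h
  e2[1:n, 1:n, 1:n, 1:n] <- mi$eri
  e2[n + 1:n, n + 1:n, n + 1:n, n + 1:n] <- mi$eri
  ord <- c(1, n + 1, 2:n, n + 2:n)
  mi2 <- mo_integral_set(h2[ord, ord], eri = e2[ord, ord, ord, ord],
                         core_energy = 2 * mi$core_energy)
  for (variant in c("lccd", "lccsd")) {
    p1 <- solve_pccd(mi, 2); p2 <- solve_pccd(mi2, 4)
    e1 <- solve_lcc(p1$t, mi, 2, variant)$E_lcc
    e2v <- solve_lcc(p2$t, mi2, 4, variant)$E_lcc
    expect_equal(e2v, 2 * e1, tolerance = 1e-9)
  }
})

test_that("an exact two-electron reference leaves nothing for the correction", {
  ao <- ao_h2_sto3g()
  oo <- solve_oopccd(ao, solve_rhf(ao), nfrozen = 0)
  lc <- solve_lcc(oo$pccd$t, oo$mi, 2, "lccd")
  expect_lt(abs(lc$E_lcc), 1e-7)
})

test_that("Lambda equations solve the adjoint system", {
  set.seed(36)
  no <- 2; nv <- 2
  mi <- random_mi(no + nv, vscale = 0.5)
  tp <- matrix(rnorm(no * nv), no, nv) * 0.2
  lc <- solve_lcc_lambda(solve_lcc(tp, mi, 2 * no, "lccsd"))
  sys <- lc$sys
  ## residual of the adjoint equations at the returned lambda
  ap <- paircc:::lcc_apply_terms(sys$terms, sys$bl, sys$tp, lc$l1, lc$l2,
                                 "lccsd", adjoint = TRUE, coef = sys$coef)
  a1 <- ap$r1 + paircc:::lcc_t1_sector_adjoint(sys, lc$l1, lc$l2)
  bl <- sys$bl
  L <- 2 * aperm(bl$g_ovov, c(1, 3, 2, 4)) - aperm(bl$g_ovov, c(1, 3, 4, 2))
  expect_lt(max(abs(a1 + 2 * bl$f_ov)), 1e-7)
  expect_lt(max(abs(paircc:::zero_pair(ap$r2 + L))), 1e-7)
})

test_that("LCC correlation density matches the determinant-space derivative", {
  set.seed(37)
  no <- 2; nv <- 3; norb <- no + nv
  mi <- random_mi(norb, vscale = 0.5)
  tp <- matrix(rnorm(no * nv), no, nv) * 0.2
  det_gamma <- function(t1, t2, l1, l2) {
    occ <- 1:no; virt <- (no + 1):norb
    sp <- paircc:::det_space(norb, 2 * no, "all")
    v0 <- numeric(sp$ndet); v0[paircc:::ref_det_index(sp)] <- 1
    vp <- paircc:::apply_exp_Tp(sp, v0, tp, occ, virt)
    Tpr <- function(v) paircc:::apply_Tprime(sp, v, t1, t2, occ, virt)
    Tvp <- Tpr(vp)
    lbra <- numeric(sp$ndet)
    if (!is.null(l1)) for (i in 1:no) for (a in 1:nv) {
      lbra <- lbra + l1[i, a] *
        paircc:::apply_single(sp, v0, virt[a], occ[i], "a")
    }
    for (i in 1:no) for (j in 1:no) for (a in 1:nv) for (b in 1:nv) {
      if (i == j && a == b) next
      lbra <- lbra + l2[i, j, a, b] *
        paircc:::apply_single(sp,
          paircc:::apply_single(sp, v0, virt[a], occ[i], "a"),
          virt[b], occ[j], "b")
    }
    g <- matrix(0, norb, norb)
    for (p in 1:norb) for (q in 1:norb) {
      Evp <- paircc:::apply_Epq(sp, vp, p, q)
      w <- Evp + paircc:::apply_Epq(sp, Tvp, p, q) - Tpr(Evp)
      g[p, q] <- sum(v0 * paircc:::apply_Epq(sp, Tvp, p, q)) + sum(lbra * w)
    }
    (g + t(g)) / 2
  }
  for (variant in c("lccd", "lccsd")) {
    lc <- solve_lcc_lambda(solve_lcc(tp, mi, 2 * no, variant))
    gp <- lcc_correlation_1rdm(lc)
    gd <- det_gamma(lc$t1, lc$t2, lc$l1, lc$l2)
    expect_lt(max(abs(gp$gamma - gd)), 1e-8)
    expect_lt(abs(sum(diag(gp$gamma))), 1e-8)     # particle conserving
    expect_lt(max(abs(gp$gamma - t(gp$gamma))), 1e-12) # symmetric
  }
})

test_that("combining densities preserves the trace and the identity limit", {
  res <- mi_for(ao_lih_sto3g())
  p <- solve_pccd_lambda(solve_pccd(res$mi, 4), res$mi)
  ref <- pccd_response_1rdm(p)
  expect_identical(combine_rdm(ref, NULL), ref)
  lc <- solve_lcc_lambda(solve_lcc(p$t, res$mi, 4, "lccsd"))
  comb <- combine_rdm(ref, lcc_correlation_1rdm(lc))
  expect_equal(sum(diag(comb$gamma)), 4, tolerance = 1e-8)
})

test_that("LCC on an oo-pCCD reference recovers the FCI density for H2", {
  ao <- ao_h2_sto3g()
  oo <- solve_oopccd(ao, solve_rhf(ao), nfrozen = 0)
  oo$pccd <- solve_pccd_lambda(oo$pccd, oo$mi)
  lc <- solve_lcc_lambda(solve_lcc(oo$pccd$t, oo$mi, 2, "lccsd"))
  comb <- combine_rdm(pccd_response_1rdm(oo$pccd), lcc_correlation_1rdm(lc))
  fci <- dense_fci(oo$mi, 2)
  expect_lt(max(abs(comb$gamma - fci_rdm1(fci))), 1e-6)
})
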