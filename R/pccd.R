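## Pair coupled-cluster doubles (pCCD).
##
## In the seniority-zero sector the electronic Hamiltonian acts as a
## hard-core boson (pairing) Hamiltonian: determinant energies E(Omega) on
## the diagonal and the exchange integrals K_pq = (pq|pq) as pair-hopping
## elements.  The amplitude equations below are derived in that picture and
## certified against the determinant-space oracle
## (projected_residual_check); t is the occupied-pair x virtual amplitude
## matrix of the pair cluster operator.

## ---- integral intermediates ----------------------------------------------

## J_pq = (pp|qq) and K_pq = (pq|pq) for either storage
mo_jk_diag <- function(mi) {
  n <- mi$n_orb
  if (!is.null(mi$eri)) {
    J <- matrix(0, n, n); K <- matrix(0, n, n)
    for (p in 1:n) for (q in 1:n) {
      J[p, q] <- mi$eri[p, p, q, q]
      K[p, q] <- mi$eri[p, q, p, q]
    }
  } else {
    L <- mi$chol # n x n x rank
    r <- dim(L)[3]
    Ld <- t(vapply(seq_len(r), function(p) diag(L[, , p]), numeric(n))) # r x n
    J <- crossprod(Ld)   # J_pq = sum_P L_pp L_qq
    K <- matrix(0, n, n)
    for (p in seq_len(r)) K <- K + L[, , p]^2
  }
  list(J = J, K = K)
}

## closed-shell Fock matrix over the active space, F = h + sum_j [2(pq|jj)
## - (pj|qj)] for j in the occupied-pair set
mo_fock <- function(mi, occ) {
  n <- mi$n_orb
  if (!is.null(mi$eri)) {
    F <- mi$h
    for (j in occ) F <- F + 2 * mi$eri[, , j, j] - mi$eri[, j, , j]
  } else {
    L <- mi$chol
    r <- dim(L)[3]
    F <- mi$h
    for (p in seq_len(r)) {
      Lp <- L[, , p]
      F <- F + 2 * Lp * sum(diag(Lp)[occ]) -
        tcrossprod(Lp[, occ, drop = FALSE])
    }
  }
  (F + t(F)) / 2
}

## ---- residual and Jacobian ------------------------------------------------

pccd_parts <- function(mi, nelec) {
  npair <- nelec / 2
  n <- mi$n_orb
  occ <- seq_len(npair)
  virt <- setdiff(seq_len(n), occ)
  jk <- mo_jk_diag(mi)
  F <- mo_fock(mi, occ)
  J <- jk$J; K <- jk$K
  Fd <- diag(F)
  ## determinant energy gap for the pair excitation i -> a
  Delta <- outer(occ, virt, function(i, a)
    2 * Fd[a] - 2 * Fd[i] + J[cbind(a, a)] + J[cbind(i, i)] -
      4 * J[cbind(i, a)] + 2 * K[cbind(i, a)])
  list(occ = occ, virt = virt, no = npair, nv = length(virt),
       Kov = K[occ, virt, drop = FALSE],
       Koo = K[occ, occ, drop = FALSE],
       Kvv = K[virt, virt, drop = FALSE],
       Delta = Delta, F = F, J = J, K = K)
}

#' pCCD amplitude residual
#'
#' Projected amplitude equations
#' `<Phi_i^a| exp(-T_p) H exp(T_p) |Phi_0>` in closed form (quartic in t);
#' agreement with the determinant-space oracle is part of the test suite.
#'
#' @param t pair-amplitude matrix (occupied pairs x virtuals).
#' @param mi active-space `mo_integrals`.
#' @param nelec active electron count.
#' @return residual matrix, same shape as `t`.
#' @export
pccd_residual <- function(t, mi, nelec) {
  P <- pccd_parts(mi, nelec)
  pccd_residual_parts(t, P)
}

pccd_residual_parts <- function(t, P) {
  Kov <- P$Kov
  lin <- P$Delta - matrix(diag(P$Kvv), P$no, P$nv, byrow = TRUE) -
    matrix(diag(P$Koo), P$no, P$nv)
  Si <- rowSums(Kov * t)           # per occupied i
  Sa <- colSums(Kov * t)           # per virtual a
  M <- crossprod(Kov, t)           # M[b, a] = sum_j K_jb t_ja
  Kov + lin * t + t %*% P$Kvv + P$Koo %*% t + t %*% M -
    2 * t * (matrix(Si, P$no, P$nv) + matrix(Sa, P$no, P$nv, byrow = TRUE)) +
    2 * Kov * t^2
}

## analytic Jacobian d R_ia / d t_jb as a (no*nv) x (no*nv) matrix
## (row-major over (i,a) with i fastest)
pccd_jacobian_parts <- function(t, P) {
  no <- P$no; nv <- P$nv
  Kov <- P$Kov; Koo <- P$Koo; Kvv <- P$Kvv
  Si <- rowSums(Kov * t)
  Sa <- colSums(Kov * t)
  M <- crossprod(Kov, t)          # M[b,a] = sum_j K_jb t_ja
  N <- t %*% t(Kov)               # N[i,j] = sum_b t_ib K_jb
  lin <- P$Delta - matrix(diag(Kvv), no, nv, byrow = TRUE) -
    matrix(diag(Koo), no, nv)
  nt <- no * nv
  Jac <- matrix(0, nt, nt)
  idx <- function(i, a) (a - 1) * no + i
  for (j in seq_len(no)) for (b in seq_len(nv)) {
    col <- matrix(0, no, nv)
    ## delta_ij delta_ab part
    col[j, b] <- lin[j, b] - 2 * (Si[j] + Sa[b]) + 4 * Kov[j, b] * t[j, b]
    ## delta_ij part (i = j, all a)
    col[j, ] <- col[j, ] + Kvv[b, ] + M[b, ] - 2 * t[j, ] * Kov[j, b]
    ## delta_ab part (a = b, all i)
    col[, b] <- col[, b] + Koo[, j] + N[, j] - 2 * t[, b] * Kov[j, b]
    Jac[, idx(j, b)] <- as.numeric(col)
  }
  Jac
}

## ---- solvers ---------------------------------------------------------------

#' Solve the pCCD amplitude equations
#'
#' Newton iterations with the exact analytic Jacobian (the amplitude space
#' is small: occupied pairs x virtuals), damped on residual increase.
#'
#' @param mi active-space `mo_integrals`.
#' @param nelec active electron count.
#' @param guess starting amplitudes (default: perturbative
#'   `K_ia / (2F_ii - 2F_aa)`).
#' @param tol residual max-norm convergence threshold.
#' @param max_iter iteration cap.
#' @return `pccd_result` with `E_ref` (reference determinant energy +
#'   core), `E_corr`, `energy`, amplitude matrix `t`, `iterations`.
#' @export
solve_pccd <- function(mi, nelec, guess = NULL, tol = 1e-10, max_iter = 50) {
  P <- pccd_parts(mi, nelec)
  occ <- P$occ
  Fd <- diag(P$F)
  ## MP2-like pair guess; degenerate denominators shifted
  den <- outer(2 * Fd[occ], 2 * Fd[P$virt], "-")
  den[abs(den) < 1e-6] <- -0.1
  t <- if (is.null(guess)) P$Kov / den else guess
  E_ref <- 2 * sum(mi$h[cbind(occ, occ)]) +
    sum(2 * P$J[occ, occ, drop = FALSE] - P$K[occ, occ, drop = FALSE]) +
    mi$core_energy
  it <- 0; converged <- FALSE
  r <- pccd_residual_parts(t, P)
  while (it < max_iter) {
    it <- it + 1
    Jac <- pccd_jacobian_parts(t, P)
    dt <- tryCatch(solve(Jac, -as.numeric(r)), error = function(e) NULL)
    if (is.null(dt)) stop("pCCD Newton step failed: singular Jacobian")
    step <- 1
    repeat {
      t_new <- t + step * matrix(dt, P$no, P$nv)
      r_new <- pccd_residual_parts(t_new, P)
      if (max(abs(r_new)) < max(abs(r)) || step < 1 / 64) break
      step <- step / 2
    }
    t <- t_new; r <- r_new
    if (max(abs(r)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("pCCD not converged after %d iterations (residual %g)",
                 it, max(abs(r))))
  }
  E_corr <- sum(P$Kov * t)
  structure(list(E_ref = E_ref, E_corr = E_corr, energy = E_ref + E_corr,
                 t = t, lam = NULL, iterations = it, nelec = nelec,
                 occ = P$occ, virt = P$virt, converged = converged,
                 jacobian = pccd_jacobian_parts(t, P), Kov = P$Kov),
            class = "pccd_result")
}

#' @export
print.pccd_result <- function(x, ...) {
  cat(sprintf("pCCD: E_ref = %.10f, E_corr = %.10f, E = %.10f Ha (%d iterations)\n",
              x$E_ref, x$E_corr, x$energy, x$iterations))
  invisible(x)
}

#' Solve the pCCD Lambda (pair de-excitation) equations
#'
#' The Lagrangian stationarity conditions with respect to the amplitudes
#' are the linear adjoint equations `J^T lambda = -dE/dt` with `J` the
#' amplitude-equation Jacobian; they are solved directly.
#'
#' @param pccd converged `pccd_result`.
#' @param mi the `mo_integrals` used for the amplitude solve.
#' @return the `pccd_result` with a `lam` field added (matrix indexed like
#'   `t`; `lam[i, a]` is the de-excitation amplitude lambda_{ai}).
#' @export
solve_pccd_lambda <- function(pccd, mi) {
  if (!is.null(pccd$jacobian)) {
    Jac <- pccd$jacobian
    Kov <- pccd$Kov
  } else {
    P <- pccd_parts(mi, pccd$nelec)
    Jac <- pccd_jacobian_parts(pccd$t, P)
    Kov <- P$Kov
  }
  rhs <- -as.numeric(Kov) # dE_corr/dt_ia = K_ia
  lam <- tryCatch(solve(t(Jac), rhs), error = function(e)
    stop("pCCD Lambda equations singular: degenerate reference"))
  pccd$lam <- matrix(lam, nrow(pccd$t), ncol(pccd$t))
  pccd
}

## ---- response density matrices --------------------------------------------

## response expectation values of the seniority-zero operators; all RDM
## blocks are assembled from these.
pccd_expectations <- function(t, lam) {
  no <- nrow(t); nv <- ncol(t)
  tls <- t * lam
  tl_i <- rowSums(tls)   # sum_a t_ia l_ia
  tl_a <- colSums(tls)   # sum_i t_ia l_ia
  S1 <- sum(tls)
  rS <- matrix(tl_i, no, nv)              # broadcast over a
  cS <- matrix(tl_a, no, nv, byrow = TRUE) # broadcast over i
  ## <n_p n_q> blocks (response expectations)
  nn_oo <- 1 - outer(tl_i, rep(1, no)) - outer(rep(1, no), tl_i)
  diag(nn_oo) <- 1 - tl_i    # <n_i n_i> = <n_i> (hard-core occupations)
  nn_ov <- cS - tls          # <n_i n_a> = sum_{j != i} t_ja l_ja
  nn_vv <- matrix(0, nv, nv)
  diag(nn_vv) <- tl_a
  ## pair-transfer <b_p^+ b_q>
  bb_vo <- t(lam)                          # <b_a^+ b_i> = lambda_ai
  bb_oo <- t %*% t(lam)                    # i != j: sum_b t_ib l_jb
  bb_vv <- crossprod(lam, t)               # a != b: sum_j l_ja t_jb
  ## <b_i^+ b_a> = t_ia + sum_{j!=i,b!=a} l_jb (t_ia t_jb + t_ib t_ja)
  ##              - t_ia S1; inclusion-exclusion collapses to:
  M <- t %*% t(lam)        # M[i,j] = sum_b t_ib l_jb
  bb_ov <- t + M %*% t - 2 * t * (rS + cS) + 2 * t^2 * lam
  list(n_o = 1 - tl_i, n_v = tl_a,
       nn_oo = nn_oo, nn_ov = nn_ov, nn_vv = nn_vv,
       bb_vo = bb_vo, bb_ov = bb_ov, bb_oo = bb_oo, bb_vv = bb_vv,
       tl = S1)
}

#' pCCD response one-particle density matrix
#'
#' Diagonal in the pCCD orbital basis (seniority-zero structure):
#' `gamma_ii = 2(1 - sum_a t_ia lam_ia)`, `gamma_aa = 2 sum_i t_ia lam_ia`.
#' The trace equals the active electron count identically.
#'
#' @param pccd `pccd_result` with Lambda solved (see
#'   [solve_pccd_lambda()]).
#' @return `onerdm` object (matrix with attributes).
#' @export
pccd_response_1rdm <- function(pccd) {
  if (is.null(pccd$lam)) stop("solve the pCCD Lambda equations first")
  t <- pccd$t; lam <- pccd$lam
  n <- length(pccd$occ) + length(pccd$virt)
  g <- numeric(n)
  g[pccd$occ] <- 2 * (1 - rowSums(t * lam))
  g[pccd$virt] <- 2 * colSums(t * lam)
  gamma <- diag(g, n)
  new_onerdm(gamma, nelec = pccd$nelec)
}

## container for one-particle densities
new_onerdm <- function(gamma, nelec) {
  structure(list(gamma = gamma, nelec = nelec), class = "onerdm")
}

#' @export
print.onerdm <- function(x, ...) {
  cat(sprintf("1-RDM: %d orbitals, trace %.10f\n", nrow(x$gamma),
              sum(diag(x$gamma))))
  invisible(x)
}

#' pCCD response two-particle density blocks
#'
#' The seniority-zero response 2-RDM: pair-transfer block
#' `<b_p^+ b_q>` and the diagonal occupation-correlation block
#' `<n_p n_q>`.  Contracting them with the integrals reproduces the pCCD
#' energy (tested).
#'
#' @param pccd `pccd_result` with Lambda solved.
#' @return list with matrices `nn` (n x n) and `pair` (n x n) in the full
#'   active MO basis.
#' @export
pccd_response_2rdm <- function(pccd) {
  if (is.null(pccd$lam)) stop("solve the pCCD Lambda equations first")
  ex <- pccd_expectations(pccd$t, pccd$lam)
  occ <- pccd$occ; virt <- pccd$virt
  n <- length(occ) + length(virt)
  nn <- matrix(0, n, n); pair <- matrix(0, n, n)
  nn[occ, occ] <- ex$nn_oo
  nn[occ, virt] <- ex$nn_ov
  nn[virt, occ] <- t(ex$nn_ov)
  nn[virt, virt] <- ex$nn_vv
  pair[occ, occ] <- ex$bb_oo
  diag(pair)[occ] <- ex$n_o
  pair[virt, occ] <- ex$bb_vo
  pair[occ, virt] <- ex$bb_ov
  pair[virt, virt] <- ex$bb_vv
  diag(pair)[virt] <- ex$n_v
  list(nn = nn, pair = pair)
}

## energy from the response RDMs (internal identity used in tests):
## E = 2 sum_p h_pp <n_p> + sum_p J_pp <n_p> + sum_{p!=q} (2J-K)_pq <n_p n_q>
##     + sum_{p!=q} K_pq <b_p^+ b_q> + core
pccd_energy_from_rdm <- function(rdm2, mi) {
  jk <- mo_jk_diag(mi)
  n <- mi$n_orb
  npq <- rdm2$nn; bpq <- rdm2$pair
  dn <- diag(npq)
  offd <- npq; diag(offd) <- 0
  offb <- bpq; diag(offb) <- 0
  2 * sum(diag(mi$h) * dn) + sum(diag(jk$J) * dn) +
    sum((2 * jk$J - jk$K) * offd) + sum(jk$K * offb) + mi$core_energy
}
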