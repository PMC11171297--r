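## Variational orbital optimization of the pCCD energy (oo-pCCD).
##
## The energy is minimized over orthogonal rotations C -> C exp(kappa) of
## the active orbitals (occupied-occupied, occupied-virtual and
## virtual-virtual rotations are all active: the pCCD energy is not
## invariant under any of them).  Frozen-core orbitals are excluded from
## the rotation; their mean field is folded into the active one-electron
## operator at the AO level.  The orbital gradient is the generalized-Fock
## expression contracted with the pCCD response densities; each gradient
## is evaluated at a fresh expansion point, and steps are taken by a
## limited-memory quasi-Newton update with an energy-decrease line search
## and a trust cap on the rotation angle.

## exp(kappa) for antisymmetric kappa via scaling-and-squaring series,
## polished to exact orthogonality
expm_antisym <- function(K) {
  nrm <- max(abs(K))
  if (nrm == 0) return(diag(nrow(K)))
  s <- max(0, ceiling(log2(nrm / 0.25)))
  A <- K / 2^s
  X <- diag(nrow(K))
  term <- X
  for (k in 1:30) {
    term <- term %*% A / k
    X <- X + term
    if (max(abs(term)) < 1e-16) break
  }
  for (k in seq_len(s)) X <- X %*% X
  sv <- svd(X)
  sv$u %*% t(sv$v)
}

## Re-orthonormalize warm-start orbitals against a (new) overlap matrix:
## project out the fixed block (frozen core), then Loewdin-orthonormalize.
## Used when orbitals are carried between neighbouring scan geometries.
orthonormalize_against <- function(C, S, C_fixed = NULL) {
  if (!is.null(C_fixed) && ncol(C_fixed) > 0) {
    C <- C - C_fixed %*% (crossprod(C_fixed, S %*% C))
  }
  M <- crossprod(C, S %*% C)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- es$values > 1e-8
  if (!all(keep)) stop("warm-start orbitals became linearly dependent")
  C %*% (es$vectors %*% (t(es$vectors) / sqrt(es$values)))
}

## Frozen-core environment at fixed core orbitals: effective one-electron
## operator (AO), core energy (incl. nuclear), frozen-core dipole.
freeze_core_env <- function(aoints, C_full, nfrozen) {
  n <- aoints$nbf
  if (nfrozen == 0) {
    return(list(heff = aoints$Hcore, e_core = aoints$enuc,
                frozen_dipole = c(0, 0, 0), nfrozen = 0L))
  }
  Cc <- C_full[, seq_len(nfrozen), drop = FALSE]
  Dc <- 2 * tcrossprod(Cc)
  jk <- fock_jk(Dc, aoints$eri, aoints$chol)
  heff <- aoints$Hcore + jk$J - 0.5 * jk$K
  e_core <- 0.5 * sum(Dc * (aoints$Hcore + heff)) + aoints$enuc
  fdip <- unname(vapply(aoints$dipole, function(d) -sum(Dc * d), 0)) # electronic, a.u.
  list(heff = heff, e_core = e_core, frozen_dipole = fdip,
       nfrozen = as.integer(nfrozen))
}

## Active-space MO integrals at given active orbitals.
active_space_ints <- function(aoints, env, C_act) {
  h <- crossprod(C_act, env$heff %*% C_act)
  h <- (h + t(h)) / 2
  dip <- lapply(aoints$dipole, function(d) {
    m <- crossprod(C_act, d %*% C_act); (m + t(m)) / 2
  })
  nact <- ncol(C_act)
  if (!is.null(aoints$chol)) {
    r <- ncol(aoints$chol)
    nao <- aoints$nbf
    ## batched half-transforms: L'[p,q,P] = C^T L^P C for all P at once
    T1 <- crossprod(C_act, matrix(aoints$chol, nao, nao * r))
    T1 <- aperm(array(T1, c(nact, nao, r)), c(2, 1, 3))
    T2 <- crossprod(C_act, matrix(T1, nao, nact * r))
    Lact <- array(T2, c(nact, nact, r))
    mo_integral_set(h, chol = Lact, core_energy = env$e_core, dipole = dip,
                    frozen_dipole = env$frozen_dipole)
  } else {
    eri <- transform_eri_index(aoints$eri, t(C_act))
    mo_integral_set(h, eri = eri, core_energy = env$e_core, dipole = dip,
                    frozen_dipole = env$frozen_dipole)
  }
}

## Three-index integral slices for the generalized Fock:
##   A[n,m,r] = (nm|rr),  X[n,m,q] = (nq|mq)  (= (nq|qm), real orbitals)
gradient_3idx <- function(mi) {
  n <- mi$n_orb
  if (!is.null(mi$eri)) {
    A <- array(0, c(n, n, n)); X <- array(0, c(n, n, n))
    for (r in 1:n) {
      A[, , r] <- mi$eri[, , r, r]
      X[, , r] <- mi$eri[, r, , r]
    }
  } else {
    L <- mi$chol
    r <- dim(L)[3]
    Ld <- t(vapply(seq_len(r), function(p) diag(L[, , p]), numeric(n))) # r x n
    A <- array(matrix(L, n * n, r) %*% Ld, c(n, n, n))
    X <- array(0, c(n, n, n))
    for (q in 1:n) {
      Lq <- matrix(L[, q, ], n, r)
      X[, , q] <- tcrossprod(Lq)
    }
  }
  list(A = A, X = X)
}

#' oo-pCCD orbital gradient
#'
#' Generalized-Fock gradient `g = 2(F~ - F~^T)` built from the pCCD
#' response one- and two-particle densities; verified against finite
#' differences of the energy in the test suite.
#'
#' @param mi active-space `mo_integrals`.
#' @param pccd converged `pccd_result` with Lambda solved.
#' @return antisymmetric matrix `dE/dkappa` over active orbitals.
#' @export
orbital_gradient <- function(mi, pccd) {
  rdm2 <- pccd_response_2rdm(pccd)
  g1 <- pccd_response_1rdm(pccd)
  n <- mi$n_orb
  tix <- gradient_3idx(mi)
  gdiag <- diag(g1$gamma)
  ## w1[m,r]: coefficient of (nm|rr); diagonal r = m is the 2<n_m> term
  w1 <- 4 * rdm2$nn
  diag(w1) <- 2 * diag(rdm2$nn)
  ## w3[m,q]: coefficient of (nq|mq) for q != m; the pair-transfer block is
  ## non-Hermitian (lambda vs t) and enters permutation-symmetrized
  pair_s <- (rdm2$pair + t(rdm2$pair)) / 2
  w3 <- 2 * (pair_s - rdm2$nn)
  diag(w3) <- 0
  Ft <- gdiag * mi$h        # F~[m,n] = gamma_mm h_nm (h symmetric)
  for (m in 1:n) {
    Ft[m, ] <- Ft[m, ] + tix$A[, m, ] %*% w1[m, ] + tix$X[, m, ] %*% w3[m, ]
  }
  ## sign fixed against finite differences of E(C exp(kappa))
  2 * (t(Ft) - Ft)
}

## pack/unpack antisymmetric matrices
kappa_pack <- function(K) K[upper.tri(K)]
kappa_unpack <- function(x, n) {
  K <- matrix(0, n, n)
  K[upper.tri(K)] <- x
  K - t(K)
}

#' Orbital-optimized pCCD
#'
#' Minimizes the pCCD energy over orthogonal rotations of the active
#' orbitals.  Macro-iterations: (re-)solve the pCCD amplitude and Lambda
#' equations, form the response-density orbital gradient, take a
#' quasi-Newton step with line search; converged when the gradient
#' max-norm and the energy change fall below the thresholds.
#'
#' @param aoints `ao_integrals` (dense or Cholesky two-electron storage).
#' @param scf converged `scf_result` (or an AO x MO coefficient matrix).
#' @param nfrozen number of frozen-core orbitals; `"auto"` applies the
#'   nonvalence rule of [count_core_orbitals()].
#' @param localize `"none"`, `"occupied"`, or `"both"`: Pipek-Mezey
#'   localization of the starting orbital blocks (speeds up and stabilizes
#'   the optimization away from equilibrium).
#' @param conv_grad gradient max-norm threshold.
#' @param conv_e energy-change threshold.
#' @param max_iter cap on gradient evaluations.
#' @param trust initial cap on the largest rotation angle per step (rad).
#' @param memory L-BFGS history length.
#' @param verbose print per-iteration energies.
#' @return `oopccd_result`: active orbitals `C_act` (AO basis), full
#'   `mocoeffs`, the converged `pccd` result (with Lambda), active-space
#'   integrals `mi`, `energy`, `orbital_gradient_norm`, `iterations`,
#'   `energy_trace`.
#' @export
solve_oopccd <- function(aoints, scf, nfrozen = "auto",
                         localize = c("none", "occupied", "both"),
                         conv_grad = 1e-6, conv_e = 1e-9,
                         max_iter = 300, trust = 0.3, memory = 12,
                         verbose = FALSE) {
  localize <- match.arg(localize)
  C_full <- if (inherits(scf, "scf_result")) scf$mocoeffs$C else scf
  nelec_tot <- aoints$molecule$n_electrons
  if (identical(nfrozen, "auto")) nfrozen <- count_core_orbitals(aoints$molecule)
  nfrozen <- as.integer(nfrozen)
  nocc_tot <- nelec_tot / 2
  nelec_act <- nelec_tot - 2L * nfrozen
  if (localize != "none") {
    ao_atom <- rep(vapply(aoints$shells, `[[`, 0L, "atom"),
                   2L * vapply(aoints$shells, `[[`, 0L, "l") + 1L)
    occ_block <- setdiff(seq_len(nocc_tot), seq_len(nfrozen))
    if (length(occ_block) > 1) {
      C_full <- pipek_mezey_localize(C_full, aoints$S, ao_atom, occ_block)$C
    }
    if (localize == "both" && nocc_tot < ncol(C_full) - 1) {
      C_full <- pipek_mezey_localize(C_full, aoints$S, ao_atom,
                                     (nocc_tot + 1):ncol(C_full))$C
    }
  }
  env <- freeze_core_env(aoints, C_full, nfrozen)
  C_act <- C_full[, setdiff(seq_len(ncol(C_full)), seq_len(nfrozen)),
                  drop = FALSE]
  nact <- ncol(C_act)

  tp_guess <- NULL
  eval_point <- function(C) {
    mi <- active_space_ints(aoints, env, C)
    p <- tryCatch(solve_pccd(mi, nelec_act, guess = tp_guess),
                  error = function(e) solve_pccd(mi, nelec_act))
    tp_guess <<- p$t
    list(mi = mi, pccd = p, E = p$energy)
  }
  with_lambda <- function(pt) {
    if (is.null(pt$pccd$lam)) pt$pccd <- solve_pccd_lambda(pt$pccd, pt$mi)
    pt
  }
  ## Hessian-model preconditioner.  The occupied-virtual block is treated
  ## in the semicanonical basis (eigenbases of the occupied and virtual
  ## Fock blocks) with 4*(e_a - e_i) curvatures - essential because the
  ## optimized orbitals leave the Fock matrix far from diagonal.  The
  ## occupied-occupied and virtual-virtual rotations, whose curvature comes
  ## from the pair-correlation terms, use a floored diagonal estimate.
  npair_act <- nelec_act / 2
  occ_idx <- seq_len(npair_act)
  virt_idx <- setdiff(seq_len(nact), occ_idx)
  precond_make <- function(cur) {
    F <- mo_fock(cur$mi, occ_idx)
    eo <- eigen((F[occ_idx, occ_idx] + t(F[occ_idx, occ_idx])) / 2,
                symmetric = TRUE)
    ev <- eigen((F[virt_idx, virt_idx] + t(F[virt_idx, virt_idx])) / 2,
                symmetric = TRUE)
    gap <- outer(ev$values, eo$values, "-")
    gap <- 4 * pmax(gap, 0.05)
    gd <- diag(pccd_response_1rdm(cur$pccd)$gamma)
    fd <- diag(F)
    Hd <- pmax(abs(2 * outer(gd, gd, "-") * outer(fd, fd, "-")), 0.1)
    function(qv) {
      K <- kappa_unpack(qv, nact)
      Gov <- K[occ_idx, virt_idx, drop = FALSE]
      Gov <- eo$vectors %*% ((crossprod(eo$vectors, Gov %*% ev$vectors)) / t(gap)) %*%
        t(ev$vectors)
      K[occ_idx, virt_idx] <- Gov
      K[virt_idx, occ_idx] <- -t(Gov)
      K[occ_idx, occ_idx] <- K[occ_idx, occ_idx, drop = FALSE] /
        Hd[occ_idx, occ_idx]
      K[virt_idx, virt_idx] <- K[virt_idx, virt_idx, drop = FALSE] /
        Hd[virt_idx, virt_idx]
      kappa_pack(K)
    }
  }

  cur <- with_lambda(eval_point(C_act))
  g <- orbital_gradient(cur$mi, cur$pccd)
  gv <- kappa_pack(g)
  e_trace <- cur$E
  it <- 0L
  gmax <- max(abs(gv))
  ## Newton-CG: the Hessian-vector product is a forward difference of the
  ## fixed-amplitude orbital gradient (amplitude relaxation enters only
  ## through the outer exact gradients), preconditioned by the
  ## semicanonical model.
  fd_h <- 1e-4
  grad_fixed <- function(C) {
    mi <- active_space_ints(aoints, env, C)
    kappa_pack(orbital_gradient(mi, cur$pccd))
  }
  while (gmax > conv_grad && it < max_iter) {
    it <- it + 1L
    P0 <- precond_make(cur)
    g0_fixed <- grad_fixed(C_act)
    hv <- function(v) {
      nrm <- sqrt(sum(v^2))
      if (nrm == 0) return(v)
      K <- kappa_unpack(fd_h * v / nrm, nact)
      (grad_fixed(C_act %*% expm_antisym(K)) - g0_fixed) * (nrm / fd_h)
    }
    ## Steihaug preconditioned CG on H d = -g: stops at the trust-region
    ## boundary or on (near-)negative curvature
    Delta <- trust
    d <- numeric(length(gv))
    r <- -gv
    z <- P0(r)
    p <- z
    rz <- sum(r * z)
    for (cg in seq_len(25)) {
      Hp <- hv(p)
      pHp <- sum(p * Hp)
      if (pHp <= 1e-8 * sum(p^2)) {
        if (cg == 1) {
          d <- z
          if (sqrt(sum(d^2)) > Delta) d <- d * Delta / sqrt(sum(d^2))
        }
        break
      }
      alpha <- rz / pHp
      d_new <- d + alpha * p
      if (sqrt(sum(d_new^2)) > Delta) {
        ## step to the boundary along p
        a <- sum(p^2); b <- 2 * sum(d * p); cc <- sum(d^2) - Delta^2
        tau <- (-b + sqrt(max(b^2 - 4 * a * cc, 0))) / (2 * a)
        d <- d + tau * p
        break
      }
      d <- d_new
      r <- r - alpha * Hp
      if (sqrt(sum(r^2)) < 0.05 * sqrt(sum(gv^2))) break
      z <- P0(r)
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    if (sum(d^2) == 0) {
      d <- P0(-gv)
      if (sqrt(sum(d^2)) > Delta) d <- d * Delta / sqrt(sum(d^2))
    }
    step <- d
    accepted <- FALSE
    for (ls in 1:8) {
      K <- kappa_unpack(step, nact)
      C_try <- C_act %*% expm_antisym(K)
      new <- tryCatch(eval_point(C_try), error = function(e) NULL)
      if (!is.null(new) && new$E <= cur$E + 1e-12) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    new <- with_lambda(new)
    g_new <- orbital_gradient(new$mi, new$pccd)
    gv_new <- kappa_pack(g_new)
    de <- cur$E - new$E
    C_act <- C_try; cur <- new; gv <- gv_new
    gmax <- max(abs(gv))
    e_trace <- c(e_trace, cur$E)
    if (verbose) {
      message(sprintf("  oo-pCCD it %3d  E = %.10f  |g|max = %.2e", it, cur$E, gmax))
    }
    if (de < conv_e && gmax < 100 * conv_grad) break
  }
  C_all <- cbind(C_full[, seq_len(nfrozen), drop = FALSE], C_act)
  structure(
    list(C_act = C_act, nfrozen = nfrozen,
         mocoeffs = mo_coefficients(C_all, nelec_tot,
                                    frozen_core = seq_len(nfrozen)),
         pccd = cur$pccd, mi = cur$mi, energy = cur$E,
         orbital_gradient_norm = gmax, iterations = it,
         energy_trace = e_trace,
         converged = gmax <= conv_grad ||
           (length(e_trace) > 1 && abs(diff(tail(e_trace, 2))) < conv_e)),
    class = "oopccd_result")
}

#' @export
print.oopccd_result <- function(x, ...) {
  cat(sprintf("oo-pCCD: E = %.10f Ha (|g|max = %.2e, %d gradient evaluations)\n",
              x$energy, x$orbital_gradient_norm, x$iterations))
  invisible(x)
}

#' Relaxed reference one-particle density of oo-pCCD
#'
#' At the variational orbital optimum the orbital-response terms vanish,
#' so the relaxed reference density is the pCCD response density expressed
#' in the optimized orbital basis.
#'
#' @param oo `oopccd_result`.
#' @param tol gradient norm above which the result is refused.
#' @return `onerdm` in the optimized active MO basis.
#' @export
relaxed_reference_rdm <- function(oo, tol = 1e-4) {
  if (oo$orbital_gradient_norm > tol) {
    stop("orbital gradient not converged (", format(oo$orbital_gradient_norm),
         "); the relaxed-density identity requires the variational optimum")
  }
  pccd_response_1rdm(oo$pccd)
}
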