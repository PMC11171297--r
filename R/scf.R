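## Restricted Hartree-Fock with DIIS acceleration, plus Pipek-Mezey
## localization of orbital blocks.

## J/K builds from either dense AO two-electron integrals or Cholesky
## factors (npair x rank matrix, columns L^P reshaped n x n).
fock_jk <- function(D, eri = NULL, chol = NULL) {
  n <- nrow(D)
  if (!is.null(chol)) {
    J <- matrix(0, n, n); K <- matrix(0, n, n)
    r <- ncol(chol)
    dv <- as.numeric(D)
    w <- drop(crossprod(chol, dv)) # sum_{mu nu} L^P_{mu nu} D_{mu nu}
    J <- matrix(chol %*% w, n, n)
    for (p in seq_len(r)) {
      Lp <- matrix(chol[, p], n, n)
      K <- K + Lp %*% D %*% Lp
    }
    list(J = J, K = K)
  } else {
    n2 <- n * n
    J <- matrix(matrix(eri, n2, n2) %*% as.numeric(D), n, n)
    ## K_pq = sum_kl D_kl (pk|ql)
    Ex <- aperm(eri, c(1, 3, 2, 4))
    K <- matrix(matrix(Ex, n2, n2) %*% as.numeric(D), n, n)
    list(J = J, K = K)
  }
}

#' Restricted Hartree-Fock
#'
#' Closed-shell SCF with a diagonalized-core-Hamiltonian initial guess and
#' DIIS acceleration.  Converged when `max|FDS - SDF| < conv_grad` and
#' `|dE| < conv_e`.
#'
#' @param aoints `ao_integrals` (dense `eri` or a `chol` field from
#'   [cholesky_decompose()]).
#' @param nelec electron count (default: from the molecule).
#' @param conv_grad,conv_e convergence thresholds.
#' @param max_iter iteration cap.
#' @param level_shift virtual-orbital level shift in hartree (0 = off);
#'   useful for stretched geometries where plain SCF oscillates.
#' @param C0 optional starting orbitals (AO x MO) for warm starts.
#' @return `scf_result`: `mocoeffs`, `orbital_energies`, `E_total`,
#'   `converged`, `iterations`, `fock`, `density`.
#' @export
solve_rhf <- function(aoints, nelec = NULL, conv_grad = 1e-8, conv_e = 1e-10,
                      max_iter = 200, level_shift = 0, C0 = NULL) {
  if (is.null(nelec)) nelec <- aoints$molecule$n_electrons
  if (nelec %% 2 != 0) stop("RHF needs an even electron count")
  n <- aoints$nbf
  if (nelec > 2 * n) stop("more electrons than 2 x basis functions")
  nocc <- nelec / 2
  S <- aoints$S; H <- aoints$Hcore
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    keep <- es$values > 1e-9
    X <- es$vectors[, keep] %*% diag(1 / sqrt(es$values[keep]))
  } else {
    X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  }
  orth_diag <- function(F) {
    Fo <- crossprod(X, F %*% X)
    ee <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(ee$values)
    list(C = X %*% ee$vectors[, ord], eps = ee$values[ord])
  }
  C <- if (is.null(C0)) orth_diag(H)$C else C0
  Cocc <- C[, seq_len(nocc), drop = FALSE]
  D <- 2 * tcrossprod(Cocc)
  E_old <- Inf
  err_list <- list(); F_list <- list()
  converged <- FALSE; it <- 0; E <- NA_real_; eps <- NULL
  while (it < max_iter) {
    it <- it + 1
    jk <- fock_jk(D, aoints$eri, aoints$chol)
    F <- H + jk$J - 0.5 * jk$K
    E <- 0.5 * sum(D * (H + F)) + aoints$enuc
    err <- F %*% D %*% S - S %*% D %*% F
    gmax <- max(abs(err))
    if (gmax < conv_grad && abs(E - E_old) < conv_e) { converged <- TRUE }
    E_old <- E
    ## DIIS over the orthonormal-basis error
    err_list[[length(err_list) + 1]] <- crossprod(X, err %*% X)
    F_list[[length(F_list) + 1]] <- F
    if (length(F_list) > 8) { err_list <- err_list[-1]; F_list <- F_list[-1] }
    m <- length(F_list)
    Fd <- F
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (i in 1:m) for (j in 1:m) B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(numeric(m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        Fd <- matrix(0, n, n)
        for (i in 1:m) Fd <- Fd + cf[i] * F_list[[i]]
      }
    }
    if (level_shift > 0) {
      ## shift virtual space: F + shift * S (I - D S / 2)-projector
      Q <- S - S %*% D %*% S / 2
      Fd <- Fd + level_shift * Q
    }
    od <- orth_diag(Fd)
    C <- od$C; eps <- od$eps
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * tcrossprod(Cocc)
    if (converged) break
  }
  if (!converged) {
    warning(sprintf("RHF not converged after %d iterations (E = %.10f)", it, E))
  }
  if (level_shift > 0 && converged) {
    ## recompute clean orbital energies without the shift
    jk <- fock_jk(D, aoints$eri, aoints$chol)
    F <- H + jk$J - 0.5 * jk$K
    od <- orth_diag(F)
    C <- od$C; eps <- od$eps
    E <- 0.5 * sum((2 * tcrossprod(C[, seq_len(nocc)])) * (H + F)) + aoints$enuc
  }
  structure(
    list(mocoeffs = mo_coefficients(C, nelec),
         orbital_energies = eps, E_total = E, converged = converged,
         iterations = it, density = D),
    class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("RHF: E = %.10f Ha (%s, %d iterations)\n", x$E_total,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Pipek-Mezey orbital localization
#'
#' Maximizes the sum of squared Mulliken atomic charges of each orbital by
#' 2x2 Jacobi rotations within one orbital block (occupied or virtual);
#' occupied-virtual mixing never occurs because only the listed columns are
#' rotated.  The SCF energy is invariant under these rotations.
#'
#' @param C AO x MO coefficient matrix.
#' @param S AO overlap.
#' @param ao_atom integer vector: owning atom of each AO.
#' @param block integer vector of MO columns to localize.
#' @param max_sweeps sweep cap.
#' @param tol convergence threshold on the largest rotation angle (rad).
#' @return list with rotated `C`, the final PM functional `value`, number
#'   of `sweeps`, and the per-sweep functional `trace` (non-decreasing).
#' @export
pipek_mezey_localize <- function(C, S, ao_atom, block, max_sweeps = 200,
                                 tol = 1e-8) {
  block <- as.integer(block)
  natom <- max(ao_atom)
  if (length(block) < 2) {
    return(list(C = C, value = NA_real_, sweeps = 0L, trace = numeric(0)))
  }
  SC <- S %*% C
  pm_value <- function() {
    v <- 0
    for (i in block) {
      q <- rowsum(C[, i] * SC[, i], ao_atom)
      v <- v + sum(q^2)
    }
    v
  }
  qmat <- function(i, j) {
    ## Mulliken transition charges per atom
    drop(rowsum(0.5 * (C[, i] * SC[, j] + C[, j] * SC[, i]), ao_atom))
  }
  trace <- pm_value()
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    max_ang <- 0
    for (ii in seq_along(block)[-length(block)]) {
      for (jj in (ii + 1):length(block)) {
        i <- block[ii]; j <- block[jj]
        Qii <- qmat(i, i); Qjj <- qmat(j, j); Qij <- qmat(i, j)
        A <- sum(Qij^2 - 0.25 * (Qii - Qjj)^2)
        B <- sum(Qij * (Qii - Qjj))
        if (A^2 + B^2 < 1e-24) next
        gamma <- 0.25 * atan2(B, -A)
        ## degenerate rotation angles: prefer the smaller |angle| solution
        if (gamma > pi / 4) gamma <- gamma - pi / 2
        if (gamma < -pi / 4) gamma <- gamma + pi / 2
        if (abs(gamma) < 1e-12) next
        max_ang <- max(max_ang, abs(gamma))
        cg <- cos(gamma); sg <- sin(gamma)
        ci <- C[, i]; cj <- C[, j]
        C[, i] <- cg * ci + sg * cj
        C[, j] <- -sg * ci + cg * cj
        sci <- SC[, i]; scj <- SC[, j]
        SC[, i] <- cg * sci + sg * scj
        SC[, j] <- -sg * sci + cg * scj
      }
    }
    trace <- c(trace, pm_value())
    if (max_ang < tol || sweeps >= max_sweeps) break
  }
  list(C = C, value = trace[length(trace)], sweeps = sweeps, trace = trace)
}
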