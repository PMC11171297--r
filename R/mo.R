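## Molecular-orbital integral containers: AO->MO transformation, Cholesky
## vectors in MO basis, frozen-core folding, and the MO coefficient
## bookkeeping (frozen core / occupied pairs / virtuals partition).

#' MO coefficient container
#'
#' @param C AO x MO coefficient matrix.
#' @param nelec total electron count carried by these orbitals.
#' @param frozen_core integer vector of frozen (doubly occupied, inactive)
#'   MO indices; may be empty.
#' @return object of class `mo_coefficients` with the partition into
#'   `frozen_core`, `occupied_pairs` (active doubly occupied) and
#'   `virtuals`.
#' @export
mo_coefficients <- function(C, nelec, frozen_core = integer(0)) {
  nmo <- ncol(C)
  npair <- nelec / 2
  if (npair != round(npair)) stop("odd electron count")
  occ <- seq_len(npair)
  if (length(frozen_core) > 0 && !all(frozen_core %in% occ)) {
    stop("frozen_core must be among the doubly occupied MOs")
  }
  structure(
    list(C = C, nelec = as.integer(nelec),
         frozen_core = as.integer(frozen_core),
         occupied_pairs = setdiff(occ, frozen_core),
         virtuals = setdiff(seq_len(nmo), occ)),
    class = "mo_coefficients")
}

#' MO integral set container
#'
#' Carrier for the (effective) one-electron integrals, two-electron
#' integrals (dense or Cholesky-decomposed), core energy and MO-basis dipole
#' integrals of an orbital space.
#'
#' @param h MO x MO one-electron matrix (hartree).
#' @param eri dense MO two-electron tensor `(pq|rs)` in chemists' notation,
#'   or `NULL` when Cholesky factors are supplied.
#' @param chol MO Cholesky vectors, array `n x n x rank`, or `NULL`.
#' @param core_energy nuclear repulsion plus any folded frozen-core energy.
#' @param dipole list of three MO x MO dipole matrices (optional).
#' @param frozen_dipole 3-vector: electronic dipole contribution of folded
#'   frozen-core orbitals (a.u.), to be added back at the property layer.
#' @param nelec active electron count described by this set.
#' @return object of class `mo_integrals`.
#' @export
mo_integral_set <- function(h, eri = NULL, chol = NULL, core_energy = 0,
                            dipole = NULL, frozen_dipole = c(0, 0, 0),
                            nelec = NULL) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (max(abs(h - t(h))) > 1e-9) stop("one-electron integrals not symmetric")
  if (is.null(eri) && is.null(chol)) stop("need eri or chol")
  if (!is.null(eri)) stopifnot(all(dim(eri) == n))
  if (!is.null(chol)) stopifnot(dim(chol)[1] == n, dim(chol)[2] == n)
  structure(
    list(h = h, eri = eri, chol = chol, core_energy = core_energy,
         dipole = dipole, frozen_dipole = frozen_dipole,
         n_orb = n, nelec = nelec),
    class = "mo_integrals")
}

#' @export
print.mo_integrals <- function(x, ...) {
  cat(sprintf("MO integrals: %d orbitals, core energy %.8f Ha, %s two-electron storage\n",
              x$n_orb, x$core_energy,
              if (!is.null(x$eri)) "dense" else sprintf("Cholesky (rank %d)", dim(x$chol)[3])))
  invisible(x)
}

## Dense (pq|rs) retrieval that works for both storages.
mo_eri_full <- function(mi) {
  if (!is.null(mi$eri)) return(mi$eri)
  n <- mi$n_orb
  r <- dim(mi$chol)[3]
  Lm <- matrix(mi$chol, n * n, r)
  array(tcrossprod(Lm), c(n, n, n, n))
}

#' AO to MO transformation
#'
#' Transforms core Hamiltonian, two-electron integrals (dense one-index-at-
#' a-time, or Cholesky vectors as `t(C) L C`) and dipole integrals into the
#' MO basis.
#'
#' @param aoints `ao_integrals` object.
#' @param mocoeffs `mo_coefficients` or a plain AO x MO matrix.
#' @param chol optional AO-basis Cholesky factors (`npair x rank` matrix
#'   from [cholesky_decompose()]); when given, MO Cholesky vectors are
#'   produced instead of a dense MO tensor.
#' @return an `mo_integrals` object over all MOs (no frozen-core folding;
#'   see [fold_frozen_core()]).
#' @export
transform_to_mo <- function(aoints, mocoeffs, chol = NULL) {
  C <- if (inherits(mocoeffs, "mo_coefficients")) mocoeffs$C else mocoeffs
  nao <- nrow(C)
  if (nao != aoints$nbf) stop("dimension mismatch between AO integrals and coefficients")
  h <- crossprod(C, aoints$Hcore %*% C)
  h <- (h + t(h)) / 2
  dip <- lapply(aoints$dipole, function(d) {
    m <- crossprod(C, d %*% C); (m + t(m)) / 2
  })
  eri_mo <- NULL; chol_mo <- NULL
  if (is.null(chol) && !is.null(aoints$chol) && is.null(aoints$eri)) {
    chol <- aoints$chol
  }
  if (!is.null(chol)) {
    if (inherits(chol, "cholesky_factors")) chol <- chol$vectors
    rank <- ncol(chol)
    nmo <- ncol(C)
    chol_mo <- array(0, c(nmo, nmo, rank))
    for (p in seq_len(rank)) {
      Lp <- matrix(chol[, p], nao, nao)
      chol_mo[, , p] <- crossprod(C, Lp %*% C)
    }
  } else if (!is.null(aoints$eri)) {
    eri_mo <- transform_eri_index(aoints$eri, t(C))
  } else {
    stop("AO integrals carry no two-electron data; supply chol")
  }
  mo_integral_set(h, eri = eri_mo, chol = chol_mo,
                  core_energy = aoints$enuc, dipole = dip,
                  nelec = aoints$molecule$n_electrons)
}

#' Fold frozen-core orbitals into an effective Hamiltonian
#'
#' Restricted closed-shell folding: the active one-electron operator gains
#' the Coulomb-minus-half-exchange field of the frozen orbitals,
#' `h_eff = h + sum_c [2(pq|cc) - (pc|qc)]`, the core energy gains the
#' frozen-core energy, and all tensors are re-indexed to the active space.
#' The frozen orbitals' dipole contribution `2 sum_c d_cc` is kept so the
#' property layer can add it back.
#'
#' @param mi `mo_integrals` over the full MO space.
#' @param frozen_core integer vector of frozen MO indices (must be the
#'   lowest doubly occupied MOs of a closed-shell reference).
#' @return `mo_integrals` over the active space.
#' @export
fold_frozen_core <- function(mi, frozen_core) {
  frozen_core <- as.integer(frozen_core)
  if (length(frozen_core) == 0) return(mi)
  n <- mi$n_orb
  act <- setdiff(seq_len(n), frozen_core)
  if (!is.null(mi$nelec) && 2 * length(frozen_core) >= mi$nelec) {
    stop("frozen set leaves no active electrons")
  }
  if (!is.null(mi$chol)) {
    Lc <- mi$chol
    r <- dim(Lc)[3]
    ## J_pq = sum_P L_pq * (sum_c L_cc);  K_pq = sum_P sum_c L_pc L_qc
    dcc <- vapply(seq_len(r), function(p) sum(diag(Lc[, , p])[frozen_core]), 0)
    J <- matrix(0, n, n); K <- matrix(0, n, n)
    for (p in seq_len(r)) {
      J <- J + Lc[, , p] * dcc[p]
      Lpc <- Lc[, frozen_core, p, drop = FALSE]
      K <- K + tcrossprod(matrix(Lpc, n, length(frozen_core)))
    }
  } else {
    e <- mi$eri
    J <- matrix(0, n, n); K <- matrix(0, n, n)
    for (cc in frozen_core) {
      J <- J + e[, , cc, cc]
      K <- K + e[, cc, , cc]
    }
  }
  heff <- mi$h + 2 * J - K
  e_core <- 2 * sum(diag(mi$h)[frozen_core]) +
    sum((2 * J - K)[cbind(frozen_core, frozen_core)])
  dip_act <- NULL
  fdip <- mi$frozen_dipole
  if (!is.null(mi$dipole)) {
    ## electronic contribution of the folded core (electron charge -1)
    fdip <- fdip - unname(vapply(mi$dipole, function(d) 2 * sum(diag(d)[frozen_core]), 0))
    dip_act <- lapply(mi$dipole, function(d) d[act, act, drop = FALSE])
  }
  mo_integral_set(
    h = heff[act, act, drop = FALSE],
    eri = if (!is.null(mi$eri)) mi$eri[act, act, act, act, drop = FALSE] else NULL,
    chol = if (!is.null(mi$chol)) mi$chol[act, act, , drop = FALSE] else NULL,
    core_energy = mi$core_energy + e_core,
    dipole = dip_act, frozen_dipole = fdip,
    nelec = if (is.null(mi$nelec)) NULL else mi$nelec - 2L * length(frozen_core))
}

#' Frozen-core orbital selection by the nonvalence rule
#'
#' "Nonvalence" orbitals are counted per element by noble-gas cores: He core
#' (1 orbital) for Li-Ne, Ne core (5) for Na-Ar, Ar core + 3d (14) for
#' Ga-Kr.  H and He contribute none.
#'
#' @param mol a [molecule()].
#' @return number of frozen (lowest) spatial MOs.
#' @export
count_core_orbitals <- function(mol) {
  z <- mol$nuclear_charges
  sum(vapply(z, function(zi) {
    if (zi <= 2) 0
    else if (zi <= 10) 1
    else if (zi <= 18) 5
    else if (zi <= 20) 9   # K, Ca: Ar core
    else 14
  }, 0))
}
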