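## AO integral assembly: drives the McMurchie-Davidson engine in src/ and
## returns spherical-harmonic AO integrals with exact per-AO normalization.

#' Compute AO integrals for a molecule
#'
#' Evaluates overlap, core Hamiltonian (kinetic + nuclear attraction), dipole
#' integrals about a stated origin, and (optionally) the full two-electron
#' repulsion tensor, in the real solid-harmonic AO basis.
#'
#' @param mol a [molecule()].
#' @param basis basis-set name (resolved against the shipped basis library)
#'   or a parsed basis from [load_basis()].
#' @param origin dipole-integral origin, 3-vector in bohr.  The default is
#'   the coordinate origin; for charged species the dipole is
#'   origin-dependent and the origin used is recorded in the result.
#' @param eri `"dense"` to compute and store the full AO tensor, `"none"`
#'   to skip two-electron integrals.
#' @return an object of class `ao_integrals` with fields `S`, `Hcore`,
#'   `kinetic`, `dipole` (list of three AO matrices), `eri`, `enuc`, `nbf`,
#'   `origin`, `molecule`, `basis`.
#' @export
build_from_backend <- function(mol, basis, origin = c(0, 0, 0),
                               eri = c("dense", "none")) {
  eri <- match.arg(eri)
  stopifnot(inherits(mol, "molecule"))
  shells <- build_shells(mol, basis)
  basis_name <- if (is.character(basis)) basis else attr(basis, "name")

  one <- cpp_one_electron(
    lapply(shells, function(s) s[c("l", "exps", "coefs", "center")]),
    mol$coords, mol$nuclear_charges, as.numeric(origin))

  T0 <- cart_to_sph_matrix(shells)
  ## normalize each spherical AO against the exact Cartesian overlap
  Ssph_raw <- T0 %*% one$S %*% t(T0)
  Tm <- T0 / sqrt(diag(Ssph_raw))

  tr2 <- function(M) Tm %*% M %*% t(Tm)
  S <- tr2(one$S)
  kin <- tr2(one$T)
  V <- tr2(one$V)
  dip <- list(x = tr2(one$DX), y = tr2(one$DY), z = tr2(one$DZ))

  eri_sph <- NULL
  if (eri == "dense") {
    ## per-shell normalized solid-harmonic blocks; the quartet-level
    ## transformation happens inside the engine
    ls <- vapply(shells, `[[`, 0L, "l")
    blocks <- vector("list", length(shells))
    ic <- 0L; is <- 0L
    for (k in seq_along(shells)) {
      cc <- (ls[k] + 1L) * (ls[k] + 2L) / 2L
      ss <- 2L * ls[k] + 1L
      blocks[[k]] <- Tm[is + seq_len(ss), ic + seq_len(cc), drop = FALSE]
      ic <- ic + cc; is <- is + ss
    }
    eri_sph <- cpp_eri(
      lapply(shells, function(s) s[c("l", "exps", "coefs", "center")]),
      blocks)
  }

  structure(
    list(S = S, Hcore = kin + V, kinetic = kin, dipole = dip,
         chol = NULL, eri = eri_sph, enuc = nuclear_repulsion(mol),
         nbf = nrow(S), origin = as.numeric(origin),
         molecule = mol, basis = basis_name, shells = shells,
         v_emb = NULL),
    class = "ao_integrals")
}

## Apply matrix C (m x n) to all four indices of an n^4 tensor.
transform_eri_index <- function(eri, C) {
  n <- dim(eri)[1]
  m <- nrow(C)
  X <- eri
  for (k in 1:4) {
    d <- dim(X)
    X <- C %*% matrix(X, d[1], prod(d[-1]))
    X <- aperm(array(X, c(m, d[-1])), c(2, 3, 4, 1))
  }
  X
}

#' @export
print.ao_integrals <- function(x, ...) {
  cat(sprintf("AO integrals: %d basis functions (%s), E_nuc = %.8f Ha\n",
              x$nbf, x$basis, x$enuc))
  cat(sprintf("  dipole origin (bohr): %g %g %g\n",
              x$origin[1], x$origin[2], x$origin[3]))
  if (!is.null(x$v_emb)) cat("  static embedding potential included\n")
  invisible(x)
}

#' Add a static embedding potential
#'
#' Adds a precomputed one-electron embedding potential (for example from a
#' frozen-density DFT environment) to the core Hamiltonian.  Generation of
#' the potential is outside the scope of this package; it is accepted as a
#' symmetric AO-basis matrix.
#'
#' @param aoints an `ao_integrals` object.
#' @param v_emb symmetric `nbf x nbf` matrix in hartree.
#' @return the modified `ao_integrals` object.
#' @export
add_embedding_potential <- function(aoints, v_emb) {
  stopifnot(inherits(aoints, "ao_integrals"))
  v_emb <- as.matrix(v_emb)
  if (!all(dim(v_emb) == aoints$nbf)) {
    stop("embedding potential has wrong dimensions: expected ",
         aoints$nbf, " x ", aoints$nbf)
  }
  if (max(abs(v_emb - t(v_emb))) > 1e-10) {
    stop("embedding potential must be symmetric")
  }
  aoints$Hcore <- aoints$Hcore + v_emb
  aoints$v_emb <- v_emb
  aoints
}

#' Read a plain-text embedding potential matrix
#'
#' Format: first line `n` (basis size), then `n` rows of `n` whitespace
#' separated values (hartree).
#'
#' @param path file path.
#' @return symmetric matrix.
#' @export
read_embedding_potential <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  vals <- scan(text = paste(lines[-1], collapse = "\n"), quiet = TRUE)
  if (length(vals) != n * n) stop("embedding potential file: expected ",
                                  n * n, " values, got ", length(vals))
  matrix(vals, n, n, byrow = TRUE)
}
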