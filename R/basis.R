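## Gaussian basis sets: parsing ("Gaussian94" text layout), shell
## construction, primitive/contraction normalization, and the
## Cartesian-to-real-solid-harmonic transformation.
##
## Shipped basis files live under inst/extdata/basis.  STO-3G is constructed
## exactly from the published three-Gaussian fits with per-element Slater
## exponents.  The correlation-consistent files are reconstructions (see the
## file headers): primitive exponents follow the standard tabulations and the
## general-contraction coefficients are re-derived from atomic SCF in the
## uncontracted primitive basis, which is the construction principle of the
## originals.  Their filenames carry the suffix ".synthetic.gbs".

double_factorial <- function(n) {
  if (n <= 0) return(1)
  prod(seq(n, 1, by = -2))
}

AM_LETTERS <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)

basis_file_path <- function(name) {
  key <- tolower(gsub("\\s", "", name))
  dir <- system.file("extdata", "basis", package = "paircc")
  for (fn in c(paste0(key, ".gbs"), paste0(key, ".synthetic.gbs"))) {
    p <- file.path(dir, fn)
    if (file.exists(p)) return(p)
  }
  stop("basis set '", name, "' not found in shipped basis library (",
       paste(list.files(dir), collapse = ", "), ")")
}

#' Load a basis set definition
#'
#' Parses a Gaussian94-format basis file from the package's basis library
#' (or an explicit path) into a per-element list of shells.
#'
#' @param name basis-set name (e.g. `"sto-3g"`, `"cc-pvdz"`,
#'   `"aug-cc-pvtz"`) or a path to a `.gbs` file.
#' @return named list: per element, a list of shells with fields `l`,
#'   `exps`, `coefs`.
#' @export
load_basis <- function(name) {
  path <- if (file.exists(name)) name else basis_file_path(name)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*!", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  basis <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "****") { i <- i + 1; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    elem <- hdr[1]
    i <- i + 1
    shells <- list()
    while (i <= n && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      am <- toupper(sh[1])
      nprim <- as.integer(sh[2])
      if (is.na(nprim)) stop("malformed shell header at line: ", lines[i])
      i <- i + 1
      rows <- lines[i:(i + nprim - 1)]
      i <- i + nprim
      vals <- lapply(strsplit(rows, "\\s+"), function(p) as.numeric(gsub("D", "E", p)))
      exps <- vapply(vals, `[[`, 0, 1)
      if (am == "SP") {
        cs <- vapply(vals, `[[`, 0, 2)
        cp <- vapply(vals, `[[`, 0, 3)
        shells[[length(shells) + 1]] <- list(l = 0L, exps = exps, coefs = cs)
        shells[[length(shells) + 1]] <- list(l = 1L, exps = exps, coefs = cp)
      } else {
        l <- AM_LETTERS[[am]]
        if (is.null(l)) stop("unsupported angular momentum: ", am)
        coefs <- vapply(vals, `[[`, 0, 2)
        shells[[length(shells) + 1]] <- list(l = l, exps = exps, coefs = coefs)
      }
    }
    basis[[elem]] <- shells
    i <- i + 1
  }
  attr(basis, "name") <- if (file.exists(name)) basename(name) else name
  basis
}

## Raw same-center overlap of two (l,0,0)-type primitives with unit
## monomial coefficient: <x^l e^{-a r^2} | x^l e^{-b r^2}>.
raw_l00_overlap <- function(l, a, b) {
  p <- a + b
  (pi / p)^1.5 * double_factorial(2 * l - 1) / (2 * p)^l
}

## Normalize a contracted shell: published coefficients refer to normalized
## primitives; fold the primitive norms in and rescale so the contracted
## (l,0,0) component has unit norm.
normalize_shell <- function(l, exps, coefs) {
  nprim <- (2 * exps / pi)^0.75 * (4 * exps)^(l / 2) /
    sqrt(double_factorial(2 * l - 1))
  c1 <- coefs * nprim
  s <- 0
  for (a in seq_along(exps)) {
    for (b in seq_along(exps)) {
      s <- s + c1[a] * c1[b] * raw_l00_overlap(l, exps[a], exps[b])
    }
  }
  c1 / sqrt(s)
}

#' Expand a molecule's shell list
#'
#' Builds the per-atom contracted-shell list consumed by the integral engine,
#' with normalization folded into the contraction coefficients.
#'
#' @param mol a [molecule()].
#' @param basis result of [load_basis()] or a basis-set name.
#' @return list of shells with fields `l`, `exps`, `coefs`, `center`
#'   (bohr), `atom` plus attributes with AO counts.
#' @export
build_shells <- function(mol, basis) {
  if (is.character(basis)) basis <- load_basis(basis)
  shells <- list()
  for (ia in seq_along(mol$elements)) {
    el <- mol$elements[ia]
    bs <- basis[[el]]
    if (is.null(bs)) {
      stop("basis '", attr(basis, "name"), "' has no entry for element ", el)
    }
    for (sh in bs) {
      shells[[length(shells) + 1]] <- list(
        l = sh$l, exps = sh$exps,
        coefs = normalize_shell(sh$l, sh$exps, sh$coefs),
        center = mol$coords[ia, ], atom = ia)
    }
  }
  ls <- vapply(shells, `[[`, 0L, "l")
  attr(shells, "ncart") <- sum((ls + 1) * (ls + 2) / 2)
  attr(shells, "nsph") <- sum(2 * ls + 1)
  shells
}

## Real solid-harmonic combinations over raw Cartesian monomials, one row per
## m = -l..l.  Overall scale per row is immaterial: every spherical AO is
## renormalized against the exact overlap diagonal afterwards.
c2s_coef <- function(l) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) {
    ## cart order x, y, z; sph order m = -1 (y), 0 (z), +1 (x)
    return(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  }
  if (l == 2) {
    ## cart order xx, xy, xz, yy, yz, zz
    return(rbind(
      c(0, 1, 0, 0, 0, 0),     # xy
      c(0, 0, 0, 0, 1, 0),     # yz
      c(-1, 0, 0, -1, 0, 2),   # 2zz - xx - yy
      c(0, 0, 1, 0, 0, 0),     # xz
      c(1, 0, 0, -1, 0, 0)))   # xx - yy
  }
  if (l == 3) {
    ## cart order xxx, xxy, xxz, xyy, xyz, xzz, yyy, yyz, yzz, zzz
    return(rbind(
      c(0, 3, 0, 0, 0, 0, -1, 0, 0, 0),   # y(3xx - yy)
      c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),    # xyz
      c(0, -1, 0, 0, 0, 0, -1, 0, 4, 0),  # y(4zz - xx - yy)
      c(0, 0, -3, 0, 0, 0, 0, -3, 0, 2),  # z(2zz - 3xx - 3yy)
      c(-1, 0, 0, -1, 0, 4, 0, 0, 0, 0),  # x(4zz - xx - yy)
      c(0, 0, 1, 0, 0, 0, 0, -1, 0, 0),   # z(xx - yy)
      c(1, 0, 0, -3, 0, 0, 0, 0, 0, 0)))  # x(xx - 3yy)
  }
  stop("angular momentum l = ", l, " not supported (max f)")
}

## Block transformation matrix T (nsph x ncart) for a whole shell list.
cart_to_sph_matrix <- function(shells) {
  ls <- vapply(shells, `[[`, 0L, "l")
  ncart <- attr(shells, "ncart")
  nsph <- attr(shells, "nsph")
  T <- matrix(0, nsph, ncart)
  ic <- 0; is <- 0
  for (l in ls) {
    cc <- (l + 1) * (l + 2) / 2
    ss <- 2 * l + 1
    T[is + seq_len(ss), ic + seq_len(cc)] <- c2s_coef(l)
    ic <- ic + cc; is <- is + ss
  }
  T
}

## AO labels for bookkeeping / debugging.
sph_ao_labels <- function(mol, shells) {
  lab <- character(0)
  lnames <- c("s", "p", "d", "f", "g")
  for (sh in shells) {
    l <- sh$l
    ms <- if (l == 0) "" else paste0("(m=", -l:l, ")")
    lab <- c(lab, paste0(mol$elements[sh$atom], sh$atom, " ",
                         lnames[l + 1], ms))
  }
  lab
}
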