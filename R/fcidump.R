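## FCIDUMP interchange format: 1-based orbital indices, chemists' notation
## (pq|rs), 8-fold permutational symmetry implied, real orbitals, no
## point-group labels used (ISYM ignored on read, written as 1).

#' Read an FCIDUMP file
#'
#' @param path file path.
#' @return `mo_integrals` with dense two-electron storage plus attributes
#'   `nelec` and `ms2` from the header.
#' @export
read_fcidump <- function(path) {
  lines <- readLines(path)
  ## header: from &FCI up to &END (or / terminator)
  hend <- grep("&END|/", lines)[1]
  if (is.na(hend)) stop("FCIDUMP parse error: no &END in header")
  header <- paste(lines[1:hend], collapse = " ")
  getfield <- function(name) {
    m <- regmatches(header, regexpr(paste0(name, "\\s*=\\s*[0-9]+"), header))
    if (length(m) == 0) stop("FCIDUMP parse error: header lacks ", name)
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- getfield("NORB")
  nelec <- getfield("NELEC")
  h <- matrix(0, norb, norb)
  eri <- array(0, c(norb, norb, norb, norb))
  core <- 0
  body <- lines[-(1:hend)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  for (ln in seq_along(body)) {
    parts <- strsplit(body[ln], "\\s+")[[1]]
    if (length(parts) != 5) {
      stop("FCIDUMP parse error at data line ", ln + hend,
           ": expected 5 fields, got ", length(parts))
    }
    v <- as.numeric(gsub("[Dd]", "E", parts[1]))
    idx <- as.integer(parts[2:5])
    if (any(is.na(idx)) || any(idx < 0) || any(idx > norb)) {
      stop("FCIDUMP parse error at data line ", ln + hend,
           ": index out of range [0, ", norb, "]")
    }
    p <- idx[1]; q <- idx[2]; r <- idx[3]; s <- idx[4]
    if (p == 0) {
      core <- v
    } else if (r == 0) {
      h[p, q] <- h[q, p] <- v
    } else {
      for (pq in list(c(p, q), c(q, p))) for (rs in list(c(r, s), c(s, r))) {
        eri[pq[1], pq[2], rs[1], rs[2]] <- v
        eri[rs[1], rs[2], pq[1], pq[2]] <- v
      }
    }
  }
  mi <- mo_integral_set(h, eri = eri, core_energy = core, nelec = nelec)
  attr(mi, "ms2") <- getfield("MS2")
  mi
}

#' Write an FCIDUMP file
#'
#' Emits only symmetry-unique entries with magnitude above `1e-16`;
#' round-trip safe with [read_fcidump()].
#'
#' @param moints `mo_integrals` (dense storage is materialized if needed).
#' @param nelec electron count for the header (default from `moints`).
#' @param path output file.
#' @export
write_fcidump <- function(moints, nelec = NULL, path) {
  if (is.null(nelec)) nelec <- moints$nelec
  if (is.null(nelec)) stop("electron count required for the FCIDUMP header")
  n <- moints$n_orb
  h <- moints$h
  if (max(abs(h - t(h))) > 1e-10) stop("one-electron integrals not symmetric")
  eri <- mo_eri_full(moints)
  ## validate 8-fold symmetry on a sample to catch asymmetric input
  chk <- max(abs(eri - aperm(eri, c(2, 1, 3, 4))),
             abs(eri - aperm(eri, c(3, 4, 1, 2))))
  if (chk > 1e-10) stop("two-electron tensor lacks 8-fold permutational symmetry")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=0,", n, nelec),
               paste0("  ORBSYM=", paste(rep("1", n), collapse = ","), ","),
               "  ISYM=1,",
               " &END"), con)
  fmt <- function(v, p, q, r, s) sprintf(" %23.16E %4d %4d %4d %4d", v, p, q, r, s)
  out <- character(0)
  for (p in 1:n) for (q in 1:p) {
    pq <- p * (p - 1) / 2 + q
    for (r in 1:p) for (s in 1:r) {
      rs <- r * (r - 1) / 2 + s
      if (rs > pq) next
      v <- eri[p, q, r, s]
      if (abs(v) > 1e-16) out <- c(out, fmt(v, p, q, r, s))
    }
  }
  for (p in 1:n) for (q in 1:p) {
    if (abs(h[p, q]) > 1e-16) out <- c(out, fmt(h[p, q], p, q, 0, 0))
  }
  out <- c(out, fmt(moints$core_energy, 0, 0, 0, 0))
  writeLines(out, con)
  invisible(path)
}
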