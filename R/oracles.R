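## Brute-force determinant-space machinery.  Everything here is written for
## transparency rather than speed and is restricted to small orbital spaces;
## it provides the independent reference against which the production pCCD,
## LCC and density solvers are verified:
##   * dense FCI / seniority-restricted CI (DOCI) by explicit Slater-Condon
##     Hamiltonian construction,
##   * exact operator application (E_pq, pair excitations, cluster
##     operators) on CI vectors,
##   * projected-residual checks for pCCD and the dressed LCC equations,
##   * a synthetic reduced-BCS pairing Hamiltonian generator.

## ---- determinant encoding -------------------------------------------------
## One integer bitmask per spin channel; bit k (0-based) = spatial orbital
## k+1 occupied.

comb_masks <- function(norb, k) {
  if (k == 0) return(0L)
  combs <- utils::combn(norb, k)
  as.integer(apply(combs, 2, function(orbs) sum(bitwShiftL(1L, orbs - 1L))))
}

mask_orbs <- function(mask, norb) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(norb - 1))) != 0L)
}

## phase of annihilating orbital q (1-based) from mask: (-1)^(occupied below q)
ann_phase <- function(mask, q) {
  below <- bitwAnd(mask, bitwShiftL(1L, q - 1L) - 1L)
  if (sum(bitwAnd(bitwShiftR(below, 0:30), 1L)) %% 2 == 0) 1 else -1
}

#' Determinant space for brute-force CI
#'
#' Enumerates all determinants of `nelec` electrons in `norb` spatial
#' orbitals for a singlet (equal alpha/beta count), optionally restricted to
#' the seniority-zero (all electrons paired) subspace.
#'
#' @param norb number of spatial orbitals (guarded, <= 14).
#' @param nelec number of electrons (even).
#' @param filter `"all"` or `"seniority-zero"`.
#' @return object of class `det_space`.
#' @export
det_space <- function(norb, nelec, filter = c("all", "seniority-zero")) {
  filter <- match.arg(filter)
  if (norb > 14) stop("determinant space too large: norb = ", norb,
                      " (oracle limit 14)")
  if (nelec %% 2 != 0) stop("only closed-shell electron counts supported")
  k <- nelec / 2
  strings <- comb_masks(norb, k)
  if (filter == "seniority-zero") {
    ia <- seq_along(strings); ib <- seq_along(strings)
    deta <- ia; detb <- ib
    dets <- cbind(deta, detb)[deta == detb, , drop = FALSE]
    dets <- cbind(seq_along(strings), seq_along(strings))
  } else {
    dets <- as.matrix(expand.grid(a = seq_along(strings), b = seq_along(strings)))
  }
  ndet <- nrow(dets)
  if (ndet > 20000) stop("determinant space too large: ", ndet, " determinants")
  key <- (dets[, 1] - 1) * length(strings) + dets[, 2]
  lookup <- integer(length(strings)^2)
  lookup[key] <- seq_len(ndet)
  structure(list(norb = norb, nelec = nelec, filter = filter,
                 strings = strings, dets = dets, ndet = ndet,
                 lookup = lookup, nstr = length(strings)),
            class = "det_space")
}

det_index <- function(space, ia, ib) {
  idx <- space$lookup[(ia - 1) * space$nstr + ib]
  if (idx == 0) NA_integer_ else idx
}

## index of the closed-shell reference determinant (lowest npair orbitals)
ref_det_index <- function(space) {
  k <- space$nelec / 2
  m <- if (k == 0) 0L else as.integer(sum(bitwShiftL(1L, seq_len(k) - 1L)))
  is <- match(m, space$strings)
  det_index(space, is, is)
}

## ---- string excitation tables --------------------------------------------
## For every ordered pair of same-spin strings: excitation degree and, for
## degree 1/2, the orbitals and fermionic phase mapping ket string J into
## bra string I.

string_tables <- function(strings, norb) {
  ns <- length(strings)
  deg <- matrix(0L, ns, ns)
  info <- vector("list", ns * ns)
  for (J in seq_len(ns)) {
    mJ <- strings[J]
    for (I in seq_len(ns)) {
      mI <- strings[I]
      d <- sum(bitwAnd(bitwShiftR(bitwXor(mI, mJ), 0:(norb - 1)), 1L)) / 2
      deg[I, J] <- as.integer(d)
      if (d == 1) {
        q <- mask_orbs(bitwAnd(mJ, bitwNot(mI)), norb)
        p <- mask_orbs(bitwAnd(mI, bitwNot(mJ)), norb)
        ph <- ann_phase(mJ, q)
        m1 <- bitwAnd(mJ, bitwNot(bitwShiftL(1L, q - 1L)))
        ph <- ph * ann_phase(m1, p) # creation phase: same counting rule
        info[[(J - 1) * ns + I]] <- list(p = p, q = q, phase = ph)
      } else if (d == 2) {
        qs <- mask_orbs(bitwAnd(mJ, bitwNot(mI)), norb) # annihilated, ascending
        ps <- mask_orbs(bitwAnd(mI, bitwNot(mJ)), norb) # created, ascending
        ## phase of <I| a+_{p1} a+_{p2} a_{q2} a_{q1} |J> (q1 applied first),
        ## the ordering under which the element is (p1q1|p2q2)-(p1q2|p2q1)
        m <- mJ; ph <- 1
        ph <- ph * ann_phase(m, qs[1]); m <- bitwAnd(m, bitwNot(bitwShiftL(1L, qs[1] - 1L)))
        ph <- ph * ann_phase(m, qs[2]); m <- bitwAnd(m, bitwNot(bitwShiftL(1L, qs[2] - 1L)))
        ph <- ph * ann_phase(m, ps[2]); m <- bitwOr(m, bitwShiftL(1L, ps[2] - 1L))
        ph <- ph * ann_phase(m, ps[1]); m <- bitwOr(m, bitwShiftL(1L, ps[1] - 1L))
        info[[(J - 1) * ns + I]] <- list(p = ps, q = qs, phase = ph)
      }
    }
  }
  list(deg = deg, info = info, ns = ns)
}

## ---- dense Hamiltonian ----------------------------------------------------

#' Dense CI Hamiltonian matrix
#'
#' Explicit Slater-Condon construction of the electronic Hamiltonian over a
#' determinant space, from spatial MO integrals in chemists' notation.
#'
#' @param space a [det_space()].
#' @param moints an `mo_integrals` object (dense two-electron storage is
#'   materialized if needed).
#' @return symmetric `ndet x ndet` matrix (core energy not included).
#' @export
ci_hamiltonian <- function(space, moints) {
  h <- moints$h
  eri <- mo_eri_full(moints)
  norb <- space$norb
  st <- string_tables(space$strings, norb)
  ns <- st$ns
  occ_list <- lapply(space$strings, mask_orbs, norb = norb)

  ## one-spin single-excitation effective element given both occupations
  single_el <- function(p, q, occ_same, occ_other) {
    v <- h[p, q]
    for (k in occ_same) v <- v + eri[p, q, k, k] - eri[p, k, q, k]
    for (k in occ_other) v <- v + eri[p, q, k, k]
    v
  }

  H <- matrix(0, space$ndet, space$ndet)
  for (J in seq_len(space$ndet)) {
    ja <- space$dets[J, 1]; jb <- space$dets[J, 2]
    occa <- occ_list[[ja]]; occb <- occ_list[[jb]]
    for (I in seq_len(J)) {
      ia <- space$dets[I, 1]; ib <- space$dets[I, 2]
      da <- st$deg[ia, ja]; db <- st$deg[ib, jb]
      if (da + db > 2) next
      val <- 0
      if (da == 0 && db == 0) {
        val <- sum(diag(h)[occa]) + sum(diag(h)[occb])
        for (k in occa) for (l in occa) val <- val + 0.5 * (eri[k, k, l, l] - eri[k, l, k, l])
        for (k in occb) for (l in occb) val <- val + 0.5 * (eri[k, k, l, l] - eri[k, l, k, l])
        for (k in occa) for (l in occb) val <- val + eri[k, k, l, l]
      } else if (da == 1 && db == 0) {
        x <- st$info[[(ja - 1) * ns + ia]]
        val <- x$phase * single_el(x$p, x$q, occa, occb)
      } else if (da == 0 && db == 1) {
        x <- st$info[[(jb - 1) * ns + ib]]
        val <- x$phase * single_el(x$p, x$q, occb, occa)
      } else if (da == 1 && db == 1) {
        xa <- st$info[[(ja - 1) * ns + ia]]
        xb <- st$info[[(jb - 1) * ns + ib]]
        val <- xa$phase * xb$phase * eri[xa$p, xa$q, xb$p, xb$q]
      } else if (da == 2 && db == 0) {
        x <- st$info[[(ja - 1) * ns + ia]]
        val <- x$phase * (eri[x$p[1], x$q[1], x$p[2], x$q[2]] -
                          eri[x$p[1], x$q[2], x$p[2], x$q[1]])
      } else if (da == 0 && db == 2) {
        x <- st$info[[(jb - 1) * ns + ib]]
        val <- x$phase * (eri[x$p[1], x$q[1], x$p[2], x$q[2]] -
                          eri[x$p[1], x$q[2], x$p[2], x$q[1]])
      }
      H[I, J] <- H[J, I] <- val
    }
  }
  H
}

#' Dense full (or seniority-restricted) configuration interaction
#'
#' Full diagonalization of the Hamiltonian in the chosen determinant space.
#' Intended as a reference oracle on small spaces only.
#'
#' @param moints `mo_integrals`.
#' @param nelec electron count.
#' @param filter `"all"` (FCI) or `"seniority-zero"` (DOCI).
#' @param nroots number of eigenpairs to return.
#' @return list with `energy` (total, including core energy), `energies`,
#'   `civec`, `space`.
#' @export
dense_fci <- function(moints, nelec, filter = c("all", "seniority-zero"),
                      nroots = 1) {
  filter <- match.arg(filter)
  space <- det_space(moints$n_orb, nelec, filter)
  H <- ci_hamiltonian(space, moints)
  ee <- eigen(H, symmetric = TRUE)
  k <- space$ndet
  sel <- k - seq_len(min(nroots, k)) + 1
  vecs <- ee$vectors[, rev(sel), drop = FALSE]
  vals <- rev(ee$values[sel])
  ## fix CI vector sign: largest component positive
  for (j in seq_len(ncol(vecs))) {
    im <- which.max(abs(vecs[, j]))
    if (vecs[im, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(energy = vals[1] + moints$core_energy,
       energies = vals + moints$core_energy,
       civec = vecs[, 1], civecs = vecs, space = space)
}

## ---- operator application -------------------------------------------------

## apply a^+_p a_q (single spin channel) to a CI vector
apply_single <- function(space, vec, p, q, spin = c("a", "b")) {
  spin <- match.arg(spin)
  out <- numeric(space$ndet)
  strings <- space$strings
  bitp <- bitwShiftL(1L, p - 1L); bitq <- bitwShiftL(1L, q - 1L)
  for (d in seq_len(space$ndet)) {
    v <- vec[d]
    if (v == 0) next
    is <- space$dets[d, if (spin == "a") 1 else 2]
    m <- strings[is]
    if (bitwAnd(m, bitq) == 0L) next
    if (p != q && bitwAnd(m, bitp) != 0L) next
    ph <- ann_phase(m, q)
    m1 <- bitwAnd(m, bitwNot(bitq))
    ph <- ph * ann_phase(m1, p)
    m2 <- bitwOr(m1, bitp)
    js <- match(m2, strings)
    if (is.na(js)) next # leaves the (filtered) space
    tgt <- if (spin == "a") det_index(space, js, space$dets[d, 2])
           else det_index(space, space$dets[d, 1], js)
    if (is.na(tgt)) next
    out[tgt] <- out[tgt] + ph * v
  }
  out
}

## spin-summed singlet excitation operator E_pq = sum_s a^+_{ps} a_{qs}
apply_Epq <- function(space, vec, p, q) {
  apply_single(space, vec, p, q, "a") + apply_single(space, vec, p, q, "b")
}

## pair excitation P^+_a P_i (moves an alpha-beta pair i -> a); applied
## atomically so that it also works in the seniority-zero-filtered space,
## where the one-spin intermediate determinant does not exist.
apply_pair <- function(space, vec, i, a) {
  out <- numeric(space$ndet)
  strings <- space$strings
  biti <- bitwShiftL(1L, i - 1L); bita <- bitwShiftL(1L, a - 1L)
  if (i == a) {
    ## P+_p P_p counts pair occupancy
    for (d in seq_len(space$ndet)) {
      if (vec[d] == 0) next
      ma <- strings[space$dets[d, 1]]; mb <- strings[space$dets[d, 2]]
      if (bitwAnd(ma, biti) != 0L && bitwAnd(mb, biti) != 0L) out[d] <- vec[d]
    }
    return(out)
  }
  move <- function(m) {
    if (bitwAnd(m, biti) == 0L || bitwAnd(m, bita) != 0L) return(NULL)
    ph <- ann_phase(m, i)
    m1 <- bitwAnd(m, bitwNot(biti))
    ph <- ph * ann_phase(m1, a)
    list(m = bitwOr(m1, bita), ph = ph)
  }
  for (d in seq_len(space$ndet)) {
    v <- vec[d]
    if (v == 0) next
    ra <- move(strings[space$dets[d, 1]])
    if (is.null(ra)) next
    rb <- move(strings[space$dets[d, 2]])
    if (is.null(rb)) next
    js_a <- match(ra$m, strings); js_b <- match(rb$m, strings)
    if (is.na(js_a) || is.na(js_b)) next
    tgt <- det_index(space, js_a, js_b)
    if (is.na(tgt)) next
    out[tgt] <- out[tgt] + ra$ph * rb$ph * v
  }
  out
}

## apply the pCCD pair-cluster operator T_p = sum_ia tp[i,a] P^+_a P_i
apply_Tp <- function(space, vec, tp, occ, virt) {
  out <- numeric(space$ndet)
  for (ii in seq_along(occ)) {
    for (aa in seq_along(virt)) {
      t <- tp[ii, aa]
      if (t != 0) out <- out + t * apply_pair(space, vec, occ[ii], virt[aa])
    }
  }
  out
}

## e^{T_p} |vec>, exact (T_p is nilpotent)
apply_exp_Tp <- function(space, vec, tp, occ, virt) {
  out <- vec
  term <- vec
  for (k in seq_len(length(occ) + 1)) {
    term <- apply_Tp(space, term, tp, occ, virt) / k
    if (max(abs(term)) == 0) break
    out <- out + term
  }
  out
}

## apply the (pair-excluded) LCC cluster operator T' = T1 + T2
## t1: occ x virt; t2: occ x occ x virt x virt with t2[i,j,a,b] = t2[j,i,b,a]
apply_Tprime <- function(space, vec, t1, t2, occ, virt) {
  out <- numeric(space$ndet)
  no <- length(occ); nv <- length(virt)
  if (!is.null(t1)) {
    for (ii in seq_len(no)) for (aa in seq_len(nv)) {
      t <- t1[ii, aa]
      if (t != 0) out <- out + t * apply_Epq(space, vec, virt[aa], occ[ii])
    }
  }
  if (!is.null(t2)) {
    for (ii in seq_len(no)) for (jj in seq_len(no)) {
      for (aa in seq_len(nv)) for (bb in seq_len(nv)) {
        t <- t2[ii, jj, aa, bb]
        if (t == 0) next
        out <- out + 0.5 * t *
          apply_Epq(space, apply_Epq(space, vec, virt[bb], occ[jj]),
                    virt[aa], occ[ii])
      }
    }
  }
  out
}

## ---- projected residual checks -------------------------------------------

## seniority-zero (hard-core boson) Hamiltonian in the pair-determinant
## basis: diagonal E(Omega) and pair-hop K_pq.  Independent of the
## Slater-Condon path above.
sz_hamiltonian <- function(space, moints) {
  stopifnot(space$filter == "seniority-zero")
  h <- moints$h
  eri <- mo_eri_full(moints)
  norb <- space$norb
  Jm <- matrix(eri[cbind(rep(1:norb, norb), rep(1:norb, norb),
                         rep(1:norb, each = norb), rep(1:norb, each = norb))], norb)
  Km <- matrix(0, norb, norb)
  for (p in 1:norb) for (q in 1:norb) Km[p, q] <- eri[p, q, p, q]
  H <- matrix(0, space$ndet, space$ndet)
  occ_list <- lapply(space$strings, mask_orbs, norb = norb)
  for (J in seq_len(space$ndet)) {
    oJ <- occ_list[[space$dets[J, 1]]]
    H[J, J] <- 2 * sum(diag(h)[oJ]) + sum(2 * Jm[oJ, oJ] - Km[oJ, oJ])
    for (I in seq_len(space$ndet)) {
      if (I == J) next
      oI <- occ_list[[space$dets[I, 1]]]
      dp <- setdiff(oI, oJ); dq <- setdiff(oJ, oI)
      if (length(dp) == 1 && length(dq) == 1) H[I, J] <- Km[dp, dq]
    }
  }
  H
}

#' Brute-force projected residual of the pCCD equations
#'
#' Expands `exp(T_p)|ref>` exactly in the seniority-zero determinant space,
#' applies the Hamiltonian, and projects onto every pair-excited
#' determinant after the (trivial, seniority-zero) similarity
#' transformation.  Certifies the production amplitude equations.
#'
#' @param tp pair-amplitude matrix (occupied-pair x virtual).
#' @param moints active-space `mo_integrals`.
#' @param nelec active electron count.
#' @return list with `residual` (matrix occ x virt), `max` (max abs),
#'   `energy` (total pCCD energy implied by tp).
#' @export
projected_residual_check <- function(tp, moints, nelec) {
  norb <- moints$n_orb
  npair <- nelec / 2
  occ <- seq_len(npair); virt <- setdiff(seq_len(norb), occ)
  space <- det_space(norb, nelec, "seniority-zero")
  H <- sz_hamiltonian(space, moints)
  v0 <- numeric(space$ndet); v0[ref_det_index(space)] <- 1
  psi <- apply_exp_Tp(space, v0, tp, occ, virt)
  w <- H %*% psi
  iref <- ref_det_index(space)
  E <- w[iref] # <0|H e^Tp|0>, correlation + reference electronic energy
  res <- matrix(0, npair, length(virt))
  for (ii in seq_along(occ)) for (aa in seq_along(virt)) {
    bra <- apply_pair(space, v0, occ[ii], virt[aa])
    d <- which(bra != 0)
    res[ii, aa] <- sum(bra[d] * w[d]) - tp[ii, aa] * E
  }
  list(residual = res, max = max(abs(res)),
       energy = E + moints$core_energy)
}

#' Synthetic reduced-BCS pairing Hamiltonian
#'
#' Builds the seniority-conserving pairing model
#' `H = sum_p eps_p (n_pa + n_pb) - G sum_pq P+_p P_q` as an
#' `mo_integrals` object: diagonal one-electron part, constant
#' pair-scattering `-G`, and Coulomb elements chosen so no spurious
#' density-density term arises.  Optionally jitters the level energies with
#' a seeded generator to lift degeneracies.
#'
#' @param levels vector of level energies (hartree).
#' @param G pair-coupling strength (hartree, >= 0).
#' @param seed integer seed for the jitter (ignored if `jitter = 0`).
#' @param jitter standard deviation of the level jitter.
#' @return `mo_integrals` with dense two-electron storage.
#' @export
make_pairing_hamiltonian <- function(levels, G, seed = NULL, jitter = 0) {
  stopifnot(G >= 0, all(is.finite(levels)))
  n <- length(levels)
  if (jitter > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    levels <- levels + rnorm(n, sd = jitter)
  }
  eri <- array(0, c(n, n, n, n))
  for (p in 1:n) for (q in 1:n) {
    if (p == q) {
      eri[p, p, p, p] <- -G
    } else {
      ## exchange/pair-scattering channel (all 8-fold images)
      eri[p, q, p, q] <- eri[q, p, q, p] <- -G
      eri[p, q, q, p] <- eri[q, p, p, q] <- -G
      ## Coulomb channel tuned so w_pq = 2(2J_pq - K_pq) = 0
      eri[p, p, q, q] <- -G / 2
    }
  }
  mo_integral_set(h = diag(levels, n), eri = eri, core_energy = 0)
}

## ---- determinant-space LCC oracle ----------------------------------------

## Exact residual of the pCCD-LCC equations in the full determinant space:
##   R_ex = <Phi_ex| (H + [H, T']) e^{Tp} |0>
## projected on alpha singles and alpha-beta doubles determinants (the
## spin-adapted projection manifold), pair rows excluded.
lcc_det_residual <- function(t1, t2, tp, moints, nelec) {
  norb <- moints$n_orb
  npair <- nelec / 2
  occ <- seq_len(npair); virt <- setdiff(seq_len(norb), occ)
  no <- npair; nv <- length(virt)
  space <- det_space(norb, nelec, "all")
  H <- ci_hamiltonian(space, moints)
  v0 <- numeric(space$ndet); v0[ref_det_index(space)] <- 1
  vp <- apply_exp_Tp(space, v0, tp, occ, virt)
  Hvp <- drop(H %*% vp)
  Tpr_vp <- apply_Tprime(space, vp, t1, t2, occ, virt)
  w <- Hvp + drop(H %*% Tpr_vp) - apply_Tprime(space, Hvp, t1, t2, occ, virt)
  r1 <- NULL
  if (!is.null(t1)) {
    r1 <- matrix(0, no, nv)
    for (ii in seq_len(no)) for (aa in seq_len(nv)) {
      bra <- apply_single(space, v0, virt[aa], occ[ii], "a")
      d <- which(bra != 0)
      r1[ii, aa] <- sum(bra[d] * w[d])
    }
  }
  r2 <- array(0, c(no, no, nv, nv))
  for (ii in seq_len(no)) for (jj in seq_len(no)) {
    for (aa in seq_len(nv)) for (bb in seq_len(nv)) {
      if (ii == jj && aa == bb) next # pair channel excluded
      bra <- apply_single(space, apply_single(space, v0, virt[aa], occ[ii], "a"),
                          virt[bb], occ[jj], "b")
      d <- which(bra != 0)
      r2[ii, jj, aa, bb] <- sum(bra[d] * w[d])
    }
  }
  E_lcc <- sum(v0 * (H %*% Tpr_vp)) # <0| H e^{Tp} T' |0>
  list(r1 = r1, r2 = r2, E_lcc = E_lcc)
}
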