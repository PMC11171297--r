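## Electric dipole moments from response densities: assembly, the
## high-level per-method pipeline, the finite-field oracle, dipole-moment
## surface scans with turning-point detection, and error statistics.

DIPOLE_METHODS <- c("rhf", "pccd", "oo-pccd", "pccd-lccd", "pccd-lccsd",
                    "oo-pccd-lccd", "oo-pccd-lccsd")

#' Electronic dipole from a one-particle density
#'
#' Contracts the (active-space) MO density with the MO dipole integrals and
#' adds back the frozen-core contribution.  Both the MO route
#' `-Tr(gamma d_MO)` and the AO route `-Tr(D_AO d_AO)` are implemented;
#' they agree to machine precision and the cross-check can be requested.
#'
#' @param onerdm `onerdm` in the active MO basis.
#' @param mi active-space `mo_integrals` carrying `dipole` and
#'   `frozen_dipole`.
#' @param axis `"x"`, `"y"`, `"z"`, or `"all"`.
#' @param check_ao optionally supply `list(aoints =, C_act =)` to also
#'   evaluate the AO-basis route and assert agreement.
#' @return electronic dipole (a.u.), scalar or 3-vector.
#' @export
electronic_dipole <- function(onerdm, mi, axis = "all", check_ao = NULL) {
  if (is.null(mi$dipole)) stop("MO integrals carry no dipole matrices")
  gamma <- onerdm$gamma
  if (!all(dim(gamma) == mi$n_orb)) stop("density/basis dimension mismatch")
  comp <- function(ax) {
    mu <- -sum(gamma * mi$dipole[[ax]]) + mi$frozen_dipole[[match(ax, c("x", "y", "z"))]]
    if (!is.null(check_ao)) {
      D_AO <- check_ao$C_act %*% gamma %*% t(check_ao$C_act)
      mu_ao <- -sum(D_AO * check_ao$aoints$dipole[[ax]]) +
        mi$frozen_dipole[[match(ax, c("x", "y", "z"))]]
      if (abs(mu - mu_ao) > 1e-10) {
        stop("AO and MO dipole routes disagree: ", mu, " vs ", mu_ao)
      }
    }
    mu
  }
  if (axis == "all") {
    vapply(c("x", "y", "z"), comp, 0)
  } else comp(axis)
}

#' Total dipole moment
#'
#' Nuclear plus electronic contributions about a common origin, reported in
#' Debye.
#'
#' @param mol a [molecule()].
#' @param electronic 3-vector, electronic dipole in a.u.
#' @param origin 3-vector (bohr) about which `electronic` was evaluated.
#' @param method label recorded in the result.
#' @return `dipole_result` with `mu`, `nuclear_part`, `electronic_part`
#'   (Debye, 3-vectors), `origin`, `method`.
#' @export
total_dipole <- function(mol, electronic, origin = c(0, 0, 0),
                         method = "unknown") {
  nuc <- unname(nuclear_dipole(mol, origin))
  electronic <- unname(electronic)
  structure(
    list(mu = au_to_debye(nuc + electronic),
         nuclear_part = au_to_debye(nuc),
         electronic_part = au_to_debye(electronic),
         origin = origin, method = method),
    class = "dipole_result")
}

#' @export
print.dipole_result <- function(x, ...) {
  cat(sprintf("%s dipole (Debye): x = %.3f, y = %.3f, z = %.3f  (|mu| = %.3f)\n",
              x$method, x$mu[1], x$mu[2], x$mu[3], sqrt(sum(x$mu^2))))
  invisible(x)
}

## ---- per-method pipeline ---------------------------------------------------

## shared state for one geometry: SCF + frozen core env + (optionally) a
## converged oo-pCCD; reused across methods and warm-startable
method_state <- function(aoints, nfrozen = "auto", warm = NULL,
                         localize = "none", scf_args = list()) {
  if (identical(nfrozen, "auto")) nfrozen <- count_core_orbitals(aoints$molecule)
  scf <- do.call(solve_rhf, c(list(aoints,
                                   C0 = if (!is.null(warm)) warm$C_scf else NULL),
                              scf_args))
  list(aoints = aoints, scf = scf, nfrozen = as.integer(nfrozen))
}

## canonical-orbital active-space integrals for a state
state_active_ints <- function(st) {
  env <- freeze_core_env(st$aoints, st$scf$mocoeffs$C, st$nfrozen)
  nmo <- ncol(st$scf$mocoeffs$C)
  C_act <- st$scf$mocoeffs$C[, setdiff(seq_len(nmo), seq_len(st$nfrozen)),
                             drop = FALSE]
  list(mi = active_space_ints(st$aoints, env, C_act), C_act = C_act, env = env)
}

#' Dipole moment by any supported method
#'
#' Runs the full pipeline (SCF, frozen core, pCCD with or without orbital
#' optimization, optional LCC correction, Lambda equations, response
#' density) and assembles the total dipole.
#'
#' @param aoints `ao_integrals`.
#' @param method one of `rhf`, `pccd`, `oo-pccd`, `pccd-lccd`,
#'   `pccd-lccsd`, `oo-pccd-lccd`, `oo-pccd-lccsd`.
#' @param nfrozen frozen-core count or `"auto"` (nonvalence rule).
#' @param warm optional warm-start data from a previous geometry (field
#'   `C_scf`, `C_act`, `tp`).
#' @param localize Pipek-Mezey start for the orbital optimizer.
#' @param oo_args extra arguments for [solve_oopccd()].
#' @return list with `dipole` (`dipole_result`), `energy`, `E_scf`,
#'   `E_lcc` (if any), `details` (method objects), `warm` (for chaining).
#' @export
compute_dipole <- function(aoints, method = "oo-pccd", nfrozen = "auto",
                           warm = NULL, localize = "none", oo_args = list()) {
  method <- match.arg(method, DIPOLE_METHODS)
  mol <- aoints$molecule
  st <- method_state(aoints, nfrozen, warm)
  out <- list(E_scf = st$scf$E_total, details = list(scf = st$scf))
  if (method == "rhf") {
    mu_e <- vapply(aoints$dipole, function(d) -sum(st$scf$density * d), 0)
    out$energy <- st$scf$E_total
    out$dipole <- total_dipole(mol, mu_e, aoints$origin, method)
    out$warm <- list(C_scf = st$scf$mocoeffs$C)
    return(out)
  }
  orbital_opt <- grepl("^oo-", method)
  lcc_variant <- if (grepl("lccsd$", method)) "lccsd"
                 else if (grepl("lccd$", method)) "lccd" else NULL
  nelec_act <- mol$n_electrons - 2L * st$nfrozen
  if (orbital_opt) {
    C0 <- st$scf$mocoeffs$C
    if (!is.null(warm$C_act)) {
      Cc <- C0[, seq_len(st$nfrozen), drop = FALSE]
      C0[, (st$nfrozen + 1):ncol(C0)] <-
        orthonormalize_against(warm$C_act, aoints$S, Cc)
    }
    oo <- do.call(solve_oopccd,
                  c(list(aoints, C0, nfrozen = st$nfrozen, localize = localize),
                    oo_args))
    mi <- oo$mi
    pccd <- oo$pccd
    rdm_ref <- relaxed_reference_rdm(oo)
    out$details$oopccd <- oo
    out$warm <- list(C_scf = st$scf$mocoeffs$C, C_act = oo$C_act, tp = pccd$t)
  } else {
    act <- state_active_ints(st)
    mi <- act$mi
    pccd <- solve_pccd(mi, nelec_act, guess = warm$tp)
    pccd <- solve_pccd_lambda(pccd, mi)
    rdm_ref <- pccd_response_1rdm(pccd)
    out$warm <- list(C_scf = st$scf$mocoeffs$C, tp = pccd$t)
  }
  out$details$pccd <- pccd
  out$energy <- pccd$energy
  rdm <- rdm_ref
  if (!is.null(lcc_variant)) {
    lcc <- solve_lcc(pccd$t, mi, nelec_act, lcc_variant)
    lcc <- solve_lcc_lambda(lcc)
    rdm <- combine_rdm(rdm_ref, lcc_correlation_1rdm(lcc))
    out$E_lcc <- lcc$E_lcc
    out$energy <- pccd$energy + lcc$E_lcc
    out$details$lcc <- lcc
  }
  mu_e <- electronic_dipole(rdm, mi)
  out$dipole <- total_dipole(mol, mu_e, aoints$origin, method)
  out$rdm <- rdm
  out
}

## ---- finite-field oracle ---------------------------------------------------

## apply a static field along one axis: Hcore -> Hcore + eps * d_axis
apply_field <- function(aoints, axis, eps) {
  aoints$Hcore <- aoints$Hcore + eps * aoints$dipole[[axis]]
  aoints
}

#' Finite-field dipole moment
#'
#' Central-difference derivative of the energy with respect to a uniform
#' field, `mu = mu_nuc - dE_elec/d(eps)`.  The re-solution protocol
#' follows the response formalism being checked: orbitals are re-optimized
#' only for orbital-optimized methods, pair and correction amplitudes are
#' re-solved per field point, and for the LCC corrections the reference
#' (orbitals and pair amplitudes) is frozen at its zero-field values (the
#' unrelaxed-LCC contract).
#'
#' @param aoints zero-field `ao_integrals`.
#' @param method method string as in [compute_dipole()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param epsilon field step (a.u.).
#' @param nfrozen frozen-core count or `"auto"`.
#' @return total dipole component in Debye.
#' @export
finite_field_dipole <- function(aoints, method = "oo-pccd", axis = "z",
                                epsilon = 1e-4, nfrozen = "auto") {
  method <- match.arg(method, DIPOLE_METHODS)
  mol <- aoints$molecule
  if (identical(nfrozen, "auto")) nfrozen <- count_core_orbitals(mol)
  orbital_opt <- grepl("^oo-", method)
  lcc_variant <- if (grepl("lccsd$", method)) "lccsd"
                 else if (grepl("lccd$", method)) "lccd" else NULL
  base_method <- if (orbital_opt) "oo-pccd" else "pccd"
  nelec_act <- mol$n_electrons - 2L * nfrozen

  ## zero-field reference (for frozen-orbital protocols)
  st0 <- method_state(aoints, nfrozen)
  env0 <- freeze_core_env(aoints, st0$scf$mocoeffs$C, nfrozen)

  e_ref <- function(eps) {
    ao_f <- apply_field(aoints, axis, eps)
    if (method == "rhf") return(solve_rhf(ao_f, C0 = st0$scf$mocoeffs$C)$E_total)
    if (orbital_opt) {
      oo <- solve_oopccd(ao_f, st0$scf$mocoeffs$C, nfrozen = nfrozen)
      oo$energy
    } else {
      ## canonical orbitals fixed at their zero-field values
      env_f <- freeze_core_env(ao_f, st0$scf$mocoeffs$C, nfrozen)
      nmo <- ncol(st0$scf$mocoeffs$C)
      C_act <- st0$scf$mocoeffs$C[, setdiff(seq_len(nmo), seq_len(nfrozen)),
                                  drop = FALSE]
      mi_f <- active_space_ints(ao_f, env_f, C_act)
      solve_pccd(mi_f, nelec_act)$energy
    }
  }
  dE <- (e_ref(epsilon) - e_ref(-epsilon)) / (2 * epsilon)
  mu <- nuclear_dipole(mol, aoints$origin)[match(axis, c("x", "y", "z"))] - dE
  if (!is.null(lcc_variant)) {
    ## unrelaxed LCC: orbitals and pair amplitudes frozen at zero field
    if (orbital_opt) {
      oo0 <- solve_oopccd(aoints, st0$scf$mocoeffs$C, nfrozen = nfrozen)
      C_act0 <- oo0$C_act
      tp0 <- oo0$pccd$t
    } else {
      nmo <- ncol(st0$scf$mocoeffs$C)
      C_act0 <- st0$scf$mocoeffs$C[, setdiff(seq_len(nmo), seq_len(nfrozen)),
                                   drop = FALSE]
      mi0 <- active_space_ints(aoints, env0, C_act0)
      tp0 <- solve_pccd(mi0, nelec_act)$t
    }
    e_lcc <- function(eps) {
      ao_f <- apply_field(aoints, axis, eps)
      env_f <- freeze_core_env(ao_f, st0$scf$mocoeffs$C, nfrozen)
      ## note: core orbitals also frozen at zero field
      mi_f <- active_space_ints(ao_f, env_f, C_act0)
      solve_lcc(tp0, mi_f, nelec_act, lcc_variant)$E_lcc
    }
    dE_lcc <- (e_lcc(epsilon) - e_lcc(-epsilon)) / (2 * epsilon)
    mu <- mu - dE_lcc
  }
  au_to_debye(mu)
}

## ---- dipole-moment surfaces ------------------------------------------------

#' Scan a diatomic dipole-moment surface
#'
#' Stretches the A-B bond along +z and evaluates mu_z for each requested
#' method at every grid point, with orbitals and amplitudes warm-started
#' outward from a central starting point in both directions.  A positive
#' mu_z indicates A(-)B(+) polarity (A at the origin).
#'
#' @param a,b element symbols: A at the origin (less electronegative), B
#'   on +z.
#' @param r_grid strictly increasing bond lengths (Angstrom).
#' @param basis basis-set name.
#' @param methods subset of the supported method labels.
#' @param nfrozen frozen-core count or `"auto"`.
#' @param r_start warm-start origin of the scan (defaults to the grid
#'   point nearest the smallest |r - 1|; pass the equilibrium distance).
#' @param charge total charge.
#' @param chol_threshold Cholesky threshold for the two-electron
#'   integrals.
#' @param localize Pipek-Mezey start for the first point.
#' @param verbose print progress.
#' @return `dms_curve`: data frame with `r` and one `mu_z` column per
#'   method (Debye) plus convergence flags.
#' @export
scan_dms <- function(a, b, r_grid, basis, methods = c("oo-pccd"),
                     nfrozen = "auto", r_start = NULL, charge = 0,
                     chol_threshold = 1e-5, localize = "none",
                     oo_conv_grad = 1e-5, oo_max_iter = 150,
                     lcc_tol = 1e-8, verbose = FALSE) {
  stopifnot(all(diff(r_grid) > 0))
  methods <- vapply(methods, function(m) match.arg(m, DIPOLE_METHODS), "")
  if (is.null(r_start)) r_start <- r_grid[which.min(abs(r_grid - 1))]
  i0 <- which.min(abs(r_grid - r_start))
  order_idx <- c(seq(i0, length(r_grid)), if (i0 > 1) seq(i0 - 1, 1))
  res <- matrix(NA_real_, length(r_grid), length(methods),
                dimnames = list(NULL, methods))
  conv <- matrix(FALSE, length(r_grid), length(methods),
                 dimnames = list(NULL, methods))
  warm_up <- NULL; warm_down <- NULL
  for (k in seq_along(order_idx)) {
    i <- order_idx[k]
    going_down <- i < i0
    warm <- if (going_down) warm_down else warm_up
    r <- r_grid[i]
    pt <- tryCatch(
      dms_point(a, b, r, basis, methods, nfrozen, warm, charge,
                chol_threshold,
                localize = if (k == 1) localize else "none",
                oo_conv_grad = oo_conv_grad,
                oo_max_iter = if (k == 1) 3L * oo_max_iter else oo_max_iter,
                lcc_tol = lcc_tol),
      error = function(e) {
        warning(sprintf("scan point r = %.3f failed: %s", r,
                        conditionMessage(e)))
        NULL
      })
    if (!is.null(pt)) {
      res[i, ] <- pt$mu_z[methods]
      conv[i, ] <- TRUE
      if (going_down || i == i0) warm_down <- pt$warm
      if (!going_down) warm_up <- pt$warm
    }
    if (verbose && !is.null(pt)) {
      message(sprintf("  r = %-6.3f  %s", r,
                      paste(sprintf("%s: %8.4f", methods, res[i, ]),
                            collapse = "  ")))
    }
  }
  out <- data.frame(r = r_grid, res, check.names = FALSE)
  for (m in methods) out[[paste0("converged.", m)]] <- conv[, m]
  class(out) <- c("dms_curve", class(out))
  attr(out, "methods") <- methods
  out
}

## single scan point: shares SCF and oo-pCCD across the method list
dms_point <- function(a, b, r, basis, methods, nfrozen, warm, charge,
                      chol_threshold, localize = "none",
                      oo_conv_grad = 1e-5, oo_max_iter = 150,
                      lcc_tol = 1e-8) {
  mol <- diatomic(a, b, r, charge = charge)
  ao <- build_from_backend(mol, basis)
  ao <- ao_attach_cholesky(ao, chol_threshold)
  mu_z <- setNames(numeric(length(methods)), methods)
  if (is.null(warm)) warm <- list()
  if (is.null(warm$lcc)) warm$lcc <- list()
  if (is.null(warm$lam)) warm$lam <- list()
  need_oo <- any(grepl("^oo-", methods))
  need_canon <- any(!grepl("^oo-", methods) & methods != "rhf")
  st <- method_state(ao, nfrozen, warm)
  nelec_act <- mol$n_electrons - 2L * st$nfrozen
  warm_out <- list(C_scf = st$scf$mocoeffs$C)
  if ("rhf" %in% methods) {
    mu_e <- -sum(st$scf$density * ao$dipole$z)
    mu_z[["rhf"]] <- au_to_debye(nuclear_dipole(mol)[3] + mu_e)
  }
  ## rotate warm amplitude tensors from the previous geometry's orbital
  ## basis into the current one (the optimizer leaves nearly-free rotation
  ## directions path-dependent, so the bases drift even between close
  ## geometries)
  rot_blocks <- function(C_prev, C_now) {
    U <- crossprod(C_prev, ao$S %*% C_now)
    no <- nelec_act / 2
    polar <- function(M) { sv <- svd(M); sv$u %*% t(sv$v) }
    list(oo = polar(U[1:no, 1:no, drop = FALSE]),
         vv = polar(U[-(1:no), -(1:no), drop = FALSE]))
  }
  rot_t2 <- function(t2, R) {
    t2 <- ein2(t2, "xjab", R$oo, "xi", "ijab")
    t2 <- ein2(t2, "ixab", R$oo, "xj", "ijab")
    t2 <- ein2(t2, "ijxb", R$vv, "xa", "ijab")
    ein2(t2, "ijax", R$vv, "xb", "ijab")
  }
  rot_amps <- function(g, R) {
    if (is.null(g)) return(NULL)
    out <- list()
    if (!is.null(g$t1)) out$t1 <- crossprod(R$oo, g$t1 %*% R$vv)
    if (!is.null(g$t2)) out$t2 <- zero_pair(rot_t2(g$t2, R))
    if (!is.null(g$l1)) out$l1 <- crossprod(R$oo, g$l1 %*% R$vv)
    if (!is.null(g$l2)) out$l2 <- zero_pair(rot_t2(g$l2, R))
    out
  }
  bl_shared <- NULL
  lccd_seed <- NULL
  compute_block <- function(mi, pccd, orbital_opt) {
    bl_shared <<- NULL
    lccd_seed <<- NULL
    rdm_ref <- pccd_response_1rdm(pccd)
    block_methods <- methods[grepl("^oo-", methods) == orbital_opt &
                             methods != "rhf"]
    for (m in block_methods) {
      variant <- if (grepl("lccsd$", m)) "lccsd"
                 else if (grepl("lccd$", m)) "lccd" else NULL
      rdm <- rdm_ref
      if (!is.null(variant)) {
        if (is.null(bl_shared)) bl_shared <<- lcc_blocks(mi, nelec_act)
        gw <- warm$lcc[[m]]; lw <- warm$lam[[m]]
        if (!is.null(Rrot)) {
          gw <- rot_amps(gw, Rrot); lw <- rot_amps(lw, Rrot)
        }
        if (is.null(gw) && variant == "lccsd" && !is.null(lccd_seed)) {
          ## same-point LCCD doubles seed the LCCSD systems
          z1 <- matrix(0, nrow(pccd$t), ncol(pccd$t))
          gw <- list(t1 = z1, t2 = lccd_seed$t2)
          lw <- list(l1 = z1, l2 = lccd_seed$l2)
        }
        lcc <- solve_lcc(pccd$t, mi, nelec_act, variant,
                         guess = gw, bl = bl_shared,
                         tol = lcc_tol)
        lcc <- solve_lcc_lambda(lcc, guess = lw, tol = 10 * lcc_tol)
        if (variant == "lccd") lccd_seed <<- list(t2 = lcc$t2, l2 = lcc$l2)
        warm_out$lcc[[m]] <<- list(t1 = lcc$t1, t2 = lcc$t2)
        warm_out$lam[[m]] <<- list(l1 = lcc$l1, l2 = lcc$l2)
        rdm <- combine_rdm(rdm_ref, lcc_correlation_1rdm(lcc))
      }
      mu_e <- electronic_dipole(rdm, mi, axis = "z")
      mu_z[[m]] <<- au_to_debye(nuclear_dipole(mol)[3] + mu_e)
    }
  }
  Rrot <- NULL
  if (need_canon) {
    act <- state_active_ints(st)
    pccd <- solve_pccd(act$mi, nelec_act, guess = warm$tp_canon)
    pccd <- solve_pccd_lambda(pccd, act$mi)
    warm_out$tp_canon <- pccd$t
    compute_block(act$mi, pccd, orbital_opt = FALSE)
  }
  if (need_oo) {
    C0 <- st$scf$mocoeffs$C
    if (!is.null(warm$C_act)) {
      Cc <- C0[, seq_len(st$nfrozen), drop = FALSE]
      C0[, (st$nfrozen + 1):ncol(C0)] <-
        orthonormalize_against(warm$C_act, ao$S, Cc)
    }
    oo <- solve_oopccd(ao, C0, nfrozen = st$nfrozen, localize = localize,
                       conv_grad = oo_conv_grad, max_iter = oo_max_iter)
    oo$pccd <- solve_pccd_lambda(oo$pccd, oo$mi)
    Rrot <- if (!is.null(warm$C_act)) rot_blocks(warm$C_act, oo$C_act) else NULL
    warm_out$C_act <- oo$C_act
    warm_out$tp <- oo$pccd$t
    compute_block(oo$mi, oo$pccd, orbital_opt = TRUE)
  }
  list(mu_z = mu_z, warm = warm_out)
}

#' Interior maximum of a dipole-moment curve
#'
#' Locates the grid maximum of the dipole magnitude among converged
#' points and refines it with a three-point quadratic fit through the
#' maximum and its neighbours.  The magnitude is used because the sign of
#' `mu_z` encodes the polarity convention (a hydrogen-at-origin hydride
#' curve is negative throughout).
#'
#' @param r grid (Angstrom), strictly increasing.
#' @param mu curve values; `NA` marks failed points.
#' @param magnitude locate the maximum of `|mu|` (default) rather than of
#'   the signed values.
#' @return list with `r_max` (fitted abscissa, Angstrom), `mu_max` (the
#'   signed fitted value), and `interior` (FALSE when the maximum sits on
#'   the grid boundary, in which case no refinement is attempted).
#' @export
turning_point <- function(r, mu, magnitude = TRUE) {
  ok <- which(!is.na(mu))
  if (length(ok) < 3) stop("need at least three converged points")
  r <- r[ok]; mu <- mu[ok]
  sgn <- 1
  if (magnitude) {
    sgn <- sign(mu[which.max(abs(mu))])
    if (sgn == 0) sgn <- 1
    mu <- abs(mu)
  }
  i <- which.max(mu)
  if (i == 1 || i == length(mu)) {
    return(list(r_max = r[i], mu_max = sgn * mu[i], interior = FALSE))
  }
  x <- r[(i - 1):(i + 1)]; y <- mu[(i - 1):(i + 1)]
  cf <- solve(cbind(1, x, x^2), y)
  r_fit <- -cf[2] / (2 * cf[3])
  list(r_max = unname(r_fit),
       mu_max = unname(sgn * (cf[1] + cf[2] * r_fit + cf[3] * r_fit^2)),
       interior = TRUE)
}

#' Mean unsigned and root-mean-square error
#'
#' @param values,references equal-length numeric vectors.
#' @return list with `mue`, `rmse`, `n`; `rmse >= mue` always.
#' @export
error_stats <- function(values, references) {
  stopifnot(length(values) == length(references), length(values) > 0)
  d <- values - references
  list(mue = mean(abs(d)), rmse = sqrt(mean(d^2)), n = length(d))
}
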