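test_that("AO and MO dipole contraction routes agree", {
  ao <- ao_lih_sto3g()
  st <- paircc:::method_state(ao, 1)
  act <- paircc:::state_active_ints(st)
  p <- solve_pccd_lambda(solve_pccd(act$mi, 2), act$mi)
  g <- pccd_response_1rdm(p)
  mu <- electronic_dipole(g, act$mi, axis = "z",
                          check_ao = list(aoints = ao, C_act = act$C_act))
  expect_true(is.finite(mu)) # the cross-check inside would stop on mismatch
})

test_that("point charges +1/-1 half a bohr apart give 1 a.u. = 2.5417 D", {
  mol <- diatomic("H", "H", 1, unit = "bohr")
  mol$nuclear_charges <- c(-1, 1)  # synthetic charge pair, no electrons
  mu <- nuclear_dipole(mol)
  expect_equal(au_to_debye(mu[3]), 2.5417464519, tolerance = 1e-10)
})

test_that("the total dipole of a neutral system is translation invariant", {
  ao1 <- ao_lih_sto3g()
  d1 <- compute_dipole(ao1, "pccd", nfrozen = 1)
  shifted <- molecule(c("Li", "H"),
                      ao1$molecule$coords + matrix(c(0.4, 0.1, -0.7), 2, 3,
                                                   byrow = TRUE),
                      unit = "bohr")
  ao2 <- build_from_backend(shifted, "sto-3g")
  d2 <- compute_dipole(ao2, "pccd", nfrozen = 1)
  expect_equal(d1$dipole$mu, d2$dipole$mu, tolerance = 1e-8)
})

test_that("HF has negative mu_z with H at the origin and F on +z", {
  ao <- fixture_ao("hf_sto3g", function()
    build_from_backend(diatomic("H", "F", 0.917), "sto-3g"))
  d <- compute_dipole(ao, "oo-pccd", nfrozen = 1)
  expect_lt(d$dipole$mu[3], 0)   # H(+)F(-) polarity
})

test_that("response dipoles equal finite-field derivatives for every method", {
  ao <- ao_lih_sto3g()
  for (m in c("pccd", "oo-pccd", "pccd-lccd", "oo-pccd-lccsd")) {
    d <- compute_dipole(ao, m, nfrozen = 1)
    ff <- finite_field_dipole(ao, m, "z", 1e-4, nfrozen = 1)
    expect_equal(d$dipole$mu[3], ff, tolerance = 1e-4,
                 label = paste(m, "response"), expected.label = "finite field")
  }
})

test_that("finite-field agreement survives a static embedding potential", {
  set.seed(19)
  ao <- ao_lih_sto3g()
  v <- matrix(rnorm(ao$nbf^2, sd = 0.01), ao$nbf)
  ao_emb <- add_embedding_potential(ao, (v + t(v)) / 2)
  d <- compute_dipole(ao_emb, "pccd", nfrozen = 1)
  ff <- finite_field_dipole(ao_emb, "pccd", "z", 1e-4, nfrozen = 1)
  expect_equal(d$dipole$mu[3], ff, tolerance = 1e-4)
})

test_that("turning-point refinement recovers closed-form maxima", {
  r <- seq(0.5, 2.0, 0.1)
  cf <- c(1, 3, -1.2) # parabola with vertex at 1.25
  tp <- turning_point(r, cf[1] + cf[2] * r + cf[3] * r^2)
  expect_equal(tp$r_max, -cf[2] / (2 * cf[3]), tolerance = 1e-10)
  expect_true(tp$interior)
  ## monotone curve: no interior turning
  tpm <- turning_point(r, 2 * r)
  expect_false(tpm$interior)
  ## mu(r) = r exp(-r^2) has its maximum at 1/sqrt(2)
  r2 <- seq(0.2, 1.5, 0.05)
  tp2 <- turning_point(r2, r2 * exp(-r2^2))
  expect_equal(tp2$r_max, 1 / sqrt(2), tolerance = 1e-3)
})

test_that("error statistics satisfy their closed forms and ordering", {
  s <- error_stats(c(1, 2), c(2, 3))
  expect_equal(s$mue, 1); expect_equal(s$rmse, 1)
  s2 <- error_stats(c(0, 2), c(0, 0))
  expect_equal(s2$mue, 1); expect_equal(s2$rmse, sqrt(2))
  expect_identical(error_stats(1:5, 1:5)$rmse, 0)
  set.seed(3)
  for (k in 1:5) {
    v <- rnorm(7); ref <- rnorm(7)
    st <- error_stats(v, ref)
    expect_gte(st$rmse, st$mue)
  }
  expect_error(error_stats(numeric(0), numeric(0)))
})

test_that("a homonuclear scan is identically zero and order flips the sign", {
  sc <- scan_dms("H", "H", c(0.7, 0.8), "sto-3g", methods = "pccd",
                 nfrozen = 0)
  expect_lt(max(abs(sc$pccd)), 1e-8)
  f1 <- scan_dms("H", "F", c(0.9, 1.0), "sto-3g", methods = "pccd", nfrozen = 1)
  f2 <- scan_dms("F", "H", c(0.9, 1.0), "sto-3g", methods = "pccd", nfrozen = 1)
  expect_equal(f1$pccd, -f2$pccd, tolerance = 1e-7)
})
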