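test_that("the shipped minimal basis reproduces its defining scaled fits", {
  b <- load_basis("sto-3g")
  h <- b$H[[1]]
  expect_equal(h$exps, c(3.425250914, 0.623913729, 0.168855403),
               tolerance = 1e-8)
  ## fluorine 1s leads with zeta^2-scaled fit exponent 166.68
  expect_equal(b$F[[1]]$exps[1], 166.68, tolerance = 1e-3)
  expect_length(b$Li, 3) # 1s, 2s, 2p shells
})

test_that("spherical AO counts follow 2l+1 per shell", {
  ao <- fixture_ao("hf_avtz_count", function()
    build_from_backend(diatomic("H", "F", 0.917), "aug-cc-pvtz",
                       eri = "none"))
  ## H: 4s+3p+2d = 23; F: 5s+4p+3d+2f = 46
  expect_equal(ao$nbf, 69L)
})

test_that("a basis lacking an element fails loudly", {
  expect_error(build_from_backend(diatomic("Na", "H", 1.9), "cc-pvdz"),
               "no entry")
})
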