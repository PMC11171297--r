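test_that("FCIDUMP round trip is lossless", {
  set.seed(4)
  mi <- random_mi(4)
  mi$nelec <- 4L
  path <- tempfile(fileext = ".fcidump")
  write_fcidump(mi, 4, path)
  back <- read_fcidump(path)
  expect_equal(back$h, mi$h, tolerance = 1e-12)
  expect_equal(back$eri, mi$eri, tolerance = 1e-12)
  expect_equal(back$core_energy, mi$core_energy, tolerance = 1e-12)
  expect_identical(back$nelec, 4L)
})

test_that("header is honored and absent entries are zero", {
  path <- tempfile(fileext = ".fcidump")
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", "  ORBSYM=1,1,", "  ISYM=1,",
               " &END",
               " -1.2500000000000000E+00    1    1    0    0",
               " -0.4500000000000000E+00    2    2    0    0",
               "  0.7000000000000000E+00    0    0    0    0"), path)
  mi <- read_fcidump(path)
  expect_equal(mi$n_orb, 2L)
  expect_equal(mi$core_energy, 0.7)
  expect_true(all(mi$eri == 0))
  expect_equal(diag(mi$h), c(-1.25, -0.45))
})

test_that("malformed input produces a parse error naming the problem", {
  p1 <- tempfile(); writeLines(c("no header here", "1.0 1 1 0 0"), p1)
  expect_error(read_fcidump(p1), "header")
  p2 <- tempfile()
  writeLines(c(" &FCI NORB=2,NELEC=2,MS2=0,", " &END",
               " 1.0   1  5  0  0"), p2)
  expect_error(read_fcidump(p2), "out of range")
  ## asymmetric tensors are refused on write
  mi <- random_mi(3)
  mi$h[1, 2] <- mi$h[1, 2] + 1
  expect_error(write_fcidump(mi, 2, tempfile()), "symmetric")
})

test_that("a zero two-electron block emits no four-index records", {
  mi <- mo_integral_set(h = diag(c(-1, -0.5)), eri = array(0, rep(2, 4)),
                        core_energy = 0.3)
  path <- tempfile()
  write_fcidump(mi, 2, path)
  body <- readLines(path)
  body <- body[-seq_len(grep("&END", body))]
  idx <- t(vapply(strsplit(trimws(body), "\\s+"),
                  function(x) as.integer(x[2:5]), integer(4)))
  expect_true(all(idx[, 3] == 0)) # only one-electron and core records
})

test_that("pairing-model FCI energies survive a round trip", {
  hm <- make_pairing_hamiltonian(c(0, 0.8, 1.7, 2.4), G = 0.22)
  e_before <- dense_fci(hm, 4)$energy
  path <- tempfile()
  write_fcidump(hm, 4, path)
  e_after <- dense_fci(read_fcidump(path), 4)$energy
  expect_equal(e_before, e_after, tolerance = 1e-12)
})

test_that("the shipped fixtures parse with the expected structure", {
  p <- system.file("extdata", "fcidump", "h2_sto3g.fcidump",
                   package = "paircc")
  mi <- read_fcidump(p)
  expect_equal(mi$n_orb, 2L)
  expect_identical(mi$nelec, 2L)
  ## core-energy record is the index-(0,0,0,0) entry
  lines <- readLines(p)
  core_line <- lines[grepl("0\\s+0\\s+0\\s+0\\s*$", lines)]
  expect_equal(mi$core_energy, as.numeric(strsplit(trimws(core_line),
                                                   "\\s+")[[1]][1]))
})
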