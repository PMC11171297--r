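# Generates the small plain-text FCIDUMP fixtures shipped under
# inst/extdata/fcidump (canonical RHF orbitals, all integrals).
suppressMessages(devtools::load_all("/root/pkg", quiet = TRUE))
for (fix in list(list("h2_sto3g", diatomic("H", "H", 1.4, unit = "bohr"), 2),
                 list(
                   "lih_sto3g", diatomic("Li", "H", 1.6), 4),
                 list("h4_sto3g",
                      molecule(rep("H", 4), cbind(0, 0, c(0, 0.95, 1.9, 2.85))), 4))) {
  ao <- build_from_backend(fix[[2]], "sto-3g")
  scf <- solve_rhf(ao)
  mi <- transform_to_mo(ao, scf$mocoeffs)
  write_fcidump(mi, fix[[3]],
                file.path("/root/pkg/inst/extdata/fcidump",
                          paste0(fix[[1]], ".fcidump")))
  cat(fix[[1]], "written\n")
}
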