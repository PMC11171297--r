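# Generates inst/extdata/basis/sto-3g.gbs from the classic three-Gaussian
# STO fits (1s and 2sp, zeta = 1) scaled by per-element Slater exponents
# (alpha -> alpha * zeta^2).
fit1s  <- list(e = c(2.227660584, 0.405771156, 0.109817510),
               c = c(0.154328967, 0.535328142, 0.444634542))
fit2s  <- list(e = c(0.994203260, 0.231031360, 0.075138460),
               c = c(-0.099967229, 0.399512826, 0.700115469))
fit2p  <- list(c = c(0.155916275, 0.607683719, 0.391957393))
zeta <- list(
  H  = c(1.24), He = c(1.69),
  Li = c(2.69, 0.80), Be = c(3.68, 1.15), B = c(4.68, 1.50),
  C  = c(5.67, 1.72), N  = c(6.67, 1.95), O = c(7.66, 2.25),
  F  = c(8.65, 2.55), Ne = c(9.64, 2.88))
fmt <- function(e, c1) paste0(sprintf("      %16.9f  %15.9f", e, c1), collapse = "\n")
out <- c("! STO-3G minimal basis, constructed from the standard three-Gaussian",
         "! STO fits with per-element Slater zeta scaling (alpha * zeta^2).",
         "****")
for (el in names(zeta)) {
  z <- zeta[[el]]
  out <- c(out, paste0(el, "     0"),
           "S   3   1.00", fmt(fit1s$e * z[1]^2, fit1s$c))
  if (length(z) > 1) {
    out <- c(out,
             "S   3   1.00", fmt(fit2s$e * z[2]^2, fit2s$c),
             "P   3   1.00", fmt(fit2s$e * z[2]^2, fit2p$c))
  }
  out <- c(out, "****")
}
writeLines(out, "/root/pkg/inst/extdata/basis/sto-3g.gbs")
cat("wrote", length(out), "lines\n")
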