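## Minimal two-tensor einsum used by the linearized-CC contractions.
## Contracts the indices shared by `ia` and `ib` that do not appear in
## `iout`; remaining indices are arranged per `iout`.  Index labels are
## single characters.  Because every term is expressed through this helper,
## adjoints of the (multi)linear maps come for free by exchanging the role
## of an input and the output.

## Pre-shaped wrapper for large static tensors: the 4-index tensor is held
## once as a matrix (rows = first two spec letters, cols = last two), so
## contractions against either index pair run without reshaping copies.
ein_mat <- function(A4, spec) {
  d <- dim(A4)
  list(mat = matrix(A4, d[1] * d[2], d[3] * d[4]),
       dims = d, spec = strsplit(spec, "")[[1]])
}

ein2 <- function(A, ia, B, ib, iout) {
  if (is.list(A) && !is.null(A$mat)) {
    ## A is an ein_mat wrapper; its spec fixes the letter layout
    sa <- A$spec
    stopifnot(identical(sort(strsplit(ia, "")[[1]]), sort(sa)))
    ia_v <- strsplit(ia, "")[[1]]
    stopifnot(identical(ia_v, sa)) # wrapper must be used with its own spec
    ib_v <- strsplit(ib, "")[[1]]
    iout_v <- strsplit(iout, "")[[1]]
    rows <- sa[1:2]; cols <- sa[3:4]
    con <- setdiff(intersect(sa, ib_v), iout_v)
    db <- dim(B); if (is.null(db)) db <- length(B)
    if (setequal(con, cols)) {
      ## contract over the column pair: out rows = row letters
      fb <- setdiff(ib_v, con)
      pb <- c(match(cols, ib_v), match(fb, ib_v))
      Bp <- if (identical(pb, seq_along(pb))) B else aperm(B, pb)
      M <- A$mat %*% matrix(Bp, prod(db[match(cols, ib_v)]), prod(db[match(fb, ib_v)]))
      res_d <- c(A$dims[1:2], db[match(fb, ib_v)])
      res_l <- c(rows, fb)
    } else if (setequal(con, rows)) {
      fb <- setdiff(ib_v, con)
      pb <- c(match(rows, ib_v), match(fb, ib_v))
      Bp <- if (identical(pb, seq_along(pb))) B else aperm(B, pb)
      M <- crossprod(A$mat, matrix(Bp, prod(db[match(rows, ib_v)]), prod(db[match(fb, ib_v)])))
      res_d <- c(A$dims[3:4], db[match(fb, ib_v)])
      res_l <- c(cols, fb)
    } else stop("ein_mat contraction must cover one full index pair")
    pout <- match(iout_v, res_l)
    R <- array(M, res_d)
    return(if (identical(pout, seq_along(pout))) R else aperm(R, pout))
  }
  ia <- strsplit(ia, "")[[1]]; ib <- strsplit(ib, "")[[1]]
  iout <- strsplit(iout, "")[[1]]
  da <- dim(A); if (is.null(da)) da <- length(A)
  db <- dim(B); if (is.null(db)) db <- length(B)
  stopifnot(length(da) == length(ia), length(db) == length(ib))
  con <- setdiff(intersect(ia, ib), iout)
  fa <- setdiff(ia, con); fb <- setdiff(ib, con)
  stopifnot(setequal(c(fa, fb), iout), !anyDuplicated(ia), !anyDuplicated(ib))
  pa <- c(match(fa, ia), match(con, ia))
  pb <- c(match(con, ib), match(fb, ib))
  dfa <- da[match(fa, ia)]; dfb <- db[match(fb, ib)]
  dcon <- prod(da[match(con, ia)])
  pout <- match(iout, c(fa, fb))
  out <- cpp_contract(A, as.integer(da), as.integer(pa),
                      B, as.integer(db), as.integer(pb),
                      as.integer(prod(dfa)), as.integer(dcon),
                      as.integer(prod(dfb)),
                      as.integer(c(dfa, dfb)), as.integer(pout))
  dim(out) <- c(dfa, dfb)[pout]
  out
}
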