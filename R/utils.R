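#' @keywords internal
"_PACKAGE"

# Run code under a temporary, seeded RNG stream and restore global RNG state.
# All generators route their randomness through this so that a spec's seed is
# the only source of randomness (no global side effects).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three-letter <-> one-letter amino acid codes
AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA1 <- stats::setNames(names(AA3), AA3)

aa3to1 <- function(x) {
  out <- unname(AA3[toupper(x)])
  out[is.na(out)] <- "X"
  out
}
aa1to3 <- function(x) {
  out <- unname(AA1[toupper(x)])
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
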