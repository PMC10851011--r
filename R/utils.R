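#' @useDynLib ampedit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rbinom runif setNames aggregate simulate sd
#' @importFrom utils read.delim write.table head
NULL

# Classed conditions so callers (and the command-line wrapper) can
# distinguish configuration problems from data problems.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ampedit_config_error", "ampedit_error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ampedit_input_error", "ampedit_error")))
}

stop_internal <- function(...) {
  stop(errorCondition(paste0(...), class = c("ampedit_internal_error", "ampedit_error")))
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide code -> set of bases matched
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_acgt <- function(x) grepl("^[ACGT]+$", x)

is_iupac <- function(x) grepl("^[ACGTRYSWKMBDHVN]+$", x)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(x, function(s) paste(rev(seq_chars(s)), collapse = ""), ""))
}

# does `pattern` (IUPAC codes) match `subject` (ACGT) exactly, same length?
iupac_match <- function(pattern, subject) {
  if (nchar(pattern) != nchar(subject)) return(FALSE)
  p <- seq_chars(pattern)
  s <- seq_chars(subject)
  all(mapply(function(pc, sc) sc %in% IUPAC[[pc]], p, s))
}

# run the expression under a private RNG stream seeded with `seed`,
# restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# short stable fingerprint of a configuration object, for output provenance
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
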