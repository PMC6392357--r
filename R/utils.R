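# Small shared helpers.

#' Round half away from zero
#'
#' Table-style rounding: halves round up (47.45 -> 47.5), unlike base
#' [round()], which rounds half to even. Used wherever percentages are
#' reported to fixed decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  # small epsilon guards binary-representation shortfalls at exact halves
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a root seed, staying within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shannon entropy of a non-negative vector (natural log, 0 log 0 = 0).
shannon <- function(x) {
  x <- x[x > 0]
  if (!length(x)) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
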