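# Seeding helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's random stream afterwards, so seeded operations never perturb
#' surrounding code. \code{NA} seed means "use the current stream" (no
#' seeding, no restore). All of the package's seeded operations are built on
#' this.
#'
#' @param seed integer seed or \code{NA}.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a distinct child seed from a base seed
#'
#' Deterministic mixing (multiplicative-congruential step modulo
#' 2147483647) so one experiment seed can fan out into independent,
#' 32-bit-safe per-image or per-stage seeds.
#'
#' @param seed integer base seed or \code{NA} (propagated).
#' @param k integer index of the child.
#' @return An integer seed in [0, 2^31).
#' @export
childSeed <- function(seed, k) {
  if (is.null(seed) || is.na(seed)) return(NA_integer_)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

stopIfNotFinite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
}

checkSameShape <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
}

# Uniform integer draw on [lo, hi] inclusive (sample() mangles length-1 ranges).
runifInt <- function(n, lo, hi) pmin(hi, lo + floor(runif(n) * (hi - lo + 1L)))
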