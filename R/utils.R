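# Internal helpers shared across the package: classed conditions and
# scoped RNG so seeded operations never disturb the caller's RNG stream.

abort_flex <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "flexrestrain_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_flex(sprintf("'%s' must be a single finite number", name), "spec_error")
  bad <- if (strict) x <= lower else x < lower
  if (bad)
    abort_flex(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
               "spec_error")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
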