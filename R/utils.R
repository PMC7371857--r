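#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed (must be below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Round-half-up integer percent
#'
#' Formats a fraction as an integer percent using round-half-up (so 0.625
#' prints as "63%", not banker's-rounded "62%"), matching the convention of
#' published pathway-coverage tables.
#'
#' @param x numeric fraction(s) in `[0, 1]`.
#' @return character vector like `"63%"`.
#' @export
#' @examples
#' percent_half_up(c(0.625, 0.2195, 0))
percent_half_up <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  paste0(floor(x * 100 + 0.5), "%")
}

# internal: condition helpers so callers can test error classes
paldyn_stop <- function(class, ...) {
  stop(structure(class = c(class, "paldyn_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
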