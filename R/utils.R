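# Small shared utilities.

#' Round half away from zero
#'
#' Reporting convention for printed percentages: 0.5 at the last kept digit
#' always rounds up (unlike base R's round-half-even). Raw unrounded values
#' are kept in all machine-readable output; this is for display only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(45.45, 1)   # 45.5
#' round(45.45, 1)           # 45.4 under banker's rounding
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Evaluate expr with a locally seeded RNG, restoring global RNG state after.
# seed = NULL uses (and advances) the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
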