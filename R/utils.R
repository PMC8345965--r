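#' @keywords internal
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom stats approx coef glm lm resid sd setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

## Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear interpolation with hard bounds: querying outside [min(x), max(x)] is
# an error, exact grid hits return the stored value bit-for-bit.
interp_linear <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9)) {
    stop(sprintf("%s query outside the observed span [%g, %g]",
                 what, min(x), max(x)), call. = FALSE)
  }
  hit <- match(TRUE, abs(x - xout[1]) < 1e-9)
  if (length(xout) == 1L && !is.na(hit)) return(y[hit])
  stats::approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

is_strictly_increasing <- function(x) all(diff(x) > 0)
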