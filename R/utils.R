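# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream set from \code{seed},
#' restoring the caller's stream afterwards. A \code{NULL} seed leaves the
#' stream untouched, so nested seeded calls compose predictably.
#'
#' @param seed integer seed or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Convert a time lag to an integer number of frames, validating that it is a
# non-negative multiple of dt (relative tolerance 1e-6).
steps_of <- function(lag, dt, what = "lag") {
  if (!is.numeric(lag) || any(!is.finite(lag)) || any(lag < 0))
    stop(what, " must be a finite non-negative time in seconds")
  m <- round(lag / dt)
  if (any(abs(lag - m * dt) > 1e-6 * max(dt, lag)))
    stop(what, " = ", lag[which.max(abs(lag - m * dt))],
         " s is not a multiple of the sampling interval dt = ", dt, " s")
  as.integer(m)
}

stopifnot_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a finite numeric scalar")
  invisible(x)
}

# Geometric mid-point of a fit window, used as the reference lag at which
# fitted MSD amplitudes are compared across ageing times.
window_mid <- function(window) sqrt(window[1] * window[2])
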