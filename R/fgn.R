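# Exact synthesis of fractional Gaussian noise by Davies-Harte circulant
# embedding. The target autocovariance of the increment series is
#   gamma(k) = D * dt^(2H) * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H)),
# so the cumulative path X satisfies E[(X(t) - X(0))^2] = 2 D t^(2H) per
# coordinate (4 D t^(2H) summed over x and y, matching the 2D MSD
# convention MSD = 4 D_alpha t^alpha). Circulant eigenvalues are cached per
# (H, n) since the covariance scales linearly in D * dt^(2H).

.fgn_cache <- new.env(parent = emptyenv())

# Unit-scale circulant eigenvalues for n increments; NULL if the embedding
# is not non-negative definite (does not happen for fGn, but guarded).
.fgn_eigen <- function(H, n) {
  key <- paste0(format(H, digits = 15), ":", n)
  hit <- .fgn_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 0:n
  g <- abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H)
  first_row <- if (n > 1L) c(g, g[n:2]) else g  # lags 0..n, n-1..1
  ev <- Re(stats::fft(first_row))
  tol <- 1e-8 * max(ev)
  if (min(ev) < -tol) return(NULL)
  ev[ev < 0] <- 0
  .fgn_cache[[key]] <- ev
  ev
}

# Exact Cholesky fallback for small n (used only if embedding fails).
.fgn_chol <- function(H, scale, n, s) {
  k <- 0:(n - 1L)
  g <- scale * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  R <- chol(stats::toeplitz(g))
  crossprod(R, matrix(stats::rnorm(n * s), n, s))
}

# Draw s independent fGn series of length n using the current RNG stream.
.fgn_draw <- function(H, D, n, dt, s) {
  scale <- D * dt^(2 * H)
  if (scale == 0) return(matrix(0, n, s))
  ev <- .fgn_eigen(H, n)
  if (is.null(ev)) {
    if (n > 4096L)
      stop("circulant embedding failed for H = ", H, ", n = ", n,
           " and n is too large for the Cholesky fallback")
    message("circulant embedding not nonnegative; using exact Cholesky")
    return(.fgn_chol(H, scale, n, s))
  }
  m <- 2L * n
  half <- n
  sq <- sqrt(ev * scale)
  # block the columns so the working complex matrix stays modest
  block <- max(1L, min(s, as.integer(2^22 / m)))
  out <- matrix(0, n, s)
  done <- 0L
  while (done < s) {
    nb <- min(block, s - done)
    V <- matrix(0 + 0i, m, nb)
    V[1L, ] <- stats::rnorm(nb)
    V[half + 1L, ] <- stats::rnorm(nb)
    if (half > 1L) {
      Z1 <- matrix(stats::rnorm((half - 1L) * nb), half - 1L, nb)
      Z2 <- matrix(stats::rnorm((half - 1L) * nb), half - 1L, nb)
      V[2:half, ] <- (Z1 + 1i * Z2) / sqrt(2)
      V[m:(half + 2L), ] <- Conj(V[2:half, , drop = FALSE])
    }
    X <- Re(stats::mvfft(V * sq)) / sqrt(m)
    out[, (done + 1L):(done + nb)] <- X[1:n, , drop = FALSE]
    done <- done + nb
  }
  out
}

#' Generate fractional Gaussian noise
#'
#' Exact stationary Gaussian increments of fractional Brownian motion with
#' Hurst exponent \code{H} and generalized diffusion coefficient \code{D},
#' synthesized by Davies-Harte circulant embedding (falling back to exact
#' Cholesky for short series if the embedding fails). The cumulative sum of
#' a column is an FBM path with per-coordinate MSD \code{2 D t^(2H)}.
#'
#' @param H Hurst exponent in (0, 1).
#' @param D generalized diffusion coefficient (um^2 / s^(2H)).
#' @param n_steps number of increments.
#' @param dt sampling interval (s).
#' @param n_series number of independent series (columns).
#' @param seed RNG seed.
#' @return numeric matrix \code{n_steps x n_series} of increments (um).
#' @export
generate_fgn <- function(H, D, n_steps, dt, n_series = 1L, seed = NULL) {
  if (!is.numeric(H) || H <= 0 || H >= 1) stop("H must be in (0, 1)")
  if (D < 0) stop("D must be >= 0")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  with_seed(seed, .fgn_draw(H, D, as.integer(n_steps), dt,
                            as.integer(n_series)))
}

# Theoretical fGn autocovariance at integer lags (exported for tests/docs).
#' fGn autocovariance
#'
#' Closed-form autocovariance of the increment series produced by
#' \code{\link{generate_fgn}} at integer frame lags.
#'
#' @inheritParams generate_fgn
#' @param k integer lags (0, 1, 2, ...).
#' @return numeric vector \code{D * dt^(2H) * (|k+1|^(2H) - 2|k|^(2H) +
#'   |k-1|^(2H))}.
#' @export
fgn_autocovariance <- function(k, H, D, dt) {
  D * dt^(2 * H) * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                      abs(k - 1)^(2 * H))
}
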