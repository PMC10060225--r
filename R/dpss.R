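#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the `K` leading DPSS tapers of length `N` for time-bandwidth
#' product `NW` via the classical symmetric tridiagonal eigenproblem
#' (diagonal `((N-1-2t)/2)^2 cos(2 pi W)`, off-diagonal `t(N-t)/2`), whose
#' eigenvectors are the Slepian sequences ordered by in-band energy
#' concentration. Tapers are unit-energy; polarity follows the usual
#' convention (symmetric tapers have positive mean, antisymmetric tapers
#' start with a positive lobe). Concentration ratios are computed from the
#' sinc kernel `sin(2 pi W (i-j)) / (pi (i-j))`, i.e. the fraction of each
#' taper's spectral energy inside `[-W, W]`.
#'
#' @param N Taper length in samples; must exceed `K`.
#' @param NW Time-bandwidth product (half-bandwidth `W = NW/N` cycles per
#'   sample).
#' @param K Number of tapers, `1 <= K <= 2*NW` (beyond `2*NW` concentration
#'   collapses).
#' @return A `taper_set`: list with `tapers` (K x N matrix, one taper per
#'   row), `concentrations` (strictly decreasing, in (0,1)), and `params`.
#' @examples
#' ts <- compute_dpss(256, 3, 5)
#' ts$concentrations
#' @export
compute_dpss <- function(N, NW, K) {
  if (K < 1 || K > 2 * NW) {
    stop("K must satisfy 1 <= K <= 2*NW; tapers beyond 2*NW are poorly ",
         "concentrated", call. = FALSE)
  }
  if (N <= K) stop("N must exceed K", call. = FALSE)
  W <- NW / N
  t <- 0:(N - 1)
  A <- matrix(0, N, N)
  diag(A) <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (N - t[-1]) / 2
  A[cbind(2:N, 1:(N - 1))] <- off
  A[cbind(1:(N - 1), 2:N)] <- off
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    v <- V[, k] / sqrt(sum(V[, k]^2))
    if (k %% 2 == 1) {                     # symmetric: positive mean
      if (sum(v) < 0) v <- -v
    } else {                               # antisymmetric: positive start
      if (sum((N - 1 - 2 * t) * v) < 0) v <- -v
    }
    V[, k] <- v
  }
  d <- outer(t, t, "-")
  S <- sin(2 * pi * W * d) / (pi * d)
  diag(S) <- 2 * W
  lam <- vapply(seq_len(K), function(k) drop(V[, k] %*% S %*% V[, k]),
                numeric(1))
  structure(list(tapers = t(V), concentrations = lam,
                 params = list(N = N, NW = NW, K = K, W = W)),
            class = "taper_set")
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf("<taper_set> K = %d DPSS tapers, N = %d, NW = %g (W = %.4g)\n",
              x$params$K, x$params$N, x$params$NW, x$params$W))
  cat("concentrations:", format(x$concentrations, digits = 6), "\n")
  invisible(x)
}

# a single boxcar "taper set" (unit energy); used to reduce the multitaper
# estimator to a plain windowed periodogram for cross-checks
boxcar_taper <- function(N) {
  structure(list(tapers = matrix(1 / sqrt(N), 1, N),
                 concentrations = 1,
                 params = list(N = N, NW = NA_real_, K = 1L, W = NA_real_)),
            class = "taper_set")
}
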