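#' Gauss-Legendre quadrature nodes and weights
#'
#' Computes an n-point Gauss-Legendre rule on \code{[a, b]} via the
#' Golub-Welsch eigenvalue method (symmetric tridiagonal Jacobi matrix).
#'
#' @param n number of nodes (>= 1).
#' @param a,b interval endpoints.
#' @return list with numeric vectors \code{nodes} and \code{weights}.
#' @export
gauss_legendre <- function(n, a = -1, b = 1) {
  stopifnot(n >= 1, is.finite(a), is.finite(b))
  if (n == 1L) {
    x <- 0
    w <- 2
  } else {
    k <- seq_len(n - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- 2 * e$vectors[1L, ]^2
    o <- order(x)
    x <- x[o]
    w <- w[o]
  }
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Trapezoidal integration
#' @param x grid (strictly increasing).
#' @param y values at \code{x}.
#' @return scalar integral estimate.
#' @export
trapz <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Wrap angles to (-pi, pi]
#' @param theta numeric vector of angles (radians).
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor maps pi to (-pi]; put the branch point at +pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# centered moving average with truncated windows at the edges
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cnt <- cumsum(c(0, !is.na(x)))
  i0 <- pmax(seq_len(n) - half, 1L)
  i1 <- pmin(seq_len(n) + half, n)
  s <- cs[i1 + 1L] - cs[i0]
  m <- cnt[i1 + 1L] - cnt[i0]
  out <- s / m
  out[m == 0] <- NA_real_
  out
}
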