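#' @keywords internal
"_PACKAGE"

## Numerically stable inverse logit and log(1 + exp(x)).
expit <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

logit <- function(p) log(p) - log1p(-p)

## log(1 + exp(x)) without overflow; used for -log(1 + theta(a, c)).
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out[!lo & !mid] <- x[!lo & !mid]
  out
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule (weight function
#' exp(-x^2)), computed by the Golub-Welsch eigenvalue method on the
#' symmetric tridiagonal Jacobi matrix. Used to evaluate Gaussian-weighted
#' integrals such as the logistic-normal counterfactual probability: for
#' M ~ N(mu, sigma^2), E[f(M)] is approximated by
#' sum(w * f(mu + sigma * sqrt(2) * x)) / sqrt(pi).
#'
#' @param n number of nodes (>= 1).
#' @return list with components `nodes` and `weights`, each length `n`.
#' @examples
#' gh <- gauss_hermite(32)
#' # integral of exp(-x^2) is sqrt(pi)
#' all.equal(sum(gh$weights), sqrt(pi))
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (n == 1L) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = sqrt(pi) * e$vectors[1, idx]^2)
}

## Central finite-difference gradient of scalar-valued f at x.
num_gradient <- function(f, x, step = 1e-6 * (1 + abs(x))) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hi <- x; hi[j] <- x[j] + step[j]
    lo <- x; lo[j] <- x[j] - step[j]
    g[j] <- (f(hi) - f(lo)) / (2 * step[j])
  }
  g
}

## Central finite-difference Hessian of scalar-valued f at x.
num_hessian <- function(f, x, step = 1e-5 * (1 + abs(x))) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    hi <- x; hi[i] <- x[i] + step[i]
    lo <- x; lo[i] <- x[i] - step[i]
    H[i, i] <- (f(hi) - 2 * f0 + f(lo)) / step[i]^2
    if (i < k) {
      for (j in seq((i + 1L), k)) {
        pp <- x; pp[i] <- x[i] + step[i]; pp[j] <- x[j] + step[j]
        pm <- x; pm[i] <- x[i] + step[i]; pm[j] <- x[j] - step[j]
        mp <- x; mp[i] <- x[i] - step[i]; mp[j] <- x[j] + step[j]
        mm <- x; mm[i] <- x[i] - step[i]; mm[j] <- x[j] - step[j]
        H[i, j] <- H[j, i] <-
          (f(pp) - f(pm) - f(mp) + f(mm)) / (4 * step[i] * step[j])
      }
    }
  }
  H
}

#' Derive a reproducible child seed from a master seed and a counter
#'
#' Counter-based seed splitting so replicate r of a benchmark run is
#' reproducible in isolation. The result is always a valid 32-bit seed.
#'
#' @param master integer master seed.
#' @param counter nonnegative integer stream index.
#' @return an integer in [0, 2^31 - 2].
#' @export
split_seed <- function(master, counter) {
  ## affine hash over the Mersenne prime 2^31 - 1; coefficients are the
  ## classic MINSTD multiplier and Knuth's multiplicative constant
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + (as.numeric(counter) %% m) * 69621) %% m
  as.integer((x * 16807 + 12345) %% m)
}
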