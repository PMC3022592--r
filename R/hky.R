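#' HKY85 substitution model parameters
#'
#' Container for the parameters of the HKY85 nucleotide substitution model
#' with Gamma-distributed among-site rate variation: the
#' transition/transversion rate ratio `kappa`, the stationary base frequencies
#' `pi` (order A, C, G, T) and the Gamma shape `gamma_shape` (mean-1 rates).
#' The rate matrix is scaled so that the expected number of substitutions per
#' site per unit branch length equals 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0). `kappa = 1` with
#'   uniform frequencies reduces the model to Jukes-Cantor.
#' @param pi Base frequencies, positive and summing to 1.
#' @param gamma_shape Gamma shape parameter for among-site rate variation
#'   (> 0); `Inf` means equal rates.
#' @return An object of class `hky_params`.
#' @examples
#' hky_params(kappa = 4)
#' @export
hky_params <- function(kappa = 4,
                       pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       gamma_shape = 1) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    .stopf("'kappa' must be a positive number")
  }
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    .stopf("'pi' must be 4 positive frequencies summing to 1")
  }
  names(pi) <- c("A", "C", "G", "T")
  if (!is.numeric(gamma_shape) || length(gamma_shape) != 1L || gamma_shape <= 0) {
    .stopf("'gamma_shape' must be positive (use Inf for equal rates)")
  }
  structure(list(kappa = kappa, pi = pi, gamma_shape = gamma_shape),
            class = "hky_params")
}

#' @export
print.hky_params <- function(x, ...) {
  cat(sprintf("HKY+G model: kappa = %.4g, gamma shape = %.4g\n",
              x$kappa, x$gamma_shape))
  cat("  base frequencies:",
      paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = " "), "\n")
  invisible(x)
}

# Scaled HKY rate matrix (rows = from, cols = to; order A, C, G, T).
.hky_q <- function(model) {
  pi <- model$pi
  k <- model$kappa
  Q <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  # transitions: A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    trans <- (i == 1 && j == 3) || (i == 3 && j == 1) ||
      (i == 2 && j == 4) || (i == 4 && j == 2)
    Q[i, j] <- if (trans) k * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # mean substitution rate
  Q / mu
}

# Symmetric eigendecomposition of the (reversible) HKY generator.
# Returns eigenvalues `lambda` and the tensor A with
# P[a, b](t) = sum_k A[a, b, k] * exp(lambda[k] * t).
.hky_eigen <- function(model) {
  Q <- .hky_q(model)
  pi <- model$pi
  s <- sqrt(pi)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  V <- diag(1 / s) %*% e$vectors
  Vi <- t(e$vectors) %*% diag(s)
  A <- array(0, c(4, 4, 4))
  for (k in 1:4) A[, , k] <- outer(V[, k], Vi[k, ])
  # W: 16 x 4 joint-probability weights, cell (a-1)*4+b row-major, so that
  # J_ab(t) = pi_a P_ab(t) = W %*% exp(lambda t)
  W <- matrix(0, 16, 4)
  for (k in 1:4) W[, k] <- as.vector(t(pi * A[, , k]))
  list(lambda = e$values, A = A, pi = pi, W = W)
}

# 16-vector of joint probabilities at a single distance d (Gamma-averaged)
.hky_joint_one <- function(eig, d, rates) {
  v <- rowMeans(exp(outer(eig$lambda, d * rates)))
  J <- as.vector(eig$W %*% v)
  J[J < 1e-300] <- 1e-300
  J
}

# Transition probability matrix for a branch of length d (scalar).
.hky_pmat <- function(eig, d) {
  P <- matrix(0, 4, 4)
  ed <- exp(eig$lambda * d)
  for (k in 1:4) P <- P + eig$A[, , k] * ed[k]
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete Gamma rate categories
#'
#' Mean rates of `k` equal-probability categories of a Gamma distribution with
#' the given shape and mean 1 (the standard discrete-Gamma approximation used
#' for likelihood computation).
#'
#' @param shape Gamma shape parameter; `Inf` returns all-1 rates.
#' @param k Number of categories.
#' @return Numeric vector of `k` category rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (is.infinite(shape)) return(rep(1, k))
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  # mean of the Gamma(shape, shape) density over each inter-quantile slice
  cdf1 <- stats::pgamma(q, shape = shape + 1, rate = shape)
  r <- k * diff(cdf1)
  r / mean(r)
}

# Joint log-probability table machinery for pairwise ML distances -------------

# 16-row matrix (cells a*4+b in row-major order A..T x A..T) of joint
# probabilities J_ab(d) = pi_a * mean_c P_ab(d * r_c), evaluated at every
# distance in `dgrid`; returns 16 x length(dgrid).
.hky_joint_grid <- function(eig, dgrid, rates) {
  J <- matrix(0, 16, length(dgrid))
  for (r in rates) {
    E <- exp(outer(eig$lambda, dgrid * r))  # 4 x G
    J <- J + eig$W %*% E
  }
  J <- J / length(rates)
  J[J < 1e-300] <- 1e-300
  J
}

# Pairwise log-likelihood for a 16-vector of site-pattern counts at distance d.
.hky_pair_ll <- function(counts16, eig, d, rates) {
  sum(counts16 * log(.hky_joint_one(eig, d, rates)))
}
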