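# Independent straight-line re-evaluations used as oracles. These deliberately
# avoid the package's numerical shortcuts (log-sum-exp, Cholesky solves,
# compiled code) so that agreement is evidence, not tautology.

# attention block re-evaluated formula by formula on one 21x4 window
oracle_attention <- function(window, params) {
  pooled <- rep(0, 4)
  for (i in seq_len(nrow(window))) {
    f <- window[i, ]
    g <- as.numeric(params$gate_weights %*% f + params$gate_bias)
    c_t <- 4 * exp(g) / sum(exp(g))
    pooled <- pooled + c_t * f + f
  }
  pooled <- pooled / nrow(window)
  as.numeric(t(params$projection) %*% pooled)
}

# bivariate normal density via explicit inverse and determinant
oracle_dmvnorm <- function(s, mean, cov) {
  d <- s - mean
  inv <- solve(cov)
  exp(-0.5 * as.numeric(t(d) %*% inv %*% d)) /
    (2 * pi * sqrt(det(cov)))
}

# mixture density by naive summation (no log-sum-exp)
oracle_gmm_density <- function(s, params) {
  sum(vapply(seq_len(params$K), function(k) {
    params$weights[k] * oracle_dmvnorm(s, params$means[k, ], params$covs[, , k])
  }, numeric(1)))
}

# posterior responsibilities term by term
oracle_responsibility <- function(s, params) {
  terms <- vapply(seq_len(params$K), function(k) {
    params$weights[k] * oracle_dmvnorm(s, params$means[k, ], params$covs[, , k])
  }, numeric(1))
  terms / sum(terms)
}

# Dirichlet KLD by numerical integration (K = 2 reduces to a Beta integral)
oracle_beta_kld <- function(a, b) {
  q <- function(x) stats::dbeta(x, a[1], a[2])
  p <- function(x) stats::dbeta(x, b[1], b[2])
  stats::integrate(function(x) {
    v <- q(x) * (log(q(x)) - log(p(x)))
    ifelse(is.finite(v), v, 0)
  }, 0, 1, rel.tol = 1e-10)$value
}

# Gamma KLD by numerical integration (shape/scale)
oracle_gamma_kld <- function(a1, s1, a2, s2) {
  q <- function(x) stats::dgamma(x, shape = a1, scale = s1)
  p <- function(x) stats::dgamma(x, shape = a2, scale = s2)
  stats::integrate(function(x) {
    v <- q(x) * (log(q(x)) - log(p(x)))
    ifelse(is.finite(v), v, 0)
  }, 0, Inf, rel.tol = 1e-9)$value
}

# Gaussian KLD by numerical integration (univariate)
oracle_gaussian_kld <- function(m1, v1, m2, v2) {
  q <- function(x) stats::dnorm(x, m1, sqrt(v1))
  p <- function(x) stats::dnorm(x, m2, sqrt(v2))
  stats::integrate(function(x) {
    v <- q(x) * (log(q(x)) - log(p(x)))
    ifelse(is.finite(v), v, 0)
  }, -Inf, Inf, rel.tol = 1e-10)$value
}

# a random valid variational state for property sweeps
random_state <- function(K = 3L, covariance_mode = "full", dim = 2L,
                         attention = NULL) {
  N1 <- matrix(rnorm(K * dim), K, dim)
  N2 <- matrix(exp(runif(K * dim, -3, 1)), K, dim)
  W1 <- (dim - 1) + exp(runif(K, -1, 3))
  W2 <- array(0, dim = c(dim, dim, K))
  for (k in seq_len(K)) {
    if (covariance_mode == "full") {
      L <- matrix(0, 2, 2)
      diag(L) <- exp(runif(2, -1, 1))
      L[2, 1] <- rnorm(1, 0, 0.5)
      W2[, , k] <- L %*% t(L)
    } else {
      W2[, , k] <- diag(exp(runif(2, -1, 1)), 2)
    }
  }
  D <- exp(runif(K, -1, 2))
  variational_state(N1, N2, W1, W2, D,
    covariance_mode = covariance_mode,
    attention = attention
  )
}

random_gmm <- function(K = 3L) {
  w <- exp(runif(K))
  means <- matrix(rnorm(K * 2, 0, 2), K, 2)
  covs <- array(0, dim = c(2, 2, K))
  for (k in seq_len(K)) {
    L <- matrix(0, 2, 2)
    diag(L) <- exp(runif(2, -1, 0.5))
    L[2, 1] <- rnorm(1, 0, 0.4)
    covs[, , k] <- L %*% t(L)
  }
  gmm_params(w / sum(w), means, covs)
}

# convex-hull overlap of two point clouds on a raster (Jaccard of hull areas)
hull_overlap <- function(f1, f2, n = 120) {
  grid <- as.matrix(expand.grid(
    x = seq(0, 1, length.out = n),
    y = seq(0, 1, length.out = n)
  ))
  inhull <- function(f) {
    h <- grDevices::chull(f$s1, f$s2)
    pracma::inpolygon(grid[, 1], grid[, 2], f$s1[h], f$s2[h])
  }
  a <- inhull(f1)
  b <- inhull(f2)
  sum(a & b) / sum(a | b)
}
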