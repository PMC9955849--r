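# multivariate log-gamma and digamma for dimension d
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}
mvdigamma <- function(a, d) {
  sum(digamma(a + (1 - seq_len(d)) / 2))
}

# KL( N(m1, diag(v1)) || N(m2, v2 * I) ) with independent coordinates
kld_gaussian_diag <- function(m1, v1, m2, v2) {
  0.5 * sum(v1 / v2 + (m1 - m2)^2 / v2 - 1 - log(v1 / v2))
}

# KL( Wishart(nu1, V1) || Wishart(nu2, V2) ), d-dimensional
kld_wishart <- function(nu1, V1, nu2, V2, d = nrow(V1)) {
  V2inv_V1 <- solve(V2, V1)
  ((nu1 - nu2) / 2) * mvdigamma(nu1 / 2, d) -
    nu1 * d / 2 + (nu1 / 2) * sum(diag(V2inv_V1)) +
    lmvgamma(nu2 / 2, d) - lmvgamma(nu1 / 2, d) +
    (nu2 / 2) * (determinant(V2)$modulus - determinant(V1)$modulus)
}

# KL( Gamma(a1, scale s1) || Gamma(a2, scale s2) )
kld_gamma <- function(a1, s1, a2, s2) {
  (a1 - a2) * digamma(a1) - lgamma(a1) + lgamma(a2) +
    a2 * (log(s2) - log(s1)) + a1 * (s1 - s2) / s2
}

# KL( Dirichlet(a) || Dirichlet(b) )
kld_dirichlet <- function(a, b) {
  a0 <- sum(a)
  b0 <- sum(b)
  lgamma(a0) - sum(lgamma(a)) - lgamma(b0) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(a0)))
}

#' Kullback-Leibler divergence of the variational state from the prior
#'
#' Sums the closed-form divergences of the per-cluster mean distributions
#' (Gaussian-to-Gaussian), precision distributions (Wishart-to-Wishart in full
#' mode; its diagonal Gamma analogue in diagonal mode) and the weight
#' distribution (Dirichlet-to-Dirichlet). Always nonnegative.
#'
#' @param state A [variational_state()].
#' @param prior A [prior_spec()].
#' @return A nonnegative scalar.
#' @export
kld_variational_prior <- function(state, prior) {
  stopifnot(inherits(state, "variational_state"), inherits(prior, "prior_spec"))
  validate_state(state)
  if (state$K != prior$K || state$dim != prior$dim) {
    stop("invalid distribution: state and prior dimensions differ", call. = FALSE)
  }
  d <- state$dim
  total <- 0
  for (k in seq_len(state$K)) {
    total <- total + kld_gaussian_diag(
      state$N1[k, ], state$N2[k, ],
      prior$mean_mean[k, ], prior$mean_var
    )
    if (state$covariance_mode == "full") {
      total <- total + kld_wishart(
        state$W1[k], state$W2[, , k],
        prior$wishart_df[k], prior$wishart_scale[, , k], d
      )
    } else {
      for (i in seq_len(d)) {
        total <- total + kld_gamma(
          state$W1[k] / 2, 2 * state$W2[i, i, k],
          prior$wishart_df[k] / 2, 2 * prior$wishart_scale[i, i, k]
        )
      }
    }
  }
  total <- total + kld_dirichlet(state$D, prior$dirichlet)
  as.numeric(total)
}
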