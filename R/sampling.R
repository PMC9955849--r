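#' Reparameterized draws of mixture parameters from the variational state
#'
#' Means are drawn by the location-scale transform `N1 + sqrt(N2) * eps`;
#' precisions by the Bartlett decomposition of the Wishart (inverse-CDF
#' chi-square diagonal, so the draw is a smooth function of the degrees of
#' freedom given fixed uniforms); weights by normalized inverse-CDF Gamma
#' draws. All draws are therefore pathwise-differentiable in the variational
#' parameters with the underlying noise held fixed, and deterministic given
#' the seed.
#'
#' @param state A [variational_state()].
#' @param L Number of draws (sampling size).
#' @param seed Integer seed.
#' @return A list of `L` [gmm_params()] objects.
#' @export
sample_gmm_params <- function(state, L, seed = 1L) {
  stopifnot(inherits(state, "variational_state"), L >= 1)
  K <- state$K
  dim <- state$dim
  noise <- withr::with_seed(seed, list(
    eps = array(rnorm(L * K * dim), dim = c(L, K, dim)),
    u_chi = array(runif(L * K * dim), dim = c(L, K, dim)),
    z_off = matrix(rnorm(L * K), L, K),
    u_gam = matrix(runif(L * K), L, K)
  ))
  lapply(seq_len(L), function(l) {
    gmm_draw_from_noise(
      state,
      eps = noise$eps[l, , , drop = FALSE][1, , , drop = TRUE],
      u_chi = noise$u_chi[l, , , drop = FALSE][1, , , drop = TRUE],
      z_off = noise$z_off[l, ],
      u_gam = noise$u_gam[l, ]
    )
  })
}

# build one gmm_params draw from fixed base noise (K x dim matrices / K vecs)
gmm_draw_from_noise <- function(state, eps, u_chi, z_off, u_gam) {
  K <- state$K
  dim <- state$dim
  eps <- matrix(eps, K, dim)
  u_chi <- matrix(u_chi, K, dim)
  means <- state$N1 + sqrt(state$N2) * eps
  covs <- array(0, dim = c(dim, dim, K))
  for (k in seq_len(K)) {
    nu <- state$W1[k]
    if (state$covariance_mode == "full") {
      A <- matrix(0, 2, 2)
      A[1, 1] <- sqrt(qchisq(u_chi[k, 1], df = nu))
      A[2, 2] <- sqrt(qchisq(u_chi[k, 2], df = nu - 1))
      A[2, 1] <- z_off[k]
      Lw <- t(chol(state$W2[, , k]))
      B <- Lw %*% A
      prec <- B %*% t(B)
    } else {
      lambda <- vapply(seq_len(dim), function(i) {
        qgamma(u_chi[k, i], shape = nu / 2, scale = 2 * state$W2[i, i, k])
      }, numeric(1))
      prec <- diag(lambda, dim)
    }
    covs[, , k] <- solve(prec)
  }
  g <- pmax(qgamma(u_gam, shape = state$D, scale = 1), 1e-12)
  gmm_params(weights = g / sum(g), means = means, covs = covs)
}

#' Monte-Carlo stochastic-variational loss
#'
#' The negative of the Monte-Carlo evidence lower bound: minus the average
#' over `L` reparameterized parameter draws of the mean mixture
#' log-likelihood of the batch, plus the KLD between the variational state
#' and the prior. Because the KLD is nonnegative, the loss is always at least
#' the negative Monte-Carlo likelihood term.
#'
#' @param batch Feature vectors (tibble with `s1`, `s2`, or an n x 2 matrix).
#' @param state A [variational_state()].
#' @param prior A [prior_spec()].
#' @param L Sampling size.
#' @param seed Integer seed for the draws.
#' @param kld_weight Weight on the KLD term (1 reproduces the plain
#'   batch-mean objective; `1/n` puts prior and likelihood on the same
#'   per-sample scale during training).
#' @return A scalar loss.
#' @export
svi_loss <- function(batch, state, prior, L = 10L, seed = 1L, kld_weight = 1) {
  smat <- as_feature_matrix(batch)
  if (nrow(smat) == 0L) stop("empty input: batch has no rows", call. = FALSE)
  draws <- sample_gmm_params(state, L, seed = seed)
  mc <- mean(vapply(
    draws,
    function(p) mean(gmm_log_likelihood(smat, p)),
    numeric(1)
  ))
  kld <- kld_variational_prior(state, prior)
  loss <- -(mc - kld_weight * kld)
  if (!is.finite(loss)) stop("numerical failure: non-finite loss", call. = FALSE)
  loss
}
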