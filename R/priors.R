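#' Prior specification for the variational mixture
#'
#' Per cluster, the mean prior is standard Normal per coordinate, the
#' precision prior is Wishart with 3 degrees of freedom and scale `I/3`
#' (so the prior mean precision is the identity), and the mixture weights
#' carry a symmetric Dirichlet prior. The Dirichlet concentration is `2/K`
#' per component by default; the literal reading `2K` is selectable.
#'
#' @param K Number of mixture components.
#' @param dim Feature-space dimension (2).
#' @param dirichlet_interpretation `"2/K"` (default) or `"2K"`.
#' @return An object of class `prior_spec` with per-cluster fields
#'   `mean_mean` (K x dim), `mean_var` (scalar), `wishart_df` (length K),
#'   `wishart_scale` (dim x dim x K) and `dirichlet` (length K).
#' @export
prior_spec <- function(K, dim = 2L, dirichlet_interpretation = c("2/K", "2K")) {
  stopifnot(K >= 1, dim >= 1)
  dirichlet_interpretation <- match.arg(dirichlet_interpretation)
  conc <- if (dirichlet_interpretation == "2/K") 2 / K else 2 * K
  wdf <- dim + 1 # > dim - 1; equals 3 in the 2-D feature space
  scale <- diag(dim) / wdf # prior mean precision = wdf * scale = I
  structure(
    list(
      K = as.integer(K), dim = as.integer(dim),
      mean_mean = matrix(0, K, dim), mean_var = 1,
      wishart_df = rep(wdf, K),
      wishart_scale = array(scale, dim = c(dim, dim, K)),
      dirichlet = rep(conc, K),
      dirichlet_interpretation = dirichlet_interpretation
    ),
    class = "prior_spec"
  )
}

#' Training configuration for stochastic variational inference
#'
#' @param L Monte-Carlo sampling size for the likelihood term.
#' @param batch_size Mini-batch size.
#' @param step_size Gradient-descent step size.
#' @param momentum Momentum coefficient.
#' @param steps Number of gradient steps.
#' @param kld_weight Weight on the KLD term in the training objective;
#'   `NULL` (default) uses `1/n` so the likelihood and prior are on the same
#'   per-sample scale, the standard stochastic-variational scaling.
#' @param prior_refresh_every If positive, every this many steps the prior is
#'   refreshed with the current variational summary (an empirical-Bayes mode);
#'   0 disables it (default).
#' @param train_projection Whether gradient descent also updates the 4-to-2
#'   projection of the attention block. Off by default: the gates (the
#'   attention weights proper) and the mixture are trained, while the
#'   projection stays at its vertical-kinematics template, because an
#'   unconstrained projection lets the unsupervised likelihood rotate the
#'   rare, heavy-tailed fall direction out of the feature plane.
#' @param fd_eps Relative step for the finite-difference pathwise gradients.
#' @return A list of class `svi_config`.
#' @export
svi_config <- function(L = 10L, batch_size = 64L, step_size = 1e-2,
                       momentum = 0.9, steps = 2000L, kld_weight = NULL,
                       prior_refresh_every = 0L, train_projection = FALSE,
                       fd_eps = 1e-6) {
  stopifnot(L >= 1, batch_size >= 1, step_size > 0, momentum >= 0,
    momentum < 1, steps >= 1, fd_eps > 0)
  structure(
    list(
      L = as.integer(L), batch_size = as.integer(batch_size),
      step_size = step_size, momentum = momentum, steps = as.integer(steps),
      kld_weight = kld_weight,
      prior_refresh_every = as.integer(prior_refresh_every),
      train_projection = isTRUE(train_projection), fd_eps = fd_eps
    ),
    class = "svi_config"
  )
}
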