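#' Fit the stochastic-variational Gaussian mixture
#'
#' Minimizes the Monte-Carlo evidence-lower-bound loss by mini-batch gradient
#' descent with momentum, jointly over the variational distribution parameters
#' (`N1`, `N2`, `W1`, `W2`, `D`, through unconstrained reparameterizations:
#' Cholesky factors for positive-definite scales, shifted log for degrees of
#' freedom, softplus for concentrations) and, when `x` is a set of feature
#' windows, the attention-block parameters. Gradients are pathwise
#' (reparameterized draws with the noise held fixed) computed in compiled
#' code. Deterministic given `seed`.
#'
#' @param x Training data: a tibble with columns `s1`, `s2` (attention
#'   bypassed) or a `feature_windows` tibble from [make_windows()] (attention
#'   trained jointly).
#' @param K Number of mixture components (2 or 3 in the posture model; other
#'   values are allowed with a warning).
#' @param covariance_mode `"full"` or `"diagonal"`.
#' @param prior A [prior_spec()]; defaults to `prior_spec(K)`.
#' @param config An [svi_config()].
#' @param attention Initial [attention_params()] when fitting windows;
#'   defaults to [init_attention()] under `seed`.
#' @param seed Integer seed governing initialization, mini-batches and
#'   reparameterization noise.
#' @return An object of class `svi_gmm`: the final `variational_state`, the
#'   per-step loss trace, the training features at the final attention
#'   parameters, and the configuration. See [expected_gmm()], [tidy.svi_gmm()],
#'   [assign_cluster_labels()].
#' @export
svi_fit <- function(x, K = 3L, covariance_mode = c("full", "diagonal"),
                    prior = NULL, config = svi_config(), attention = NULL,
                    seed = 1L) {
  covariance_mode <- match.arg(covariance_mode)
  if (!K %in% c(2L, 3L)) {
    warning("the posture model uses K = 2 or 3; fitting K = ", K)
  }
  if (is.null(prior)) prior <- prior_spec(K)
  stopifnot(prior$K == K)
  dim <- prior$dim

  is_windows <- inherits(x, "feature_windows")
  if (!is_windows && is.data.frame(x) && !is.null(x[["features"]])) {
    stop("windows must be a feature_windows object from make_windows()",
      call. = FALSE
    )
  }
  labels <- if (is.data.frame(x)) x[["label"]] else NULL
  n <- if (is_windows) nrow(x) else nrow(as_feature_matrix(x))
  if (is.null(n) || n == 0L) stop("empty input: no training data", call. = FALSE)
  kld_weight <- config$kld_weight
  if (is.null(kld_weight)) kld_weight <- 1 / n

  res <- withr::with_seed(seed, {
    if (is_windows) {
      if (is.null(attention)) attention <- init_attention()
      f0 <- as.matrix(attention_forward(x, attention)[, c("s1", "s2")])
    } else {
      attention <- NULL
      f0 <- as_feature_matrix(x)
    }
    state0 <- init_state_kmeans(f0, K, covariance_mode, attention)
    theta0 <- pack_state(state0)
    fit <- cpp_svi_fit(
      windows = if (is_windows) x$features else list(),
      rawF = if (is_windows) matrix(0, 0, dim) else f0,
      theta0 = theta0, K = K, dim = dim,
      full_cov = covariance_mode == "full",
      has_attention = is_windows,
      prior_mean = prior$mean_mean, prior_mean_var = prior$mean_var,
      prior_wdf = prior$wishart_df, prior_wscale = prior$wishart_scale,
      prior_dir = prior$dirichlet,
      L = config$L, batch_size = config$batch_size,
      step_size = config$step_size, momentum = config$momentum,
      steps = config$steps, kld_weight = kld_weight,
      prior_refresh_every = config$prior_refresh_every,
      train_projection = config$train_projection %||% FALSE,
      fd_eps = config$fd_eps
    )
    fit
  })

  state <- unpack_state(as.numeric(res$theta), K, dim, covariance_mode, is_windows)
  feats <- if (is_windows) {
    attention_forward(x, state$attention)
  } else {
    fm <- as_feature_matrix(x)
    tibble::tibble(t = seq_len(nrow(fm)), s1 = fm[, 1], s2 = fm[, 2])
  }
  if (!is.null(labels)) feats$label <- labels

  out <- structure(
    list(
      state = state, prior = prior, config = config, seed = seed,
      K = K, covariance_mode = covariance_mode, n = n,
      kld_weight = kld_weight,
      trace = tibble::tibble(
        step = seq_along(res$trace), loss = as.numeric(res$trace)
      ),
      features = feats, cluster_labels = NULL, normalization = NULL
    ),
    class = "svi_gmm"
  )
  if (!is.null(labels)) out <- assign_cluster_labels(out)
  out
}

# k-means initialization of the variational state on the initial features
init_state_kmeans <- function(f0, K, covariance_mode, attention) {
  dim <- ncol(f0)
  km <- kmeans(f0, centers = K, nstart = 5, iter.max = 50)
  ord <- order(km$centers[, 1], km$centers[, 2]) # stable cluster ordering
  centers <- km$centers[ord, , drop = FALSE]
  sizes <- km$size[ord]
  # posterior-like concentrations: a Wishart with nu ~ n_k draws precisions
  # with the sampling noise the data actually supports, instead of the wild
  # fluctuations of a diffuse nu that destabilize early training
  W1 <- pmax(sizes, dim + 2)
  W2 <- array(0, dim = c(dim, dim, K))
  ridge <- max(1e-8, 1e-4 * mean(apply(f0, 2, stats::var)))
  N2 <- matrix(1e-4, K, dim)
  for (j in seq_len(K)) {
    pts <- f0[km$cluster == ord[j], , drop = FALSE]
    cv <- if (nrow(pts) > dim) stats::cov(pts) else diag(dim)
    cv <- cv + diag(ridge, dim)
    if (covariance_mode == "diagonal") cv <- diag(diag(cv), dim)
    W2[, , j] <- solve(cv) / W1[j] # prior-mean precision matches the cluster
    # mean uncertainty starts at the sampling variance of the cluster mean
    N2[j, ] <- pmax(diag(cv) / max(nrow(pts), 2), 1e-10)
  }
  variational_state(
    N1 = centers,
    N2 = N2,
    W1 = W1, W2 = W2,
    D = pmax(sizes, 0.5),
    covariance_mode = covariance_mode,
    attention = attention
  )
}

#' Name mixture components after posture regions
#'
#' Each cluster is tagged by the majority ground-truth label among the
#' training points it claims (hard assignment by maximum responsibility);
#' ties break toward the more severe label (normal < transition < falling).
#'
#' @param fit An `svi_gmm` object.
#' @param features Labeled feature tibble (`s1`, `s2`, `label`); defaults to
#'   the training features stored in the fit.
#' @return `fit` with `cluster_labels` set (a character vector of length K).
#' @export
assign_cluster_labels <- function(fit, features = NULL) {
  stopifnot(inherits(fit, "svi_gmm"))
  if (is.null(features)) features <- fit$features
  if (is.null(features$label)) {
    stop("labeled features are required to name clusters", call. = FALSE)
  }
  params <- expected_gmm(fit$state)
  assign <- responsibility_argmax(posterior_responsibility(features, params))
  lvls <- region_levels()
  labs <- character(fit$K)
  for (k in seq_len(fit$K)) {
    counts <- table(factor(features$label[assign == k], levels = lvls))
    if (sum(counts) == 0L) {
      labs[k] <- "normal"
      next
    }
    best <- which(counts == max(counts))
    labs[k] <- lvls[max(best)] # ties toward the more severe label
  }
  fit$cluster_labels <- labs
  fit
}

#' @export
print.svi_gmm <- function(x, ...) {
  cat(
    "Stochastic-variational Gaussian mixture\n",
    "  K = ", x$K, ", covariance: ", x$covariance_mode,
    ", n = ", x$n, ", steps = ", x$config$steps, "\n",
    sep = ""
  )
  cat("  final loss:", signif(mean(tail(x$trace$loss, 25)), 6), "\n")
  if (!is.null(x$cluster_labels)) {
    cat("  regions:", paste(x$cluster_labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-cluster summary of a fitted mixture
#'
#' @param x An `svi_gmm` object.
#' @param ... Unused.
#' @return A tibble with one row per cluster: weight, mean and covariance
#'   entries of the expected mixture, and the region label when assigned.
#' @export
tidy.svi_gmm <- function(x, ...) {
  p <- expected_gmm(x$state)
  out <- tibble::tibble(
    cluster = seq_len(x$K),
    weight = p$weights,
    mean_s1 = p$means[, 1],
    mean_s2 = p$means[, 2],
    var_s1 = p$covs[1, 1, ],
    var_s2 = p$covs[2, 2, ],
    cov_s1_s2 = p$covs[1, 2, ]
  )
  if (!is.null(x$cluster_labels)) out$region <- x$cluster_labels
  out
}

#' One-row summary of a fitted mixture
#'
#' @param x An `svi_gmm` object.
#' @param ... Unused.
#' @return A one-row tibble: K, covariance mode, sample size, steps, final
#'   loss (mean of the last 25 steps) and the seed.
#' @export
glance.svi_gmm <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    covariance_mode = x$covariance_mode,
    n = x$n,
    steps = x$config$steps,
    final_loss = mean(tail(x$trace$loss, 25)),
    seed = x$seed
  )
}

#' Loss-trace plot for a fitted mixture
#'
#' @param object An `svi_gmm` object.
#' @param ... Unused.
#' @return A ggplot of the per-step training loss.
#' @export
autoplot.svi_gmm <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "gradient step", y = "loss",
      title = "Stochastic-variational training loss"
    ) +
    ggplot2::theme_minimal()
}

#' Mean held-out log-likelihood of a fitted mixture
#'
#' @param fit An `svi_gmm` object.
#' @param newdata Feature tibble or matrix.
#' @return Mean mixture log-likelihood under the expected mixture.
#' @export
mean_loglik <- function(fit, newdata) {
  mean(gmm_log_likelihood(newdata, expected_gmm(fit$state)))
}
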