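test_that("mixture log-likelihood matches closed forms and a naive oracle", {
  p1 <- gmm_params(1, matrix(0, 1, 2), diag(2))
  expect_equal(gmm_log_likelihood(c(0, 0), p1), -log(2 * pi), tolerance = 1e-12)

  # symmetric two-component mixture at the midpoint: both components
  # contribute the density of a single component at distance 1
  p2 <- gmm_params(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
    array(diag(2), c(2, 2, 2))
  )
  expect_equal(
    gmm_log_likelihood(c(0, 0), p2),
    log(oracle_dmvnorm(c(0, 0), c(1, 0), diag(2))),
    tolerance = 1e-12
  )

  withr::with_seed(31, {
    for (rep in 1:5) {
      p <- random_gmm(3)
      s <- rnorm(2, 0, 2)
      expect_equal(gmm_log_likelihood(s, p), log(oracle_gmm_density(s, p)),
        tolerance = 1e-10
      )
    }
  })
})

test_that("a singular covariance is reported as a degenerate component", {
  expect_error(
    gmm_params(1, matrix(0, 1, 2), matrix(c(1, 1, 1, 1), 2, 2)),
    "degenerate component"
  )
})

test_that("posterior responsibilities normalize and match the direct formula", {
  p2 <- gmm_params(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
    array(diag(2), c(2, 2, 2))
  )
  r <- posterior_responsibility(c(0, 0), p2)
  expect_equal(as.numeric(r[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  p1 <- gmm_params(1, matrix(c(3, -2), 1, 2), diag(2))
  expect_equal(as.numeric(posterior_responsibility(c(10, 4), p1)), 1.0)

  withr::with_seed(33, {
    for (rep in 1:5) {
      p <- random_gmm(3)
      s <- rnorm(2, 0, 2)
      expect_equal(
        as.numeric(posterior_responsibility(s, p)),
        oracle_responsibility(s, p),
        tolerance = 1e-10
      )
    }
    pts <- matrix(rnorm(400, 0, 3), 200, 2)
    p <- random_gmm(3)
    rows <- rowSums(as.matrix(posterior_responsibility(pts, p)))
    expect_true(all(abs(rows - 1) < 1e-12))
  })
})

test_that("KLD of the state from the prior is zero at the prior and matches quadrature", {
  prior <- prior_spec(2)
  expect_equal(kld_variational_prior(state_from_prior(prior), prior), 0,
    tolerance = 1e-10
  )
  expect_equal(
    kld_variational_prior(state_from_prior(prior, "diagonal"), prior), 0,
    tolerance = 1e-10
  )

  # move one mean coordinate to 1: the Gaussian term contributes
  # (mu1 - mu2)^2 / 2 = 0.5, confirmed against numerical quadrature
  st <- state_from_prior(prior)
  st$N1[1, 1] <- 1
  expect_equal(kld_variational_prior(st, prior), 0.5, tolerance = 1e-10)
  expect_equal(
    oracle_gaussian_kld(1, 1, 0, 1), 0.5,
    tolerance = 1e-8
  )

  # Dirichlet term against the Beta-integral oracle (K = 2)
  st2 <- state_from_prior(prior)
  st2$D <- c(2, 2)
  expect_equal(
    kld_variational_prior(st2, prior),
    oracle_beta_kld(c(2, 2), prior$dirichlet),
    tolerance = 1e-7
  )

  # diagonal-mode precision term against the Gamma-integral oracle
  st3 <- state_from_prior(prior, "diagonal")
  st3$W1 <- c(5, prior$wishart_df[2])
  st3$W2[, , 1] <- diag(c(0.5, 0.2))
  expect_equal(
    kld_variational_prior(st3, prior),
    oracle_gamma_kld(5 / 2, 2 * 0.5, 1.5, 2 / 3) +
      oracle_gamma_kld(5 / 2, 2 * 0.2, 1.5, 2 / 3),
    tolerance = 1e-6
  )
})

test_that("KLD is nonnegative over many random states in both modes", {
  withr::with_seed(99, {
    for (i in 1:500) {
      mode <- if (i %% 2 == 0) "full" else "diagonal"
      st <- random_state(3, mode)
      expect_gte(kld_variational_prior(st, prior_spec(3)), -1e-10)
    }
  })
})

test_that("reparameterized draws are deterministic and collapse with N2", {
  prior <- prior_spec(2)
  st <- state_from_prior(prior)
  st$N1 <- rbind(c(1, -1), c(2, 0.5))
  st$N2 <- matrix(1e-18, 2, 2)
  draws <- sample_gmm_params(st, 5, seed = 3)
  for (d in draws) expect_equal(d$means, st$N1, tolerance = 1e-8)

  st$N2 <- matrix(0.5, 2, 2)
  a <- sample_gmm_params(st, 4, seed = 9)
  b <- sample_gmm_params(st, 4, seed = 9)
  expect_identical(a, b)
})

test_that("the empirical mean of sampled component means converges to N1", {
  prior <- prior_spec(2)
  st <- state_from_prior(prior)
  st$N1 <- rbind(c(0.7, -0.4), c(-1.1, 0.2))
  st$N2 <- matrix(c(0.3, 0.8, 0.1, 0.5), 2, 2)
  L <- 1e5
  draws <- sample_gmm_params(st, L, seed = 12)
  mu_bar <- Reduce(`+`, lapply(draws, function(d) d$means)) / L
  se <- sqrt(st$N2 / L)
  expect_true(all(abs(mu_bar - st$N1) < 3 * se))
})

test_that("the loss equals the negative Monte-Carlo term at the prior and bounds hold", {
  prior <- prior_spec(2)
  st <- state_from_prior(prior)
  batch <- matrix(rnorm(8), 4, 2)

  mc_term <- function(state, L, seed) {
    draws <- sample_gmm_params(state, L, seed = seed)
    mean(vapply(draws, function(p) {
      mean(vapply(
        seq_len(nrow(batch)),
        function(i) log(oracle_gmm_density(batch[i, ], p)), numeric(1)
      ))
    }, numeric(1)))
  }

  # at the prior the KLD vanishes and the loss is exactly -MC
  expect_equal(svi_loss(batch, st, prior, L = 5, seed = 2),
    -mc_term(st, 5, 2),
    tolerance = 1e-10
  )

  # for any state: loss + MC = KLD >= 0, and dropping the KLD recovers -MC
  withr::with_seed(41, {
    st2 <- random_state(2, "full")
    loss <- svi_loss(batch, st2, prior, L = 5, seed = 7)
    mc <- mc_term(st2, 5, 7)
    expect_gte(loss + mc, -1e-10)
    expect_equal(svi_loss(batch, st2, prior, L = 5, seed = 7, kld_weight = 0),
      -mc,
      tolerance = 1e-10
    )
    # straight-line re-evaluation of the full loss
    expect_equal(loss, -(mc - kld_variational_prior(st2, prior)),
      tolerance = 1e-10
    )
  })
})

test_that("the expected mixture summarizes the state correctly", {
  prior <- prior_spec(3)
  st <- state_from_prior(prior)
  st$D <- c(1, 1, 1)
  p <- expected_gmm(st)
  expect_equal(p$weights, rep(1 / 3, 3))
  # Wishart mean nu * V = I at the prior, so Sigma = I
  expect_equal(p$covs[, , 1], diag(2), tolerance = 1e-12)
  expect_equal(p$means, st$N1)

  withr::with_seed(55, {
    for (i in 1:500) {
      mode <- if (i %% 2 == 0) "full" else "diagonal"
      p <- expected_gmm(random_state(3, mode))
      for (k in 1:3) expect_silent(chol(p$covs[, , k]))
    }
  })
})

test_that("the expected mixture density integrates to one on a wide grid", {
  withr::with_seed(71, {
    st <- random_state(2, "full")
    p <- expected_gmm(st)
    sds <- sqrt(vapply(1:2, function(k) diag(p$covs[, , k]), numeric(2)))
    lo <- apply(p$means - 8 * t(sds), 2, min)
    hi <- apply(p$means + 8 * t(sds), 2, max)
    n <- 500
    xs <- seq(lo[1], hi[1], length.out = n)
    ys <- seq(lo[2], hi[2], length.out = n)
    cell <- diff(xs)[1] * diff(ys)[1]
    grid <- as.matrix(expand.grid(xs, ys))
    mass <- sum(exp(gmm_log_likelihood(grid, p))) * cell
    expect_equal(mass, 1, tolerance = 0.01)
  })
})

test_that("fitting recovers three well-separated clusters and matches EM", {
  skip_if_not_installed("mclust")
  truth <- cluster_truth()
  d <- simulate_feature_clusters(2000, truth, seed = 61)
  fit <- svi_fit(d[, c("s1", "s2")], K = 3, config = fast_config(800), seed = 62)
  est <- expected_gmm(fit$state)

  # match components to the generating means by nearest assignment
  perm <- apply(
    as.matrix(dist(rbind(est$means, truth$means)))[1:3, 4:6], 1, which.min
  )
  expect_setequal(perm, 1:3)
  expect_lt(max(abs(est$means - truth$means[perm, ])), 0.1)
  expect_lt(max(abs(est$weights - truth$weights[perm])), 0.05)

  hard <- max.col(
    as.matrix(posterior_responsibility(d[, 1:2], est)),
    ties.method = "first"
  )
  em <- mclust::Mclust(d[, c("s1", "s2")], G = 3, modelNames = "VVV",
    verbose = FALSE
  )
  expect_gte(mclust::adjustedRandIndex(hard, em$classification), 0.95)
})

test_that("a single-component fit recovers a standard normal", {
  d <- withr::with_seed(81, tibble::tibble(s1 = rnorm(5000), s2 = rnorm(5000)))
  fit <- suppressWarnings(
    svi_fit(d, K = 1, config = fast_config(800), seed = 82)
  )
  est <- expected_gmm(fit$state)
  expect_lt(max(abs(est$means)), 0.05)
  expect_lt(max(abs(est$covs[, , 1] - diag(2))), 0.1)
})

test_that("training is bit-identical under a repeated seed", {
  d <- simulate_feature_clusters(600, cluster_truth(), seed = 90)
  f1 <- svi_fit(d[, 1:2], K = 3, config = fast_config(120), seed = 91)
  f2 <- svi_fit(d[, 1:2], K = 3, config = fast_config(120), seed = 91)
  expect_identical(f1$trace$loss, f2$trace$loss)
  expect_identical(f1$state$N1, f2$state$N1)
})

test_that("the loss trace improves and stays improved", {
  fit <- cached_posture_fit() # large initial drop makes the trend visible
  ma <- stats::filter(fit$trace$loss, rep(1 / 50, 50), sides = 1)
  ma <- ma[!is.na(ma)]
  ma <- ma[-seq_len(ceiling(length(ma) * 0.1))]
  drop_total <- max(ma) - min(ma)
  # non-increasing up to minibatch/Monte-Carlo jitter
  expect_lt(max(diff(ma)), max(1e-8, 0.02 * drop_total))
  expect_lte(ma[length(ma)], ma[1] + 1e-8)
})

test_that("full covariance beats diagonal on correlated clusters", {
  truth <- cluster_truth(correlation = 0.8)
  tr <- simulate_feature_clusters(1500, truth, seed = 101)
  te <- simulate_feature_clusters(800, truth, seed = 102)
  full <- svi_fit(tr[, 1:2], K = 3, covariance_mode = "full",
    config = fast_config(800), seed = 103
  )
  diagf <- svi_fit(tr[, 1:2], K = 3, covariance_mode = "diagonal",
    config = fast_config(800), seed = 103
  )
  expect_gt(mean_loglik(full, te[, 1:2]), mean_loglik(diagf, te[, 1:2]))
})

test_that("the variational state round-trips through JSON bit-exactly", {
  withr::with_seed(111, {
    st <- random_state(3, "full", attention = init_attention(seed = 5))
    path <- withr::local_tempfile(fileext = ".json")
    write_state_json(st, path)
    back <- read_state_json(path)
    expect_identical(back$N1, st$N1)
    expect_identical(back$N2, st$N2)
    expect_identical(back$W1, st$W1)
    expect_identical(back$W2, st$W2)
    expect_identical(back$D, st$D)
    expect_identical(back$attention$projection, st$attention$projection)
    expect_identical(back$covariance_mode, st$covariance_mode)
  })
})

test_that("fit inputs are validated", {
  expect_error(svi_fit(tibble::tibble(s1 = numeric(), s2 = numeric()), K = 2),
    "empty input"
  )
  d <- simulate_feature_clusters(100, cluster_truth(), seed = 1)
  expect_warning(
    svi_fit(d[, 1:2], K = 4, config = fast_config(5), seed = 1),
    "K = 2 or 3"
  )
})
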