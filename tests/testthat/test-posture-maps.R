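test_that("min-max normalization scales endpoints, midpoints, and new points", {
  pts <- tibble::tibble(s1 = c(0, 2), s2 = c(0, 4))
  nf <- normalize_features(pts)
  expect_equal(nf$points$s1, c(0, 1))
  expect_equal(nf$points$s2, c(0, 1))
  mid <- apply_normalization(tibble::tibble(s1 = 1, s2 = 2), nf$record)
  expect_equal(unname(c(mid$s1, mid$s2)), c(0.5, 0.5))
})

test_that("re-normalizing already-normalized features is rejected", {
  pts <- tibble::tibble(s1 = c(0, 2, 1), s2 = c(0, 4, 3))
  nf <- normalize_features(pts)
  expect_error(apply_normalization(nf$points, nf$record), "already normalized")
  expect_error(normalize_features(nf$points), "already normalized")
  degenerate <- tibble::tibble(s1 = c(1, 1), s2 = c(0, 1))
  expect_error(normalize_features(degenerate), "degenerate axis")
})

test_that("the mixture transforms exactly under the stored normalization", {
  withr::with_seed(7, {
    p <- random_gmm(2)
    pts <- tibble::tibble(s1 = rnorm(50, 0, 2), s2 = rnorm(50, 0, 2))
    nf <- normalize_features(pts)
    pn <- transform_gmm(p, nf$record)
    # densities transform with the Jacobian of the affine map
    jac <- prod(nf$record$ranges)
    expect_equal(
      gmm_log_likelihood(nf$points, pn),
      gmm_log_likelihood(pts, p) + log(jac),
      tolerance = 1e-10
    )
  })
})

test_that("likelihood maps peak at the component and carry the right mass", {
  p <- gmm_params(1, matrix(c(0.5, 0.5), 1, 2), 0.01 * diag(2))
  m <- likelihood_map(p, resolution = 101)
  peak <- m[which.max(m$value), ]
  expect_equal(c(peak$x, peak$y), c(0.5, 0.5), tolerance = 1e-6)

  # grid mass vs the analytic Gaussian rectangle probability on [0,1]^2
  mass <- sum(m$value) / 101^2
  analytic <- (stats::pnorm(1, 0.5, 0.1) - stats::pnorm(0, 0.5, 0.1))^2
  expect_equal(mass, analytic, tolerance = 1e-3)

  p2 <- gmm_params(c(0.5, 0.5), rbind(c(0.2, 0.2), c(0.8, 0.8)),
    array(0.005 * diag(2), c(2, 2, 2))
  )
  m2 <- likelihood_map(p2, resolution = 101)
  vals <- matrix(m2$value, 101, 101, byrow = TRUE)
  # two local maxima: both component centers dominate their neighbourhood
  i1 <- round(0.2 * 101)
  i2 <- round(0.8 * 101)
  expect_gt(vals[i1, i1], vals[i1, i2])
  expect_gt(vals[i2, i2], vals[i2, i1])
})

test_that("region maps partition the grid and follow the posterior argmax", {
  p2 <- gmm_params(c(0.5, 0.5), rbind(c(0.25, 0.5), c(0.75, 0.5)),
    array(0.01 * diag(2), c(2, 2, 2))
  )
  rm2 <- region_map(p2, c("normal", "falling"), resolution = 64)
  codes <- attr(rm2, "codes")
  expect_true(all(rm2$value %in% codes))
  # symmetric mixture: the boundary is the perpendicular bisector x = 0.5
  left <- rm2$value[rm2$x < 0.5]
  right <- rm2$value[rm2$x > 0.5]
  expect_true(all(left == codes[["normal"]]))
  expect_true(all(right == codes[["falling"]]))

  p1 <- gmm_params(1, matrix(c(0.5, 0.5), 1, 2), diag(2))
  rm1 <- region_map(p1, "normal", resolution = 16)
  expect_true(all(rm1$value == 1))

  withr::with_seed(19, {
    p3 <- random_gmm(3)
    # place the mixture inside the unit square
    p3$means <- matrix(runif(6, 0.1, 0.9), 3, 2)
    p3$covs <- p3$covs * 0.02
    labs <- c("normal", "transition", "falling")
    rm3 <- region_map(p3, labs, resolution = 32)
    cds <- attr(rm3, "codes")
    for (i in sample(nrow(rm3), 40)) {
      r <- oracle_responsibility(c(rm3$x[i], rm3$y[i]), p3)
      expect_equal(rm3$value[i], cds[[labs[which.max(r)]]])
    }
  })
})

test_that("likelihood maps ignore component order; region maps permute with it", {
  withr::with_seed(23, {
    p <- random_gmm(3)
    p$means <- matrix(runif(6, 0.2, 0.8), 3, 2)
    p$covs <- p$covs * 0.02
    perm <- c(3, 1, 2)
    pp <- gmm_params(p$weights[perm], p$means[perm, ], p$covs[, , perm])
    expect_equal(likelihood_map(p, 32)$value, likelihood_map(pp, 32)$value,
      tolerance = 1e-12
    )
    labs <- c("normal", "transition", "falling")
    m1 <- region_map(p, labs, 32)
    m2 <- region_map(pp, labs[perm], 32)
    c1 <- attr(m1, "codes")
    c2 <- attr(m2, "codes")
    expect_identical(
      names(c1)[match(m1$value, c1)],
      names(c2)[match(m2$value, c2)]
    )
  })
})

test_that("region mass converges to mixture weights as resolution grows", {
  p <- gmm_params(
    c(0.3, 0.5, 0.2),
    rbind(c(0.2, 0.2), c(0.7, 0.3), c(0.4, 0.8)),
    array(0.002 * diag(2), c(2, 2, 3))
  )
  labs <- c("a", "b", "c")
  # density mass claimed by each region (not grid area)
  frac <- function(res) {
    rm <- region_map(p, labs, res)
    lm <- likelihood_map(p, res)
    vapply(1:3, function(k) sum(lm$value[rm$value == k]), numeric(1)) /
      sum(lm$value)
  }
  f128 <- frac(128)
  f512 <- frac(512)
  expect_lt(max(abs(f512 - f128)), 0.02)
  expect_lt(max(abs(f512 - p$weights)), 0.02)
})

test_that("covariance ellipses eigendecompose and round-trip the covariance", {
  p <- gmm_params(
    c(0.5, 0.5), rbind(c(0, 0), c(1, 1)),
    array(c(diag(2), diag(c(4, 1))), c(2, 2, 2))
  )
  e <- covariance_ellipses(p, n_std = 1)
  expect_equal(e$semi_major[1], 1)
  expect_equal(e$semi_minor[1], 1)
  expect_equal(e$semi_major[2], 2)
  expect_equal(e$semi_minor[2], 1)
  expect_equal(e$rotation[2], 0)

  withr::with_seed(29, {
    for (rep in 1:5) {
      p <- random_gmm(1)
      e <- covariance_ellipses(p, n_std = 2)
      ang <- e$rotation
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      rebuilt <- R %*% diag(c(e$semi_major / 2, e$semi_minor / 2)^2) %*% t(R)
      expect_equal(rebuilt, p$covs[, , 1], tolerance = 1e-9)
    }
  })
})

test_that("map grids round-trip through the CSV layout", {
  p <- gmm_params(1, matrix(c(0.5, 0.5), 1, 2), 0.05 * diag(2))
  m <- likelihood_map(p, resolution = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(m, path)
  back <- read_map_csv(path)
  expect_equal(back$value, m$value, tolerance = 1e-9)
  expect_equal(attr(back, "x_centers"), attr(m, "x_centers"), tolerance = 1e-10)

  rm3 <- region_map(
    gmm_params(c(0.5, 0.5), rbind(c(0.25, 0.5), c(0.75, 0.5)),
      array(0.01 * diag(2), c(2, 2, 2))
    ),
    c("normal", "falling"), 24
  )
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(rm3, path2)
  back2 <- read_map_csv(path2)
  expect_identical(attr(back2, "kind"), "region")
  expect_equal(back2$value, rm3$value)
  expect_equal(unlist(attr(back2, "codes")), unlist(attr(rm3, "codes")))
})

test_that("map and trace plots build without error", {
  p <- gmm_params(1, matrix(c(0.5, 0.5), 1, 2), 0.05 * diag(2))
  expect_s3_class(autoplot(likelihood_map(p, 16)), "ggplot")
  rm1 <- region_map(p, "normal", 16)
  expect_s3_class(autoplot(rm1), "ggplot")
})
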