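test_that("centroid extraction normalizes midpoints and differences speeds", {
  stream <- tibble::tibble(
    frame = 0:2, t = (0:2) / 60,
    x_min = c(10, 16, 16), y_min = 10,
    x_max = c(30, 36, 36), y_max = 50,
    confidence = 1
  )
  cent <- extract_centroids(stream, fps = 60, frame_size = c(100, 100))
  expect_equal(cent$x[1], 0.20)
  expect_equal(cent$y[1], 0.30)
  expect_equal(cent$vx[1], 0) # first sample has zero speed by convention
  expect_equal(cent$vx[2], (0.26 - 0.20) * 60)
  expect_equal(cent$vx[3], 0)
})

test_that("a constant box yields zero speeds throughout", {
  stream <- tibble::tibble(
    frame = 0:9, t = (0:9) / 60,
    x_min = 10, y_min = 10, x_max = 30, y_max = 50, confidence = 1
  )
  cent <- extract_centroids(stream, fps = 60, frame_size = c(100, 100))
  expect_true(all(cent$vx == 0))
  expect_true(all(cent$vy == 0))
})

test_that("centroid extraction rejects bad streams", {
  expect_error(
    extract_centroids(tibble::tibble(), 60, c(100, 100)),
    "empty input"
  )
  unsorted <- tibble::tibble(
    frame = c(1L, 0L), t = c(1 / 60, 0),
    x_min = 0, y_min = 0, x_max = 1, y_max = 1
  )
  expect_error(extract_centroids(unsorted, 60, c(100, 100)), "unsorted")
})

test_that("window counts follow the sliding-window arithmetic", {
  mk <- function(n) {
    tibble::tibble(
      t = (seq_len(n) - 1) / 60,
      x = 0.5, y = 0.5, vx = 0, vy = 0
    )
  }
  expect_equal(nrow(make_windows(mk(21))), 1L)
  expect_equal(nrow(make_windows(mk(100))), 80L)
  # stride 20: starts 1, 21, 41, 61 fit; 81 would overrun 100 - 21 + 1
  expect_equal(nrow(make_windows(mk(100), stride = 20)), 4L)
  expect_error(make_windows(mk(20)), "stream too short")
})

test_that("windows spanning a recording gap are dropped", {
  samples <- tibble::tibble(
    t = c((0:29) / 60, (0:29) / 60 + 1.0), # one-second hole in the middle
    x = 0.5, y = 0.5, vx = 0, vy = 0
  )
  win <- make_windows(samples, fps = 60)
  # only windows fully inside one contiguous block survive: 2 x (30 - 21 + 1)
  expect_equal(nrow(win), 20L)
  expect_true(all(vapply(
    win$features,
    function(f) TRUE, logical(1)
  )))
})

test_that("zero gating and identity-like projection reduce to doubled means", {
  win <- matrix(runif(21 * 4), 21, 4)
  params <- attention_params(
    gate_weights = matrix(0, 4, 4), gate_bias = rep(0, 4),
    projection = matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 4, 2, byrow = TRUE)
  )
  s <- attention_forward(win, params)
  # uniform softmax rescaled by 4 gives unit gates; the residual doubles f
  expect_equal(s, 2 * c(mean(win[, 1]), mean(win[, 2])), tolerance = 1e-12)
})

test_that("a constant window pools to the single-sample formula", {
  f <- c(0.3, 0.6, -0.1, 0.2)
  win <- matrix(f, 21, 4, byrow = TRUE)
  params <- withr::with_seed(11, attention_params(
    gate_weights = matrix(rnorm(16, 0, 0.5), 4, 4),
    gate_bias = rnorm(4, 0, 0.5),
    projection = matrix(rnorm(8), 4, 2)
  ))
  g <- as.numeric(params$gate_weights %*% f + params$gate_bias)
  c_t <- 4 * exp(g) / sum(exp(g))
  expected <- as.numeric(t(params$projection) %*% (c_t * f + f))
  expect_equal(attention_forward(win, params), expected, tolerance = 1e-12)
})

test_that("attention forward matches a straight-line re-evaluation", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      win <- matrix(rnorm(21 * 4), 21, 4)
      params <- attention_params(
        gate_weights = matrix(rnorm(16, 0, 0.7), 4, 4),
        gate_bias = rnorm(4, 0, 0.7),
        projection = matrix(rnorm(8), 4, 2)
      )
      expect_equal(attention_forward(win, params), oracle_attention(win, params),
        tolerance = 1e-10
      )
    }
  })
})

test_that("mean pooling makes the output invariant to sample order", {
  withr::with_seed(7, {
    win <- matrix(rnorm(21 * 4), 21, 4)
    params <- attention_params(
      gate_weights = matrix(rnorm(16, 0, 0.5), 4, 4),
      gate_bias = rnorm(4), projection = matrix(rnorm(8), 4, 2)
    )
    perm <- sample(21)
    # mean pooling is order-free up to floating-point summation order
    expect_equal(
      attention_forward(win, params),
      attention_forward(win[perm, ], params),
      tolerance = 1e-13
    )
  })
})

test_that("the output is linear in the projection matrix", {
  withr::with_seed(8, {
    win <- matrix(rnorm(21 * 4), 21, 4)
    params <- attention_params(
      gate_weights = matrix(rnorm(16, 0, 0.5), 4, 4),
      gate_bias = rnorm(4), projection = matrix(rnorm(8), 4, 2)
    )
    doubled <- attention_params(params$gate_weights, params$gate_bias,
      projection = 2 * params$projection
    )
    expect_equal(attention_forward(win, doubled),
      2 * attention_forward(win, params),
      tolerance = 1e-12
    )
  })
})

test_that("windowed mean speeds recover a constant generating velocity", {
  fps <- 60
  n <- 120
  vx_true <- 0.08
  vy_true <- -0.03
  stream <- tibble::tibble(
    frame = 0:(n - 1), t = (0:(n - 1)) / fps,
    x_min = 100 + vx_true * 640 * (0:(n - 1)) / fps,
    y_min = 200 + vy_true * 480 * (0:(n - 1)) / fps,
    confidence = 1
  )
  stream$x_max <- stream$x_min + 80
  stream$y_max <- stream$y_min + 200
  cent <- extract_centroids(stream, fps, c(640, 480))
  win <- make_windows(cent, fps)
  for (i in c(1, 25, nrow(win))) {
    f <- win$features[[i]]
    # skip the stream's first sample, whose speed is 0 by convention
    rows <- if (win$t_anchor[i] == 0) 2:21 else 1:21
    expect_equal(mean(f[rows, 3]), vx_true, tolerance = 1e-9)
    expect_equal(mean(f[rows, 4]), vy_true, tolerance = 1e-9)
  }
})

test_that("window anchors inherit the label of their anchor frame", {
  labels <- tibble::tibble(
    frame = 0:99,
    label = rep(c("normal", "falling"), each = 50)
  )
  samples <- tibble::tibble(
    t = (0:99) / 60, x = 0.5, y = 0.5, vx = 0, vy = 0
  )
  win <- label_windows(make_windows(samples, 60), labels, fps = 60)
  expect_identical(win$label[1], "normal")
  expect_identical(win$label[win$t_anchor == 50 / 60], "falling")
})
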