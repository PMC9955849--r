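#' Convert a bounding-box stream to centroid positions and speeds
#'
#' Each detected box is reduced to its centroid, normalized by the frame
#' dimensions so that streams recorded under different camera geometries share
#' a common scale. Speeds are first-order backward differences of the
#' normalized position scaled by the frame rate; the first sample of a stream
#' has speed zero by convention.
#'
#' @param stream A data frame with columns `frame`, `t`, `x_min`, `y_min`,
#'   `x_max`, `y_max` (pixels) and optionally `confidence`, sorted by `frame`.
#' @param fps Frame rate in frames per second.
#' @param frame_size Integer vector `c(width, height)` of the frame in pixels.
#' @return A tibble with columns `t`, `x`, `y` (normalized to `[0, 1]`,
#'   image convention: origin top-left, y increasing downward) and `vx`, `vy`
#'   (normalized units per second).
#' @examples
#' boxes <- tibble::tibble(
#'   frame = 0:1, t = c(0, 1 / 60),
#'   x_min = c(10, 16), y_min = 10, x_max = c(30, 36), y_max = 50
#' )
#' extract_centroids(boxes, fps = 60, frame_size = c(100, 100))
#' @export
extract_centroids <- function(stream, fps, frame_size = c(640L, 480L)) {
  if (is.null(stream) || nrow(stream) == 0L) {
    stop("empty input: the bounding-box stream has no rows", call. = FALSE)
  }
  stopifnot(fps > 0, length(frame_size) == 2L, all(frame_size > 0))
  need <- c("frame", "t", "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(stream))
  if (length(missing_cols) > 0L) {
    stop("parse error: missing columns ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.unsorted(stream$frame, strictly = TRUE) ||
    is.unsorted(stream$t, strictly = TRUE)) {
    stop("unsorted stream: frames and times must be strictly increasing",
      call. = FALSE
    )
  }
  if (any(stream$x_max <= stream$x_min) || any(stream$y_max <= stream$y_min)) {
    stop("invalid boxes: x_max/y_max must exceed x_min/y_min", call. = FALSE)
  }
  x <- (stream$x_min + stream$x_max) / 2 / frame_size[1]
  y <- (stream$y_min + stream$y_max) / 2 / frame_size[2]
  n <- length(x)
  vx <- c(0, diff(x) * fps)
  vy <- c(0, diff(y) * fps)
  tibble::tibble(t = stream$t, x = x, y = y, vx = vx, vy = vy)
}

#' Slice a centroid stream into 21-frame feature windows
#'
#' Windows hold the 21 consecutive samples from `t` to `t + 20` frames that
#' feed the attention block; each window is dated by its first sample
#' (`t_anchor`). Windows spanning a recording gap larger than two frame
#' periods are dropped.
#'
#' @param samples Tibble of centroid samples from [extract_centroids()].
#' @param fps Frame rate used to detect gaps (frames per second).
#' @param stride Step, in samples, between consecutive window anchors.
#' @param window_length Number of samples per window (21 by default).
#' @return A tibble of class `feature_windows` with columns `window_id`,
#'   `t_anchor` and a list-column `features` of 21x4 matrices (columns
#'   `x`, `y`, `vx`, `vy`).
#' @export
make_windows <- function(samples, fps = 60, stride = 1L, window_length = 21L) {
  stopifnot(stride >= 1L, window_length >= 2L)
  n <- nrow(samples)
  if (is.null(n) || n < window_length) {
    stop("stream too short: need at least ", window_length, " samples",
      call. = FALSE
    )
  }
  starts <- seq.int(1L, n - window_length + 1L, by = stride)
  fmat <- as.matrix(samples[, c("x", "y", "vx", "vy")])
  tvec <- samples$t
  max_gap <- 2 / fps + 1e-9
  keep <- vapply(starts, function(i) {
    idx <- i:(i + window_length - 1L)
    all(diff(tvec[idx]) <= max_gap)
  }, logical(1))
  starts <- starts[keep]
  out <- tibble::tibble(
    window_id = seq_along(starts),
    t_anchor = tvec[starts],
    features = lapply(starts, function(i) {
      fmat[i:(i + window_length - 1L), , drop = FALSE]
    })
  )
  class(out) <- c("feature_windows", class(out))
  attr(out, "fps") <- fps
  attr(out, "window_length") <- window_length
  out
}

#' Attention-block parameters
#'
#' The attention block gates the four instant centroid features
#' (x, y, vx, vy) at every time point of a window, adds a residual, pools by
#' mean over the window and projects to the two-dimensional feature space
#' consumed by the mixture model. The gate is
#' `c(t) = 4 * softmax(gate_weights %*% f(t) + gate_bias)`, scaled by 4 so the
#' all-equal gate multiplies each feature by exactly 1.
#'
#' @param gate_weights 4x4 matrix of the gating affine map.
#' @param gate_bias Length-4 bias of the gating affine map.
#' @param projection 4x2 matrix mapping the pooled gated features to the
#'   feature space.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(gate_weights = matrix(0, 4, 4),
                             gate_bias = rep(0, 4),
                             projection = default_projection()) {
  gate_weights <- matrix(as.numeric(gate_weights), 4, 4)
  gate_bias <- as.numeric(gate_bias)
  projection <- matrix(as.numeric(projection), 4, 2)
  stopifnot(length(gate_bias) == 4L)
  if (!all(is.finite(gate_weights)) || !all(is.finite(gate_bias)) ||
    !all(is.finite(projection))) {
    stop("invalid attention parameters: non-finite entries", call. = FALSE)
  }
  structure(
    list(
      gate_weights = gate_weights, gate_bias = gate_bias,
      projection = projection
    ),
    class = "attention_params"
  )
}

# Vertical position and vertical speed are the canonical fall-discriminative
# centroid features; the default projection passes them through and leaves the
# horizontal channels to be learned.
default_projection <- function() {
  matrix(c(
    0, 0,
    1, 0,
    0, 0,
    0, 1
  ), nrow = 4, ncol = 2, byrow = TRUE)
}

#' Draw small random attention parameters
#'
#' Gate weights and bias start near zero (identity gating); the projection
#' starts at the vertical-kinematics template of [attention_params()], the
#' fall-discriminative feature plane.
#'
#' @param sd Standard deviation of the Gaussian gate perturbations.
#' @param seed Optional seed for reproducibility.
#' @return An `attention_params` object.
#' @export
init_attention <- function(sd = 0.02, seed = NULL) {
  draw <- function() {
    attention_params(
      gate_weights = matrix(rnorm(16, 0, sd), 4, 4),
      gate_bias = rnorm(4, 0, sd),
      projection = default_projection()
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply the attention block to feature windows
#'
#' For every window the block computes, per time point, the gate
#' `c(t) = 4 * softmax(W f(t) + b)`, the gated feature
#' `o(t) = c(t) * f(t) + f(t)` (Hadamard product plus residual), pools `o(t)`
#' by mean over the 21 samples and projects the pooled vector to the
#' two-dimensional feature space.
#'
#' @param windows A `feature_windows` tibble from [make_windows()], or a
#'   single 21x4 feature matrix.
#' @param params An [attention_params()] object.
#' @return A tibble with columns `t` (the window anchor), `s1`, `s2`. When
#'   `windows` is a single matrix, a length-2 numeric vector.
#' @export
attention_forward <- function(windows, params) {
  stopifnot(inherits(params, "attention_params"))
  if (is.matrix(windows)) {
    s <- cpp_attention_forward(
      list(windows), params$gate_weights, params$gate_bias,
      params$projection
    )
    s <- drop(s)
    if (!all(is.finite(s))) stop("numerical failure in attention block", call. = FALSE)
    return(s)
  }
  stopifnot(inherits(windows, "feature_windows"))
  s <- cpp_attention_forward(
    windows$features, params$gate_weights, params$gate_bias,
    params$projection
  )
  if (!all(is.finite(s))) stop("numerical failure in attention block", call. = FALSE)
  out <- tibble::tibble(t = windows$t_anchor, s1 = s[, 1], s2 = s[, 2])
  if (!is.null(windows[["label"]])) out$label <- windows$label
  out
}

#' Attach ground-truth labels to window anchors
#'
#' @param windows A `feature_windows` tibble.
#' @param labels Tibble with columns `frame` and `label` (one row per frame).
#' @param fps Frame rate relating anchor times to frame indices.
#' @return `windows` with a `label` column (label of the anchor frame).
#' @export
label_windows <- function(windows, labels, fps = attr(windows, "fps")) {
  stopifnot(inherits(windows, "feature_windows"))
  frame <- as.integer(round(windows$t_anchor * fps))
  idx <- match(frame, labels$frame)
  windows$label <- labels$label[idx]
  windows
}
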