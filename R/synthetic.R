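#' Session specification for the trajectory simulator
#'
#' Describes one recorded session of the fall protocol: the subject walks,
#' rotates in place (~30 s, the dizziness imitation), then falls onto a
#' mattress and rests prone. Two camera geometries are modelled (mounting
#' heights 1.6 m and 3.1 m) through a pinhole approximation with the camera
#' aimed at the standing subject's centroid.
#'
#' @param fps Frame rate (frames per second).
#' @param walk_s,spin_s,rest_s Phase durations in seconds.
#' @param fall_s Descent duration in seconds (~40 frames at 60 FPS).
#' @param camera_height Camera mounting height in meters (1.6 or 3.1).
#' @param subject_height Subject height in meters; `NULL` draws one from
#'   Normal(1.586, 0.143^2), the cohort's height distribution.
#' @param noise_sd Detection jitter, standard deviation in pixels added to
#'   every box corner.
#' @param frame_size `c(width, height)` in pixels.
#' @param transition_frames Frames before impact labeled `"transition"`.
#' @param seed Integer seed.
#' @return A list of class `session_spec`.
#' @export
session_spec <- function(fps = 60, walk_s = 5, spin_s = 30, rest_s = 3,
                         fall_s = 0.7, camera_height = 1.6,
                         subject_height = NULL, noise_sd = 1,
                         frame_size = c(640L, 480L), transition_frames = 40L,
                         seed = 1L) {
  stopifnot(
    fps > 0, walk_s >= 0, spin_s >= 0, rest_s >= 0, fall_s > 0,
    camera_height > 0, noise_sd >= 0
  )
  structure(
    list(
      fps = fps, walk_s = walk_s, spin_s = spin_s, rest_s = rest_s,
      fall_s = fall_s, camera_height = camera_height,
      subject_height = subject_height, noise_sd = noise_sd,
      frame_size = frame_size,
      transition_frames = as.integer(transition_frames),
      seed = as.integer(seed)
    ),
    class = "session_spec"
  )
}

# smoothstep: accelerates then decelerates into the mattress, so the centroid
# comes to rest exactly at the annotated impact time
smoothstep <- function(u) u^2 * (3 - 2 * u)

#' Simulate one labeled session of the fall protocol
#'
#' Kinematic template: walking (constant-velocity centroid with a small gait
#' bob, stable box aspect), in-place spinning (stationary centroid with small
#' oscillation, box width oscillating with the rotation), then a fall whose
#' centroid descends along a smoothstep over `fall_s` seconds while the box
#' aspect flips (height shrinking, width growing), followed by prone rest.
#' Box size and vertical displacements are perspective-scaled by the camera
#' geometry, and independent Gaussian jitter of `noise_sd` pixels is added to
#' every corner. Deterministic given the spec's seed.
#'
#' @param spec A [session_spec()].
#' @return A list of class `fall_session`: `bboxes` (tibble `frame`, `t`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `confidence`), `labels` (tibble
#'   `frame`, `label` with tags normal/transition/falling), `impact_time`
#'   (seconds; the instant the centroid comes to rest on the mattress) and
#'   the spec (with the drawn subject height filled in).
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  withr::with_seed(spec$seed, {
    h_s <- spec$subject_height
    if (is.null(h_s)) h_s <- rnorm(1, 1.586, 0.143)
    h_s <- max(h_s, 1.0)
    fw <- spec$frame_size[1]
    fh <- spec$frame_size[2]
    focal <- 500 # pixels
    d_eff <- sqrt(3.0^2 + spec$camera_height^2) # camera-to-subject distance

    # world heights (m above floor) mapped to image rows; camera aimed at the
    # standing centroid so both geometries keep the subject in frame
    h_stand <- 0.5 * h_s
    h_prone <- 0.15
    y_of <- function(h) 0.55 * fh + focal * (h_stand - h) / d_eff

    H_stand <- focal * h_s / d_eff # standing box height, px
    W_stand <- 0.38 * H_stand
    H_prone <- 0.30 * H_stand
    W_prone <- 0.90 * H_stand

    total_s <- spec$walk_s + spec$spin_s + spec$fall_s + spec$rest_s
    n <- max(1L, as.integer(round(total_s * spec$fps)))
    t <- (seq_len(n) - 1L) / spec$fps
    impact_time <- spec$walk_s + spec$spin_s + spec$fall_s

    x_spin <- 0.70 * fw
    cx <- numeric(n)
    cy <- numeric(n)
    Hb <- rep(H_stand, n)
    Wb <- rep(W_stand, n)

    walk <- t < spec$walk_s
    spin <- t >= spec$walk_s & t < spec$walk_s + spec$spin_s
    desc <- t >= spec$walk_s + spec$spin_s & t < impact_time
    rest <- t >= impact_time

    if (spec$walk_s > 0) {
      u <- t[walk] / spec$walk_s
      cx[walk] <- (0.55 + 0.15 * u) * fw # short approach walk to the mattress
      cy[walk] <- y_of(h_stand) + 2 * sin(2 * pi * 2.0 * t[walk])
    }
    cx[spin] <- x_spin + 3 * sin(2 * pi * 0.5 * t[spin])
    cy[spin] <- y_of(h_stand) + 1 * sin(2 * pi * 1.0 * t[spin])
    Wb[spin] <- W_stand * (1 + 0.2 * sin(2 * pi * 0.5 * t[spin]))
    if (any(desc)) {
      u <- (t[desc] - (spec$walk_s + spec$spin_s)) / spec$fall_s
      p <- smoothstep(u)
      cx[desc] <- x_spin
      cy[desc] <- y_of(h_stand) + (y_of(h_prone) - y_of(h_stand)) * p
      Hb[desc] <- H_stand + (H_prone - H_stand) * p
      Wb[desc] <- W_stand + (W_prone - W_stand) * p
    }
    cx[rest] <- x_spin
    cy[rest] <- y_of(h_prone)
    Hb[rest] <- H_prone
    Wb[rest] <- W_prone

    jit <- function() rnorm(n, 0, spec$noise_sd)
    bboxes <- tibble::tibble(
      frame = seq_len(n) - 1L,
      t = t,
      x_min = cx - Wb / 2 + jit(),
      y_min = cy - Hb / 2 + jit(),
      x_max = cx + Wb / 2 + jit(),
      y_max = cy + Hb / 2 + jit(),
      confidence = 0.95
    )
    # jitter can never invert a box at plausible noise levels, but guard it
    bad <- bboxes$x_max <= bboxes$x_min | bboxes$y_max <= bboxes$y_min
    if (any(bad)) {
      bboxes$x_max[bad] <- pmax(bboxes$x_max[bad], bboxes$x_min[bad] + 1)
      bboxes$y_max[bad] <- pmax(bboxes$y_max[bad], bboxes$y_min[bad] + 1)
    }

    impact_frame <- as.integer(round(impact_time * spec$fps))
    label <- rep("normal", n)
    label[bboxes$frame >= impact_frame - spec$transition_frames &
      bboxes$frame < impact_frame] <- "transition"
    label[bboxes$frame >= impact_frame] <- "falling"

    spec$subject_height <- h_s
    structure(
      list(
        bboxes = bboxes,
        labels = tibble::tibble(frame = bboxes$frame, label = label),
        impact_time = impact_time,
        spec = spec
      ),
      class = "fall_session"
    )
  })
}

#' Simulate a cohort of subjects under both camera geometries
#'
#' Subject heights are drawn from Normal(1.586 m, 0.143 m^2's square root);
#' every subject is recorded by both apparatuses (camera heights 1.6 m and
#' 3.1 m), mirroring the two-device validation protocol.
#'
#' @param n_subjects Number of subjects (the study cohort had 15).
#' @param overrides Named list of [session_spec()] arguments applied to every
#'   session (e.g. `list(noise_sd = 0)`).
#' @param seed Integer seed; per-session sub-seeds derive from it.
#' @return A tibble with one row per session: `subject`, `camera_height`,
#'   `subject_height`, `seed` and a `session` list-column of `fall_session`
#'   objects.
#' @export
simulate_cohort <- function(n_subjects = 15L, overrides = list(), seed = 1L) {
  stopifnot(n_subjects >= 1)
  cameras <- c(1.6, 3.1)
  withr::with_seed(seed, {
    heights <- rnorm(n_subjects, 1.586, 0.143)
    sub_seeds <- sample.int(.Machine$integer.max - 1L,
      n_subjects * length(cameras))
    grid <- tidyr::expand_grid(
      subject = seq_len(n_subjects),
      camera_height = cameras
    )
    grid$subject_height <- heights[grid$subject]
    grid$seed <- sub_seeds
    grid$session <- purrr::pmap(
      grid,
      function(subject, camera_height, subject_height, seed) {
        args <- modifyList(
          list(
            camera_height = camera_height,
            subject_height = subject_height, seed = seed
          ),
          overrides
        )
        simulate_session(do.call(session_spec, args))
      }
    )
    grid
  })
}

#' Sample labeled points from a Gaussian mixture
#'
#' Utility generator for module-level tests and model comparisons: draws
#' cluster memberships from the weights and points from the component
#' Gaussians.
#'
#' @param n Number of points.
#' @param truth A list with `means` (K x 2), `covs` (2 x 2 x K) and `weights`.
#' @param seed Integer seed.
#' @return A tibble with `s1`, `s2`, `cluster`.
#' @export
simulate_feature_clusters <- function(n, truth = cluster_truth(), seed = 1L) {
  K <- nrow(truth$means)
  withr::with_seed(seed, {
    z <- sample.int(K, n, replace = TRUE, prob = truth$weights)
    pts <- matrix(0, n, 2)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (length(idx) == 0) next
      ch <- chol(truth$covs[, , k])
      e <- matrix(rnorm(2 * length(idx)), ncol = 2)
      pts[idx, ] <- sweep(e %*% ch, 2, truth$means[k, ], "+")
    }
    tibble::tibble(s1 = pts[, 1], s2 = pts[, 2], cluster = z)
  })
}

#' Ground-truth mixture used by the simulation studies
#'
#' Three well-separated components; `correlation` sets a common within-cluster
#' correlation (0.8 reproduces the anisotropic clusters that separate full
#' from diagonal covariance fits).
#'
#' @param K 2 or 3 components.
#' @param correlation Within-cluster correlation in `(-1, 1)`.
#' @param sd Within-cluster standard deviation per axis.
#' @return A list with `means`, `covs`, `weights`.
#' @export
cluster_truth <- function(K = 3L, correlation = 0, sd = 0.35) {
  stopifnot(K %in% c(2L, 3L), abs(correlation) < 1)
  means <- rbind(c(-1.5, -0.9), c(1.5, -0.9), c(0, 1.6))[seq_len(K), , drop = FALSE]
  cv <- sd^2 * matrix(c(1, correlation, correlation, 1), 2, 2)
  covs <- array(cv, dim = c(2, 2, K))
  weights <- rep(1 / K, K)
  list(means = means, covs = covs, weights = weights)
}
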