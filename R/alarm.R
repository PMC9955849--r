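#' Classify feature vectors into posture regions
#'
#' Each point takes the region of the component with the largest posterior
#' responsibility, provided that responsibility reaches `threshold`;
#' otherwise the point is `"uncertain"`. Ties break toward the lowest cluster
#' index.
#'
#' @param s Feature vectors (tibble with `s1`, `s2`, matrix, or length-2
#'   vector).
#' @param params A [gmm_params()] object, or an `svi_gmm` fit with assigned
#'   cluster labels.
#' @param labels Character vector mapping cluster index to region; taken from
#'   the fit when `params` is an `svi_gmm`.
#' @param threshold Minimum posterior probability in `(0, 1]`.
#' @return Character vector of region tags (or `"uncertain"`).
#' @export
classify_point <- function(s, params, labels = NULL, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (inherits(params, "svi_gmm")) {
    if (is.null(labels)) labels <- params$cluster_labels
    params <- expected_gmm(params$state)
  }
  if (is.null(labels) || length(labels) != params$K) {
    stop("labels must cover all clusters", call. = FALSE)
  }
  resp <- as.matrix(posterior_responsibility(s, params))
  k <- max.col(resp, ties.method = "first")
  p <- resp[cbind(seq_len(nrow(resp)), k)]
  ifelse(p >= threshold, labels[k], "uncertain")
}

#' Staged fall-alarm state machine
#'
#' Walks a time-ordered feature stream and raises `warning1` on sustained
#' entry into the transition region and `warning2` on sustained entry into
#' the falling region. A transition (escalation or de-escalation) fires after
#' `persistence` consecutive points classify into the same new region;
#' `"uncertain"` points neither advance nor reset the run. Severity is
#' ordered normal < transition < falling.
#'
#' @param points Time-ordered feature tibble (`t`, `s1`, `s2`).
#' @param params A [gmm_params()] or a labeled `svi_gmm` fit.
#' @param labels Cluster-to-region labels (taken from the fit if omitted).
#' @param threshold Posterior threshold passed to [classify_point()].
#' @param persistence Consecutive consistent classifications required.
#' @return A tibble of alarm events: `state` (`normal`, `warning1`,
#'   `warning2`), `t_enter`, `trigger_index`, and the posterior probabilities
#'   `p_normal`, `p_transition`, `p_falling` at the trigger.
#' @export
alarm_state_machine <- function(points, params, labels = NULL, threshold = 0.5,
                                persistence = 3L) {
  stopifnot(persistence >= 1L)
  if (inherits(params, "svi_gmm")) {
    if (is.null(labels)) labels <- params$cluster_labels
    params <- expected_gmm(params$state)
  }
  if (is.null(labels) || length(labels) != params$K) {
    stop("labels must cover all clusters", call. = FALSE)
  }
  if (is.unsorted(points$t)) {
    stop("unsorted stream: points must be time-ordered", call. = FALSE)
  }
  tags <- classify_point(points, params, labels, threshold)
  resp <- as.matrix(posterior_responsibility(points, params))
  region_prob <- function(i, region) {
    sum(resp[i, labels == region])
  }
  state <- "normal"
  run_tag <- NA_character_
  run_len <- 0L
  events <- list()
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "uncertain") next # neither advances nor resets the run
    if (tag == state) {
      run_tag <- NA_character_
      run_len <- 0L
      next
    }
    if (!is.na(run_tag) && tag == run_tag) {
      run_len <- run_len + 1L
    } else {
      run_tag <- tag
      run_len <- 1L
    }
    if (run_len >= persistence) {
      state <- run_tag
      events[[length(events) + 1L]] <- tibble::tibble(
        state = switch(state,
          normal = "normal", transition = "warning1", falling = "warning2"
        ),
        t_enter = points$t[i],
        trigger_index = i,
        p_normal = region_prob(i, "normal"),
        p_transition = region_prob(i, "transition"),
        p_falling = region_prob(i, "falling")
      )
      run_tag <- NA_character_
      run_len <- 0L
    }
  }
  if (length(events) == 0L) {
    return(tibble::tibble(
      state = character(), t_enter = numeric(), trigger_index = integer(),
      p_normal = numeric(), p_transition = numeric(), p_falling = numeric()
    ))
  }
  dplyr::bind_rows(events)
}

#' Alarm lead time from a centroid-point count
#'
#' The time spanned by `n_points` consecutive bounding-box centroids at the
#' given frame rate: 40 points at 60 FPS give 0.667 s, the transit of the
#' transition region during a fall.
#'
#' @param n_points Number of centroid points (nonnegative).
#' @param fps Frame rate in frames per second (positive).
#' @return Seconds.
#' @export
lead_time <- function(n_points, fps) {
  stopifnot(n_points >= 0)
  if (fps <= 0) stop("invalid rate: fps must be positive", call. = FALSE)
  n_points / fps
}

#' Write an alarm event log to CSV
#'
#' @param events Tibble from [alarm_state_machine()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alarm_log <- function(events, path) {
  readr::write_csv(
    events[, c(
      "t_enter", "state", "trigger_index",
      "p_normal", "p_transition", "p_falling"
    )],
    path
  )
  invisible(path)
}
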