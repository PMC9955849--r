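#' Windowed, labeled features of a simulated or recorded session
#'
#' Runs centroid extraction and windowing on a session's bounding boxes and
#' attaches the ground-truth label of each window's anchor frame.
#'
#' @param session A `fall_session`, or a list with `bboxes` (and optionally
#'   `labels`) tibbles.
#' @param fps,frame_size Recording geometry; defaults come from the session
#'   spec when present.
#' @return A labeled `feature_windows` tibble.
#' @export
session_windows <- function(session, fps = NULL, frame_size = NULL) {
  if (is.null(fps)) fps <- session$spec$fps %||% 60
  if (is.null(frame_size)) frame_size <- session$spec$frame_size %||% c(640L, 480L)
  cent <- extract_centroids(session$bboxes, fps = fps, frame_size = frame_size)
  win <- make_windows(cent, fps = fps)
  if (!is.null(session$labels)) win <- label_windows(win, session$labels, fps)
  win
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Concatenate feature windows from several sessions
#'
#' @param window_list List of `feature_windows` tibbles.
#' @return One `feature_windows` tibble with fresh window ids.
#' @export
combine_windows <- function(window_list) {
  stopifnot(length(window_list) >= 1)
  fps <- attr(window_list[[1]], "fps")
  wl <- attr(window_list[[1]], "window_length")
  out <- dplyr::bind_rows(lapply(window_list, tibble::as_tibble))
  out$window_id <- seq_len(nrow(out))
  class(out) <- c("feature_windows", class(tibble::tibble()))
  attr(out, "fps") <- fps
  attr(out, "window_length") <- wl
  out
}

#' Fit the full posture model on simulated or recorded sessions
#'
#' Extracts windowed centroid features from every session, trains the
#' attention block and the variational mixture jointly, names the clusters
#' from the training labels, and fits the min-max feature normalization used
#' by the probabilistic maps.
#'
#' @param sessions A list of sessions, or the tibble from [simulate_cohort()].
#' @param K,covariance_mode,config,seed Passed to [svi_fit()].
#' @param balance `"match"` (default) subsamples normal-labeled windows down
#'   to the count of transition plus falling windows before training, so the
#'   mixture is not dominated by the long normal phases (the study's own
#'   classified point counts are likewise balanced toward non-normal
#'   samples); `"none"` trains on every window. Labels are used only to
#'   construct the training set, never in the loss.
#' @return A labeled `svi_gmm` fit with its `normalization` record set.
#' @export
fit_posture_model <- function(sessions, K = 3L, covariance_mode = "full",
                              config = svi_config(), seed = 1L,
                              balance = c("match", "none")) {
  balance <- match.arg(balance)
  if (is.data.frame(sessions) && !is.null(sessions$session)) {
    sessions <- sessions$session
  }
  if (inherits(sessions, "fall_session")) sessions <- list(sessions)
  windows <- combine_windows(lapply(sessions, session_windows))
  if (balance == "match" && !is.null(windows$label)) {
    normal_idx <- which(windows$label == "normal")
    n_other <- sum(windows$label != "normal")
    if (n_other > 0 && length(normal_idx) > n_other) {
      keep <- withr::with_seed(
        seed,
        sort(sample(normal_idx, n_other))
      )
      fps <- attr(windows, "fps")
      wl <- attr(windows, "window_length")
      windows <- windows[sort(c(keep, which(windows$label != "normal"))), ]
      class(windows) <- c("feature_windows", class(tibble::tibble()))
      attr(windows, "fps") <- fps
      attr(windows, "window_length") <- wl
    }
  }
  fit <- svi_fit(windows,
    K = K, covariance_mode = covariance_mode,
    config = config, seed = seed
  )
  fit$normalization <- normalize_features(fit$features)$record
  fit
}

#' Classify every window of a session under a fitted posture model
#'
#' @param fit A labeled `svi_gmm` from [fit_posture_model()].
#' @param session A session (list with `bboxes`, optionally `labels`).
#' @param threshold Posterior threshold for [classify_point()].
#' @return A tibble `t`, `s1`, `s2`, `region` (predicted) and `label`
#'   (ground truth, when available).
#' @export
predict_session <- function(fit, session, threshold = 0.5) {
  stopifnot(inherits(fit, "svi_gmm"))
  if (is.null(fit$cluster_labels)) {
    stop("incompatible model: cluster labels not assigned", call. = FALSE)
  }
  windows <- session_windows(session)
  feats <- attention_forward(windows, fit$state$attention)
  feats$region <- classify_point(feats, expected_gmm(fit$state),
    labels = fit$cluster_labels, threshold = threshold
  )
  if (!is.null(windows$label)) feats$label <- windows$label
  feats
}
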