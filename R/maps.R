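#' Min-max normalization of feature vectors
#'
#' Scales each feature axis to `[0, 1]` using the range of the supplied
#' (training) points, and returns the transform so the same scaling can be
#' re-applied to new points. Already-normalized tibbles are refused, so the
#' transform cannot be applied twice by accident.
#'
#' @param points Feature tibble with columns `s1`, `s2`.
#' @return A list with `points` (normalized tibble, flagged with the
#'   `normalized` attribute) and `record` (a `feature_normalization` object
#'   holding the per-axis minima and ranges).
#' @export
normalize_features <- function(points) {
  smat <- as_feature_matrix(points)
  if (isTRUE(attr(points, "normalized"))) {
    stop("features are already normalized; re-application is rejected",
      call. = FALSE
    )
  }
  if (nrow(smat) < 2L) {
    stop("degenerate axis: need at least 2 points per axis", call. = FALSE)
  }
  mins <- apply(smat, 2, min)
  maxs <- apply(smat, 2, max)
  ranges <- maxs - mins
  if (any(ranges <= 0)) {
    stop("degenerate axis: zero range on axis ", which(ranges <= 0)[1],
      call. = FALSE
    )
  }
  record <- structure(
    list(mins = unname(mins), ranges = unname(ranges)),
    class = "feature_normalization"
  )
  list(points = apply_normalization(points, record), record = record)
}

#' Apply a stored feature normalization to new points
#'
#' @param points Feature tibble with `s1`, `s2` (raw scale).
#' @param record A `feature_normalization` from [normalize_features()].
#' @return The normalized tibble, flagged so a second application errors.
#' @export
apply_normalization <- function(points, record) {
  stopifnot(inherits(record, "feature_normalization"))
  if (isTRUE(attr(points, "normalized"))) {
    stop("features are already normalized; re-application is rejected",
      call. = FALSE
    )
  }
  smat <- as_feature_matrix(points)
  scaled <- sweep(sweep(smat, 2, record$mins), 2, record$ranges, "/")
  out <- if (is.data.frame(points)) points else
    tibble::tibble(s1 = smat[, 1], s2 = smat[, 2])
  out$s1 <- scaled[, 1]
  out$s2 <- scaled[, 2]
  attr(out, "normalized") <- TRUE
  out
}

#' Transform mixture parameters under a feature normalization
#'
#' Min-max scaling is affine, so the mixture maps exactly: means are scaled
#' like points and covariances by the diagonal scaling on both sides.
#'
#' @param params A [gmm_params()] object in raw feature space.
#' @param record A `feature_normalization`.
#' @return The [gmm_params()] in normalized coordinates.
#' @export
transform_gmm <- function(params, record) {
  stopifnot(inherits(params, "gmm_params"), inherits(record, "feature_normalization"))
  S <- diag(1 / record$ranges, params$dim)
  means <- sweep(params$means, 2, record$mins)
  means <- means %*% S
  covs <- params$covs
  for (k in seq_len(params$K)) covs[, , k] <- S %*% covs[, , k] %*% S
  gmm_params(params$weights, means, covs)
}

new_map_grid <- function(x_centers, y_centers, values, kind,
                         codes = NULL) {
  grid <- tidyr::expand_grid(y = y_centers, x = x_centers)
  grid$value <- as.vector(t(values)) # row-major: y outer, x inner
  out <- tibble::as_tibble(grid[, c("x", "y", "value")])
  structure(out,
    class = c("map_grid", class(out)),
    x_centers = x_centers, y_centers = y_centers, kind = kind, codes = codes
  )
}

map_values_matrix <- function(map) {
  xc <- attr(map, "x_centers")
  yc <- attr(map, "y_centers")
  matrix(map$value, nrow = length(yc), ncol = length(xc), byrow = TRUE)
}

#' Variational likelihood map over the normalized feature square
#'
#' Evaluates the mixture density at the centers of a regular grid over
#' `[0, 1]^2`.
#'
#' @param params A [gmm_params()] (already in normalized coordinates, e.g.
#'   via [transform_gmm()]).
#' @param resolution Cells per axis (at least 16).
#' @return A `map_grid` tibble (`x`, `y`, `value`) with kind `"likelihood"`.
#' @export
likelihood_map <- function(params, resolution = 200L) {
  stopifnot(inherits(params, "gmm_params"), resolution >= 16L)
  centers <- (seq_len(resolution) - 0.5) / resolution
  grid <- as.matrix(expand.grid(s1 = centers, s2 = centers))
  dens <- exp(gmm_log_likelihood(grid, params))
  values <- matrix(dens, nrow = resolution, ncol = resolution) # [x, y]
  new_map_grid(centers, centers, t(values), kind = "likelihood")
}

#' Region map: posture classification of every grid cell
#'
#' Each cell is tagged by the region of the component with the largest
#' posterior responsibility (ties to the lowest cluster index).
#'
#' @param params A [gmm_params()] in normalized coordinates.
#' @param labels Character vector mapping cluster index to region tag; must
#'   cover all clusters.
#' @param resolution Cells per axis.
#' @return A `map_grid` with kind `"region"`; `value` holds integer codes,
#'   the `codes` attribute maps codes to tags.
#' @export
region_map <- function(params, labels, resolution = 200L) {
  stopifnot(inherits(params, "gmm_params"), resolution >= 16L)
  if (length(labels) != params$K || anyNA(labels)) {
    stop("labels must cover all clusters", call. = FALSE)
  }
  centers <- (seq_len(resolution) - 0.5) / resolution
  grid <- as.matrix(expand.grid(s1 = centers, s2 = centers))
  resp <- posterior_responsibility(grid, params)
  assign <- responsibility_argmax(resp)
  tags <- unique(labels)
  codes <- setNames(seq_along(tags), tags)
  values <- matrix(codes[labels[assign]], nrow = resolution, ncol = resolution)
  new_map_grid(centers, centers, t(values), kind = "region", codes = codes)
}

#' Covariance ellipses of the mixture components
#'
#' Eigen-decomposes each component covariance; semi-axes are
#' `n_std * sqrt(eigenvalue)` and the rotation is the angle of the leading
#' eigenvector.
#'
#' @param params A [gmm_params()].
#' @param n_std Number of standard deviations spanned by the semi-axes.
#' @return A tibble with one row per cluster: `cluster`, `center_s1`,
#'   `center_s2`, `semi_major`, `semi_minor`, `rotation` (radians in
#'   `(-pi/2, pi/2]`).
#' @export
covariance_ellipses <- function(params, n_std = 1) {
  stopifnot(inherits(params, "gmm_params"), n_std > 0)
  purrr::map_dfr(seq_len(params$K), function(k) {
    e <- eigen(params$covs[, , k], symmetric = TRUE)
    if (min(e$values) <= 0) {
      stop("degenerate component: covariance not positive-definite",
        call. = FALSE
      )
    }
    v <- e$vectors[, 1]
    ang <- atan2(v[2], v[1])
    if (ang <= -pi / 2) ang <- ang + pi
    if (ang > pi / 2) ang <- ang - pi
    tibble::tibble(
      cluster = k,
      center_s1 = params$means[k, 1],
      center_s2 = params$means[k, 2],
      semi_major = n_std * sqrt(e$values[1]),
      semi_minor = n_std * sqrt(e$values[2]),
      rotation = ang
    )
  })
}

#' Raster plot of a posture map
#'
#' @param object A `map_grid`.
#' @param ... Unused.
#' @return A ggplot: filled raster of the likelihood, or discrete regions.
#' @export
autoplot.map_grid <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (kind == "region") {
    codes <- attr(object, "codes")
    df$region <- names(codes)[match(df$value, codes)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$region)) +
      ggplot2::scale_fill_manual(values = c(
        normal = "#4477AA", transition = "#66BB66", falling = "#EE8833"
      ), na.value = "grey80")
  } else {
    p <- p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(name = "likelihood")
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "s1 (normalized)", y = "s2 (normalized)") +
    ggplot2::theme_minimal()
}

#' Write a map grid to CSV
#'
#' Layout: first row holds the x-centers (first cell blank), the first column
#' holds the y-centers, and the body holds the values. Region maps also write
#' a JSON sidecar (`<path>.codes.json`) mapping integer codes to region tags.
#'
#' @param map A `map_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "map_grid"))
  xc <- attr(map, "x_centers")
  yc <- attr(map, "y_centers")
  vals <- map_values_matrix(map)
  header <- paste(c("", format(xc, digits = 12)), collapse = ",")
  rows <- vapply(seq_along(yc), function(i) {
    paste(c(format(yc[i], digits = 12), format(vals[i, ], digits = 12)),
      collapse = ","
    )
  }, character(1))
  writeLines(c(header, rows), path)
  codes <- attr(map, "codes")
  if (!is.null(codes)) {
    jsonlite::write_json(as.list(codes), paste0(path, ".codes.json"),
      auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Read a map grid written by [write_map_csv()]
#'
#' @param path CSV path.
#' @param kind Map kind to record (`"likelihood"`, `"posterior"`, `"region"`).
#' @return A `map_grid`.
#' @export
read_map_csv <- function(path, kind = "likelihood") {
  lines <- readLines(path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  xc <- as.numeric(header[-1])
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  yc <- vapply(body, function(r) as.numeric(r[1]), numeric(1))
  vals <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(length(xc))))
  codes <- NULL
  sidecar <- paste0(path, ".codes.json")
  if (file.exists(sidecar)) {
    codes <- unlist(jsonlite::read_json(sidecar))
    kind <- "region"
  }
  new_map_grid(xc, yc, vals, kind = kind, codes = codes)
}
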