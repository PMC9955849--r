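bbox_columns <- c("frame", "t", "x_min", "y_min", "x_max", "y_max", "confidence")

#' Read a bounding-box stream
#'
#' CSV streams carry a mandatory header `frame,t,x_min,y_min,x_max,y_max,
#' confidence`; JSON streams are an array of records with the same keys. One
#' stream per file.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A tibble with the bounding-box columns.
#' @export
read_bbox_stream <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
  }
  missing_cols <- setdiff(setdiff(bbox_columns, "confidence"), names(df))
  if (length(missing_cols) > 0L) {
    stop("parse error in ", basename(path), " line 1: missing columns ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  num_cols <- setdiff(bbox_columns, "confidence")
  for (cl in num_cols) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  bad <- which(!stats::complete.cases(df[, num_cols]))
  if (length(bad) > 0L) {
    stop("parse error in ", basename(path), " line ", bad[1] + 1L,
      ": non-numeric or missing value",
      call. = FALSE
    )
  }
  if (is.null(df$confidence)) df$confidence <- 1
  df[, bbox_columns]
}

#' Write a bounding-box stream to CSV
#'
#' @param bboxes Tibble with the bounding-box columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bbox_stream <- function(bboxes, path) {
  readr::write_csv(bboxes[, bbox_columns], path)
  invisible(path)
}

#' Write feature vectors to CSV (`t,s1,s2,label`)
#'
#' @param features Feature tibble; a missing `label` column is written empty.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  out <- tibble::tibble(
    t = features$t, s1 = features$s1, s2 = features$s2,
    label = if (is.null(features$label)) NA_character_ else features$label
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read feature vectors written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return A tibble `t`, `s1`, `s2`, `label`.
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      t = readr::col_double(), s1 = readr::col_double(),
      s2 = readr::col_double(), label = readr::col_character()
    ),
    show_col_types = FALSE
  )
}

#' Write a simulated session to disk
#'
#' Emits the bounding-box CSV, a labels CSV (`frame,label`) and a session
#' JSON echoing the spec plus the impact time.
#'
#' @param session A `fall_session` from [simulate_session()].
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_session <- function(session, dir, stem = "session") {
  stopifnot(inherits(session, "fall_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    bboxes = file.path(dir, paste0(stem, "_bboxes.csv")),
    labels = file.path(dir, paste0(stem, "_labels.csv")),
    session = file.path(dir, paste0(stem, "_session.json"))
  )
  write_bbox_stream(session$bboxes, paths[["bboxes"]])
  readr::write_csv(session$labels, paths[["labels"]])
  spec <- session$spec
  jsonlite::write_json(
    list(
      spec = unclass(spec),
      impact_time = session$impact_time
    ),
    paths[["session"]],
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(paths)
}

#' Read a run configuration JSON
#'
#' Recognized keys: `K`, `covariance_mode`, `L`, `batch_size`, `step_size`,
#' `momentum`, `steps`, `seed`, `dirichlet_interpretation`, plus subcommand
#' settings; unknown keys are preserved.
#'
#' @param path JSON path.
#' @param overrides Named list overriding file values.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE) else list()
  modifyList(cfg, overrides)
}
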