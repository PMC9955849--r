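#' Confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integers.
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification accuracy from confusion counts
#'
#' `(tp + tn) / (tp + tn + fp + fn)`, kept at full precision; rounding to two
#' decimals is for display only.
#'
#' @param counts A [confusion_counts()] object (or a list with fields
#'   `tp`, `tn`, `fp`, `fn`).
#' @return The accuracy fraction in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0) stop("empty counts: total must be positive", call. = FALSE)
  (counts$tp + counts$tn) / total
}

#' Confusion counts from predicted and true label streams
#'
#' Labels are binarized per sample (the positive class is alert-centric:
#' transition and falling by default) and tallied into a standard 2x2 table.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive Character set of labels counted as positive.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_streams <- function(predicted, truth,
                                   positive = c("transition", "falling")) {
  if (length(predicted) != length(truth)) {
    stop("misaligned streams: predicted and truth lengths differ", call. = FALSE)
  }
  p <- predicted %in% positive
  a <- truth %in% positive
  confusion_counts(
    tp = sum(p & a), tn = sum(!p & !a),
    fp = sum(p & !a), fn = sum(!p & a)
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(
    "Confusion counts: TP", x$tp, " TN", x$tn, " FP", x$fp, " FN", x$fn,
    "\n  accuracy:", format(round(accuracy(x), 2), nsmall = 2), "\n"
  )
  invisible(x)
}

#' Held-out log-likelihood comparison across model variants
#'
#' Fits every requested variant (component count x covariance mode) on the
#' training points with a shared seed and scores each on the held-out points
#' by the mean mixture log-likelihood of the expected mixture. Reproduces the
#' qualitative model comparison: on correlated clusters the full-covariance
#' fit should beat the diagonal one, and K = 3 should beat K = 2 on
#' three-cluster data.
#'
#' @param train,test Disjoint feature tibbles (`s1`, `s2`).
#' @param variants A data frame with columns `K` and `covariance_mode`;
#'   defaults to the four-way comparison K in (2, 3) x (diagonal, full).
#' @param config An [svi_config()] shared by all fits.
#' @param seed Shared seed, so duplicate variants produce identical scores.
#' @return `variants` as a tibble with a `heldout_loglik` column.
#' @export
heldout_loglik <- function(train, test,
                           variants = tidyr::expand_grid(
                             K = c(2L, 3L),
                             covariance_mode = c("diagonal", "full")
                           ),
                           config = svi_config(), seed = 1L) {
  variants <- tibble::as_tibble(variants)
  variants$heldout_loglik <- purrr::pmap_dbl(
    variants[, c("K", "covariance_mode")],
    function(K, covariance_mode) {
      fit <- svi_fit(train,
        K = K, covariance_mode = covariance_mode,
        config = config, seed = seed
      )
      mean_loglik(fit, test)
    }
  )
  variants
}
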