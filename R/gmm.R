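# log density of N(mean, cov) evaluated at the rows of s (n x dim matrix)
mvn_log_density <- function(s, mean, cov) {
  dim <- ncol(s)
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("degenerate component: covariance not positive-definite", call. = FALSE)
  })
  logdet <- 2 * sum(log(diag(ch)))
  centered <- sweep(s, 2, mean)
  # solve against the Cholesky factor: quadratic form via back-substitution
  z <- backsolve(ch, t(centered), transpose = TRUE)
  quad <- colSums(z^2)
  -0.5 * (dim * log(2 * pi) + logdet + quad)
}

as_feature_matrix <- function(s) {
  if (is.matrix(s)) {
    return(s)
  }
  if (is.numeric(s)) {
    return(matrix(s, nrow = 1))
  }
  if (is.data.frame(s)) {
    return(as.matrix(s[, c("s1", "s2")]))
  }
  stop("features must be a matrix, numeric vector or tibble with s1, s2",
    call. = FALSE
  )
}

# n x K matrix of log(alpha_k) + log N(s | mu_k, Sigma_k)
component_log_terms <- function(s, params) {
  smat <- as_feature_matrix(s)
  K <- params$K
  out <- matrix(0, nrow(smat), K)
  for (k in seq_len(K)) {
    out[, k] <- log(params$weights[k]) +
      mvn_log_density(smat, params$means[k, ], params$covs[, , k])
  }
  out
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Mixture log-likelihood of feature vectors
#'
#' Evaluates the log of the weighted sum of component Gaussian densities,
#' computed stably via log-sum-exp.
#'
#' @param s Feature vectors: a tibble with columns `s1`, `s2`, an n x 2
#'   matrix, or a length-2 numeric vector.
#' @param params A [gmm_params()] object.
#' @return Numeric vector of log-densities, one per feature vector.
#' @export
gmm_log_likelihood <- function(s, params) {
  stopifnot(inherits(params, "gmm_params"))
  unname(log_sum_exp_rows(component_log_terms(s, params)))
}

#' Posterior cluster responsibilities
#'
#' The posterior probability that each feature vector belongs to each mixture
#' component: `r_k = alpha_k N(s | mu_k, Sigma_k) / sum_j alpha_j N(s | mu_j,
#' Sigma_j)`, computed in the log domain.
#'
#' @inheritParams gmm_log_likelihood
#' @return A tibble with K columns `r1 ... rK`; rows sum to 1.
#' @export
posterior_responsibility <- function(s, params) {
  stopifnot(inherits(params, "gmm_params"))
  lt <- component_log_terms(s, params)
  lse <- log_sum_exp_rows(lt)
  if (any(!is.finite(lse))) {
    stop("point outside support: all component densities underflow",
      call. = FALSE
    )
  }
  r <- exp(lt - lse)
  out <- tibble::as_tibble(r, .name_repair = "minimal")
  names(out) <- paste0("r", seq_len(params$K))
  out
}

# hard assignment with ties broken toward the lowest cluster index
responsibility_argmax <- function(resp) {
  r <- as.matrix(resp)
  max.col(r, ties.method = "first")
}
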