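#' Construct a variational state
#'
#' Holds every trainable quantity of the model: for each cluster the
#' variational mean distribution `Normal(N1, diag(N2))`, the precision
#' distribution `Wishart(W1, W2)` (diagonal-Gamma analogue in diagonal mode),
#' the weight distribution `Dirichlet(D)`, and optionally the attention
#' parameters trained jointly with them.
#'
#' @param N1 K x dim matrix of variational mean locations.
#' @param N2 K x dim matrix of variational mean variances (positive).
#' @param W1 Length-K vector of Wishart degrees of freedom (> dim - 1).
#' @param W2 dim x dim x K array of Wishart scale matrices (symmetric
#'   positive-definite; diagonal when `covariance_mode = "diagonal"`).
#' @param D Length-K vector of Dirichlet concentrations (positive).
#' @param covariance_mode `"full"` or `"diagonal"`.
#' @param attention Optional [attention_params()] object.
#' @return An object of class `variational_state`.
#' @export
variational_state <- function(N1, N2, W1, W2, D,
                              covariance_mode = c("full", "diagonal"),
                              attention = NULL) {
  covariance_mode <- match.arg(covariance_mode)
  N1 <- as.matrix(N1)
  N2 <- as.matrix(N2)
  K <- nrow(N1)
  dim <- ncol(N1)
  W2 <- array(W2, dim = c(dim, dim, K))
  state <- structure(
    list(
      K = K, dim = dim, N1 = N1, N2 = N2, W1 = as.numeric(W1), W2 = W2,
      D = as.numeric(D), covariance_mode = covariance_mode,
      attention = attention, schema_version = 1L
    ),
    class = "variational_state"
  )
  validate_state(state)
  state
}

validate_state <- function(state) {
  with(state, {
    if (!all(is.finite(N1)) || !all(is.finite(N2)) || !all(is.finite(W1)) ||
      !all(is.finite(W2)) || !all(is.finite(D))) {
      stop("invalid distribution: non-finite variational parameters",
        call. = FALSE
      )
    }
    if (any(N2 <= 0)) stop("invalid distribution: N2 must be positive", call. = FALSE)
    if (any(W1 <= dim - 1)) {
      stop("invalid distribution: Wishart degrees of freedom must exceed dim - 1",
        call. = FALSE
      )
    }
    if (any(D <= 0)) stop("invalid distribution: D must be positive", call. = FALSE)
    for (k in seq_len(K)) {
      Wk <- W2[, , k]
      if (max(abs(Wk - t(Wk))) > 1e-8) {
        stop("invalid distribution: W2 must be symmetric", call. = FALSE)
      }
      if (covariance_mode == "diagonal" && max(abs(Wk - diag(diag(Wk)))) > 1e-12) {
        stop("invalid distribution: W2 must be diagonal in diagonal mode",
          call. = FALSE
        )
      }
      ev <- eigen(Wk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) {
        stop("invalid distribution: W2 must be positive-definite", call. = FALSE)
      }
    }
  })
  invisible(state)
}

#' A variational state matching the prior
#'
#' @param prior A [prior_spec()] object.
#' @param covariance_mode `"full"` or `"diagonal"`.
#' @param attention Optional attention parameters.
#' @return A `variational_state` whose distributions equal the prior's.
#' @export
state_from_prior <- function(prior, covariance_mode = "full", attention = NULL) {
  variational_state(
    N1 = prior$mean_mean,
    N2 = matrix(prior$mean_var, prior$K, prior$dim),
    W1 = prior$wishart_df,
    W2 = prior$wishart_scale,
    D = prior$dirichlet,
    covariance_mode = covariance_mode,
    attention = attention
  )
}

#' Mixture parameters
#'
#' @param weights Length-K vector on the simplex.
#' @param means K x dim matrix of component means.
#' @param covs dim x dim x K array of component covariances.
#' @return An object of class `gmm_params`.
#' @export
gmm_params <- function(weights, means, covs) {
  means <- as.matrix(means)
  K <- nrow(means)
  dim <- ncol(means)
  weights <- as.numeric(weights)
  covs <- array(covs, dim = c(dim, dim, K))
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("invalid weights: must lie on the simplex", call. = FALSE)
  }
  for (k in seq_len(K)) {
    ev <- eigen(covs[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("degenerate component: covariance not positive-definite",
      call. = FALSE)
  }
  structure(
    list(K = K, dim = dim, weights = weights, means = means, covs = covs),
    class = "gmm_params"
  )
}

#' Point summary of the variational state
#'
#' Means are the variational mean locations `N1`; each covariance is the
#' inverse of the Wishart mean precision `W1 * W2`; weights are the Dirichlet
#' mean `D / sum(D)`. In diagonal mode the off-diagonal entries are zero.
#'
#' @param state A `variational_state`.
#' @return A [gmm_params()] object.
#' @export
expected_gmm <- function(state) {
  stopifnot(inherits(state, "variational_state"))
  K <- state$K
  dim <- state$dim
  covs <- array(0, dim = c(dim, dim, K))
  for (k in seq_len(K)) {
    prec <- state$W1[k] * state$W2[, , k]
    covs[, , k] <- solve(prec)
    if (state$covariance_mode == "diagonal") {
      covs[, , k] <- diag(diag(covs[, , k, drop = FALSE][, , 1]), dim)
    }
  }
  gmm_params(
    weights = state$D / sum(state$D),
    means = state$N1,
    covs = covs
  )
}

# ---- unconstrained parameter packing shared with the compiled core ----------
# layout: [attention: G(16) b(4) P(8), column-major] [N1 (K*dim)]
#         [log N2 (K*dim)] [log(W1 - (dim-1)) (K)]
#         [full: per-cluster lower-Cholesky of W2 as (log l11, l21, log l22);
#          diagonal: per-cluster log diagonal of W2] [log(expm1(D)) (K)]

pack_state <- function(state) {
  att <- numeric(0)
  if (!is.null(state$attention)) {
    att <- c(
      as.numeric(state$attention$gate_weights),
      state$attention$gate_bias,
      as.numeric(state$attention$projection)
    )
  }
  K <- state$K
  dim <- state$dim
  w2 <- numeric(0)
  for (k in seq_len(K)) {
    Wk <- state$W2[, , k]
    if (state$covariance_mode == "full") {
      L <- t(chol(Wk))
      w2 <- c(w2, log(L[1, 1]), L[2, 1], log(L[2, 2]))
    } else {
      w2 <- c(w2, log(diag(Wk)))
    }
  }
  c(
    att,
    as.numeric(state$N1),
    log(as.numeric(state$N2)),
    log(state$W1 - (dim - 1)),
    w2,
    ifelse(state$D > 30, state$D, log(expm1(state$D))) # stable softplus-inverse
  )
}

unpack_state <- function(theta, K, dim, covariance_mode, has_attention) {
  pos <- 0L
  attention <- NULL
  if (has_attention) {
    G <- matrix(theta[pos + 1:16], 4, 4)
    b <- theta[pos + 17:20]
    P <- matrix(theta[pos + 21:28], 4, 2)
    attention <- attention_params(G, b, P)
    pos <- pos + 28L
  }
  N1 <- matrix(theta[pos + seq_len(K * dim)], K, dim)
  pos <- pos + K * dim
  N2 <- matrix(exp(theta[pos + seq_len(K * dim)]), K, dim)
  pos <- pos + K * dim
  W1 <- (dim - 1) + exp(theta[pos + seq_len(K)])
  pos <- pos + K
  W2 <- array(0, dim = c(dim, dim, K))
  if (covariance_mode == "full") {
    for (k in seq_len(K)) {
      L <- matrix(0, 2, 2)
      L[1, 1] <- exp(theta[pos + 1])
      L[2, 1] <- theta[pos + 2]
      L[2, 2] <- exp(theta[pos + 3])
      W2[, , k] <- L %*% t(L)
      pos <- pos + 3L
    }
  } else {
    for (k in seq_len(K)) {
      W2[, , k] <- diag(exp(theta[pos + 1:2]), dim)
      pos <- pos + 2L
    }
  }
  th_d <- theta[pos + seq_len(K)]
  D <- ifelse(th_d > 30, th_d, log1p(exp(th_d))) # stable softplus
  variational_state(N1, N2, W1, W2, D,
    covariance_mode = covariance_mode, attention = attention
  )
}

#' Serialize a variational state to JSON
#'
#' All matrices are written row-major at full double precision so that
#' `read_state_json(write_state_json(state, path))` round-trips bit-exactly.
#'
#' @param state A `variational_state`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_state_json <- function(state, path) {
  stopifnot(inherits(state, "variational_state"))
  doc <- list(
    schema_version = 1L,
    K = state$K,
    dim = state$dim,
    covariance_mode = state$covariance_mode,
    N1 = as.numeric(t(state$N1)),
    N2 = as.numeric(t(state$N2)),
    W1 = state$W1,
    W2 = lapply(seq_len(state$K), function(k) as.numeric(t(state$W2[, , k]))),
    D = state$D
  )
  if (!is.null(state$attention)) {
    doc$attention <- list(
      gate_weights = as.numeric(t(state$attention$gate_weights)),
      gate_bias = state$attention$gate_bias,
      projection = as.numeric(t(state$attention$projection))
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a variational state from JSON
#'
#' @param path Path written by [write_state_json()].
#' @return A `variational_state`.
#' @export
read_state_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("incompatible model: unknown state schema version", call. = FALSE)
  }
  K <- doc$K
  dim <- doc$dim
  W2 <- array(0, dim = c(dim, dim, K))
  w2in <- doc$W2
  for (k in seq_len(K)) {
    row <- if (is.matrix(w2in)) w2in[k, ] else w2in[[k]]
    W2[, , k] <- matrix(row, dim, dim, byrow = TRUE)
  }
  attention <- NULL
  if (!is.null(doc$attention)) {
    attention <- attention_params(
      gate_weights = matrix(doc$attention$gate_weights, 4, 4, byrow = TRUE),
      gate_bias = doc$attention$gate_bias,
      projection = matrix(doc$attention$projection, 4, 2, byrow = TRUE)
    )
  }
  variational_state(
    N1 = matrix(doc$N1, K, dim, byrow = TRUE),
    N2 = matrix(doc$N2, K, dim, byrow = TRUE),
    W1 = doc$W1, W2 = W2, D = doc$D,
    covariance_mode = doc$covariance_mode, attention = attention
  )
}
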