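#' Settings for regularized network estimation
#'
#' @param gamma extended BIC hyperparameter (0 = ordinary BIC; 0.5 is the
#'   conventional default for psychological networks).
#' @param n_lambdas number of penalties on the log-spaced path.
#' @param lambda_min_ratio ratio of the smallest to the largest penalty; the
#'   largest is the maximum absolute off-diagonal input correlation.
#' @param convergence_tol maximum absolute parameter change at convergence of
#'   the coordinate descent.
#' @param max_iter cap on outer coordinate-descent sweeps.
#' @return An object of class `ggm_config`.
#' @export
ggm_config <- function(gamma = 0.5, n_lambdas = 100, lambda_min_ratio = 0.01,
                       convergence_tol = 1e-7, max_iter = 1000) {
  stopifnot(gamma >= 0, n_lambdas >= 1,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            convergence_tol > 0, max_iter >= 1)
  structure(list(gamma = gamma, n_lambdas = n_lambdas,
                 lambda_min_ratio = lambda_min_ratio,
                 convergence_tol = convergence_tol, max_iter = max_iter),
            class = "ggm_config")
}

as_cor_matrix <- function(R) {
  if (inherits(R, "correlation_matrix_est")) R <- R$R
  R <- as.matrix(R)
  stopifnot(isSymmetric(unname(R), tol = 1e-7))
  R
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Theta) - trace(R Theta) - lambda * sum_{i != j}
#' |Theta_ij|` by block coordinate descent; the penalty is applied to
#' off-diagonal entries only. `lambda = 0` returns the unpenalized maximum
#' likelihood estimate, the inverse of `R`.
#'
#' @param R positive definite correlation (or covariance) matrix, or a
#'   [correlation_matrix()] result.
#' @param lambda nonnegative penalty.
#' @param config a [ggm_config()] supplying tolerance and iteration cap.
#' @return The estimated precision matrix.
#' @export
glasso_fit <- function(R, lambda, config = ggm_config()) {
  R <- as_cor_matrix(R)
  stopifnot(lambda >= 0)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("input matrix must be positive definite")
  fit <- cpp_glasso(R, lambda, config$convergence_tol, config$max_iter)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge at lambda = %g after %d iterations",
                 lambda, fit$iters))
  Theta <- fit$Theta
  dimnames(Theta) <- dimnames(R)
  Theta
}

#' Partial correlations from a precision matrix
#'
#' `W[i, j] = -Theta[i, j] / sqrt(Theta[i, i] * Theta[j, j])` with zero
#' diagonal.
#'
#' @param Theta precision matrix with strictly positive diagonal.
#' @return Symmetric weight matrix with zero diagonal.
#' @export
precision_to_pcor <- function(Theta) {
  Theta <- as.matrix(Theta)
  d <- diag(Theta)
  if (any(d <= 0)) stop("precision matrix has non-positive diagonal entries")
  W <- -Theta / sqrt(outer(d, d))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

new_ggm_network <- function(W, Theta, lambda, ebic, node_labels) {
  structure(list(W = W, Theta = Theta, lambda_selected = lambda, ebic = ebic,
                 n_edges = sum(abs(W[upper.tri(W)]) > 1e-10),
                 global_strength = sum(abs(W[upper.tri(W)])),
                 node_labels = node_labels),
            class = "ggm_network")
}

#' Estimate a sparse partial-correlation network by EBIC model selection
#'
#' Fits the graphical lasso along a log-spaced penalty path from the maximum
#' absolute off-diagonal correlation down to `lambda_min_ratio` times it, and
#' selects the penalty minimizing the extended BIC,
#' `-2 L + E log(n) + 4 E gamma log(p)`, where
#' `L = (n/2) (log det Theta - trace(R Theta))` and `E` is the number of
#' nonzero off-diagonal pairs. Ties are broken toward the larger penalty
#' (sparser model).
#'
#' @param R correlation matrix or [correlation_matrix()] result.
#' @param n effective sample size used in the likelihood and the EBIC.
#' @param config a [ggm_config()].
#' @return An object of class `ggm_network`: `W` (partial-correlation weight
#'   matrix, zero diagonal), `Theta`, `lambda_selected`, `ebic`, `n_edges`,
#'   `global_strength`, `node_labels`, plus the evaluated `path`.
#' @export
ebic_path <- function(R, n, config = ggm_config()) {
  R <- as_cor_matrix(R)
  p <- ncol(R)
  if (n < p) warning("effective sample size below the number of nodes")
  off <- abs(R[upper.tri(R)])
  lambda_max <- max(off)
  labels <- colnames(R)
  if (is.null(labels)) labels <- paste0("node", seq_len(p))

  if (lambda_max < .Machine$double.eps) {
    Theta <- diag(1 / diag(R))
    dimnames(Theta) <- dimnames(R)
    W <- precision_to_pcor(Theta)
    ll <- determinant(Theta, logarithm = TRUE)$modulus - sum(R * Theta)
    ebic <- -n * as.numeric(ll)
    return(new_ggm_network(W, Theta, 0, ebic, labels))
  }

  lambdas <- exp(seq(log(lambda_max), log(lambda_max * config$lambda_min_ratio),
                     length.out = config$n_lambdas))
  fit <- cpp_glasso_path(R, lambdas, config$convergence_tol, config$max_iter)
  E <- as.numeric(fit$n_edges)
  ebic <- -n * fit$loglik + E * log(n) + 4 * E * config$gamma * log(p)
  sel <- which.min(ebic)   # lambdas descend, so ties resolve to larger lambda
  if (!fit$converged[sel])
    stop(sprintf("graphical lasso did not converge at selected lambda = %g",
                 lambdas[sel]))
  Theta <- fit$Thetas[, , sel]
  dimnames(Theta) <- list(labels, labels)
  W <- precision_to_pcor(Theta)
  net <- new_ggm_network(W, Theta, lambdas[sel], ebic[sel], labels)
  net$path <- data.frame(lambda = lambdas, ebic = ebic, n_edges = E,
                         converged = as.logical(fit$converged))
  net
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf("ggm_network: %d nodes, %d edges, lambda = %.4g, global strength = %.3f\n",
              length(x$node_labels), x$n_edges, x$lambda_selected,
              x$global_strength))
  invisible(x)
}

#' Global strength (overall connectivity) of a network
#'
#' Sum of absolute edge weights over unordered node pairs.
#'
#' @param network a `ggm_network` or a symmetric weight matrix.
#' @return Nonnegative scalar.
#' @export
global_strength <- function(network) {
  W <- if (inherits(network, "ggm_network")) network$W else as.matrix(network)
  sum(abs(W[upper.tri(W)]))
}

#' One-call network estimation from ordinal data
#'
#' Convenience wrapper chaining [correlation_matrix()] and [ebic_path()]; the
#' effective sample size is the number of subjects with any observation at the
#' wave.
#'
#' @inheritParams correlation_matrix
#' @param config a [ggm_config()].
#' @return A `ggm_network`.
#' @export
estimate_network <- function(data, config = ggm_config(),
                             pairwise_complete = TRUE, min_pairwise_n = 10) {
  cm <- correlation_matrix(data, pairwise_complete = pairwise_complete,
                           min_pairwise_n = min_pairwise_n)
  n_eff <- sum(rowSums(!is.na(data$values)) > 0)
  net <- ebic_path(cm$R, n_eff, config)
  net$correlations <- cm
  net$n_eff <- n_eff
  net
}
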