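#' Standardize per-subject momenta into a feature matrix
#'
#' Flattens each subject's `K x 3` momenta (shared control points) into a
#' row of `3K` features and z-scores every column (mean 0, SD 1); columns
#' with zero variance are set to 0 so they contribute nothing.
#'
#' @param momenta_list list of `K x 3` matrices, one per subject.
#' @return `n_subjects x 3K` matrix with attributes `"center"` and
#'   `"scale"` (the per-column means/SDs).
#' @export
standardize_momenta <- function(momenta_list) {
  if (length(momenta_list) < 2) stop("need at least two subjects to standardize")
  K <- nrow(momenta_list[[1]])
  X <- t(vapply(momenta_list, function(m) {
    if (!all(dim(m) == c(K, 3))) stop("momenta shapes differ across subjects")
    as.vector(m)
  }, numeric(3 * K)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu)
  nz <- sdv > 0
  Xs[, nz] <- sweep(Xs[, nz, drop = FALSE], 2, sdv[nz], "/")
  Xs[, !nz] <- 0
  attr(Xs, "center") <- mu
  attr(Xs, "scale") <- sdv
  Xs
}

#' Kernel PCA with an RBF kernel
#'
#' Gram matrix `K[i, j] = exp(-gamma ||x_i - x_j||^2)` is double-centred and
#' eigendecomposed; subject scores use the `eigenvector * sqrt(eigenvalue)`
#' convention, so they are centred and their variance equals the eigenvalue
#' divided by `n`.
#'
#' @param X `n x p` feature matrix (e.g. from [standardize_momenta()]).
#' @param gamma RBF bandwidth; default `1 / (p * var(X))`, the usual
#'   scale-free choice when no value is prescribed.
#' @param n_components number of score columns returned (default `n - 1`).
#' @return object of class `kpca_result`: `eigenvalues` (non-increasing),
#'   `scores` (`n x n_components`), `gamma`.
#' @export
kpca_rbf <- function(X, gamma = NULL, n_components = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("kernel PCA needs at least 3 subjects")
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(X))
    gamma <- 1 / (ncol(X) * max(v, .Machine$double.eps))
  }
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * tcrossprod(X)
  Km <- exp(-gamma * pmax(d2, 0))
  # double centring in feature space
  J <- diag(n) - matrix(1 / n, n, n)
  Kc <- J %*% Km %*% J
  Kc <- (Kc + t(Kc)) / 2
  eig <- eigen(Kc, symmetric = TRUE)
  vals <- eig$values
  if (is.null(n_components)) n_components <- n - 1L
  n_components <- min(n_components, n - 1L)
  pos <- pmax(vals[seq_len(n_components)], 0)
  scores <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pos), n_components)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(eigenvalues = vals, scores = scores, gamma = gamma),
            class = "kpca_result")
}

#' @export
print.kpca_result <- function(x, ...) {
  ev <- pmax(x$eigenvalues, 0)
  cat(sprintf(
    "kpca_result: %d subjects, gamma %.4g; PC1 explains %.1f%% of kernel variance\n",
    nrow(x$scores), x$gamma, 100 * ev[1] / max(sum(ev), .Machine$double.eps)
  ))
  invisible(x)
}
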