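#' Principal component analysis of PH descriptors
#'
#' Column-centered PCA (covariance eigendecomposition via \code{prcomp})
#' of a fruits-by-descriptor matrix. The sign of each component is fixed by
#' the convention that the loading of largest absolute value is positive, so
#' scores are reproducible across runs and years.
#'
#' @param X numeric matrix, one row per fruit (at least 3 rows).
#' @param k number of components to retain in the output (default
#'   \code{min(dim(X)) - 1}, capped at 10).
#' @return Object of class \code{"ph_pca"}: \code{mean} (column means),
#'   \code{loadings} (p x k, orthonormal), \code{var_explained} (fractions of
#'   total variance, all components), \code{scores} (n x k), \code{sdev}.
#' @export
fit_pca <- function(X, k = NULL) {
  stopifnot(is.matrix(X), nrow(X) >= 3L)
  if (is.null(k)) k <- min(10L, nrow(X) - 1L, ncol(X))
  tot <- sum(apply(X, 2, stats::var))
  if (tot <= 0) {
    warning("zero-variance descriptor matrix; all scores set to 0")
    k <- min(k, 2L)
    return(structure(list(
      mean = colMeans(X),
      loadings = diag(1, ncol(X))[, seq_len(k), drop = FALSE],
      var_explained = rep(0, k),
      scores = matrix(0, nrow(X), k,
                      dimnames = list(rownames(X), paste0("PC", seq_len(k)))),
      sdev = rep(0, k)), class = "ph_pca"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$rotation))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {           # largest-|loading|-positive convention
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  colnames(S) <- colnames(L) <- paste0("PC", seq_len(k))
  structure(list(mean = colMeans(X), loadings = L, var_explained = ve,
                 scores = S, sdev = pc$sdev[seq_len(k)]),
            class = "ph_pca")
}

#' @export
print.ph_pca <- function(x, ...) {
  cat(sprintf("<ph_pca: %d fruit x %d descriptors, %d components>\n",
              nrow(x$scores), length(x$mean), ncol(x$scores)))
  ve <- x$var_explained[seq_len(min(4, length(x$var_explained)))]
  cat("  var explained:", paste(sprintf("%.1f%%", 100 * ve), collapse = " "), "\n")
  invisible(x)
}

#' Project new descriptors onto a fitted PCA
#' @param object a \code{ph_pca}.
#' @param newdata descriptor matrix with the same columns as the fit.
#' @param ... unused.
#' @return Score matrix.
#' @export
predict.ph_pca <- function(object, newdata, ...) {
  sweep(newdata, 2, object$mean) %*% object$loadings
}
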