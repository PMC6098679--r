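#' Average per-fruit measurements to genotype-year means
#'
#' @param per_fruit data frame with columns \code{id}, \code{year},
#'   \code{trait} (optional) and \code{value}, or wide trait columns after
#'   \code{id}, \code{year}, \code{fruit}.
#' @return Data frame with one row per genotype-year(-trait): arithmetic
#'   mean \code{value} and fruit count \code{n}. The full genotype x year
#'   grid is emitted; combinations with no fruit get \code{NA} means and
#'   \code{n = 0} so downstream fits can drop them.
#' @export
genotype_means <- function(per_fruit) {
  stopifnot(all(c("id", "year", "value") %in% names(per_fruit)))
  tr <- if ("trait" %in% names(per_fruit)) per_fruit$trait else "trait"
  key <- interaction(per_fruit$id, per_fruit$year, tr, drop = FALSE)
  grid <- expand.grid(id = unique(per_fruit$id),
                      year = sort(unique(per_fruit$year)),
                      trait = unique(tr), stringsAsFactors = FALSE)
  gkey <- interaction(grid$id, grid$year, grid$trait, drop = FALSE)
  sums <- tapply(per_fruit$value, key, sum)
  ns <- tapply(per_fruit$value, key, length)
  grid$value <- as.numeric(sums[as.character(gkey)]) /
    as.numeric(ns[as.character(gkey)])
  grid$n <- as.integer(ns[as.character(gkey)])
  grid$n[is.na(grid$n)] <- 0L
  grid[order(grid$trait, grid$year, grid$id), , drop = FALSE]
}

#' Marker-based additive relationship matrix for a four-way cross
#'
#' Each marker contributes two biallelic indicator dosages — maternal allele
#' \code{a} (codes 1, 2) and paternal allele \code{c} (codes 1, 3) — centered
#' by their observed frequencies. With \eqn{W} the centered indicator matrix,
#' \eqn{A = W W^\top / \sum_k p_k (1 - p_k)} summed over the indicator
#' columns (VanRaden-style scaling), which puts the mean diagonal near 1.
#' Missing genotypes are imputed to the column mean; monomorphic indicator
#' columns are dropped.
#'
#' @param geno n x m integer matrix of codes 0--4 (0 = missing), or a
#'   \code{fourway_cross}.
#' @param ridge added to the diagonal if the smallest eigenvalue is below
#'   \code{-1e-8} (default \code{1e-8} scaling).
#' @return Object of class \code{"kinship"}: \code{A} (n x n), \code{ids}.
#' @export
kinship <- function(geno, ridge = 1e-8) {
  ids <- NULL
  if (inherits(geno, "fourway_cross")) { ids <- geno$ids; geno <- geno$geno }
  stopifnot(is.matrix(geno), nrow(geno) >= 2L, ncol(geno) >= 10L,
            all(geno %in% 0:4))
  if (is.null(ids)) ids <- rownames(geno) %||% sprintf("ind%03d", seq_len(nrow(geno)))
  miss <- geno == 0L
  if (any(rowSums(!miss) == 0L)) stop("individual with all genotypes missing")
  Wm <- matrix(as.numeric(geno %in% c(1L, 2L)), nrow(geno))  # maternal a
  Wp <- matrix(as.numeric(geno %in% c(1L, 3L)), nrow(geno))  # paternal c
  Wm[miss] <- NA; Wp[miss] <- NA
  W <- cbind(Wm, Wp)
  p <- colMeans(W, na.rm = TRUE)
  for (j in which(colSums(is.na(W)) > 0L)) W[is.na(W[, j]), j] <- p[j]
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all indicator columns monomorphic")
  W <- sweep(W[, keep, drop = FALSE], 2, p[keep])
  denom <- sum(p[keep] * (1 - p[keep]))
  A <- tcrossprod(W) / denom
  ev_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) A <- A + diag(ridge - ev_min, nrow(A))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, ids = ids), class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship: %d individuals, mean diagonal %.3f>\n",
              nrow(x$A), mean(diag(x$A))))
  invisible(x)
}

# profiled restricted log-likelihood of lambda = sigma_u^2/sigma_e^2
# given eigen-rotated data; returns list(ll, mu, sigma2_e)
reml_profile <- function(log_lambda, d, ystar, xstar) {
  lam <- exp(log_lambda)
  w <- lam * d + 1
  xx <- sum(xstar^2 / w)
  mu <- sum(xstar * ystar / w) / xx
  r <- ystar - xstar * mu
  rss <- sum(r^2 / w)
  n <- length(ystar)
  s2 <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xx) + (n - 1))
  list(ll = ll, mu = mu, sigma2_e = s2)
}

#' Kinship-BLUP mixed model by spectral REML
#'
#' Fits \eqn{y = 1\mu + u + \varepsilon} with \eqn{u \sim N(0, A\sigma_u^2)}
#' and \eqn{\varepsilon \sim N(0, I\sigma_e^2)}: the restricted likelihood is
#' profiled over \eqn{\lambda = \sigma_u^2/\sigma_e^2} using the spectral
#' decomposition of \eqn{A} and maximized by 1-D bounded search on
#' \eqn{\log\lambda \in [-10, 10]} (tolerance \code{1e-6}). BLUPs follow
#' from the mixed-model equations at the optimum; genomic heritability is
#' \eqn{h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_e^2)}.
#'
#' @param y numeric response (genotype means for one trait-year); \code{NA}s
#'   are dropped casewise together with the matching rows of \code{A}.
#' @param K a \code{\link{kinship}} object or bare relationship matrix.
#' @param bounds search bounds on \eqn{\log\lambda}.
#' @param tol optimizer tolerance.
#' @return Object of class \code{"kinblup"}: \code{sigma2_u}, \code{sigma2_e},
#'   \code{mu}, \code{u} (named BLUP vector, \code{NA} for dropped cases),
#'   \code{h2}, \code{lambda}, \code{loglik_reml}, \code{n}.
#' @export
reml_fit <- function(y, K, bounds = c(-10, 10), tol = 1e-6) {
  A <- if (inherits(K, "kinship")) K$A else K
  stopifnot(is.matrix(A), length(y) == nrow(A))
  ids <- rownames(A) %||% seq_along(y)
  ok <- !is.na(y)
  if (sum(ok) < 10L) stop("need >= 10 non-missing observations")
  yv <- y[ok]; Av <- A[ok, ok, drop = FALSE]
  n <- length(yv)
  u_full <- rep(NA_real_, length(y)); names(u_full) <- ids
  if (stats::var(yv) == 0) {
    u_full[ok] <- 0
    return(structure(list(sigma2_u = 0, sigma2_e = 0, mu = yv[1], u = u_full,
                          h2 = 0, lambda = 0, loglik_reml = NA_real_, n = n),
                     class = "kinblup"))
  }
  eg <- eigen(Av, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6) stop("relationship matrix not PSD after ridge")
  U <- eg$vectors
  ystar <- drop(crossprod(U, yv))
  xstar <- drop(crossprod(U, rep(1, n)))
  opt <- stats::optimize(function(l) reml_profile(l, d, ystar, xstar)$ll,
                         interval = bounds, maximum = TRUE, tol = tol)
  at <- reml_profile(opt$maximum, d, ystar, xstar)
  lam <- exp(opt$maximum)
  # shrink to boundary when the optimum sits at the search edge
  if (opt$maximum <= bounds[1] + 1e-6) lam <- 0
  mu <- at$mu; s2e <- at$sigma2_e
  w <- lam * d + 1
  resid_star <- ystar - xstar * mu
  u <- drop(U %*% ((lam * d / w) * resid_star))
  u_full[ok] <- u
  structure(list(sigma2_u = lam * s2e, sigma2_e = s2e, mu = mu, u = u_full,
                 h2 = lam / (1 + lam), lambda = lam,
                 loglik_reml = opt$objective, n = n),
            class = "kinblup")
}

#' @export
print.kinblup <- function(x, ...) {
  cat(sprintf("<kinblup: n = %d, sigma2_u = %.4g, sigma2_e = %.4g, h2 = %.3f>\n",
              x$n, x$sigma2_u, x$sigma2_e, x$h2))
  invisible(x)
}

#' @export
coef.kinblup <- function(object, ...) object$u

#' @export
summary.kinblup <- function(object, ...) {
  cat("Kinship-BLUP mixed model (spectral REML)\n")
  print(object)
  cat(sprintf("  intercept mu = %.4g; restricted log-likelihood = %.4g\n",
              object$mu, object$loglik_reml))
  invisible(object)
}

#' BLUPs and genomic heritability for every trait-year
#'
#' Runs \code{\link{reml_fit}} per trait and year on genotype means, the
#' strictly per-year analysis used for the seven study traits.
#'
#' @param means data frame from \code{\link{genotype_means}} (columns
#'   \code{id}, \code{year}, \code{trait}, \code{value}).
#' @param K a \code{\link{kinship}} object; rows are matched to \code{id}.
#' @return List: \code{blups} (id, year, trait, mean, blup), \code{h2}
#'   (trait, year, h2, sigma2_u, sigma2_e).
#' @export
fit_all_traits <- function(means, K) {
  A <- if (inherits(K, "kinship")) K$A else K
  blups <- list(); h2 <- list()
  for (tr in unique(means$trait)) for (yr in sort(unique(means$year))) {
    sub <- means[means$trait == tr & means$year == yr, , drop = FALSE]
    y <- sub$value[match(rownames(A), sub$id)]
    fit <- reml_fit(y, A)
    blups[[length(blups) + 1L]] <- data.frame(
      id = rownames(A), year = yr, trait = tr, mean = y, blup = fit$u)
    h2[[length(h2) + 1L]] <- data.frame(
      trait = tr, year = yr, h2 = fit$h2, sigma2_u = fit$sigma2_u,
      sigma2_e = fit$sigma2_e)
  }
  list(blups = do.call(rbind, blups), h2 = do.call(rbind, h2))
}
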