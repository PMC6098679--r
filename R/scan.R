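# residual sum of squares of least squares y ~ X (X includes intercept);
# rank-deficient columns are dropped by the pivoted QR inside .lm.fit
rss_fit <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  sum(f$residuals^2)
}

# LOD from null and alternative RSS
lod_from_rss <- function(rss0, rss1, n) {
  if (rss0 <= .Machine$double.eps || rss1 <= .Machine$double.eps) {
    if (rss0 <= .Machine$double.eps) return(0)
    return(Inf)
  }
  max(n / 2 * log10(rss0 / rss1), 0)
}

#' Haley-Knott single-QTL genome scan
#'
#' At every position the phenotype is regressed on an intercept, the
#' optional covariates, and three genotype-class probability contrasts; the
#' null model drops the genotype term. \eqn{LOD = (n/2)\log_{10}(RSS_0 /
#' RSS_1)}.
#'
#' @param gp a \code{\link{calc_genoprob}} object.
#' @param y phenotype vector aligned to the individuals in \code{gp}.
#' @param covar optional numeric matrix or data frame of covariates.
#' @return Object of class \code{"hk_scan"}: data frame \code{lg},
#'   \code{pos}, \code{lod}, with attributes \code{n} and \code{df} (3).
#' @export
hk_scan <- function(gp, y, covar = NULL) {
  stopifnot(inherits(gp, "genoprobs"))
  ok <- stats::complete.cases(y, covar)
  yv <- y[ok]
  n <- length(yv)
  C <- if (is.null(covar)) NULL else as.matrix(covar)[ok, , drop = FALSE]
  X0 <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  if (n <= ncol(X0) + 3L) stop("too few individuals for the scan design")
  rss0 <- rss_fit(X0, yv)
  blocks <- genoprob_positions(gp)
  lod <- vapply(blocks, function(b) {
    lod_from_rss(rss0, rss_fit(cbind(X0, b$P[ok, , drop = FALSE]), yv), n)
  }, numeric(1))
  out <- data.frame(lg = vapply(blocks, `[[`, integer(1), "lg"),
                    pos = vapply(blocks, `[[`, numeric(1), "pos"),
                    lod = lod)
  structure(out, class = c("hk_scan", "data.frame"), n = n, df = 3L)
}

#' @export
plot.hk_scan <- function(x, threshold = NULL, main = "Haley-Knott scan", ...) {
  lgs <- unique(x$lg)
  graphics::par(mfrow = c(1, length(lgs)), mar = c(4, 4, 2, 0.5))
  for (g in lgs) {
    s <- x[x$lg == g, ]
    graphics::plot(s$pos, s$lod, type = "l", xlab = sprintf("LG %s (cM)", g),
                   ylab = if (g == lgs[1]) "LOD" else "",
                   ylim = c(0, max(x$lod, threshold, 0.1) * 1.05),
                   main = if (g == lgs[ceiling(length(lgs) / 2)]) main else "",
                   ...)
    if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2, col = 2)
  }
  invisible(x)
}

#' Genome-wide permutation threshold for the scan
#'
#' Permutes phenotype rows against genotype rows (covariates travel with the
#' phenotype, preserving trait-covariate correlation under the genome-wide
#' null) and records the genome-wide maximum LOD of each permuted scan;
#' \eqn{T_m} is the empirical \eqn{1-\alpha} quantile (type 7). The whole
#' permutation matrix is drawn up front from \code{seed}, so each permutation
#' is an independent job whose result does not depend on execution order or
#' worker count.
#'
#' @param gp a \code{genoprobs} object.
#' @param y phenotype vector.
#' @param covar optional covariates.
#' @param n_perm number of permutations (>= 100; study default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed.
#' @return Object of class \code{"perm_threshold"}: \code{T_m}, \code{alpha},
#'   \code{n_perm}, \code{seed}, \code{max_lods}.
#' @export
perm_threshold <- function(gp, y, covar = NULL, n_perm = 1000, alpha = 0.05,
                           seed = 1) {
  stopifnot(n_perm >= 100, alpha > 0, alpha < 1)
  ok <- stats::complete.cases(y, covar)
  yv <- y[ok]
  n <- length(yv)
  C <- if (is.null(covar)) NULL else as.matrix(covar)[ok, , drop = FALSE]
  perms <- with_seed(seed,
                     vapply(seq_len(n_perm), function(i) sample.int(n),
                            integer(n)))
  blocks <- genoprob_positions(gp)
  if (is.null(C)) {
    # fast path: designs fixed under permutation; RSS via projections
    Y <- matrix(yv[perms], n, n_perm)
    cs_y <- colSums(Y^2)
    Q0 <- qr.Q(qr(matrix(1, n, 1)))
    rss0 <- cs_y - colSums(crossprod(Q0, Y)^2)
    maxlod <- rep(0, n_perm)
    for (b in blocks) {
      X <- cbind(1, b$P[ok, , drop = FALSE])
      qrx <- qr(X)
      Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
      rss1 <- pmax(cs_y - colSums(crossprod(Q, Y)^2), 0)
      lod <- ifelse(rss0 <= .Machine$double.eps, 0,
                    n / 2 * log10(pmax(rss0, .Machine$double.eps) /
                                  pmax(rss1, .Machine$double.eps)))
      maxlod <- pmax(maxlod, lod)
    }
  } else {
    maxlod <- vapply(seq_len(n_perm), function(i) {
      pi_ <- perms[, i]
      yp <- yv[pi_]; Cp <- C[pi_, , drop = FALSE]
      X0 <- cbind(1, Cp)
      rss0 <- rss_fit(X0, yp)
      max(vapply(blocks, function(b)
        lod_from_rss(rss0, rss_fit(cbind(X0, b$P[ok, , drop = FALSE]), yp), n),
        numeric(1)))
    }, numeric(1))
  }
  structure(list(T_m = as.numeric(stats::quantile(maxlod, 1 - alpha, type = 7)),
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 max_lods = maxlod),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("<perm_threshold: T_m = %.3f at alpha = %g (%d permutations)>\n",
              x$T_m, x$alpha, x$n_perm))
  invisible(x)
}
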