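# Separable Gaussian blur of a numeric matrix (zero-padded), truncated at
# 4 sigma. Exact up to kernel truncation; used for kernel density sums.
gauss_blur <- function(mat, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  conv1 <- function(m, kern) {
    n <- nrow(m); h <- (length(kern) - 1L) / 2L
    pad <- rbind(matrix(0, h, ncol(m)), m, matrix(0, h, ncol(m)))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) out <- out + kern[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(mat, k)), k))
}

#' Pixel density map of a fruit mask
#'
#' Assigns each foreground pixel a density: the Gaussian-kernel sum over all
#' foreground pixels (default) or over the boundary pixels only, with
#' bandwidth \eqn{\sigma = } \code{bandwidth_frac} times the centroid-to-rim
#' distance \eqn{r_{max}}. Densities are min--max normalized to \code{[0, 1]}
#' over the foreground; this is the filtration function whose superlevel sets
#' the Euler-characteristic curves summarize.
#'
#' @param mask a \code{\link{fruit_mask}}.
#' @param bandwidth_frac kernel bandwidth as a fraction of \eqn{r_{max}}
#'   (default 0.2).
#' @param mode \code{"all"} (kernel over all foreground pixels, default) or
#'   \code{"contour"} (over boundary pixels only).
#' @return List of class \code{"density_map"}: \code{values} (matrix, NA off
#'   the foreground), \code{bandwidth} (px), \code{mode}.
#' @export
density_map <- function(mask, bandwidth_frac = 0.2,
                        mode = c("all", "contour")) {
  stopifnot(inherits(mask, "fruit_mask"))
  mode <- match.arg(mode)
  g <- mask$grid
  ctr <- mask_centroid(g)
  idx <- which(g, arr.ind = TRUE)
  r_max <- sqrt(max((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  src <- if (mode == "contour") boundary_mask(g) else g
  if (sum(src) < 4L) stop("degenerate mask: fewer than 4 boundary pixels")
  sigma <- bandwidth_frac * r_max
  dens <- gauss_blur(matrix(as.numeric(src), nrow(g), ncol(g)), sigma)
  v <- dens[g]
  rng <- range(v)
  vals <- matrix(NA_real_, nrow(g), ncol(g))
  vals[g] <- if (rng[2] > rng[1]) (dens[g] - rng[1]) / (rng[2] - rng[1]) else 0
  structure(list(values = vals, bandwidth = sigma, mode = mode),
            class = "density_map")
}

#' Partition a mask into concentric annuli
#'
#' Foreground pixels are binned by normalized distance from the centroid into
#' \code{n_annuli} radial bands of equal width; annulus \eqn{i} holds pixels
#' with normalized radius in \eqn{[(i-1)/n, i/n)}, the last bin closed so the
#' rim pixel belongs to annulus \code{n_annuli}.
#'
#' @param mask a \code{\link{fruit_mask}}.
#' @param n_annuli number of annuli (default 4).
#' @return List of class \code{"annulus_partition"}: \code{labels} (integer
#'   matrix, NA off the foreground), \code{n_annuli}, \code{center},
#'   \code{r_max}.
#' @export
annulus_partition <- function(mask, n_annuli = 4) {
  stopifnot(inherits(mask, "fruit_mask"), n_annuli >= 1)
  g <- mask$grid
  ctr <- mask_centroid(g)
  idx <- which(g, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  r_max <- max(r)
  band <- pmin(as.integer(floor(r / r_max * n_annuli)) + 1L, as.integer(n_annuli))
  labels <- matrix(NA_integer_, nrow(g), ncol(g))
  labels[idx] <- band
  structure(list(labels = labels, n_annuli = n_annuli, center = ctr,
                 r_max = r_max),
            class = "annulus_partition")
}

#' Euler characteristic of a binary pixel set
#'
#' Components minus holes under the standard digital-topology pairing:
#' 8-connected foreground, 4-connected background. Computed by the vectorized
#' 2x2 quad-count formula \eqn{\chi = (Q_1 - Q_3 - 2 Q_d)/4}.
#'
#' @param grid logical (or 0/1) matrix.
#' @return Integer Euler characteristic (0 for the empty set).
#' @examples
#' disk <- make_fruit_mask(shape_params("round", a = 5, b = 5), 4)$grid
#' euler_characteristic(disk)  # 1
#' @export
euler_characteristic <- function(grid) {
  if (!any(grid)) return(0L)
  nr <- nrow(grid); nc <- ncol(grid)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- grid
  a <- p[-(nr + 2L), -(nc + 2L)]; b <- p[-(nr + 2L), -1]
  c_ <- p[-1, -(nc + 2L)];        d <- p[-1, -1]
  s <- a + b + c_ + d
  q1 <- sum(s == 1L)
  q3 <- sum(s == 3L)
  qd <- sum(s == 2L & ((a & d) | (b & c_)) & !(a & b))
  as.integer(round((q1 - q3 - 2L * qd) / 4))
}

#' Euler-characteristic curve of one annulus
#'
#' Thresholds the density over \code{n_levels} values evenly spaced on
#' \code{[0, 1]}; entry \eqn{j} is the Euler characteristic of the superlevel
#' set \eqn{\{p \in \mathrm{annulus} : \mathrm{density}(p) \ge t_j\}}
#' (sublevel sets, \eqn{\le t_j}, behind \code{direction}).
#'
#' @param density a \code{\link{density_map}}.
#' @param annuli an \code{\link{annulus_partition}} from the same mask.
#' @param which_annulus annulus index.
#' @param n_levels number of thresholds (default 30).
#' @param direction \code{"superlevel"} (default) or \code{"sublevel"}.
#' @return List of class \code{"ecc_curve"}: \code{values} (integer vector),
#'   \code{thresholds}.
#' @export
ecc_curve <- function(density, annuli, which_annulus, n_levels = 30,
                      direction = c("superlevel", "sublevel")) {
  stopifnot(inherits(density, "density_map"),
            inherits(annuli, "annulus_partition"),
            all(dim(density$values) == dim(annuli$labels)))
  direction <- match.arg(direction)
  sel <- !is.na(annuli$labels) & annuli$labels == which_annulus
  # restrict work to the annulus bounding box
  rr <- range(which(rowSums(sel) > 0)); cc <- range(which(colSums(sel) > 0))
  dsub <- density$values[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  ssub <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  thr <- seq(0, 1, length.out = n_levels)
  vals <- vapply(thr, function(t) {
    set <- if (direction == "superlevel") ssub & !is.na(dsub) & dsub >= t
           else ssub & !is.na(dsub) & dsub <= t
    euler_characteristic(set)
  }, integer(1))
  structure(list(values = vals, thresholds = thr), class = "ecc_curve")
}

#' Persistent-homology shape descriptor of a fruit mask
#'
#' Concatenates the Euler-characteristic curves of all annuli (innermost
#' first): with the defaults of 4 annuli and 30 density thresholds each
#' fruit is characterized by 120 values.
#'
#' @param mask a \code{\link{fruit_mask}}.
#' @param n_annuli number of annuli (default 4).
#' @param n_levels thresholds per annulus (default 30).
#' @param bandwidth_frac,mode,direction passed to \code{\link{density_map}}
#'   and \code{\link{ecc_curve}}.
#' @return Numeric vector of class \code{"ph_descriptor"}, length
#'   \code{n_annuli * n_levels}, names \code{a<annulus>_t<level>}.
#' @export
ph_descriptor <- function(mask, n_annuli = 4, n_levels = 30,
                          bandwidth_frac = 0.2, mode = "all",
                          direction = "superlevel") {
  dm <- density_map(mask, bandwidth_frac = bandwidth_frac, mode = mode)
  an <- annulus_partition(mask, n_annuli = n_annuli)
  v <- unlist(lapply(seq_len(n_annuli), function(i)
    ecc_curve(dm, an, i, n_levels = n_levels, direction = direction)$values))
  names(v) <- paste0("a", rep(seq_len(n_annuli), each = n_levels),
                     "_t", rep(seq_len(n_levels), n_annuli))
  structure(as.numeric(v), names = names(v), class = "ph_descriptor")
}

#' Descriptor matrix for a set of masks
#' @param masks list of \code{fruit_mask}.
#' @param ... passed to \code{\link{ph_descriptor}}.
#' @return Numeric matrix, one row per mask.
#' @export
ph_descriptor_matrix <- function(masks, ...) {
  rows <- lapply(masks, ph_descriptor, ...)
  out <- do.call(rbind, lapply(rows, as.numeric))
  colnames(out) <- names(rows[[1]])
  rownames(out) <- vapply(masks, function(m) m$source_id, character(1))
  out
}
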