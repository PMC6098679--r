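#' Parameters of a synthetic fruit silhouette
#'
#' The silhouette family spans the three shape classes seen in cranberry
#' fruit: \code{round} and \code{elongated} fruit are superellipses
#' \eqn{|x/a|^n + |y/b|^n = 1}; \code{bell} fruit are piriform, with
#' half-width \eqn{w(t) = b (1 - k t)(1 - t^2)^{1/n}} at axial coordinate
#' \eqn{t \in [-1, 1]}, giving one blunt and one tapered end.
#'
#' @param shape_class one of \code{"round"}, \code{"elongated"}, \code{"bell"}.
#' @param a semi-axis along the length direction, mm.
#' @param b semi-axis along the width direction, mm; \code{a >= b > 0}.
#' @param n_exp superellipse exponent, \code{>= 1}; 2 gives an ellipse.
#' @param bell_k asymmetry coefficient in \code{[0, 1)}; must be \code{> 0}
#'   for the bell class and is ignored otherwise.
#' @param rotation rotation of the length axis, radians in \code{[0, pi)}.
#' @param center object center \code{(x, y)} in scene pixels (used only when
#'   composing scenes).
#' @return A list of class \code{"shape_params"}.
#' @export
shape_params <- function(shape_class = c("round", "elongated", "bell"),
                         a, b, n_exp = 2, bell_k = 0, rotation = 0,
                         center = c(NA_real_, NA_real_)) {
  shape_class <- match.arg(shape_class)
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0, a >= b, n_exp >= 1,
            bell_k >= 0, bell_k < 1)
  if (shape_class == "round" && abs(a / b - 1) > 0.05)
    stop("round class requires |a/b - 1| <= 0.05")
  if (shape_class == "bell" && bell_k <= 0)
    stop("bell class requires bell_k > 0")
  rotation <- rotation %% pi
  structure(list(shape_class = shape_class, a = a, b = b, n_exp = n_exp,
                 bell_k = bell_k, rotation = rotation, center = center),
            class = "shape_params")
}

#' Binary fruit mask
#'
#' Container for one fruit silhouette: a logical pixel grid (row-major,
#' origin top-left) plus the physical pixel scale.
#'
#' @param grid logical matrix, \code{TRUE} = foreground.
#' @param mm_per_px physical scale, mm per pixel (\code{> 0}, or \code{NA}
#'   before calibration).
#' @param source_id identifier (scene + object index).
#' @return Object of class \code{"fruit_mask"}.
#' @export
fruit_mask <- function(grid, mm_per_px = NA_real_, source_id = "") {
  stopifnot(is.matrix(grid))
  storage.mode(grid) <- "logical"
  if (!is.na(mm_per_px)) stopifnot(mm_per_px > 0)
  structure(list(grid = grid, mm_per_px = mm_per_px, source_id = source_id),
            class = "fruit_mask")
}

#' @export
print.fruit_mask <- function(x, ...) {
  cat(sprintf("<fruit_mask %s: %d x %d px, %d foreground px, %s mm/px>\n",
              x$source_id, nrow(x$grid), ncol(x$grid), sum(x$grid),
              format(x$mm_per_px)))
  invisible(x)
}

#' Check that a mask satisfies the single-component contract
#'
#' A valid mask has exactly one 8-connected foreground component and no
#' enclosed holes (Euler characteristic 1).
#'
#' @param mask a \code{fruit_mask}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
validate_mask <- function(mask) {
  stopifnot(inherits(mask, "fruit_mask"))
  lab <- label_components(mask$grid, connectivity = 8)
  if (max(lab) != 1L) stop("mask has ", max(lab), " components; expected 1")
  if (euler_characteristic(mask$grid) != 1L)
    stop("mask is not simply connected (Euler characteristic != 1)")
  invisible(TRUE)
}

# Signed membership test for the silhouette family, vectorized over (x, y)
# in mm, object frame (length axis = x). TRUE = inside.
silhouette_inside <- function(params, x, y) {
  a <- params$a; b <- params$b; n <- params$n_exp
  if (params$shape_class == "bell") {
    t <- x / a
    inside <- abs(t) < 1
    w <- numeric(length(x))
    ti <- t[inside]
    w[inside] <- b * (1 - params$bell_k * ti) * (1 - ti^2)^(1 / n)
    inside & abs(y) <= w
  } else {
    (abs(x) / a)^n + (abs(y) / b)^n <= 1
  }
}

#' Rasterize a fruit silhouette into a binary mask
#'
#' @param params a \code{\link{shape_params}} object.
#' @param px_per_mm rasterization scale (pixels per mm, \code{> 0}).
#' @param pad margin of background pixels around the object (default 2).
#' @return A \code{\link{fruit_mask}} with \code{mm_per_px = 1/px_per_mm}.
#'   Errors if the rasterized object covers fewer than 25 pixels.
#' @examples
#' m <- make_fruit_mask(shape_params("round", a = 10, b = 10), px_per_mm = 5)
#' sum(m$grid) / (pi * 50^2)  # close to 1
#' @export
make_fruit_mask <- function(params, px_per_mm, pad = 2L) {
  stopifnot(inherits(params, "shape_params"), px_per_mm > 0)
  # conservative bounding radius in mm (bell half-width can exceed b)
  rmax <- sqrt(params$a^2 + (params$b * (1 + params$bell_k))^2)
  half <- ceiling(rmax * px_per_mm) + pad
  n <- 2L * half + 1L
  ctr <- half + 1L
  # pixel-center coordinates in mm relative to the object center;
  # x = column (right), y = row (down)
  px <- (seq_len(n) - ctr) / px_per_mm
  X <- matrix(px, n, n, byrow = TRUE)
  Y <- matrix(px, n, n)
  th <- params$rotation
  xr <- cos(th) * X + sin(th) * Y
  yr <- -sin(th) * X + cos(th) * Y
  grid <- matrix(silhouette_inside(params, xr, yr), n, n)
  if (sum(grid) < 25L)
    stop("degenerate shape: rasterized object has fewer than 25 pixels")
  # tight crop with pad
  rows <- range(which(rowSums(grid) > 0))
  cols <- range(which(colSums(grid) > 0))
  r0 <- max(1L, rows[1] - pad); r1 <- min(n, rows[2] + pad)
  c0 <- max(1L, cols[1] - pad); c1 <- min(n, cols[2] + pad)
  fruit_mask(grid[r0:r1, c0:c1, drop = FALSE], mm_per_px = 1 / px_per_mm,
             source_id = params$shape_class)
}
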