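# Moment-ellipse eccentricity of a logical grid: sqrt(1 - lambda_min/lambda_max)
# of the second-central-moment matrix, clipped to [0, 1].
moment_eccentricity <- function(grid) {
  idx <- which(grid, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(0)
  S <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  min(max(sqrt(1 - ev[2] / ev[1]), 0), 1)
}

# Chord of the mask through `from` (row, col) at angle theta from the +x
# (column) axis, by dense sampling at `step` px. Returns length in px of the
# run containing the center; if the center is outside the foreground, falls
# back to the longest run (documented fallback for non-convex masks).
chord_length <- function(grid, from, theta, step = 0.35, rmax) {
  s <- seq(-rmax, rmax, by = step)
  rr <- round(from[1] - s * sin(theta))  # rows grow downwards; y-up convention
  cc <- round(from[2] + s * cos(theta))
  ok <- rr >= 1 & rr <= nrow(grid) & cc >= 1 & cc <= ncol(grid)
  inside <- logical(length(s))
  inside[ok] <- grid[cbind(rr[ok], cc[ok])]
  if (!any(inside)) return(0)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- which.min(abs(s))
  hit <- which(r$values & starts <= mid & ends >= mid)
  if (length(hit) == 0L) hit <- which(r$values)[which.max(r$lengths[r$values])]
  (r$lengths[hit] - 1L) * step + 1
}

#' Basic morphometric descriptors of a fruit mask
#'
#' Length and width are the extreme chords through the centroid: chords are
#' measured at \code{n_angles} directions over \eqn{[0, \pi)}; length is the
#' maximum and width the minimum, both in mm. Area is the foreground pixel
#' count times the squared scale. Eccentricity is the second-central-moment
#' (best-fit) ellipse eccentricity, 0 for a circle and approaching 1 for a
#' line segment.
#'
#' @param mask a \code{\link{fruit_mask}} with \code{mm_per_px} set.
#' @param n_angles number of chord directions (default 360).
#' @param method \code{"centroid_chord"} (default, chords through the
#'   centroid) or \code{"feret"} (extremes of directional extents).
#' @return List of class \code{"basic_descriptors"}: \code{length},
#'   \code{width}, \code{lw_ratio}, \code{area}, \code{eccentricity}.
#' @examples
#' m <- make_fruit_mask(shape_params("elongated", a = 10, b = 5), 5)
#' measure_basic(m)
#' @export
measure_basic <- function(mask, n_angles = 360,
                          method = c("centroid_chord", "feret")) {
  stopifnot(inherits(mask, "fruit_mask"), !is.na(mask$mm_per_px))
  method <- match.arg(method)
  g <- mask$grid
  scale <- mask$mm_per_px
  ctr <- mask_centroid(g)
  idx <- which(g, arr.ind = TRUE)
  thetas <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  if (method == "centroid_chord") {
    rmax <- sqrt(max((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)) + 1
    ch <- vapply(thetas, function(th) chord_length(g, ctr, th, rmax = rmax),
                 numeric(1))
  } else {
    x <- idx[, 2]; y <- -idx[, 1]
    ch <- vapply(thetas, function(th) {
      p <- x * cos(th) + y * sin(th)
      diff(range(p)) + 1
    }, numeric(1))
  }
  len <- max(ch) * scale
  wid <- min(ch) * scale
  structure(list(length = len, width = wid, lw_ratio = len / wid,
                 area = nrow(idx) * scale^2,
                 eccentricity = moment_eccentricity(g)),
            class = "basic_descriptors")
}

#' @export
print.basic_descriptors <- function(x, ...) {
  cat(sprintf("length %.2f mm, width %.2f mm, L/W %.3f, area %.2f mm^2, ecc %.3f\n",
              x$length, x$width, x$lw_ratio, x$area, x$eccentricity))
  invisible(x)
}

#' Measure all fruit in a segmented, calibrated scene
#'
#' @param fruit list of calibrated \code{fruit_mask}s.
#' @param scene_id identifier copied to the output.
#' @param ... passed to \code{\link{measure_basic}}.
#' @return Data frame with one row per fruit: \code{scene_id}, \code{fruit_id},
#'   \code{length_mm}, \code{width_mm}, \code{lw_ratio}, \code{area_mm2},
#'   \code{eccentricity}.
#' @export
measure_scene <- function(fruit, scene_id = "scene", ...) {
  rows <- lapply(seq_along(fruit), function(i) {
    d <- measure_basic(fruit[[i]], ...)
    data.frame(scene_id = scene_id, fruit_id = i, length_mm = d$length,
               width_mm = d$width, lw_ratio = d$lw_ratio, area_mm2 = d$area,
               eccentricity = d$eccentricity)
  })
  do.call(rbind, rows)
}
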