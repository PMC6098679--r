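#' Specification of a synthetic fruit scene
#'
#' A scene emulates the photographing protocol: fruit on a light background
#' with size-reference circles of known physical diameter arranged in two
#' horizontal bands (top and bottom).
#'
#' @param fruits list of \code{\link{shape_params}} objects (default protocol:
#'   25 fruit per scene).
#' @param n_ref_circles_per_side reference circles in each band (default 6).
#' @param ref_diameter_mm physical diameter of the reference circles.
#' @param px_per_mm rasterization scale.
#' @param image_size \code{c(H, W)} in pixels, or \code{NULL} to size the
#'   canvas automatically from the objects.
#' @param bg,fg background and foreground intensities in \code{[0, 1]};
#'   the background is lighter by default.
#' @param pixel_noise_sd optional Gaussian pixel noise SD (default 0, which
#'   keeps segmentation exact).
#' @return List of class \code{"scene_spec"}.
#' @export
scene_spec <- function(fruits, n_ref_circles_per_side = 6,
                       ref_diameter_mm = 25.4, px_per_mm = 4,
                       image_size = NULL, bg = 1, fg = 0.15,
                       pixel_noise_sd = 0) {
  stopifnot(is.list(fruits), px_per_mm > 0, ref_diameter_mm > 0,
            n_ref_circles_per_side >= 0, bg != fg)
  structure(list(fruits = fruits,
                 n_ref_circles_per_side = n_ref_circles_per_side,
                 ref_diameter_mm = ref_diameter_mm, px_per_mm = px_per_mm,
                 image_size = image_size, bg = bg, fg = fg,
                 pixel_noise_sd = pixel_noise_sd),
            class = "scene_spec")
}

#' Draw random fruit shape parameters
#'
#' Samples fruit silhouettes from one of the three shape classes, with sizes
#' typical of cranberry fruit (roughly 10--22 mm long).
#'
#' @param n number of fruit.
#' @param class shape class, or \code{"mixed"} to sample classes uniformly.
#' @param length_mm range of fruit length (2a), mm.
#' @param lw range of the length-to-width ratio used to set \code{b}
#'   (forced to \code{[1, 1.05]} for the round class).
#' @param bell_k range of the bell asymmetry coefficient (bell class only).
#' @param n_exp range of the superellipse exponent.
#' @return List of \code{\link{shape_params}}.
#' @export
random_fruits <- function(n, class = "mixed", length_mm = c(12, 20),
                          lw = c(1.2, 1.9), bell_k = c(0.25, 0.5),
                          n_exp = c(1.8, 2.6)) {
  classes <- if (class == "mixed")
    sample(c("round", "elongated", "bell"), n, replace = TRUE) else rep(class, n)
  lapply(seq_len(n), function(i) {
    cl <- classes[i]
    L <- stats::runif(1, length_mm[1], length_mm[2])
    r <- if (cl == "round") stats::runif(1, 1, 1.05) else stats::runif(1, lw[1], lw[2])
    shape_params(cl, a = L / 2, b = L / 2 / r,
                 n_exp = stats::runif(1, n_exp[1], n_exp[2]),
                 bell_k = if (cl == "bell") stats::runif(1, bell_k[1], bell_k[2]) else 0,
                 rotation = stats::runif(1, 0, pi))
  })
}

# stamp a logical object grid onto the image at (row, col) center
stamp <- function(img, grid, center_rc, fg) {
  hr <- nrow(grid); hc <- ncol(grid)
  r0 <- round(center_rc[1] - (hr - 1) / 2); c0 <- round(center_rc[2] - (hc - 1) / 2)
  rr <- r0:(r0 + hr - 1); cc <- c0:(c0 + hc - 1)
  sub <- img[rr, cc]
  sub[grid] <- fg
  img[rr, cc] <- sub
  img
}

#' Compose a synthetic fruit scene
#'
#' Places the reference circles in two horizontal bands (top and bottom) and
#' the fruit in the central region, rejecting placements whose bounding boxes
#' would touch. With a fixed seed the scene is reproducible bit-for-bit.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param seed integer seed controlling placement.
#' @param max_tries placement attempts per fruit before a packing error.
#' @return List of class \code{"scene"} with elements \code{image} (numeric
#'   matrix in \code{[0, 1]}), \code{truth} (data frame of placed objects and
#'   their generating parameters) and \code{spec}.
#' @export
compose_scene <- function(spec, seed = NULL, max_tries = 200L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    ppm <- spec$px_per_mm
    ref_px <- spec$ref_diameter_mm * ppm
    grids <- lapply(spec$fruits, make_fruit_mask, px_per_mm = ppm)
    sizes <- vapply(grids, function(m) c(nrow(m$grid), ncol(m$grid)),
                    numeric(2))
    maxdim <- if (length(grids)) max(sizes) else 0
    band_h <- ceiling(ref_px) + 8L
    if (is.null(spec$image_size)) {
      n <- length(grids)
      ncols <- max(4L, ceiling(sqrt(n * 1.4)))
      nrows <- max(1L, ceiling(n / ncols))
      W <- max(ceiling(ncols * (maxdim + 6)),
               ceiling(2 * spec$n_ref_circles_per_side * (ref_px + 8)), 200L)
      H <- ceiling(nrows * (maxdim + 6)) + 2L * band_h + 16L
    } else { H <- spec$image_size[1]; W <- spec$image_size[2] }
    img <- matrix(spec$bg, H, W)
    truth <- list()
    # reference circles: evenly spaced in top and bottom bands
    nref <- spec$n_ref_circles_per_side
    if (nref > 0) {
      ref_par <- shape_params("round", a = spec$ref_diameter_mm / 2,
                              b = spec$ref_diameter_mm / 2, n_exp = 2)
      ref_grid <- make_fruit_mask(ref_par, ppm)$grid
      xs <- seq(ref_px / 2 + 6, W - ref_px / 2 - 6, length.out = nref)
      for (side in c("top", "bottom")) {
        yc <- if (side == "top") band_h / 2 + 4 else H - band_h / 2 - 4
        for (i in seq_len(nref)) {
          img <- stamp(img, ref_grid, c(yc, xs[i]), spec$fg)
          truth[[length(truth) + 1L]] <- data.frame(
            object_id = sprintf("ref_%s_%d", side, i), type = "reference",
            shape_class = "round", a = spec$ref_diameter_mm / 2,
            b = spec$ref_diameter_mm / 2, n_exp = 2, bell_k = 0, rotation = 0,
            center_row = yc, center_col = xs[i])
        }
      }
    }
    # fruit: rejection-sampled non-overlapping bounding boxes in the middle
    occ <- matrix(FALSE, H, W)  # occupied bounding boxes (with margin)
    top_lim <- if (nref > 0) band_h + 10L else 4L
    bot_lim <- if (nref > 0) H - band_h - 10L else H - 3L
    for (i in seq_along(grids)) {
      g <- grids[[i]]$grid
      hr <- nrow(g); hc <- ncol(g)
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        rc <- c(stats::runif(1, top_lim + hr / 2 + 2, bot_lim - hr / 2 - 2),
                stats::runif(1, hc / 2 + 3, W - hc / 2 - 3))
        r0 <- round(rc[1] - (hr - 1) / 2); c0 <- round(rc[2] - (hc - 1) / 2)
        rr <- max(1, r0 - 2):min(H, r0 + hr + 1)
        cc <- max(1, c0 - 2):min(W, c0 + hc + 1)
        if (!any(occ[rr, cc])) {
          occ[rr, cc] <- TRUE
          img <- stamp(img, g, rc, spec$fg)
          p <- spec$fruits[[i]]
          truth[[length(truth) + 1L]] <- data.frame(
            object_id = sprintf("fruit_%d", i), type = "fruit",
            shape_class = p$shape_class, a = p$a, b = p$b, n_exp = p$n_exp,
            bell_k = p$bell_k, rotation = p$rotation,
            center_row = rc[1], center_col = rc[2])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("packing error: could not place fruit ", i, " after ",
             max_tries, " tries; enlarge image_size")
    }
    if (spec$pixel_noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, spec$pixel_noise_sd), H, W)
      img <- pmin(pmax(img, 0), 1)
    }
    structure(list(image = img,
                   truth = do.call(rbind, truth %||% list(data.frame())),
                   spec = spec),
              class = "scene")
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write a scene image as PNG
#' @param scene a \code{"scene"} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image, path)
  invisible(path)
}

#' Read a scene image from PNG
#' @param path PNG file; RGB images are averaged to grayscale.
#' @return Numeric intensity matrix in \code{[0, 1]}.
#' @export
read_scene_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- apply(x[, , 1:3, drop = FALSE], c(1, 2), mean)
  x
}
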