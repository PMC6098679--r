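#' Segment a scene into fruit masks and reference circles
#'
#' Global thresholding (Otsu by default) followed by 8-connected component
#' labeling. Components smaller than \code{min_area_px} are dropped.
#' Reference circles are recognized by size and circularity: a component is
#' a reference when its area lies within \code{ref_area_band} of the expected
#' reference area \emph{and} its moment-ellipse eccentricity is at most
#' \code{ref_ecc_max}. All remaining components are returned as fruit.
#'
#' @param image numeric intensity matrix in \code{[0, 1]}, background lighter
#'   than the objects (set \code{invert = TRUE} otherwise).
#' @param threshold \code{"otsu"} or a fixed numeric cut; foreground is
#'   intensity below the cut.
#' @param invert logical; invert intensities first.
#' @param min_area_px drop components below this pixel area (default 25).
#' @param max_area_px if finite, components above this area trigger a
#'   touching-objects warning naming the component.
#' @param ref_expected_area_px expected reference-circle area in pixels
#'   (e.g. \code{pi * (d/2 * px_per_mm)^2}); \code{NULL} disables reference
#'   detection (calibration off).
#' @param ref_area_band relative half-width of the reference area band
#'   (default 0.3).
#' @param ref_ecc_max maximum eccentricity of a reference circle (default 0.3).
#' @param scene_id identifier stamped into each mask's \code{source_id}.
#' @return List with elements \code{fruit} and \code{refs}, each a list of
#'   \code{\link{fruit_mask}} (cropped; \code{mm_per_px} unset). Errors if
#'   reference detection was requested and none are found.
#' @export
segment_scene <- function(image, threshold = "otsu", invert = FALSE,
                          min_area_px = 25, max_area_px = Inf,
                          ref_expected_area_px = NULL, ref_area_band = 0.3,
                          ref_ecc_max = 0.3, scene_id = "scene") {
  stopifnot(is.matrix(image))
  if (invert) image <- max(image) - image
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(image), range = range(image)) else threshold
  fg <- image < thr
  if (!any(fg)) {
    if (!is.null(ref_expected_area_px))
      stop("calibration error: no reference circles found")
    return(list(fruit = list(), refs = list()))
  }
  lab <- label_components(fg, connectivity = 8)
  nlab <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas >= min_area_px)
  big <- which(areas > max_area_px)
  if (length(big))
    warning("possible touching objects: component(s) ",
            paste(big, collapse = ", "), " exceed max_area_px")
  fruit <- list(); refs <- list()
  for (k in keep) {
    idx <- which(lab == k, arr.ind = TRUE)
    r <- range(idx[, 1]); cc <- range(idx[, 2])
    g <- lab[r[1]:r[2], cc[1]:cc[2], drop = FALSE] == k
    is_ref <- FALSE
    if (!is.null(ref_expected_area_px)) {
      a <- areas[k]
      if (abs(a - ref_expected_area_px) <= ref_area_band * ref_expected_area_px &&
          moment_eccentricity(g) <= ref_ecc_max)
        is_ref <- TRUE
    }
    m <- fruit_mask(g, mm_per_px = NA_real_,
                    source_id = sprintf("%s_obj%d", scene_id, k))
    if (is_ref) refs[[length(refs) + 1L]] <- m
    else fruit[[length(fruit) + 1L]] <- m
  }
  if (!is.null(ref_expected_area_px) && length(refs) == 0L)
    stop("calibration error: no reference circles found")
  list(fruit = fruit, refs = refs)
}

#' Calibrate the pixel scale from reference circles
#'
#' Each reference's diameter in pixels is taken as the equivalent-area-circle
#' diameter \eqn{2\sqrt{A/\pi}}; the scale is the known physical diameter
#' divided by the mean pixel diameter.
#'
#' @param refs list of reference \code{\link{fruit_mask}}s (at least one).
#' @param known_diameter_mm physical diameter of the reference circles.
#' @param cv_tol maximum allowed coefficient of variation of the pixel
#'   diameters (default 0.05); above it the references are inconsistent.
#' @return List of class \code{"scale_calibration"} with \code{mm_per_px},
#'   \code{n_references_used} and \code{cv}.
#' @export
calibrate_scale <- function(refs, known_diameter_mm, cv_tol = 0.05) {
  stopifnot(length(refs) >= 1L, known_diameter_mm > 0)
  d_px <- vapply(refs, function(m) 2 * sqrt(sum(m$grid) / pi), numeric(1))
  cv <- if (length(d_px) > 1L) stats::sd(d_px) / mean(d_px) else 0
  if (cv > cv_tol)
    stop(sprintf("calibration error: reference diameters inconsistent (cv = %.3f > %.3f)",
                 cv, cv_tol))
  structure(list(mm_per_px = known_diameter_mm / mean(d_px),
                 n_references_used = length(d_px), cv = cv),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("<scale_calibration: %.5f mm/px from %d references (cv %.4f)>\n",
              x$mm_per_px, x$n_references_used, x$cv))
  invisible(x)
}

#' Apply a calibration to segmented masks
#' @param masks list of \code{fruit_mask}.
#' @param calibration a \code{scale_calibration} or numeric mm-per-px.
#' @return The masks with \code{mm_per_px} set.
#' @export
apply_scale <- function(masks, calibration) {
  s <- if (inherits(calibration, "scale_calibration")) calibration$mm_per_px
       else calibration
  lapply(masks, function(m) { m$mm_per_px <- s; m })
}
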