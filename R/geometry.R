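#' Voxel geometry of a 4D laryngeal CT acquisition
#'
#' Describes the anisotropic voxel grid on which all annotations live. The
#' defaults match the standard dynamic laryngeal protocol: axial slices of
#' 512 x 512 pixels at 0.222 mm in-plane spacing and 0.5 mm slice thickness.
#' All package distances are reported in millimetres; conversion from pixel
#' or slice units happens exactly once, through this object.
#'
#' @param pixel_size_x In-plane pixel spacing along x, in mm/pixel.
#' @param pixel_size_y In-plane pixel spacing along y, in mm/pixel.
#' @param slice_thickness Spacing between axial slices, in mm/slice.
#' @param grid_width,grid_height Axial slice dimensions in pixels.
#' @return An object of class `voxel_geometry`.
#' @examples
#' geom <- voxel_geometry()
#' pixels_to_mm(15, geom, axis = "x")  # 3.33 mm
#' @export
voxel_geometry <- function(pixel_size_x = 0.222, pixel_size_y = 0.222,
                           slice_thickness = 0.5,
                           grid_width = 512L, grid_height = 512L) {
  spacings <- c(pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
                slice_thickness = slice_thickness)
  if (!all(vapply(spacings, function(s) is.numeric(s) && length(s) == 1 &&
                    is.finite(s) && s > 0, logical(1)))) {
    abort_validation("All voxel spacings must be single, finite, strictly positive numbers.")
  }
  if (!is_count(grid_width) || !is_count(grid_height)) {
    abort_validation("`grid_width` and `grid_height` must be positive integers.")
  }
  structure(
    list(pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
         slice_thickness = slice_thickness,
         grid_width = as.integer(grid_width),
         grid_height = as.integer(grid_height)),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %d x %d px, %.3f x %.3f x %.3f mm voxels\n",
              x$grid_width, x$grid_height,
              x$pixel_size_x, x$pixel_size_y, x$slice_thickness))
  invisible(x)
}

axis_spacing <- function(geometry, axis) {
  switch(axis,
         x = geometry$pixel_size_x,
         y = geometry$pixel_size_y,
         z = geometry$slice_thickness,
         abort_validation(sprintf("Unknown axis '%s'; must be one of 'x', 'y', 'z'.", axis)))
}

#' Convert pixel (or slice) counts to millimetres
#'
#' Linear conversion through the voxel spacing of the chosen axis: the z axis
#' uses the slice thickness, x and y the in-plane pixel size.
#'
#' @param pixels Numeric vector of pixel (x, y) or slice (z) counts.
#' @param geometry A [voxel_geometry()].
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Lengths in mm, same length as `pixels`.
#' @export
pixels_to_mm <- function(pixels, geometry = voxel_geometry(), axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    abort_validation("`pixels` must be finite numeric.")
  }
  pixels * axis_spacing(geometry, axis)
}

#' @rdname pixels_to_mm
#' @param mm Numeric vector of lengths in millimetres.
#' @export
mm_to_pixels <- function(mm, geometry = voxel_geometry(), axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  stopifnot(inherits(geometry, "voxel_geometry"))
  if (!is.numeric(mm) || any(!is.finite(mm))) {
    abort_validation("`mm` must be finite numeric.")
  }
  mm / axis_spacing(geometry, axis)
}

#' Bounding box around one arytenoid cartilage
#'
#' Boxes use 0-based pixel coordinates with the half-open convention
#' `[min, max)`, so the box width in pixels is exactly `x_max - x_min`.
#'
#' @param x_min,y_min,x_max,y_max Pixel coordinates of the box edges.
#' @param side `"left"` or `"right"` arytenoid.
#' @param geometry A [voxel_geometry()] used to check that the box lies on
#'   the grid.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max, side = c("left", "right"),
                         geometry = voxel_geometry()) {
  side <- match.arg(side)
  vals <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (!all(is.finite(vals))) abort_validation("Box coordinates must be finite.")
  if (x_min >= x_max || y_min >= y_max) {
    abort_validation("Degenerate bounding box: need x_min < x_max and y_min < y_max.")
  }
  if (x_min < 0 || y_min < 0 ||
      x_max > geometry$grid_width || y_max > geometry$grid_height) {
    abort_validation("Bounding box extends beyond the voxel grid.")
  }
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 side = side),
            class = "bounding_box")
}

#' In-plane gap between a left/right box pair, in mm
#'
#' The x-axis distance between the facing edges of the two boxes on one axial
#' slice: `(right.x_min - left.x_max) * pixel_size_x`, clamped at zero when
#' the boxes touch or overlap (contact implies zero distance). Before the gap
#' is taken, the boxes are relabeled so that "left" is the box with the
#' smaller x centroid, making the result robust to the annotation source's
#' left/right convention.
#'
#' @param left,right [bounding_box()] objects on the same slice; must carry
#'   opposite `side` labels.
#' @param geometry A [voxel_geometry()].
#' @return Gap in mm (scalar, never negative).
#' @export
slice_gap <- function(left, right, geometry = voxel_geometry()) {
  stopifnot(inherits(left, "bounding_box"), inherits(right, "bounding_box"))
  if (left$side == right$side) {
    abort_validation("`slice_gap()` needs one left and one right box; got two of the same side.")
  }
  gap_px(left$x_min, left$x_max, right$x_min, right$x_max) * geometry$pixel_size_x
}

# Vectorised core: edge-to-edge x gap in pixels with centroid relabeling and
# clamping at contact.
gap_px <- function(l_min, l_max, r_min, r_max) {
  swap <- (l_min + l_max) / 2 > (r_min + r_max) / 2
  lo_max <- ifelse(swap, r_max, l_max)
  hi_min <- ifelse(swap, l_min, r_min)
  pmax(0, hi_min - lo_max)
}
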