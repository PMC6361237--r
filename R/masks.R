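#' Binary image mask
#'
#' A 2D boolean pixel grid, stored as a logical matrix (rows = y, columns =
#' x, origin at the top-left, 0-based pixel coordinates in all interfaces).
#' An optional physical pixel size (micrometres per pixel) travels with the
#' mask and is used only when converting lengths to physical units.
#'
#' @param grid A logical matrix (or something coercible: numeric matrices are
#'   interpreted as nonzero = TRUE).
#' @param pixel_size Physical pixel size in micrometres per pixel (> 0).
#' @return An object of class `binary_mask`: a logical matrix with a
#'   `pixel_size` attribute.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' mask_fraction(m)
#' @export
binary_mask <- function(grid, pixel_size = 1.0) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (nrow(grid) < 1L || ncol(grid) < 1L) stop("mask dimensions must be positive")
  if (is.numeric(grid)) {
    if (anyNA(grid)) stop("mask values must not be NA")
    grid <- grid != 0
  }
  if (!is.logical(grid)) stop("`grid` must be logical or numeric")
  if (anyNA(grid)) stop("mask values must be strictly boolean (no NA)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(grid, pixel_size = as.numeric(pixel_size), class = c("binary_mask", "matrix", "array"))
}

#' @export
as.matrix.binary_mask <- function(x, ...) {
  matrix(as.logical(x), nrow(x), ncol(x))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g true fraction, pixel size %g um/px\n",
              ncol(x), nrow(x), mean(x), attr(x, "pixel_size")))
  invisible(x)
}

as_mask <- function(x, pixel_size = NULL) {
  if (inherits(x, "binary_mask")) {
    if (!is.null(pixel_size)) attr(x, "pixel_size") <- pixel_size
    return(x)
  }
  binary_mask(x, pixel_size = if (is.null(pixel_size)) 1.0 else pixel_size)
}

#' Fraction of true pixels in a mask
#' @param mask A `binary_mask` or logical matrix.
#' @return Scalar in \[0, 1\].
#' @export
mask_fraction <- function(mask) mean(as_mask(mask))

#' Pixel size attribute of a mask
#' @param mask A `binary_mask`.
#' @return Pixel size in micrometres per pixel (1 if unset).
#' @export
mask_pixel_size <- function(mask) {
  ps <- attr(mask, "pixel_size")
  if (is.null(ps)) 1.0 else ps
}

#' Disk model of a cell of interest (COI)
#'
#' Cells are modelled as pixelated disks of a given diameter. The radius is
#' always exactly `diameter / 2`; a pixel at offset (dx, dy) from the centre
#' belongs to the disk iff dx^2 + dy^2 <= radius^2 (pixel-centre convention).
#' The same rasterization is used everywhere: network dilation, placement,
#' packing and the overlap oracle, so that "centre inside the dilated
#' network" is exactly equivalent to "disk overlaps the network".
#'
#' @param diameter Cell diameter in pixels (>= 1, need not be an integer).
#' @return An object of class `cell_model` with fields `diameter`, `radius`.
#' @examples
#' cell_model(10)
#' @export
cell_model <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter))
    stop("`diameter` must be a single finite number")
  if (diameter < 1) stop("`diameter` must be >= 1 pixel")
  structure(list(diameter = as.numeric(diameter), radius = as.numeric(diameter) / 2),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> diameter %g px (radius %g px)\n", x$diameter, x$radius))
  invisible(x)
}

as_cell <- function(x) {
  if (inherits(x, "cell_model")) x else cell_model(x)
}

#' Cell-dilated network fraction (CDNF) value
#'
#' The CDNF is the fraction of image pixels at which a cell centre yields at
#' least one pixel of overlap with the network; equivalently the true-pixel
#' fraction of the network mask dilated by the cell radius. It is the exact
#' success probability of the binomial model of random placement.
#'
#' @param dilated_pixels Count of true pixels in the dilated network mask.
#' @param total_pixels Total pixel count of the contributing image(s).
#' @return An object of class `cdnf_value` with fields `p`, `dilated_pixels`,
#'   `total_pixels`.
#' @export
cdnf_value <- function(dilated_pixels, total_pixels) {
  dilated_pixels <- as.numeric(dilated_pixels)
  total_pixels <- as.numeric(total_pixels)
  if (length(dilated_pixels) != 1L || length(total_pixels) != 1L ||
      is.na(dilated_pixels) || is.na(total_pixels))
    stop("pixel counts must be single numbers")
  if (total_pixels < 1 || dilated_pixels < 0 || dilated_pixels > total_pixels)
    stop("require 0 <= dilated_pixels <= total_pixels, total_pixels >= 1")
  structure(list(p = dilated_pixels / total_pixels,
                 dilated_pixels = dilated_pixels,
                 total_pixels = total_pixels),
            class = "cdnf_value")
}

#' @export
print.cdnf_value <- function(x, ...) {
  cat(sprintf("<cdnf_value> p = %.6g (%g / %g px)\n",
              x$p, x$dilated_pixels, x$total_pixels))
  invisible(x)
}

as_cdnf <- function(x) {
  if (inherits(x, "cdnf_value")) return(x)
  if (is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1) {
    # bare probability: represent on a unit denominator
    return(structure(list(p = as.numeric(x), dilated_pixels = as.numeric(x),
                          total_pixels = 1), class = "cdnf_value"))
  }
  stop("expected a cdnf_value or a probability in [0, 1]")
}

#' Per-image colocalization observation
#'
#' @param n Total number of cells in the image (integer >= 0).
#' @param c Number of cells colocalizing with the network (0 <= c <= n).
#' @return An object of class `coloc_observation` with fields `n`, `c`.
#' @export
coloc_observation <- function(n, c) {
  n <- as.integer(n); c <- as.integer(c)
  if (length(n) != 1L || length(c) != 1L || is.na(n) || is.na(c))
    stop("`n` and `c` must be single integers")
  if (n < 0L || c < 0L || c > n) stop("require 0 <= c <= n")
  structure(list(n = n, c = c), class = "coloc_observation")
}

#' @export
print.coloc_observation <- function(x, ...) {
  cat(sprintf("<coloc_observation> %d / %d cells colocalized\n", x$c, x$n))
  invisible(x)
}

# run `expr` under a temporary seed if one is given, without disturbing the
# caller's RNG state; seed = NULL leaves the current RNG stream in charge
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
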