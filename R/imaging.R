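#' Segment an intensity image with a global threshold
#'
#' Pixels with intensity greater than or equal to the threshold become true.
#' The threshold is user-supplied (no automatic selection), mirroring an
#' adjustable global threshold in interactive use.
#'
#' @param image A 2D numeric matrix of intensities (single channel). For a
#'   multi-channel array, select a channel first (see [read_mask_png()]).
#' @param threshold Intensity cutoff; must lie within `range`.
#' @param pixel_size Micrometres per pixel to attach to the result.
#' @param range Representable intensity range of the image format, used only
#'   to validate the threshold. Defaults to the span of 0, 1 and the observed
#'   intensities (so unit-scaled and integer-scaled images both validate).
#' @return A `binary_mask` of identical dimensions.
#' @examples
#' img <- matrix(0:8, 3, 3)
#' sum(segment_global_threshold(img, 5))  # 4 pixels >= 5
#' @export
segment_global_threshold <- function(image, threshold, pixel_size = 1.0,
                                     range = NULL) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a single-channel 2D numeric matrix; ",
         "for RGB arrays select one channel, e.g. image[, , 1]")
  if (anyNA(image)) stop("`image` must not contain NA")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("`threshold` must be a single finite number")
  if (is.null(range)) range <- c(min(0, image), max(1, image))
  if (threshold < range[1] || threshold > range[2])
    stop(sprintf("threshold %g outside the representable intensity range [%g, %g]",
                 threshold, range[1], range[2]))
  binary_mask(image >= threshold, pixel_size = pixel_size)
}

# integer (drow, dcol) offsets of the pixelated disk of a given radius;
# the single shared rasterization rule of the whole package
disk_offsets <- function(radius) {
  if (radius < 0.5) stop("`radius` must be >= 0.5 (sub-pixel cell)")
  f <- floor(radius)
  d <- expand.grid(dr = -f:f, dc = -f:f)
  keep <- d$dr^2 + d$dc^2 <= radius^2
  as.matrix(d[keep, , drop = FALSE])
}

#' Pixelated disk structuring element
#'
#' Rasterizes a disk of the given radius on the pixel grid: the element is a
#' square, odd-sided mask whose pixel at offset (dx, dy) from the centre is
#' true iff dx^2 + dy^2 <= radius^2.
#'
#' @param radius Disk radius in pixels (>= 0.5).
#' @return A `binary_mask` of side `2 * floor(radius) + 1`.
#' @examples
#' sum(disk_element(2))  # 13 pixels
#' @export
disk_element <- function(radius) {
  off <- disk_offsets(radius)
  f <- floor(radius)
  side <- 2L * as.integer(f) + 1L
  m <- matrix(FALSE, side, side)
  m[cbind(off[, 1] + f + 1, off[, 2] + f + 1)] <- TRUE
  binary_mask(m)
}

#' Dilate a network mask by the cell radius
#'
#' Morphological binary dilation of the segmented network by the pixelated
#' disk of the cell's radius, evaluated within the image bounds only (the
#' image is not padded; network outside the field of view is unknowable).
#' The result is the colocalization acceptance region: a cell centred on any
#' true pixel overlaps the network by at least one pixel.
#'
#' @param network A `binary_mask` (or logical matrix) of the network channel.
#' @param cell A `cell_model` (or bare diameter in pixels).
#' @return A `binary_mask` containing the input network.
#' @export
dilate_network <- function(network, cell) {
  network <- as_mask(network)
  cell <- as_cell(cell)
  out <- cpp_dilate(network, disk_offsets(cell$radius))
  binary_mask(out, pixel_size = mask_pixel_size(network))
}

#' Cell-dilated network fraction of an image
#'
#' @inheritParams dilate_network
#' @return A [cdnf_value()]: p = true pixels of the dilated network divided
#'   by the image area.
#' @examples
#' net <- matrix(FALSE, 9, 9); net[5, 5] <- TRUE
#' compute_cdnf(net, cell_model(4))$dilated_pixels  # 13
#' @export
compute_cdnf <- function(network, cell) {
  network <- as_mask(network)
  dil <- dilate_network(network, cell)
  cdnf_value(sum(dil), length(dil))
}

#' Pool CDNF values across images
#'
#' The combined CDNF of a set of images is the area-weighted ratio: summed
#' dilated pixels over summed image areas. For equal-sized images this is
#' the plain mean of the per-image fractions. Pooling a dilate-then-split
#' partition of one image reproduces the whole-image CDNF exactly.
#'
#' @param values A non-empty list of [cdnf_value()] objects.
#' @return A pooled [cdnf_value()].
#' @export
pool_cdnf <- function(values) {
  if (!is.list(values) || length(values) == 0L)
    stop("`values` must be a non-empty list of cdnf_value objects")
  values <- lapply(values, as_cdnf)
  cdnf_value(sum(vapply(values, function(v) v$dilated_pixels, 0)),
             sum(vapply(values, function(v) v$total_pixels, 0)))
}

#' Count cells colocalizing with the (dilated) network
#'
#' A cell colocalizes iff its centre pixel is true in the dilated network
#' mask — exactly equivalent to its pixelated disk sharing at least one
#' pixel with the raw network.
#'
#' @param centers An n x 2 matrix (or data.frame) of 0-based pixel
#'   coordinates, columns `x` (column index) and `y` (row index).
#' @param dilated The dilated network `binary_mask` (see [dilate_network()]).
#' @return A [coloc_observation()] with `n = nrow(centers)`.
#' @export
count_colocalized <- function(centers, dilated) {
  dilated <- as_mask(dilated)
  centers <- as_centers(centers, nrow(dilated), ncol(dilated))
  if (nrow(centers) == 0L) return(coloc_observation(0L, 0L))
  hits <- dilated[cbind(centers[, "y"] + 1L, centers[, "x"] + 1L)]
  coloc_observation(nrow(centers), sum(hits))
}

# validate/normalize a centre table to an integer matrix with columns x, y
as_centers <- function(centers, h, w) {
  if (is.null(centers) || (is.matrix(centers) && nrow(centers) == 0L) ||
      (is.data.frame(centers) && nrow(centers) == 0L)) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  }
  if (is.data.frame(centers)) centers <- as.matrix(centers[, c("x", "y")])
  if (!is.matrix(centers) || ncol(centers) < 2L)
    stop("`centers` must be a matrix/data.frame with columns x, y")
  if (is.null(colnames(centers))) colnames(centers) <- c("x", "y")
  m <- cbind(x = as.integer(round(centers[, "x"])),
             y = as.integer(round(centers[, "y"])))
  bad <- which(m[, "x"] < 0L | m[, "x"] >= w | m[, "y"] < 0L | m[, "y"] >= h)
  if (length(bad) > 0L)
    stop(sprintf("center %d at (%d, %d) is outside the %d x %d image",
                 bad[1], m[bad[1], "x"], m[bad[1], "y"], w, h))
  m
}

#' Effective disk model from measured cell areas
#'
#' Represents a heterogeneous cell population as a single disk whose area
#' equals the mean measured cell area: diameter = 2 * sqrt(mean(area) / pi).
#' This is the mitigation used when connected-component quantification
#' merges overlapping cells into larger objects.
#'
#' @param areas Positive cell pixel areas (non-empty numeric vector).
#' @return A [cell_model()].
#' @examples
#' effective_cell_model(pi * 25)$diameter  # 10
#' @export
effective_cell_model <- function(areas) {
  if (length(areas) == 0L) stop("`areas` must be non-empty")
  if (!is.numeric(areas) || any(!is.finite(areas)) || any(areas <= 0))
    stop("all areas must be positive finite numbers")
  cell_model(2 * sqrt(mean(areas) / pi))
}

#' Quantify a cell mask by connected components
#'
#' Counts 8-connected components of a binary cell mask, the failure-prone
#' quantification in which any overlap (even diagonal touching) merges cells
#' into a single counted object.
#'
#' @param cell_mask A `binary_mask` or logical matrix of the cell channel.
#' @return A list with `count`, `mean_area` (NA when count is 0), and
#'   `labels` (integer matrix, 0 = background).
#' @export
quantify_connected_components <- function(cell_mask) {
  cell_mask <- as_mask(cell_mask)
  labels <- cpp_label_components(cell_mask)
  count <- max(labels)
  list(count = count,
       mean_area = if (count == 0L) NA_real_ else sum(cell_mask) / count,
       labels = labels)
}
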