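#' Read a grayscale or RGB PNG as an intensity matrix
#'
#' Requires the `png` package. RGB images need an explicit channel.
#'
#' @param path PNG file path.
#' @param channel For RGB input: `"R"`, `"G"` or `"B"`.
#' @param pixel_size Micrometres per pixel recorded on the result.
#' @return A numeric intensity matrix in \[0, 1\] with attribute
#'   `pixel_size`.
#' @export
read_image_png <- function(path, channel = NULL, pixel_size = 1.0) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required to read PNG files")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (is.null(channel))
      stop("multi-channel image: pass channel = \"R\", \"G\" or \"B\"")
    ch <- match(toupper(channel), c("R", "G", "B"))
    if (is.na(ch) || ch > dim(img)[3]) stop("invalid channel selection")
    img <- img[, , ch]
  }
  attr(img, "pixel_size") <- pixel_size
  img
}

#' Read a binary mask from PNG
#'
#' @inheritParams read_image_png
#' @param threshold Intensity at or above which a pixel is true (default
#'   0.5: masks written by [write_mask_png()] use 0/1).
#' @return A `binary_mask`.
#' @export
read_mask_png <- function(path, channel = NULL, threshold = 0.5,
                          pixel_size = 1.0) {
  img <- read_image_png(path, channel, pixel_size)
  segment_global_threshold(img, threshold, pixel_size = pixel_size)
}

#' Write a binary mask as an 8-bit grayscale PNG (0/255)
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required to write PNG files")
  png::writePNG(matrix(as.numeric(as_mask(mask)), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read/write a binary mask as plain-text PGM/PBM (P1)
#'
#' Portable bitmap text format: line 1 `P1`, line 2 `width height`, then 0/1
#' pixels. A plain-text alternative to PNG for fixtures and interchange; no
#' installed package reads P1, so a minimal reader lives here.
#'
#' @param path File path.
#' @param pixel_size Micrometres per pixel recorded on the result.
#' @return `read_mask_pbm()`: a `binary_mask`; `write_mask_pbm()`: the path.
#' @export
read_mask_pbm <- function(path, pixel_size = 1.0) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P1") stop("not a plain-text PBM (P1) file")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  if (length(vals) != dims[1] * dims[2]) stop("pixel count does not match header")
  binary_mask(matrix(vals == 1L, nrow = dims[2], ncol = dims[1], byrow = TRUE),
              pixel_size = pixel_size)
}

#' @rdname read_mask_pbm
#' @param mask A `binary_mask` or logical matrix.
#' @export
write_mask_pbm <- function(mask, path) {
  mask <- as_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P1", paste(ncol(mask), nrow(mask))), con)
  apply(mask, 1, function(row)
    writeLines(paste(as.integer(row), collapse = " "), con))
  invisible(path)
}

#' Read a cell-centroid table
#'
#' CSV with header `x,y`: 0-based pixel coordinates (x = column, y = row).
#'
#' @param path CSV file path.
#' @return A data.frame with integer columns `x`, `y`.
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("centroid CSV must have header columns `x,y`")
  df[, c("x", "y")]
}

#' Read a cell-area table
#'
#' CSV with header `area_px`: measured per-cell pixel areas, the input to
#' [effective_cell_model()].
#'
#' @param path CSV file path.
#' @return A numeric vector of areas.
#' @export
read_cell_areas_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"area_px" %in% names(df))
    stop("cell-area CSV must have a header column `area_px`")
  as.numeric(df$area_px)
}

#' Read a study manifest
#'
#' CSV with header `group,replicate,image_path,cells_path_or_count,threshold`
#' describing a replicate-per-row layout of network images and their cell
#' inputs (a centroid CSV path or a bare cell count).
#'
#' @param path Manifest CSV path.
#' @return The manifest data.frame, with paths resolved relative to the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("group", "replicate", "image_path", "cells_path_or_count", "threshold")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(file.path(base, p)),
                                file.path(base, p), p)
  df$image_path <- resolve(df$image_path)
  numeric_cells <- suppressWarnings(!is.na(as.numeric(df$cells_path_or_count)))
  df$cells_path_or_count[!numeric_cells] <-
    resolve(df$cells_path_or_count[!numeric_cells])
  df$threshold <- as.numeric(df$threshold)
  df
}

#' Serialize a per-image result record to JSON
#'
#' @param obs A [coloc_observation()].
#' @param cdnf A [cdnf_value()].
#' @param p The image's CIRCOAST p-value.
#' @param path Optional output path; if NULL the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_image_record <- function(obs, cdnf, p, path = NULL) {
  rec <- list(n = obs$n, c = obs$c, cdnf = cdnf$p,
              dilated_pixels = cdnf$dilated_pixels,
              total_pixels = cdnf$total_pixels,
              circoast_p = p, model = "BMRP")
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
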