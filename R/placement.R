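#' Uniform random placement of cell centres
#'
#' The Monte Carlo random-placement paradigm: every pixel site of the image
#' has an equal chance of receiving a cell centre, placements are
#' independent, overlap is allowed and centres may fall anywhere in the
#' image (including within a cell radius of the border).
#'
#' @param n Number of cells (>= 0).
#' @param width,height Image dimensions in pixels.
#' @param seed Optional integer seed.
#' @return An n x 2 integer matrix of 0-based coordinates, columns `x`, `y`.
#' @export
place_cells_uniform <- function(n, width, height, seed = NULL) {
  if (n < 0) stop("`n` must be >= 0")
  if (n == 0) return(cbind(x = integer(0), y = integer(0)))
  with_opt_seed(seed, {
    cbind(x = sample.int(width, n, replace = TRUE) - 1L,
          y = sample.int(height, n, replace = TRUE) - 1L)
  })
}

#' Empirical ICF distribution under random placement (MCMRP)
#'
#' For each Monte Carlo trial, `n` cell centres are placed uniformly in the
#' image and the intercellular colocalization fraction ICF = c / n is
#' recorded, where c counts centres falling inside the cell-dilated network.
#' The colocalized count per trial is exactly Binomial(n, CDNF) by
#' construction, so the sample mean converges to the CDNF.
#'
#' @param network A `binary_mask` of the (undilated) network.
#' @param cell A `cell_model` or bare diameter.
#' @param n Cells per trial (>= 1).
#' @param trials Number of Monte Carlo trials (>= 1).
#' @param seed Optional integer seed.
#' @return An object of class `icf_distribution`: list with `samples`,
#'   `trials`, `n`, `mean`, `sd`, and the image `cdnf`.
#' @export
mcmrp_distribution <- function(network, cell, n, trials, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  if (trials < 1) stop("`trials` must be >= 1")
  network <- as_mask(network)
  dil <- dilate_network(network, cell)
  icf_from_dilated(dil, n, trials, seed, cdnf = cdnf_value(sum(dil), length(dil)))
}

# shared core: sample ICFs against a precomputed dilated mask
icf_from_dilated <- function(dilated, n, trials, seed = NULL, cdnf = NULL) {
  hits <- with_opt_seed(seed, {
    idx <- sample.int(length(dilated), n * trials, replace = TRUE)
    matrix(dilated[idx], nrow = n, ncol = trials)
  })
  samples <- colMeans(hits)
  structure(list(samples = samples, trials = as.integer(trials), n = as.integer(n),
                 mean = mean(samples), sd = stats::sd(samples), cdnf = cdnf),
            class = "icf_distribution")
}

#' @export
print.icf_distribution <- function(x, ...) {
  cat(sprintf("<icf_distribution> %d trials of n = %d: mean ICF %.5f (sd %.5f)\n",
              x$trials, x$n, x$mean, x$sd))
  invisible(x)
}

# centre offsets at which two equal pixelated disks share >= 1 pixel:
# the Minkowski sum of the disk's offset set with itself (symmetric)
forbidden_offsets <- function(radius) {
  off <- disk_offsets(radius)
  f <- floor(radius)
  side <- 4L * as.integer(f) + 1L
  acc <- matrix(FALSE, side, side)
  ctr <- 2L * as.integer(f) + 1L
  base <- matrix(FALSE, side, side)
  base[cbind(off[, 1] + ctr, off[, 2] + ctr)] <- TRUE
  for (t in seq_len(nrow(off))) {
    dr <- off[t, 1]; dc <- off[t, 2]
    rows <- (1L + max(0L, dr)):(side + min(0L, dr))
    cols <- (1L + max(0L, dc)):(side + min(0L, dc))
    acc[rows, cols] <- acc[rows, cols] | base[rows - dr, cols - dc]
  }
  w <- which(acc, arr.ind = TRUE)
  cbind(dr = w[, 1] - ctr, dc = w[, 2] - ctr)
}

#' Sequential random placement of non-overlapping cells
#'
#' Cells are placed one at a time at centres drawn uniformly from the sites
#' still admissible: the pixelated disk must be fully contained in the image
#' and share no pixel with any previously placed disk. This is
#' distributionally identical to rejection sampling over all pixels. If
#' fewer than `n` cells fit, the partial result is returned with a
#' saturation flag.
#'
#' @param n Requested number of cells (>= 1).
#' @param cell A `cell_model` or bare diameter.
#' @param width,height Image dimensions in pixels.
#' @param seed Optional integer seed.
#' @return An m x 2 matrix of centres (m <= n), columns `x`, `y`, with
#'   attribute `saturated` (TRUE iff no admissible centre remained).
#' @export
place_cells_nonoverlapping <- function(n, cell, width, height, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  cell <- as_cell(cell)
  res <- with_opt_seed(seed,
    cpp_place_nonoverlap(height, width, as.integer(floor(cell$radius)),
                         forbidden_offsets(cell$radius), as.integer(n)))
  ctr <- res$centers
  out <- cbind(x = ctr[, 2], y = ctr[, 1])
  attr(out, "saturated") <- res$saturated
  out
}

#' Monte Carlo packing ratio of randomly placed disks
#'
#' Places fully contained, non-overlapping pixelated disks at uniformly
#' random admissible centres until none fits (saturation is detected exactly
#' from the emptied free-position set), then reports the fraction of image
#' area covered by the placed disks. Random sequential packing stays well
#' below the hexagonal-packing bound of 0.901 and varies with both cell
#' diameter and image size.
#'
#' @param cell A `cell_model` or bare diameter; diameter must be >= 5 pixels
#'   (below that, distinct cells cannot be discerned at high density).
#' @param width,height Image dimensions in pixels.
#' @param seed Optional integer seed.
#' @return The packing ratio (scalar), with attribute `n_placed`.
#' @export
saturate_packing <- function(cell, width, height, seed = NULL) {
  cell <- as_cell(cell)
  if (cell$diameter < 5)
    stop("cell diameter < 5 px: resolution too low for distinct cells")
  res <- with_opt_seed(seed,
    cpp_place_nonoverlap(height, width, as.integer(floor(cell$radius)),
                         forbidden_offsets(cell$radius), -1L))
  if (!res$saturated) stop("internal error: saturation loop exited early")
  disk_area <- nrow(disk_offsets(cell$radius))
  eta <- nrow(res$centers) * disk_area / (width * height)
  attr(eta, "n_placed") <- nrow(res$centers)
  eta
}

#' Build a Monte Carlo packing-ratio lookup table
#'
#' Estimates the saturation packing ratio for every combination of cell
#' diameter and image size over independent seeded repetitions. The table
#' feeds the hypergeometric model's maximum-population parameter.
#'
#' @param diameters Integer cell diameters in pixels (all >= 5).
#' @param widths,heights Image dimensions; recycled pairwise against each
#'   other (use equal lengths for a list of sizes).
#' @param trials Repetitions per key (>= 1).
#' @param seed Optional integer seed for the whole table.
#' @return A data.frame of class `packing_table` with columns `diameter`,
#'   `width`, `height`, `eta`, `sd`, `trials`; the seed is attached as
#'   attribute `seed`.
#' @export
build_packing_table <- function(diameters, widths = 512, heights = widths,
                                trials = 50, seed = NULL) {
  if (any(diameters < 5)) stop("all diameters must be >= 5 pixels")
  sizes <- data.frame(width = widths, height = heights)
  grid <- merge(data.frame(diameter = as.integer(diameters)), sizes)
  run <- function() {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      etas <- vapply(seq_len(trials), function(t)
        as.numeric(saturate_packing(cell_model(grid$diameter[i]),
                                    grid$width[i], grid$height[i])), 0)
      data.frame(diameter = grid$diameter[i], width = grid$width[i],
                 height = grid$height[i], eta = mean(etas),
                 sd = stats::sd(etas), trials = as.integer(trials))
    })
    do.call(rbind, rows)
  }
  tab <- with_opt_seed(seed, run())
  attr(tab, "seed") <- seed
  class(tab) <- c("packing_table", "data.frame")
  tab
}

#' Look up a packing ratio
#'
#' Keys are exact (rounded diameter, width, height); absent keys are an
#' error unless `interpolate = TRUE`, in which case linear interpolation in
#' diameter (within the same image size) is used.
#'
#' @param table A [build_packing_table()] result.
#' @param diameter Cell diameter in pixels (rounded to the nearest integer
#'   key).
#' @param width,height Image dimensions.
#' @param interpolate Allow linear interpolation across diameters.
#' @return The packing ratio eta (scalar).
#' @export
packing_lookup <- function(table, diameter, width, height, interpolate = FALSE) {
  d <- round_half_up(diameter)
  hit <- table$diameter == d & table$width == width & table$height == height
  if (any(hit)) return(table$eta[which(hit)[1]])
  if (!interpolate)
    stop(sprintf("no packing entry for diameter %d at %d x %d (set interpolate = TRUE)",
                 d, width, height))
  sub <- table[table$width == width & table$height == height, ]
  if (nrow(sub) < 2L || d < min(sub$diameter) || d > max(sub$diameter))
    stop("cannot interpolate: need bracketing diameters at this image size")
  stats::approx(sub$diameter, sub$eta, xout = d)$y
}

#' Clumped cell placement
#'
#' Places clump anchors uniformly over the image and the remaining clump
#' members adjacent to their anchor: for non-overlapping clumps, members sit
#' on the touching ring (the nearest centre offsets at which two pixelated
#' disks are disjoint, typically one pixel beyond the cell diameter) and
#' must not overlap any cell already placed; for overlapping clumps, members
#' are jittered uniformly within one radius of the anchor. Member positions
#' wrap toroidally at the image border, which keeps every cell's marginal
#' position distribution exactly uniform — the property under which clumped
#' placement has the same mean ICF as independent placement.
#'
#' @param n_clumps Number of clumps (>= 1).
#' @param clump_size Cells per clump (>= 1); `clump_size = 1` with overlap
#'   allowed reduces to uniform placement.
#' @param overlap_allowed Logical: may member disks overlap?
#' @param cell A `cell_model` or bare diameter.
#' @param width,height Image dimensions.
#' @param seed Optional integer seed.
#' @return An m x 2 matrix of centres (m <= n_clumps * clump_size), columns
#'   `x`, `y`, with attribute `saturated` set if a non-overlapping member
#'   could not be placed after exhausting the ring.
#' @export
place_clumps <- function(n_clumps, clump_size, overlap_allowed, cell,
                         width, height, seed = NULL) {
  if (n_clumps < 1 || clump_size < 1) stop("`n_clumps` and `clump_size` must be >= 1")
  cell <- as_cell(cell)
  forb <- forbidden_offsets(cell$radius)
  ring <- touching_ring(forb)
  run <- function() {
    anchors <- place_cells_uniform(n_clumps, width, height)
    xs <- integer(0); ys <- integer(0)
    saturated <- FALSE
    for (k in seq_len(n_clumps)) {
      cx <- anchors[k, "x"]; cy <- anchors[k, "y"]
      xs <- c(xs, cx); ys <- c(ys, cy)
      members <- clump_size - 1L
      if (members == 0L) next
      if (overlap_allowed) {
        off <- disk_offsets(cell$radius)
        pick <- off[sample.int(nrow(off), members, replace = TRUE), , drop = FALSE]
        xs <- c(xs, (cx + pick[, "dc"]) %% width)
        ys <- c(ys, (cy + pick[, "dr"]) %% height)
      } else {
        for (m in seq_len(members)) {
          cand <- ring[sample.int(nrow(ring)), , drop = FALSE]
          placed <- FALSE
          for (t in seq_len(nrow(cand))) {
            px <- (cx + cand[t, "dc"]) %% width
            py <- (cy + cand[t, "dr"]) %% height
            if (length(xs) > 0L) {
              # toroidal centre offsets against all placed cells
              ddx <- wrap_delta(px - xs, width)
              ddy <- wrap_delta(py - ys, height)
              clash <- overlaps_any(ddy, ddx, forb)
            } else clash <- FALSE
            if (!clash) {
              xs <- c(xs, px); ys <- c(ys, py)
              placed <- TRUE
              break
            }
          }
          if (!placed) saturated <- TRUE
        }
      }
    }
    out <- cbind(x = as.integer(xs), y = as.integer(ys))
    attr(out, "saturated") <- saturated
    out
  }
  with_opt_seed(seed, run())
}

# offsets just outside the forbidden (overlap) set: disjoint but touching
touching_ring <- function(forb) {
  f <- max(abs(forb))
  side <- 2L * (f + 1L) + 1L
  ctr <- f + 2L
  m <- matrix(FALSE, side, side)
  m[cbind(forb[, "dr"] + ctr, forb[, "dc"] + ctr)] <- TRUE
  dil <- cpp_dilate(m, cbind(dr = c(-1L, 0L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                             dc = c(0L, -1L, 0L, 1L, 0L, -1L, 1L, -1L, 1L)))
  w <- which(dil & !m, arr.ind = TRUE)
  cbind(dr = w[, 1] - ctr, dc = w[, 2] - ctr)
}

# signed minimal toroidal difference
wrap_delta <- function(d, size) {
  d <- d %% size
  ifelse(d > size / 2, d - size, d)
}

overlaps_any <- function(ddy, ddx, forb) {
  key <- paste(ddy, ddx)
  any(key %in% paste(forb[, "dr"], forb[, "dc"]))
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)
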