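#' Sample a random point cloud with an enforced minimum distance
#'
#' Dart-throwing (sequential rejection) sampling of integer pixel sites:
#' uniform proposals are accepted while they lie at Euclidean distance >=
#' `min_dist` from every accepted point, and sampling stops once a budget of
#' consecutive rejections is exhausted (near-saturation of the domain).
#'
#' @param width,height Image dimensions in pixels.
#' @param min_dist Minimum pairwise distance between points (>= 2 px, less
#'   than the smaller image side).
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @param max_failures Consecutive rejected proposals after which the domain
#'   is declared saturated.
#' @return An m x 2 integer matrix of 0-based pixel coordinates, columns
#'   `x`, `y`. Errors if fewer than 4 points fit (no network derivable).
#' @export
sample_min_distance_points <- function(width, height, min_dist, seed = NULL,
                                       max_failures = 200L) {
  if (min_dist < 2) stop("`min_dist` must be >= 2 pixels")
  if (min_dist >= min(width, height))
    stop("`min_dist` must be smaller than the smaller image side")
  with_opt_seed(seed, {
    cap <- ceiling(4 * width * height / min_dist^2) + 16L
    xs <- integer(cap); ys <- integer(cap)
    m <- 0L; fails <- 0L
    d2 <- min_dist^2
    while (fails < max_failures) {
      px <- sample.int(width, 1L) - 1L
      py <- sample.int(height, 1L) - 1L
      ok <- m == 0L ||
        all((xs[seq_len(m)] - px)^2 + (ys[seq_len(m)] - py)^2 >= d2)
      if (ok) {
        m <- m + 1L
        xs[m] <- px; ys[m] <- py
        fails <- 0L
      } else fails <- fails + 1L
    }
    if (m < 4L)
      stop(sprintf("only %d point(s) fit at min_dist = %g; no network derivable",
                   m, min_dist))
    cbind(x = xs[seq_len(m)], y = ys[seq_len(m)])
  })
}

#' Watershed bisection skeleton of a point cloud
#'
#' The ridge lines of the watershed of the distance-to-nearest-seed
#' transform, i.e. the pixelated Voronoi boundaries of the point set: every
#' pair of adjacent Voronoi regions is bisected by a line of skeleton
#' pixels. Labels use exact integer squared distances with ties broken
#' toward the lowest seed index; a boundary pixel is one whose nearest-seed
#' label differs from its right or lower 4-neighbour, and the marked set is
#' thinned (topology-preserving) to a strictly 1-pixel-wide skeleton, since
#' diagonal boundaries otherwise mark two pixels per step. Seed pixels
#' themselves are never part of the skeleton.
#'
#' @param points An m x 2 matrix of 0-based seed coordinates (columns x, y),
#'   m >= 4.
#' @param width,height Image dimensions in pixels.
#' @return A `binary_mask` with the 1-pixel-wide skeleton.
#' @export
bisecting_skeleton <- function(points, width, height) {
  if (nrow(points) < 4L) stop("need at least 4 points")
  labels <- cpp_nearest_labels(height, width,
                               cbind(as.integer(points[, "y"]),
                                     as.integer(points[, "x"])))
  ridge <- matrix(FALSE, height, width)
  ridge[, -width] <- labels[, -width, drop = FALSE] != labels[, -1, drop = FALSE]
  ridge[-height, ] <- ridge[-height, , drop = FALSE] |
    (labels[-height, , drop = FALSE] != labels[-1, , drop = FALSE])
  ridge <- cpp_thin(ridge)
  ridge[cbind(points[, "y"] + 1L, points[, "x"] + 1L)] <- FALSE
  binary_mask(ridge)
}

# Decompose a 1-px skeleton into removable segments. Junction pixels (more
# than two 8-neighbours) are shared: a junction pixel survives while any
# incident segment survives. Returns a list with per-pixel segment ids and
# the junction incidence structure used by prune_segments().
skeleton_segments <- function(skeleton) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  idx <- which(skeleton)
  if (length(idx) == 0L)
    return(list(n_segments = 0L, seg_pixels = list(), junctions = integer(0),
                junction_segs = list(), dim = c(h, w)))
  # 8-neighbour degree of every skeleton pixel
  deg <- matrix(0L, h, w)
  sk <- matrix(FALSE, h + 2L, w + 2L)
  sk[2:(h + 1L), 2:(w + 1L)] <- skeleton
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    deg <- deg + sk[(2:(h + 1L)) + di, (2:(w + 1L)) + dj]
  }
  junction <- skeleton & deg > 2L
  body <- skeleton & !junction
  lab <- cpp_label_components(body)
  n_seg <- max(lab)
  seg_pixels <- split(which(lab > 0L), lab[lab > 0L])
  # incidence: segments 8-adjacent to each junction pixel
  jidx <- which(junction)
  junction_segs <- vector("list", length(jidx))
  if (length(jidx) > 0L) {
    ji <- ((jidx - 1L) %% h) + 1L
    jj <- ((jidx - 1L) %/% h) + 1L
    for (t in seq_along(jidx)) {
      i0 <- max(1L, ji[t] - 1L); i1 <- min(h, ji[t] + 1L)
      j0 <- max(1L, jj[t] - 1L); j1 <- min(w, jj[t] + 1L)
      nb <- lab[i0:i1, j0:j1]
      junction_segs[[t]] <- unique(nb[nb > 0L])
    }
  }
  list(n_segments = n_seg, seg_pixels = seg_pixels, junctions = jidx,
       junction_segs = junction_segs, dim = c(h, w))
}

# skeleton state after removing the first k segments of `order`
prune_state <- function(decomp, order, k) {
  keep <- rep(TRUE, decomp$n_segments)
  if (k > 0L) keep[order[seq_len(k)]] <- FALSE
  m <- matrix(FALSE, decomp$dim[1], decomp$dim[2])
  for (s in which(keep)) m[decomp$seg_pixels[[s]]] <- TRUE
  if (length(decomp$junctions) > 0L) {
    jk <- vapply(decomp$junction_segs,
                 function(ss) length(ss) > 0L && any(keep[ss]), TRUE)
    m[decomp$junctions[jk]] <- TRUE
  }
  m
}

#' Iteratively prune skeleton segments toward a target measure
#'
#' Segments (maximal skeleton arcs between junction or end pixels) are
#' removed one at a time in a seeded uniform-random order; removal stops at
#' the first state whose measured value — network fraction of the rasterized
#' mask, or skeleton length density — is at or below the target. Removal
#' states are nested, so the stopping state is located by bisection over the
#' removal order; the result is identical to stepwise removal. Undershoot by
#' up to one segment's rasterized contribution is inherent to the quantized
#' stop rule.
#'
#' @param skeleton A 1-pixel-wide `binary_mask` skeleton.
#' @param network_radius Vessel half-thickness in pixels (>= 1), used when
#'   the target is a network fraction.
#' @param target Target value (see `target_type`), below the skeleton's
#'   initial value.
#' @param target_type `"network_fraction"` (true-pixel fraction after
#'   rasterization) or `"length_density"` (centreline length per pixel area).
#' @param seed Optional integer seed for the removal order.
#' @return A `binary_mask` of the pruned skeleton. If the target is not
#'   below the initial value, the skeleton is returned unchanged with
#'   attribute `target_unreachable = TRUE`. The removal order is attached as
#'   attribute `removal_order`, the number of removed segments as `removed`.
#' @export
prune_segments <- function(skeleton, network_radius, target,
                           target_type = c("network_fraction", "length_density"),
                           seed = NULL) {
  skeleton <- as_mask(skeleton)
  target_type <- match.arg(target_type)
  if (target <= 0) stop("`target` must be positive")
  measure <- function(sk) {
    if (target_type == "network_fraction")
      mean(cpp_dilate(sk, disk_offsets(network_radius)))
    else skeleton_length(sk) / length(sk)
  }
  decomp <- skeleton_segments(skeleton)
  order <- with_opt_seed(seed, sample.int(max(decomp$n_segments, 1L)))
  initial <- measure(skeleton)
  if (target >= initial) {
    warning("target at or above the unpruned skeleton's value; returning unchanged")
    out <- binary_mask(skeleton)
    attr(out, "target_unreachable") <- TRUE
    attr(out, "removal_order") <- order
    attr(out, "removed") <- 0L
    return(out)
  }
  # bisect for the smallest k with measure(state_k) <= target
  lo <- 0L; hi <- decomp$n_segments   # measure(state_hi) = 0 or junctions only
  hi_state <- prune_state(decomp, order, hi)
  if (measure(hi_state) > target) {
    # junction-only residue still above target: drop everything
    out <- binary_mask(matrix(FALSE, decomp$dim[1], decomp$dim[2]))
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (measure(prune_state(decomp, order, mid)) <= target) hi <- mid
      else lo <- mid
    }
    out <- binary_mask(prune_state(decomp, order, hi))
  }
  attr(out, "target_unreachable") <- FALSE
  attr(out, "removal_order") <- order
  attr(out, "removed") <- hi
  out
}

#' Rasterize a skeleton into a vessel mask
#'
#' Dilates the centreline by the pixelated disk of the network radius, giving
#' vessels of thickness ~ 2 * radius orthogonal to the centreline.
#'
#' @param skeleton A `binary_mask` centreline.
#' @param network_radius Vessel half-thickness in pixels (>= 1).
#' @return A `binary_mask` of the rasterized network.
#' @export
rasterize_network <- function(skeleton, network_radius) {
  if (network_radius < 1) stop("`network_radius` must be >= 1")
  skeleton <- as_mask(skeleton)
  binary_mask(cpp_dilate(skeleton, disk_offsets(network_radius)),
              pixel_size = mask_pixel_size(skeleton))
}

# centreline length of a 1-px-wide skeleton: unit steps count 1, diagonal
# steps sqrt(2); a diagonal pair bridged by a shared 4-neighbour is skipped
skeleton_length <- function(skeleton) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  if (!any(skeleton)) return(0)
  s <- matrix(FALSE, h + 2L, w + 2L)
  s[2:(h + 1L), 2:(w + 1L)] <- skeleton
  core <- s[2:(h + 1L), 2:(w + 1L)]
  right <- core & s[2:(h + 1L), 3:(w + 2L)]
  down  <- core & s[3:(h + 2L), 2:(w + 1L)]
  # diagonals, each counted once (down-right and down-left)
  dr <- core & s[3:(h + 2L), 3:(w + 2L)] &
    !(s[3:(h + 2L), 2:(w + 1L)] & s[2:(h + 1L), 3:(w + 2L)])
  dl <- core & s[3:(h + 2L), 1:w] &
    !(s[3:(h + 2L), 2:(w + 1L)] & s[2:(h + 1L), 1:w])
  n4 <- sum(right) + sum(down)
  nd <- sum(dr) + sum(dl)
  n4 + sqrt(2) * nd
}

#' Measure structural parameters of a network mask
#'
#' Network fraction is the true-pixel fraction. The centreline is recovered
#' by morphological thinning; its length uses the unit/sqrt(2) step
#' convention, and length density divides by the image area. The radius
#' estimate is true pixels / (2 * centreline length).
#'
#' @param mask A `binary_mask` of the network.
#' @return A list with `network_fraction`, `length_density`,
#'   `centerline_length`, `network_radius` (all 0 for an empty mask), and
#'   the thinned `skeleton`.
#' @export
measure_network <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) {
    return(list(network_fraction = 0, length_density = 0,
                centerline_length = 0, network_radius = 0,
                skeleton = binary_mask(matrix(FALSE, nrow(mask), ncol(mask)))))
  }
  sk <- cpp_thin(mask)
  len <- skeleton_length(sk)
  list(network_fraction = mean(mask),
       length_density = len / length(mask),
       centerline_length = len,
       network_radius = if (len > 0) sum(mask) / (2 * len) else 0,
       skeleton = binary_mask(sk))
}

#' Generate a synthetic vessel-like network
#'
#' Composition of the generator stages: minimum-distance point cloud,
#' watershed bisection skeleton, seeded iterative segment pruning to the
#' target, and disk rasterization. Emulates the arborized, interconnected
#' appearance of microvascular networks over a controllable range of
#' densities.
#'
#' @param width,height Image dimensions in pixels.
#' @param min_dist Minimum seed-point distance (sets the mesh size).
#' @param network_radius Vessel half-thickness in pixels (>= 1).
#' @param target Target network fraction in (0, 1\] or length density,
#'   per `target_type`.
#' @param target_type `"network_fraction"` or `"length_density"`.
#' @param seed Optional integer seed; the whole composition is reproducible
#'   from it.
#' @return A list of class `synthetic_network` with `skeleton` (pruned
#'   centreline), `mask` (rasterized vessels), `measured` (achieved
#'   parameters incl. skeleton length density of the pruned centreline),
#'   `target_unreachable` (TRUE when the target exceeded the unpruned
#'   skeleton's value, with a warning), `params` (the request) and `seed`.
#' @export
generate_network <- function(width, height, min_dist, network_radius, target,
                             target_type = c("network_fraction", "length_density"),
                             seed = NULL) {
  target_type <- match.arg(target_type)
  if (network_radius < 1) stop("`network_radius` must be >= 1")
  if (target <= 0) stop("`target` must be positive")
  if (target_type == "network_fraction" && target > 1)
    stop("a network fraction target must be <= 1")
  run <- function() {
    pts <- sample_min_distance_points(width, height, min_dist)
    sk0 <- bisecting_skeleton(pts, width, height)
    sk <- prune_segments(sk0, network_radius, target, target_type)
    mask <- rasterize_network(sk, network_radius)
    len <- skeleton_length(sk)
    list(skeleton = sk, mask = mask,
         target_unreachable = isTRUE(attr(sk, "target_unreachable")),
         measured = list(network_fraction = mean(mask),
                         length_density = len / length(mask),
                         centerline_length = len,
                         network_radius = network_radius),
         params = list(width = width, height = height, min_dist = min_dist,
                       network_radius = network_radius, target = target,
                       target_type = target_type),
         seed = seed)
  }
  out <- with_opt_seed(seed, run())
  class(out) <- "synthetic_network"
  out
}

#' @export
print.synthetic_network <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_network> %d x %d px, radius %g, ",
                     "fraction %.4f (target %s = %g)\n"),
              x$params$width, x$params$height, x$params$network_radius,
              x$measured$network_fraction, x$params$target_type, x$params$target))
  invisible(x)
}
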