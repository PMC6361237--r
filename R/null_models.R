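#' Binomial model of random placement (BMRP): probability mass
#'
#' Under uniform random placement the number of colocalized cells out of n
#' is exactly Binomial(n, p) with p the cell-dilated network fraction, so
#' f(c; n, p) = choose(n, c) p^c (1-p)^(n-c). Evaluated in log space for
#' numerical stability at large n.
#'
#' @param c Colocalized count (0 <= c <= n).
#' @param n Total cell count.
#' @param p Success probability (the CDNF), in \[0, 1\].
#' @return The probability mass at c.
#' @export
binomial_pmf <- function(c, n, p) {
  check_count_pair(c, n)
  check_prob(p)
  stats::dbinom(c, n, p)
}

#' BMRP mean and standard deviation
#'
#' mu = n p, sigma = sqrt(n p (1 - p)): the closed-form moments that replace
#' repeated Monte Carlo trials. The model's mean ICF is mu / n = p.
#'
#' @inheritParams binomial_pmf
#' @return A list with `mean` and `sd`.
#' @export
binomial_moments <- function(n, p) {
  check_prob(p)
  if (n < 0) stop("`n` must be >= 0")
  list(mean = n * p, sd = sqrt(n * p * (1 - p)))
}

#' Single-image CIRCOAST test
#'
#' Upper-tail binomial test for enriched colocalization: the probability,
#' under random placement, of observing colocalization to an equal or
#' greater extent than in the image, P(X >= c) with X ~ Binomial(n, p).
#' Computed as a direct tail sum (not 1 - CDF) so no cancellation occurs;
#' c = 0 gives exactly 1.
#'
#' @param obs A [coloc_observation()] (n >= 1).
#' @param p The image's CDNF: a [cdnf_value()] or bare probability.
#' @return The one-tailed p-value in \[0, 1\].
#' @examples
#' circoast_image_p(coloc_observation(10, 6), 0.3)
#' @export
circoast_image_p <- function(obs, p) {
  if (!inherits(obs, "coloc_observation")) stop("`obs` must be a coloc_observation")
  if (obs$n < 1) stop("no cells sampled (n = 0): the test is undefined")
  p <- as_cdnf(p)$p
  if (obs$c == 0L) return(1)
  # pbinom(lower.tail = FALSE) accumulates the upper tail directly
  stats::pbinom(obs$c - 1L, obs$n, p, lower.tail = FALSE)
}

#' Hypergeometric model of random placement (HMRP): probability mass
#'
#' Finite-population correction of the BMRP: with at most N non-overlapping
#' cells placeable in the image, of which K would colocalize, the number of
#' colocalized cells among n observed is hypergeometric:
#' h(k | N, n, K) = choose(K, k) choose(N-K, n-k) / choose(N, n).
#'
#' @param k Colocalized count.
#' @param N Maximum number of cells that can exist in the image.
#' @param n Observed cell count (n <= N).
#' @param K Colocalizing count of the maximum population (K <= N).
#' @return The probability mass at k.
#' @export
hypergeom_pmf <- function(k, N, n, K) {
  check_hyper(k, N, n, K)
  stats::dhyper(k, K, N - K, n)
}

#' HMRP mean and standard deviation
#'
#' mu = n K / N, sigma = sqrt(n K (N - K) (N - n) / (N^2 (N - 1))). For
#' N = 1 the variance is 0 by convention (a census of one).
#'
#' @inheritParams hypergeom_pmf
#' @return A list with `mean` and `sd`.
#' @export
hypergeom_moments <- function(N, n, K) {
  if (N < 1 || n < 0 || K < 0 || n > N || K > N)
    stop("require 0 <= n <= N, 0 <= K <= N, N >= 1")
  mu <- n * K / N
  sd <- if (N == 1) 0 else sqrt(n * K * (N - K) * (N - n) / (N^2 * (N - 1)))
  list(mean = mu, sd = sd)
}

#' HMRP population parameters from image geometry and packing
#'
#' The maximum placeable population is N = round(A * eta / (pi r^2)) with A
#' the image pixel area, eta the Monte Carlo packing ratio for this cell
#' diameter and image size, and r the cell pixel radius. The colocalizing
#' share of that population is K = round(N * p) with p the CDNF (the
#' fraction of the image where colocalization occurs), clamped to \[0, N\].
#' Rounding is half-away-from-zero; fractional populations are meaningless
#' for the pmf.
#'
#' @param width,height Image dimensions in pixels.
#' @param cell A `cell_model` or bare diameter (>= 5 px).
#' @param p The image CDNF ([cdnf_value()] or probability).
#' @param table A [build_packing_table()] lookup table containing the key
#'   (round(diameter), width, height).
#' @param interpolate Passed to [packing_lookup()].
#' @return A list with `N`, `K` and the `eta` used.
#' @export
hmrp_params <- function(width, height, cell, p, table, interpolate = FALSE) {
  cell <- as_cell(cell)
  if (cell$diameter < 5) stop("cell diameter must be >= 5 pixels for the HMRP")
  p <- as_cdnf(p)$p
  eta <- packing_lookup(table, cell$diameter, width, height, interpolate)
  A <- width * height
  N <- as.integer(round_half_up(A * eta / (pi * cell$radius^2)))
  K <- as.integer(max(0, min(N, round_half_up(N * p))))
  list(N = N, K = K, eta = eta)
}

check_prob <- function(p) {
  if (!is.numeric(p) || any(p < 0) || any(p > 1))
    stop("probability must lie in [0, 1]")
}

check_count_pair <- function(c, n) {
  if (any(c < 0) || any(c > n)) stop("require 0 <= c <= n")
}

check_hyper <- function(k, N, n, K) {
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N) ||
      any(n - k > N - K))
    stop("hypergeometric domain violated: need 0 <= k <= min(n, K), n <= N, K <= N, n - k <= N - K")
}
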