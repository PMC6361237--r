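#' CIRCOAST test for one biological replicate (pooled images)
#'
#' Sufficient sampling is set by the number of cells examined, not fields of
#' view, so the images of one replicate are pooled: the combined CDNF is the
#' area-weighted ratio of dilated pixels over total pixels, and cell counts
#' are summed. The replicate's p-value is the single-image upper-tail
#' binomial test on the pooled observation. Pooling the dilate-then-split
#' quadrants of an image reproduces the whole-image p exactly.
#'
#' @param images A non-empty list; each element is a list with either
#'   * `network` (a `binary_mask`) plus `centers` (0-based x, y table), or
#'   * `network` plus `obs` (a [coloc_observation()]), or
#'   * `cdnf` (a [cdnf_value()]) plus `obs` (precomputed inputs).
#' @param cell A `cell_model` or bare diameter shared by the replicate
#'   (required whenever a `network` must be dilated).
#' @param id Optional replicate identifier.
#' @return An object of class `replicate_result`: list with `id`,
#'   `per_image` (data.frame of n, c, cdnf), `cdnf` (pooled), `obs`
#'   (pooled), `p` (the replicate CIRCOAST p-value).
#' @export
replicate_test <- function(images, cell = NULL, id = NULL) {
  if (!is.list(images) || length(images) == 0L)
    stop("`images` must be a non-empty list")
  per <- lapply(images, function(img) {
    if (!is.null(img$cdnf)) {
      cdnf <- as_cdnf(img$cdnf)
      obs <- img$obs
    } else {
      if (is.null(img$network)) stop("each image needs `network` or `cdnf`")
      if (is.null(cell)) stop("`cell` is required to dilate networks")
      net <- as_mask(img$network)
      dil <- dilate_network(net, cell)
      cdnf <- cdnf_value(sum(dil), length(dil))
      obs <- if (!is.null(img$obs)) img$obs else count_colocalized(img$centers, dil)
    }
    if (!inherits(obs, "coloc_observation"))
      stop("each image needs `centers` or a coloc_observation `obs`")
    list(cdnf = cdnf, obs = obs)
  })
  pooled_cdnf <- pool_cdnf(lapply(per, `[[`, "cdnf"))
  n <- sum(vapply(per, function(x) x$obs$n, 0L))
  c <- sum(vapply(per, function(x) x$obs$c, 0L))
  if (n == 0L) stop("zero cells in the replicate: the test is undefined")
  pooled_obs <- coloc_observation(n, c)
  structure(list(id = id,
                 per_image = data.frame(
                   n = vapply(per, function(x) x$obs$n, 0L),
                   c = vapply(per, function(x) x$obs$c, 0L),
                   cdnf = vapply(per, function(x) x$cdnf$p, 0)),
                 cdnf = pooled_cdnf, obs = pooled_obs,
                 p = circoast_image_p(pooled_obs, pooled_cdnf)),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("<replicate_result> %s: %d images, pooled c/n = %d/%d, CDNF %.4f, p = %.4g\n",
              if (is.null(x$id)) "?" else x$id, nrow(x$per_image),
              x$obs$c, x$obs$n, x$cdnf$p, x$p))
  invisible(x)
}

#' Exact CDF of the mean of N uniform p-values (Bates distribution)
#'
#' Analytic form of the pseudo-null used by the 1-sample test: if the null
#' holds, each replicate's p-value is Uniform(0, 1), so the mean of N of
#' them follows the Bates distribution (Irwin-Hall sum scaled by 1/N):
#' P(mean <= m) = (1/N!) * sum_{k=0}^{floor(mN)} (-1)^k choose(N, k) (mN - k)^N.
#'
#' @param m Observed mean in \[0, 1\] (vectorized).
#' @param N Number of averaged uniforms (>= 1).
#' @return P(mean of N uniforms <= m).
#' @export
bates_mean_cdf <- function(m, N) {
  if (N < 1) stop("`N` must be >= 1")
  check_prob(m)
  vapply(m, function(mi) {
    s <- mi * N
    k <- 0:floor(s)
    # alternating Irwin-Hall sum in log space, signs handled explicitly
    terms <- exp(lchoose(N, k) + N * log(pmax(s - k, 0)) - lfactorial(N))
    val <- sum(terms * (-1)^k)
    min(max(val, 0), 1)
  }, 0)
}

# simulate `trials` means of N iid Uniform(0,1), chunked to bound memory
simulate_null_means <- function(N, trials, chunk = 2e6) {
  out <- numeric(trials)
  done <- 0L
  while (done < trials) {
    take <- min(as.integer(chunk), trials - done)
    out[done + seq_len(take)] <- colMeans(matrix(stats::runif(N * take), nrow = N))
    done <- done + take
  }
  out
}

#' One-sample CIRCOAST test for a study group
#'
#' Combines the replicate-level CIRCOAST p-values of one study group. Under
#' the random-placement null each is Uniform(0, 1), so the pseudo-null of
#' the group mean p-value is simulated as means of N iid uniforms; the
#' reported p is the (add-one corrected) fraction of simulated null means at
#' or below the observed mean — small when the replicate p-values are
#' systematically enriched (small).
#'
#' @param p_values Replicate CIRCOAST p-values (non-empty, in \[0, 1\]).
#' @param trials Pseudo-null Monte Carlo trials (default 1e7).
#' @param seed Optional integer seed.
#' @return An object of class `group_result`: list with `p_values`,
#'   `observed_mean`, `trials`, `one_sample_p`, `seed`.
#' @export
one_sample_circoast <- function(p_values, trials = 1e7, seed = NULL) {
  if (length(p_values) == 0L) stop("`p_values` must be non-empty")
  check_prob(p_values)
  if (trials < 1e4) stop("`trials` must be >= 1e4 for a usable pseudo-null")
  N <- length(p_values)
  obs <- mean(p_values)
  hits <- with_opt_seed(seed, {
    total <- 0
    done <- 0
    while (done < trials) {
      take <- as.integer(min(2e6, trials - done))
      nm <- colMeans(matrix(stats::runif(N * take), nrow = N))
      total <- total + sum(nm <= obs)
      done <- done + take
    }
    total
  })
  structure(list(p_values = p_values, observed_mean = obs,
                 trials = as.integer(trials),
                 one_sample_p = (1 + hits) / (trials + 1),
                 seed = seed),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> N = %d replicates, mean p = %.4f, 1-sample CIRCOAST p = %.4g (%d trials)\n",
              length(x$p_values), x$observed_mean, x$one_sample_p, x$trials))
  invisible(x)
}

# two-sample statistic p-value used inside the permutation scheme
two_sample_stat_p <- function(a, b, test) {
  if (test == "rank-sum")
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  else
    stats::t.test(a, b)$p.value
}

#' Two-sample CIRCOAST test between study groups
#'
#' The replicate CIRCOAST p-values of the two groups are compared with a
#' standard two-sample test (Wilcoxon rank-sum by default, Student's t
#' optionally) to give an observed p. Its pseudo-null is built by permuting
#' the group labels and recomputing the same test; the 2-sample CIRCOAST p
#' is the fraction of permuted test p-values at or below the observed one
#' (add-one corrected in Monte Carlo mode; exact when all distinct splits
#' are enumerated).
#'
#' @param a,b Replicate p-values of the two groups (>= 2 each).
#' @param test `"rank-sum"` or `"t"`.
#' @param permutations Number of random label permutations (default 1e7), or
#'   `"exhaustive"` to enumerate every distinct split.
#' @param seed Optional integer seed (Monte Carlo mode).
#' @return An object of class `comparison_result`: list with `a`, `b`,
#'   `test`, `observed_p` (the two-sample test p), `permutations`,
#'   `two_sample_p`, `exhaustive`, `seed`.
#' @export
two_sample_circoast <- function(a, b, test = c("rank-sum", "t"),
                                permutations = 1e7, seed = NULL) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  check_prob(a); check_prob(b)
  pooled <- c(a, b)
  na <- length(a)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups: two-sample p set to 1")
    return(structure(list(a = a, b = b, test = test, observed_p = 1,
                          permutations = 0L, two_sample_p = 1,
                          exhaustive = FALSE, seed = seed),
                     class = "comparison_result"))
  }
  observed <- two_sample_stat_p(a, b, test)
  exhaustive <- identical(permutations, "exhaustive")
  if (exhaustive) {
    splits <- utils::combn(length(pooled), na)
    perm_p <- apply(splits, 2, function(ix)
      two_sample_stat_p(pooled[ix], pooled[-ix], test))
    two_p <- mean(perm_p <= observed)
    nperm <- ncol(splits)
  } else {
    if (permutations < 1e3) stop("`permutations` must be >= 1e3")
    hits <- with_opt_seed(seed, {
      sum(vapply(seq_len(permutations), function(i) {
        ix <- sample.int(length(pooled), na)
        two_sample_stat_p(pooled[ix], pooled[-ix], test) <= observed
      }, TRUE))
    })
    two_p <- (1 + hits) / (permutations + 1)
    nperm <- as.integer(permutations)
  }
  structure(list(a = a, b = b, test = test, observed_p = observed,
                 permutations = nperm, two_sample_p = two_p,
                 exhaustive = exhaustive, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s test p = %.4g; 2-sample CIRCOAST p = %.4g (%d permutations%s)\n",
              x$test, x$observed_p, x$two_sample_p, x$permutations,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Generic per-image colocalization statistics between two groups
#'
#' The three density-confounded metrics a generic analysis would use:
#' colocalized cells per field of view (c), colocalized cells per mm of
#' vessel centreline, and the fraction of cells colocalizing (c / n) — each
#' compared across groups with an unpaired two-sample t-test. Provided for
#' contrast with the CIRCOAST tests, which are not confounded by density.
#'
#' @param records A data.frame with columns `group` (two levels), `c`, `n`,
#'   `centerline_px` (vessel centreline length in pixels) and optionally
#'   `pixel_size` (micrometres per pixel, default 1).
#' @return A list with `per_image` (the records plus derived metrics) and
#'   `tests`: a data.frame of metric, group means and t-test p. Images with
#'   zero length or zero cells are excluded from the affected metric with a
#'   warning.
#' @export
generic_group_stats <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("group", "c", "n", "centerline_px") %in% names(records)))
  if (length(unique(records$group)) != 2L) stop("exactly two groups required")
  ps <- if ("pixel_size" %in% names(records)) records$pixel_size else 1
  records$length_mm <- records$centerline_px * ps / 1000
  records$per_fov <- records$c
  records$per_mm <- ifelse(records$length_mm > 0, records$c / records$length_mm, NA)
  records$fraction <- ifelse(records$n > 0, records$c / records$n, NA)
  if (anyNA(records$per_mm)) warning("images with zero vessel length excluded from the per-mm metric")
  if (anyNA(records$fraction)) warning("images with zero cells excluded from the fraction metric")
  one <- function(metric) {
    v <- records[[metric]]
    ok <- !is.na(v)
    g <- records$group[ok]
    t <- stats::t.test(v[ok] ~ g)
    data.frame(metric = metric,
               mean_a = t$estimate[1], mean_b = t$estimate[2],
               p = t$p.value, row.names = NULL)
  }
  list(per_image = records,
       tests = do.call(rbind, lapply(c("per_fov", "per_mm", "fraction"), one)))
}
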