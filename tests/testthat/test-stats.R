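test_that("replicate pooling sums counts and area-weights the CDNF", {
  # single image: identical to the single-image test
  one <- replicate_test(list(list(cdnf = cdnf_value(300, 1000),
                                  obs = coloc_observation(10, 6))))
  expect_equal(one$p, circoast_image_p(coloc_observation(10, 6), 0.3))
  # two images at p = 0.5: pooled (10, 5) -> P(X >= 5 | 10, 0.5)
  two <- replicate_test(list(
    list(cdnf = cdnf_value(500, 1000), obs = coloc_observation(5, 5)),
    list(cdnf = cdnf_value(500, 1000), obs = coloc_observation(5, 0))))
  expect_equal(two$obs$n, 10L)
  expect_equal(two$obs$c, 5L)
  expect_equal(two$p, oracle_binom_tail(5, 10, 0.5))
  expect_equal(two$p, 0.623047, tolerance = 1e-6)
  expect_error(replicate_test(list(list(cdnf = cdnf_value(1, 10),
                                        obs = coloc_observation(0, 0)))),
               "zero cells")
})

test_that("dilate-then-split quadrants give the whole-image p exactly", {
  net <- unit_network(seed = 20)$mask
  cell <- cell_model(8)
  dil <- dilate_network(net, cell)
  centers <- place_cells_uniform(80, 128, 128, seed = 21)
  whole <- replicate_test(list(list(network = net, centers = centers)),
                          cell = cell)
  h <- nrow(dil); w <- ncol(dil)
  quad <- function(rows, cols, x0, y0) {
    q <- dil[rows, cols]
    inq <- centers[, "x"] >= x0 & centers[, "x"] < x0 + w / 2 &
           centers[, "y"] >= y0 & centers[, "y"] < y0 + h / 2
    sub <- centers[inq, , drop = FALSE]
    sub[, "x"] <- sub[, "x"] - x0; sub[, "y"] <- sub[, "y"] - y0
    list(cdnf = cdnf_value(sum(q), length(q)), obs = count_colocalized(sub, q))
  }
  parts <- list(quad(1:(h / 2), 1:(w / 2), 0, 0),
                quad(1:(h / 2), (w / 2 + 1):w, w / 2, 0),
                quad((h / 2 + 1):h, 1:(w / 2), 0, h / 2),
                quad((h / 2 + 1):h, (w / 2 + 1):w, w / 2, h / 2))
  split4 <- replicate_test(parts)
  expect_identical(split4$obs$n, whole$obs$n)
  expect_identical(split4$obs$c, whole$obs$c)
  expect_identical(split4$cdnf$p, whole$cdnf$p)
  expect_identical(split4$p, whole$p)
})

test_that("Bates CDF matches its closed forms and the simulated pseudo-null", {
  expect_equal(bates_mean_cdf(0.37, 1), 0.37)
  expect_equal(bates_mean_cdf(0.25, 2), 0.125)
  expect_equal(bates_mean_cdf(0.75, 2), 0.875)
  for (N in c(1, 2, 3, 6, 11)) expect_equal(bates_mean_cdf(0.5, N), 0.5)
  # numeric integration oracle at N = 3
  grid <- seq(0, 1, length.out = 2001)
  f2 <- function(m) bates_mean_cdf(m, 2)      # CDF of mean of 2
  # P(mean3 <= m) = E_z[P(mean2 <= (3m - z)/2)] with z ~ U(0,1)
  m <- 0.4
  ref <- mean(f2(pmin(pmax((3 * m - grid) / 2, 0), 1)))
  expect_equal(bates_mean_cdf(m, 3), ref, tolerance = 1e-3)
  # simulation agrees
  sim <- mean(circoast:::simulate_null_means(3, 2e5) <= 0.4)
  expect_lt(abs(sim - bates_mean_cdf(0.4, 3)), 4 * sqrt(0.35 / 2e5))
})

test_that("one-sample CIRCOAST converges to the Bates percentile", {
  g1 <- one_sample_circoast(0.3, trials = 1e5, seed = 31)
  expect_lt(abs(g1$one_sample_p - 0.3), 4 * sqrt(0.3 * 0.7 / 1e5))
  g2 <- one_sample_circoast(c(0.1, 0.4), trials = 1e5, seed = 32)
  expect_lt(abs(g2$one_sample_p - 0.125), 4 * sqrt(0.125 * 0.875 / 1e5))
  g0 <- one_sample_circoast(rep(0, 4), trials = 1e4, seed = 33)
  expect_lte(g0$one_sample_p, 1 / 1e4)   # add-one guard, never exactly 0
  expect_gt(g0$one_sample_p, 0)
  expect_error(one_sample_circoast(numeric(0)), "non-empty")
  expect_error(one_sample_circoast(0.5, trials = 100), "1e4")
  # determinism
  expect_identical(one_sample_circoast(c(0.2, 0.6), 1e4, seed = 5)$one_sample_p,
                   one_sample_circoast(c(0.2, 0.6), 1e4, seed = 5)$one_sample_p)
})

test_that("two-sample permutation test matches exhaustive enumeration", {
  a <- c(0.02, 0.11, 0.35)
  b <- c(0.40, 0.62, 0.90)
  for (tst in c("rank-sum", "t")) {
    got <- two_sample_circoast(a, b, test = tst, permutations = "exhaustive")
    expect_equal(got$two_sample_p, oracle_perm_p(a, b, tst), info = tst)
    expect_equal(got$permutations, choose(6, 3))
  }
  a4 <- c(0.03, 0.2, 0.5, 0.55); b4 <- c(0.1, 0.6, 0.7, 0.95)
  got4 <- two_sample_circoast(a4, b4, permutations = "exhaustive")
  expect_equal(got4$two_sample_p, oracle_perm_p(a4, b4))
  # identical multisets: observed p is maximal
  same <- two_sample_circoast(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9),
                              permutations = "exhaustive")
  expect_equal(same$two_sample_p, 1)
  expect_warning(tied <- two_sample_circoast(rep(0.4, 3), rep(0.4, 3)),
                 "tied")
  expect_equal(tied$two_sample_p, 1)
  # Monte Carlo mode approaches the exhaustive answer
  mc <- two_sample_circoast(a4, b4, permutations = 4000, seed = 41)
  expect_lt(abs(mc$two_sample_p - got4$two_sample_p), 0.05)
})

test_that("two-sample CIRCOAST holds its type-I error on null data", {
  repeats <- 300
  rej <- withr::with_seed(51, vapply(seq_len(repeats), function(i) {
    x <- runif(4); y <- runif(4)
    two_sample_circoast(x, y, permutations = "exhaustive")$two_sample_p <= 0.05
  }, TRUE))
  ci <- stats::binom.test(sum(rej), repeats)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2],
              label = sprintf("rate %.3f CI [%.3f, %.3f]",
                              mean(rej), ci[1], ci[2]))
})

test_that("generic per-image statistics match hand computation", {
  recs <- data.frame(group = c("a", "a", "b", "b"),
                     c = c(10, 12, 5, 7),
                     n = c(50, 60, 40, 45),
                     centerline_px = c(2000, 2500, 1500, 1800),
                     pixel_size = 1)
  out <- generic_group_stats(recs)
  expect_equal(out$per_image$per_mm, recs$c / (recs$centerline_px / 1000))
  expect_equal(out$per_image$fraction, recs$c / recs$n)
  # spreadsheet oracle for the per-FOV t-test
  expect_equal(out$tests$p[out$tests$metric == "per_fov"],
               stats::t.test(c(10, 12), c(5, 7))$p.value)
  # identical groups: p = 1
  same <- generic_group_stats(data.frame(
    group = rep(c("a", "b"), each = 3), c = rep(c(4, 6, 8), 2),
    n = rep(50, 6), centerline_px = rep(c(1000, 1200, 1400), 2)))
  expect_true(all(same$tests$p > 0.999))
  # doubling c in one group shrinks the per-FOV p
  shift <- generic_group_stats(data.frame(
    group = rep(c("a", "b"), each = 3), c = c(4, 6, 8, 8, 12, 16),
    n = rep(50, 6), centerline_px = rep(c(1000, 1200, 1400), 2)))
  expect_lt(shift$tests$p[shift$tests$metric == "per_fov"],
            same$tests$p[same$tests$metric == "per_fov"])
})
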