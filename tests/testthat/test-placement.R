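test_that("uniform placement covers the pixel grid uniformly", {
  expect_equal(nrow(place_cells_uniform(0, 10, 10)), 0)
  one <- place_cells_uniform(25, 1, 1, seed = 2)
  expect_true(all(one == 0L))
  pts <- place_cells_uniform(1e5, 64, 64, seed = 3)
  bin <- table(factor(pts[, "x"] %/% 16, levels = 0:3),
               factor(pts[, "y"] %/% 16, levels = 0:3))
  expect_gt(stats::chisq.test(as.vector(bin))$p.value, 0.001)
  expect_identical(pts, place_cells_uniform(1e5, 64, 64, seed = 3))
})

test_that("MCMRP colocalized counts are exactly binomial in CDNF", {
  net <- unit_network(seed = 14, size = 64, target = 0.2, radius = 2)$mask
  cell <- cell_model(6)
  p <- compute_cdnf(net, cell)$p
  d <- mcmrp_distribution(net, cell, n = 5, trials = 4000, seed = 9)
  counts <- table(factor(round(d$samples * 5), levels = 0:5))
  expect_gt(stats::chisq.test(as.vector(counts), p = dbinom(0:5, 5, p))$p.value,
            0.001)
  # mean converges to the CDNF within the Monte Carlo error bound
  d2 <- mcmrp_distribution(net, cell, n = 60, trials = 5000, seed = 10)
  expect_lt(abs(d2$mean - p), 4 * sqrt(p * (1 - p) / (60 * 5000)))
  # degenerate networks
  expect_equal(mcmrp_distribution(matrix(FALSE, 16, 16), 4, 5, 50)$mean, 0)
  expect_equal(mcmrp_distribution(matrix(TRUE, 16, 16), 4, 5, 50)$mean, 1)
  # mean ICF does not depend on the cell number (up to MC error)
  d3 <- mcmrp_distribution(net, cell, n = 200, trials = 5000, seed = 11)
  se <- sqrt(p * (1 - p) * (1 / (60 * 5000) + 1 / (200 * 5000)))
  expect_lt(abs(d3$mean - d2$mean), 4 * se)
})

test_that("non-overlapping placement yields disjoint contained disks", {
  cell <- cell_model(9)
  pts <- place_cells_nonoverlapping(25, cell, 96, 96, seed = 4)
  expect_false(attr(pts, "saturated"))
  off <- oracle_disk_offsets(4.5)
  cover <- matrix(0L, 96, 96)
  for (t in seq_len(nrow(pts))) {
    rr <- pts[t, "y"] + off[, 1] + 1L
    cc <- pts[t, "x"] + off[, 2] + 1L
    expect_true(all(rr >= 1 & rr <= 96 & cc >= 1 & cc <= 96))  # containment
    cover[cbind(rr, cc)] <- cover[cbind(rr, cc)] + 1L
  }
  expect_lte(max(cover), 1L)                                   # disjoint
  # oversized cell: at most one fits
  tiny <- place_cells_nonoverlapping(5, cell_model(64), 64, 64, seed = 1)
  expect_lte(nrow(tiny), 1)
})

test_that("saturation flag matches the exhaustive free-position oracle", {
  cell <- cell_model(5)
  pts <- place_cells_nonoverlapping(200, cell, 24, 24, seed = 6)
  expect_lt(nrow(pts), 200)
  expect_true(attr(pts, "saturated"))
  # oracle: scan every admissible centre for a conflict-free position
  margin <- floor(cell$radius)
  forb <- circoast:::forbidden_offsets(cell$radius)
  free <- 0L
  for (x in margin:(23 - margin)) for (y in margin:(23 - margin)) {
    dd <- cbind(pts[, "y"] - y, pts[, "x"] - x)
    key <- paste(dd[, 1], dd[, 2])
    if (!any(key %in% paste(forb[, "dr"], forb[, "dc"]))) free <- free + 1L
  }
  expect_identical(free, 0L)
  # a clearly unsaturated placement is flagged FALSE
  few <- place_cells_nonoverlapping(2, cell, 96, 96, seed = 6)
  expect_false(attr(few, "saturated"))
})

test_that("packing ratios stay below hexagonal packing and vary with size", {
  expect_error(saturate_packing(cell_model(4), 64, 64), "diameter")
  etas <- vapply(1:8, function(s) as.numeric(
    saturate_packing(cell_model(6), 128, 128, seed = s)), 0)
  expect_true(all(etas > 0 & etas < 0.901))
  # a disk as wide as the (odd-sided) image admits exactly one centre
  one <- saturate_packing(cell_model(63), 63, 63, seed = 2)
  expect_equal(as.numeric(one), nrow(oracle_disk_offsets(31.5)) / 63^2)
  expect_equal(attr(one, "n_placed"), 1L)
})

test_that("packing tables are reproducible and the SE scales as 1/sqrt(trials)", {
  t1 <- build_packing_table(c(6, 8), 96, 96, trials = 6, seed = 42)
  t2 <- build_packing_table(c(6, 8), 96, 96, trials = 6, seed = 42)
  expect_identical(t1$eta, t2$eta)
  expect_true(all(t1$eta > 0 & t1$eta < 0.901))
  expect_equal(packing_lookup(t1, 6.4, 96, 96), t1$eta[t1$diameter == 6])
  expect_error(packing_lookup(t1, 12, 96, 96), "interpolate")
  expect_equal(packing_lookup(t1, 7, 96, 96, interpolate = TRUE),
               mean(t1$eta))
  # the sd column estimates a trial-count-invariant spread; the standard
  # error of the mean shrinks with trials
  small <- build_packing_table(8, 96, 96, trials = 10, seed = 7)
  big <- build_packing_table(8, 96, 96, trials = 40, seed = 7)
  expect_lt(abs(log(small$sd / big$sd)), log(2.5))
  expect_lt(big$sd / sqrt(big$trials), small$sd / sqrt(small$trials))
})

test_that("clump placement keeps members adjacent and the mean ICF unbiased", {
  cell <- cell_model(8)
  member_dists <- function(cl, n_clumps, clump_size, size) {
    out <- numeric(0)
    idx <- 1L
    for (k in seq_len(n_clumps)) {
      a <- cl[idx, ]
      for (m in seq_len(clump_size - 1L)) {
        b <- cl[idx + m, ]
        dx <- circoast:::wrap_delta(b[["x"]] - a[["x"]], size)
        dy <- circoast:::wrap_delta(b[["y"]] - a[["y"]], size)
        out <- c(out, sqrt(dx^2 + dy^2))
      }
      idx <- idx + clump_size
    }
    out
  }
  cl <- place_clumps(6, 4, overlap_allowed = FALSE, cell, 160, 160, seed = 13)
  expect_equal(nrow(cl), 24)              # sparse enough: nothing dropped
  expect_false(attr(cl, "saturated"))
  # touching pixelated disks sit ~1 px beyond the diameter
  expect_true(all(member_dists(cl, 6, 4, 160) <= cell$diameter + 2))
  cl2 <- place_clumps(5, 3, overlap_allowed = TRUE, cell, 160, 160, seed = 14)
  expect_true(all(member_dists(cl2, 5, 3, 160) <= cell$radius))
  # clump_size 1 in overlap mode reduces to uniform placement
  u <- place_clumps(50, 1, TRUE, cell, 64, 64, seed = 15)
  expect_equal(nrow(u), 50)
  # mean ICF of clumped placement equals independent placement
  net <- unit_network(seed = 16)$mask
  dil <- dilate_network(net, cell)
  trials <- 1500
  icf_clump <- withr::with_seed(17, vapply(seq_len(trials), function(t) {
    pts <- place_clumps(8, 3, TRUE, cell, 128, 128)
    count_colocalized(pts, dil)$c / nrow(pts)
  }, 0))
  icf_ind <- mcmrp_distribution(net, cell, 24, trials, seed = 18)
  se <- sqrt(stats::var(icf_clump) / trials + icf_ind$sd^2 / trials)
  expect_lt(abs(mean(icf_clump) - icf_ind$mean), 4 * se)
})
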