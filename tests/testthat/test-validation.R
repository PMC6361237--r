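# small sweep shared by the validation unit tests (128 px images)
small_ranges <- list(width = 128L, height = 128L, diameter = c(6, 16),
                     cell_number = c(30L, 80L), network_radius = c(2, 5),
                     network_fraction = c(0.1, 0.45), min_dist = c(12, 20))

test_that("the parameter sweep records consistent per-image quantities", {
  sw <- run_parameter_sweep(12, trials_per_image = 400, ranges = small_ranges,
                            seed = 61)
  expect_equal(nrow(sw), 12)
  expect_identical(sw$bmrp_mean, sw$cdnf)
  expect_true(all(sw$network_fraction <= 0.45 + 1e-9))
  expect_true(all(sw$cdnf >= sw$network_fraction))  # dilation only grows
  bound <- 4 * sqrt(sw$cdnf * (1 - sw$cdnf) / (sw$cell_number * 400)) + 1e-12
  expect_true(all(abs(sw$mcmrp_mean - sw$cdnf) <= bound))
  # reproducible from the seed
  sw2 <- run_parameter_sweep(12, trials_per_image = 400, ranges = small_ranges,
                             seed = 61)
  expect_identical(sw, sw2)
})

test_that("sweep correlations and the z-scored MVLR find CDNF and only CDNF", {
  sw <- run_parameter_sweep(40, trials_per_image = 600, ranges = small_ranges,
                            seed = 62)
  co <- correlate_sweep(sw)
  expect_equal(co$parameter, c("diameter", "cell_number", "network_radius",
                               "network_fraction", "length_density", "cdnf"))
  # response = exact copy of a predictor -> r = 1
  sw_copy <- sw; sw_copy$mcmrp_mean <- sw_copy$cdnf
  co_copy <- correlate_sweep(sw_copy)
  expect_equal(co_copy$r[co_copy$parameter == "cdnf"], 1)
  # textbook Pearson formula on a hand-sized dataset
  x <- sw$cdnf[1:5]; y <- sw$mcmrp_mean[1:5]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(co$r[co$parameter == "cdnf"],
               unname(stats::cor.test(sw$cdnf, sw$mcmrp_mean)$estimate))
  expect_equal(stats::cor(x, y), r_hand)
  # zero-variance predictor is flagged, not silently dropped
  sw_flat <- sw; sw_flat$diameter <- 7
  expect_true(correlate_sweep(sw_flat)$degenerate[1])
  # MVLR: solved identically by the normal equations
  fit <- zscore_mvlr(sw)
  X <- cbind(1, scale(as.matrix(sw[, c("diameter", "cell_number",
                                       "network_radius", "network_fraction",
                                       "length_density", "cdnf")])))
  y <- as.numeric(scale(sw$mcmrp_mean))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-10)
  expect_gt(fit$r_squared, 0.99)
  cdnf_coef <- fit$coefficients$estimate[fit$coefficients$term == "cdnf"]
  expect_equal(cdnf_coef, 1, tolerance = 0.05)
  # response constructed from one predictor + noise: that coefficient ~ 1
  sw_syn <- sw
  sw_syn$mcmrp_mean <- sw_syn$cdnf
  fit_syn <- suppressWarnings(zscore_mvlr(sw_syn))  # exact fit by design
  expect_equal(fit_syn$r_squared, 1, tolerance = 1e-12)
  # rank deficiency is reported with diagnostics
  sw_dup <- sw; sw_dup$diameter <- sw_dup$cell_number
  expect_error(zscore_mvlr(sw_dup), "rank|aliased|deficient")
})

test_that("Bland-Altman limits follow the two-point arithmetic", {
  same <- bland_altman(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(same$mean_difference, 0)
  expect_equal(same$lower, 0)
  expect_equal(same$upper, 0)
  ba <- bland_altman(c(0.2, 0.4), c(0.1, 0.5))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$upper, 1.96 * sqrt(0.02))
  expect_equal(ba$lower, -1.96 * sqrt(0.02))
  expect_error(bland_altman(1, c(1, 2)), "pairs")
})

test_that("the density confound inflates generic statistics, not CIRCOAST", {
  res <- density_confound_experiment(n_replicates_per_group = 5,
                                     images_per_replicate = 1,
                                     repeats = 4, seed = 63)
  expect_equal(nrow(res$runs), 4)
  # generic per-FOV counts differ enormously between the two densities
  expect_true(all(res$runs$per_fov_p < 0.01))
  expect_true(all(res$runs$circoast_p > 0 & res$runs$circoast_p <= 1))
  # equal-density groups: generic statistics are calm too
  eq <- density_confound_experiment(n_replicates_per_group = 4,
                                    images_per_replicate = 1,
                                    dense = confound_default_params("sparse"),
                                    sparse = confound_default_params("sparse"),
                                    repeats = 6, seed = 64)
  expect_lt(mean(eq$runs$per_fov_p <= 0.05), 0.5)
})

test_that("connected-component quantification is exact when cells never touch", {
  cell <- cell_model(9)
  # centres drawn with a wider exclusion zone so stamped disks cannot even
  # touch diagonally (disjoint disks sharing a corner would merge under
  # 8-connectivity)
  pts <- place_cells_nonoverlapping(12, cell_model(13), 128, 128, seed = 65)
  off <- circoast:::disk_offsets(cell$radius)
  cmask <- circoast:::stamp_disks(pts, off, 128L, 128L)
  q <- quantify_connected_components(cmask)
  expect_equal(q$count, nrow(pts))
  expect_equal(q$mean_area, nrow(off))
  expect_equal(effective_cell_model(rep(q$mean_area, q$count))$diameter,
               2 * sqrt(nrow(off) / pi), tolerance = 1e-12)
  # component-overlap measurement equals the per-cell overlap oracle
  net <- unit_network(seed = 66)$mask
  hits <- circoast:::component_hits(q$labels, net)
  for (t in seq_len(nrow(pts))) {
    lbl <- q$labels[pts[t, "y"] + 1L, pts[t, "x"] + 1L]
    expect_identical(hits[lbl],
                     oracle_disk_overlaps(net, pts[t, "x"], pts[t, "y"],
                                          cell$radius))
  }
})

test_that("miscount experiment wiring produces sane reports at small scale", {
  res <- miscount_experiment(n_groups = 4, images_per_group = 6,
                             density = 40, diameter = 10,
                             net_params = list(width = 128L, height = 128L,
                                               min_dist = 16,
                                               network_radius = 3,
                                               network_fraction = 0.25),
                             trials = 1e4, seed = 67)
  expect_equal(nrow(res$groups), 4)
  expect_gt(res$mean_miscount_fraction, 0.05)   # the density does merge cells
  expect_true(all(res$groups$naive_p > 0 & res$groups$naive_p <= 1))
  # merging biases the naive analysis toward enrichment
  expect_lt(mean(res$groups$naive_p), mean(res$groups$truth_p))
})

test_that("heterogeneous diameters are well approximated by the mean disk", {
  net <- unit_network(seed = 68)$mask
  deg <- heterogeneous_diameter_check(rep(10, 5), net, n = 60, trials = 800,
                                      seed = 69)
  se <- sqrt(stats::var(deg$icf$het) / 800 + stats::var(deg$icf$homo) / 800)
  expect_lt(deg$abs_difference, 4 * se)      # same model, MC noise only
  het <- heterogeneous_diameter_check(6:14, net, n = 60, trials = 1500,
                                      seed = 70)
  expect_lt(abs(het$effect_size), 0.5)       # close agreement, small effect
  # repeatable sign/magnitude across seeds
  reps <- vapply(1:5, function(s)
    heterogeneous_diameter_check(6:14, net, n = 60, trials = 800,
                                 seed = s)$mean_hetero, 0)
  expect_lt(max(reps) - min(reps), 0.02)
})
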