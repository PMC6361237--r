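#' Default parameter ranges for the randomized sweep
#'
#' Reconstructed defaults for 512 x 512 images: cell diameter 6-30 px, cell
#' number 50-300, network radius 2-10 px, pruning target network fraction
#' 0.05-0.6, seed-point minimum distance 15-40 px. Chosen to span the vessel
#' densities of vascularized tissues and the cell sizes resolvable at
#' typical magnifications.
#'
#' @return A list of ranges consumed by [run_parameter_sweep()].
#' @export
sweep_default_ranges <- function() {
  list(width = 512L, height = 512L,
       diameter = c(6, 30), cell_number = c(50L, 300L),
       network_radius = c(2, 10), network_fraction = c(0.05, 0.6),
       min_dist = c(15, 40))
}

#' Randomized parameter sweep of synthetic networks
#'
#' Generates `n_images` synthetic networks with parameters drawn uniformly
#' at random from `ranges`, computes each image's CDNF and the Monte Carlo
#' (MCMRP) mean ICF, and records the six system parameters per image. The
#' BMRP mean ICF equals the CDNF by construction and is recorded alongside.
#'
#' @param n_images Number of simulated experiments (>= 10).
#' @param trials_per_image MCMRP trials per image (>= 100).
#' @param ranges A list as returned by [sweep_default_ranges()].
#' @param seed Optional integer seed for the whole sweep.
#' @return A data.frame with one row per image: `diameter`, `cell_number`,
#'   `network_radius`, `network_fraction` (measured), `length_density`
#'   (measured on the pruned centreline), `cdnf`, `mcmrp_mean`, `mcmrp_sd`,
#'   `bmrp_mean`, `seed` (per-image subseed), `min_dist`, `target`; the
#'   recorded seed and parameters regenerate each network exactly.
#'   Infeasible draws are skipped with a message and redrawn.
#' @export
run_parameter_sweep <- function(n_images, trials_per_image = 2000,
                                ranges = sweep_default_ranges(), seed = NULL) {
  if (n_images < 10) stop("`n_images` must be >= 10")
  if (trials_per_image < 100) stop("`trials_per_image` must be >= 100")
  runif_in <- function(r) stats::runif(1, r[1], r[2])
  with_opt_seed(seed, {
    rows <- vector("list", n_images)
    i <- 1L
    while (i <= n_images) {
      diameter <- runif_in(ranges$diameter)
      n_cells <- sample(seq(ranges$cell_number[1], ranges$cell_number[2]), 1)
      radius <- runif_in(ranges$network_radius)
      target <- runif_in(ranges$network_fraction)
      min_dist <- runif_in(ranges$min_dist)
      sub <- sample.int(.Machine$integer.max, 1)
      rec <- tryCatch({
        net <- withCallingHandlers(
          generate_network(ranges$width, ranges$height, min_dist,
                           radius, target, "network_fraction", seed = sub),
          warning = function(w) invokeRestart("muffleWarning"))
        if (net$target_unreachable)
          stop(sprintf("target fraction %.3f above the achievable maximum", target))
        cell <- cell_model(diameter)
        dil <- dilate_network(net$mask, cell)
        cdnf <- sum(dil) / length(dil)
        icf <- icf_from_dilated(dil, n_cells, trials_per_image)
        data.frame(diameter = diameter, cell_number = n_cells,
                   network_radius = radius,
                   network_fraction = net$measured$network_fraction,
                   length_density = net$measured$length_density,
                   cdnf = cdnf, mcmrp_mean = icf$mean, mcmrp_sd = icf$sd,
                   bmrp_mean = cdnf, seed = sub,
                   min_dist = min_dist, target = target)
      }, error = function(e) {
        message(sprintf("sweep draw skipped (%s); redrawing", conditionMessage(e)))
        NULL
      })
      if (!is.null(rec)) {
        rows[[i]] <- rec
        i <- i + 1L
      }
    }
    do.call(rbind, rows)
  })
}

sweep_predictors <- c("diameter", "cell_number", "network_radius",
                      "network_fraction", "length_density", "cdnf")

#' Pearson correlation of each sweep parameter with the MCMRP mean ICF
#'
#' @param records A [run_parameter_sweep()] data.frame (>= 10 rows).
#' @param response Response column, default `"mcmrp_mean"`.
#' @return A data.frame with one row per parameter: `parameter`, `r`,
#'   `ci_lo`, `ci_hi` (Fisher-z 95% CI), `p`. Zero-variance parameters get
#'   NA and a `degenerate` flag.
#' @export
correlate_sweep <- function(records, response = "mcmrp_mean") {
  if (nrow(records) < 10) stop("need >= 10 records")
  y <- records[[response]]
  rows <- lapply(sweep_predictors, function(par) {
    x <- records[[par]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(parameter = par, r = NA, ci_lo = NA, ci_hi = NA,
                        p = NA, degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y)
    data.frame(parameter = par, r = unname(ct$estimate),
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               p = ct$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' z-scored multivariable linear regression on the sweep
#'
#' Ordinary least squares of the z-scored response on the six z-scored
#' system parameters with intercept, so all coefficients share one scale.
#' On the sweep, only the CDNF coefficient carries weight (~1) and the model
#' R^2 is ~1: the CDNF alone determines the random-placement mean ICF.
#'
#' @param records A [run_parameter_sweep()] data.frame.
#' @param response Response column, default `"mcmrp_mean"`.
#' @return An object of class `mvlr_summary`: list with `coefficients`
#'   (data.frame: term, estimate, se, statistic, p), `r_squared`,
#'   `f_statistic`, `f_p`, and the underlying `fit`. Errors with condition
#'   diagnostics on rank deficiency.
#' @export
zscore_mvlr <- function(records, response = "mcmrp_mean") {
  if (nrow(records) < length(sweep_predictors) + 2)
    stop("need at least predictors + 2 records")
  X <- as.data.frame(scale(records[, sweep_predictors]))
  if (anyNA(as.matrix(X))) stop("a predictor has zero variance; cannot z-score")
  X$.y <- as.numeric(scale(records[[response]]))
  fit <- stats::lm(.y ~ ., data = X)
  if (fit$rank < length(sweep_predictors) + 1L) {
    kappa_x <- kappa(stats::model.matrix(fit))
    stop(sprintf("rank-deficient design (rank %d of %d, condition number %.3g)",
                 fit$rank, length(sweep_predictors) + 1L, kappa_x))
  }
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "statistic", "p")
  co <- cbind(term = rownames(co), co, row.names = NULL)
  structure(list(coefficients = co,
                 r_squared = sm$r.squared,
                 f_statistic = unname(sm$fstatistic[1]),
                 f_p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                        sm$fstatistic[3], lower.tail = FALSE)),
                 fit = fit),
            class = "mvlr_summary")
}

#' @export
print.mvlr_summary <- function(x, ...) {
  cat(sprintf("<mvlr_summary> R^2 = %.6f, model F = %.4g (p = %.3g)\n",
              x$r_squared, x$f_statistic, x$f_p))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Bland-Altman agreement between two model predictions
#'
#' @param x,y Paired predictions (e.g. BMRP and MCMRP mean ICFs), >= 2 pairs.
#' @return A list with `mean_difference` (x - y), `lower`, `upper` (mean
#'   +/- 1.96 sd of the differences), `sd_difference` and the `differences`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) stop("need >= 2 pairs")
  d <- x - y
  m <- mean(d); s <- stats::sd(d)
  list(mean_difference = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       sd_difference = s, differences = d)
}

# one simulated study arm: synthetic networks + one random placement each,
# pooled into replicate-level CIRCOAST p-values and per-image records
simulate_group_arm <- function(n_replicates, images_per_replicate, params, cell) {
  reps <- vector("list", n_replicates)
  per_image <- list()
  for (r in seq_len(n_replicates)) {
    imgs <- vector("list", images_per_replicate)
    for (i in seq_len(images_per_replicate)) {
      net <- generate_network(params$width, params$height, params$min_dist,
                              params$network_radius, params$network_fraction)
      centers <- place_cells_uniform(params$n_cells, params$width, params$height)
      dil <- dilate_network(net$mask, cell)
      obs <- count_colocalized(centers, dil)
      imgs[[i]] <- list(cdnf = cdnf_value(sum(dil), length(dil)), obs = obs)
      per_image[[length(per_image) + 1L]] <- data.frame(
        replicate = r, c = obs$c, n = obs$n,
        centerline_px = net$measured$centerline_length)
    }
    reps[[r]] <- replicate_test(imgs, id = r)
  }
  list(p_values = vapply(reps, `[[`, 0, "p"),
       per_image = do.call(rbind, per_image),
       replicates = reps)
}

#' Density-confound false-positive experiment
#'
#' Two study groups differing in both cell count and network density, with
#' cells placed truly at random in every image: correct inference should
#' find no colocalization difference. Reports the three generic-statistic
#' t-test p-values (confounded by density) next to the 2-sample CIRCOAST p
#' (not confounded). With `repeats > 1`, whole-experiment repetitions give
#' rejection rates at `alpha`.
#'
#' @param n_replicates_per_group Biological replicates per group.
#' @param images_per_replicate Images per replicate.
#' @param dense,sparse Parameter lists for the two groups: `width`, `height`,
#'   `min_dist`, `network_radius`, `network_fraction`, `n_cells`, `diameter`.
#' @param repeats Number of independent repetitions (1 = single report).
#' @param alpha Rejection level for the rate summary.
#' @param permutations Permutations for the 2-sample test (`"exhaustive"`
#'   by default: group sizes are small).
#' @param seed Optional integer seed.
#' @return A list with `runs` (data.frame of per-repeat p-values: the three
#'   generic tests and CIRCOAST) and `rejection_rates` at `alpha`.
#' @export
density_confound_experiment <- function(n_replicates_per_group = 6,
                                        images_per_replicate = 1,
                                        dense = confound_default_params("dense"),
                                        sparse = confound_default_params("sparse"),
                                        repeats = 1, alpha = 0.05,
                                        permutations = "exhaustive",
                                        seed = NULL) {
  run_one <- function() {
    ga <- simulate_group_arm(n_replicates_per_group, images_per_replicate,
                             dense, cell_model(dense$diameter))
    gb <- simulate_group_arm(n_replicates_per_group, images_per_replicate,
                             sparse, cell_model(sparse$diameter))
    recs <- rbind(cbind(ga$per_image, group = "dense"),
                  cbind(gb$per_image, group = "sparse"))
    gen <- generic_group_stats(recs)
    cmp <- two_sample_circoast(ga$p_values, gb$p_values,
                               permutations = permutations)
    data.frame(per_fov_p = gen$tests$p[gen$tests$metric == "per_fov"],
               per_mm_p = gen$tests$p[gen$tests$metric == "per_mm"],
               fraction_p = gen$tests$p[gen$tests$metric == "fraction"],
               circoast_p = cmp$two_sample_p)
  }
  runs <- with_opt_seed(seed, do.call(rbind, lapply(seq_len(repeats),
                                                    function(i) run_one())))
  list(runs = runs,
       rejection_rates = colMeans(runs <= alpha),
       alpha = alpha, repeats = repeats, seed = seed)
}

#' Default parameters of the density-confound experiment groups
#'
#' "Dense" mimics healthy tissue (high cell and network density), "sparse"
#' the dropout of early diabetic retinopathy; densities differ by >= 2x.
#'
#' @param which `"dense"` or `"sparse"`.
#' @return A parameter list for [density_confound_experiment()].
#' @export
confound_default_params <- function(which = c("dense", "sparse")) {
  which <- match.arg(which)
  base <- list(width = 256L, height = 256L, min_dist = 20, network_radius = 3,
               diameter = 10)
  if (which == "dense") c(base, list(network_fraction = 0.35, n_cells = 120L))
  else c(base, list(network_fraction = 0.15, n_cells = 50L))
}

#' Miscount (connected-components quantification) experiment
#'
#' Cells are placed at random with overlap allowed (fully contained, so that
#' component areas are not clipped at the border) at a density high enough
#' that overlapping cells are frequently merged by connected-component
#' quantification. Each study group of images is then analyzed three ways:
#' (a) miscounted components with the true input diameter, (b) miscounted
#' components with the effective diameter recovered from the mean component
#' area (the mitigation), and (c) ground truth (true centres and diameter).
#' One-sample CIRCOAST p-values per group give false-positive rates at
#' `alpha`; only (a) should inflate them.
#'
#' @param n_groups Number of study groups (the false-positive unit).
#' @param images_per_group Images per group.
#' @param density Cells per image (chosen so cells overlap frequently).
#' @param diameter True cell diameter in pixels.
#' @param net_params Network parameter list (`width`, `height`, `min_dist`,
#'   `network_radius`, `network_fraction`).
#' @param trials Pseudo-null trials of the 1-sample test.
#' @param alpha Rejection level.
#' @param seed Optional integer seed.
#' @return A list with `groups` (per-group p-values under the three
#'   conditions), `false_positive_rates`, `mean_miscount_fraction` (share of
#'   cells lost to merging), `alpha`.
#' @export
miscount_experiment <- function(n_groups = 50, images_per_group = 20,
                                density = 50, diameter = 10,
                                net_params = list(width = 256L, height = 256L,
                                                  min_dist = 20,
                                                  network_radius = 3,
                                                  network_fraction = 0.25),
                                trials = 2e4, alpha = 0.05, seed = NULL) {
  cell_true <- cell_model(diameter)
  margin <- floor(cell_true$radius)
  off <- disk_offsets(cell_true$radius)
  run <- function() {
    rows <- vector("list", n_groups)
    miscount <- numeric(0)
    for (g in seq_len(n_groups)) {
      net <- generate_network(net_params$width, net_params$height,
                              net_params$min_dist, net_params$network_radius,
                              net_params$network_fraction)
      img_p <- matrix(NA_real_, images_per_group, 3,
                      dimnames = list(NULL, c("naive", "mitigated", "truth")))
      for (i in seq_len(images_per_group)) {
        w <- net_params$width; h <- net_params$height
        centers <- cbind(
          x = sample(seq.int(margin, w - 1L - margin), density, replace = TRUE),
          y = sample(seq.int(margin, h - 1L - margin), density, replace = TRUE))
        cmask <- stamp_disks(centers, off, h, w)
        q <- quantify_connected_components(cmask)
        miscount <- c(miscount, 1 - q$count / density)
        # a quantified object colocalizes iff its pixels touch the network
        comp_hit <- component_hits(q$labels, net$mask)
        obs_q <- coloc_observation(q$count, sum(comp_hit))
        cell_eff <- effective_cell_model(tabulate(q$labels[q$labels > 0]))
        img_p[i, "naive"] <- interior_image_p(net$mask, cell_true, obs_q, margin)
        img_p[i, "mitigated"] <- interior_image_p(net$mask, cell_eff, obs_q, margin)
        dil_true <- dilate_network(net$mask, cell_true)
        obs_t <- count_colocalized(centers, dil_true)
        img_p[i, "truth"] <- interior_image_p(net$mask, cell_true, obs_t, margin)
      }
      rows[[g]] <- data.frame(
        group = g,
        naive_p = one_sample_circoast(img_p[, "naive"], trials)$one_sample_p,
        mitigated_p = one_sample_circoast(img_p[, "mitigated"], trials)$one_sample_p,
        truth_p = one_sample_circoast(img_p[, "truth"], trials)$one_sample_p)
    }
    list(groups = do.call(rbind, rows), miscount = miscount)
  }
  out <- with_opt_seed(seed, run())
  fp <- colMeans(out$groups[, c("naive_p", "mitigated_p", "truth_p")] <= alpha)
  list(groups = out$groups, false_positive_rates = fp,
       mean_miscount_fraction = mean(out$miscount), alpha = alpha, seed = seed)
}

# stamp pixelated disks onto an empty canvas
stamp_disks <- function(centers, off, h, w) {
  m <- matrix(FALSE, h, w)
  for (t in seq_len(nrow(centers))) {
    rr <- centers[t, "y"] + off[, "dr"] + 1L
    cc <- centers[t, "x"] + off[, "dc"] + 1L
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    m[cbind(rr[ok], cc[ok])] <- TRUE
  }
  binary_mask(m)
}

# which labelled components share >= 1 pixel with the network mask
component_hits <- function(labels, network) {
  hit <- labels[as_mask(network) & labels > 0]
  seq_len(max(labels)) %in% unique(hit)
}

# CIRCOAST p with centres restricted to the interior margin (fully
# contained cells): the CDNF is evaluated over the admissible centre region
interior_image_p <- function(network, cell, obs, margin) {
  dil <- dilate_network(network, cell)
  h <- nrow(dil); w <- ncol(dil)
  interior <- dil[(margin + 1L):(h - margin), (margin + 1L):(w - margin)]
  circoast_image_p(obs, cdnf_value(sum(interior), length(interior)))
}

#' Heterogeneous-diameter approximation check
#'
#' Compares the MCMRP mean ICF when each cell samples its own diameter from
#' a distribution against the single mean-diameter disk model. The two are
#' not identical (CDNF is not linear in diameter) but agree closely, with
#' negligible standardized effect size.
#'
#' @param diameters Integer support of the diameter distribution (sampled
#'   uniformly), or a vector to sample from.
#' @param network A `binary_mask` of the network.
#' @param n Cells per trial.
#' @param trials Monte Carlo trials per arm.
#' @param seed Optional integer seed.
#' @return A list with `mean_hetero`, `mean_homo`, `abs_difference`,
#'   `effect_size` (Cohen's d against the pooled ICF spread) and the two
#'   `icf` sample vectors.
#' @export
heterogeneous_diameter_check <- function(diameters, network, n = 100,
                                         trials = 2000, seed = NULL) {
  network <- as_mask(network)
  run <- function() {
    uniq <- sort(unique(as.integer(diameters)))
    dils <- lapply(uniq, function(d) dilate_network(network, cell_model(d)))
    npx <- length(network)
    het <- vapply(seq_len(trials), function(t) {
      ds <- sample(seq_along(uniq), n, replace = TRUE,
                   prob = tabulate(match(as.integer(diameters), uniq)))
      idx <- sample.int(npx, n, replace = TRUE)
      mean(vapply(seq_len(n), function(i) dils[[ds[i]]][idx[i]], TRUE))
    }, 0)
    mean_d <- mean(diameters)
    homo <- icf_from_dilated(dilate_network(network, cell_model(mean_d)),
                             n, trials)$samples
    list(het = het, homo = homo)
  }
  res <- with_opt_seed(seed, run())
  pooled_sd <- sqrt((stats::var(res$het) + stats::var(res$homo)) / 2)
  diff <- mean(res$het) - mean(res$homo)
  list(mean_hetero = mean(res$het), mean_homo = mean(res$homo),
       abs_difference = abs(diff),
       effect_size = if (pooled_sd > 0) diff / pooled_sd else 0,
       icf = res)
}
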