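#' Generate a synthetic study fixture on disk
#'
#' Builds a directory of synthetic network masks (plain-text PBM), centroid
#' CSVs and a manifest CSV, standing in for a microscopy study. Cells are
#' placed uniformly at random; with `enrichment > 0`, that fraction of the
#' cells is forced onto the cell-dilated network (the known ground-truth
#' colocalization excess), so `enrichment = 0` is an exact null fixture and
#' `enrichment = 1` puts every cell on the network.
#'
#' @param dir Output directory (created if missing).
#' @param kind `"image-set"` (one group) or `"confound"` (dense + sparse
#'   groups as in [confound_default_params()]).
#' @param n_replicates Replicates per group.
#' @param images_per_replicate Images per replicate.
#' @param n_cells Cells per image.
#' @param diameter Cell diameter in pixels.
#' @param enrichment Fraction of cells forced onto the dilated network.
#' @param net_params Network generator parameters (`width`, `height`,
#'   `min_dist`, `network_radius`, `network_fraction`).
#' @param seed Optional integer seed.
#' @return The manifest path, invisibly; attribute `manifest` holds the
#'   manifest data.frame, attribute `truth` the per-image (n, c) used.
#' @export
make_fixture <- function(dir, kind = c("image-set", "confound"),
                         n_replicates = 2, images_per_replicate = 2,
                         n_cells = 60, diameter = 10, enrichment = 0,
                         net_params = list(width = 128L, height = 128L,
                                           min_dist = 16, network_radius = 2,
                                           network_fraction = 0.2),
                         seed = NULL) {
  kind <- match.arg(kind)
  if (enrichment < 0 || enrichment > 1) stop("`enrichment` must be in [0, 1]")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- if (kind == "image-set") list(g1 = net_params)
            else list(dense = utils::modifyList(net_params,
                                                list(network_fraction = 0.35,
                                                     network_radius = 3)),
                      sparse = utils::modifyList(net_params,
                                                 list(network_fraction = 0.12)))
  cell <- cell_model(diameter)
  build <- function() {
    rows <- list(); truth <- list()
    for (gname in names(groups)) {
      gp <- groups[[gname]]
      for (r in seq_len(n_replicates)) {
        for (i in seq_len(images_per_replicate)) {
          net <- generate_network(gp$width, gp$height, gp$min_dist,
                                  gp$network_radius, gp$network_fraction)
          dil <- dilate_network(net$mask, cell)
          centers <- place_cells_uniform(n_cells, gp$width, gp$height)
          n_forced <- round(enrichment * n_cells)
          if (n_forced > 0 && any(dil)) {
            on_net <- which(dil) # linear indices (column-major)
            pick <- on_net[sample.int(length(on_net), n_forced, replace = TRUE)]
            centers[seq_len(n_forced), "y"] <- (pick - 1L) %% nrow(dil)
            centers[seq_len(n_forced), "x"] <- (pick - 1L) %/% nrow(dil)
          }
          stem <- sprintf("%s_rep%d_img%d", gname, r, i)
          img_path <- file.path(dir, paste0(stem, "_network.pbm"))
          cel_path <- file.path(dir, paste0(stem, "_cells.csv"))
          write_mask_pbm(net$mask, img_path)
          utils::write.csv(as.data.frame(centers), cel_path, row.names = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            group = gname, replicate = as.character(r),
            image_path = basename(img_path),
            cells_path_or_count = basename(cel_path), threshold = 0.5)
          obs <- count_colocalized(centers, dil)
          truth[[length(truth) + 1L]] <- data.frame(
            group = gname, replicate = r, image = i, n = obs$n, c = obs$c,
            cdnf = mean(dil))
        }
      }
    }
    list(manifest = do.call(rbind, rows), truth = do.call(rbind, truth))
  }
  out <- with_opt_seed(seed, build())
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(out$manifest, manifest_path, row.names = FALSE)
  res <- invisible(manifest_path)
  attr(res, "manifest") <- out$manifest
  attr(res, "truth") <- out$truth
  res
}

#' Run the replicate-pooled CIRCOAST analysis over a manifest
#'
#' Reads every image of a manifest (PBM or PNG network masks; centroid CSVs
#' or bare cell counts are accepted, but a cell count alone cannot supply an
#' observed colocalized count and is rejected), pools images per replicate
#' and returns replicate p-values per group.
#'
#' @param manifest_path Path to a manifest CSV (see [read_manifest()]).
#' @param cell A `cell_model` or bare diameter.
#' @return A list per group of [replicate_test()] results, plus a `p_values`
#'   list mapping group -> replicate p vector.
#' @export
analyze_manifest <- function(manifest_path, cell) {
  mf <- read_manifest(manifest_path)
  out <- list()
  for (gname in unique(mf$group)) {
    sub <- mf[mf$group == gname, ]
    reps <- list()
    for (r in unique(sub$replicate)) {
      rows <- sub[sub$replicate == r, ]
      imgs <- lapply(seq_len(nrow(rows)), function(i) {
        path <- rows$image_path[i]
        net <- if (grepl("\\.pbm$", path)) read_mask_pbm(path)
               else read_mask_png(path, threshold = rows$threshold[i])
        cells <- rows$cells_path_or_count[i]
        if (suppressWarnings(!is.na(as.numeric(cells))))
          stop("a bare cell count cannot supply an observed colocalized count; ",
               "provide a centroid CSV")
        list(network = net, centers = read_centroids_csv(cells))
      })
      reps[[r]] <- replicate_test(imgs, cell = cell, id = paste0(gname, "/", r))
    }
    out[[gname]] <- reps
  }
  list(replicates = out,
       p_values = lapply(out, function(g) vapply(g, `[[`, 0, "p")))
}
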