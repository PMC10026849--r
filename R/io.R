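# File formats: point patterns and vessel segments as documented CSV,
# masks as multi-page TIFF, grids as TSV matrices, metadata as YAML sidecars.
# Conventions used everywhere: coordinates in micrometers with the lesion
# center at the origin and y increasing upward; rasters indexed (row, col)
# with row 1 at the top.

#' Write a list of point patterns to CSV
#'
#' Header: `x_um, y_um, z_um, group, animal, section`. Patterns without a z
#' column are written with z 0.
#'
#' @param patterns list of [point_pattern()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_point_patterns <- function(patterns, path) {
  rows <- lapply(patterns, function(p) {
    z <- if ("z_um" %in% colnames(p$coords)) p$coords[, "z_um"] else 0
    data.frame(x_um = p$coords[, "x_um"], y_um = p$coords[, "y_um"], z_um = z,
               group = p$group, animal = p$animal, section = p$section)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read point patterns from CSV
#'
#' Inverse of [write_point_patterns()]: one [point_pattern()] per unique
#' (group, animal, section) combination, in file order.
#'
#' @param path CSV path with the documented header.
#' @return List of [point_pattern()].
#' @export
read_point_patterns <- function(path) {
  d <- utils::read.csv(path)
  key <- interaction(d$group, d$animal, d$section, drop = TRUE, lex.order = TRUE)
  lapply(split(d, key), function(s)
    point_pattern(as.matrix(s[, c("x_um", "y_um", "z_um")]),
                  group = s$group[1], animal = s$animal[1], section = s$section[1]))
}

#' Write a vessel graph as a segment-per-row CSV
#'
#' Header: `x1_um, y1_um, z1_um, x2_um, y2_um, z2_um, radius_um` (z and
#' radius 0 when absent).
#'
#' @param vessels a [vessel_graph()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_vessel_csv <- function(vessels, path) {
  gz <- function(m) if (ncol(m) >= 3) m[, 3] else 0
  p1 <- vessels$nodes[vessels$segments[, 1], , drop = FALSE]
  p2 <- vessels$nodes[vessels$segments[, 2], , drop = FALSE]
  utils::write.csv(data.frame(
    x1_um = p1[, 1], y1_um = p1[, 2], z1_um = gz(p1),
    x2_um = p2[, 1], y2_um = p2[, 2], z2_um = gz(p2),
    radius_um = vessels$radius %||% 0), path, row.names = FALSE)
  invisible(path)
}

#' Read a vessel graph from a segment-per-row CSV
#'
#' @param path CSV with the [write_vessel_csv()] header.
#' @return A [vessel_graph()] (endpoint nodes are deduplicated).
#' @export
read_vessel_csv <- function(path) {
  d <- utils::read.csv(path)
  pts <- rbind(as.matrix(d[, c("x1_um", "y1_um", "z1_um")]),
               as.matrix(d[, c("x2_um", "y2_um", "z2_um")]))
  key <- apply(pts, 1, paste, collapse = "|")
  nodes <- pts[!duplicated(key), , drop = FALSE]
  idx <- match(key, key[!duplicated(key)])
  n <- nrow(d)
  colnames(nodes) <- c("x_um", "y_um", "z_um")
  vessel_graph(nodes, cbind(idx[seq_len(n)], idx[n + seq_len(n)]),
               radius = if (any(d$radius_um > 0)) d$radius_um else NULL)
}

#' Write a voxel mask as a multi-page TIFF with a YAML sidecar
#'
#' Each z-slice becomes one page; the voxel size is stored in
#' `<path>.meta.yaml` together with any extra metadata supplied.
#'
#' @param mask a [voxel_mask()].
#' @param path output TIFF path.
#' @param extra named list merged into the sidecar.
#' @return The path, invisibly.
#' @export
write_mask_tiff <- function(mask, path, extra = list()) {
  m <- mask$mask * 1
  if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1)
  pages <- lapply(seq_len(dim(m)[3]), function(k) m[, , k])
  tiff::writeTIFF(pages, path)
  yaml::write_yaml(c(list(voxel_size_um = mask$voxel_size_um,
                          shape = dim(mask$mask)), extra),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a voxel mask written by [write_mask_tiff()]
#'
#' @param path TIFF path (expects the `.meta.yaml` sidecar next to it).
#' @return A [voxel_mask()].
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  arr <- array(arr >= 0.5, dim = unlist(meta$shape))
  voxel_mask(arr, unlist(meta$voxel_size_um))
}

#' Write a p-value map as TSV matrices with a YAML sidecar
#'
#' Writes `<stem>_delta.tsv`, `<stem>_p.tsv` and `<stem>_mask_<dir>.tsv`
#' (node grids as ny x nx matrices, row 1 = top / maximal y) plus
#' `<stem>.meta.yaml` with grid ranges, spacing, k, permutation count and
#' mode.
#'
#' @param pvmap a [density_pvalue_map()] result.
#' @param stem output path stem.
#' @return The stem, invisibly.
#' @export
write_pvalue_map <- function(pvmap, stem) {
  g <- pvmap$grid
  as_grid <- function(v) {
    m <- matrix(v, nrow = g$ny, ncol = g$nx, byrow = TRUE)
    m[rev(seq_len(g$ny)), , drop = FALSE]      # row 1 = maximal y
  }
  wr <- function(v, suffix)
    utils::write.table(as_grid(v), paste0(stem, suffix), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  wr(pvmap$delta, "_delta.tsv")
  wr(pvmap$p, "_p.tsv")
  wr(pvmap$mask_B_gt_A * 1, "_mask_B_gt_A.tsv")
  wr(pvmap$mask_A_gt_B * 1, "_mask_A_gt_B.tsv")
  yaml::write_yaml(list(x_range = g$x_range, y_range = g$y_range,
                        spacing = g$spacing, k = pvmap$k, alpha = pvmap$alpha,
                        B_perm = pvmap$B_perm,
                        mode = if (pvmap$exhaustive) "exhaustive" else "sampled",
                        unit = pvmap$unit),
                   paste0(stem, ".meta.yaml"))
  invisible(stem)
}
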