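#' Labeled cell point pattern in lesion-centered coordinates
#'
#' A set of cell positions from one tissue section, in micrometers, with the
#' lesion center at the origin. Coordinates are stored as a numeric matrix
#' with columns `x_um`, `y_um` and optionally `z_um`; the z axis is carried
#' through but ignored by the 2D analyses (sections are thin slabs).
#'
#' @param coords numeric matrix or data frame with columns `x_um`, `y_um`
#'   and optionally `z_um` (micrometers, lesion-centered).
#' @param group group label (e.g. `"A"`/`"B"` or a diet/treatment label).
#' @param animal animal identifier.
#' @param section section identifier.
#' @return An object of class `point_pattern`.
#' @export
point_pattern <- function(coords, group = "A", animal = "a1", section = "s1") {
  coords <- as.matrix(coords)
  if (is.null(colnames(coords)))
    colnames(coords) <- c("x_um", "y_um", "z_um")[seq_len(ncol(coords))]
  if (!all(c("x_um", "y_um") %in% colnames(coords)))
    stop("point_pattern coordinates need columns 'x_um' and 'y_um'")
  storage.mode(coords) <- "double"
  rownames(coords) <- NULL
  if (nrow(coords) > 0 && !all(is.finite(coords)))
    stop("point_pattern coordinates must be finite")
  structure(
    list(coords = coords, group = as.character(group),
         animal = as.character(animal), section = as.character(section)),
    class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d cells (group=%s, animal=%s, section=%s)\n",
              nrow(x$coords), x$group, x$animal, x$section))
  invisible(x)
}

n_cells <- function(p) nrow(p$coords)

#' Regular 2D analysis grid
#'
#' Defines the lattice of query positions for density mapping. Nodes include
#' both range endpoints on each axis.
#'
#' @param x_range,y_range numeric length-2, grid extent in micrometers.
#' @param spacing node spacing in micrometers.
#' @return Object of class `grid_spec` with precomputed node coordinates.
#' @export
grid_spec <- function(x_range = c(-1000, 1000), y_range = c(-1000, 1000),
                      spacing = 50) {
  if (spacing <= 0) stop("grid spacing must be > 0")
  if (diff(range(x_range)) <= 0 || diff(range(y_range)) <= 0)
    stop("grid ranges must be non-degenerate")
  xs <- seq(x_range[1], x_range[2], by = spacing)
  ys <- seq(y_range[1], y_range[2], by = spacing)
  nodes <- cbind(x_um = rep(xs, times = length(ys)),
                 y_um = rep(ys, each = length(xs)))
  structure(list(x_range = x_range, y_range = y_range, spacing = spacing,
                 xs = xs, ys = ys, nodes = nodes,
                 nx = length(xs), ny = length(ys)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d nodes, spacing %g um\n", x$nx, x$ny, x$spacing))
  invisible(x)
}

#' Vessel centerline graph
#'
#' Polyline representation of a vascular network: nodes are centerline points,
#' segments join node pairs with an optional radius. Total centerline length
#' and junction count (nodes of degree >= 3) are derived on construction.
#'
#' @param nodes numeric matrix of node coordinates (columns x, y, optionally z),
#'   micrometers.
#' @param segments two-column integer matrix of node index pairs.
#' @param radius optional per-segment radius in micrometers.
#' @return Object of class `vessel_graph` with `total_length_um` and
#'   `junction_count` fields.
#' @export
vessel_graph <- function(nodes, segments, radius = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  segments <- matrix(as.integer(as.matrix(segments)), ncol = 2)
  if (nrow(segments) == 0) stop("vessel_graph needs at least one segment")
  if (max(segments) > nrow(nodes) || min(segments) < 1)
    stop("segment endpoints must index existing nodes")
  p1 <- nodes[segments[, 1], , drop = FALSE]
  p2 <- nodes[segments[, 2], , drop = FALSE]
  seg_len <- sqrt(rowSums((p2 - p1)^2))
  if (any(seg_len <= 0)) stop("zero-length vessel segments are not allowed")
  degree <- tabulate(c(segments), nbins = nrow(nodes))
  structure(list(nodes = nodes, segments = segments, radius = radius,
                 segment_length_um = seg_len,
                 total_length_um = sum(seg_len),
                 junction_count = sum(degree >= 3)),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("vessel_graph: %d nodes, %d segments, length %.1f um, %d junctions\n",
              nrow(x$nodes), nrow(x$segments), x$total_length_um, x$junction_count))
  invisible(x)
}

#' Per-fiber electron-microscopy measurements
#'
#' Axon and fiber (axon + myelin) outer diameters per myelinated fiber, in
#' micrometers. Records violating 0 < axon <= fiber are rejected at
#' construction and reported via the `rejected` attribute.
#'
#' @param axon_diameter_um,fiber_diameter_um numeric vectors, micrometers.
#' @param group optional group label(s).
#' @return Object of class `fiber_set` (a data frame).
#' @export
fiber_set <- function(axon_diameter_um, fiber_diameter_um, group = "A") {
  d <- data.frame(axon_diameter_um = as.numeric(axon_diameter_um),
                  fiber_diameter_um = as.numeric(fiber_diameter_um),
                  group = rep_len(as.character(group),
                                  length(axon_diameter_um)))
  bad <- !(d$axon_diameter_um > 0 & d$axon_diameter_um <= d$fiber_diameter_um)
  rejected <- d[bad, , drop = FALSE]
  d <- d[!bad, , drop = FALSE]
  structure(d, class = c("fiber_set", "data.frame"), rejected = rejected)
}

#' Per-animal serial-section lesion areas
#'
#' Sparse lesion cross-section areas (typically 3-5 sections of 40 um
#' thickness) used to bootstrap a full-lesion volume distribution.
#'
#' @param areas_um2 numeric vector of lesion areas, square micrometers.
#' @param animal,group identifiers.
#' @param section_thickness_um section thickness (default 40 um).
#' @param target_sections number of sections spanning the full lesion in a
#'   bootstrap replicate (default 25, i.e. a 1 mm span at 40 um).
#' @return Object of class `section_area_set`.
#' @export
section_area_set <- function(areas_um2, animal = "a1", group = "A",
                             section_thickness_um = 40, target_sections = 25) {
  areas_um2 <- as.numeric(areas_um2)
  if (length(areas_um2) < 1) stop("section_area_set needs at least one area")
  if (any(areas_um2 < 0)) stop("lesion areas must be >= 0")
  if (section_thickness_um <= 0) stop("section thickness must be > 0")
  structure(list(areas_um2 = areas_um2, animal = as.character(animal),
                 group = as.character(group),
                 section_thickness_um = section_thickness_um,
                 target_sections = as.integer(target_sections)),
            class = "section_area_set")
}

#' Binary voxel mask with physical voxel size
#'
#' @param mask logical (or 0/1) 2D or 3D array.
#' @param voxel_size_um numeric, per-axis voxel edge length in micrometers
#'   (recycled to the array dimensionality).
#' @return Object of class `voxel_mask`.
#' @export
voxel_mask <- function(mask, voxel_size_um = 1) {
  mask <- array(as.logical(mask), dim = dim(mask) %||% length(mask))
  nd <- length(dim(mask))
  voxel_size_um <- rep_len(as.numeric(voxel_size_um), nd)
  if (any(voxel_size_um <= 0)) stop("voxel size must be > 0")
  structure(list(mask = mask, voxel_size_um = voxel_size_um), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %s, %d foreground voxels, voxel %s um\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              paste(x$voxel_size_um, collapse = "x")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
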