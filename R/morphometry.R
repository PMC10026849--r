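# EM g-ratio statistics, raster vessel-network morphometry, voxel
# colocalization, particle-filtered object measurement and radial profiles.

#' g-ratio statistics of a fiber set
#'
#' The g-ratio of a myelinated fiber is the axon diameter divided by the
#' total fiber (axon + myelin) diameter; higher values mean thinner myelin.
#' Myelin thickness is (fiber - axon) / 2. Records rejected at construction
#' (axon > fiber) are reported via `n_rejected`.
#'
#' @param fibers a [fiber_set()].
#' @return List with `mean_g`, `sem_g`, `n`, `n_rejected`, and `table`
#'   (per-fiber axon diameter, fiber diameter, g, myelin thickness — the
#'   axon-diameter-versus-g scatter pairs).
#' @export
gratio_stats <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  if (nrow(fibers) == 0) stop("fiber set is empty")
  g <- fibers$axon_diameter_um / fibers$fiber_diameter_um
  tab <- data.frame(axon_diameter_um = fibers$axon_diameter_um,
                    fiber_diameter_um = fibers$fiber_diameter_um,
                    g = g,
                    myelin_thickness_um =
                      (fibers$fiber_diameter_um - fibers$axon_diameter_um) / 2,
                    group = fibers$group)
  list(mean_g = mean(g), sem_g = stats::sd(g) / sqrt(length(g)),
       n = length(g), n_rejected = nrow(attr(fibers, "rejected") %||% data.frame()),
       table = tab)
}

#' Convert cross-sectional areas to equivalent-circle diameters
#'
#' For measurements reported as areas rather than diameters:
#' `d = 2 * sqrt(area / pi)`.
#'
#' @param area_um2 numeric vector of areas.
#' @return Equivalent diameters in micrometers.
#' @export
equivalent_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Vessel-network length and junction count from a grayscale raster
#'
#' Mirrors the measurement semantics of an AngioTool-style analysis at its
#' stated settings: threshold the image to `intensity_range`, band-pass the
#' foreground to vessel widths within `diameter_range` pixels (morphological
#' opening at the lower bound removes sub-minimum structures; the opening at
#' the upper bound is subtracted to remove super-maximum cores), drop
#' connected components below `min_component` pixels, skeletonize, and
#' measure skeleton length (diagonal steps count sqrt(2) pixel pitches) and
#' junction zones (skeleton pixels with >= 3 skeleton neighbors, merged by
#' 8-connectivity so a thick branch point counts once).
#'
#' @param image numeric matrix of intensities (e.g. 0-255).
#' @param intensity_range inclusive foreground intensity band, default
#'   c(40, 255).
#' @param min_component minimum connected-component size in pixels, default
#'   10000 (the published particle filter; scale to the image at hand).
#' @param diameter_range vessel width band in pixels, default c(5, 40);
#'   NULL disables the band-pass.
#' @param pixel_size_um physical pixel pitch, default 1.
#' @return List with `total_length_um`, `junction_count`, and the
#'   intermediate `skeleton` mask. Empty foreground after filtering returns
#'   zero metrics with a warning.
#' @export
vessel_raster_metrics <- function(image, intensity_range = c(40, 255),
                                  min_component = 10000,
                                  diameter_range = c(5, 40),
                                  pixel_size_um = 1) {
  if (length(dim(image)) != 2) stop("expected a 2D raster")
  mask <- image >= intensity_range[1] & image <= intensity_range[2]
  if (!is.null(diameter_range)) {
    r_lo <- max(1, floor(diameter_range[1] / 2))
    lo_brush <- EBImage::makeBrush(2 * r_lo + 1, shape = "disc")
    kept <- EBImage::opening(mask * 1, lo_brush) > 0
    r_hi <- ceiling(diameter_range[2] / 2) + 1
    hi_brush <- EBImage::makeBrush(2 * r_hi + 1, shape = "disc")
    wide <- EBImage::opening(mask * 1, hi_brush) > 0
    mask <- kept & !wide
  }
  if (any(mask)) mask <- filter_small_components(mask, min_component)
  if (!any(mask)) {
    warning("no vessel foreground after filtering")
    return(list(total_length_um = 0, junction_count = 0L,
                skeleton = mask & FALSE))
  }
  skel <- skeletonize(mask)
  list(total_length_um = skeleton_length(skel, pixel_size_um),
       junction_count = skeleton_junctions(skel),
       skeleton = skel)
}

#' Render a polyline vessel network into a binary raster
#'
#' Draws each segment as a tube of the given diameter on a pixel grid, for
#' validating raster morphometry against a known centerline ground truth.
#'
#' @param vessels a [vessel_graph()] (x,y in micrometers).
#' @param extent c(xmin, xmax, ymin, ymax) of the raster, micrometers.
#' @param pixel_size_um pixel pitch.
#' @param diameter_um tube diameter.
#' @param intensity foreground intensity value, default 255.
#' @return Numeric matrix (rows = y, cols = x) with background 0.
#' @export
render_vessel_raster <- function(vessels, extent, pixel_size_um = 1,
                                 diameter_um = 8, intensity = 255) {
  xs <- seq(extent[1] + pixel_size_um / 2, extent[2], by = pixel_size_um)
  ys <- seq(extent[3] + pixel_size_um / 2, extent[4], by = pixel_size_um)
  px <- cbind(x_um = rep(xs, times = length(ys)),
              y_um = rep(ys, each = length(xs)))
  d <- nearest_vessel_distances(point_pattern(px), vessels)$distance_um
  img <- matrix(0, nrow = length(ys), ncol = length(xs))
  img[matrix(d <= diameter_um / 2, nrow = length(ys), byrow = TRUE)] <- intensity
  img
}

#' Vessel volume from a voxel mask with small-particle suppression
#'
#' Removes 26-connected components with physical volume below `min_particle`
#' cubic micrometers (background interference), then returns the surviving
#' voxel count times the voxel volume.
#'
#' @param mask a [voxel_mask()].
#' @param min_particle_um3 particle-volume cutoff, default 30.
#' @return Volume in cubic micrometers.
#' @export
vessel_volume_from_mask <- function(mask, min_particle_um3 = 30) {
  stopifnot(inherits(mask, "voxel_mask"))
  voxvol <- prod(mask$voxel_size_um)
  min_vox <- min_particle_um3 / voxvol
  kept <- filter_small_components(mask$mask, min_vox)
  sum(kept) * voxvol
}

#' Percentage of a marker mask colocalizing with a reference (vessel) mask
#'
#' `100 * |marker AND vessel| / |marker|`: the denominator is always the
#' marker, so the measure is asymmetric by design. An empty marker yields an
#' undefined (NA) percentage with `defined = FALSE`.
#'
#' @param marker,vessel [voxel_mask()]s of identical shape and voxel size.
#' @return List with `percent`, `n_marker`, `n_overlap`, `defined`.
#' @export
colocalization_percent <- function(marker, vessel) {
  stopifnot(inherits(marker, "voxel_mask"), inherits(vessel, "voxel_mask"))
  if (!identical(dim(marker$mask), dim(vessel$mask)))
    stop("marker and vessel masks must have identical shapes")
  if (!isTRUE(all.equal(marker$voxel_size_um, vessel$voxel_size_um)))
    stop("marker and vessel masks must share one voxel size")
  n_marker <- sum(marker$mask)
  n_overlap <- sum(marker$mask & vessel$mask)
  list(percent = if (n_marker) 100 * n_overlap / n_marker else NA_real_,
       n_marker = n_marker, n_overlap = n_overlap, defined = n_marker > 0)
}

#' Per-object sizes of a mask after a voxel-count particle filter
#'
#' Labels connected components (26-connectivity in 3D, 8 in 2D), drops
#' objects below `min_voxels`, and tabulates per-object voxel counts and
#' physical sizes (cell-area/volume measurements after background
#' suppression).
#'
#' @param mask a [voxel_mask()].
#' @param min_voxels voxel-count cutoff, default 800.
#' @return Data frame with `object`, `n_voxels`, `size_um` (physical volume
#'   in um^3, or area in um^2 for 2D masks); empty if nothing survives.
#' @export
object_areas <- function(mask, min_voxels = 800) {
  stopifnot(inherits(mask, "voxel_mask"))
  labels <- label_components(mask$mask)
  voxvol <- prod(mask$voxel_size_um)
  if (max(labels) == 0L)
    return(data.frame(object = integer(0), n_voxels = integer(0),
                      size_um = numeric(0)))
  sz <- component_sizes(labels)
  keep <- sz >= min_voxels
  data.frame(object = seq_len(sum(keep)),
             n_voxels = as.integer(unname(sz[keep])),
             size_um = unname(sz[keep]) * voxvol)
}

#' Radial mean-intensity profile around a center point
#'
#' Assigns pixels to half-open radial annuli `[0,w), [w,2w), ...` around the
#' center and reports the mean intensity and pixel count per annulus
#' (peri-infarct marker intensity as a function of distance from the stroke
#' core). Empty annuli get NA intensity; annuli extending beyond the image
#' are flagged truncated.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param center (x, y) in physical units with the pixel grid starting at
#'   pixel centers `pixel_size/2`.
#' @param bin_width_um annulus width.
#' @param max_radius_um outermost radius.
#' @param pixel_size_um pixel pitch, default 1.
#' @return Data frame with `r_lo_um`, `r_hi_um`, `mean_intensity`,
#'   `n_pixels`, `truncated`.
#' @export
radial_intensity_profile <- function(image, center, bin_width_um,
                                     max_radius_um, pixel_size_um = 1) {
  if (length(dim(image)) != 2) stop("expected a 2D raster")
  nr <- nrow(image); nc <- ncol(image)
  xs <- (seq_len(nc) - 0.5) * pixel_size_um
  ys <- (seq_len(nr) - 0.5) * pixel_size_um
  if (center[1] < 0 || center[1] > nc * pixel_size_um ||
      center[2] < 0 || center[2] > nr * pixel_size_um)
    stop("center must lie inside the image")
  r <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, "+"))
  edges <- seq(0, max_radius_um, by = bin_width_um)
  if (edges[length(edges)] < max_radius_um) edges <- c(edges, max_radius_um)
  max_r_img <- max(r)
  out <- lapply(seq_len(length(edges) - 1), function(i) {
    sel <- r >= edges[i] & r < edges[i + 1]
    data.frame(r_lo_um = edges[i], r_hi_um = edges[i + 1],
               mean_intensity = if (any(sel)) mean(image[sel]) else NA_real_,
               n_pixels = sum(sel),
               truncated = edges[i + 1] > max_r_img)
  })
  do.call(rbind, out)
}
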