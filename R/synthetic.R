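# Synthetic-data generators. Every generator is a pure function of its
# parameters plus a seed, and emits ground truth alongside the data so all
# downstream analyses can be validated without any external download.

#' Derive a reproducible per-generator seed from one global seed
#'
#' Each generator draws from its own substream so that adding a generator to
#' a pipeline run never perturbs the streams of existing ones. The substream
#' seed is `(seed + 1000 * offset) mod (2^31 - 1)` with a fixed per-stream
#' offset registry.
#'
#' @param seed integer global seed.
#' @param stream one of `"cohort"`, `"vessels"`, `"opc"`, `"fibers"`,
#'   `"areas"`, `"masks"`, `"summaries"`.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stream) {
  offsets <- c(cohort = 101, vessels = 211, opc = 307, fibers = 401,
               areas = 503, masks = 601, summaries = 701)
  if (!stream %in% names(offsets)) stop("unknown seed substream: ", stream)
  as.integer((as.numeric(seed) + 1000 * offsets[[stream]]) %% 2147483647)
}

#' Specification of a two-group point-pattern cohort
#'
#' Describes the study design emulated by [gen_cohort_patterns()]: two groups
#' of animals with several sections each, cells scattered as an inhomogeneous
#' Poisson process around an elliptical lesion, and a multiplicative
#' peri-infarct density excess for group B inside a radial annulus.
#'
#' @param n_animals_per_group animals per group (default 3, the study design).
#' @param n_sections_per_animal sections per animal (default 3).
#' @param cells_per_section_mean expected baseline cell count per section.
#' @param lesion_semi_axes ellipse semi-axes (a, b) in micrometers; the lesion
#'   is ~1 mm across.
#' @param excess_ratio multiplicative density excess added for group B inside
#'   the annulus (0 = null cohort; 1 = doubled density).
#' @param annulus radial annulus (r_inner, r_outer) in micrometers carrying
#'   the group-B excess.
#' @param window half-widths (wx, wy) of the rectangular analysis window, um.
#' @param slab_um slab thickness for the z coordinate (drawn uniformly; the
#'   2D analyses ignore it).
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals_per_group = 3, n_sections_per_animal = 3,
                        cells_per_section_mean = 200,
                        lesion_semi_axes = c(500, 350),
                        excess_ratio = 1, annulus = c(300, 500),
                        window = c(1000, 1000), slab_um = 10, seed = 1) {
  if (n_animals_per_group < 1) stop("need at least one animal per group")
  if (n_sections_per_animal < 1) stop("need at least one section per animal")
  if (cells_per_section_mean <= 0) stop("cells_per_section_mean must be > 0")
  if (any(lesion_semi_axes <= 0) || any(window <= 0) || slab_um <= 0)
    stop("all lengths must be > 0")
  if (excess_ratio < 0) stop("excess_ratio must be >= 0")
  if (annulus[1] >= annulus[2]) stop("annulus r_inner must be < r_outer")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a two-group cohort of lesion-centered point patterns
#'
#' Cells are drawn from an inhomogeneous Poisson process: a spatially uniform
#' baseline over the analysis window in both groups, plus, for group B only,
#' an added intensity of `baseline * excess_ratio` inside the peri-infarct
#' annulus. Counts are Poisson; coordinates are lesion-centered micrometers.
#' With `excess_ratio = 0` the two groups are draws from one and the same
#' intensity (a null cohort).
#'
#' @param spec a [cohort_spec()].
#' @return List with `patterns` (list of [point_pattern()]) and
#'   `ground_truth` (baseline intensity, annulus, expected counts).
#' @export
gen_cohort_patterns <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  area_win <- 4 * spec$window[1] * spec$window[2]
  lambda <- spec$cells_per_section_mean / area_win          # cells / um^2
  area_ann <- pi * (spec$annulus[2]^2 - spec$annulus[1]^2)
  mu_extra <- lambda * spec$excess_ratio * area_ann
  patterns <- list()
  for (g in c("A", "B")) for (a in seq_len(spec$n_animals_per_group))
    for (s in seq_len(spec$n_sections_per_animal)) {
      n_base <- stats::rpois(1, spec$cells_per_section_mean)
      x <- stats::runif(n_base, -spec$window[1], spec$window[1])
      y <- stats::runif(n_base, -spec$window[2], spec$window[2])
      if (g == "B" && mu_extra > 0) {
        n_ex <- stats::rpois(1, mu_extra)
        r <- sqrt(stats::runif(n_ex, spec$annulus[1]^2, spec$annulus[2]^2))
        th <- stats::runif(n_ex, 0, 2 * pi)
        x <- c(x, r * cos(th)); y <- c(y, r * sin(th))
      }
      z <- stats::runif(length(x), 0, spec$slab_um)
      patterns[[length(patterns) + 1]] <- point_pattern(
        cbind(x_um = x, y_um = y, z_um = z),
        group = g, animal = sprintf("%s%d", tolower(g), a),
        section = sprintf("s%d", s))
    }
  list(patterns = patterns,
       ground_truth = list(
         baseline_intensity_per_um2 = lambda,
         annulus = spec$annulus, excess_ratio = spec$excess_ratio,
         expected_extra_cells_B = mu_extra,
         expected_annulus_count_A = lambda * area_ann,
         expected_annulus_count_B = lambda * area_ann * (1 + spec$excess_ratio)))
}

#' Generate a branching random-walk vessel network
#'
#' Grows `n_branches` polyline branches of persistent random-walk steps inside
#' a rectangular domain. Branches after the first sprout from a random point
#' of the existing network, creating junction nodes. Ground-truth total length
#' and junction count are those of the returned graph.
#'
#' @param domain half-widths (wx, wy) of the domain, micrometers.
#' @param n_branches number of branches (>= 1).
#' @param step step length of the growth walk, micrometers (> 0).
#' @param steps_per_branch number of steps grown per branch.
#' @param seed integer seed.
#' @param turn_sd angular diffusion of the walk, radians per step.
#' @return A [vessel_graph()]; its `total_length_um` and `junction_count`
#'   fields are the generator's ground truth.
#' @export
gen_vessel_network <- function(domain = c(1000, 1000), n_branches = 6,
                               step = 20, steps_per_branch = 40, seed = 1,
                               turn_sd = 0.25) {
  if (n_branches < 1) stop("n_branches must be >= 1")
  if (step <= 0) stop("step length must be > 0")
  set.seed(seed)
  nodes <- matrix(numeric(0), ncol = 2)
  segs <- matrix(integer(0), ncol = 2)
  for (b in seq_len(n_branches)) {
    if (b == 1) {
      start <- stats::runif(2, -domain / 2, domain / 2)  # seed the tree centrally
      nodes <- rbind(nodes, start)
      cur <- nrow(nodes)
    } else {
      cur <- sample.int(nrow(nodes), 1)  # sprout from the existing network
      start <- nodes[cur, ]
    }
    theta <- stats::runif(1, 0, 2 * pi)
    pos <- start
    for (i in seq_len(steps_per_branch)) {
      theta <- theta + stats::rnorm(1, 0, turn_sd)
      nxt <- pos + step * c(cos(theta), sin(theta))
      nxt <- pmin(pmax(nxt, -domain), domain)   # reflect softly at the border
      if (all(nxt == pos)) break
      nodes <- rbind(nodes, nxt)
      segs <- rbind(segs, c(cur, nrow(nodes)))
      cur <- nrow(nodes); pos <- nxt
    }
  }
  colnames(nodes) <- c("x_um", "y_um")
  vessel_graph(nodes, segs)
}

#' Specification for vessel-attracted cell placement
#'
#' @param n_cells number of cells to place.
#' @param attraction_weight fraction of cells in the vessel-proximal channel,
#'   in 0..1.
#' @param decay_length_um scale of the exponential displacement kernel away
#'   from the vessel centerline, micrometers (> 0).
#' @param domain half-widths (wx, wy) of the uniform-channel domain, um.
#' @param seed integer seed.
#' @return A list of class `attraction_spec`.
#' @export
attraction_spec <- function(n_cells = 200, attraction_weight = 0.5,
                            decay_length_um = 10, domain = c(1000, 1000),
                            seed = 1) {
  if (attraction_weight < 0 || attraction_weight > 1)
    stop("attraction_weight must be in [0, 1]")
  if (decay_length_um <= 0) stop("decay_length_um must be > 0")
  structure(as.list(environment()), class = "attraction_spec")
}

#' Place cells with a configurable attraction to a vessel network
#'
#' A fraction `attraction_weight` of cells is placed at a random point of the
#' vessel centerline (segments chosen proportional to length) and displaced by
#' an Exponential(`decay_length_um`) distance in a uniform random direction;
#' the remainder is uniform over the domain. The generation channel of each
#' cell is recorded as ground truth.
#'
#' @param vessels a [vessel_graph()].
#' @param spec an [attraction_spec()].
#' @return List with `pattern` (a [point_pattern()]) and `channel`
#'   (per-cell `"vessel"`/`"uniform"` labels, the ground truth).
#' @export
gen_opc_positions <- function(vessels, spec) {
  stopifnot(inherits(vessels, "vessel_graph"), inherits(spec, "attraction_spec"))
  if (nrow(vessels$segments) == 0) stop("vessel graph is empty")
  set.seed(spec$seed)
  n_v <- round(spec$attraction_weight * spec$n_cells)
  n_u <- spec$n_cells - n_v
  pts <- matrix(numeric(0), ncol = 2)
  if (n_v > 0) {
    seg <- sample.int(nrow(vessels$segments), n_v, replace = TRUE,
                      prob = vessels$segment_length_um)
    t <- stats::runif(n_v)
    p1 <- vessels$nodes[vessels$segments[seg, 1], 1:2, drop = FALSE]
    p2 <- vessels$nodes[vessels$segments[seg, 2], 1:2, drop = FALSE]
    base <- p1 + t * (p2 - p1)
    d <- stats::rexp(n_v, rate = 1 / spec$decay_length_um)
    phi <- stats::runif(n_v, 0, 2 * pi)
    pts <- base + cbind(d * cos(phi), d * sin(phi))
  }
  if (n_u > 0)
    pts <- rbind(pts, cbind(stats::runif(n_u, -spec$domain[1], spec$domain[1]),
                            stats::runif(n_u, -spec$domain[2], spec$domain[2])))
  colnames(pts) <- c("x_um", "y_um")
  list(pattern = point_pattern(pts),
       channel = rep(c("vessel", "uniform"), c(n_v, n_u)))
}

#' Generate per-fiber EM measurements with a specified mean g-ratio
#'
#' Axon diameters are lognormal; each fiber's g-ratio is drawn from a normal
#' distribution truncated to (0, 1), and the fiber diameter is axon / g, so
#' fiber diameter strictly exceeds the axon diameter whenever g < 1. Default
#' calibrations of 0.80 (control) and 0.88 (thin-myelin) reproduce the
#' published contrast between chow-fed and obese cohorts.
#'
#' @param n number of fibers.
#' @param mean_g target mean g-ratio, in (0, 1).
#' @param sd_g standard deviation of the per-fiber g-ratio (0 allowed).
#' @param axon_diam_mean_um mean axon diameter, micrometers.
#' @param axon_diam_cv lognormal coefficient of variation of axon diameter.
#' @param seed integer seed.
#' @param group group label attached to the output.
#' @return A [fiber_set()].
#' @export
gen_fiber_set <- function(n, mean_g = 0.80, sd_g = 0.04,
                          axon_diam_mean_um = 0.8, axon_diam_cv = 0.3,
                          seed = 1, group = "A") {
  if (mean_g <= 0 || mean_g >= 1) stop("mean_g must lie in (0, 1)")
  if (sd_g < 0) stop("sd_g must be >= 0")
  set.seed(seed)
  sdlog <- sqrt(log(1 + axon_diam_cv^2))
  axon <- stats::rlnorm(n, meanlog = log(axon_diam_mean_um) - sdlog^2 / 2,
                        sdlog = sdlog)
  if (sd_g == 0) {
    g <- rep(mean_g, n)
  } else {
    # truncated normal on (0, 1) by inverse-CDF sampling
    lo <- stats::pnorm(0, mean_g, sd_g); hi <- stats::pnorm(1, mean_g, sd_g)
    g <- stats::qnorm(stats::runif(n, lo, hi), mean_g, sd_g)
  }
  fiber_set(axon_diameter_um = axon, fiber_diameter_um = axon / g, group = group)
}

#' Generate serial-section lesion areas from a known ellipsoid
#'
#' Section planes are spaced `section_spacing_um` apart along the c axis and
#' centered on the ellipsoid; the true cross-section area at offset z is
#' `pi * a * b * (1 - z^2/c^2)` (zero outside the ellipsoid, retained as 0).
#' Observed areas are the true areas times lognormal noise with coefficient of
#' variation `noise_cv`. The true ellipsoid volume `(4/3) pi a b c` is emitted
#' as ground truth.
#'
#' @param semi_axes ellipsoid semi-axes (a, b, c), micrometers.
#' @param section_spacing_um spacing between sampled planes (> 0),
#'   micrometers; the default 240 um spreads the 3-5 sampled sections across
#'   the ~1 mm lesion rather than clustering them at its widest part.
#'   Sampled planes need not be adjacent sections (each section is still
#'   `section_thickness_um` thick downstream).
#' @param n_sampled number of planes sampled (>= 1), centered on the lesion.
#' @param noise_cv lognormal noise CV (0 = noise-free).
#' @param seed integer seed.
#' @param ... passed to [section_area_set()] (animal, group, thickness, target).
#' @return A [section_area_set()] with attribute `ground_truth` (true areas,
#'   plane offsets, true volume).
#' @export
gen_section_areas <- function(semi_axes = c(500, 350, 500),
                              section_spacing_um = 240, n_sampled = 5,
                              noise_cv = 0.1, seed = 1, ...) {
  if (n_sampled < 1) stop("n_sampled must be >= 1")
  if (section_spacing_um <= 0) stop("section spacing must be > 0")
  set.seed(seed)
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  z <- (seq_len(n_sampled) - (n_sampled + 1) / 2) * section_spacing_um
  true_area <- pi * a * b * pmax(0, 1 - (z / cc)^2)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(n_sampled, -sdlog^2 / 2, sdlog)
  } else noise <- rep(1, n_sampled)
  s <- section_area_set(true_area * noise, ...)
  attr(s, "ground_truth") <- list(true_areas_um2 = true_area, plane_z_um = z,
                                  true_volume_um3 = 4 / 3 * pi * a * b * cc)
  s
}

#' Generate a pair of voxel masks with a set overlap fraction
#'
#' Mask A (the reference / vessel channel) is a random union of balls. Mask B
#' (the marker channel) is built by exact voxel sampling: `round(f * nB)`
#' voxels drawn from A and the remainder from outside A, so that
#' `|A intersect B| / |B|` equals `overlap_fraction` to one-voxel rounding by
#' construction. B is therefore a voxel set, not a blob, which is immaterial
#' to voxel-count colocalization.
#'
#' @param shape integer vector (2D or 3D) of array dimensions.
#' @param overlap_fraction target fraction of B inside A, in 0..1.
#' @param n_blobs,blob_radius shape parameters of mask A.
#' @param n_marker target foreground size of mask B (voxels).
#' @param voxel_size_um physical voxel size.
#' @param seed integer seed.
#' @return List of two [voxel_mask()]s (`vessel`, `marker`) plus
#'   `ground_truth` (exact voxel counts and achieved fraction).
#' @export
gen_voxel_masks <- function(shape = c(48, 48, 16), overlap_fraction = 0.5,
                            n_blobs = 6, blob_radius = 5, n_marker = 400,
                            voxel_size_um = 1, seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (any(shape <= 0)) stop("mask shape must be positive")
  set.seed(seed)
  nd <- length(shape)
  A <- array(FALSE, dim = shape)
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  for (i in seq_len(n_blobs)) {
    ctr <- sapply(shape, function(s)
      stats::runif(1, min(1 + blob_radius, s / 2), max(s - blob_radius, s / 2)))
    d2 <- rowSums(sweep(idx, 2, ctr)^2)
    A[d2 <= blob_radius^2] <- TRUE
  }
  inA <- which(A); outA <- which(!A)
  n_in <- round(overlap_fraction * n_marker)
  n_out <- n_marker - n_in
  if (n_in > length(inA) || n_out > length(outA))
    stop("overlap_fraction unattainable for these mask sizes")
  B <- array(FALSE, dim = shape)
  if (n_in > 0) B[sample(inA, n_in)] <- TRUE
  if (n_out > 0) B[sample(outA, n_out)] <- TRUE
  list(vessel = voxel_mask(A, voxel_size_um),
       marker = voxel_mask(B, voxel_size_um),
       ground_truth = list(n_marker = n_marker, n_overlap = n_in,
                           achieved_fraction = n_in / n_marker))
}

#' Generate per-animal summary values calibrated to printed group statistics
#'
#' Emulates published per-animal summary statistics (e.g. vessel-associated
#' OPCs per mm: 6.46 +/- 0.23 versus 8.94 +/- 0.31 cells/mm, n = 3/group,
#' where +/- is the SEM) by drawing per-animal values from normal
#' distributions with matching means and SDs (`sd = sem * sqrt(n)`).
#'
#' @param means,sems per-group mean and SEM of the printed statistic.
#' @param n_per_group animals per group.
#' @param groups group labels.
#' @param seed integer seed.
#' @return Data frame with columns `group`, `animal`, `value`.
#' @export
gen_group_summaries <- function(means = c(6.46, 8.94), sems = c(0.23, 0.31),
                                n_per_group = 3, groups = c("A", "B"),
                                seed = 1) {
  set.seed(seed)
  sds <- sems * sqrt(n_per_group)
  do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(group = groups[i],
               animal = sprintf("%s%d", tolower(groups[i]), seq_len(n_per_group)),
               value = stats::rnorm(n_per_group, means[i], sds[i]))
  }))
}
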