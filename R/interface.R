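# Configuration and stage runner binding the modules into the published
# analyses. The numbered scripts under analysis/ are thin drivers over
# run_stage(); every default below mirrors a printed tool setting.

#' Default run configuration
#'
#' All defaults mirror the study's printed settings: smoothing k = 8,
#' per-position threshold alpha = 0.05, 0-35 um proximity bins, 30 um^3 and
#' 800-voxel particle filters, intensity band 40-255, vessel diameter band
#' 5-40 px, components under 10000 px dropped, 40-um sections with a
#' 25-section bootstrap span.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    grid = list(x_range = c(-1000, 1000), y_range = c(-1000, 1000),
                spacing = 50, k = 8, alpha = 0.05, B_perm = 999,
                unit = "section"),
    cohort = list(n_animals_per_group = 3, n_sections_per_animal = 3,
                  cells_per_section_mean = 200,
                  lesion_semi_axes = c(500, 350), excess_ratio = 1,
                  annulus = c(300, 500)),
    proximity = list(bin_width_um = 5, max_range_um = 35,
                     assoc_threshold_um = 5),
    morphometry = list(min_particle_um3 = 30, min_object_voxels = 800,
                       intensity_range = c(40, 255), diameter_range = c(5, 40),
                       min_component_px = 10000),
    bootstrap = list(section_thickness_um = 40, target_sections = 25,
                     n_boot = 1000)),
    class = "run_config")
}

#' Load a YAML run configuration over the defaults
#'
#' Keys present in the file override the corresponding [default_config()]
#' entries; everything else keeps its default.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "run_config")
}

#' Run one pipeline stage
#'
#' Executes the named stage with the given configuration, writes its
#' artifacts under `outdir` along with a resolved-config snapshot
#' (`config_<stage>.yaml`) and a run log, and returns the stage's result
#' invisibly. Stages: `simulate` (generate cohort, vessels, cells, fibers,
#' section areas and masks), `density-map` (p-value map of the simulated
#' cohort), `proximity` (cell-vessel distances and association summary),
#' `morphometry` (g-ratio, raster metrics, colocalization), `bootstrap-volume`,
#' `stats-report` (group comparisons over the simulated readouts), `all`.
#' Outputs are deterministic given the config seed.
#'
#' @param name stage name.
#' @param config a `run_config` (default [default_config()]).
#' @param outdir output directory (created if needed).
#' @return Stage result, invisibly.
#' @export
run_stage <- function(name, config = default_config(), outdir = "results") {
  stages <- c("simulate", "density-map", "proximity", "morphometry",
              "bootstrap-volume", "stats-report", "all")
  if (!name %in% stages)
    stop("unknown stage '", name, "'; expected one of: ",
         paste(stages, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config),
                   file.path(outdir, paste0("config_", gsub("-", "_", name), ".yaml")))
  log_path <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", name, sprintf(...)),
                               file = log_path, append = TRUE)
  logline("seed=%s", config$seed)
  res <- switch(name,
    "simulate" = stage_simulate(config, outdir),
    "density-map" = stage_density_map(config, outdir),
    "proximity" = stage_proximity(config, outdir),
    "morphometry" = stage_morphometry(config, outdir),
    "bootstrap-volume" = stage_bootstrap(config, outdir),
    "stats-report" = stage_stats(config, outdir),
    "all" = lapply(stages[1:6], run_stage, config = config, outdir = outdir))
  logline("done")
  invisible(res)
}

stage_simulate <- function(config, outdir) {
  cs <- do.call(cohort_spec, c(config$cohort,
                               list(seed = substream_seed(config$seed, "cohort"))))
  cohort <- gen_cohort_patterns(cs)
  write_point_patterns(cohort$patterns, file.path(outdir, "cohort_patterns.csv"))
  vessels <- gen_vessel_network(seed = substream_seed(config$seed, "vessels"))
  write_vessel_csv(vessels, file.path(outdir, "vessels.csv"))
  opc <- gen_opc_positions(vessels, attraction_spec(
    seed = substream_seed(config$seed, "opc")))
  write_point_patterns(list(opc$pattern), file.path(outdir, "opc_positions.csv"))
  fibers <- list(A = gen_fiber_set(300, mean_g = 0.80, group = "A",
                                   seed = substream_seed(config$seed, "fibers")),
                 B = gen_fiber_set(300, mean_g = 0.88, group = "B",
                                   seed = substream_seed(config$seed, "fibers") + 1))
  areas <- gen_section_areas(seed = substream_seed(config$seed, "areas"),
                             section_thickness_um = config$bootstrap$section_thickness_um,
                             target_sections = config$bootstrap$target_sections)
  masks <- gen_voxel_masks(seed = substream_seed(config$seed, "masks"))
  write_mask_tiff(masks$vessel, file.path(outdir, "mask_vessel.tif"))
  write_mask_tiff(masks$marker, file.path(outdir, "mask_marker.tif"),
                  extra = masks$ground_truth)
  yaml::write_yaml(cohort$ground_truth, file.path(outdir, "cohort_truth.yaml"))
  list(cohort = cohort, vessels = vessels, opc = opc, fibers = fibers,
       areas = areas, masks = masks)
}

stage_density_map <- function(config, outdir) {
  sim <- stage_simulate(config, outdir)
  is_B <- vapply(sim$cohort$patterns, function(p) p$group == "B", logical(1))
  g <- config$grid
  grid <- grid_spec(g$x_range, g$y_range, g$spacing)
  pv <- density_pvalue_map(sim$cohort$patterns[!is_B], sim$cohort$patterns[is_B],
                           grid, k = g$k, B_perm = g$B_perm, unit = g$unit,
                           seed = config$seed, alpha = g$alpha)
  write_pvalue_map(pv, file.path(outdir, "density_map"))
  pv
}

stage_proximity <- function(config, outdir) {
  vessels <- gen_vessel_network(seed = substream_seed(config$seed, "vessels"))
  opc <- gen_opc_positions(vessels, attraction_spec(
    seed = substream_seed(config$seed, "opc")))
  d <- nearest_vessel_distances(opc$pattern, vessels)
  pr <- config$proximity
  dist <- distance_distribution(d, pr$bin_width_um, pr$max_range_um)
  assoc <- vessel_association_metrics(d, pr$assoc_threshold_um)
  utils::write.csv(dist, file.path(outdir, "distance_distribution.csv"),
                   row.names = FALSE)
  yaml::write_yaml(assoc, file.path(outdir, "vessel_association.yaml"))
  list(distances = d, distribution = dist, association = assoc)
}

stage_morphometry <- function(config, outdir) {
  mo <- config$morphometry
  sd <- substream_seed(config$seed, "fibers")
  gr <- list(A = gratio_stats(gen_fiber_set(300, mean_g = 0.80, seed = sd)),
             B = gratio_stats(gen_fiber_set(300, mean_g = 0.88, seed = sd + 1)))
  masks <- gen_voxel_masks(seed = substream_seed(config$seed, "masks"))
  coloc <- colocalization_percent(masks$marker, masks$vessel)
  vol <- vessel_volume_from_mask(masks$vessel, mo$min_particle_um3)
  vessels <- gen_vessel_network(domain = c(100, 100), n_branches = 3,
                                step = 15, steps_per_branch = 12,
                                seed = substream_seed(config$seed, "vessels"))
  img <- render_vessel_raster(vessels, extent = c(-130, 130, -130, 130))
  rm <- vessel_raster_metrics(img, mo$intensity_range, min_component = 50,
                              diameter_range = mo$diameter_range)
  summary <- data.frame(
    metric = c("mean_g_A", "mean_g_B", "coloc_percent", "vessel_volume_um3",
               "skeleton_length_um", "junction_count"),
    value = c(gr$A$mean_g, gr$B$mean_g, coloc$percent, vol,
              rm$total_length_um, rm$junction_count))
  utils::write.csv(summary, file.path(outdir, "morphometry_summary.csv"),
                   row.names = FALSE)
  list(gratio = gr, coloc = coloc, vessel_volume = vol, raster = rm)
}

stage_bootstrap <- function(config, outdir) {
  bs <- config$bootstrap
  areas <- gen_section_areas(seed = substream_seed(config$seed, "areas"),
                             section_thickness_um = bs$section_thickness_um,
                             target_sections = bs$target_sections)
  boot <- bootstrap_lesion_volume(areas, n_boot = bs$n_boot, seed = config$seed)
  yaml::write_yaml(list(mean_volume_um3 = boot$mean_volume_um3,
                        ci_um3 = boot$ci_um3,
                        true_volume_um3 = attr(areas, "ground_truth")$true_volume_um3),
                   file.path(outdir, "lesion_volume.yaml"))
  boot
}

stage_stats <- function(config, outdir) {
  sums <- gen_group_summaries(seed = substream_seed(config$seed, "summaries"))
  res <- compare_groups(sums, "welch_t")
  sd <- substream_seed(config$seed, "fibers")
  gA <- gratio_stats(gen_fiber_set(300, mean_g = 0.80, seed = sd))$table
  gB <- gratio_stats(gen_fiber_set(300, mean_g = 0.88, seed = sd + 1))$table
  gg <- data.frame(group = rep(c("A", "B"), c(nrow(gA), nrow(gB))),
                   value = c(gA$g, gB$g))
  res <- rbind(res, compare_groups(gg, "mann_whitney_u"))
  utils::write.csv(res, file.path(outdir, "group_stats.csv"), row.names = FALSE)
  res
}
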