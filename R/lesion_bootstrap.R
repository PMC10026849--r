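# Bootstrap lesion-volume estimation from sparse serial-section areas.

#' Bootstrap a lesion-volume distribution from sampled section areas
#'
#' Lesion volume is estimated from 3-5 measured 40-um section areas by
#' resampling: each replicate draws `target_sections` areas with replacement
#' from the animal's observed areas and sums `area x thickness` (the default
#' 25 sections x 40 um span the approximate 1 mm lesion). Resampling is
#' per-animal; group comparison of the resulting per-animal volumes is
#' delegated to [compare_groups()] (Mann-Whitney U by convention).
#'
#' When `length(areas)^target_sections` is at most `exhaustive_cap`, the full
#' resampling distribution is enumerated exactly instead of simulated, and
#' the exact support and probabilities are returned.
#'
#' An alternative reading of the resampling scheme — `n_boot` fixed at 25
#' replicates, each resampling as many areas as observed and scaling the mean
#' area to the full 25-section span — is available as
#' `scheme = "replicates"`; the default `"sections"` scheme treats 25 as the
#' number of resampled sections spanning the lesion.
#'
#' @param s a [section_area_set()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param scheme `"sections"` (default) or `"replicates"`, see Details.
#' @param exhaustive_cap enumerate exactly when the number of equally likely
#'   draws is at most this (default 4096).
#' @param conf percentile confidence level, default 0.95.
#' @return List with `volumes_um3` (replicate volumes; for the exhaustive
#'   mode, `support_um3` and `prob` instead), `mean_volume_um3`, `ci_um3`,
#'   `exhaustive`, and the resolved scheme.
#' @export
bootstrap_lesion_volume <- function(s, n_boot = 1000, seed = 1,
                                    scheme = c("sections", "replicates"),
                                    exhaustive_cap = 4096, conf = 0.95) {
  stopifnot(inherits(s, "section_area_set"))
  scheme <- match.arg(scheme)
  if (n_boot < 1) stop("n_boot must be >= 1")
  areas <- s$areas_um2
  th <- s$section_thickness_um
  tgt <- s$target_sections
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  if (scheme == "sections" && length(areas)^tgt <= exhaustive_cap) {
    draws <- as.matrix(do.call(expand.grid, rep(list(areas), tgt)))
    vols <- rowSums(draws) * th
    support <- sort(unique(vols))
    prob <- as.numeric(table(factor(vols, levels = support))) / length(vols)
    return(list(support_um3 = support, prob = prob,
                mean_volume_um3 = sum(support * prob),
                ci_um3 = unname(stats::quantile(vols, qs)),
                exhaustive = TRUE, scheme = scheme))
  }
  set.seed(seed)
  vols <- if (scheme == "sections") {
    vapply(seq_len(n_boot),
           function(i) sum(sample(areas, tgt, replace = TRUE)) * th,
           numeric(1))
  } else {
    vapply(seq_len(n_boot),
           function(i) mean(sample(areas, length(areas), replace = TRUE)) * tgt * th,
           numeric(1))
  }
  list(volumes_um3 = vols, mean_volume_um3 = mean(vols),
       ci_um3 = unname(stats::quantile(vols, qs)),
       exhaustive = FALSE, scheme = scheme)
}
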