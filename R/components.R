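# Connected-component labeling for 2D (8-connectivity) and 3D
# (26-connectivity) binary arrays. Written here because the installed image
# stack labels 2D only; a breadth-first flood fill with vectorized frontier
# expansion is ample for the mask sizes this package handles.

#' Label connected components of a binary array
#'
#' Components are 8-connected in 2D and 26-connected in 3D (all neighbors
#' sharing a face, edge or corner), the conventions used throughout the
#' package's morphometry.
#'
#' @param mask logical 2D or 3D array.
#' @return Integer array of the same shape: 0 for background, 1..n_components
#'   for foreground, labeled in first-encounter order.
#' @export
label_components <- function(mask) {
  dm <- dim(mask)
  nd <- length(dm)
  if (!nd %in% 2:3) stop("label_components expects a 2D or 3D array")
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  labels <- array(0L, dim = dm)
  fg <- which(mask)
  next_label <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    frontier <- seed
    while (length(frontier)) {
      ci <- arrayInd(frontier, .dim = dm)
      nb <- ci[rep(seq_len(nrow(ci)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(ci)), , drop = FALSE]
      ok <- rep(TRUE, nrow(nb))
      for (ax in seq_len(nd)) ok <- ok & nb[, ax] >= 1 & nb[, ax] <= dm[ax]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1]
      mult <- 1
      for (ax in 2:nd) { mult <- mult * dm[ax - 1]; lin <- lin + (nb[, ax] - 1L) * mult }
      lin <- unique(lin[mask[lin] & labels[lin] == 0L])
      labels[lin] <- next_label
      frontier <- lin
    }
  }
  labels
}

# Component voxel counts as a named integer vector (names = labels).
component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  stats::setNames(tab, seq_along(tab))
}

# Drop components smaller than min_voxels; returns the filtered logical mask.
filter_small_components <- function(mask, min_voxels) {
  labels <- label_components(mask)
  if (max(labels) == 0L) return(mask & FALSE)
  keep <- which(component_sizes(labels) >= min_voxels)
  array(labels %in% keep, dim = dim(mask))
}
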