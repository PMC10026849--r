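# Independent brute-force oracles used to validate the package's optimized
# paths. These deliberately use the most literal formulation of each
# quantity (full sorts, explicit loops, recursive flood fill).

# kNN density by full per-node distance sort over all cells.
oracle_knn_density <- function(coords, nodes, k, n, floor_d) {
  vapply(seq_len(nrow(nodes)), function(i) {
    d <- sort(sqrt((coords[, 1] - nodes[i, 1])^2 +
                   (coords[, 2] - nodes[i, 2])^2))
    k / (n * pi * max(d[k], floor_d)^2)
  }, numeric(1))
}

# Point-to-segment distance by explicit scalar geometry, one pair at a time.
oracle_point_segment <- function(p, a, b) {
  v <- b - a
  t <- sum((p - a) * v) / sum(v * v)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * v - p)^2))
}

oracle_nn_distances <- function(cells, A, B) {
  vapply(seq_len(nrow(cells)), function(i) {
    min(vapply(seq_len(nrow(A)), function(j)
      oracle_point_segment(cells[i, ], A[j, ], B[j, ]), numeric(1)))
  }, numeric(1))
}

# Connected components by a plain stack-based flood fill, one voxel at a
# time (26-connectivity in 3D, 8 in 2D).
oracle_flood_fill <- function(mask) {
  dm <- dim(mask)
  nd <- length(dm)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  labels <- array(0L, dim = dm)
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    stack <- list(arrayInd(start, dm)[1, ])
    labels[start] <- lab
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > dm)) next
        lin <- nb[1]
        mult <- 1
        for (ax in 2:nd) { mult <- mult * dm[ax - 1]; lin <- lin + (nb[ax] - 1) * mult }
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- lab
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  labels
}

# Uniform random pattern on a window, as a point_pattern.
runif_pattern <- function(n, w = c(1000, 1000), ...) {
  point_pattern(cbind(x_um = stats::runif(n, -w[1], w[1]),
                      y_um = stats::runif(n, -w[2], w[2])), ...)
}

# Split a generated cohort into its two groups of patterns.
split_cohort <- function(cohort) {
  is_B <- vapply(cohort$patterns, function(p) p$group == "B", logical(1))
  list(A = cohort$patterns[!is_B], B = cohort$patterns[is_B])
}
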