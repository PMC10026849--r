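# Morphological thinning (Zhang-Suen) and skeleton measurement. No installed
# package offers 2D thinning, so the standard two-subiteration algorithm is
# implemented here with whole-matrix shifts; it converges in a number of
# passes proportional to the maximum vessel half-width.

# Shift a matrix by (di, dj), padding with FALSE/0.
shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(vector(typeof(m), 1), nr, nc)
  ri <- seq_len(nr) - di; cj <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- cj >= 1 & cj <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
  out
}

# The 8 neighbors in the Zhang-Suen circular order P2..P9
# (N, NE, E, SE, S, SW, W, NW) for an image whose rows increase downward.
zs_neighbors <- function(m) {
  list(p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
}

#' Skeletonize a binary 2D mask by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels in two alternating subiterations until
#' stable, producing a one-pixel-wide 8-connected skeleton that preserves
#' connectivity and endpoints.
#'
#' @param mask logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- mask
  storage.mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      B <- Reduce(`+`, nb)
      ring <- cbind(c(nb$p2), c(nb$p3), c(nb$p4), c(nb$p5),
                    c(nb$p6), c(nb$p7), c(nb$p8), c(nb$p9))
      A <- rowSums(!ring & ring[, c(2:8, 1)])   # 0 -> 1 transitions around the ring
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  prune_corners(m)
}

# Parallel thinning leaves staircase elbows and two-pixel steps on diagonal
# runs (a known Zhang-Suen artifact) which inflate path length and create
# fake 3-neighbor junction pixels. A serial pass deletes non-endpoint pixels
# that are 8-simple by the Hilditch crossing number: with neighbors ordered
# E, NE, N, NW, W, SW, S, SE, X_H counts, over the four orthogonal
# directions k, cases where n_k is background but one of the following two
# ring positions is foreground; X_H == 1 means the foreground around the
# pixel stays one 8-connected piece after its removal.
prune_corners <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ring_ij <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                   c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    changed <- FALSE
    for (lin in which(m)) {
      i <- (lin - 1) %% nr + 1; j <- (lin - 1) %/% nr + 1
      ri <- i + ring_ij[, 1]; rj <- j + ring_ij[, 2]
      ok <- ri >= 1 & ri <= nr & rj >= 1 & rj <= nc
      ring <- logical(8)
      ring[ok] <- m[cbind(ri[ok], rj[ok])]
      B <- sum(ring)
      if (B < 2 || B > 6) next
      xh <- 0L
      for (k in c(1L, 3L, 5L, 7L))
        if (!ring[k] && (ring[k %% 8L + 1L] || ring[(k + 1L) %% 8L + 1L]))
          xh <- xh + 1L
      if (xh == 1L) { m[i, j] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Skeleton path length: each pair of 8-adjacent skeleton pixels contributes
# one edge, orthogonal edges count 1 pixel pitch and diagonal edges sqrt(2).
# Each edge is counted once by only looking at 4 of the 8 directions.
skeleton_length <- function(skel, pixel_size = 1) {
  orth <- sum(skel & shift_mat(skel, 1, 0)) + sum(skel & shift_mat(skel, 0, 1))
  diag <- sum(skel & shift_mat(skel, 1, 1)) + sum(skel & shift_mat(skel, 1, -1))
  (orth + sqrt(2) * diag) * pixel_size
}

# Junction zones: skeleton pixels with >= 3 skeleton neighbors, merged by
# 8-connectivity so one thick branch point counts once.
skeleton_junctions <- function(skel) {
  nb <- zs_neighbors(skel)
  nnb <- Reduce(`+`, nb)
  jmask <- skel & nnb >= 3
  if (!any(jmask)) return(0L)
  max(label_components(jmask))
}
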