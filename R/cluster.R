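# label 6-connected clusters in a logical 3-D mask; returns integer labels
# (0 = background) as a vector over the grid
label_clusters <- function(mask, grid_dim) {
  idx <- which(mask)
  labels <- integer(prod(grid_dim))
  if (length(idx) == 0L) return(labels)
  labels[idx] <- seq_along(idx)
  nx <- grid_dim[1]; nxy <- grid_dim[1] * grid_dim[2]
  co <- voxel_coords(idx, grid_dim)
  # neighbour offsets valid only when not crossing a face
  offs <- list(c(-1L, 1L), c(-nx, 2L), c(-nxy, 3L))
  repeat {
    changed <- FALSE
    for (o in offs) {
      ok <- co[, o[2]] > 1L
      nb <- idx[ok] + o[1]
      has <- labels[nb] > 0L
      a <- idx[ok][has]; b <- nb[has]
      mn <- pmin(labels[a], labels[b])
      if (any(labels[a] != mn)) { labels[a] <- mn; changed <- TRUE }
      if (any(labels[b] != pmin(labels[b], labels[a]))) {
        labels[b] <- pmin(labels[b], labels[a]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  # compact label ids
  u <- sort(unique(labels[labels > 0L]))
  labels[labels > 0L] <- match(labels[labels > 0L], u)
  labels
}

cluster_sizes <- function(mask, grid_dim) {
  labels <- label_clusters(mask, grid_dim)
  if (!any(labels > 0L)) return(integer(0))
  tabulate(labels[labels > 0L])
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates smoothed Gaussian null maps on the grid, thresholds each at the
#' voxelwise `voxel_p` (two-sided), records the largest 6-connected cluster,
#' and returns the smallest cluster extent `k` whose family-wise false
#' positive rate across simulations is at most `alpha`.
#'
#' @param grid_dim Grid dimensions.
#' @param voxel_p Voxelwise two-sided p threshold applied before clustering.
#' @param n_sims Number of null simulations (at least 100).
#' @param smooth_sigma Gaussian smoothing width of the null maps, in voxels.
#' @param alpha Target family-wise cluster false-positive rate.
#' @param seed Integer seed.
#' @return Integer minimum cluster extent `k`, with attribute
#'   `"max_cluster_sizes"` (the simulated distribution).
#' @export
cluster_threshold <- function(grid_dim, voxel_p = 0.005, n_sims = 200L,
                              smooth_sigma = 1, alpha = 0.05, seed = 1L) {
  if (n_sims < 100L) stopf("need at least 100 simulations")
  if (smooth_sigma < 0) stopf("smoothness must be non-negative")
  nvox <- prod(grid_dim)
  zcrit <- -qnorm(voxel_p / 2)
  maxes <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      e <- matrix(rnorm(nvox), nvox, 1)
      if (smooth_sigma > 0) {
        e <- smooth_matrix_gaussian(e, grid_dim, smooth_sigma)
        e <- e / sd(e)  # restandardise so voxel_p is calibrated
      }
      sz <- cluster_sizes(abs(e) > zcrit, grid_dim)
      if (length(sz) == 0L) 0L else max(sz)
    }, integer(1))
  })
  # smallest k with P(max cluster >= k) <= alpha
  k <- 1L
  while (mean(maxes >= k) > alpha) k <- k + 1L
  structure(k, max_cluster_sizes = maxes)
}
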