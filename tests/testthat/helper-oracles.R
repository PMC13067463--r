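# Independent oracles used by the tests.  These deliberately avoid the
# package's own kernels: connected components by breadth-first search in
# plain R, and TFCE by exact piecewise-constant integration between the
# sorted distinct heights of the map.

bfs_offsets <- function(connectivity) {
  g <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  nz <- abs(g$a) + abs(g$b) + abs(g$c)
  keep <- nz > 0 & nz <= switch(as.character(connectivity),
                                "6" = 1, "18" = 2, "26" = 3)
  as.matrix(g[keep, ])
}

# Flood-fill labeling by BFS; returns list(labels = 3D array, sizes).
bfs_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- bfs_offsets(connectivity)
  labels <- array(0L, dim = d)
  sizes <- integer(0)
  nxt <- 0L
  idx_all <- which(mask != 0, arr.ind = TRUE)
  ord <- order(idx_all[, 3], idx_all[, 2], idx_all[, 1])
  idx_all <- idx_all[ord, , drop = FALSE]
  for (s in seq_len(nrow(idx_all))) {
    p <- idx_all[s, ]
    if (labels[p[1], p[2], p[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(p)
    labels[p[1], p[2], p[3]] <- nxt
    count <- 0L
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      count <- count + 1L
      for (r in seq_len(nrow(off))) {
        w <- v + off[r, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] != 0 && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
    sizes[nxt] <- count
  }
  list(labels = labels, sizes = sizes)
}

# Exact TFCE: integral over h of e(h,v)^E * h^H between the distinct
# heights (e is piecewise constant: for h in (h_{k-1}, h_k] the
# supra-threshold set is {z >= h_k}).
tfce_exact <- function(z, H = 2, E = 0.5, connectivity = 26) {
  z <- pmax(z, 0)
  out <- array(0, dim = dim(z))
  hs <- sort(unique(z[z > 0]))
  prev <- 0
  for (h in hs) {
    cc <- bfs_components(z >= h, connectivity)
    supra <- which(cc$labels != 0L)
    ext <- cc$sizes[cc$labels[supra]]
    out[supra] <- out[supra] + ext^E * (h^(H + 1) - prev^(H + 1)) / (H + 1)
    prev <- h
  }
  out
}

# Per-voxel bound on the discretization error of the step-sum TFCE:
# one step's contribution, using the largest extent the voxel ever has
# (its component at the lowest threshold).
tfce_step_bound <- function(z, H = 2, E = 0.5, dh, connectivity = 26) {
  z <- pmax(z, 0)
  bound <- array(0, dim = dim(z))
  if (!any(z > 0)) return(bound)
  hmin <- min(z[z > 0])
  cc <- bfs_components(z >= hmin, connectivity)
  supra <- which(cc$labels != 0L)
  ext <- cc$sizes[cc$labels[supra]]
  bound[supra] <- ext^E * z[supra]^H * dh
  bound
}

# Small random binary mask on a fresh grid.
random_mask <- function(shape = c(16, 16, 16), p = 0.2, seed = NULL,
                        label = "m") {
  if (!is.null(seed)) set.seed(seed)
  g <- grid_spec(shape)
  mask_volume(g, array(rbinom(prod(shape), 1, p), dim = shape), label = label)
}
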