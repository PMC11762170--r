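# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized cell machinery: responses are obtained by direct
# triple counting with nested loops over coordinates.

# count of occupied centered antipodal triples per direction, visiting
# EVERY voxel of the grid as a potential center
brute_force_response <- function(grid) {
  arr <- unclass(grid)
  d <- dim(arr)
  U <- as.matrix(orientation_templates()[, c("ux", "uy", "uz")])
  counts <- numeric(13)
  for (o in 1:13) {
    u <- U[o, ]
    for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
      p <- c(x, y, z)
      if (arr[x, y, z] != 1) next
      pp <- p + u; pm <- p - u
      if (any(pp < 1) || any(pp > d) || any(pm < 1) || any(pm > d)) next
      if (arr[pp[1], pp[2], pp[3]] == 1 && arr[pm[1], pm[2], pm[3]] == 1) {
        counts[o] <- counts[o] + 1
      }
    }
  }
  counts
}

# positive set per Algorithm-1 semantics, by brute force: an occupied voxel
# is positive iff it is the center of at least one complete collinear triple
brute_force_positive <- function(grid) {
  arr <- unclass(grid)
  d <- dim(arr)
  U <- as.matrix(orientation_templates()[, c("ux", "uy", "uz")])
  occ <- which(arr == 1L, arr.ind = TRUE)
  keep <- logical(nrow(occ))
  if (nrow(occ)) for (i in seq_len(nrow(occ))) {
    p <- occ[i, ]
    for (o in 1:13) {
      u <- U[o, ]
      pp <- p + u; pm <- p - u
      if (any(pp < 1) || any(pp > d) || any(pm < 1) || any(pm > d)) next
      if (arr[pp[1], pp[2], pp[3]] == 1 && arr[pm[1], pm[2], pm[3]] == 1) {
        keep[i] <- TRUE
        break
      }
    }
  }
  list(positive = occ[keep, , drop = FALSE],
       negative = occ[!keep, , drop = FALSE])
}

random_grid <- function(dims, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_voxel_grid(array(as.integer(runif(prod(dims)) < p), dim = dims))
}

# the 48 signed axis permutations of the cube's symmetry group
octahedral_group <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  out <- list()
  for (pm in perms) for (i in seq_len(nrow(signs))) {
    out[[length(out) + 1]] <- list(perm = pm, sign = signs[i, ])
  }
  out
}

# apply a signed axis permutation to a grid: new coordinate axis a reads
# old axis perm[a], flipped when sign[a] == -1
transform_grid <- function(grid, op) {
  d <- dim(grid)
  nd <- d[op$perm]
  occ <- occupied_coords(grid)
  if (nrow(occ) == 0) return(voxel_grid(nd))
  q <- occ[, op$perm, drop = FALSE]
  for (a in 1:3) if (op$sign[a] < 0) q[, a] <- nd[a] + 1L - q[, a]
  voxel_grid(nd, coords = q)
}

# the induced permutation of template ids: direction u in the original grid
# appears as the transformed direction in the transformed grid
transform_direction_id <- function(id, op) {
  u <- template_direction(id)
  v <- u[op$perm] * op$sign
  direction_id(v)
}

# straight thickness-1 segment of length L along template id, centered in a
# grid of the given dims
segment_grid <- function(dims, id, L, anchor = NULL) {
  u <- template_direction(id)
  if (is.null(anchor)) {
    anchor <- ifelse(u < 0, dims - floor((dims - L) / 2), 1 + floor((dims - L) / 2))
    anchor[u == 0] <- ceiling(dims[u == 0] / 2)
  }
  coords <- t(vapply(0:(L - 1), function(i) anchor + i * u, numeric(3)))
  voxel_grid(dims, coords = coords)
}
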