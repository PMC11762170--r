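#' Binary 3D occupancy volumes
#'
#' A `voxel_grid` is a dense binary occupancy volume: a 3D integer array
#' whose entries are exactly 0 or 1. Coordinates in the R API are 1-based
#' array coordinates `(x, y, z)` with x varying fastest in the linearized
#' order; anything outside the grid is treated as empty (zero padding).
#' File formats ([write_voxel_coords()], [write_ply()], [write_xyz()]) use
#' 0-based geometric coordinates; the conversion happens at the I/O and
#' point-cloud boundary.
#'
#' @param dims Integer vector of length 3 `(nx, ny, nz)`, all >= 1.
#' @param coords Optional n x 3 matrix (or data frame) of 1-based occupied
#'   coordinates.
#' @return A `voxel_grid` object (a classed 3D integer array).
#' @examples
#' g <- voxel_grid(c(5, 5, 5), coords = rbind(c(2, 3, 3), c(3, 3, 3), c(4, 3, 3)))
#' n_occupied(g)
#' @export
voxel_grid <- function(dims, coords = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(is.na(dims)) || any(dims < 1)) {
    stop("`dims` must be three positive integers", call. = FALSE)
  }
  arr <- array(0L, dim = dims)
  g <- structure(arr, class = "voxel_grid")
  if (!is.null(coords)) g <- set_voxels(g, coords)
  g
}

#' Coerce a 3D array to a voxel grid
#'
#' @param x A 3D array with entries 0/1 (or logical).
#' @return A `voxel_grid`.
#' @export
as_voxel_grid <- function(x) {
  if (inherits(x, "voxel_grid")) return(x)
  if (!is.array(x) || length(dim(x)) != 3) {
    stop("`x` must be a 3D array", call. = FALSE)
  }
  v <- as.integer(x)
  if (any(is.na(v)) || !all(v %in% c(0L, 1L))) {
    stop("occupancy values must be exactly 0 or 1", call. = FALSE)
  }
  structure(array(v, dim = dim(x)), class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param x Object to test.
#' @export
is_voxel_grid <- function(x) inherits(x, "voxel_grid")

.check_coords <- function(coords, dims = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coordinates must have 3 columns", call. = FALSE)
  storage.mode(coords) <- "integer"
  if (any(is.na(coords))) stop("coordinates must be integer-valued", call. = FALSE)
  if (!is.null(dims)) {
    bad <- which(coords[, 1] < 1 | coords[, 1] > dims[1] |
                 coords[, 2] < 1 | coords[, 2] > dims[2] |
                 coords[, 3] < 1 | coords[, 3] > dims[3])
    if (length(bad)) {
      stop(sprintf("coordinate out of bounds at row %d: (%d, %d, %d)",
                   bad[1], coords[bad[1], 1], coords[bad[1], 2], coords[bad[1], 3]),
           call. = FALSE)
    }
  }
  coords
}

#' Set voxels of a grid to occupied
#'
#' @param grid A [voxel_grid].
#' @param coords n x 3 matrix of 1-based coordinates.
#' @return The modified grid.
#' @export
set_voxels <- function(grid, coords) {
  stopifnot(is_voxel_grid(grid))
  coords <- .check_coords(coords, dim(grid))
  grid[coords] <- 1L
  grid
}

#' Occupied coordinates of a grid
#'
#' @param grid A [voxel_grid].
#' @return An n x 3 integer matrix of 1-based coordinates (x, y, z), ordered
#'   x fastest.
#' @export
occupied_coords <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  out <- which(unclass(grid) == 1L, arr.ind = TRUE)
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' @rdname occupied_coords
#' @export
n_occupied <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  sum(unclass(grid))
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_grid %d x %d x %d, %d occupied>\n",
              d[1], d[2], d[3], n_occupied(x)))
  invisible(x)
}
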