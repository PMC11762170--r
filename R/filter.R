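#' Separation rules for positive/negative information
#'
#' A spatial element is *positive* when its local neighborhood contains
#' local stereo-orientation information. Let `m` be the number of
#' orientation types active at the element (out of 13). The rules are:
#'
#' * `any`: `m >= 1` — the default separation rule (preserve an element as
#'   soon as one simple cell fires; discard otherwise).
#' * `single`: `m == 1` — elements carrying exactly one orientation type.
#' * `multi`: `2 <= m <= 12` — several but not all orientation types.
#' * `all`: `m == 13` — every orientation type present (fully embedded
#'   elements).
#'
#' For every element exactly one of `m = 0`, `single`, `multi`, `all`
#' holds, and `any` is their union minus `m = 0`.
#'
#' @param name One of `"any"`, `"single"`, `"multi"`, `"all"`.
#' @return A `separation_rule` object (the validated name with a predicate).
#' @export
separation_rule <- function(name = c("any", "single", "multi", "all")) {
  name <- match.arg(name)
  pred <- switch(name,
    any    = function(m) m >= 1,
    single = function(m) m == 1,
    multi  = function(m) m >= 2 & m <= 12,
    all    = function(m) m == 13
  )
  structure(list(name = name, predicate = pred), class = "separation_rule")
}

.as_rule <- function(rule) {
  if (inherits(rule, "separation_rule")) rule else separation_rule(rule)
}

#' Number of active orientation types at an element
#'
#' Counts the templates whose simple-cell activation at this patch center
#' exceeds 0.5. With the default sharp sigmoid that is exactly the number
#' of complete centered collinear triples through the element.
#'
#' @param grid A [voxel_grid].
#' @param element 1-based coordinate inside the grid.
#' @param params A [cell_params] object.
#' @return Integer in 0..13.
#' @export
orientation_count <- function(grid, element, params = cell_params()) {
  patch <- extract_patch(grid, element)
  sum(local_profile(patch, params) > 0.5)
}

#' Is an element positive information?
#'
#' Applies a [separation_rule] to the element's orientation count. The
#' default rule (`any`) preserves the element iff at least one local
#' stereo-orientation is present in its neighborhood.
#'
#' @inheritParams orientation_count
#' @param rule A [separation_rule] or its name.
#' @return 1 (positive, preserve) or 0 (negative, discard).
#' @export
is_positive <- function(grid, element, params = cell_params(), rule = "any") {
  rule <- .as_rule(rule)
  as.integer(rule$predicate(orientation_count(grid, element, params)))
}

#' Separate a volume into positive and negative information
#'
#' Classifies every occupied element of the grid against the separation
#' rule and splits the occupancy set into two disjoint grids. All
#' orientation counts are computed against the original grid before any
#' element is removed (each element is judged independently).
#'
#' @param grid A [voxel_grid].
#' @param params A [cell_params] object.
#' @param rule A [separation_rule] or its name.
#' @return List with `positive` and `negative` [voxel_grid]s whose union is
#'   the original occupied set.
#' @examples
#' g <- voxel_grid(c(7, 7, 7), coords = cbind(2:6, 4, 4))
#' parts <- separate_features(g)            # endpoints are negative
#' n_occupied(parts$positive)               # 3 interior voxels
#' @export
separate_features <- function(grid, params = cell_params(), rule = "any") {
  stopifnot(is_voxel_grid(grid))
  rule <- .as_rule(rule)
  occ <- occupied_coords(grid)
  pos <- voxel_grid(dim(grid))
  neg <- voxel_grid(dim(grid))
  if (nrow(occ) > 0) {
    m <- rowSums(.activation_matrix(grid, params) > 0.5)
    keep <- rule$predicate(m)
    if (any(keep)) pos <- set_voxels(pos, occ[keep, , drop = FALSE])
    if (any(!keep)) neg <- set_voxels(neg, occ[!keep, , drop = FALSE])
  }
  list(positive = pos, negative = neg)
}

#' Point clouds
#'
#' A `point_cloud` stores n points as an n x 3 numeric matrix of 0-based
#' geometric coordinates, with an optional per-point label (e.g.
#' `"positive"` / `"negative"`).
#'
#' @param points n x 3 numeric matrix (columns x, y, z).
#' @param label Optional character vector of length n.
#' @return A `point_cloud` object.
#' @export
point_cloud <- function(points, label = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3) stop("`points` must have 3 columns", call. = FALSE)
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("point coordinates must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(label)) {
    if (length(label) != nrow(points)) {
      stop("`label` must cover every point", call. = FALSE)
    }
    label <- as.character(label)
  }
  structure(list(points = points, label = label), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud, %d points%s>\n", nrow(x$points),
              if (is.null(x$label)) "" else ", labeled"))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud A [point_cloud].
#' @return Integer count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  nrow(cloud$points)
}

#' Convert a voxel grid to a point cloud
#'
#' One point per occupied voxel. Grid coordinate `(1, 1, 1)` maps to point
#' `(0, 0, 0)` (the file/geometry convention), so rasterizing back at the
#' same dims is the exact inverse.
#'
#' @param grid A [voxel_grid].
#' @return A [point_cloud].
#' @export
to_point_cloud <- function(grid) {
  occ <- occupied_coords(grid)
  point_cloud(occ - 1L)
}

#' Rasterize a point cloud into a voxel grid
#'
#' Inverse of [to_point_cloud()]: point `(0, 0, 0)` becomes grid voxel
#' `(1, 1, 1)`. Coordinates must be integral and fall inside `dims`.
#'
#' @param cloud A [point_cloud].
#' @param dims Grid dimensions, length 3.
#' @return A [voxel_grid].
#' @export
rasterize_cloud <- function(cloud, dims) {
  stopifnot(inherits(cloud, "point_cloud"))
  pts <- cloud$points
  if (nrow(pts) == 0) return(voxel_grid(dims))
  if (any(pts != round(pts))) {
    stop("point coordinates must be integral to rasterize", call. = FALSE)
  }
  voxel_grid(dims, coords = round(pts) + 1)
}

#' Uniform random subsampling of a point cloud
#'
#' @param cloud A [point_cloud].
#' @param n Number of points to keep, `0 <= n <= n_points(cloud)`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [point_cloud] of `n` points drawn without replacement.
#' @export
sample_random <- function(cloud, n, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  N <- n_points(cloud)
  if (!is.numeric(n) || length(n) != 1 || n != as.integer(n) || n < 0 || n > N) {
    stop(sprintf("`n` must be an integer in 0..%d", N), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n)
  point_cloud(cloud$points[idx, , drop = FALSE],
              label = if (is.null(cloud$label)) NULL else cloud$label[idx])
}

#' Farthest point sampling (FPS) of a point cloud
#'
#' Greedy farthest-point subsampling under Euclidean distance: the first
#' point is a seeded uniform draw, then each subsequent point is the one
#' farthest from the already-selected set. Deterministic given the seed.
#'
#' @inheritParams sample_random
#' @return A [point_cloud] of `n` points in selection order.
#' @export
sample_fps <- function(cloud, n, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  N <- n_points(cloud)
  if (!is.numeric(n) || length(n) != 1 || n != as.integer(n) || n < 0 || n > N) {
    stop(sprintf("`n` must be an integer in 0..%d", N), call. = FALSE)
  }
  if (n == 0) {
    return(point_cloud(matrix(numeric(0), ncol = 3)))
  }
  if (!is.null(seed)) set.seed(seed)
  pts <- cloud$points
  sel <- integer(n)
  sel[1] <- sample.int(N, 1)
  ## squared distance of every point to the nearest selected point
  mind <- colSums((t(pts) - pts[sel[1], ])^2)
  if (n > 1) {
    for (i in 2:n) {
      sel[i] <- which.max(mind)
      mind <- pmin(mind, colSums((t(pts) - pts[sel[i], ])^2))
    }
  }
  point_cloud(pts[sel, , drop = FALSE],
              label = if (is.null(cloud$label)) NULL else cloud$label[sel])
}
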