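#' Extract a 3x3x3 local patch around a grid element
#'
#' The patch holds the 27 binary entries of the neighborhood in v-index
#' order (`v = 14 + dx + 3*dy + 9*dz`; x fastest, the center is v14).
#' Neighbors outside the parent grid are zero-padded.
#'
#' @param grid A [voxel_grid].
#' @param center Integer vector of length 3, a 1-based coordinate inside the
#'   grid.
#' @return A `local_patch` object: an integer vector of length 27 named
#'   `v1..v27`, with the center coordinate stored as an attribute.
#' @export
extract_patch <- function(grid, center) {
  stopifnot(is_voxel_grid(grid))
  center <- .check_coords(matrix(center, nrow = 1), dim(grid))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  pos <- offs + matrix(center, nrow = 27, ncol = 3, byrow = TRUE)
  d <- dim(grid)
  inb <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
         pos[, 2] >= 1 & pos[, 2] <= d[2] &
         pos[, 3] >= 1 & pos[, 3] <= d[3]
  vals <- integer(27)
  vals[inb] <- unclass(grid)[pos[inb, , drop = FALSE]]
  names(vals) <- paste0("v", 1:27)
  structure(vals, center = as.integer(center), class = "local_patch")
}

#' @export
print.local_patch <- function(x, ...) {
  ctr <- attr(x, "center")
  cat(sprintf("<local_patch at (%d, %d, %d), %d occupied>\n",
              ctr[1], ctr[2], ctr[3], sum(unclass(x))))
  invisible(x)
}

#' Simple-cell activation profile of one local patch
#'
#' Evaluates all 13 simple stereo-orientation selective cells on a patch.
#' Cell `o` combines the depth responses at template `o`'s member offsets
#' (`-u`, center, `+u`) through the sigmoid of [simple_activation()].
#'
#' @param patch A [local_patch][extract_patch].
#' @param params A [cell_params] object.
#' @return Named numeric vector of length 13 (names `o1..o13`).
#' @export
local_profile <- function(patch, params = cell_params()) {
  stopifnot(inherits(patch, "local_patch"), inherits(params, "cell_params"))
  vals <- unclass(patch)
  s <- vapply(1:13, function(o) {
    vi <- template_vindices(o)
    .sigmoid(params$k * (sum(vals[vi]) - params$theta))
  }, numeric(1))
  names(s) <- paste0("o", 1:13)
  s
}

## Vectorized core: n_occupied x 13 matrix of simple-cell activations, one
## row per occupied voxel taken as a patch center. Centers are restricted
## to occupied voxels: an empty center caps the input sum at 2 < theta, so
## its activation underflows to 0 at the default sensitivity.
.activation_matrix <- function(grid, params = cell_params()) {
  occ <- occupied_coords(grid)
  U <- template_directions()
  n <- nrow(occ)
  S <- matrix(0, nrow = n, ncol = 13, dimnames = list(NULL, paste0("o", 1:13)))
  if (n == 0) return(S)
  d <- dim(grid)
  arr <- unclass(grid)
  for (o in 1:13) {
    u <- U[o, ]
    dsum <- rep(1L, n)  # the center itself is occupied
    for (sgn in c(-1L, 1L)) {
      nb <- occ + matrix(sgn * u, nrow = n, ncol = 3, byrow = TRUE)
      inb <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
             nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3]
      dv <- integer(n)
      dv[inb] <- arr[nb[inb, , drop = FALSE]]
      dsum <- dsum + dv
    }
    S[, o] <- .sigmoid(params$k * (dsum - params$theta))
  }
  S
}

#' Complex-cell responses over a whole volume
#'
#' Pools the simple-cell activation of every local neighborhood into the 13
#' complex stereo-orientation selective cells: `c_o` is the sum of cell
#' `o`'s activation over all patch centers. Only occupied voxels are
#' visited as centers; with the default sharp sigmoid this is exactly
#' equivalent to visiting every voxel, because an empty center can
#' contribute at most an input sum of 2, below the threshold.
#'
#' @param grid A [voxel_grid].
#' @param params A [cell_params] object.
#' @return A named numeric vector of length 13 (the `ResponseVector`).
#' @examples
#' g <- voxel_grid(c(9, 9, 9), coords = cbind(2:8, 5, 5))  # x-segment, L = 7
#' global_response(g)  # c_1 ~ 5, rest ~ 0
#' @export
global_response <- function(grid, params = cell_params()) {
  colSums(.activation_matrix(grid, params))
}

#' Classify the global stereo-orientation of a volume
#'
#' The complex cell with the greatest activation indicates the global
#' orientation. Ties are broken deterministically to the lowest template
#' id. If every response is below 0.5 (featureless input: no local
#' collinear triple anywhere), the prediction is the sentinel `NA`.
#'
#' @param grid A [voxel_grid].
#' @param params A [cell_params] object.
#' @return An `avs_recognition` object: list with `responses` (length-13
#'   named vector), `predicted` (template id or `NA`), and `n_centers`
#'   (number of patch centers evaluated).
#' @export
classify_orientation <- function(grid, params = cell_params()) {
  responses <- global_response(grid, params)
  predicted <- if (all(responses < 0.5)) NA_integer_ else which.max(responses)
  structure(
    list(responses = responses,
         predicted = as.integer(predicted),
         n_centers = n_occupied(grid)),
    class = "avs_recognition"
  )
}

#' @export
print.avs_recognition <- function(x, ...) {
  lab <- if (is.na(x$predicted)) "NONE" else {
    u <- template_direction(x$predicted)
    sprintf("%d (%d, %d, %d)", x$predicted, u[1], u[2], u[3])
  }
  cat(sprintf("<avs_recognition: predicted orientation %s, %d centers>\n",
              lab, x$n_centers))
  print(round(x$responses, 3))
  invisible(x)
}

#' Normalize complex-cell response traces
#'
#' Divides each cell's activation series by its own maximum over the trace,
#' as is conventional when plotting neuron responses to drifting stimuli.
#' Series that are zero everywhere are left at zero.
#'
#' @param trace A numeric matrix, one row per frame and one column per cell
#'   (13 columns for the full model), or a list of response vectors.
#' @return A matrix of the same shape with each column scaled to max 1.
#' @export
normalize_responses <- function(trace) {
  if (is.list(trace)) trace <- do.call(rbind, trace)
  trace <- as.matrix(trace)
  if (nrow(trace) == 0) stop("`trace` must be nonempty", call. = FALSE)
  mx <- apply(trace, 2, max)
  mx[mx == 0] <- 1
  sweep(trace, 2, mx, "/")
}
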