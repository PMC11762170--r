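#' Simple-cell sigmoid parameters
#'
#' The simple stereo-orientation selective cell fires according to
#' `s = 1 / (1 + exp(-k * (sum(d) - theta)))`, where `d` are the three
#' binary depth responses of its afferents. With the defaults
#' (`k = 1e4`, `theta = 2.5`) the sigmoid is effectively a step function on
#' the integer input sum: `s` is ~1 when all three elements of the collinear
#' triple are present (sum = 3) and ~0 otherwise (sum <= 2).
#'
#' @param k Response sensitivity (sigmoid steepness), > 0. Default `1e4`.
#' @param theta Activation threshold on the input sum. Default `2.5`.
#' @return A `cell_params` object.
#' @export
cell_params <- function(k = 1e4, theta = 2.5) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta)) {
    stop("`theta` must be a single finite number", call. = FALSE)
  }
  structure(list(k = k, theta = theta), class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params k = %g, theta = %g>\n", x$k, x$theta))
  invisible(x)
}

## numerically stable sigmoid via the logistic CDF: exact at extreme
## arguments (k = 1e4 gives hard 0/1 rather than denormal dust, so silent
## complex cells sum to exactly zero) and immune to exp() overflow
.sigmoid <- function(z) {
  stats::plogis(z)
}

#' Depth-selective cell response
#'
#' Reads one entry of a 3x3x3 local patch by v-index: 1 if the spatial
#' element exists, 0 otherwise. Entries whose absolute coordinate fell
#' outside the parent grid are 0 by the zero-padding convention.
#'
#' @param patch A [local_patch][extract_patch].
#' @param index v-index in 1..27 (center is 14).
#' @return 0 or 1.
#' @export
depth_response <- function(patch, index) {
  stopifnot(inherits(patch, "local_patch"))
  if (!is.numeric(index) || length(index) != 1 || is.na(index) ||
      index != as.integer(index) || index < 1 || index > 27) {
    stop("`index` must be an integer in 1..27", call. = FALSE)
  }
  unname(unclass(patch)[as.integer(index)])
}

#' Simple stereo-orientation selective cell activation
#'
#' Sigmoid combination of three depth responses:
#' `s = 1 / (1 + exp(-k * (d1 + d2 + d3 - theta)))`.
#'
#' @param d Binary vector of length 3 (the three depth responses).
#' @param params A [cell_params] object.
#' @return Activation in \[0, 1\].
#' @examples
#' simple_activation(c(1, 1, 1))  # ~1
#' simple_activation(c(1, 1, 0))  # ~0
#' @export
simple_activation <- function(d, params = cell_params()) {
  stopifnot(inherits(params, "cell_params"))
  d <- as.numeric(d)
  if (length(d) != 3 || any(is.na(d)) || !all(d %in% c(0, 1))) {
    stop("`d` must be three binary depth responses", call. = FALSE)
  }
  .sigmoid(params$k * (sum(d) - params$theta))
}

#' Complex stereo-orientation selective cell aggregation
#'
#' The complex cell pools same-orientation simple cells by plain summation:
#' `c = sum(s_i)`. An empty input gives 0.
#'
#' @param activations Numeric vector of simple-cell activations in \[0, 1\].
#' @return The sum, a single non-negative number.
#' @export
complex_aggregate <- function(activations) {
  activations <- as.numeric(activations)
  if (length(activations) == 0) return(0)
  if (any(is.na(activations)) || any(activations < 0) || any(activations > 1)) {
    stop("activations must lie in [0, 1]", call. = FALSE)
  }
  sum(activations)
}
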