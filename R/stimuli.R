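#' Drift-grating stimulus protocol
#'
#' Defines the periodic bar stimulus used to probe orientation selectivity:
#' a single-voxel-thick frame containing parallel bars at one of four
#' in-plane orientations (0, 45, 90, 135 degrees), drifting one voxel per
#' frame perpendicular to the bars. Each orientation is driven in both
#' orthogonal drift directions; every 100-frame motion block is followed by
#' a 100-frame blank rest block, giving
#' `4 orientations x 2 directions x 200 = 1600` frames by default.
#'
#' Default geometry: 32 x 32 x 1 frames, bar width 2, spatial period 8.
#' Width-2 bars guarantee that only the along-bar template fires (wider
#' bars would co-activate perpendicular templates).
#'
#' @param frame_dims Frame dimensions `(W, H, 1)`.
#' @param bar_width Bar thickness in voxels, `< period`.
#' @param period Spatial period of the bar pattern in voxels.
#' @param orientations In-plane bar orientations in degrees (subset of
#'   0, 45, 90, 135).
#' @param frames_per_phase Frames per motion block and per rest block.
#' @return A `grating_protocol` object.
#' @export
grating_protocol <- function(frame_dims = c(32, 32, 1), bar_width = 2,
                             period = 8, orientations = c(0, 45, 90, 135),
                             frames_per_phase = 100) {
  frame_dims <- as.integer(frame_dims)
  stopifnot(length(frame_dims) == 3, all(frame_dims >= 1), frame_dims[3] == 1,
            bar_width >= 1, bar_width < period,
            all(orientations %in% c(0, 45, 90, 135)),
            frames_per_phase >= 1)
  structure(list(frame_dims = frame_dims, bar_width = as.integer(bar_width),
                 period = as.integer(period), orientations = orientations,
                 frames_per_phase = as.integer(frames_per_phase)),
            class = "grating_protocol")
}

## stripe coordinate of each (0-based) pixel for a bar orientation:
## bars are the level sets of s; drift shifts s by +-1 per frame
.stripe_coord <- function(orientation_deg, x0, y0) {
  switch(as.character(orientation_deg),
         "0"   = y0,        # bars extend along x
         "45"  = x0 - y0,   # bars along (1, 1)
         "90"  = x0,        # bars along y
         "135" = x0 + y0,   # bars along (1, -1)
         stop("unsupported orientation", call. = FALSE))
}

#' Template id matching a grating orientation
#'
#' Maps the in-plane bar angle to the stereo-orientation template that
#' extends along the bars (e.g. 0 degrees -> the x-axis template).
#'
#' @param orientation_deg One of 0, 45, 90, 135.
#' @return Integer template id.
#' @export
grating_orientation_template <- function(orientation_deg) {
  u <- switch(as.character(orientation_deg),
              "0"   = c(1, 0, 0),
              "45"  = c(1, 1, 0),
              "90"  = c(0, 1, 0),
              "135" = c(1, -1, 0),
              stop("unsupported orientation", call. = FALSE))
  direction_id(u)
}

#' Generate a drift-grating stimulus sequence
#'
#' Produces the full ordered frame sequence of the protocol: for each
#' orientation and each of its two opposite drift directions, a motion
#' block (the bar pattern shifted cyclically by one voxel per frame) is
#' followed by an all-blank rest block of equal length.
#'
#' @param protocol A [grating_protocol].
#' @param seed Ignored (the sequence is deterministic); accepted for
#'   interface uniformity with the other generators.
#' @return A `stimulus_sequence`: list with `frames` (a `W x H x n_frames`
#'   0/1 array), `annotation` (data frame with columns `frame`, `state`
#'   (`"moving"`/`"rest"`), `orientation_deg`, `direction`, `phase`), and
#'   the `protocol`.
#' @export
gen_grating_sequence <- function(protocol = grating_protocol(), seed = NULL) {
  stopifnot(inherits(protocol, "grating_protocol"))
  W <- protocol$frame_dims[1]; H <- protocol$frame_dims[2]
  fpp <- protocol$frames_per_phase
  xy <- expand.grid(x0 = 0:(W - 1), y0 = 0:(H - 1))
  n_blocks <- length(protocol$orientations) * 2L
  n_frames <- n_blocks * 2L * fpp
  frames <- array(0L, dim = c(W, H, n_frames))
  ann <- data.frame(frame = seq_len(n_frames), state = "rest",
                    orientation_deg = NA_real_, direction = NA_integer_,
                    phase = NA_integer_)
  f <- 0L
  for (ori in protocol$orientations) {
    s <- .stripe_coord(ori, xy$x0, xy$y0)
    for (dir in c(1L, -1L)) {
      for (phase in 0:(fpp - 1)) {
        f <- f + 1L
        occ <- ((s + dir * phase) %% protocol$period) < protocol$bar_width
        frames[, , f] <- matrix(as.integer(occ), nrow = W)
        ann$state[f] <- "moving"
        ann$orientation_deg[f] <- ori
        ann$direction[f] <- dir
        ann$phase[f] <- phase
      }
      f <- f + fpp  # rest block: frames stay all-zero
    }
  }
  structure(list(frames = frames, annotation = ann, protocol = protocol),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<stimulus_sequence: %d frames of %d x %d (%d moving, %d rest)>\n",
              d[3], d[1], d[2],
              sum(x$annotation$state == "moving"),
              sum(x$annotation$state == "rest")))
  invisible(x)
}

#' Extract one frame of a stimulus sequence as a voxel grid
#'
#' @param sequence A `stimulus_sequence`.
#' @param i Frame index.
#' @return A [voxel_grid] of dims `(W, H, 1)`.
#' @export
frame_grid <- function(sequence, i) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  d <- dim(sequence$frames)
  stopifnot(i >= 1, i <= d[3])
  as_voxel_grid(array(sequence$frames[, , i], dim = c(d[1], d[2], 1)))
}

#' Random-dot stimulus configuration
#'
#' @param volume_dims Volume dimensions, default 32^3.
#' @param n_dots Number of uniformly placed dots per sample (default 300,
#'   about 0.9% occupancy at the default dims).
#' @param n_moving Number of "moving dots": dots extended by one step in
#'   `+u` and `-u`, creating a 3-voxel collinear orientation fragment
#'   (0..5).
#' @param n_samples Samples per dataset/condition (default 1300).
#' @return A `random_dot_config` object.
#' @export
random_dot_config <- function(volume_dims = c(32, 32, 32), n_dots = 300,
                              n_moving = 0, n_samples = 1300) {
  volume_dims <- as.integer(volume_dims)
  stopifnot(length(volume_dims) == 3, all(volume_dims >= 1),
            n_dots >= 1, n_dots <= prod(volume_dims),
            n_moving >= 0, n_moving <= n_dots, n_samples >= 1)
  structure(list(volume_dims = volume_dims, n_dots = as.integer(n_dots),
                 n_moving = as.integer(n_moving),
                 n_samples = as.integer(n_samples)),
            class = "random_dot_config")
}

#' Generate one random-dot volume with embedded orientation fragments
#'
#' Places `n_dots` dots uniformly without replacement, then picks
#' `n_moving` of them and performs the forward/reverse motion: for a chosen
#' dot at `p` with label direction `u`, the voxels `p + u` and `p - u` are
#' additionally occupied, forming a centered collinear triple. Only dots
#' whose full triple fits inside the volume are eligible; with zero moving
#' dots the label carries no signal.
#'
#' @param config A [random_dot_config].
#' @param label Orientation template id 1..13 shared by all moving dots of
#'   the sample.
#' @param seed Optional integer seed.
#' @return List with `grid` (a [voxel_grid]), `label`, and
#'   `moving_centers` (coordinates of the moved dots).
#' @export
gen_random_dot_sample <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "random_dot_config"),
            length(label) == 1, label %in% 1:13)
  if (!is.null(seed)) set.seed(seed)
  d <- config$volume_dims
  idx <- sample.int(prod(d), config$n_dots)
  dots <- arrayInd(idx, d)
  grid <- voxel_grid(d, coords = dots)
  centers <- NULL
  if (config$n_moving > 0) {
    u <- template_direction(label)
    ok <- rep(TRUE, nrow(dots))
    for (a in 1:3) {
      if (u[a] != 0) ok <- ok & dots[, a] - abs(u[a]) >= 1 &
                            dots[, a] + abs(u[a]) <= d[a]
    }
    cand <- which(ok)
    if (length(cand) < config$n_moving) {
      stop("volume too small to fit the requested orientation fragments",
           call. = FALSE)
    }
    pick <- cand[sample.int(length(cand), config$n_moving)]
    centers <- dots[pick, , drop = FALSE]
    um <- matrix(u, nrow = config$n_moving, ncol = 3, byrow = TRUE)
    grid <- set_voxels(grid, rbind(centers + um, centers - um))
  }
  list(grid = grid, label = as.integer(label), moving_centers = centers)
}

#' Oriented line/bar dataset configuration
#'
#' The benchmark objects are straight runs of unit steps along one of the
#' 13 canonical directions: thickness-1 line segments for all classes, and
#' additionally thickness-2 bars (2x2 cross-section) for the three
#' axis-aligned classes. Lengths are drawn uniformly from `lengths`;
#' objects are anchored uniformly at random so they fit entirely inside
#' the volume. Splits are class-balanced.
#'
#' @param volume_dims Volume dimensions, default 16^3.
#' @param lengths Candidate segment lengths (voxels), default 3:9.
#' @param split_sizes Named sizes for the train/validation/test splits,
#'   each divisible by 13. Defaults 15600/5200/5200.
#' @param noise_intensities Background-noise intensities (percent of total
#'   volume voxels) the benchmark evaluates, default 0:5.
#' @param axis_thicknesses Thickness choices for axis-aligned classes,
#'   default `c(1, 2)` drawn with equal probability.
#' @return An `object_dataset_config` object.
#' @export
object_dataset_config <- function(volume_dims = c(16, 16, 16), lengths = 3:9,
                                  split_sizes = c(train = 15600,
                                                  validation = 5200,
                                                  test = 5200),
                                  noise_intensities = 0:5,
                                  axis_thicknesses = c(1, 2)) {
  volume_dims <- as.integer(volume_dims)
  stopifnot(length(volume_dims) == 3, all(volume_dims >= 3),
            all(lengths >= 3), max(lengths) <= max(volume_dims),
            length(split_sizes) >= 1, all(split_sizes %% 13 == 0),
            !is.null(names(split_sizes)),
            all(noise_intensities >= 0), all(noise_intensities <= 100),
            all(axis_thicknesses %in% c(1, 2)))
  structure(list(volume_dims = volume_dims, lengths = as.integer(lengths),
                 split_sizes = split_sizes,
                 noise_intensities = noise_intensities,
                 axis_thicknesses = as.integer(axis_thicknesses)),
            class = "object_dataset_config")
}

## relative voxel offsets of an object (before anchoring)
.object_offsets <- function(class_id, length, thickness) {
  u <- template_direction(class_id)
  base <- outer(0:(length - 1), u)  # length x 3
  if (thickness == 1) return(base)
  if (sum(abs(u)) != 1) {
    stop("thickness-2 bars are defined for axis-aligned classes only",
         call. = FALSE)
  }
  ortho <- which(u == 0)
  ext <- expand.grid(d1 = 0:1, d2 = 0:1)
  out <- do.call(rbind, lapply(seq_len(nrow(ext)), function(i) {
    off <- base
    off[, ortho[1]] <- off[, ortho[1]] + ext$d1[i]
    off[, ortho[2]] <- off[, ortho[2]] + ext$d2[i]
    off
  }))
  out
}

#' Generate a single oriented line/bar object
#'
#' @param config An [object_dataset_config] (supplies the volume dims).
#' @param class_id Orientation template id 1..13.
#' @param length Segment length in unit steps (>= 3).
#' @param thickness 1 (line) or 2 (2x2 bar; axis classes only).
#' @param anchor Optional 1-based coordinate of the object's first voxel;
#'   drawn uniformly among placements that fit when `NULL`.
#' @param seed Optional integer seed (used only when `anchor` is `NULL`).
#' @return List with `grid` (a [voxel_grid]), `class_id`, and the `anchor`
#'   used.
#' @export
gen_object <- function(config, class_id, length, thickness = 1,
                       anchor = NULL, seed = NULL) {
  stopifnot(inherits(config, "object_dataset_config"),
            length >= 3, thickness %in% c(1, 2), class_id %in% 1:13)
  d <- config$volume_dims
  offs <- .object_offsets(class_id, length, thickness)
  lo <- 1 - apply(offs, 2, min)
  hi <- d - apply(offs, 2, max)
  if (any(hi < lo)) {
    stop("object does not fit inside the volume", call. = FALSE)
  }
  if (is.null(anchor)) {
    if (!is.null(seed)) set.seed(seed)
    anchor <- lo + floor(runif(3) * (hi - lo + 1))
    anchor <- pmin(anchor, hi)  # guard the measure-zero runif(1) == 1 case
  } else {
    anchor <- as.integer(anchor)
    if (any(anchor < lo) || any(anchor > hi)) {
      stop("`anchor` places the object outside the volume", call. = FALSE)
    }
  }
  coords <- offs + matrix(anchor, nrow = nrow(offs), ncol = 3, byrow = TRUE)
  list(grid = voxel_grid(d, coords = coords),
       class_id = as.integer(class_id), anchor = as.integer(anchor))
}

#' Generate a class-balanced labeled dataset of oriented objects
#'
#' Draws the full manifest for the configured splits: per sample a class
#' (balanced within each split), a length, a thickness (1 or 2 with equal
#' probability for axis classes, 1 otherwise) and a uniformly drawn anchor.
#' Volumes are realized lazily from the manifest by [realize_sample()],
#' so regeneration under the same seed is exactly reproducible.
#'
#' @param config An [object_dataset_config].
#' @param seed Integer seed for the whole dataset.
#' @return A `labeled_dataset`: list with `manifest` (data frame with
#'   columns `split`, `sample`, `class_id`, `length`, `thickness`, `ax`,
#'   `ay`, `az`), `config`, and `seed`.
#' @export
gen_dataset <- function(config = object_dataset_config(), seed = 1) {
  stopifnot(inherits(config, "object_dataset_config"))
  set.seed(seed)
  d <- config$volume_dims
  U <- template_directions()
  pieces <- lapply(names(config$split_sizes), function(sp) {
    n <- config$split_sizes[[sp]]
    cls <- rep(1:13, each = n / 13)
    len <- sample(config$lengths, n, replace = TRUE)
    thick <- ifelse(cls <= 3,
                    sample(config$axis_thicknesses, n, replace = TRUE), 1L)
    ## vectorized anchor ranges: per axis, offsets span
    ## [min(0, (L-1) u_a), max(0, (L-1) u_a)] plus +1 on the orthogonal
    ## axes of thickness-2 bars
    anc <- matrix(0L, nrow = n, ncol = 3)
    for (a in 1:3) {
      ua <- U[cls, a]
      lo <- 1 - pmin(0L, (len - 1L) * ua)
      hi <- d[a] - pmax(0L, (len - 1L) * ua) - ifelse(thick == 2 & ua == 0, 1L, 0L)
      anc[, a] <- as.integer(lo + pmin(floor(runif(n) * (hi - lo + 1)), hi - lo))
    }
    data.frame(split = sp, sample = seq_len(n), class_id = cls,
               length = len, thickness = as.integer(thick),
               ax = anc[, 1], ay = anc[, 2], az = anc[, 3])
  })
  structure(list(manifest = do.call(rbind, pieces), config = config,
                 seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat("<labeled_dataset>\n")
  for (sp in names(tab)) cat(sprintf("  %s: %d samples\n", sp, tab[[sp]]))
  invisible(x)
}

#' Realize one sample of a labeled dataset as a voxel grid
#'
#' @param dataset A `labeled_dataset` from [gen_dataset()].
#' @param i Row index into `dataset$manifest` (optionally restricted with
#'   `split`).
#' @param split Optional split name; `i` then indexes within that split.
#' @return List with `grid` and `class_id`.
#' @export
realize_sample <- function(dataset, i, split = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  man <- dataset$manifest
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  stopifnot(i >= 1, i <= nrow(man))
  row <- man[i, ]
  gen_object(dataset$config, row$class_id, row$length, row$thickness,
             anchor = c(row$ax, row$ay, row$az))
}

#' Inject uniform background noise into a volume
#'
#' Sets `round(intensity/100 * total voxels)` distinct currently-empty
#' voxels to occupied; the original object voxels are untouched. Intensity
#' is expressed as a percentage of the *total* volume voxel count.
#'
#' @param grid A [voxel_grid].
#' @param intensity_percent Noise intensity in \[0, 100\].
#' @param seed Optional integer seed.
#' @return The noisy [voxel_grid].
#' @examples
#' g <- voxel_grid(c(16, 16, 16))
#' n_occupied(inject_noise(g, 5, seed = 1))  # round(0.05 * 4096) = 205
#' @export
inject_noise <- function(grid, intensity_percent, seed = NULL) {
  stopifnot(is_voxel_grid(grid))
  if (!is.numeric(intensity_percent) || length(intensity_percent) != 1 ||
      is.na(intensity_percent) || intensity_percent < 0 ||
      intensity_percent > 100) {
    stop("`intensity_percent` must be a single number in [0, 100]",
         call. = FALSE)
  }
  n_noise <- round(intensity_percent / 100 * prod(dim(grid)))
  if (n_noise == 0) return(grid)
  if (!is.null(seed)) set.seed(seed)
  empty <- which(unclass(grid) == 0L)
  if (length(empty) < n_noise) {
    stop("not enough empty voxels for the requested noise intensity",
         call. = FALSE)
  }
  grid[empty[sample.int(length(empty), n_noise)]] <- 1L
  grid
}
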