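#' Record complex-cell responses to a drift-grating sequence
#'
#' Runs the recognizer on every frame of a grating stimulus and records the
#' raw and max-normalized activation traces of the 13 complex cells.
#'
#' @param protocol A [grating_protocol].
#' @param params A [cell_params] object.
#' @param seed Ignored (the experiment is deterministic); kept for
#'   interface uniformity.
#' @return A `trace_record`: list with `responses` (n_frames x 13 matrix),
#'   `normalized` (same shape, each cell scaled by its trace maximum),
#'   `annotation` (the frame annotation of the sequence) and `protocol`.
#' @export
run_grating_experiment <- function(protocol = grating_protocol(),
                                   params = cell_params(), seed = NULL) {
  seqn <- gen_grating_sequence(protocol)
  n <- nrow(seqn$annotation)
  responses <- matrix(0, nrow = n, ncol = 13,
                      dimnames = list(NULL, paste0("o", 1:13)))
  for (i in seq_len(n)) {
    if (seqn$annotation$state[i] == "rest") next  # blank frames stay zero
    responses[i, ] <- global_response(frame_grid(seqn, i), params)
  }
  structure(list(responses = responses,
                 normalized = normalize_responses(responses),
                 annotation = seqn$annotation, protocol = protocol),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("<trace_record: %d frames x 13 cells>\n", nrow(x$responses)))
  invisible(x)
}

.empty_confusion <- function() {
  matrix(0L, nrow = 13, ncol = 14,
         dimnames = list(true = paste0("o", 1:13),
                         predicted = c(paste0("o", 1:13), "NONE")))
}

## seeds for per-sample randomness, all < 2^31
.derive_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Orientation-recognition accuracy on a labeled dataset split
#'
#' Optionally injects background noise into every sample, classifies it
#' with the AVS argmax rule, and tallies accuracy and a confusion matrix.
#' A `NONE` prediction (no complex cell reaches 0.5) counts as incorrect.
#'
#' @param dataset A `labeled_dataset` from [gen_dataset()].
#' @param split Split name, default `"test"`.
#' @param params A [cell_params] object.
#' @param noise_intensity Background-noise intensity in percent of total
#'   volume voxels (0 = clean).
#' @param seed Integer seed driving the per-sample noise placement.
#' @param n_samples Optional cap on the number of samples evaluated (the
#'   first `n_samples` of the split, which is class-balanced by
#'   interleaving); `NULL` evaluates the whole split.
#' @return An `accuracy_report`: list with `accuracy`, `n_samples`,
#'   `n_correct`, `noise_intensity`, `split`, `seed` and `confusion`
#'   (13 true classes x 13 predictions + NONE).
#' @export
evaluate_accuracy <- function(dataset, split = "test", params = cell_params(),
                              noise_intensity = 0, seed = 1,
                              n_samples = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  man <- dataset$manifest[dataset$manifest$split == split, , drop = FALSE]
  if (nrow(man) == 0) stop("no samples in split ", split, call. = FALSE)
  if (!is.null(n_samples)) {
    stopifnot(n_samples >= 1, n_samples <= nrow(man))
    ## interleave classes so truncated evaluations stay balanced
    per_class <- nrow(man) / 13
    man <- man[order((man$sample - 1) %% per_class, man$class_id), ,
               drop = FALSE]
    man <- man[seq_len(n_samples), , drop = FALSE]
  }
  n <- nrow(man)
  seeds <- .derive_seeds(n, seed)
  confusion <- .empty_confusion()
  correct <- 0L
  for (i in seq_len(n)) {
    row <- man[i, ]
    obj <- gen_object(dataset$config, row$class_id, row$length,
                      row$thickness, anchor = c(row$ax, row$ay, row$az))
    g <- obj$grid
    if (noise_intensity > 0) g <- inject_noise(g, noise_intensity, seeds[i])
    pred <- classify_orientation(g, params)$predicted
    col <- if (is.na(pred)) 14L else pred
    confusion[row$class_id, col] <- confusion[row$class_id, col] + 1L
    if (!is.na(pred) && pred == row$class_id) correct <- correct + 1L
  }
  structure(list(accuracy = correct / n, n_samples = n, n_correct = correct,
                 noise_intensity = noise_intensity, split = split,
                 seed = seed, confusion = confusion),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report: %.2f%% (%d/%d) at %g%% noise, split %s>\n",
              100 * x$accuracy, x$n_correct, x$n_samples,
              x$noise_intensity, x$split))
  invisible(x)
}

#' Accuracy across a range of background-noise intensities
#'
#' Convenience wrapper running [evaluate_accuracy()] at each intensity
#' with seeds derived from one master seed.
#'
#' @inheritParams evaluate_accuracy
#' @param intensities Noise intensities in percent, default `0:5`.
#' @return A data frame with columns `noise_intensity`, `accuracy`,
#'   `n_samples`, and the list column `report`.
#' @export
run_noise_benchmark <- function(dataset, split = "test",
                                params = cell_params(), intensities = 0:5,
                                seed = 1, n_samples = NULL) {
  seeds <- .derive_seeds(length(intensities), seed)
  reports <- lapply(seq_along(intensities), function(i) {
    evaluate_accuracy(dataset, split, params, intensities[i], seeds[i],
                      n_samples)
  })
  out <- data.frame(noise_intensity = intensities,
                    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
                    n_samples = vapply(reports, `[[`, integer(1), "n_samples"))
  out$report <- reports
  out
}

#' Random-dot sensitivity experiment
#'
#' Measures classification accuracy as a function of the number of moving
#' dots (orientation fragments) embedded in sparse random-dot volumes.
#' Each sample draws a uniform label among the 13 orientations; a `NONE`
#' output (no cell active, typical when no fragment exists) is resolved by
#' a seeded uniform guess, so accuracy at zero moving dots sits at chance
#' (~1/13).
#'
#' @param config A [random_dot_config] (its `n_moving` field is ignored;
#'   the sweep is over `n_moving_values`).
#' @param n_moving_values Conditions to sweep, default `0:5`.
#' @param n_samples Samples per condition; defaults to `config$n_samples`.
#' @param params A [cell_params] object.
#' @param seed Integer master seed.
#' @return A data frame with columns `n_moving`, `accuracy`, `n_samples`.
#' @export
run_random_dot_experiment <- function(config = random_dot_config(),
                                      n_moving_values = 0:5,
                                      n_samples = config$n_samples,
                                      params = cell_params(), seed = 1) {
  stopifnot(inherits(config, "random_dot_config"))
  set.seed(seed)
  acc <- numeric(length(n_moving_values))
  for (j in seq_along(n_moving_values)) {
    cfg <- random_dot_config(config$volume_dims, config$n_dots,
                             n_moving_values[j], n_samples)
    labels <- sample(1:13, n_samples, replace = TRUE)
    sample_seeds <- sample.int(.Machine$integer.max, n_samples)
    guesses <- sample(1:13, n_samples, replace = TRUE)
    correct <- 0L
    for (i in seq_len(n_samples)) {
      smp <- gen_random_dot_sample(cfg, labels[i], sample_seeds[i])
      pred <- classify_orientation(smp$grid, params)$predicted
      if (is.na(pred)) pred <- guesses[i]
      if (pred == labels[i]) correct <- correct + 1L
    }
    acc[j] <- correct / n_samples
  }
  data.frame(n_moving = n_moving_values, accuracy = acc,
             n_samples = n_samples)
}

#' Count the free parameters of the cell cascade
#'
#' Under the dense-mask convention each simple-cell type owns a 27-entry
#' binary connection mask over its 3x3x3 receptive field (3 ones marking
#' the member triple), and the sigmoid constants `k` and `theta` are shared
#' across all cells. The full 13-template model therefore has
#' `13 * 27 + 2 = 353` parameters.
#'
#' @param params A [cell_params] object.
#' @param templates Template table, default [orientation_templates()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(params = cell_params(),
                             templates = orientation_templates()) {
  stopifnot(inherits(params, "cell_params"), is.data.frame(templates))
  nrow(templates) * 27L + 2L
}
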