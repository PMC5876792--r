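# Processing chain applied to each 120 s acquisition before feature
# extraction: zero-phase Butterworth high-pass, non-overlapping 2 s epochs,
# within-epoch z-score artifact rejection.

#' Preprocessing parameters
#'
#' @param hp_cutoff High-pass cutoff, Hz.
#' @param hp_order Butterworth order (the filter is applied forward-backward,
#'   doubling the effective order; features downstream are phase-insensitive).
#' @param epoch_seconds Epoch length, seconds.
#' @param z_threshold Within-epoch |z-score| rejection threshold.
#' @return An object of class `"preprocess_params"`.
#' @export
preprocess_params <- function(hp_cutoff = 500, hp_order = 2,
                              epoch_seconds = 2, z_threshold = 5) {
  stopifnot(hp_cutoff > 0, hp_order >= 1, epoch_seconds > 0, z_threshold > 0)
  structure(list(hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order),
                 epoch_seconds = epoch_seconds, z_threshold = z_threshold),
            class = "preprocess_params")
}

#' Zero-phase Butterworth high-pass filter
#'
#' Designs a Butterworth high-pass of the stated order and cutoff and applies
#' it forward-backward (`signal::filtfilt`), so the output is phase-neutral.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param params A [preprocess_params()].
#' @return Filtered vector, same length.
#' @export
highpass <- function(samples, fs, params = preprocess_params()) {
  if (params$hp_cutoff >= fs / 2)
    stop("invalid-config: high-pass cutoff at or above Nyquist")
  stopifnot(length(samples) >= 3 * params$hp_order)
  bf <- signal::butter(params$hp_order, params$hp_cutoff / (fs / 2),
                       type = "high")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Split a signal into non-overlapping epochs
#'
#' Consecutive windows of `round(fs * epoch_seconds)` samples; a trailing
#' partial window is dropped. Epoch indices are 0-based.
#'
#' @inheritParams highpass
#' @param class_label,particle_id Metadata carried onto each epoch.
#' @return List of `"epoch"` objects (`samples`, `fs`, `index`,
#'   `class_label`, `particle_id`, `accepted = NA`). Empty list (with a
#'   warning) if the input is shorter than one epoch.
#' @export
epoch_split <- function(samples, fs, params = preprocess_params(),
                        class_label = NA_character_,
                        particle_id = NA_character_) {
  len <- round(fs * params$epoch_seconds)
  n_ep <- length(samples) %/% len
  if (n_ep == 0) {
    warning("input shorter than one epoch; returning no epochs")
    return(list())
  }
  lapply(seq_len(n_ep) - 1L, function(i) {
    structure(list(samples = samples[(i * len + 1):((i + 1) * len)],
                   fs = fs, index = i, class_label = class_label,
                   particle_id = particle_id, accepted = NA),
              class = "epoch")
  })
}

#' Z-score artifact rejection rule
#'
#' Computes within-epoch z-scores `(x - mean) / SD` (sample SD, denominator
#' n-1) and accepts the epoch iff no |z| exceeds the threshold and the SD is
#' strictly positive (a constant epoch is degenerate and rejected).
#'
#' @param epoch An `"epoch"` or a numeric vector.
#' @param params A [preprocess_params()].
#' @return Logical: accepted?
#' @export
artifact_reject <- function(epoch, params = preprocess_params()) {
  x <- if (inherits(epoch, "epoch")) epoch$samples else epoch
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(FALSE)
  max(abs(x - mean(x))) / s <= params$z_threshold
}

#' Preprocess one acquisition: filter, split, reject
#'
#' Applies the high-pass to the whole acquisition, splits it into epochs,
#' then flags each epoch by the z-score rule, in that order.
#'
#' @param acq An `"acquisition"`.
#' @param params A [preprocess_params()].
#' @param verbose Report the rejected-epoch tally (default `FALSE`).
#' @return An `"epoch_set"`: list with `epochs` (all epochs, each flagged
#'   `accepted`), and counts `n_total`, `n_accepted`, `n_rejected`.
#' @export
preprocess_acquisition <- function(acq, params = preprocess_params(),
                                   verbose = FALSE) {
  stopifnot(inherits(acq, "acquisition"))
  if (length(acq$samples) == 0 ||
      length(acq$samples) < round(acq$fs * params$epoch_seconds)) {
    return(structure(list(epochs = list(), n_total = 0L, n_accepted = 0L,
                          n_rejected = 0L), class = "epoch_set"))
  }
  filt <- highpass(acq$samples, acq$fs, params)
  eps <- epoch_split(filt, acq$fs, params,
                     class_label = acq$class_label,
                     particle_id = acq$particle_id)
  eps <- lapply(eps, function(e) {
    e$accepted <- artifact_reject(e, params)
    e
  })
  acc <- vapply(eps, function(e) e$accepted, logical(1))
  if (verbose)
    message(sprintf("%s: %d/%d epochs accepted (%d rejected)",
                    acq$particle_id, sum(acc), length(acc), sum(!acc)))
  structure(list(epochs = eps, n_total = length(eps),
                 n_accepted = sum(acc), n_rejected = sum(!acc)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs: %d accepted, %d rejected\n",
              x$n_total, x$n_accepted, x$n_rejected))
  invisible(x)
}
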