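# Preprocessing: recording container, amplitude-threshold artifact
# rejection on the 2-s block grid, and non-overlapping epoching.

#' Construct a raw MEG recording
#'
#' @param values Numeric `[channels x samples]` matrix, tesla.
#' @param sampling_rate Sampling rate, Hz.
#' @param subject_id,condition Labels carried through the pipeline.
#' @return An object of class `meg_recording`.
#' @export
meg_recording <- function(values, sampling_rate, subject_id = NA_character_,
                          condition = NA_character_) {
  stopifnot(is.matrix(values), all(is.finite(values)), sampling_rate > 0)
  structure(list(values = values, sampling_rate = sampling_rate,
                 subject_id = subject_id, condition = condition,
                 band = NULL),
            class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              x$sampling_rate, ncol(x$values) / x$sampling_rate))
  invisible(x)
}

#' Remove blocks contaminated by large-amplitude artifacts
#'
#' Scans the recording in contiguous blocks aligned to the epoch grid
#' (default 2 s, matching downstream segmentation) and excises every block
#' in which any channel exceeds `threshold` in absolute value. The default
#' threshold of 10 pT follows standard practice for whole-head MEG. A
#' trailing partial block is kept (it is discarded later by epoching), so
#' rejection and epoching commute and rejection is idempotent.
#'
#' @param rec A `meg_recording`.
#' @param threshold Rejection threshold in tesla (default `10e-12`).
#' @param block_length Block length in seconds (default 2).
#' @return The cleaned `meg_recording`, with a `rejection` field:
#'   `removed_blocks` (1-based indices on the input grid), `n_blocks`, and
#'   `retained_seconds`.
#' @export
reject_artifacts <- function(rec, threshold = 10e-12, block_length = 2) {
  stopifnot(inherits(rec, "meg_recording"), threshold > 0)
  spb <- as.integer(round(block_length * rec$sampling_rate))
  n <- ncol(rec$values)
  n_blocks <- n %/% spb
  removed <- integer(0)
  keep <- rep(TRUE, n)
  if (n_blocks > 0) {
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1L) * spb + 1L):(b * spb)
      if (max(abs(rec$values[, idx])) > threshold) {
        removed <- c(removed, b)
        keep[idx] <- FALSE
      }
    }
  }
  if (sum(keep) < spb) {
    stop_megspect(sprintf(
      "no usable data after artifact rejection (subject %s, condition %s)",
      rec$subject_id, rec$condition), "megspect_no_data")
  }
  rec$values <- rec$values[, keep, drop = FALSE]
  rec$rejection <- list(removed_blocks = removed, n_blocks = n_blocks,
                        retained_seconds = sum(keep) / rec$sampling_rate)
  rec
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the recording into `floor(duration / epoch_length)` consecutive
#' non-overlapping epochs; the trailing remainder is discarded.
#'
#' @param rec A `meg_recording`.
#' @param epoch_length Epoch length in seconds (default 2).
#' @return An object of class `meg_epochs` with fields `epochs`
#'   (`[epochs x channels x samples]` array), `sampling_rate`,
#'   `epoch_length`, `band`, `subject_id`, `condition`, and `provenance`
#'   (retained epoch indices).
#' @export
segment_epochs <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "meg_recording"))
  spe <- as.integer(round(epoch_length * rec$sampling_rate))
  n <- ncol(rec$values)
  if (n < spe) {
    stop_megspect("recording shorter than one epoch", "megspect_too_short")
  }
  n_epochs <- n %/% spe
  nch <- nrow(rec$values)
  arr <- array(NA_real_, dim = c(n_epochs, nch, spe))
  for (e in seq_len(n_epochs)) {
    arr[e, , ] <- rec$values[, ((e - 1L) * spe + 1L):(e * spe)]
  }
  structure(list(epochs = arr, sampling_rate = rec$sampling_rate,
                 epoch_length = epoch_length, band = rec$band,
                 subject_id = rec$subject_id, condition = rec$condition,
                 provenance = seq_len(n_epochs)),
            class = "meg_epochs")
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<meg_epochs> %s/%s: %d epochs x %d channels x %d samples (%s)\n",
              x$subject_id, x$condition, d[1], d[2], d[3],
              x$band %||% "broadband"))
  invisible(x)
}
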