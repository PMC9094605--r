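#' Multi-channel LFP recording container
#'
#' A `recording` bundles a channels-by-time sample matrix (microvolts), the
#' sampling rate and per-animal metadata. The canonical montage has four
#' depth electrodes: hippocampal CA1 (`HPC`), retrosplenial cortex (`RSC`),
#' medial entorhinal cortex (`MEC`) and thalamus (`Tha`), sampled at
#' 1000 Hz, but any channel set is accepted.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique channel names; defaults
#'   to the rownames of `samples` or `ch1..chK`.
#' @param meta optional [animal_meta()] record (or any named list) carried
#'   through the pipeline.
#' @return An object of class `recording`.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), 1000,
#'                  channel_labels = c("HPC", "RSC"))
#' rec
#' @export
recording <- function(samples, sampling_rate, channel_labels = NULL,
                      meta = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix")
  }
  assert_scalar_num(sampling_rate, "sampling_rate", lower = .Machine$double.eps)
  channel_labels <- channel_labels %||% rownames(samples) %||%
    paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples)) {
    abort("`channel_labels` length must equal the number of channels")
  }
  if (anyDuplicated(channel_labels)) abort("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = channel_labels, meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, as.character)),
                         sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' Animal metadata record
#'
#' Closed-vocabulary study metadata attached to recordings and rows of the
#' study table: transgenic (`TG`) vs wild-type (`WT`) genotype, tau-seed vs
#' buffer injection, age at injection (3 or 6 months) and recording
#' timepoint (pre-injection, one day post, then 1/3/5 months post
#' injection).
#'
#' @param animal_id character scalar.
#' @param sex `"M"` or `"F"`.
#' @param genotype `"TG"` or `"WT"`.
#' @param treatment `"tau"` or `"buffer"`.
#' @param age_at_injection `"3mo"` or `"6mo"`.
#' @param timepoint one of `"Pre"`, `"Post"`, `"1mpi"`, `"3mpi"`, `"5mpi"`.
#' @return A named list of class `animal_meta`.
#' @export
animal_meta <- function(animal_id, sex = "F", genotype = "WT",
                        treatment = "buffer", age_at_injection = "3mo",
                        timepoint = "Pre") {
  sex <- match.arg(sex, c("M", "F"))
  genotype <- match.arg(genotype, c("TG", "WT"))
  treatment <- match.arg(treatment, c("tau", "buffer"))
  age_at_injection <- match.arg(age_at_injection, c("3mo", "6mo"))
  timepoint <- match.arg(timepoint, c("Pre", "Post", "1mpi", "3mpi", "5mpi"))
  structure(list(animal_id = as.character(animal_id), sex = sex,
                 genotype = genotype, treatment = treatment,
                 age_at_injection = age_at_injection, timepoint = timepoint),
            class = "animal_meta")
}

#' Animal motion trace
#'
#' Nonnegative per-frame displacement (pixels/frame) from video tracking,
#' sampled at the video frame rate (25 Hz by default). Used only for
#' activity gating of epochs; the tracking itself is upstream of this
#' package.
#'
#' @param displacement numeric vector of nonnegative displacements.
#' @param frame_rate frames per second (> 0), default 25.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(displacement, frame_rate = 25) {
  if (!is.numeric(displacement) || any(displacement < 0) ||
      anyNA(displacement)) {
    abort("`displacement` must be a nonnegative numeric vector")
  }
  assert_scalar_num(frame_rate, "frame_rate", lower = .Machine$double.eps)
  structure(list(displacement = as.numeric(displacement),
                 frame_rate = frame_rate),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames @ %g Hz (%.1f s), peak %.3g\n",
              length(x$displacement), x$frame_rate,
              length(x$displacement) / x$frame_rate,
              if (length(x$displacement)) max(x$displacement) else NA))
  invisible(x)
}
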