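#' Fixed-length epoch set
#'
#' Internal constructor for the container produced by [segment_epochs()]:
#' an `n_epochs x channels x samples` array plus per-epoch activity and
#' artifact labels and the original epoch indices.
#'
#' @param epochs 3D numeric array, epoch x channel x sample.
#' @param sampling_rate Hz.
#' @param channel_labels channel names.
#' @param epoch_length seconds.
#' @param index original 1-based epoch indices within the session.
#' @param activity,artifact optional 0/1 integer vectors per epoch.
#' @param meta carried metadata.
#' @return An object of class `epoch_set`.
#' @keywords internal
#' @export
epoch_set <- function(epochs, sampling_rate, channel_labels, epoch_length,
                      index = seq_len(dim(epochs)[1]), activity = NULL,
                      artifact = NULL, meta = NULL) {
  stopifnot(length(dim(epochs)) == 3)
  if (dim(epochs)[3] != round(epoch_length * sampling_rate)) {
    abort("epoch sample count must equal epoch_length * sampling_rate")
  }
  chk <- function(x, nm) {
    if (!is.null(x) && (!all(x %in% c(0L, 1L)) || length(x) != dim(epochs)[1]))
      abort(sprintf("`%s` must be 0/1 per epoch", nm))
    if (is.null(x)) NULL else as.integer(x)
  }
  structure(list(epochs = epochs, sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 epoch_length = epoch_length, index = as.integer(index),
                 activity = chk(activity, "activity"),
                 artifact = chk(artifact, "artifact"), meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) x %d channel(s) x %d samples (%g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_length, x$sampling_rate))
  if (!is.null(x$activity)) cat("  active:", sum(x$activity), "\n")
  if (!is.null(x$artifact)) cat("  artifactual:", sum(x$artifact), "\n")
  cat("  retained:", n_retained(x), "\n")
  invisible(x)
}

#' Number of retained (active, artifact-free) epochs
#' @param epochs an [epoch_set()].
#' @return Integer count of epochs with activity 1 and artifact 0; epochs
#'   with missing labels are counted via the available labels only.
#' @export
n_retained <- function(epochs) {
  act <- epochs$activity %||% rep(1L, dim(epochs$epochs)[1])
  art <- epochs$artifact %||% rep(0L, dim(epochs$epochs)[1])
  sum(act == 1L & art == 0L)
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' Splits the session into contiguous, non-overlapping epochs of
#' `epoch_length` seconds (4 s by default) in temporal order; a trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param rec a [recording()].
#' @param epoch_length epoch length in seconds, default 4.
#' @return An [epoch_set()] with `floor(duration / epoch_length)` epochs.
#' @examples
#' rec <- simulate_lfp(lfp_spec(duration = 10), channel_labels = "HPC")
#' segment_epochs(rec) # 2 epochs; final 2 s discarded
#' @export
segment_epochs <- function(rec, epoch_length = 4) {
  stopifnot(inherits(rec, "recording"))
  assert_scalar_num(epoch_length, "epoch_length", lower = .Machine$double.eps)
  spp <- round(epoch_length * rec$sampling_rate) # samples per epoch
  n_ep <- ncol(rec$samples) %/% spp
  if (n_ep < 1) {
    abort(sprintf("recording (%.3g s) is shorter than one %g-s epoch",
                  rec_duration(rec), epoch_length))
  }
  ep <- array(0, c(n_ep, nrow(rec$samples), spp))
  for (i in seq_len(n_ep)) {
    ep[i, , ] <- rec$samples[, ((i - 1) * spp + 1):(i * spp), drop = FALSE]
  }
  epoch_set(ep, rec$sampling_rate, rec$channel_labels, epoch_length,
            meta = rec$meta)
}

#' Classify epochs as active or inactive from the motion trace
#'
#' The activity threshold is relative: 30% (by default) of the peak
#' displacement over the entire session. An epoch is active iff at least
#' `min_active_fraction` of its video frames exceed that threshold. The
#' rule is invariant to uniform scaling of the trace. An all-zero trace
#' yields all-inactive epochs with a warning.
#'
#' @param motion a [motion_trace()] time-matched to the session.
#' @param n_epochs number of epochs to label (frames beyond
#'   `n_epochs * epoch_length` are ignored).
#' @param epoch_length seconds, default 4.
#' @param threshold_fraction fraction of the session peak, default 0.30.
#' @param min_active_fraction minimum fraction of supra-threshold frames
#'   for an active epoch, default 0.25.
#' @return Integer 0/1 vector of length `n_epochs`.
#' @export
classify_activity <- function(motion, n_epochs, epoch_length = 4,
                              threshold_fraction = 0.30,
                              min_active_fraction = 0.25) {
  stopifnot(inherits(motion, "motion_trace"))
  fpe <- round(epoch_length * motion$frame_rate) # frames per epoch
  need <- n_epochs * fpe
  if (length(motion$displacement) < need) {
    abort(sprintf("motion trace (%d frames) does not cover %d epochs (%d frames)",
                  length(motion$displacement), n_epochs, need))
  }
  peak <- max(motion$displacement)
  if (peak == 0) {
    warn("all-zero motion trace: every epoch classified inactive")
    return(rep(0L, n_epochs))
  }
  thr <- threshold_fraction * peak
  above <- motion$displacement[seq_len(need)] > thr
  frac <- vapply(seq_len(n_epochs), function(i) {
    mean(above[((i - 1) * fpe + 1):(i * fpe)])
  }, numeric(1))
  as.integer(frac >= min_active_fraction)
}

#' Artifact-detection parameters
#'
#' Permissive defaults intended to catch only gross faults: an absolute
#' amplitude clip, a robust z-score limit against the session-wide median
#' and MAD, and a minimum flatline run of zero first differences. These
#' are package conventions exposed as knobs, not values taken from any
#' particular acquisition setup.
#'
#' @param amplitude_limit microvolts, default 1000.
#' @param zscore_limit robust z-score limit, default 8.
#' @param flatline_min_run samples of constant signal, default 100.
#' @return A list of class `artifact_params`.
#' @export
artifact_params <- function(amplitude_limit = 1000, zscore_limit = 8,
                            flatline_min_run = 100) {
  assert_scalar_num(amplitude_limit, "amplitude_limit",
                    lower = .Machine$double.eps)
  assert_scalar_num(zscore_limit, "zscore_limit", lower = .Machine$double.eps)
  assert_scalar_num(flatline_min_run, "flatline_min_run", lower = 1)
  structure(list(amplitude_limit = amplitude_limit,
                 zscore_limit = zscore_limit,
                 flatline_min_run = as.integer(flatline_min_run)),
            class = "artifact_params")
}

longest_constant_run <- function(x) {
  if (length(x) < 2) return(length(x))
  r <- rle(diff(x) == 0)
  z <- r$lengths[r$values]
  if (length(z) == 0) 1L else max(z) + 1L
}

#' Flag artifactual epochs
#'
#' An epoch is flagged iff, in any channel, (a) any sample exceeds the
#' absolute amplitude limit, (b) any sample's robust z-score (against the
#' session-wide per-channel median and MAD) exceeds the z limit, or (c) a
#' run of at least `flatline_min_run` identical samples occurs. Flags are
#' order-independent across epochs, and monotone in the parameters:
#' loosening any limit can only unflag.
#'
#' @param epochs an [epoch_set()].
#' @param params an [artifact_params()].
#' @return Integer 0/1 vector per epoch.
#' @export
detect_artifacts <- function(epochs, params = artifact_params()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(params, "artifact_params"))
  ne <- dim(epochs$epochs)[1]
  nc <- dim(epochs$epochs)[2]
  med <- numeric(nc); mad_ <- numeric(nc)
  for (c in seq_len(nc)) {
    all_c <- as.numeric(epochs$epochs[, c, ])
    med[c] <- median(all_c)
    mad_[c] <- stats::mad(all_c)
  }
  flags <- integer(ne)
  for (i in seq_len(ne)) {
    bad <- FALSE
    for (c in seq_len(nc)) {
      x <- epochs$epochs[i, c, ]
      if (max(abs(x)) > params$amplitude_limit) { bad <- TRUE; break }
      if (mad_[c] > 0 &&
          max(abs(x - med[c])) / mad_[c] > params$zscore_limit) {
        bad <- TRUE; break
      }
      if (longest_constant_run(x) >= params$flatline_min_run) {
        bad <- TRUE; break
      }
    }
    flags[i] <- as.integer(bad)
  }
  flags
}

#' Retain active, artifact-free epochs
#'
#' Subsets the epoch set to epochs with activity 1 and artifact 0; the
#' original epoch indices are preserved in `$index`. Re-running the
#' selection on a retained set is the identity.
#'
#' @param epochs an [epoch_set()] with activity and artifact labels.
#' @return The retained [epoch_set()].
#' @export
select_analysis_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$activity) || is.null(epochs$artifact)) {
    abort("activity and artifact labels must be populated before selection")
  }
  keep <- epochs$activity == 1L & epochs$artifact == 0L
  if (!any(keep)) {
    abort("no retained epochs: session must be excluded from analysis")
  }
  epoch_set(epochs$epochs[keep, , , drop = FALSE], epochs$sampling_rate,
            epochs$channel_labels, epochs$epoch_length,
            index = epochs$index[keep],
            activity = epochs$activity[keep], artifact = epochs$artifact[keep],
            meta = epochs$meta)
}

#' Session inclusion decision
#'
#' A session enters the study only if it retains at least `min_retained`
#' clean active epochs (a package convention; the cutoff is a knob).
#'
#' @param epochs an [epoch_set()] with labels populated.
#' @param min_retained minimum retained epochs, default 30.
#' @return Logical scalar.
#' @export
session_inclusion <- function(epochs, min_retained = 30) {
  n_retained(epochs) >= min_retained
}

#' Run the full preprocessing stage on one session
#'
#' Segments the recording, labels activity from the motion trace, flags
#' artifacts, and returns the retained epoch set plus the per-epoch
#' report.
#'
#' @param rec a [recording()].
#' @param motion a [motion_trace()] covering the session.
#' @param epoch_length seconds, default 4.
#' @param params an [artifact_params()].
#' @param threshold_fraction,min_active_fraction see [classify_activity()].
#' @return A list with `retained` (an [epoch_set()]) and `report`, a
#'   tibble with columns `epoch`, `active`, `artifact`, `retained`.
#' @export
preprocess_session <- function(rec, motion, epoch_length = 4,
                               params = artifact_params(),
                               threshold_fraction = 0.30,
                               min_active_fraction = 0.25) {
  ep <- segment_epochs(rec, epoch_length)
  ep$activity <- classify_activity(motion, dim(ep$epochs)[1], epoch_length,
                                   threshold_fraction, min_active_fraction)
  ep$artifact <- detect_artifacts(ep, params)
  report <- tibble::tibble(
    epoch = ep$index, active = ep$activity, artifact = ep$artifact,
    retained = as.integer(ep$activity == 1L & ep$artifact == 0L)
  )
  list(retained = select_analysis_epochs(ep), report = report)
}
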