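#' Specification for a synthetic motion trace
#'
#' Emulates a video-tracked displacement trace with alternating active and
#' inactive bouts. Bout durations are exponential; the inactive-bout mean
#' is scaled so the long-run fraction of time spent active equals
#' `active_bout_fraction`. Active frames draw displacements uniformly on
#' `[0.4, 1] * active_amplitude`, so every active frame clears the
#' 30%-of-session-peak activity threshold used downstream; inactive frames
#' are at `inactive_amplitude` (default 0, a still animal).
#'
#' @param duration seconds (> 0).
#' @param frame_rate video frame rate in Hz, default 25.
#' @param active_bout_fraction long-run active fraction in \[0, 1\].
#' @param bout_mean_length mean active-bout length, seconds.
#' @param active_amplitude peak-scale displacement of active frames
#'   (pixels/frame).
#' @param inactive_amplitude upper bound of inactive-frame displacement.
#' @param seed integer seed.
#' @return A list of class `motion_spec`.
#' @seealso [simulate_motion()]
#' @export
motion_spec <- function(duration, frame_rate = 25, active_bout_fraction = 0.5,
                        bout_mean_length = 20, active_amplitude = 10,
                        inactive_amplitude = 0, seed = 1) {
  assert_scalar_num(duration, "duration", lower = .Machine$double.eps)
  assert_scalar_num(active_bout_fraction, "active_bout_fraction", 0, 1)
  assert_scalar_num(bout_mean_length, "bout_mean_length",
                    lower = .Machine$double.eps)
  assert_scalar_num(active_amplitude, "active_amplitude", lower = 0)
  assert_scalar_num(inactive_amplitude, "inactive_amplitude", lower = 0)
  structure(list(duration = duration, frame_rate = frame_rate,
                 active_bout_fraction = active_bout_fraction,
                 bout_mean_length = bout_mean_length,
                 active_amplitude = active_amplitude,
                 inactive_amplitude = inactive_amplitude, seed = seed),
            class = "motion_spec")
}

#' Simulate an animal motion trace
#'
#' @param spec a [motion_spec()].
#' @return A [motion_trace()].
#' @examples
#' tr <- simulate_motion(motion_spec(duration = 120, active_bout_fraction = 0.5))
#' mean(tr$displacement > 0.3 * max(tr$displacement))
#' @export
simulate_motion <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  n <- round(spec$duration * spec$frame_rate)
  f <- spec$active_bout_fraction
  with_seed(spec$seed, {
    if (f <= 0) {
      active <- rep(FALSE, n)
    } else if (f >= 1) {
      active <- rep(TRUE, n)
    } else {
      mean_active <- spec$bout_mean_length
      mean_inactive <- mean_active * (1 - f) / f
      active <- logical(0)
      state <- runif(1) < f
      while (length(active) < n) {
        len <- rexp(1, rate = 1 / (if (state) mean_active else mean_inactive))
        active <- c(active, rep(state, max(1L, round(len * spec$frame_rate))))
        state <- !state
      }
      active <- active[seq_len(n)]
    }
    disp <- numeric(n)
    disp[active] <- spec$active_amplitude * runif(sum(active), 0.4, 1)
    disp[!active] <- spec$inactive_amplitude * runif(sum(!active), 0, 1)
    motion_trace(disp, spec$frame_rate)
  })
}
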