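#' Pupil orienting-response kernel
#'
#' Parameters of the event-locked pupil constriction used by the
#' synthetic generators. The orienting response is a transient
#' constriction that begins roughly 200-300 ms after stimulus onset and
#' resolves by roughly 700-1200 ms. Only its timing and amplitude
#' matter for median-window features, so the functional form is a
#' smooth raised-cosine dip: zero before `onset_latency_ms`, most
#' negative at `time_to_trough_ms`, back to zero at `recovery_end_ms`
#' and afterwards.
#'
#' @param onset_latency_ms Constriction onset latency (ms).
#' @param time_to_trough_ms Time of maximum constriction (ms);
#'   must exceed `onset_latency_ms`.
#' @param recovery_end_ms Time at which the response has returned to
#'   baseline (ms); must exceed `time_to_trough_ms`.
#' @param amplitude Peak deflection in arbitrary units; negative values
#'   are constrictions. Generators draw this per event.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(onset_latency_ms = 250,
                          time_to_trough_ms = 650,
                          recovery_end_ms = 1000,
                          amplitude = -100) {
  k <- list(onset_latency_ms = as.numeric(onset_latency_ms),
            time_to_trough_ms = as.numeric(time_to_trough_ms),
            recovery_end_ms = as.numeric(recovery_end_ms),
            amplitude = as.numeric(amplitude))
  if (!(k$onset_latency_ms < k$time_to_trough_ms &&
        k$time_to_trough_ms < k$recovery_end_ms))
    stop("kernel timing must satisfy onset < trough < end", call. = FALSE)
  if (!is.finite(k$amplitude))
    stop("kernel amplitude must be finite", call. = FALSE)
  structure(k, class = "kernel_params")
}

#' Evaluate the pupil orienting kernel
#'
#' @param t_ms Time since model/stimulus onset (ms, >= 0); vectorized.
#' @param k A [kernel_params()].
#' @return Pupil deflection in arbitrary units at each `t_ms`: 0 before
#'   onset and after recovery, `k$amplitude` exactly at the trough.
#' @examples
#' k <- kernel_params()
#' pupil_kernel(0, k)                     # 0 (pre-onset)
#' pupil_kernel(k$time_to_trough_ms, k)   # the extremum
#' @export
pupil_kernel <- function(t_ms, k) {
  k$amplitude * kernel_shape(t_ms, k)
}

# Unit-amplitude raised-cosine dip: 0 outside [onset, end], 1 at trough.
kernel_shape <- function(t_ms, k) {
  s <- numeric(length(t_ms))
  up <- t_ms >= k$onset_latency_ms & t_ms <= k$time_to_trough_ms
  dn <- t_ms > k$time_to_trough_ms & t_ms <= k$recovery_end_ms
  s[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - k$onset_latency_ms) /
                            (k$time_to_trough_ms - k$onset_latency_ms)))
  s[dn] <- 0.5 * (1 - cos(pi * (k$recovery_end_ms - t_ms[dn]) /
                            (k$recovery_end_ms - k$time_to_trough_ms)))
  s
}

#' Median kernel gain over the orienting window
#'
#' The orienting amplitude feature is the (negated) median of the
#' baseline-corrected pupil trace over the orienting window, not the
#' kernel's peak. This helper returns the median of the unit-amplitude
#' kernel shape over the window's 1-ms grid, i.e. the factor relating a
#' kernel's peak amplitude to the feature the extractor measures. The
#' generators divide planted orienting amplitudes by this gain so that,
#' in the noiseless limit, extracted features equal planted values.
#'
#' @param k A [kernel_params()].
#' @param window_ms Length-2 closed window in ms (default the standard
#'   orienting window 500-1000 ms).
#' @return A scalar in (0, 1].
#' @export
kernel_window_gain <- function(k, window_ms = c(500, 1000)) {
  grid <- seq(window_ms[1], window_ms[2], by = 1)
  g <- stats::median(kernel_shape(grid, k))
  if (g <= 0)
    stop("kernel has no constriction mass in the orienting window; ",
         "check kernel timing against the window", call. = FALSE)
  g
}
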