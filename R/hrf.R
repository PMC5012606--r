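#' Canonical double-gamma hemodynamic response function
#'
#' The response peaks at `peak` seconds and undershoots at `undershoot`
#' seconds (gamma-density modes), with the undershoot scaled by
#' `1 / undershoot_ratio`. The curve is rescaled to a maximum of 1 so that
#' regressor amplitudes are interpretable as response peaks.
#'
#' @param t numeric vector of times in seconds (values before 0 return 0).
#' @param peak time-to-peak of the positive lobe, seconds.
#' @param undershoot time of the undershoot trough, seconds.
#' @param undershoot_ratio positive-to-undershoot amplitude ratio.
#' @return numeric vector of responses, unit peak.
#' @export
#' @examples
#' hrf_double_gamma(seq(0, 30, by = 0.5))
hrf_double_gamma <- function(t, peak = 5, undershoot = 15,
                             undershoot_ratio = 6) {
  h <- function(tt, mode) {
    # gamma density with rate 1 has mode shape - 1
    shape <- mode + 1
    out <- numeric(length(tt))
    pos <- tt > 0
    out[pos] <- stats::dgamma(tt[pos], shape = shape, rate = 1)
    out
  }
  y <- h(t, peak) - h(t, undershoot) / undershoot_ratio
  # unit peak over a dense reference grid so scaling is input-independent
  ref <- h(seq(0, 40, by = 0.01), peak) -
    h(seq(0, 40, by = 0.01), undershoot) / undershoot_ratio
  y / max(ref)
}

#' Build an HRF-convolved regressor sampled at volume times
#'
#' Events are laid down as boxcars of the given durations and amplitudes on a
#' finely oversampled time grid, convolved with the HRF, and sampled at
#' `(0:(n_vol - 1)) * tr`. The convolved response to a single unit event is
#' rescaled to unit peak, so `amplitudes` are peak responses.
#'
#' @param onsets,durations,amplitudes per-event vectors (seconds, seconds,
#'   arbitrary units). `durations` and `amplitudes` are recycled.
#' @param n_vol number of volumes.
#' @param tr repetition time, seconds.
#' @param hrf_fun function of time returning the response shape.
#' @param oversample fine-grid steps per second.
#' @return numeric vector of length `n_vol`.
#' @export
convolve_regressor <- function(onsets, durations, amplitudes, n_vol, tr = 2.2,
                               hrf_fun = hrf_double_gamma, oversample = 10) {
  durations <- rep_len(durations, length(onsets))
  amplitudes <- rep_len(amplitudes, length(onsets))
  dt <- 1 / oversample
  t_max <- n_vol * tr + 32
  grid <- seq(0, t_max, by = dt)
  neural <- numeric(length(grid))
  for (i in seq_along(onsets)) {
    idx <- which(grid >= onsets[i] & grid < onsets[i] + durations[i])
    neural[idx] <- neural[idx] + amplitudes[i]
  }
  kern <- hrf_fun(seq(0, 32, by = dt))
  conv <- convolve(neural, rev(kern), type = "open")[seq_along(grid)]
  # normalize so one unit event of the first duration has unit peak response
  unit <- numeric(length(grid))
  unit[grid < durations[1]] <- 1
  unit_conv <- convolve(unit, rev(kern), type = "open")[seq_along(grid)]
  scale <- max(unit_conv)
  if (scale > 0) conv <- conv / scale
  conv[pmin(length(grid), 1 + round((seq_len(n_vol) - 1) * tr / dt))]
}
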