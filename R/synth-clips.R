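#' Per-quadrant generative profile for synthetic clips
#'
#' Controls the target distributions of the motion and brightness levels of
#' synthetic clips per affect quadrant, plus audio parameters. The default
#' emulates the structure of the naturalistic stimulus set the pipeline was
#' designed around: high-arousal clips carry more motion than low-arousal
#' clips (standardized effect `motion_d`, default 2), while colour (HSV) and
#' audio distributions are identical across quadrants.
#'
#' Motion levels are on a 0-1 scale driving both the speed of a drifting
#' object and the rate of transient pixel changes; `motion_level = 0` yields
#' perfectly static frames.
#'
#' @param motion_mean named numeric (HN, LN, HP, LP) mean motion level.
#' @param motion_sd named numeric, per-quadrant SD of the motion level.
#' @param brightness_mean,brightness_sd per-quadrant HSV value (brightness)
#'   distribution.
#' @param audio_freq_hz,audio_amp per-quadrant sine frequency and linear
#'   amplitude of the soundtrack.
#' @param fps frames per second (default 25).
#' @param duration_s clip duration, seconds (default 5).
#' @param width,height frame size in pixels.
#' @param sample_rate audio sample rate, Hz.
#' @param motion_d convenience: if `motion_mean` is `NULL`, means are set to
#'   `0.35 +/- motion_d * motion_sd / 2` by arousal level.
#' @return A list of class `clip_profile`.
#' @export
clip_profile <- function(motion_mean = NULL,
                         motion_sd = c(HN = 0.08, LN = 0.08, HP = 0.08, LP = 0.08),
                         brightness_mean = c(HN = 0.5, LN = 0.5, HP = 0.5, LP = 0.5),
                         brightness_sd = c(HN = 0.1, LN = 0.1, HP = 0.1, LP = 0.1),
                         audio_freq_hz = c(HN = 440, LN = 440, HP = 440, LP = 440),
                         audio_amp = c(HN = 0.2, LN = 0.2, HP = 0.2, LP = 0.2),
                         fps = 25, duration_s = 5, width = 24, height = 24,
                         sample_rate = 8000, motion_d = 2) {
  quads <- c("HN", "LN", "HP", "LP")
  if (is.null(motion_mean)) {
    base <- 0.35
    half <- motion_d * mean(motion_sd) / 2
    motion_mean <- c(HN = base + half, LN = base - half,
                     HP = base + half, LP = base - half)
  }
  prof <- list(motion_mean = motion_mean[quads], motion_sd = motion_sd[quads],
               brightness_mean = brightness_mean[quads],
               brightness_sd = brightness_sd[quads],
               audio_freq_hz = audio_freq_hz[quads],
               audio_amp = audio_amp[quads],
               fps = fps, duration_s = duration_s, width = width,
               height = height, sample_rate = sample_rate)
  if (any(vapply(prof[c("motion_sd", "brightness_sd")], function(v) any(v < 0),
                 logical(1)))) {
    stop_affect("Profile variances must be nonnegative.")
  }
  if (any(is.na(unlist(prof[1:6])))) {
    stop_affect("Profile must name all four quadrants (HN, LN, HP, LP).")
  }
  structure(prof, class = "clip_profile")
}

#' Generate synthetic audiovisual clips
#'
#' Each clip is a coloured background with a static bright patch and a
#' transient pixel-change process whose per-frame rate is set by the clip's
#' motion level, so lagged frame-difference features grow linearly with that
#' level at every lag. The soundtrack is a stereo sine with additive noise.
#' Clip-level visual realism is out of scope; the generator reproduces the
#' feature-level structure (motion differing by arousal, colour balanced)
#' that the pipeline's nuisance control is designed around.
#'
#' @param design the `design` tibble from [affect_design()] /
#'   [generate_design()].
#' @param profile a [clip_profile()].
#' @param seed integer seed; output is a pure function of it.
#' @return A list of 32 `synthetic_clip` objects (fields `frames`
#'   (T x H x W x 3 in `[0,1]`), `fps`, `audio` (2 x N in `[-1,1]`),
#'   `sample_rate`, `exemplar_id`, `motion_level`).
#' @export
generate_clips <- function(design, profile = clip_profile(), seed = 1) {
  if (!inherits(profile, "clip_profile")) {
    stop_affect("`profile` must be a clip_profile().")
  }
  withr_seed(seed)
  n_frames <- max(8L, as.integer(round(profile$fps * profile$duration_s)))
  H <- profile$height; W <- profile$width
  n_samp <- as.integer(profile$sample_rate * profile$duration_s)

  lapply(seq_len(nrow(design)), function(i) {
    q <- design$quadrant[i]
    motion <- max(0, rnorm(1, profile$motion_mean[[q]], profile$motion_sd[[q]]))
    bright <- min(1, max(0.05, rnorm(1, profile$brightness_mean[[q]],
                                     profile$brightness_sd[[q]])))
    hue <- runif(1); sat <- runif(1, 0.2, 0.6)
    bg <- grDevices::hsv(hue, sat, bright)
    bg_rgb <- as.numeric(grDevices::col2rgb(bg)) / 255

    frames <- array(0, c(n_frames, H, W, 3))
    for (ch in 1:3) frames[, , , ch] <- bg_rgb[ch]

    # a static bright patch gives the scene some luminance structure without
    # contributing to frame differences
    sq <- 5L
    x0 <- sample(seq_len(W - sq + 1L), 1)
    y0 <- sample(seq_len(H - sq + 1L), 1)
    lum <- min(1, bright + 0.45)
    for (ch in 1:3) frames[, y0:(y0 + sq - 1L), x0:(x0 + sq - 1L), ch] <- lum

    # motion is carried by a transient pixel-change process: per frame, a
    # random pixel subset (rate proportional to the motion level) flips far
    # from the background, so lagged difference counts grow linearly with the
    # motion level at every lag
    if (motion > 0) {
      rate <- motion * 0.08
      npix <- H * W
      for (t in seq_len(n_frames)) {
        k <- min(npix, round(rate * npix))
        if (k > 0) {
          pix <- sample.int(npix, k)
          val <- ifelse(bright > 0.5, 0.02, 0.98)
          for (ch in 1:3) {
            plane <- frames[t, , , ch]
            plane[pix] <- val
            frames[t, , , ch] <- plane
          }
        }
      }
    }

    tt <- seq_len(n_samp) / profile$sample_rate
    amp <- profile$audio_amp[[q]]
    wave <- sin(2 * pi * profile$audio_freq_hz[[q]] * tt)
    audio <- rbind(wave, wave) * amp +
      matrix(rnorm(2 * n_samp, 0, amp / 20), nrow = 2)
    audio <- matrix(pmin(1, pmax(-1, audio)), nrow = 2)

    structure(list(frames = frames, fps = profile$fps, audio = audio,
                   sample_rate = profile$sample_rate,
                   exemplar_id = design$exemplar_id[i],
                   motion_level = motion),
              class = "synthetic_clip")
  })
}
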