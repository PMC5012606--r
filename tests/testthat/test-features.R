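# Low-level stimulus features: colour, motion, audio, balance ANOVA, PCA.

test_that("hsv_features handles degenerate colours and matches brute force", {
  black <- clip_from_frames(const_frames(3, 4, 4, c(0, 0, 0)))
  expect_equal(unlist(hsv_features(black)), c(hue = 0, saturation = 0, value = 0))

  red <- clip_from_frames(const_frames(3, 4, 4, c(1, 0, 0)))
  expect_equal(unlist(hsv_features(red)), c(hue = 0, saturation = 1, value = 1))

  # brute-force oracle: per-pixel RGB -> HSV by the sector formulas
  set.seed(11)
  fr <- array(runif(4 * 3 * 5 * 3), c(4, 3, 5, 3))
  oracle <- sapply(1:4, function(t) {
    hsvs <- sapply(seq_len(15), function(p) {
      ij <- arrayInd(p, c(3, 5))
      r <- fr[t, ij[1], ij[2], 1]; g <- fr[t, ij[1], ij[2], 2]
      b <- fr[t, ij[1], ij[2], 3]
      mx <- max(r, g, b); mn <- min(r, g, b); dl <- mx - mn
      h <- if (dl == 0) 0 else if (mx == r) ((g - b) / dl) %% 6 else
        if (mx == g) (b - r) / dl + 2 else (r - g) / dl + 4
      c(h / 6, if (mx == 0) 0 else dl / mx, mx)
    })
    rowMeans(hsvs)
  })
  got <- unlist(hsv_features(clip_from_frames(fr)))
  expect_equal(unname(got), unname(rowMeans(oracle)), tolerance = 1e-12)

  expect_error(hsv_features(list(frames = NULL)), "frames")
})

test_that("motion_features counts changed pixels at each lag", {
  static <- clip_from_frames(const_frames(10, 4, 4, c(0.3, 0.5, 0.2)))
  m <- motion_features(static, lags = c(5, 3, 1))
  expect_true(all(unlist(m) == 0))

  # one pixel toggling 0 <-> 1 every frame: lag-1 count = T - 1
  fr <- const_frames(9, 4, 4, c(0, 0, 0))
  fr[seq(2, 9, by = 2), 2, 2, ] <- 1
  tog <- clip_from_frames(fr)
  expect_equal(motion_features(tog, lags = 1, threshold = 0.5)$motion_1, 8)

  # random clip vs double-loop brute force
  set.seed(21)
  fr <- array(runif(8 * 3 * 4 * 3), c(8, 3, 4, 3))
  th <- 0.12
  lags <- c(4, 2, 1)
  oracle <- sapply(lags, function(L) {
    cnt <- 0
    for (t in 1:(8 - L)) for (i in 1:3) for (j in 1:4) {
      g1 <- mean(fr[t, i, j, ]); g2 <- mean(fr[t + L, i, j, ])
      if (abs(g2 - g1) > th) cnt <- cnt + 1
    }
    cnt
  })
  got <- unlist(motion_features(clip_from_frames(fr), lags = lags,
                                threshold = th))
  expect_equal(unname(got), oracle)

  expect_error(motion_features(clip_from_frames(fr), lags = 10), "frames")
})

test_that("normalize_amplitude equalizes RMS by pure gains", {
  tt <- seq_len(400) / 400
  a <- rbind(sin(2 * pi * 5 * tt), sin(2 * pi * 5 * tt)) * 0.1
  b <- a * 3
  out <- normalize_amplitude(list(a = a, b = b))
  rms <- function(w) sqrt(mean(w^2))
  expect_equal(rms(out$a), 2 * rms(a), tolerance = 1e-12)
  expect_equal(rms(out$b), 2 * rms(a), tolerance = 1e-12)
  # shape preserved up to gain
  expect_equal(out$b / rms(out$b), b / rms(b), tolerance = 1e-12)

  same <- normalize_amplitude(list(a, a))
  expect_equal(attr(same, "gains"), c(1, 1))

  expect_error(normalize_amplitude(list(a = a, zero = a * 0)), "zero")
})

test_that("audio_features: centroid and dB behave as defined", {
  sr <- 2000; n <- 2000
  tt <- seq_len(n) / sr
  sine <- rbind(sin(2 * pi * 440 * tt), sin(2 * pi * 440 * tt)) * 0.5
  f <- audio_features(sine, sr)
  expect_lt(abs(f$freq_left - 440), sr / n + 1e-6)
  expect_lt(abs(f$freq_right - 440), sr / n + 1e-6)

  # doubling gain changes the dB magnitude by 20 log10(2)
  f2 <- audio_features(sine * 2, sr)
  expect_equal(abs(f$amp_left - f2$amp_left), 20 * log10(2), tolerance = 1e-9)

  # two-sine mixture: centroid = amplitude-weighted mean of bin frequencies
  f1 <- 200; f2h <- 600 # exact bins for n = sr
  mix <- 0.6 * sin(2 * pi * f1 * tt) + 0.2 * sin(2 * pi * f2h * tt)
  fm <- audio_features(rbind(mix, mix), sr)
  expect_equal(fm$freq_left, (f1 * 0.6 + f2h * 0.2) / 0.8, tolerance = 1e-6)

  expect_error(audio_features(rbind(0 * tt, sin(tt)), sr), "Silent")
  expect_error(audio_features(matrix(1, 3, 10), sr), "stereo")
})

test_that("summary ANOVA reproduces the published motion arousal F values", {
  cells <- stimulus_feature_cells()
  published <- c(23.469, 24.016, 21.884, 19.629, 20.431, 16.776, 10.275)
  for (k in 1:7) {
    row <- cells[cells$description == paste0("motion_", k), ]
    res <- summary_anova_2x2(
      c(row$mean_nh, row$mean_nl, row$mean_ph, row$mean_pl),
      c(row$sd_nh, row$sd_nl, row$sd_ph, row$sd_pl))
    expect_equal(res$F[res$effect == "arousal"], published[k],
                 tolerance = 5e-4)
    expect_equal(res$df2[1], 28)
  }
})

test_that("summary ANOVA matches a raw-data oracle on moment-matched cells", {
  # zero effect
  z <- summary_anova_2x2(rep(2, 4), c(1, 2, 1, 2))
  expect_equal(z$F, c(0, 0))

  set.seed(31)
  for (rep in 1:5) {
    ms <- rnorm(4, 10, 3); ss <- runif(4, 0.5, 2)
    base <- scale(rnorm(8))[, 1] # exactly mean 0, sd 1
    y <- c(outer(base, ss) + rep(ms, each = 8))
    df <- data.frame(
      y = y,
      valence = factor(rep(c(-1, -1, 1, 1), each = 8)),
      arousal = factor(rep(c(1, -1, 1, -1), each = 8)))
    a <- anova(lm(y ~ valence * arousal, data = df))
    got <- summary_anova_2x2(ms, ss)
    expect_equal(got$F[got$effect == "valence"], a["valence", "F value"],
                 tolerance = 1e-9)
    expect_equal(got$F[got$effect == "arousal"], a["arousal", "F value"],
                 tolerance = 1e-9)
  }
  expect_error(summary_anova_2x2(1:4, c(1, 1, 0, 1)), "positive")
})

test_that("nuisance_pca retains 2+1+2 standardized component scores", {
  set.seed(41)
  ft <- tibble::tibble(exemplar_id = 1:32)
  base <- rnorm(32)
  ft$hue <- base * 0.5 + 0.5        # rank-1 visual block
  ft$saturation <- base * 0.2 + 0.4
  ft$value <- -base * 0.3 + 0.5
  for (k in 1:7) ft[[paste0("motion_", k)]] <- abs(rnorm(32, 100, 30))
  ft$amp_left <- rnorm(32, 12, 2); ft$amp_right <- rnorm(32, 12, 2)
  ft$freq_left <- rnorm(32, 400, 80); ft$freq_right <- rnorm(32, 420, 80)
  ft$valence <- rep(c(-1, 1), each = 16); ft$arousal <- rep(c(1, -1), 16)

  nc <- nuisance_pca(ft)
  expect_equal(unname(nc$variance_explained["visual"]), 1, tolerance = 1e-9)
  expect_equal(dim(as.matrix(nc$scores[, -1])), c(32L, 5L))
  expect_equal(colMeans(as.matrix(nc$scores[, -1])), rep(0, 5),
               tolerance = 1e-10, ignore_attr = TRUE)

  # eigen oracle for variance explained (audio block)
  x <- scale(as.matrix(ft[, c("amp_left", "amp_right", "freq_left", "freq_right")]))
  ev <- eigen(cor(x))$values
  expect_equal(unname(nc$variance_explained["audio"]),
               sum(ev[1:2]) / sum(ev), tolerance = 1e-9)

  # orthogonality of within-block scores
  expect_lt(abs(sum(nc$scores$aud_pc1 * nc$scores$aud_pc2)), 1e-9)
  expect_lt(abs(sum(nc$scores$vis_pc1 * nc$scores$vis_pc2)), 1e-9)

  ft$hue <- 0.5
  expect_error(nuisance_pca(ft), "hue")
})

test_that("feature extraction is invariant to container round-trips", {
  d <- affect_design()
  clips <- generate_clips(d[1:2, ],
                          clip_profile(fps = 10, duration_s = 1.5,
                                       width = 10, height = 10),
                          seed = 5)
  dir <- withr::local_tempdir()
  write_clip(clips[[1]], file.path(dir, "clip1"))
  back <- read_clip(file.path(dir, "clip1"))
  lags <- c(5, 3, 1)
  expect_equal(hsv_features(back), hsv_features(clips[[1]]), tolerance = 1e-12)
  expect_equal(motion_features(back, lags = lags),
               motion_features(clips[[1]], lags = lags))
})
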