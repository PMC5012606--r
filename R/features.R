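#' Mean HSV colour features of a clip
#'
#' Per-pixel RGB values are converted to hue/saturation/value, averaged within
#' each frame, and the per-frame means averaged over frames. Achromatic pixels
#' take hue 0 by the HSV convention.
#'
#' @param clip a `synthetic_clip` or any list with a `frames` array
#'   (T x H x W x 3, RGB in `[0,1]`).
#' @return A 1-row tibble: `hue`, `saturation`, `value`, all in `[0,1]`.
#' @export
hsv_features <- function(clip) {
  fr <- clip$frames
  if (is.null(fr) || length(dim(fr)) != 4 || dim(fr)[1] < 1) {
    stop_affect("Clip has no frames.")
  }
  if (min(fr) < -1e-9 || max(fr) > 1 + 1e-9) {
    stop_affect("Frames must be RGB in [0, 1].")
  }
  nt <- dim(fr)[1]
  per_frame <- vapply(seq_len(nt), function(t) {
    rgb <- rbind(as.vector(fr[t, , , 1]), as.vector(fr[t, , , 2]),
                 as.vector(fr[t, , , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    rowMeans(hsv)
  }, numeric(3))
  m <- unname(rowMeans(per_frame))
  tibble(hue = m[1], saturation = m[2], value = m[3])
}

#' Lagged motion features of a clip
#'
#' Total motion is measured as the number of changed pixels between frames at
#' several temporal lags, from slow drifting changes (long lags) to fast
#' transients (lag 1): for lag `L`, the count over all frame pairs `(t, t+L)`
#' of pixels whose grayscale absolute difference exceeds `threshold`.
#' Grayscale is the unweighted RGB mean. `motion_1` corresponds to the first
#' (largest) lag, `motion_k` to the last (smallest).
#'
#' @param clip a clip with a `frames` array.
#' @param lags integer lags in frames, ordered slow-to-fast (decreasing);
#'   default `c(25, 18, 12, 8, 5, 3, 1)` at 25 fps.
#' @param threshold grayscale change threshold (default 10/255).
#' @return A 1-row tibble `motion_1` ... `motion_k` of nonnegative counts.
#' @export
motion_features <- function(clip, lags = c(25, 18, 12, 8, 5, 3, 1),
                            threshold = 10 / 255) {
  fr <- clip$frames
  nt <- dim(fr)[1]
  if (nt <= max(lags)) {
    stop_affect(sprintf("Clip has %d frames; needs more than the largest lag (%d).",
                        nt, max(lags)))
  }
  gray <- (fr[, , , 1] + fr[, , , 2] + fr[, , , 3]) / 3
  dim(gray) <- c(nt, prod(dim(fr)[2:3]))
  counts <- vapply(lags, function(L) {
    d <- abs(gray[(1 + L):nt, , drop = FALSE] -
               gray[1:(nt - L), , drop = FALSE])
    sum(d > threshold)
  }, numeric(1))
  as_tibble(as.list(setNames(counts, paste0("motion_", seq_along(lags)))))
}

#' Equalize the mean RMS amplitude of a set of waveforms
#'
#' Each waveform is rescaled by a pure gain so its RMS amplitude equals the
#' grand mean RMS of the input set; within-file dynamics are preserved.
#'
#' @param waveforms list of numeric matrices (channels x samples).
#' @return The rescaled list, with a `gains` attribute.
#' @export
normalize_amplitude <- function(waveforms) {
  if (!length(waveforms)) stop_affect("No waveforms supplied.")
  rms <- vapply(waveforms, function(w) sqrt(mean(w^2)), numeric(1))
  silent <- which(rms == 0)
  if (length(silent)) {
    nm <- names(waveforms)[silent[1]] %||% as.character(silent[1])
    stop_affect(sprintf("Waveform %s is silent (RMS 0); cannot normalize.", nm))
  }
  target <- mean(rms)
  gains <- target / rms
  out <- Map(function(w, g) w * g, waveforms, gains)
  attr(out, "gains") <- gains
  out
}

#' Stereo amplitude and frequency features
#'
#' Amplitude per channel is the dB-magnitude of the RMS level relative to
#' full scale, `|20 log10(RMS)|`, reported as a positive number. Frequency per
#' channel is the spectral centroid of the magnitude spectrum (DC excluded).
#'
#' @param audio numeric matrix 2 x N, samples in `[-1, 1]`.
#' @param sample_rate sampling rate, Hz.
#' @return A 1-row tibble: `amp_left`, `amp_right` (dB), `freq_left`,
#'   `freq_right` (Hz).
#' @export
audio_features <- function(audio, sample_rate) {
  if (!is.matrix(audio) || nrow(audio) != 2) {
    stop_affect("`audio` must be a 2 x N stereo matrix.")
  }
  chan <- function(x) {
    r <- sqrt(mean(x^2))
    if (r == 0) stop_affect("Silent channel: frequency undefined.")
    spec <- Mod(fft(x))
    nf <- floor(length(x) / 2)
    freqs <- (1:nf) * sample_rate / length(x)
    mag <- spec[2:(nf + 1)]
    c(amp = abs(20 * log10(r)), freq = sum(freqs * mag) / sum(mag))
  }
  l <- chan(audio[1, ]); r <- chan(audio[2, ])
  tibble(amp_left = l[["amp"]], amp_right = r[["amp"]],
         freq_left = l[["freq"]], freq_right = r[["freq"]])
}

#' Full low-level feature table for a clip set
#'
#' Runs amplitude normalization across the set (optional), then colour,
#' motion and audio feature extraction per clip, and joins the affect labels.
#'
#' @param clips list of 32 clips from [generate_clips()].
#' @param design the design tibble carrying `exemplar_id`, `valence`,
#'   `arousal`.
#' @param lags,threshold passed to [motion_features()].
#' @param normalize equalize RMS amplitude across clips first (default TRUE).
#' @return A `feature_table` tibble, one row per exemplar.
#' @export
extract_features <- function(clips, design, lags = c(25, 18, 12, 8, 5, 3, 1),
                             threshold = 10 / 255, normalize = TRUE) {
  waves <- lapply(clips, `[[`, "audio")
  if (normalize) waves <- normalize_amplitude(waves)
  rows <- lapply(seq_along(clips), function(i) {
    dplyr::bind_cols(
      tibble(exemplar_id = clips[[i]]$exemplar_id %||% i),
      hsv_features(clips[[i]]),
      motion_features(clips[[i]], lags = lags, threshold = threshold),
      audio_features(waves[[i]], clips[[i]]$sample_rate)
    )
  })
  out <- bind_rows(rows) %>%
    left_join(design[, c("exemplar_id", "valence", "arousal")],
              by = "exemplar_id")
  class(out) <- c("feature_table", class(out))
  out
}

#' Two-way ANOVA from cell summary statistics
#'
#' Main-effect F tests for valence and arousal in the balanced 2x2 design,
#' computed from the four cell means and SDs alone:
#' `SS_effect = 2n * sum_levels (level mean - grand mean)^2`, error mean
#' square = mean of the cell variances on `4(n-1)` df. With the default
#' `n_per_cell = 8` this gives F(1, 28).
#'
#' @param cell_means,cell_sds length-4 numeric, cells ordered (negative-high,
#'   negative-low, positive-high, positive-low).
#' @param n_per_cell observations per cell (default 8).
#' @return A tibble with rows for the valence and arousal main effects:
#'   `effect`, `F`, `df1`, `df2`, `p`.
#' @export
#' @examples
#' summary_anova_2x2(c(122108.01, 36616.89, 91659.27, 32263.66),
#'                   c(54831.82, 34589.29, 44101.18, 31748.91))
summary_anova_2x2 <- function(cell_means, cell_sds, n_per_cell = 8) {
  if (length(cell_means) != 4 || length(cell_sds) != 4) {
    stop_affect("Exactly four cells required (neg-high, neg-low, pos-high, pos-low).")
  }
  if (any(cell_sds <= 0)) stop_affect("Cell SDs must be positive.")
  if (n_per_cell < 2) stop_affect("n_per_cell must be at least 2.")
  grand <- mean(cell_means)
  ms_error <- mean(cell_sds^2)
  df2 <- 4 * (n_per_cell - 1)
  eff <- function(level_a, level_b) {
    m_a <- mean(cell_means[level_a]); m_b <- mean(cell_means[level_b])
    ss <- 2 * n_per_cell * ((m_a - grand)^2 + (m_b - grand)^2)
    f <- ss / ms_error
    tibble(F = f, df1 = 1, df2 = df2, p = pf(f, 1, df2, lower.tail = FALSE))
  }
  bind_rows(
    dplyr::bind_cols(tibble(effect = "valence"), eff(c(3, 4), c(1, 2))),
    dplyr::bind_cols(tibble(effect = "arousal"), eff(c(1, 3), c(2, 4)))
  )
}

#' Balance ANOVA across a whole feature table
#'
#' Applies [summary_anova_2x2()] to every feature column, using the table's
#' quadrant labels to form the four cells.
#'
#' @param feature_table a [extract_features()] table.
#' @param features columns to test; defaults to all feature columns.
#' @return A tibble: `feature`, `effect`, `F`, `df1`, `df2`, `p`.
#' @export
feature_anova <- function(feature_table, features = NULL) {
  features <- features %||%
    setdiff(names(feature_table), c("exemplar_id", "valence", "arousal"))
  cells <- list(c(-1, 1), c(-1, -1), c(1, 1), c(1, -1)) # NH, NL, PH, PL
  purrr::map_dfr(features, function(fc) {
    x <- feature_table[[fc]]
    ms <- vapply(cells, function(cc) {
      mean(x[feature_table$valence == cc[1] & feature_table$arousal == cc[2]])
    }, numeric(1))
    ss <- vapply(cells, function(cc) {
      sd(x[feature_table$valence == cc[1] & feature_table$arousal == cc[2]])
    }, numeric(1))
    n <- sum(feature_table$valence == -1 & feature_table$arousal == 1)
    dplyr::bind_cols(tibble(feature = fc), summary_anova_2x2(ms, ss, n))
  })
}

#' Block-wise principal-component nuisance scores
#'
#' Three separate PCAs on standardized feature blocks reduce the low-level
#' features to five nuisance component scores: two visual components (hue,
#' saturation, value), one motion component (the seven lagged motion counts),
#' and two auditory components (bilateral amplitude and frequency). Component
#' signs are fixed so the largest-magnitude loading is positive.
#'
#' @param feature_table a [extract_features()] table (32 rows).
#' @return A list of class `nuisance_components`: `scores` (tibble:
#'   `exemplar_id`, `vis_pc1`, `vis_pc2`, `mot_pc1`, `aud_pc1`, `aud_pc2`),
#'   `variance_explained` (named: visual, motion, audio), `loadings`.
#' @export
nuisance_pca <- function(feature_table) {
  blocks <- list(
    visual = c("hue", "saturation", "value"),
    motion = grep("^motion_", names(feature_table), value = TRUE),
    audio = c("amp_left", "amp_right", "freq_left", "freq_right")
  )
  n_keep <- c(visual = 2L, motion = 1L, audio = 2L)
  scores <- list(); varexp <- c(); loadings <- list()
  for (bl in names(blocks)) {
    cols <- blocks[[bl]]
    x <- as.matrix(feature_table[, cols])
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      stop_affect(sprintf("Zero-variance feature column: %s.",
                          paste(cols[sds == 0], collapse = ", ")))
    }
    pc <- prcomp(x, center = TRUE, scale. = TRUE)
    k <- n_keep[[bl]]
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    sc <- pc$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      if (rot[which.max(abs(rot[, j])), j] < 0) {
        rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j]
      }
    }
    scores[[bl]] <- sc
    loadings[[bl]] <- rot
    varexp[bl] <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  }
  out <- tibble(
    exemplar_id = feature_table$exemplar_id,
    vis_pc1 = scores$visual[, 1], vis_pc2 = scores$visual[, 2],
    mot_pc1 = scores$motion[, 1],
    aud_pc1 = scores$audio[, 1], aud_pc2 = scores$audio[, 2]
  )
  structure(list(scores = out, variance_explained = varexp,
                 loadings = loadings),
            class = "nuisance_components")
}

#' @export
print.nuisance_components <- function(x, ...) {
  cat("<nuisance_components> variance explained:",
      paste(sprintf("%s %.1f%%", names(x$variance_explained),
                    100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Per-trial nuisance score matrix
#'
#' Expands per-exemplar component scores to one row per trial via the event
#' table's exemplar ids.
#'
#' @param components a [nuisance_pca()] result (or a 32 x 5 matrix with
#'   rownames-free rows ordered by exemplar id).
#' @param exemplar_id integer vector of trial exemplar ids.
#' @return numeric matrix, trials x 5.
#' @export
trial_feature_scores <- function(components, exemplar_id) {
  if (inherits(components, "nuisance_components")) {
    sc <- as.matrix(components$scores[, -1])
    ids <- components$scores$exemplar_id
  } else {
    sc <- as.matrix(components)
    ids <- seq_len(nrow(sc))
  }
  sc[match(exemplar_id, ids), , drop = FALSE]
}

#' Reference cell statistics for the normed audiovisual stimulus set
#'
#' Per-feature cell means and SDs (8 clips per affect quadrant) for the
#' normed set of 32 naturalistic audiovisual clips around which the pipeline
#' was developed. Used to reproduce the published balance ANOVAs from summary
#' statistics alone.
#'
#' @return A tibble: `description`, then mean/sd per cell (`nh`, `nl`, `ph`,
#'   `pl` = negative-high ... positive-low).
#' @export
stimulus_feature_cells <- function() {
  path <- system.file("extdata", "stimulus_feature_cells.csv",
                      package = "affectmvpa")
  readr::read_csv(path, show_col_types = FALSE)
}
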