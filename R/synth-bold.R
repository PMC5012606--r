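#' Generate multi-participant synthetic BOLD datasets with known ground truth
#'
#' Simulates a slow event-related affect experiment: per participant, four
#' runs of 32 trials (one presentation block per run; 128 trials total, 12 s
#' spacing: 5 s stimulus + 7 s fixation). Voxels inside a `valence` region
#' carry a +/- `effect_pct` pattern by trial valence, voxels inside a disjoint
#' `arousal` region likewise by arousal; both are convolved with the canonical
#' double-gamma HRF. Every voxel additionally receives nuisance signal driven
#' by the five low-level feature component scores (by default the motion
#' component tracks arousal, emulating the motion-arousal confound of
#' naturalistic clips), and AR(1) Gaussian noise. Six head-motion parameter
#' time series are simulated as smoothed random walks.
#'
#' Signal units are percent of the voxel baseline (100): `effect_pct = 3`
#' means a trial's peak response is 3% signal change.
#'
#' @param design a [generate_design()] result (its `design` table defines the
#'   exemplar labels; the presentation order is re-drawn per participant).
#' @param grid_dim integer(3) voxel grid (default 20 x 20 x 20).
#' @param effect_pct peak affect response, percent of baseline.
#' @param nuisance_sd SD of the per-voxel nuisance loading, percent of
#'   baseline per unit component score.
#' @param noise_sd marginal SD of the AR(1) voxel noise, percent of baseline.
#' @param n_participants number of simulated participants (default 11).
#' @param seed integer; the full output is a pure function of it.
#' @param tr repetition time, seconds.
#' @param rho AR(1) autocorrelation of the voxel noise.
#' @param stim_s,fix_s stimulus and fixation durations, seconds.
#' @param feature_scores optional 32 x 5 per-exemplar component score matrix;
#'   default emulates a motion-arousal confound (`mot_pc1` correlated with the
#'   arousal label) with the other components unrelated to the design.
#' @param shared_pattern if `TRUE` (default) the +/- voxel pattern inside each
#'   region is common to all participants (affect coded the same way across
#'   brains); if `FALSE` each participant gets an idiosyncratic pattern.
#' @param valence_mask,arousal_mask optional logical ground-truth region
#'   arrays; defaults are two disjoint 5 x 5 x 5 blocks. Overlapping masks are
#'   an error.
#' @param baseline voxel baseline level.
#' @return A list of `bold_dataset` objects, one per participant: fields
#'   `participant_id`, `runs` (each with `data` volumes x voxels, `events`,
#'   `motion`), `dim`, `tr`, and `ground_truth` (masks, patterns, loadings,
#'   feature scores, noise parameters, seed).
#' @export
generate_bold <- function(design, grid_dim = c(20, 20, 20), effect_pct = 1,
                          nuisance_sd = 0.5, noise_sd = 1,
                          n_participants = 11, seed = 1, tr = 2.2, rho = 0.3,
                          stim_s = 5, fix_s = 7, feature_scores = NULL,
                          shared_pattern = TRUE, valence_mask = NULL,
                          arousal_mask = NULL, baseline = 100) {
  if (effect_pct < 0) stop_affect("effect_pct must be nonnegative.")
  grid_dim <- as.integer(grid_dim)
  V <- prod(grid_dim)
  base_design <- if (inherits(design, "stimulus_design")) design$design else design

  masks <- default_region_masks(grid_dim, valence_mask, arousal_mask)
  if (any(masks$valence & masks$arousal)) {
    stop_affect("Ground-truth valence and arousal masks overlap.")
  }
  vox_val <- which(masks$valence)
  vox_aro <- which(masks$arousal)

  withr_seed(seed)
  if (is.null(feature_scores)) {
    # motion component tracks arousal at r ~ 0.7, the confound magnitude
    # implied by the balance ANOVAs of the reference stimulus set
    mot <- scale(base_design$arousal + rnorm(32, 0, 1))[, 1]
    other <- matrix(rnorm(32 * 4), 32, 4)
    other <- scale(other)
    feature_scores <- cbind(other[, 1:2], mot, other[, 3:4])
    colnames(feature_scores) <- c("vis_pc1", "vis_pc2", "mot_pc1",
                                  "aud_pc1", "aud_pc2")
  }
  feature_scores <- as.matrix(feature_scores)
  if (!all(dim(feature_scores) == c(32, 5))) {
    stop_affect("feature_scores must be 32 x 5.")
  }

  spacing <- stim_s + fix_s
  onsets <- (0:31) * spacing
  n_vol <- ceiling((32 * spacing + 2 * spacing) / tr)

  pattern_shared_val <- sample(c(-1, 1), length(vox_val), replace = TRUE)
  pattern_shared_aro <- sample(c(-1, 1), length(vox_aro), replace = TRUE)

  datasets <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    withr_seed(sub_seed(seed, p))
    des_p <- generate_design(sub_seed(seed, 10000 + p))
    order_p <- des_p$order

    pat_val <- if (shared_pattern) pattern_shared_val else
      sample(c(-1, 1), length(vox_val), replace = TRUE)
    pat_aro <- if (shared_pattern) pattern_shared_aro else
      sample(c(-1, 1), length(vox_aro), replace = TRUE)
    loadings <- matrix(rnorm(V * 5, 0, nuisance_sd), V, 5)

    runs <- vector("list", 4)
    for (r in 1:4) {
      ord <- order_p[order_p$presentation == r, ]
      events <- tibble(
        trial = ord$trial, onset = onsets, duration = stim_s,
        exemplar_id = ord$exemplar_id, quadrant = ord$quadrant,
        valence = ord$valence, arousal = ord$arousal, presentation = r
      )
      reg_val <- convolve_regressor(events$onset, stim_s, events$valence,
                                    n_vol, tr)
      reg_aro <- convolve_regressor(events$onset, stim_s, events$arousal,
                                    n_vol, tr)
      trial_scores <- feature_scores[events$exemplar_id, , drop = FALSE]
      reg_feat <- vapply(1:5, function(j) {
        convolve_regressor(events$onset, stim_s, trial_scores[, j], n_vol, tr)
      }, numeric(n_vol))

      signal <- matrix(0, n_vol, V)
      if (effect_pct > 0) {
        signal[, vox_val] <- signal[, vox_val] +
          outer(reg_val, pat_val) * effect_pct
        signal[, vox_aro] <- signal[, vox_aro] +
          outer(reg_aro, pat_aro) * effect_pct
      }
      if (nuisance_sd > 0) {
        signal <- signal + reg_feat %*% t(loadings)
      }
      noise <- ar1_noise(n_vol, V, rho, noise_sd)
      data <- baseline * (1 + (signal + noise) / 100)

      motion <- vapply(1:6, function(j) {
        as.numeric(stats::filter(cumsum(rnorm(n_vol, 0, 0.02)),
                                 rep(1 / 5, 5), sides = 2, circular = TRUE))
      }, numeric(n_vol))

      runs[[r]] <- list(data = data, events = events, motion = motion)
    }

    gt <- list(valence_mask = masks$valence, arousal_mask = masks$arousal,
               effect_pct = effect_pct, pattern_valence = pat_val,
               pattern_arousal = pat_aro, loadings = loadings,
               feature_scores = feature_scores, noise_sd = noise_sd,
               nuisance_sd = nuisance_sd, rho = rho, seed = seed)
    datasets[[p]] <- structure(
      list(participant_id = p, runs = runs, dim = grid_dim, tr = tr,
           baseline = baseline, ground_truth = gt),
      class = "bold_dataset"
    )
  }
  datasets
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("<bold_dataset> participant %d: %d runs x %d volumes, grid %s\n",
              x$participant_id, length(x$runs), nrow(x$runs[[1]]$data),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# Two disjoint ground-truth blocks (5x5x5 on the default grid, shrunk on
# small grids), separated along the x axis by construction and centred on the
# other axes.
default_region_masks <- function(grid_dim, valence_mask = NULL,
                                 arousal_mask = NULL) {
  side <- pmin(5L, grid_dim)
  side[1] <- min(side[1], grid_dim[1] %/% 2)
  if (side[1] < 1) stop_affect("Grid too small for two disjoint regions.")
  mk <- function(x_lo) {
    m <- array(FALSE, grid_dim)
    lo <- pmax(1L, as.integer(floor((grid_dim - side) / 2) + 1L))
    hi <- lo + side - 1L
    m[x_lo:(x_lo + side[1] - 1L), lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  if (is.null(valence_mask)) valence_mask <- mk(1L)
  if (is.null(arousal_mask)) {
    arousal_mask <- mk(grid_dim[1] - side[1] + 1L)
  }
  stopifnot(identical(dim(valence_mask), as.integer(grid_dim)),
            identical(dim(arousal_mask), as.integer(grid_dim)))
  list(valence = valence_mask, arousal = arousal_mask)
}

# Columnwise AR(1) Gaussian noise with unit-free marginal SD `sd_pct`.
ar1_noise <- function(n_vol, n_vox, rho, sd_pct) {
  e <- matrix(rnorm(n_vol * n_vox), n_vol, n_vox)
  if (rho != 0) {
    for (t in 2:n_vol) e[t, ] <- rho * e[t - 1, ] + sqrt(1 - rho^2) * e[t, ]
  }
  e * sd_pct
}

#' Generate pure-noise standardized trial patterns
#'
#' A light-weight null model for calibration studies (permutation and
#' family-wise-error checks): per participant, a counterbalanced 128-trial
#' design whose standardized patterns are i.i.d. Gaussian noise with no
#' label information anywhere.
#'
#' @param grid_dim integer(3) voxel grid.
#' @param n_participants number of pattern sets.
#' @param seed integer seed.
#' @return A list of standardized [trial_pattern_set()]s.
#' @export
generate_null_patterns <- function(grid_dim, n_participants = 1, seed = 1) {
  grid_dim <- as.integer(grid_dim)
  nv <- prod(grid_dim)
  lapply(seq_len(n_participants), function(p) {
    ord <- generate_design(sub_seed(seed, p))$order
    withr_seed(sub_seed(seed, 20000 + p))
    ord$participant_id <- p
    x <- matrix(rnorm(128 * nv), 128, nv)
    standardize(trial_pattern_set(x, ord, grid_dim, seq_len(nv)))
  })
}

#' Generate behavioural ratings from a weighted 2-D affect space
#'
#' Each subject's rating of each stimulus on each of six scales (excited,
#' positive, calm, anxious, negative, sad) is a fixed linear readout of the
#' group stimulus space scaled per-dimension by that subject's weights, plus
#' Gaussian noise. Readout directions: positive/negative load on dimension 1
#' (valence), excited/calm on dimension 2 (arousal), anxious and sad on
#' mixtures, so both dimensions are recoverable from the six scales.
#'
#' @param group_space 32 x 2 matrix of stimulus coordinates.
#' @param subject_weights n x 2 nonnegative per-subject dimension weights.
#' @param noise_sd rating noise SD.
#' @param seed integer seed.
#' @return A `rating_set`: list with `ratings` (n x 32 x 6 array), `long`
#'   (tibble: subject, exemplar_id, scale, rating), `group_space`,
#'   `subject_weights`.
#' @export
generate_ratings <- function(group_space, subject_weights, noise_sd = 0.1,
                             seed = 1) {
  group_space <- as.matrix(group_space)
  subject_weights <- as.matrix(subject_weights)
  if (ncol(group_space) != 2 || nrow(group_space) != 32) {
    stop_affect("group_space must be 32 x 2.")
  }
  if (any(subject_weights < 0)) {
    stop_affect("Subject weights must be nonnegative.")
  }
  readout <- rbind(
    excited  = c(0, 1),
    positive = c(1, 0),
    calm     = c(0, -1),
    anxious  = c(-0.6, 0.8),
    negative = c(-1, 0),
    sad      = c(-0.6, -0.8)
  )
  withr_seed(seed)
  n <- nrow(subject_weights)
  ratings <- array(NA_real_, c(n, 32, 6),
                   dimnames = list(NULL, NULL, rownames(readout)))
  for (i in seq_len(n)) {
    conf <- sweep(group_space, 2, subject_weights[i, ], `*`)
    ratings[i, , ] <- conf %*% t(readout) +
      matrix(rnorm(32 * 6, 0, noise_sd), 32, 6)
  }
  long <- purrr::map_dfr(seq_len(n), function(i) {
    tibble(subject = i,
           exemplar_id = rep(1:32, times = 6),
           scale = rep(rownames(readout), each = 32),
           rating = as.vector(ratings[i, , ]))
  })
  structure(list(ratings = ratings, long = long, group_space = group_space,
                 subject_weights = subject_weights, noise_sd = noise_sd,
                 seed = seed),
            class = "rating_set")
}

#' @export
print.rating_set <- function(x, ...) {
  cat(sprintf("<rating_set> %d subjects x 32 stimuli x 6 scales\n",
              dim(x$ratings)[1]))
  invisible(x)
}
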