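#' Regress low-level feature components and head motion out of a BOLD series
#'
#' Per run and voxel, ordinary least squares of the time series on an
#' intercept, the five HRF-convolved per-trial feature-component regressors,
#' and the six motion parameter columns. The returned series are the
#' residuals with the fitted intercept restored, so percent-signal-change
#' baselines stay meaningful.
#'
#' @param dataset a `bold_dataset` (from [generate_bold()] or
#'   [read_bold_dataset()]).
#' @param feature_scores 32 x 5 per-exemplar component scores, or a
#'   [nuisance_pca()] result. `NULL` uses the dataset's ground-truth scores if
#'   present.
#' @param include_motion include the six motion columns (default TRUE).
#' @param hrf_fun hemodynamic response used for convolution.
#' @return The dataset with each run's `data` replaced by cleaned series.
#' @export
regress_nuisance <- function(dataset, feature_scores = NULL,
                             include_motion = TRUE,
                             hrf_fun = hrf_double_gamma) {
  feature_scores <- feature_scores %||% dataset$ground_truth$feature_scores
  if (is.null(feature_scores)) {
    stop_affect("feature_scores must be supplied (none stored in the dataset).")
  }
  if (inherits(feature_scores, "nuisance_components")) {
    feature_scores <- as.matrix(feature_scores$scores[, -1])
  }
  for (r in seq_along(dataset$runs)) {
    run <- dataset$runs[[r]]
    n_vol <- nrow(run$data)
    trial_scores <- feature_scores[run$events$exemplar_id, , drop = FALSE]
    reg_feat <- vapply(seq_len(ncol(feature_scores)), function(j) {
      convolve_regressor(run$events$onset, run$events$duration,
                         trial_scores[, j], n_vol, dataset$tr,
                         hrf_fun = hrf_fun)
    }, numeric(n_vol))
    colnames(reg_feat) <- paste0("feature_", seq_len(ncol(reg_feat)))
    X <- cbind(intercept = rep(1, n_vol), reg_feat)
    if (include_motion && !is.null(run$motion)) {
      motion <- as.matrix(run$motion)
      colnames(motion) <- paste0("motion_", seq_len(ncol(motion)))
      X <- cbind(X, motion)
    }
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop_affect(paste0("Nuisance design is rank deficient; collinear column(s): ",
                         paste(bad, collapse = ", ")))
    }
    beta <- qr.coef(qrX, run$data)
    resid <- run$data - X %*% beta
    dataset$runs[[r]]$data <- resid + rep(1, n_vol) %o% beta["intercept", ]
  }
  dataset
}

#' Extract percent-signal-change trial patterns
#'
#' Per voxel, the series is converted to percent signal change relative to
#' its run mean, `100 (x - mean) / mean`; each trial's pattern is the mean of
#' `n_avg` volumes starting `offset` seconds after stimulus onset (default two
#' volumes offset 4.4 s, accounting for hemodynamic delay).
#'
#' @param dataset a `bold_dataset` (typically after [regress_nuisance()]).
#' @param offset hemodynamic sampling offset in seconds; must be a multiple
#'   of the TR.
#' @param n_avg number of consecutive volumes averaged per trial.
#' @return An unstandardized [trial_pattern_set()] (128 trials when all four
#'   runs are present).
#' @export
extract_psc <- function(dataset, offset = 4.4, n_avg = 2) {
  tr <- dataset$tr
  k <- assert_near_integer(offset / tr, "offset / tr")
  pat <- list(); info <- list()
  for (r in seq_along(dataset$runs)) {
    run <- dataset$runs[[r]]
    mu <- colMeans(run$data)
    if (any(mu == 0)) {
      stop_affect(sprintf("Voxel(s) with zero run mean in run %d.", r))
    }
    psc <- 100 * sweep(sweep(run$data, 2, mu, `-`), 2, mu, `/`)
    # onsets need not be volume-locked; sample relative to the nearest volume
    v0 <- as.integer(round(run$events$onset / tr)) + 1L
    rows <- t(vapply(seq_along(v0), function(i) {
      idx <- v0[i] + k + 0:(n_avg - 1)
      if (any(idx < 1 | idx > nrow(psc))) {
        stop_affect(sprintf("Trial %d samples volumes outside run %d.",
                            run$events$trial[i], r))
      }
      colMeans(psc[idx, , drop = FALSE])
    }, numeric(ncol(psc))))
    pat[[r]] <- rows
    info[[r]] <- run$events %>%
      mutate(run = r, participant_id = dataset$participant_id)
  }
  trial_pattern_set(do.call(rbind, pat), bind_rows(info), dataset$dim,
                    seq_len(prod(dataset$dim)), standardized = FALSE)
}

#' Standardize trial patterns across voxels
#'
#' Z-scores each trial's voxel vector (mean 0, SD 1 across voxels), the form
#' in which patterns enter all decoding analyses.
#'
#' @param tps a [trial_pattern_set()].
#' @return The standardized pattern set.
#' @export
standardize <- function(tps) {
  if (ncol(tps$patterns) < 2) stop_affect("Need at least 2 voxels.")
  s <- apply(tps$patterns, 1, sd)
  if (any(s == 0)) {
    stop_affect(sprintf("Constant pattern in trial(s) %s; cannot standardize.",
                        paste(which(s == 0), collapse = ", ")))
  }
  m <- rowMeans(tps$patterns)
  tps$patterns <- (tps$patterns - m) / s
  tps$standardized <- TRUE
  tps
}

#' One-call pattern preparation pipeline
#'
#' [regress_nuisance()], then [extract_psc()], then [standardize()].
#'
#' @inheritParams regress_nuisance
#' @inheritParams extract_psc
#' @return A standardized [trial_pattern_set()].
#' @export
prep_patterns <- function(dataset, feature_scores = NULL,
                          include_motion = TRUE, offset = 4.4, n_avg = 2) {
  dataset %>%
    regress_nuisance(feature_scores, include_motion = include_motion) %>%
    extract_psc(offset = offset, n_avg = n_avg) %>%
    standardize()
}

#' Block-design localizer GLM with Bonferroni-thresholded cluster masks
#'
#' Per-voxel OLS of a localizer series on HRF-convolved boxcar regressors
#' (one per condition; baseline is the implicit reference), the t statistic
#' of the requested contrast, a one-sided Bonferroni threshold at `p_fwe`
#' across in-mask voxels, and retention of suprathreshold clusters larger
#' than `min_cluster` voxels (face connectivity).
#'
#' @param data volumes x voxels matrix.
#' @param blocks tibble: `onset`, `duration`, `condition` (baseline blocks
#'   may be omitted; they are the reference).
#' @param contrast named numeric over conditions, e.g.
#'   `c(audiovisual = 1)` for audiovisual vs baseline.
#' @param dim integer(3) voxel grid.
#' @param tr repetition time, seconds.
#' @param mask optional logical grid restricting the analysis.
#' @param p_fwe family-wise alpha for the Bonferroni voxel threshold.
#' @param min_cluster retain clusters strictly larger than this (default 5).
#' @return A list of class `localizer_result`: `tmap` ([volume_map()]),
#'   `mask` (logical grid of retained voxels), `threshold`, `df`.
#' @export
localizer_glm <- function(data, blocks, contrast, dim, tr = 2.2, mask = NULL,
                          p_fwe = 0.05, min_cluster = 5) {
  conds <- sort(unique(blocks$condition))
  bad <- setdiff(names(contrast), conds)
  if (length(bad)) {
    stop_affect(paste0("Contrast names not among conditions: ",
                       paste(bad, collapse = ", ")))
  }
  n_vol <- nrow(data)
  X <- cbind(intercept = rep(1, n_vol),
             vapply(conds, function(cc) {
               b <- blocks[blocks$condition == cc, ]
               convolve_regressor(b$onset, b$duration, rep(1, nrow(b)),
                                  n_vol, tr)
             }, numeric(n_vol)))
  cvec <- c(0, as.numeric(contrast[match(conds, names(contrast))]))
  cvec[is.na(cvec)] <- 0
  qrX <- qr(X)
  beta <- qr.coef(qrX, data)
  res <- data - X %*% beta
  df <- n_vol - qrX$rank
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * as.numeric(t(cvec) %*% xtxi %*% cvec), 1e-300))
  tval <- as.numeric(cvec %*% beta) / se

  mask <- mask %||% array(TRUE, dim)
  v_in <- sum(mask)
  thr <- qt(p_fwe / v_in, df = df, lower.tail = FALSE)
  tarr <- array(NA_real_, dim)
  tarr[seq_along(tval)] <- tval
  supra <- array(FALSE, dim)
  supra[mask] <- !is.na(tarr[mask]) & tarr[mask] > thr
  lab <- label_components(supra, connectivity = 6)
  keep <- as.integer(names(which(table(lab[lab > 0]) > min_cluster)))
  outmask <- array(lab %in% keep, dim)
  structure(list(tmap = volume_map(tarr, mask, kind = "tstat"),
                 mask = outmask, threshold = thr, df = df),
            class = "localizer_result")
}

#' Combine localizer masks into the analysis mask
#'
#' Boolean algebra of the localizer masks: the combined mask is
#' `GM & VA & !(VP | AP)` - gray-matter voxels responsive to naturalistic
#' audiovisual stimulation but not to the flickering checkerboard or the beep.
#'
#' @param VA,VP,AP,GM logical 3-D arrays on a common grid (audiovisual,
#'   visual-percept, auditory-percept, gray matter).
#' @return A list of class `localizer_masks` with the four inputs and
#'   `combined`.
#' @export
combine_masks <- function(VA, VP, AP, GM) {
  dims <- lapply(list(VA, VP, AP, GM), dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_affect("All masks must share the same grid.")
  }
  combined <- GM & VA & !(VP | AP)
  structure(list(VA = VA, VP = VP, AP = AP, GM = GM, combined = combined),
            class = "localizer_masks")
}

#' @export
print.localizer_masks <- function(x, ...) {
  cat(sprintf("<localizer_masks> VA %d, VP %d, AP %d, GM %d -> combined %d voxels\n",
              sum(x$VA), sum(x$VP), sum(x$AP), sum(x$GM), sum(x$combined)))
  invisible(x)
}

#' Connected components of a 3-D mask
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 6) {
  if (!connectivity %in% c(6, 26)) stop_affect("connectivity must be 6 or 26.")
  cpp_label_components(as.logical(mask), as.integer(dim(mask)),
                       as.integer(connectivity))
}
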