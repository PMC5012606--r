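#' Trial pattern set
#'
#' The central container for decoding: a trials-by-voxels matrix of
#' percent-signal-change patterns plus a tibble of trial metadata and the
#' mapping of matrix columns back into the 3-D voxel grid.
#'
#' @param patterns numeric matrix, trials x voxels.
#' @param trial_info tibble with one row per trial; must contain
#'   `trial`, `presentation`, `exemplar_id`, `valence`, `arousal`; typically
#'   also `run`, `onset`, `participant_id`.
#' @param dim integer(3), the voxel grid dimensions.
#' @param voxel_idx integer vector of 1-based linear grid indices, one per
#'   pattern column.
#' @param affine 4x4 voxel-to-world matrix carried through untouched.
#' @param standardized logical; `TRUE` after [standardize()].
#' @return An object of class `trial_pattern_set`.
#' @export
trial_pattern_set <- function(patterns, trial_info, dim, voxel_idx,
                              affine = diag(4), standardized = FALSE) {
  patterns <- as.matrix(patterns)
  trial_info <- as_tibble(trial_info)
  need <- c("trial", "presentation", "exemplar_id", "valence", "arousal")
  miss <- setdiff(need, names(trial_info))
  if (length(miss)) {
    stop_affect(paste0("trial_info lacks column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (nrow(patterns) != nrow(trial_info)) {
    stop_affect("patterns and trial_info disagree on the number of trials.")
  }
  if (ncol(patterns) != length(voxel_idx)) {
    stop_affect("voxel_idx must have one entry per pattern column.")
  }
  assert_pm1(trial_info$valence, "valence")
  assert_pm1(trial_info$arousal, "arousal")
  structure(
    list(patterns = patterns, trial_info = trial_info,
         dim = as.integer(dim), voxel_idx = as.integer(voxel_idx),
         affine = affine, standardized = isTRUE(standardized)),
    class = "trial_pattern_set"
  )
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat(sprintf("<trial_pattern_set> %d trials x %d voxels (grid %s)%s\n",
              nrow(x$patterns), ncol(x$patterns),
              paste(x$dim, collapse = "x"),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
as.matrix.trial_pattern_set <- function(x, ...) x$patterns

#' @export
dim.trial_pattern_set <- function(x) dim(x$patterns)

#' @rdname trial_pattern_set
#' @param x a `trial_pattern_set`.
#' @param ... unused.
#' @export
tidy.trial_pattern_set <- function(x, ...) x$trial_info

# Restrict a pattern set to the voxels of a logical grid mask (or to explicit
# column indices). Used by the searchlight and cluster analyses.
#' Subset a trial pattern set to a voxel mask
#'
#' @param tps a [trial_pattern_set()].
#' @param mask logical 3-D array on the grid, or integer column indices.
#' @return A `trial_pattern_set` over the retained voxels.
#' @export
subset_voxels <- function(tps, mask) {
  if (is.array(mask) || is.logical(mask)) {
    if (!identical(as.integer(dim(mask)), tps$dim)) {
      stop_affect("Mask grid does not match the pattern set grid.")
    }
    keep <- which(tps$voxel_idx %in% which(mask))
  } else {
    keep <- as.integer(mask)
  }
  if (!length(keep)) stop_affect("Mask retains no voxels.")
  trial_pattern_set(tps$patterns[, keep, drop = FALSE], tps$trial_info,
                    tps$dim, tps$voxel_idx[keep], tps$affine,
                    tps$standardized)
}

#' Subset a trial pattern set to selected presentation blocks
#'
#' @param tps a [trial_pattern_set()].
#' @param presentations presentation indices to keep.
#' @return A `trial_pattern_set` over the retained trials.
#' @export
subset_presentations <- function(tps, presentations) {
  rows <- tps$trial_info$presentation %in% presentations
  if (!any(rows)) stop_affect("No trials in the requested presentations.")
  trial_pattern_set(tps$patterns[rows, , drop = FALSE], tps$trial_info[rows, ],
                    tps$dim, tps$voxel_idx, tps$affine, tps$standardized)
}

#' 3-D scalar map on a voxel grid
#'
#' @param values 3-D numeric array (values outside `mask` are `NA`).
#' @param mask logical 3-D array of defined voxels.
#' @param affine 4x4 voxel-to-world matrix.
#' @param kind `"accuracy_minus_chance"` or `"tstat"`.
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, mask, affine = diag(4),
                       kind = c("accuracy_minus_chance", "tstat")) {
  kind <- match.arg(kind)
  if (!identical(dim(values), dim(mask))) {
    stop_affect("values and mask must share dimensions.")
  }
  values[!mask] <- NA_real_
  if (kind == "accuracy_minus_chance") {
    rng <- range(values[mask & !is.na(values)], na.rm = TRUE)
    if (length(rng) == 2 && is.finite(rng[1]) &&
        (rng[1] < -0.5 - 1e-9 || rng[2] > 0.5 + 1e-9)) {
      stop_affect("accuracy_minus_chance values must lie in [-0.5, 0.5].")
    }
  }
  structure(list(values = values, mask = mask, affine = affine, kind = kind),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("<volume_map:%s> grid %s, %d voxels in mask\n", x$kind,
              paste(dim(x$values), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' @rdname volume_map
#' @param x a `volume_map`.
#' @param ... unused.
#' @export
tidy.volume_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  vals <- x$values[x$mask]
  kind <- x$kind
  tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3],
         value = vals, kind = kind)
}

#' Permutation null distribution
#'
#' Holds the vector of permutation statistics together with the add-one
#' p-value rule `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param stats numeric vector of permutation statistics.
#' @param observed optional observed statistic.
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(stats, observed = NULL) {
  if (!length(stats)) stop_affect("Empty null distribution.")
  structure(list(stats = as.numeric(stats), observed = observed,
                 n_perm = length(stats)),
            class = "null_distribution")
}

#' @rdname null_distribution
#' @param x a `null_distribution`.
#' @param observed observed statistic; defaults to the stored one.
#' @export
p_value <- function(x, observed = NULL) {
  stopifnot(inherits(x, "null_distribution"))
  obs <- observed %||% x$observed
  if (is.null(obs)) stop_affect("No observed statistic supplied.")
  perm_pvalue(obs, x$stats)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d permutations", x$n_perm))
  if (!is.null(x$observed)) {
    cat(sprintf("; observed = %.4g, p = %.4g", x$observed, p_value(x)))
  }
  cat("\n")
  invisible(x)
}
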