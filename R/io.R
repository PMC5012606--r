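# Readers and writers for the standard interchange formats: BOLD runs as 4-D
# NIfTI with TSV events/motion sidecars, masks as NIfTI, ratings and feature
# tables as CSV, solutions as JSON.

#' Write a BOLD dataset to disk
#'
#' One 4-D NIfTI per run (`run-<r>_bold.nii.gz`) with sidecar
#' `run-<r>_events.tsv` (onset, duration, exemplar_id, valence, arousal) and
#' `run-<r>_motion.tsv`; ground-truth masks as NIfTI plus a JSON parameter
#' file when present.
#'
#' @param dataset a `bold_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(dataset$runs)) {
    run <- dataset$runs[[r]]
    arr <- array(t(run$data), c(dataset$dim, nrow(run$data)))
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, sprintf("run-%d_bold.nii.gz", r)))
    readr::write_tsv(run$events[, c("onset", "duration", "exemplar_id",
                                    "valence", "arousal")],
                     file.path(dir, sprintf("run-%d_events.tsv", r)))
    readr::write_tsv(as.data.frame(run$motion),
                     file.path(dir, sprintf("run-%d_motion.tsv", r)),
                     col_names = FALSE)
  }
  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    RNifti::writeNifti(RNifti::asNifti(gt$valence_mask + 0),
                       file.path(dir, "truth_valence_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(gt$arousal_mask + 0),
                       file.path(dir, "truth_arousal_mask.nii.gz"))
    jsonlite::write_json(
      list(effect_pct = gt$effect_pct, noise_sd = gt$noise_sd,
           nuisance_sd = gt$nuisance_sd, rho = gt$rho, seed = gt$seed),
      file.path(dir, "truth_params.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(participant_id = dataset$participant_id, tr = dataset$tr,
         dim = dataset$dim, baseline = dataset$baseline),
    file.path(dir, "dataset.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a BOLD dataset written by [write_bold_dataset()]
#'
#' @param dir dataset directory.
#' @return A `bold_dataset` (without ground-truth patterns; masks and noise
#'   parameters are restored when present).
#' @export
read_bold_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  runs <- list()
  r <- 1
  while (file.exists(file.path(dir, sprintf("run-%d_bold.nii.gz", r)))) {
    arr <- RNifti::readNifti(file.path(dir, sprintf("run-%d_bold.nii.gz", r)))
    d <- dim(arr)
    data <- t(matrix(arr, prod(d[1:3]), d[4]))
    events <- readr::read_tsv(file.path(dir, sprintf("run-%d_events.tsv", r)),
                              show_col_types = FALSE)
    events$presentation <- r
    events$trial <- (r - 1) * nrow(events) + seq_len(nrow(events))
    motion <- as.matrix(readr::read_tsv(
      file.path(dir, sprintf("run-%d_motion.tsv", r)),
      col_names = FALSE, show_col_types = FALSE))
    runs[[r]] <- list(data = data, events = events, motion = motion)
    r <- r + 1
  }
  gt <- NULL
  if (file.exists(file.path(dir, "truth_params.json"))) {
    gt <- jsonlite::read_json(file.path(dir, "truth_params.json"),
                              simplifyVector = TRUE)
    gt$valence_mask <- array(
      as.logical(RNifti::readNifti(file.path(dir, "truth_valence_mask.nii.gz"))),
      meta$dim)
    gt$arousal_mask <- array(
      as.logical(RNifti::readNifti(file.path(dir, "truth_arousal_mask.nii.gz"))),
      meta$dim)
  }
  structure(list(participant_id = meta$participant_id, runs = runs,
                 dim = as.integer(meta$dim), tr = meta$tr,
                 baseline = meta$baseline, ground_truth = gt),
            class = "bold_dataset")
}

#' Write / read a trial pattern set (matrix + JSON sidecar)
#'
#' The pattern matrix goes to a TSV; trial metadata, grid, voxel map and the
#' standardization flag to a JSON sidecar.
#'
#' @param tps a [trial_pattern_set()].
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_patterns <- function(tps, path) {
  readr::write_tsv(as.data.frame(tps$patterns), paste0(path, "_patterns.tsv"),
                   col_names = FALSE)
  jsonlite::write_json(
    list(trial_info = tps$trial_info, dim = tps$dim,
         voxel_idx = tps$voxel_idx, affine = tps$affine,
         standardized = tps$standardized),
    paste0(path, "_patterns.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  pat <- as.matrix(readr::read_tsv(paste0(path, "_patterns.tsv"),
                                   col_names = FALSE, show_col_types = FALSE))
  dimnames(pat) <- NULL
  meta <- jsonlite::read_json(paste0(path, "_patterns.json"),
                              simplifyVector = TRUE)
  trial_pattern_set(pat, as_tibble(meta$trial_info), meta$dim, meta$voxel_idx,
                    matrix(unlist(meta$affine), 4, 4),
                    standardized = meta$standardized)
}

#' Write / read a rating set as CSV (long format)
#'
#' @param ratings a `rating_set` or its long tibble.
#' @param path CSV path.
#' @return `path` invisibly; `read_ratings()` returns the n x 32 x 6 array.
#' @export
write_ratings <- function(ratings, path) {
  long <- if (inherits(ratings, "rating_set")) ratings$long else ratings
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  subs <- sort(unique(long$subject))
  scales <- unique(long$scale)
  arr <- array(NA_real_, c(length(subs), max(long$exemplar_id), length(scales)),
               dimnames = list(NULL, NULL, scales))
  for (i in seq_along(subs)) {
    for (s in seq_along(scales)) {
      rows <- long$subject == subs[i] & long$scale == scales[s]
      arr[i, long$exemplar_id[rows], s] <- long$rating[rows]
    }
  }
  arr
}

#' Write / read a synthetic clip (lossless plain-text container)
#'
#' Frames are stored as a TSV (one row per frame, pixels column-major per
#' channel), audio as a two-row TSV, and shape metadata as JSON; values
#' round-trip exactly, so features recomputed after a round trip are
#' identical.
#'
#' @param clip a `synthetic_clip`.
#' @param path base path (without extension).
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path) {
  d <- dim(clip$frames)
  fr <- matrix(clip$frames, nrow = d[1])
  readr::write_tsv(as.data.frame(fr), paste0(path, "_frames.tsv"),
                   col_names = FALSE)
  readr::write_tsv(as.data.frame(clip$audio), paste0(path, "_audio.tsv"),
                   col_names = FALSE)
  jsonlite::write_json(
    list(dim = d, fps = clip$fps, sample_rate = clip$sample_rate,
         exemplar_id = clip$exemplar_id),
    paste0(path, "_clip.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clip
#' @export
read_clip <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_clip.json"),
                              simplifyVector = TRUE)
  fr <- as.matrix(readr::read_tsv(paste0(path, "_frames.tsv"),
                                  col_names = FALSE, show_col_types = FALSE))
  audio <- as.matrix(readr::read_tsv(paste0(path, "_audio.tsv"),
                                     col_names = FALSE,
                                     show_col_types = FALSE))
  dimnames(audio) <- NULL
  structure(list(frames = array(fr, meta$dim), fps = meta$fps,
                 audio = audio, sample_rate = meta$sample_rate,
                 exemplar_id = meta$exemplar_id),
            class = "synthetic_clip")
}

#' Write a volume map or mask as NIfTI
#'
#' @param x a [volume_map()] or a logical/numeric 3-D array.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "volume_map")) {
    v <- x$values
    v[is.na(v)] <- 0
    v
  } else x + 0
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write an INDSCAL or STATIS solution as JSON
#'
#' @param solution an `indscal_solution` or `statis_solution`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  out <- unclass(solution)
  out <- lapply(out, function(v) if (is.matrix(v)) unname(v) else v)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
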