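# Shared engine: box-searchlight CV accuracy for one participant under one or
# more label sets (column 1 observed, later columns permutations). Returns the
# centers x label-sets accuracy matrix plus the center bookkeeping.
searchlight_engine <- function(tps, label_matrix, mask, box, lambda, maxit,
                               tol) {
  if (box %% 2 != 1 || box < 1) stop_affect("box must be an odd size.")
  mask <- mask %||% array(TRUE, tps$dim)
  if (!identical(as.integer(dim(mask)), tps$dim)) {
    stop_affect("Mask grid does not match the pattern set grid.")
  }
  centers <- which(mask)
  if (!length(centers)) stop_affect("Mask retains no voxels.")
  col_of <- match(centers, tps$voxel_idx)
  if (anyNA(col_of)) {
    stop_affect("Mask includes voxels absent from the pattern set.")
  }
  neigh <- cpp_box_neighbors(as.integer(tps$dim), as.integer(centers),
                             as.integer((box - 1) / 2))
  if (any(lengths(neigh) == 0)) {
    stop_affect("A searchlight neighborhood contains no in-mask voxels.")
  }
  x <- tps$patterns[, col_of, drop = FALSE]
  pres <- as.integer(tps$trial_info$presentation)
  acc <- cpp_searchlight(x, label_matrix, pres, neigh, lambda,
                         as.integer(maxit), tol)
  list(acc = acc, centers = centers, mask = mask)
}

#' Box-searchlight decoding map
#'
#' For every in-mask voxel, the trials' patterns over the in-mask voxels of
#' its `box`^3 neighborhood (truncated at grid and mask boundaries) are
#' decoded with the standard within-participant four-fold CV, and the mean
#' accuracy minus chance (.5) is assigned to the center voxel.
#'
#' @param tps a standardized [trial_pattern_set()].
#' @param target `"valence"` or `"arousal"`.
#' @param mask logical grid of centers to scan (default: all pattern voxels).
#'   Regions responsive to low-level sensory localizers are typically
#'   excluded here.
#' @param box box side length in voxels (default 5).
#' @param lambda,maxit,tol classifier settings.
#' @return A [volume_map()] of kind `accuracy_minus_chance`.
#' @export
searchlight_map <- function(tps, target = "valence", mask = NULL, box = 5,
                            lambda = 1, maxit = 50, tol = 1e-6) {
  y01 <- matrix(as.numeric(target_labels(tps, target) > 0), ncol = 1)
  eng <- searchlight_engine(tps, y01, mask, box, lambda, maxit, tol)
  vals <- array(NA_real_, tps$dim)
  vals[eng$centers] <- eng$acc[, 1] - 0.5
  volume_map(vals, eng$mask, tps$affine, kind = "accuracy_minus_chance")
}

#' Random-effects group t-map
#'
#' Voxel-wise one-sample t of accuracy-minus-chance against zero across
#' participants. Voxels with zero across-participant variance are flagged
#' undefined (`NA` in the map, `TRUE` in the `undefined` attribute).
#'
#' @param maps list of [volume_map()]s on a common grid (one per participant).
#' @return A [volume_map()] of kind `tstat` with attributes `df` and
#'   `undefined`.
#' @export
group_ttest <- function(maps) {
  if (length(maps) < 2) stop_affect("Need at least two maps.")
  dims <- lapply(maps, function(m) dim(m$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_affect("Maps are not on a common grid.")
  }
  n <- length(maps)
  arr <- vapply(maps, function(m) m$values, maps[[1]]$values)
  mu <- apply(arr, 1:3, mean)
  s <- apply(arr, 1:3, sd)
  tval <- mu / (s / sqrt(n))
  undef <- is.finite(mu) & (s == 0)
  tval[undef] <- NA_real_
  mask <- maps[[1]]$mask
  out <- volume_map(tval, mask, maps[[1]]$affine, kind = "tstat")
  attr(out, "df") <- n - 1
  attr(out, "undefined") <- undef
  out
}

#' Extract suprathreshold clusters from a t-map
#'
#' Thresholds the map at the one-sided upper-tail `voxel_p` quantile of the
#' t distribution, labels connected components (face connectivity), and
#' retains components larger than `min_size` voxels.
#'
#' @param tmap a `tstat` [volume_map()] (e.g., from [group_ttest()]).
#' @param voxel_p cluster-forming voxel threshold (default .001 uncorrected).
#' @param min_size retain clusters strictly larger than this (default 0).
#' @param df t degrees of freedom; defaults to the map's `df` attribute.
#' @return A `cluster_table` tibble: `cluster`, `size`, `peak_value`,
#'   `peak_x/y/z` (1-based grid), `world_x/y/z` (via the affine); empty when
#'   nothing survives.
#' @export
cluster_extract <- function(tmap, voxel_p = 0.001, min_size = 0, df = NULL) {
  df <- df %||% attr(tmap, "df")
  if (is.null(df)) stop_affect("Supply `df` (map has no df attribute).")
  thr <- qt(voxel_p, df = df, lower.tail = FALSE)
  supra <- !is.na(tmap$values) & tmap$values > thr
  tab <- cluster_table_from_mask(supra, tmap$values, tmap$affine, min_size)
  attr(tab, "threshold") <- thr
  tab
}

cluster_table_from_mask <- function(supra, values, affine, min_size) {
  lab <- label_components(supra, connectivity = 6)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- purrr::map_dfr(ids, function(id) {
    vox <- which(lab == id)
    size <- length(vox)
    if (size <= min_size) return(NULL)
    peak <- vox[which.max(values[vox])]
    pc <- arrayInd(peak, dim(values))
    wc <- affine %*% c(pc - 1, 1)
    tibble(orig = id, size = size, peak_value = values[peak],
           peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
           world_x = wc[1], world_y = wc[2], world_z = wc[3])
  })
  relab <- array(0L, dim(supra))
  if (nrow(rows)) {
    rows <- rows %>% arrange(dplyr::desc(.data$size)) %>%
      mutate(cluster = dplyr::row_number())
    for (i in seq_len(nrow(rows))) relab[lab == rows$orig[i]] <- i
    rows <- rows %>% select(-"orig") %>%
      select("cluster", dplyr::everything())
  }
  class(rows) <- c("cluster_table", class(rows))
  # integer array of cluster ids (0 background), matching the `cluster` column
  attr(rows, "labels") <- relab
  rows
}

#' Voxel mask of one cluster in a cluster table
#'
#' @param clusters a `cluster_table` (from [cluster_extract()] or
#'   [searchlight_group()]).
#' @param id the `cluster` id (default 1, the largest).
#' @return Logical 3-D array.
#' @export
cluster_mask <- function(clusters, id = 1) {
  lab <- attr(clusters, "labels")
  if (is.null(lab)) stop_affect("Cluster table carries no label array.")
  lab == id
}

# Max suprathreshold component size of one group-stat vector over centers.
max_cluster_size <- function(tvec, centers, dim, thr) {
  supra <- array(FALSE, dim)
  supra[centers] <- !is.na(tvec) & tvec > thr
  lab <- label_components(supra, connectivity = 6)
  if (!any(lab > 0)) return(0L)
  max(tabulate(lab[lab > 0]))
}

# Column-wise group one-sample t across participants for an accuracy array
# (participants x centers x label-sets), against chance.
group_t_columns <- function(acc_arr) {
  p <- dim(acc_arr)[1]
  mu <- apply(acc_arr, c(2, 3), mean) - 0.5
  s <- apply(acc_arr, c(2, 3), sd)
  tmat <- mu / (s / sqrt(p))
  tmat[s == 0] <- NA_real_
  tmat
}

#' Max-cluster-size permutation null for searchlight group maps
#'
#' For each permutation, every participant's condition labels are shuffled
#' (within participant, preserving the 64/64 balance), the searchlight maps
#' are rebuilt, the random-effects group t-map is thresholded at `voxel_p`,
#' and the largest suprathreshold component size is recorded (0 when nothing
#' survives). The cluster-size cutoff is the smallest size whose null
#' exceedance probability is at most `alpha`. Valence and arousal label
#' permutations are exchangeable, so one null serves both targets.
#'
#' @param tps_list list of standardized [trial_pattern_set()]s (one per
#'   participant) on a common grid.
#' @param target `"valence"` or `"arousal"` (defines the labels permuted).
#' @param mask logical grid of searchlight centers.
#' @param n_perm number of label permutations; below 20 a warning is issued
#'   (the cutoff is unstable) but the null is still computed.
#' @param seed RNG seed.
#' @param box,lambda,maxit,tol searchlight settings as in [searchlight_map()].
#' @param voxel_p cluster-forming threshold for the group t-map.
#' @param alpha cluster-level significance (default .05).
#' @return A list of class `cluster_null`: `sizes` ([null_distribution()]),
#'   `cutoff`, `voxel_p`, `alpha`, `n_perm`.
#' @export
cluster_null <- function(tps_list, target = "valence", mask = NULL,
                         n_perm = 1000, seed = 1, box = 5, lambda = 1,
                         maxit = 50, tol = 1e-6, voxel_p = 0.001,
                         alpha = 0.05) {
  if (n_perm < 1) stop_affect("n_perm must be at least 1.")
  if (n_perm < 20) {
    warn("n_perm < 20: the cluster-size cutoff will be unstable.")
  }
  run <- searchlight_group_engine(tps_list, target, mask, n_perm, seed, box,
                                  lambda, maxit, tol, include_observed = FALSE)
  thr <- qt(voxel_p, df = length(tps_list) - 1, lower.tail = FALSE)
  sizes <- vapply(seq_len(n_perm), function(b) {
    max_cluster_size(run$tmat[, b], run$centers, run$dim, thr)
  }, integer(1))
  cutoff <- cutoff_from_sizes(sizes, alpha)
  structure(list(sizes = null_distribution(sizes), cutoff = cutoff,
                 voxel_p = voxel_p, alpha = alpha, n_perm = n_perm),
            class = "cluster_null")
}

cutoff_from_sizes <- function(sizes, alpha) {
  for (k in 0:(max(sizes) + 1L)) {
    if (mean(sizes >= k) <= alpha) return(k)
  }
  max(sizes) + 1L
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf("<cluster_null> %d permutations: cluster-size cutoff %d (alpha %.2f, voxel p %.3g)\n",
              x$n_perm, x$cutoff, x$alpha, x$voxel_p))
  invisible(x)
}

# One pass over participants computing searchlight accuracies for the
# observed labels (optionally) plus n_perm within-participant permutations.
searchlight_group_engine <- function(tps_list, target, mask, n_perm, seed,
                                     box, lambda, maxit, tol,
                                     include_observed = TRUE) {
  np <- length(tps_list)
  if (np < 2) stop_affect("Need at least two participants.")
  acc <- NULL
  centers <- NULL
  for (p in seq_len(np)) {
    tps <- tps_list[[p]]
    y <- as.numeric(target_labels(tps, target) > 0)
    withr_seed(sub_seed(seed, p))
    cols <- if (include_observed) cbind(y) else NULL
    if (n_perm > 0) {
      perms <- vapply(seq_len(n_perm), function(b) sample(y), numeric(length(y)))
      cols <- cbind(cols, perms)
    }
    eng <- searchlight_engine(tps, cols, mask, box, lambda, maxit, tol)
    if (is.null(acc)) {
      acc <- array(NA_real_, c(np, nrow(eng$acc), ncol(eng$acc)))
      centers <- eng$centers
    }
    acc[p, , ] <- eng$acc
  }
  list(tmat = group_t_columns(acc), acc = acc, centers = centers,
       dim = tps_list[[1]]$dim, mask = mask %||% array(TRUE, tps_list[[1]]$dim))
}

#' Full searchlight group analysis with permutation cluster inference
#'
#' Runs the per-participant searchlight maps, the random-effects group
#' t-map, cluster extraction at `voxel_p`, and the max-cluster-size
#' permutation null - sharing the per-participant Gram computations between
#' the observed and permuted label sets. Clusters at least as large as the
#' null cutoff are marked significant; each cluster receives an add-one
#' permutation p-value.
#'
#' @inheritParams cluster_null
#' @return A list of class `searchlight_group`: `clusters` (cluster table
#'   with `p_perm` and `significant`), `tmap`, `maps` (per participant),
#'   `null` (`cluster_null`), `cutoff`.
#' @export
searchlight_group <- function(tps_list, target = "valence", mask = NULL,
                              n_perm = 100, seed = 1, box = 5, lambda = 1,
                              maxit = 50, tol = 1e-6, voxel_p = 0.001,
                              alpha = 0.05) {
  if (n_perm > 0 && n_perm < 20) {
    warn("n_perm < 20: the cluster-size cutoff will be unstable.")
  }
  run <- searchlight_group_engine(tps_list, target, mask, n_perm, seed, box,
                                  lambda, maxit, tol, include_observed = TRUE)
  np <- dim(run$acc)[1]
  thr <- qt(voxel_p, df = np - 1, lower.tail = FALSE)
  dims <- run$dim

  tarr <- array(NA_real_, dims)
  tarr[run$centers] <- run$tmat[, 1]
  tmap <- volume_map(tarr, run$mask, tps_list[[1]]$affine, kind = "tstat")
  attr(tmap, "df") <- np - 1

  maps <- lapply(seq_len(np), function(p) {
    v <- array(NA_real_, dims)
    v[run$centers] <- run$acc[p, , 1] - 0.5
    volume_map(v, run$mask, tps_list[[p]]$affine,
               kind = "accuracy_minus_chance")
  })

  clusters <- cluster_extract(tmap, voxel_p = voxel_p, min_size = 0, df = np - 1)

  nullobj <- NULL; cutoff <- NA_integer_
  if (n_perm > 0) {
    sizes <- vapply(seq_len(n_perm), function(b) {
      max_cluster_size(run$tmat[, b + 1], run$centers, dims, thr)
    }, integer(1))
    cutoff <- cutoff_from_sizes(sizes, alpha)
    nullobj <- structure(list(sizes = null_distribution(sizes),
                              cutoff = cutoff, voxel_p = voxel_p,
                              alpha = alpha, n_perm = n_perm),
                         class = "cluster_null")
    if (nrow(clusters)) {
      lab_arr <- attr(clusters, "labels")
      thr_attr <- attr(clusters, "threshold")
      clusters <- clusters %>%
        mutate(p_perm = vapply(.data$size, perm_pvalue,
                               numeric(1), null_stats = nullobj$sizes$stats),
               significant = .data$size >= cutoff)
      attr(clusters, "labels") <- lab_arr
      attr(clusters, "threshold") <- thr_attr
    }
  }
  structure(list(clusters = clusters, tmap = tmap, maps = maps,
                 null = nullobj, cutoff = cutoff, target = target),
            class = "searchlight_group")
}

#' @export
print.searchlight_group <- function(x, ...) {
  cat(sprintf("<searchlight_group> %s: %d cluster(s)%s\n", x$target,
              nrow(x$clusters),
              if (!is.na(x$cutoff)) sprintf(", size cutoff %d", x$cutoff) else ""))
  if (nrow(x$clusters)) print(as_tibble(x$clusters))
  invisible(x)
}

#' Searchlight localization target of a ground-truth region
#'
#' A box searchlight assigns information to every center whose neighborhood
#' intersects the informative region, so its finest attainable localization
#' is the region dilated by half the box width. This helper returns that
#' dilated support, the appropriate reference when scoring recovered cluster
#' masks (e.g., with [dice_overlap()]).
#'
#' @param truth_mask logical 3-D ground-truth region.
#' @param box searchlight box side (default 5).
#' @return Logical array: centers whose box intersects the region.
#' @export
searchlight_support <- function(truth_mask, box = 5) {
  half <- (box - 1) / 2
  d <- dim(truth_mask)
  out <- array(FALSE, d)
  idx <- which(truth_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    lo <- pmax(idx[i, ] - half, 1)
    hi <- pmin(idx[i, ] + half, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  out
}
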