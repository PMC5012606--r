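#' Stability-based voxel selection within a training partition
#'
#' Per voxel, stability is the mean pairwise Pearson correlation of its
#' 32-exemplar response profile across the three training presentations; the
#' most stable `keep_frac` of voxels (ceiling rule) are retained. Voxels with
#' a constant profile in any presentation get stability -1, so they are never
#' selected preferentially. Ties at the cutoff break deterministically toward
#' the lower voxel index.
#'
#' @param tps a [trial_pattern_set()] restricted to the training trials
#'   (three presentations of all 32 exemplars).
#' @param keep_frac fraction of voxels to keep (default 0.8).
#' @return Integer vector of retained voxel column indices, with the full
#'   stability vector as attribute `stability`.
#' @export
stability_select <- function(tps, keep_frac = 0.8) {
  pres <- sort(unique(tps$trial_info$presentation))
  if (length(pres) < 3) {
    stop_affect("Stability needs at least three training presentations.")
  }
  profiles <- lapply(pres, function(p) {
    rows <- tps$trial_info$presentation == p
    ord <- order(tps$trial_info$exemplar_id[rows])
    tps$patterns[rows, , drop = FALSE][ord, , drop = FALSE]
  })
  npair <- 0
  stab <- numeric(ncol(tps$patterns))
  undef <- logical(ncol(tps$patterns))
  for (a in seq_along(profiles)) {
    sda <- apply(profiles[[a]], 2, sd)
    undef <- undef | sda == 0
  }
  for (a in 1:(length(profiles) - 1)) {
    for (b in (a + 1):length(profiles)) {
      cc <- colSums(scale(profiles[[a]]) * scale(profiles[[b]])) /
        (nrow(profiles[[a]]) - 1)
      cc[!is.finite(cc)] <- 0
      stab <- stab + cc
      npair <- npair + 1
    }
  }
  stab <- stab / npair
  stab[undef] <- -1
  k <- ceiling(keep_frac * length(stab))
  keep <- order(-stab, seq_along(stab))[seq_len(k)]
  keep <- sort(keep)
  attr(keep, "stability") <- stab
  keep
}

#' Within-cluster confirmatory decoding across participants
#'
#' For each participant, four-fold within-participant CV restricted to the
#' cluster's voxels, with stability selection (top `keep_frac`) computed
#' inside each fold's training presentations only - no test leakage. Group
#' significance is a one-sample t-test of the per-participant mean accuracies
#' against chance (.5), one-sided.
#'
#' @param tps_list list of standardized [trial_pattern_set()]s.
#' @param cluster_voxels logical grid mask or integer linear grid indices of
#'   the cluster.
#' @param target `"valence"` or `"arousal"`.
#' @param keep_frac stability selection fraction (default 0.8; `1` disables).
#' @param lambda,maxit,tol classifier settings.
#' @return A list of class `cluster_mvpa_result`: `accuracies` (tibble:
#'   participant, accuracy), `mean_accuracy`, `t`, `df`, `p`.
#' @export
cluster_mvpa <- function(tps_list, cluster_voxels, target = "valence",
                         keep_frac = 0.8, lambda = 1, maxit = 50,
                         tol = 1e-6) {
  accs <- vapply(tps_list, function(tps) {
    sub <- subset_voxels(tps, cluster_voxels)
    if (ncol(sub$patterns) < 2) {
      stop_affect("Cluster has fewer than 2 voxels.")
    }
    y <- target_labels(sub, target)
    y01 <- as.numeric(y > 0)
    folds <- sub$trial_info$presentation
    fold_acc <- vapply(1:4, function(f) {
      tr <- folds != f
      tr_set <- trial_pattern_set(sub$patterns[tr, , drop = FALSE],
                                  sub$trial_info[tr, ], sub$dim,
                                  sub$voxel_idx, sub$affine,
                                  sub$standardized)
      keep <- if (keep_frac < 1) stability_select(tr_set, keep_frac) else
        seq_len(ncol(sub$patterns))
      xtr <- sub$patterns[tr, keep, drop = FALSE]
      xte <- sub$patterns[!tr, keep, drop = FALSE]
      acc <- cpp_cv_accuracy(rbind(xtr, xte),
                             c(y01[tr], y01[!tr]),
                             c(rep(2L, sum(tr)), rep(1L, sum(!tr))),
                             lambda, as.integer(maxit), tol)
      acc[1]
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  n <- length(accs)
  se <- if (n >= 2) sd(accs) / sqrt(n) else NA_real_
  tval <- if (!is.na(se) && se > 0) (mean(accs) - 0.5) / se else NA_real_
  structure(list(
    accuracies = tibble(participant = seq_len(n), accuracy = accs),
    mean_accuracy = mean(accs), t = tval, df = n - 1,
    p = if (is.na(tval)) NA_real_ else pt(tval, n - 1, lower.tail = FALSE)
  ), class = "cluster_mvpa_result")
}

#' @export
print.cluster_mvpa_result <- function(x, ...) {
  cat(sprintf("<cluster_mvpa_result> mean accuracy %.3f across %d participants; t(%d) = %.2f, one-sided p = %.4g\n",
              x$mean_accuracy, nrow(x$accuracies), x$df, x$t, x$p))
  invisible(x)
}

#' STATIS compromise analysis of exemplar-by-voxel tables
#'
#' A generalization of PCA to multiple tables sharing rows (32 exemplars)
#' but not columns (each participant's cluster voxels). Each table is
#' column-centred and converted to its 32 x 32 cross-product matrix; table
#' weights are the (normalized, nonnegative) first eigenvector of the RV
#' coefficient matrix between tables; the compromise is the weighted sum of
#' cross-product matrices and its eigendecomposition gives the factor scores
#' (eigenvectors scaled by the square root of their eigenvalues). Column
#' signs are fixed so each score column's largest-magnitude entry is
#' positive.
#'
#' @param tables list of numeric matrices, all with the same number of rows.
#' @param n_dims number of factor-score dimensions to return (default 2).
#' @return A `statis_solution`: `table_weights` (sums to 1), `factor_scores`
#'   (rows x `n_dims`), `eigenvalues` (all, nonincreasing), `rv_matrix`.
#' @export
statis <- function(tables, n_dims = 2) {
  if (!length(tables)) stop_affect("No tables supplied.")
  nr <- vapply(tables, nrow, integer(1))
  if (length(unique(nr)) != 1) {
    stop_affect("All tables must have the same number of rows.")
  }
  S <- lapply(tables, function(x) {
    xc <- scale(as.matrix(x), center = TRUE, scale = FALSE)
    tcrossprod(xc)
  })
  k <- length(S)
  rv <- matrix(1, k, k)
  norms <- vapply(S, function(s) sqrt(sum(s^2)), numeric(1))
  if (any(norms == 0)) stop_affect("A table has zero variance.")
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      rv[i, j] <- rv[j, i] <- sum(S[[i]] * S[[j]]) / (norms[i] * norms[j])
    }
  }
  ev <- eigen(rv, symmetric = TRUE)
  alpha <- abs(ev$vectors[, 1])
  alpha <- alpha / sum(alpha)
  compromise <- Reduce(`+`, Map(`*`, S, alpha))
  ec <- eigen(compromise, symmetric = TRUE)
  vals <- pmax(ec$values, 0)
  d <- min(n_dims, sum(vals > 1e-12))
  scores <- ec$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(d)]), d)
  for (j in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("dim", seq_len(ncol(scores)))
  structure(list(table_weights = alpha, factor_scores = scores,
                 eigenvalues = vals, rv_matrix = rv),
            class = "statis_solution")
}

#' @export
print.statis_solution <- function(x, ...) {
  cat(sprintf("<statis_solution> %d tables -> %d x %d compromise scores; leading eigenvalues %s\n",
              length(x$table_weights), nrow(x$factor_scores),
              ncol(x$factor_scores),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Point-biserial correlation against a +/-1 design vector
#'
#' Pearson correlation between a score vector and the dichotomous design
#' codes (+1 positive / high arousal, -1 negative / low arousal), with the
#' two-sided p-value from the t transform on `n - 2` df.
#'
#' @param scores numeric vector.
#' @param design +/-1 vector of the same length, both classes present.
#' @return A tibble: `r_pb`, `t`, `df`, `p`.
#' @export
point_biserial <- function(scores, design) {
  assert_pm1(design, "design")
  if (length(unique(design)) != 2) {
    stop_affect("Both design classes must be present.")
  }
  if (sd(scores) == 0) stop_affect("Scores are constant.")
  r <- cor(scores, design)
  df <- length(scores) - 2
  tval <- r * sqrt(df) / sqrt(max(1 - r^2, 1e-300))
  tibble(r_pb = r, t = tval, df = df,
         p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

#' Design correlation of a STATIS solution
#'
#' Correlates each factor-score dimension with the design codes and reports
#' the dimension with the largest absolute point-biserial correlation (the
#' solution's "corresponding coordinate" for that affect dimension).
#'
#' @param solution a [statis()] result.
#' @param design +/-1 design vector over the rows.
#' @return A tibble: `dimension`, `r_pb`, `t`, `df`, `p`.
#' @export
statis_design_correlation <- function(solution, design) {
  res <- purrr::map_dfr(seq_len(ncol(solution$factor_scores)), function(d) {
    dplyr::bind_cols(tibble(dimension = d),
                     point_biserial(solution$factor_scores[, d], design))
  })
  res[which.max(abs(res$r_pb)), ]
}
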