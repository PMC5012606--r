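#' L2-penalized logistic regression classifier
#'
#' Penalized maximum-likelihood logistic regression (ridge penalty of
#' strength `lambda` on the weights, intercept unpenalized), fitted by
#' iteratively reweighted least squares; with more features than
#' observations the problem is reduced exactly to the row space of the
#' design. Decisions are the sign of the linear score; a score of exactly
#' zero is broken deterministically toward the first class (the smaller
#' label).
#'
#' @param x numeric matrix, observations x features.
#' @param y two-class label vector (any type with two unique values; sorted
#'   order defines first/second class).
#' @param lambda ridge penalty (default 1, on standardized patterns).
#' @param maxit,tol IRLS iteration cap and coefficient-change tolerance.
#' @return An `affect_logit` object: `weights`, `intercept`, `classes`,
#'   `lambda`, `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, lambda = 1, maxit = 50, tol = 1e-8) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) {
    stop_affect("Training labels must contain exactly two classes.")
  }
  y01 <- as.numeric(y == classes[2])
  fit <- cpp_fit_ridge_logit(x, y01, lambda, as.integer(maxit), tol)
  structure(list(weights = as.numeric(fit$weights),
                 intercept = fit$intercept, classes = classes,
                 lambda = lambda, converged = fit$converged,
                 iterations = fit$iterations),
            class = "affect_logit")
}

#' @rdname fit_logistic
#' @param object an `affect_logit` fit.
#' @param newdata matrix of observations to classify.
#' @param type `"class"` (default) or `"score"` (linear predictor).
#' @param ... unused.
#' @export
predict.affect_logit <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  score <- as.numeric(object$intercept + as.matrix(newdata) %*% object$weights)
  if (type == "score") return(score)
  ifelse(score > 0, object$classes[2], object$classes[1])
}

#' @export
print.affect_logit <- function(x, ...) {
  cat(sprintf("<affect_logit> %d weights, lambda = %g, %s in %d iterations\n",
              length(x$weights), x$lambda,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

# ---- cross-validation machinery ------------------------------------------

target_labels <- function(tps, target) {
  target <- match.arg(target, c("valence", "arousal"))
  tps$trial_info[[target]]
}

# Balanced-fold CV accuracy via the compiled engine. Returns the cv_result
# container; when n_perm > 0 a training-label permutation test is run with
# the same engine (Gram matrices reused across permutations).
run_cv <- function(x, y_pm1, fold_id, scheme, target, fold_meta, lambda,
                   maxit, tol, n_perm, seed) {
  y01 <- as.numeric(y_pm1 > 0)
  fold_id <- as.integer(fold_id)
  if (n_perm > 0) {
    withr_seed(seed)
    perms <- lapply(sort(unique(fold_id)), function(f) {
      tr <- which(fold_id != f)
      vapply(seq_len(n_perm), function(b) sample(y01[tr]),
             numeric(length(tr)))
    })
    accs <- cpp_cv_perm_accuracy(x, y01, fold_id, perms, lambda,
                                 as.integer(maxit), tol)
    fold_acc <- accs[1, ]
    null_means <- rowMeans(accs[-1, , drop = FALSE])
  } else {
    fold_acc <- as.numeric(cpp_cv_accuracy(x, y01, fold_id, lambda,
                                           as.integer(maxit), tol))
    null_means <- NULL
  }
  n_test <- as.integer(table(fold_id))
  mean_acc <- sum(fold_acc * n_test) / sum(n_test)
  res <- list(
    folds = dplyr::bind_cols(fold_meta,
                             tibble(n_test = n_test, accuracy = fold_acc)),
    mean_accuracy = mean_acc, scheme = scheme, target = target,
    lambda = lambda,
    null = if (!is.null(null_means)) {
      null_distribution(null_means, observed = mean_acc)
    } else NULL,
    p_perm = if (!is.null(null_means)) {
      perm_pvalue(mean_acc, null_means)
    } else NA_real_
  )
  structure(res, class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result:%s> %s: mean accuracy %.3f over %d folds",
              x$scheme, x$target, x$mean_accuracy, nrow(x$folds)))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Within-participant cross-validated decoding
#'
#' Four-fold cross-validation leaving one presentation block of the 32
#' exemplars out per fold: fold k tests the 32 trials of presentation k, the
#' classifier is trained on the other three presentations.
#'
#' @param tps a standardized [trial_pattern_set()].
#' @param target `"valence"` or `"arousal"`.
#' @param lambda,maxit,tol classifier settings (see [fit_logistic()]).
#' @param n_perm if positive, run a permutation test with this many
#'   non-informative shuffles of the training labels (test labels untouched).
#' @param seed seed for the permutations.
#' @return A `cv_result`: per-fold accuracies, mean accuracy, and (with
#'   permutations) the null distribution and add-one p-value.
#' @export
cv_within <- function(tps, target = "valence", lambda = 1, maxit = 50,
                      tol = 1e-6, n_perm = 0, seed = 1) {
  pres <- tps$trial_info$presentation
  if (!setequal(unique(pres), 1:4)) {
    stop_affect("Patterns must contain presentations 1 to 4.")
  }
  run_cv(tps$patterns, target_labels(tps, target), pres, "within_presentation",
         target, tibble(fold = 1:4, presentation = 1:4), lambda, maxit, tol,
         n_perm, seed)
}

#' Cross-exemplar decoding
#'
#' Thirty-two folds: each fold trains on all trials of 31 exemplars (124
#' trials) and tests the four presentations of the held-out exemplar, so
#' test stimuli are never seen in training. Generalization across exemplars
#' is what separates affect decoding from stimulus memorization.
#'
#' @inheritParams cv_within
#' @return A `cv_result` with 32 folds.
#' @export
cv_cross_exemplar <- function(tps, target = "valence", lambda = 1, maxit = 50,
                              tol = 1e-6, n_perm = 0, seed = 1) {
  ex <- tps$trial_info$exemplar_id
  counts <- table(ex)
  if (any(counts != 4)) {
    stop_affect("Every exemplar must have exactly 4 presentations.")
  }
  ids <- sort(unique(ex))
  fold_id <- match(ex, ids)
  run_cv(tps$patterns, target_labels(tps, target), fold_id, "cross_exemplar",
         target, tibble(fold = seq_along(ids), exemplar_id = ids), lambda,
         maxit, tol, n_perm, seed)
}

#' Cross-participant decoding
#'
#' Leave-one-participant-out cross-validation: the classifier is trained on
#' the pooled trials of all other participants and predicts every trial of
#' the held-out participant. All pattern sets must live in a common voxel
#' space.
#'
#' @param tps_list list of standardized [trial_pattern_set()]s, one per
#'   participant, on a common grid and voxel selection.
#' @inheritParams cv_within
#' @return A `cv_result` with one fold per participant.
#' @export
cv_cross_participant <- function(tps_list, target = "valence", lambda = 1,
                                 maxit = 50, tol = 1e-6, n_perm = 0,
                                 seed = 1) {
  if (length(tps_list) < 2) stop_affect("Need at least two participants.")
  vox <- lapply(tps_list, `[[`, "voxel_idx")
  if (!all(vapply(vox, identical, logical(1), vox[[1]]))) {
    stop_affect("Participants are not in a common voxel space.")
  }
  x <- do.call(rbind, lapply(tps_list, `[[`, "patterns"))
  y <- unlist(lapply(tps_list, target_labels, target))
  fold_id <- rep(seq_along(tps_list),
                 vapply(tps_list, function(t) nrow(t$patterns), integer(1)))
  pid <- vapply(tps_list, function(t) {
    t$trial_info$participant_id[1] %||% NA_integer_
  }, numeric(1))
  run_cv(x, y, fold_id, "cross_participant", target,
         tibble(fold = seq_along(tps_list), participant_id = pid), lambda,
         maxit, tol, n_perm, seed)
}

#' Permutation test around an arbitrary cross-validation routine
#'
#' Builds an empirical null by re-running the supplied cross-validation with
#' non-informatively permuted training labels. The callable receives one
#' logical argument `permute`; it must return the mean CV accuracy, shuffling
#' labels within the training partition of each fold when `permute = TRUE`
#' (test labels untouched). The p-value uses the add-one rule.
#'
#' @param cv_callable `function(permute)` returning a mean accuracy.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the permutation stream.
#' @return A list: `observed`, `null` ([null_distribution()]), `p`.
#' @export
permutation_test <- function(cv_callable, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop_affect("n_perm must be at least 1.")
  withr_seed(seed)
  observed <- cv_callable(FALSE)
  nulls <- vapply(seq_len(n_perm), function(b) cv_callable(TRUE), numeric(1))
  nd <- null_distribution(nulls, observed = observed)
  list(observed = observed, null = nd, p = p_value(nd))
}
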