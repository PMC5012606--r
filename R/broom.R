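# broom-style tidiers for the fitted objects.

#' Tidy a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return One row per fold: fold metadata, `n_test`, `accuracy`.
#' @export
tidy.cv_result <- function(x, ...) {
  x$folds %>% mutate(scheme = x$scheme, target = x$target)
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(scheme = x$scheme, target = x$target,
         mean_accuracy = x$mean_accuracy, n_folds = nrow(x$folds),
         p_perm = x$p_perm, lambda = x$lambda)
}

#' Tidy an INDSCAL solution
#'
#' @param x an `indscal_solution`.
#' @param ... unused.
#' @return One row per stimulus and dimension: `stimulus`, `dimension`,
#'   `coordinate`.
#' @export
tidy.indscal_solution <- function(x, ...) {
  as_tibble(x$group_space) %>%
    mutate(stimulus = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"stimulus", names_to = "dimension",
                        values_to = "coordinate")
}

#' @rdname tidy.indscal_solution
#' @export
glance.indscal_solution <- function(x, ...) {
  tibble(stress = x$stress, r_squared = x$r_squared,
         n_dims = ncol(x$group_space), n_subjects = nrow(x$subject_weights),
         n_iterations = x$n_iterations, converged = x$converged)
}

#' Tidy a STATIS solution
#'
#' @param x a `statis_solution`.
#' @param ... unused.
#' @return One row per row-object and dimension.
#' @export
tidy.statis_solution <- function(x, ...) {
  as_tibble(x$factor_scores) %>%
    mutate(stimulus = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"stimulus", names_to = "dimension",
                        values_to = "coordinate")
}

#' @rdname tidy.statis_solution
#' @export
glance.statis_solution <- function(x, ...) {
  tibble(n_tables = length(x$table_weights),
         n_dims = ncol(x$factor_scores),
         lambda_1 = x$eigenvalues[1],
         explained_1 = x$eigenvalues[1] / sum(x$eigenvalues))
}

#' Tidy a within-cluster decoding result
#'
#' @param x a `cluster_mvpa_result`.
#' @param ... unused.
#' @return Per-participant accuracies.
#' @export
tidy.cluster_mvpa_result <- function(x, ...) x$accuracies

#' @rdname tidy.cluster_mvpa_result
#' @export
glance.cluster_mvpa_result <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, t = x$t, df = x$df, p = x$p)
}
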