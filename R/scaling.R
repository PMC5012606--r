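#' Stimulus-by-stimulus correlation matrix from one subject's ratings
#'
#' Pearson correlation between the 32 stimulus profiles across the six rating
#' scales; symmetric with unit diagonal.
#'
#' @param ratings 32 x 6 numeric matrix (one subject), or a `rating_set`, in
#'   which case a list of matrices (one per subject) is returned.
#' @return 32 x 32 correlation matrix, or a list of them.
#' @export
ratings_to_corr <- function(ratings) {
  if (inherits(ratings, "rating_set")) {
    return(lapply(seq_len(dim(ratings$ratings)[1]), function(i) {
      ratings_to_corr(ratings$ratings[i, , ])
    }))
  }
  ratings <- as.matrix(ratings)
  v <- apply(ratings, 1, sd)
  if (any(v == 0)) {
    stop_affect(sprintf("Stimulus %s has a zero-variance rating profile.",
                        paste(which(v == 0), collapse = ", ")))
  }
  r <- cor(t(ratings))
  diag(r) <- 1
  r
}

# Torgerson double-centering of 1 - r treated as squared distances.
torgerson <- function(r) {
  d2 <- 1 - r
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  -0.5 * j %*% d2 %*% j
}

# Nonnegative least squares for a handful of coefficients by active-set
# enumeration (d is 2 or 3 here; exact).
nnls_small <- function(G, c_vec) {
  d <- length(c_vec)
  best <- NULL; best_val <- Inf
  for (mask in 0:(2^d - 1)) {
    on <- which(bitwAnd(mask, 2^(seq_len(d) - 1)) > 0)
    w <- numeric(d)
    if (length(on)) {
      sol <- tryCatch(solve(G[on, on, drop = FALSE], c_vec[on]),
                      error = function(e) NULL)
      if (is.null(sol) || any(sol < 0)) next
      w[on] <- sol
    }
    val <- -2 * sum(w * c_vec) + as.numeric(t(w) %*% G %*% w)
    if (val < best_val - 1e-12) { best_val <- val; best <- w }
  }
  best %||% numeric(d)
}

#' Individual-differences scaling (INDSCAL) of correlation matrices
#'
#' Fits the weighted-Euclidean model: each subject's double-centred
#' (Torgerson-transformed, with `1 - r` as the squared-distance proxy)
#' similarity structure is approximated by the scalar products of a common
#' group space whose dimensions are stretched by nonnegative per-subject
#' weights, `B_i ~ X W_i X'`. Fitting is alternating least squares: exact
#' nonnegative weight updates and a line-searched configuration update, so
#' the loss (and hence stress) is nonincreasing over iterations. Initialized
#' from classical MDS of the mean matrix; optional random restarts are
#' governed by `seed`. Dimensions are reported as returned (INDSCAL axes are
#' not rotation-invariant); any alignment to a reference is the caller's job.
#'
#' @param corr_matrices list of symmetric stimulus correlation matrices, one
#'   per subject, all of the same order.
#' @param n_dims number of dimensions (default 2).
#' @param max_iter,tol ALS iteration cap and relative loss-change tolerance.
#' @param seed seed for random restarts.
#' @param n_restarts additional randomly perturbed starts (best fit kept).
#' @return An `indscal_solution`: `group_space` (stimuli x d, unit-norm
#'   columns), `subject_weights` (n x d, nonnegative), `stress`
#'   (`sqrt(SSE / sum ||B_i||^2)`), `r_squared` (`1 - SSE / sum ||B_i||^2`),
#'   `n_iterations`, `converged`, `stress_path`.
#' @export
indscal <- function(corr_matrices, n_dims = 2, max_iter = 200, tol = 1e-9,
                    seed = 1, n_restarts = 0) {
  if (inherits(corr_matrices, "matrix")) corr_matrices <- list(corr_matrices)
  k <- length(corr_matrices)
  if (k < 1) stop_affect("At least one matrix is required.")
  n <- nrow(corr_matrices[[1]])
  for (m in corr_matrices) {
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop_affect("Input matrices must be symmetric.")
    }
    if (!all(dim(m) == n)) stop_affect("All matrices must have the same order.")
  }
  if (n_dims >= n) stop_affect("n_dims must be smaller than the matrix order.")

  B <- lapply(corr_matrices, torgerson)
  total_ss <- sum(vapply(B, function(b) sum(b^2), numeric(1)))
  Bmean <- Reduce(`+`, B) / k
  eg <- eigen(Bmean, symmetric = TRUE)
  X0 <- eg$vectors[, seq_len(n_dims), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(n_dims)], 1e-12)), n_dims)

  withr_seed(seed)
  starts <- c(list(X0), lapply(seq_len(n_restarts), function(i) {
    X0 + matrix(rnorm(length(X0), 0, 0.1 * sd(X0)), nrow(X0))
  }))

  fit_one <- function(X) {
    normalize <- function(X, W) {
      s <- sqrt(colSums(X^2))
      s[s == 0] <- 1
      list(X = sweep(X, 2, s, `/`), W = sweep(W, 2, s^2, `*`))
    }
    sse <- function(X, W) {
      sum(vapply(seq_len(k), function(i) {
        sum((B[[i]] - X %*% (t(X) * W[i, ]))^2)
      }, numeric(1)))
    }
    weights_step <- function(X) {
      XtX <- crossprod(X)
      G <- XtX^2
      t(vapply(seq_len(k), function(i) {
        c_vec <- vapply(seq_len(n_dims), function(d) {
          as.numeric(t(X[, d]) %*% B[[i]] %*% X[, d])
        }, numeric(1))
        nnls_small(G, c_vec)
      }, numeric(n_dims)))
    }
    W <- matrix(1, k, n_dims)
    W <- weights_step(X)
    cur <- sse(X, W)
    path <- sqrt(cur / total_ss)
    converged <- FALSE
    it <- 0
    for (it in seq_len(max_iter)) {
      # configuration update (CANDECOMP step), backtracked for monotonicity
      num <- Reduce(`+`, lapply(seq_len(k), function(i) {
        B[[i]] %*% sweep(X, 2, W[i, ], `*`)
      }))
      den <- Reduce(`+`, lapply(seq_len(k), function(i) {
        (W[i, ] %o% W[i, ]) * crossprod(X)
      }))
      cand <- tryCatch(num %*% solve(den), error = function(e) NULL)
      if (!is.null(cand)) {
        t_step <- 1
        repeat {
          Xt <- (1 - t_step) * X + t_step * cand
          if (sse(Xt, weights_step(Xt)) < cur || t_step < 1e-4) break
          t_step <- t_step / 2
        }
        if (sse(Xt, weights_step(Xt)) < cur) X <- Xt
      }
      W <- weights_step(X)
      nw <- normalize(X, W)
      X <- nw$X; W <- nw$W
      new <- sse(X, W)
      path <- c(path, sqrt(new / total_ss))
      if (abs(cur - new) < tol * max(cur, 1e-12)) {
        converged <- TRUE
        cur <- new
        break
      }
      cur <- new
    }
    list(X = X, W = W, sse = cur, path = path, iter = it,
         converged = converged)
  }

  fits <- lapply(starts, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  structure(list(
    group_space = `colnames<-`(best$X, paste0("dim", seq_len(n_dims))),
    subject_weights = `colnames<-`(best$W, paste0("dim", seq_len(n_dims))),
    stress = sqrt(best$sse / total_ss),
    r_squared = 1 - best$sse / total_ss,
    n_iterations = best$iter, converged = best$converged,
    stress_path = best$path
  ), class = "indscal_solution")
}

#' @export
print.indscal_solution <- function(x, ...) {
  cat(sprintf("<indscal_solution> %d stimuli, %d dims, %d subjects: stress = %.3f, R^2 = %.3f (%d iterations%s)\n",
              nrow(x$group_space), ncol(x$group_space),
              nrow(x$subject_weights), x$stress, x$r_squared,
              x$n_iterations, if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Two-way ANOVA of configuration values against the affect design
#'
#' Raw-data 2 x 2 between-subjects ANOVA (8 stimuli per cell) of each
#' configuration dimension on the valence and arousal labels, with partial
#' eta squared. A zero error mean square (configuration exactly equal to the
#' design codes) is flagged degenerate rather than reported as an infinite F.
#'
#' @param group_space stimuli x d configuration matrix.
#' @param labels tibble/data frame with `valence` and `arousal` columns coded
#'   +/-1, one row per stimulus.
#' @return A tibble: `dimension`, `effect`, `F`, `df1`, `df2`, `p`,
#'   `eta_p_sq`, `degenerate`.
#' @export
space_anova <- function(group_space, labels) {
  group_space <- as.matrix(group_space)
  if (nrow(group_space) != nrow(labels)) {
    stop_affect("labels must have one row per configuration row.")
  }
  assert_pm1(labels$valence, "valence")
  assert_pm1(labels$arousal, "arousal")
  purrr::map_dfr(seq_len(ncol(group_space)), function(d) {
    df <- tibble(y = group_space[, d],
                 valence = factor(labels$valence),
                 arousal = factor(labels$arousal))
    fit <- lm(y ~ valence * arousal, data = df)
    # perfect fits are flagged degenerate below; silence anova's own caveat
    a <- suppressWarnings(anova(fit))
    ss_res <- a["Residuals", "Sum Sq"]
    degen <- ss_res < 1e-12 * sum(a[["Sum Sq"]])
    purrr::map_dfr(c("valence", "arousal"), function(effn) {
      ss <- a[effn, "Sum Sq"]
      tibble(dimension = d, effect = effn,
             F = if (degen) NA_real_ else a[effn, "F value"],
             df1 = a[effn, "Df"], df2 = a["Residuals", "Df"],
             p = if (degen) NA_real_ else a[effn, "Pr(>F)"],
             eta_p_sq = if (ss + ss_res > 0) ss / (ss + ss_res) else NA_real_,
             degenerate = degen)
    })
  })
}
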