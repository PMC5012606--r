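# Stability selection, within-cluster MVPA, STATIS, point-biserial.

test_that("stability_select ranks voxels by cross-fold profile correlation", {
  set.seed(130)
  ord <- generate_design(130)$order
  train <- ord[ord$presentation <= 3, ]
  nv <- 10
  # voxel 1: identical exemplar profile in every presentation
  prof <- rnorm(32)
  x <- matrix(rnorm(nrow(train) * nv), nrow(train), nv)
  x[, 1] <- prof[train$exemplar_id]
  # voxel 2: constant everywhere
  x[, 2] <- 0.4
  tps <- trial_pattern_set(x, train, c(nv, 1, 1), 1:nv)

  keep <- stability_select(tps, keep_frac = 0.8)
  stab <- attr(keep, "stability")
  expect_equal(stab[1], 1, tolerance = 1e-12)
  expect_equal(stab[2], -1)
  expect_length(keep, 8) # ceiling(0.8 * 10)
  expect_true(1 %in% keep)
  expect_false(2 %in% keep)

  # ranking matches a brute-force all-pairs correlation oracle
  oracle <- vapply(seq_len(nv), function(v) {
    profs <- sapply(1:3, function(p) {
      rows <- train$presentation == p
      x[rows, v][order(train$exemplar_id[rows])]
    })
    if (any(apply(profs, 2, sd) == 0)) return(-1)
    mean(c(cor(profs[, 1], profs[, 2]), cor(profs[, 1], profs[, 3]),
           cor(profs[, 2], profs[, 3])))
  }, numeric(1))
  expect_equal(stab, oracle, tolerance = 1e-12)
  expect_equal(sort(keep), sort(order(-oracle)[1:8]))

  expect_error(stability_select(subset_trials_pres(tps, 1:2)), "three")
})

test_that("cluster_mvpa recovers signal and stays at chance off-signal", {
  set.seed(131)
  region_vox <- 1:15
  tl <- lapply(1:5, function(p) {
    make_tps(n_vox = 60, seed = 131 + p, amp = 0.8,
             signal_vox = region_vox, participant = p)
  })
  hit <- cluster_mvpa(tl, region_vox, "valence")
  expect_gt(hit$mean_accuracy, 0.8)
  expect_lt(hit$p, 0.01)

  miss <- cluster_mvpa(tl, 31:60, "valence")
  expect_lt(abs(miss$mean_accuracy - 0.5), 0.08)

  expect_error(cluster_mvpa(tl, integer(0), "valence"), "voxels")
  gl <- glance(hit)
  expect_equal(gl$mean_accuracy, hit$mean_accuracy)
})

test_that("fold-internal stability selection does not leak test information", {
  # on pure-noise data, selecting stable voxels using all four presentations
  # (test included) inflates accuracy; fold-internal selection does not
  leaky_acc <- function(tps, keep_frac) {
    keep <- stability_select(tps, keep_frac) # uses all 4 presentations
    sub <- tps
    sub$patterns <- tps$patterns[, keep, drop = FALSE]
    sub$voxel_idx <- tps$voxel_idx[keep]
    cv_within(sub, "valence")$mean_accuracy
  }
  proper <- numeric(8); leaky <- numeric(8)
  for (p in 1:8) {
    tps <- make_tps(n_vox = 300, seed = 140 + p, participant = p)
    proper[p] <- cluster_mvpa(list(tps), 1:300, "valence",
                              keep_frac = 0.1)$mean_accuracy
    leaky[p] <- leaky_acc(tps, 0.1)
  }
  expect_gt(mean(leaky), mean(proper))
  expect_lt(abs(mean(proper) - 0.5), 0.05)
})

test_that("statis: single-table and identical-table limits", {
  set.seed(132)
  x <- matrix(rnorm(32 * 5), 32, 5)
  sol1 <- statis(list(x), n_dims = 2)
  expect_equal(sol1$table_weights, 1)

  # equals PCA of the centred cross-product (up to sign, handled by the
  # deterministic sign rule applied to both)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(tcrossprod(xc), symmetric = TRUE)
  for (j in 1:2) {
    ref <- eg$vectors[, j] * sqrt(max(eg$values[j], 0))
    if (ref[which.max(abs(ref))] < 0) ref <- -ref
    expect_equal(sol1$factor_scores[, j], ref, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  sol3 <- statis(list(x, x, x), n_dims = 2)
  expect_equal(sol3$table_weights, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sol3$factor_scores, sol1$factor_scores, tolerance = 1e-8)
  expect_true(all(diag(sol3$rv_matrix) == 1))
  expect_equal(sol3$rv_matrix, matrix(1, 3, 3))

  expect_error(statis(list(x, x[1:10, ])), "same number of rows")
})

test_that("statis matches an independently coded eigendecomposition", {
  set.seed(133)
  tables <- lapply(c(5, 7, 4), function(p) matrix(rnorm(32 * p), 32, p))
  sol <- statis(tables, n_dims = 2)

  # oracle built from scratch with svd() and explicit loops
  Ss <- lapply(tables, function(x) {
    xc <- sweep(x, 2, colMeans(x))
    xc %*% t(xc)
  })
  k <- 3
  rv <- diag(k)
  for (i in 1:k) for (j in 1:k) {
    rv[i, j] <- sum(Ss[[i]] * Ss[[j]]) /
      sqrt(sum(Ss[[i]]^2) * sum(Ss[[j]]^2))
  }
  sv <- svd(rv)
  alpha <- abs(sv$u[, 1]); alpha <- alpha / sum(alpha)
  comp <- alpha[1] * Ss[[1]] + alpha[2] * Ss[[2]] + alpha[3] * Ss[[3]]
  sc <- svd(comp)
  expect_equal(sol$table_weights, alpha, tolerance = 1e-8)
  expect_equal(sol$eigenvalues[1:2], sc$d[1:2], tolerance = 1e-8)
  for (j in 1:2) {
    ref <- sc$u[, j] * sqrt(sc$d[j])
    if (ref[which.max(abs(ref))] < 0) ref <- -ref
    expect_equal(sol$factor_scores[, j], ref, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # invariance: adding zero-variance voxels changes nothing
  aug <- c(tables[1:2], list(cbind(tables[[3]], 3.3, -1)))
  sol_aug <- statis(aug, n_dims = 2)
  expect_equal(sol_aug$factor_scores, sol$factor_scores, tolerance = 1e-10)
})

test_that("point_biserial equals the textbook formula and is affine-invariant", {
  design <- rep(c(1, -1), each = 16)
  expect_equal(point_biserial(design, design)$r_pb, 1)

  # symmetric within groups -> exactly zero
  sym <- c(rep(c(-1, 1), 8), rep(c(-1, 1), 8))
  expect_equal(point_biserial(sym, design)$r_pb, 0)

  set.seed(134)
  scores <- rnorm(32)
  res <- point_biserial(scores, design)
  m1 <- mean(scores[design == 1]); m0 <- mean(scores[design == -1])
  sn <- sqrt(mean((scores - mean(scores))^2)) # population SD
  oracle <- (m1 - m0) / sn * sqrt(16 * 16 / 32^2)
  expect_equal(res$r_pb, oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(res$t), 30, lower.tail = FALSE))

  shifted <- point_biserial(2.5 * scores + 7, design)
  expect_equal(shifted$r_pb, res$r_pb, tolerance = 1e-12)

  expect_error(point_biserial(rep(1, 32), design), "constant")
  expect_error(point_biserial(scores, rep(1, 32)), "classes")
})

test_that("STATIS scores from a signal cluster correlate with its design axis", {
  set.seed(135)
  design <- affect_design()
  pat <- sample(c(-1, 1), 20, replace = TRUE)
  tl <- lapply(1:4, function(p) {
    make_tps(n_vox = 20, seed = 135 + p, amp = 0.9, signal_vox = 1:20,
             participant = p, shared_pattern = pat)
  })
  # exemplar-by-voxel tables: presentation means per exemplar
  tables <- lapply(tl, function(tps) {
    t(vapply(1:32, function(e) {
      colMeans(tps$patterns[tps$trial_info$exemplar_id == e, , drop = FALSE])
    }, numeric(ncol(tps$patterns))))
  })
  sol <- statis(tables, n_dims = 2)
  rv <- statis_design_correlation(sol, design$valence)
  expect_gt(abs(rv$r_pb), 0.5)
  # the arousal design should not be represented
  ra <- point_biserial(sol$factor_scores[, rv$dimension], design$arousal)
  expect_lt(abs(ra$r_pb), 0.3)
})
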