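# Penalized logistic decoding, CV schemes, permutation machinery.

test_that("fit_logistic: separable data, ridge limit, tie-breaking", {
  x <- rbind(c(2, 0), c(1.5, 0.5), c(-2, 0), c(-1.5, -0.5))
  y <- c(1, 1, -1, -1)
  fit <- fit_logistic(x, y, lambda = 0.01)
  expect_equal(unname(predict(fit, x)), y)

  # lambda -> infinity: weights vanish; an exactly-zero score falls to the
  # first class (deterministic tie-break)
  big <- fit_logistic(x, y, lambda = 1e10)
  expect_lt(max(abs(big$weights)), 1e-6)
  expect_equal(big$intercept, 0) # symmetric data: exact
  expect_equal(unname(predict(big, matrix(0, 1, 2))), -1)

  expect_error(fit_logistic(x, rep(1, 4)), "two classes")
})

test_that("fit_logistic matches a direct penalized-likelihood optimizer", {
  set.seed(71)
  n <- 40; p <- 5; lambda <- 1.3
  x <- matrix(rnorm(n * p), n, p)
  y01 <- rbinom(n, 1, plogis(x %*% rnorm(p)))
  fit <- fit_logistic(x, y01, lambda = lambda, maxit = 100, tol = 1e-12)

  negll <- function(par) {
    eta <- par[1] + x %*% par[-1]
    -sum(y01 * eta - log1p(exp(eta))) + lambda / 2 * sum(par[-1]^2)
  }
  opt <- optim(rep(0, p + 1), negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$intercept, opt$par[1], tolerance = 1e-5)
  expect_equal(fit$weights, opt$par[-1], tolerance = 1e-5)

  # overparameterized regime: the row-space reduction is exact
  set.seed(72)
  xw <- matrix(rnorm(20 * 50), 20, 50)
  yw <- rep(c(0, 1), 10)
  fw <- fit_logistic(xw, yw, lambda = 2, maxit = 200, tol = 1e-12)
  # optimum must satisfy the stationarity condition of the full problem
  eta <- fw$intercept + xw %*% fw$weights
  pr <- plogis(eta)
  grad_w <- t(xw) %*% (pr - yw) + 2 * fw$weights
  expect_lt(max(abs(grad_w)), 1e-6)
  expect_lt(abs(sum(pr - yw)), 1e-6)
})

test_that("fit_logistic agrees with an independent ridge-logistic solver", {
  skip_if_not_installed("glmnet")
  set.seed(73)
  n <- 60; p <- 8
  x <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  lambda <- 0.9
  fit <- fit_logistic(x, y, lambda = lambda, maxit = 200, tol = 1e-12)
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = lambda / n, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(fit$weights, as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("cv_within: fold bookkeeping and the null case", {
  tps <- make_tps(n_vox = 60, seed = 74)
  cv <- cv_within(tps, "valence")
  expect_equal(nrow(cv$folds), 4)
  expect_equal(cv$folds$n_test, rep(32L, 4))
  for (f in 1:4) {
    test_rows <- tps$trial_info$presentation == f
    expect_equal(sort(tps$trial_info$exemplar_id[test_rows]), 1:32)
  }
  # null data: accuracy within the 95% binomial band around .5
  band <- 1.96 * sqrt(0.25 / 128)
  expect_lt(abs(cv$mean_accuracy - 0.5), band + 1e-9)
  expect_equal(cv$mean_accuracy, mean(cv$folds$accuracy))
})

test_that("accuracy is invariant to trial order shuffling", {
  tps <- make_tps(n_vox = 50, seed = 75, amp = 0.4)
  set.seed(75)
  perm <- sample(128)
  tps2 <- tps
  tps2$patterns <- tps$patterns[perm, ]
  tps2$trial_info <- tps$trial_info[perm, ]
  for (target in c("valence", "arousal")) {
    expect_equal(cv_within(tps2, target)$mean_accuracy,
                 cv_within(tps, target)$mean_accuracy)
    expect_equal(cv_cross_exemplar(tps2, target)$mean_accuracy,
                 cv_cross_exemplar(tps, target)$mean_accuracy)
  }
})

test_that("decoding accuracy is monotone in the effect size", {
  accs <- vapply(c(0, 0.15, 0.4, 1), function(a) {
    cv_within(make_tps(n_vox = 80, seed = 76, amp = a), "valence")$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[4], 0.95)
})

test_that("cross-exemplar decoding generalizes labels, not exemplars", {
  # signal carried by the labels: generalizes to held-out exemplars
  tps_lab <- make_tps(n_vox = 80, seed = 77, amp = 1)
  cvl <- cv_cross_exemplar(tps_lab, "valence")
  expect_equal(nrow(cvl$folds), 32)
  expect_gt(cvl$mean_accuracy, 0.9)
  # every fold holds out all 4 presentations of exactly one exemplar
  expect_equal(cvl$folds$n_test, rep(4L, 32))

  # signal carried by exemplar-unique patterns: within-participant decoding
  # memorizes them, cross-exemplar honestly fails to generalize
  tps_ex <- make_tps(n_vox = 80, seed = 78, amp = 0, exemplar_amp = 1.5)
  expect_gt(cv_within(tps_ex, "valence")$mean_accuracy, 0.8)
  expect_lt(abs(cv_cross_exemplar(tps_ex, "valence")$mean_accuracy - 0.5),
            0.13)

  bad <- tps_ex
  bad$trial_info$exemplar_id[1] <- 33L
  expect_error(cv_cross_exemplar(bad, "valence"), "4 presentations")
})

test_that("cross-participant decoding needs a shared pattern", {
  pat <- NULL
  set.seed(79)
  pat <- sample(c(-1, 1), 20, replace = TRUE)
  shared <- lapply(1:4, function(p) {
    make_tps(n_vox = 60, seed = 80 + p, amp = 0.8, participant = p,
             shared_pattern = pat)
  })
  cv <- cv_cross_participant(shared, "valence")
  expect_equal(nrow(cv$folds), 4)
  expect_equal(cv$folds$n_test, rep(128L, 4))
  expect_gt(cv$mean_accuracy, 0.9)

  # idiosyncratic: each participant codes valence in a different voxel set,
  # so patterns are orthogonal across participants
  idio <- lapply(1:4, function(p) {
    make_tps(n_vox = 60, seed = 90 + p, amp = 0.8, participant = p,
             signal_vox = ((p - 1) * 15 + 1):(p * 15))
  })
  cvi <- cv_cross_participant(idio, "valence")
  expect_lt(abs(cvi$mean_accuracy - 0.5), 0.1)

  # voxel spaces must match
  odd <- c(shared[1:3], list(make_tps(n_vox = 61, seed = 99, participant = 4)))
  expect_error(cv_cross_participant(odd, "valence"), "common voxel space")
})

test_that("no fold shares its unit between train and test in any scheme", {
  tps <- make_tps(n_vox = 30, seed = 85)
  # structural: within -> presentations, cross-exemplar -> exemplars
  for (f in 1:4) {
    expect_false(any(tps$trial_info$presentation[tps$trial_info$presentation != f] == f))
  }
  ids <- sort(unique(tps$trial_info$exemplar_id))
  for (e in ids[c(1, 16, 32)]) {
    train <- tps$trial_info$exemplar_id != e
    expect_false(any(tps$trial_info$exemplar_id[train] == e))
  }
  # and the union of test folds is the full trial set
  expect_equal(sort(unlist(lapply(1:4, function(f)
    which(tps$trial_info$presentation == f)))), 1:128)
})

test_that("permutation machinery: boundary p, determinism, add-one rule", {
  # observed below every null statistic -> p = 1
  res <- permutation_test(function(permute) if (permute) 1 else 0,
                          n_perm = 50, seed = 1)
  expect_equal(res$p, 1)

  # observed above every null -> smallest attainable p
  res2 <- permutation_test(function(permute) if (permute) 0 else 1,
                           n_perm = 50, seed = 1)
  expect_equal(res2$p, 1 / 51)

  expect_error(permutation_test(function(permute) 0, n_perm = 0), "at least 1")

  # same seed -> identical null vector, on a real decoder
  tps <- make_tps(n_vox = 40, seed = 86, amp = 0.3)
  a <- cv_within(tps, "valence", n_perm = 30, seed = 7)
  b <- cv_within(tps, "valence", n_perm = 30, seed = 7)
  expect_identical(a$null$stats, b$null$stats)
  expect_equal(a$p_perm, perm_pvalue(a$mean_accuracy, a$null$stats))
  # strong signal: p at the add-one floor
  strong <- cv_within(make_tps(n_vox = 40, seed = 87, amp = 1.5), "valence",
                      n_perm = 99, seed = 2)
  expect_equal(strong$p_perm, 1 / 100)
})

test_that("tidiers summarize cv results", {
  tps <- make_tps(n_vox = 40, seed = 88, amp = 0.5)
  cv <- cv_within(tps, "arousal", n_perm = 19, seed = 3)
  td <- tidy(cv)
  expect_equal(nrow(td), 4)
  expect_true(all(c("accuracy", "n_test", "scheme") %in% names(td)))
  gl <- glance(cv)
  expect_equal(gl$mean_accuracy, cv$mean_accuracy)
  expect_equal(gl$p_perm, cv$p_perm)
})
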