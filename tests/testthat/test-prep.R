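# Nuisance regression, PSC extraction, standardization, localizer, masks.

# Minimal hand-built dataset: one run, given data matrix.
manual_dataset <- function(data, onsets, tr = 2.2, motion = NULL,
                           feature_scores = NULL, exemplar_id = NULL) {
  n <- length(onsets)
  exemplar_id <- exemplar_id %||% seq_len(n)
  events <- tibble::tibble(
    trial = seq_len(n), onset = onsets, duration = 5,
    exemplar_id = exemplar_id, quadrant = "HN",
    valence = rep(c(-1, 1), length.out = n),
    arousal = rep(c(1, -1), length.out = n), presentation = 1L)
  structure(list(participant_id = 1L,
                 runs = list(list(data = data, events = events,
                                  motion = motion)),
                 dim = c(ncol(data), 1L, 1L), tr = tr, baseline = 100,
                 ground_truth = list(feature_scores = feature_scores)),
            class = "bold_dataset")
}

test_that("nuisance regression projects out exactly what it should", {
  set.seed(61)
  n_vol <- 60; tr <- 2.2
  onsets <- seq(0, by = 12, length.out = 10)
  scores <- matrix(rnorm(32 * 5), 32, 5)
  ex <- sample(1:32, 10)
  reg1 <- convolve_regressor(onsets, 5, scores[ex, 1], n_vol, tr)

  # (a) series equal to one nuisance regressor -> residual variance ~ 0
  data <- cbind(100 + 3 * reg1, 100 + rnorm(n_vol))
  ds <- manual_dataset(data, onsets, tr, feature_scores = scores,
                       exemplar_id = ex)
  out <- regress_nuisance(ds, include_motion = FALSE)
  expect_lt(sd(out$runs[[1]]$data[, 1]), 1e-8)
  # intercept restored: baseline level preserved
  expect_equal(mean(out$runs[[1]]$data[, 1]), 100, tolerance = 1e-6)

  # (b) signal orthogonal to all regressors is returned unchanged
  X <- cbind(1, vapply(1:5, function(j) {
    convolve_regressor(onsets, 5, scores[ex, j], n_vol, tr)
  }, numeric(n_vol)))
  raw <- rnorm(n_vol)
  ortho <- raw - X %*% qr.coef(qr(X), raw)
  ds2 <- manual_dataset(cbind(100 + ortho, 100 + rnorm(n_vol)), onsets, tr,
                        feature_scores = scores, exemplar_id = ex)
  out2 <- regress_nuisance(ds2, include_motion = FALSE)
  expect_equal(out2$runs[[1]]$data[, 1], 100 + as.numeric(ortho),
               tolerance = 1e-9, ignore_attr = TRUE)

  # (c) residuals orthogonal to every design column (OLS normal equations)
  set.seed(62)
  motion <- matrix(rnorm(n_vol * 6), n_vol, 6)
  data3 <- matrix(100 + rnorm(n_vol * 4), n_vol, 4)
  ds3 <- manual_dataset(data3, onsets, tr, motion = motion,
                        feature_scores = scores, exemplar_id = ex)
  out3 <- regress_nuisance(ds3)
  resid <- sweep(out3$runs[[1]]$data, 2, colMeans(out3$runs[[1]]$data))
  for (j in 2:6) expect_lt(max(abs(t(X[, j]) %*% resid)), 1e-8)
  for (j in 1:6) expect_lt(max(abs(t(motion[, j] - mean(motion[, j])) %*% resid)), 1e-8)

  # (d) rank-deficient design names the collinear columns
  motion_bad <- motion; motion_bad[, 2] <- motion_bad[, 1]
  ds4 <- manual_dataset(data3, onsets, tr, motion = motion_bad,
                        feature_scores = scores, exemplar_id = ex)
  expect_error(regress_nuisance(ds4), "motion_2")
})

test_that("extract_psc implements the two-volume offset rule", {
  tr <- 2.2
  # constant series -> PSC 0
  dsc <- manual_dataset(matrix(77, 12, 2), onsets = c(0, 11))
  expect_true(all(extract_psc(dsc)$patterns == 0))

  # run mean exactly 100; volumes 3 and 4 (onset 0: 0/2.2 -> vol 1, +2TR, +3TR)
  series <- rep(98 + 2 / 3, 12)
  series[3] <- 103; series[4] <- 105
  series[5] <- 3 * (98 + 2 / 3) - 103 - 105 + 98 + 2 / 3 # rebalance mean
  series <- series * (100 / mean(series))
  data <- cbind(series, rep(50, 12))
  ds <- manual_dataset(data, onsets = c(0, 11))
  tps <- extract_psc(ds)
  expect_equal(unname(tps$patterns[1, 1]),
               mean(c(series[3], series[4])) - 100, tolerance = 1e-9)

  # shifting onsets by one TR moves the sampled pair by one volume
  set.seed(63)
  data2 <- matrix(100 + rnorm(40), 20, 2)
  a <- extract_psc(manual_dataset(data2, onsets = c(0, 22)))
  b <- extract_psc(manual_dataset(data2, onsets = c(0, 22) + tr))
  psc <- sweep(sweep(data2, 2, colMeans(data2)), 2, colMeans(data2), `/`) * 100
  expect_equal(a$patterns[1, ], colMeans(psc[3:4, ]), ignore_attr = TRUE)
  expect_equal(b$patterns[1, ], colMeans(psc[4:5, ]), ignore_attr = TRUE)

  # trial sampling outside the run errors
  expect_error(extract_psc(manual_dataset(data2, onsets = c(0, 42))),
               "outside")
  # zero run mean errors
  data3 <- data2; data3[, 2] <- rep(c(-1, 1), 10)
  expect_error(extract_psc(manual_dataset(data3, onsets = c(0, 22))),
               "zero run mean")
})

test_that("standardize z-scores rows and is affine-invariant", {
  set.seed(64)
  tps <- make_tps(n_vox = 30, seed = 64)
  expect_equal(unname(rowMeans(tps$patterns)), rep(0, 128), tolerance = 1e-12)
  expect_equal(unname(apply(tps$patterns, 1, sd)), rep(1, 128),
               tolerance = 1e-12)

  x <- matrix(rnorm(5 * 20), 5, 20)
  base <- trial_pattern_set(
    x, tibble::tibble(trial = 1:5, presentation = 1L, exemplar_id = 1:5,
                      valence = c(-1, 1, -1, 1, -1),
                      arousal = c(1, 1, -1, -1, 1)),
    c(20, 1, 1), 1:20)
  z1 <- standardize(base)
  base$patterns <- 3.7 * x + 2
  z2 <- standardize(base)
  expect_equal(z1$patterns, z2$patterns, tolerance = 1e-12)
  # element-wise formula oracle
  expect_equal(z1$patterns[2, ], (x[2, ] - mean(x[2, ])) / sd(x[2, ]),
               tolerance = 1e-12)

  base$patterns[1, ] <- 5
  expect_error(standardize(base), "trial\\(s\\) 1")
})

test_that("localizer GLM: t oracle, detection, and family-wise control", {
  tr <- 2; n_vol <- 72
  blocks <- tibble::tibble(
    onset = seq(0, by = 24, length.out = 6),
    duration = 12,
    condition = rep(c("audiovisual", "checkerboard"), 3))
  reg <- cbind(
    1,
    convolve_regressor(blocks$onset[blocks$condition == "audiovisual"], 12,
                       rep(1, 3), n_vol, tr),
    convolve_regressor(blocks$onset[blocks$condition == "checkerboard"], 12,
                       rep(1, 3), n_vol, tr))

  # 3-voxel toy: t equals contrast / SE from the normal equations
  set.seed(65)
  data <- matrix(rnorm(n_vol * 3), n_vol, 3)
  res <- localizer_glm(data, blocks, c(audiovisual = 1), dim = c(3, 1, 1),
                       tr = tr)
  for (v in 1:3) {
    beta <- solve(crossprod(reg), crossprod(reg, data[, v]))
    r <- data[, v] - reg %*% beta
    s2 <- sum(r^2) / (n_vol - 3)
    cvec <- c(0, 1, 0)
    se <- sqrt(s2 * t(cvec) %*% solve(crossprod(reg)) %*% cvec)
    expect_equal(res$tmap$values[v, 1, 1], as.numeric((t(cvec) %*% beta) / se),
                 tolerance = 1e-9)
  }

  # injected block response at SNR 2 is detected
  set.seed(66)
  vol <- matrix(rnorm(n_vol * 64), n_vol, 64)
  vol[, 10] <- vol[, 10] + 2 * reg[, 2]
  hit <- localizer_glm(vol, blocks, c(audiovisual = 1), dim = c(4, 4, 4),
                       tr = tr, min_cluster = 0)
  expect_true(hit$mask[arrayInd(10, c(4, 4, 4))])

  # pure noise: family-wise false positives controlled
  set.seed(67)
  fp <- vapply(1:200, function(i) {
    noise <- matrix(rnorm(n_vol * 64), n_vol, 64)
    r <- localizer_glm(noise, blocks, c(audiovisual = 1), dim = c(4, 4, 4),
                       tr = tr, min_cluster = 0)
    any(r$mask)
  }, logical(1))
  expect_lte(mean(fp), 0.10)
})

test_that("combine_masks implements GM & VA & !(VP | AP)", {
  d <- c(5, 5, 3)
  rand_mask <- function(seed, p = 0.4) {
    set.seed(seed)
    array(runif(prod(d)) < p, d)
  }
  VA <- rand_mask(1); VP <- rand_mask(2); AP <- rand_mask(3); GM <- rand_mask(4, 0.8)
  lm <- combine_masks(VA, VP, AP, GM)
  # brute-force set evaluation
  oracle <- array(FALSE, d)
  for (v in seq_len(prod(d))) {
    oracle[v] <- GM[v] && VA[v] && !(VP[v] || AP[v])
  }
  expect_identical(lm$combined, oracle)
  expect_true(all(lm$combined[lm$combined] %in% VA[lm$combined]))

  empty <- array(FALSE, d)
  expect_identical(combine_masks(VA, empty, empty, GM)$combined, VA & GM)
  expect_false(any(combine_masks(VP, VP, empty, GM)$combined))
  expect_error(combine_masks(VA, VP, AP, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("label bookkeeping survives run concatenation", {
  d <- generate_design(seed = 4)
  b <- generate_bold(d, grid_dim = c(5, 5, 4), n_participants = 1, seed = 5,
                     noise_sd = 1)[[1]]
  tps <- extract_psc(b)
  for (r in 1:4) {
    ev <- b$runs[[r]]$events
    rows <- tps$trial_info$run == r
    expect_equal(tps$trial_info$exemplar_id[rows], ev$exemplar_id)
    expect_equal(tps$trial_info$valence[rows], ev$valence)
  }
})
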