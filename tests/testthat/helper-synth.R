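# Shared fixtures, all generated in code.

# A tiny clip with given frames (T x H x W x 3 array).
clip_from_frames <- function(frames, fps = 10, audio = NULL,
                             sample_rate = 1000) {
  if (is.null(audio)) {
    tt <- seq_len(sample_rate) / sample_rate
    audio <- rbind(sin(2 * pi * 100 * tt), sin(2 * pi * 100 * tt)) * 0.3
  }
  structure(list(frames = frames, fps = fps, audio = audio,
                 sample_rate = sample_rate, exemplar_id = 1),
            class = "synthetic_clip")
}

const_frames <- function(nt, h, w, rgb) {
  fr <- array(0, c(nt, h, w, 3))
  for (ch in 1:3) fr[, , , ch] <- rgb[ch]
  fr
}

# A standardized trial pattern set with optional planted label signal:
# patterns = noise + amp * label * pattern over `signal_vox` voxels, plus
# optionally exemplar-specific patterns (exemplar_amp) over `exemplar_vox`.
make_tps <- function(n_vox = 120, seed = 1, amp = 0, target = "valence",
                     signal_vox = seq_len(min(20, n_vox)),
                     exemplar_amp = 0, exemplar_vox = NULL,
                     participant = 1L, shared_pattern = NULL,
                     dim3 = NULL) {
  set.seed(seed)
  ord <- generate_design(seed)$order
  x <- matrix(rnorm(128 * n_vox), 128, n_vox)
  if (amp > 0) {
    # sign-balanced pattern so row standardization does not smear label
    # signal into off-pattern voxels
    pat <- shared_pattern %||% sample(rep(c(-1, 1),
                                          length.out = length(signal_vox)))
    lab <- ord[[target]]
    x[, signal_vox] <- x[, signal_vox] + amp * outer(lab, pat)
  }
  if (exemplar_amp > 0) {
    exemplar_vox <- exemplar_vox %||% seq_len(n_vox)
    epat <- matrix(rnorm(32 * length(exemplar_vox)), 32)
    x[, exemplar_vox] <- x[, exemplar_vox] +
      exemplar_amp * epat[ord$exemplar_id, ]
  }
  dim3 <- dim3 %||% c(n_vox, 1L, 1L)
  ord$participant_id <- participant
  standardize(trial_pattern_set(x, ord, dim3, seq_len(n_vox)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Restrict a pattern set to a subset of presentations.
subset_trials_pres <- function(tps, pres) {
  rows <- tps$trial_info$presentation %in% pres
  trial_pattern_set(tps$patterns[rows, , drop = FALSE],
                    tps$trial_info[rows, ], tps$dim, tps$voxel_idx)
}

# Independent reference: pure-R flood fill for connected components (6-conn).
flood_fill_labels <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (v in which(mask)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(v, d)[1, ])
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in 1:6) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# Align recovered dimensions to a reference space by best |correlation|
# permutation and sign; returns the per-reference-dimension correlations.
align_dims <- function(recovered, truth) {
  d <- ncol(truth)
  cors <- abs(cor(recovered, truth))
  perms <- if (d == 2) list(1:2, 2:1) else
    lapply(seq_len(factorial(d)), function(i) order(runif(d)))
  best <- NULL; best_sum <- -Inf
  for (p in perms) {
    s <- sum(diag(cors[p, , drop = FALSE]))
    if (s > best_sum) { best_sum <- s; best <- p }
  }
  vapply(seq_len(d), function(j) abs(cor(recovered[, best[j]], truth[, j])),
         numeric(1))
}
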