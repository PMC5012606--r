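#' The 2x2 affect stimulus design
#'
#' Thirty-two exemplars cross valence (positive/negative) with arousal
#' (high/low): eight exemplars per quadrant (HN, LN, HP, LP), each quadrant
#' holding four human, two animal and two inanimate clips so semantic content
#' is balanced across affect categories. Valence and arousal codes are
#' orthogonal over the set.
#'
#' @return A 32-row tibble: `exemplar_id`, `quadrant`, `valence`, `arousal`,
#'   `semantic`.
#' @export
#' @examples
#' affect_design()
affect_design <- function() {
  quad <- c("HN", "LN", "HP", "LP")
  tibble(
    exemplar_id = 1:32,
    quadrant = rep(quad, each = 8),
    valence = rep(c(-1, -1, 1, 1), each = 8),
    arousal = rep(c(1, -1, 1, -1), each = 8),
    semantic = rep(c(rep("human", 4), rep("animal", 2), rep("inanimate", 2)),
                   times = 4)
  )
}

#' Generate a counterbalanced 128-trial presentation order
#'
#' Each of four presentation blocks shows all 32 exemplars once. The order is
#' constrained so that every successive window of four trials contains all
#' four affect quadrants exactly once and no two consecutive trials share a
#' quadrant (including across window and block boundaries).
#'
#' @param seed integer seed; the order is a pure function of it.
#' @param max_tries bounded number of rejection-sampling attempts per window
#'   before the generator aborts.
#' @return A list of class `stimulus_design` with elements `design` (the
#'   [affect_design()] table) and `order` (128-row tibble: `trial`,
#'   `presentation`, `window`, `exemplar_id`, `quadrant`, `valence`,
#'   `arousal`).
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' head(d$order)
generate_design <- function(seed, max_tries = 1000L) {
  design <- affect_design()
  quads <- c("HN", "LN", "HP", "LP")
  withr_seed(seed)

  order_quadrants <- function() {
    out <- character(0)
    last <- NA_character_
    for (w in 1:32) { # 32 windows of 4 across the session
      tries <- 0L
      repeat {
        cand <- sample(quads)
        if (is.na(last) || cand[1] != last) break
        tries <- tries + 1L
        if (tries >= max_tries) {
          stop_affect("Counterbalancing unsatisfiable within `max_tries`; RNG state mishandled.")
        }
      }
      out <- c(out, cand)
      last <- cand[4]
    }
    out
  }

  quad_seq <- order_quadrants()
  # within each presentation block, assign each quadrant's 8 exemplars to its
  # 8 windows in random order
  exemplar <- integer(128)
  for (block in 1:4) {
    idx <- (block - 1) * 32 + 1:32
    block_quads <- quad_seq[idx]
    for (q in quads) {
      ex <- design$exemplar_id[design$quadrant == q]
      exemplar[idx[block_quads == q]] <- sample(ex)
    }
  }

  order <- tibble(
    trial = 1:128,
    presentation = rep(1:4, each = 32),
    window = rep(1:32, each = 4),
    exemplar_id = exemplar
  ) %>%
    left_join(design[, c("exemplar_id", "quadrant", "valence", "arousal")],
              by = "exemplar_id")
  check_design_order(order)
  structure(list(design = design, order = order), class = "stimulus_design")
}

#' Validate the counterbalancing constraints of a presentation order
#'
#' Errors if a constraint is violated: 128 trials, four presentations of each
#' exemplar, all four quadrants in each successive window of four, no two
#' consecutive trials sharing a quadrant.
#'
#' @param order the `order` tibble from [generate_design()].
#' @return `TRUE`, invisibly.
#' @export
check_design_order <- function(order) {
  if (nrow(order) != 128) stop_affect("Order must have 128 trials.")
  counts <- table(order$exemplar_id)
  if (length(counts) != 32 || any(counts != 4)) {
    stop_affect("Each of the 32 exemplars must appear exactly 4 times.")
  }
  q <- order$quadrant
  for (w in seq(1, 125, by = 4)) {
    if (length(unique(q[w:(w + 3)])) != 4) {
      stop_affect(sprintf("Window starting at trial %d lacks all four quadrants.", w))
    }
  }
  if (any(q[-1] == q[-128])) {
    stop_affect("Two consecutive trials share an affect quadrant.")
  }
  invisible(TRUE)
}

# Generators are pure functions of (parameters, seed): every public generator
# seeds the RNG itself, so identical calls give bit-identical output.
withr_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop_affect("`seed` must be a single finite number.")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Derived sub-seed for nested generators, kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k) %% 2147483629)
}
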