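# Internal helpers shared across modules.

# Consistent error with a data-bearing class for testability.
stop_affect <- function(msg, class = "affectmvpa_error") {
  abort(msg, class = class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quadrant code from +/-1 valence and arousal labels (HN, LN, HP, LP).
quadrant_code <- function(valence, arousal) {
  paste0(ifelse(arousal > 0, "H", "L"), ifelse(valence > 0, "P", "N"))
}

assert_pm1 <- function(x, name) {
  if (!all(x %in% c(-1, 1))) {
    stop_affect(sprintf("`%s` must be coded +1/-1.", name))
  }
  invisible(x)
}

# Permutation p-value with the add-one rule: p = (1 + #{null >= obs}) / (B + 1).
perm_pvalue <- function(observed, null_stats) {
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}

# Dice coefficient between two logical arrays/vectors of equal length.
#' Dice overlap between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; returns `NA` when both masks are empty.
#'
#' @param a,b logical arrays or vectors of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop_affect("Masks must have identical shape.")
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

# round() guard for sampling offsets that must land on the volume grid.
assert_near_integer <- function(x, name, tol = 1e-8) {
  if (any(abs(x - round(x)) > tol)) {
    stop_affect(sprintf("`%s` must align with the volume grid (got %s).",
                        name, paste(signif(x, 6), collapse = ", ")))
  }
  as.integer(round(x))
}
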