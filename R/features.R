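# Physiological feature maps computed from the pulsatile stacks.
#
# I_AC = I_max - I_min is the pulsatile amplitude of the reflected light;
# I_R = ln(I_max / I_min) is the absorption amplitude, which cancels the
# static absorbers (incident intensity and DC reflectance divide out under
# the log-ratio).
#
# The n-th peak pairs with the n-th trough along the depth axis.  A pixel
# can legitimately store different peak and trough counts (the pulse phase
# at the start of a 4 s clip decides whether 4 or 5 extrema of each kind
# fall inside it), so a feature position is valid only where *both* stacks
# are valid; the rest is 0, the exported padding convention.

#' Pulsatile amplitude feature I_AC
#'
#' Element-wise `I_max - I_min`; padded positions are exactly 0.  Values
#' may be negative on noisy data (the stacks sample raw frames at
#' filtered-signal extrema) and are passed through unmodified.
#'
#' @param stack a `pulsatile_stack`.
#' @return An object of class `feature_block` with `values`
#'   (`H x W x n`), `feature_kind = "AC"`, `channel` and `validity`.
#' @export
feature_ac <- function(stack) {
  valid <- check_aligned(stack)
  v <- (stack$i_max - stack$i_min) * valid
  structure(list(values = v, feature_kind = "AC", channel = stack$channel,
                 validity = valid),
            class = "feature_block")
}

#' Log-ratio absorption feature I_R
#'
#' Element-wise `ln(I_max / max(I_min, epsilon))`; padded positions are 0.
#' The epsilon guard (default 1 gray level on the 8-bit scale) absorbs
#' zero-valued troughs at masked-out or dark pixels; the number of guard
#' activations at valid positions is recorded in the `guard_count`
#' attribute.
#'
#' @param stack a `pulsatile_stack`.
#' @param epsilon positive lower bound applied to `I_min` (and `I_max`)
#'   before the log ratio.
#' @return A `feature_block` with `feature_kind = "R"`.
#' @export
feature_ratio <- function(stack, epsilon = 1) {
  valid <- check_aligned(stack)
  if (epsilon <= 0) stop("`epsilon` must be positive")
  guards <- sum(stack$i_min < epsilon & valid == 1)
  v <- log(pmax(stack$i_max, epsilon) / pmax(stack$i_min, epsilon)) * valid
  structure(list(values = v, feature_kind = "R", channel = stack$channel,
                 validity = valid, guard_count = guards),
            class = "feature_block")
}

# Combined validity of the element-wise peak/trough pairing.
check_aligned <- function(stack) {
  if (!identical(dim(stack$i_max), dim(stack$i_min))) {
    stop("I_max and I_min stacks have mismatched dimensions")
  }
  stack$peak_valid * stack$trough_valid
}

#' @export
print.feature_block <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_block> I_%s(%s), %d x %d x %d, %d valid positions\n",
              x$feature_kind, x$channel, d[1], d[2], d[3], sum(x$validity)))
  invisible(x)
}

#' Assemble classifier input from feature blocks
#'
#' A single block passes through as its `H x W x n` array; several blocks
#' (multi-wavelength or multi-feature experiments) are concatenated along
#' the depth axis, and the classifier's input layer is adapted to the
#' resulting depth.
#'
#' @param features list of `feature_block` objects sharing spatial
#'   dimensions.
#' @return Numeric `H x W x (n * length(features))` array.
#' @export
assemble_input <- function(features) {
  if (length(features) == 0L) stop("`features` must contain at least one block")
  dims <- lapply(features, function(f) dim(f$values))
  if (!all(vapply(dims, function(d) all(d[1:2] == dims[[1]][1:2]), logical(1)))) {
    stop("feature blocks have mismatched spatial dimensions")
  }
  depth <- sum(vapply(dims, `[`, numeric(1), 3L))
  out <- array(0, c(dims[[1]][1], dims[[1]][2], depth))
  at <- 0L
  for (f in features) {
    n <- dim(f$values)[3]
    out[, , at + seq_len(n)] <- f$values
    at <- at + n
  }
  out
}
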