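# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Lower median: for an even count the smaller of the two central order
# statistics is returned, so the result is always an observed value.
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) stop("lower_median() of an empty vector")
  x[ceiling(n / 2)]
}

# clamp into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pulsemap <- function(msg, class) {
  stop(structure(class = c(class, "pulsemap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# mean over the channel axis of an H x W x C array (pass-through for H x W)
channel_mean <- function(frame) {
  d <- dim(frame)
  if (length(d) < 3L) return(frame)
  out <- frame[, , 1L]
  for (ch in seq_len(d[3])[-1L]) out <- out + frame[, , ch]
  out / d[3]
}
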