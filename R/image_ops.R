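# Low-level image primitives: Otsu thresholding, block pooling, bicubic
# resampling, box blur, morphological opening, zero-aware median filtering.

#' Otsu threshold of a gray-level image
#'
#' Histogram-based binarization threshold maximizing the between-class
#' variance over 256 equal-width bins spanning the value range.  Ties are
#' broken toward the lowest threshold.
#'
#' @param x numeric matrix or vector of gray levels.
#' @param levels number of histogram bins.
#' @return The threshold value; pixels `> threshold` form the upper class.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) {
    stop_pulsemap("Otsu threshold undefined for a constant image",
                  "pulsemap_degenerate_image")
  }
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), levels),
                nbins = levels)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_tot <- mu[levels]
  # between-class variance for the split "bins 1..k vs k+1..levels"
  k <- seq_len(levels - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mu_tot * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  edges[which.max(bcv) + 1L]
}

# Apply a separable linear resampling `R %*% frame %*% t(C)` to every
# frame of a T x H x W stack in two large matrix products.
apply_separable <- function(frames, R, C) {
  is_mat <- length(dim(frames)) == 2L
  if (is_mat) dim(frames) <- c(1L, dim(frames))
  d <- dim(frames)
  M <- frames
  dim(M) <- c(d[1] * d[2], d[3])
  A <- M %*% t(C)                      # (T*H) x w_out
  wo <- ncol(A)
  dim(A) <- c(d[1], d[2], wo)
  A <- aperm(A, c(2L, 1L, 3L))         # H x T x w_out
  dim(A) <- c(d[2], d[1] * wo)
  B <- R %*% A                         # h_out x (T * w_out)
  ho <- nrow(B)
  dim(B) <- c(ho, d[1], wo)
  out <- aperm(B, c(2L, 1L, 3L))
  if (is_mat) matrix(out[1L, , ], ho, wo) else out
}

#' Block-average spatial downsampling
#'
#' Each output pixel is the mean of a `block x block` tile of the input;
#' partial tiles at the right/bottom edges are averaged over the pixels
#' they contain, so the output is `ceiling(H/block) x ceiling(W/block)`.
#'
#' @param frames a `T x H x W` array or an `H x W` matrix.
#' @param block tile side in pixels.
#' @return Array/matrix of the pooled means, same leading time axis.
#' @export
block_downsample <- function(frames, block) {
  block <- as.integer(block)
  if (block < 1L) stop("`block` must be >= 1")
  if (block == 1L) return(frames)
  d <- dim(frames)
  nr <- if (length(d) == 2L) d[1] else d[2]
  nc <- if (length(d) == 2L) d[2] else d[3]
  Ph <- pool_matrix(rep(seq_len(ceiling(nr / block)), each = block,
                        length.out = nr))
  Pw <- pool_matrix(rep(seq_len(ceiling(nc / block)), each = block,
                        length.out = nc))
  apply_separable(frames, Ph, Pw)
}

# group-mean pooling matrix from a group index vector
pool_matrix <- function(g) {
  n <- max(g)
  P <- matrix(0, n, length(g))
  P[cbind(g, seq_along(g))] <- 1
  P / rowSums(P)
}

# Separable bicubic (Catmull-Rom, a = -0.5) resampling weights mapping
# `n_in` samples to `n_out`, with centre alignment and edge replication.
bicubic_weights <- function(n_in, n_out) {
  kern <- function(x) {
    x <- abs(x); a <- -0.5
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale + 0.5  # centre-aligned source coordinate
    j0 <- floor(src) - 1L
    js <- j0:(j0 + 3L)
    w <- kern(src - js)
    js <- clamp(js, 1L, n_in)      # edge replication
    for (k in 1:4) W[i, js[k]] <- W[i, js[k]] + w[k]
  }
  W / rowSums(W)
}

#' Bicubic resize of a frame or frame stack
#'
#' Separable Catmull-Rom bicubic interpolation with centre-aligned sampling
#' and edge replication at the borders.  Constant inputs are preserved
#' exactly (weights sum to one).
#'
#' @param frames a `T x H x W` array or `H x W` matrix.
#' @param out_h,out_w output size in pixels.
#' @return Resized array/matrix.
#' @export
bicubic_resize <- function(frames, out_h, out_w) {
  d <- dim(frames)
  nr <- if (length(d) == 2L) d[1] else d[2]
  nc <- if (length(d) == 2L) d[2] else d[3]
  apply_separable(frames, bicubic_weights(nr, out_h),
                  bicubic_weights(nc, out_w))
}

#' Box blur with an averaging kernel
#'
#' Mean filter over a `k x k` window with edge replication.
#'
#' @param img numeric matrix.
#' @param k odd window side in pixels.
#' @return Blurred matrix of the same size.
#' @export
box_blur <- function(img, k = 5L) {
  k <- as.integer(k)
  if (k %% 2L != 1L) stop("`k` must be odd")
  r <- (k - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ri <- clamp(seq_len(H + 2L * r) - r, 1L, H)
  ci <- clamp(seq_len(W + 2L * r) - r, 1L, W)
  pad <- img[ri, ci]
  cs <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- rbind(0, cbind(0, cs))                     # (W+2r+1) x (H+2r+1)
  i0 <- seq_len(H); i1 <- i0 + k
  j0 <- seq_len(W); j1 <- j0 + k
  sums <- cs[j1, i1] - cs[j0, i1] - cs[j1, i0] + cs[j0, i0]
  t(sums) / (k * k)
}

#' Morphological opening of a binary mask with a square block
#'
#' Set-theoretic opening: a pixel survives iff it is covered by at least
#' one fully contained `size x size` block, so features narrower than the
#' block are removed and pixels are never added.  This anchor-free
#' formulation is well defined for even block sizes such as the default
#' 10 x 10.
#'
#' @param mask binary matrix (0/1).
#' @param size block side in pixels.
#' @return Opened binary matrix.
#' @export
morph_open <- function(mask, size = 10L) {
  size <- as.integer(size)
  if (size < 1L) stop("`size` must be >= 1")
  if (size == 1L) return((mask != 0) * 1L)
  m <- (mask != 0) * 1L
  H <- nrow(m); W <- ncol(m)
  if (size > H || size > W) return(matrix(0L, H, W))
  cs <- rbind(0, cbind(0, apply(apply(m, 2L, cumsum), 1L, cumsum)))
  # cs is transposed: cs[j+1, i+1] = sum of m[1..i, 1..j]
  nph <- H - size + 1L; npw <- W - size + 1L
  i0 <- seq_len(nph); j0 <- seq_len(npw)
  sums <- t(cs[j0 + size, i0 + size] - cs[j0, i0 + size] -
              cs[j0 + size, i0] + cs[j0, i0])
  placed <- (sums == size * size) * 1L        # fully contained placements
  # dilate placements back to pixel coverage: pixel (i,j) is covered by
  # placement (p,q) iff p in [i-size+1, i] and q likewise
  cp <- rbind(0, cbind(0, apply(apply(placed, 2L, cumsum), 1L, cumsum)))
  out <- matrix(0L, H, W)
  i <- seq_len(H); j <- seq_len(W)
  p1 <- clamp(i, 1L, nph); p0 <- clamp(i - size, 0L, nph)
  q1 <- clamp(j, 1L, npw); q0 <- clamp(j - size, 0L, npw)
  cov <- t(cp[q1 + 1L, p1 + 1L] - cp[q0 + 1L, p1 + 1L] -
             cp[q1 + 1L, p0 + 1L] + cp[q0 + 1L, p0 + 1L])
  (cov > 0) * 1L
}

#' Spatial median filter that can ignore zero-valued neighbours
#'
#' Used to smooth per-pixel frequency maps in which zero marks "not skin":
#' each pixel is replaced by the median of the non-zero values in its
#' `k x k` neighbourhood (clipped at the borders).  If the neighbourhood
#' contains no non-zero value the output is 0.  With
#' `exclude_zeros = FALSE` all neighbours enter the median.  Even-sized
#' medians use the lower-median convention so the output is always an
#' observed value.
#'
#' @param img numeric matrix.
#' @param k odd window side.
#' @param exclude_zeros logical; drop zero neighbours before taking the
#'   median.
#' @return Filtered matrix.
#' @export
median_filter <- function(img, k = 3L, exclude_zeros = TRUE) {
  k <- as.integer(k)
  if (k %% 2L != 1L) stop("`k` must be odd")
  r <- (k - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    ri <- max(1L, i - r):min(H, i + r)
    for (j in seq_len(W)) {
      v <- img[ri, max(1L, j - r):min(W, j + r)]
      if (exclude_zeros) v <- v[v != 0]
      out[i, j] <- if (length(v) == 0L) 0 else lower_median(v)
    }
  }
  out
}
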