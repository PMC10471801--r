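# Standalone, weight-explicit forms of the attention operators. These mirror
# the network's internal CBAM and strip-pooling blocks but work on single
# C x H x W feature maps with caller-supplied transform weights, which makes
# the arithmetic easy to inspect and test in isolation.

as_chw <- function(f) {
  f <- as.array(f)
  if (length(dim(f)) != 3) stop("feature map must be a C x H x W array")
  if (!all(is.finite(f))) stop("feature map must be finite")
  f
}

#' Weight initializers for the standalone attention operators
#'
#' `cam_init` creates the shared two-layer bottleneck of the channel
#' attention module (`W1`: C/reduction x C, `W2`: C x C/reduction);
#' `sam_init` the single 7 x 7 spatial-attention kernel on the stacked
#' average/max maps; `spl_init` the strip-pooling transform (two 1-D kernels
#' of length `D`, a 1 x 1 mixing matrix and its bias).
#'
#' @param C number of channels.
#' @param reduction channel bottleneck ratio (must divide `C`).
#' @param D odd 1-D kernel length.
#' @param seed RNG seed.
#' @return named list of weight arrays.
#' @export
cam_init <- function(C, reduction = 8L, seed = 0L) {
  if (reduction >= C || C %% reduction != 0) {
    stop("reduction must divide the channel count and be smaller than it")
  }
  rng <- local_rng(seed)
  Cr <- C %/% reduction
  list(W1 = matrix(he_init(rng, Cr * C, C), Cr, C),
       W2 = matrix(he_init(rng, C * Cr, Cr), C, Cr))
}

#' @rdname cam_init
#' @export
sam_init <- function(seed = 0L) {
  rng <- local_rng(seed)
  list(K = array(he_init(rng, 2 * 7 * 7, 2 * 7 * 7), c(7, 7, 2)))
}

#' @rdname cam_init
#' @export
spl_init <- function(C, D = 3L, seed = 0L) {
  if (D %% 2 == 0) stop("D must be odd")
  rng <- local_rng(seed)
  list(Kh = array(he_init(rng, C * C * D, C * D), c(C, C, D)),
       Kv = array(he_init(rng, C * C * D, C * D), c(C, C, D)),
       W = matrix(he_init(rng, C * C, C), C, C),
       b = numeric(C))
}

#' Channel attention weights (CAM)
#'
#' Global average- and max-pooled channel descriptors are passed through a
#' shared two-layer bottleneck (C -> C/reduction -> C, ReLU between), summed,
#' and squashed by a sigmoid, giving one gate in (0, 1) per channel.
#'
#' @param f C x H x W feature map.
#' @param reduction bottleneck ratio (used when `weights` is `NULL`).
#' @param weights list with `W1`, `W2` (see [cam_init()]).
#' @param seed seed for default weights.
#' @return C x 1 x 1 array of channel gates.
#' @export
cam_weights <- function(f, reduction = 8L, weights = NULL, seed = 0L) {
  f <- as_chw(f)
  C <- dim(f)[1]
  if (is.null(weights)) weights <- cam_init(C, reduction, seed)
  fm <- f
  dim(fm) <- c(C, dim(f)[2] * dim(f)[3])
  avg <- rowMeans(fm)
  mx <- apply(fm, 1, max)
  a <- weights$W2 %*% pmax(weights$W1 %*% avg, 0) +
    weights$W2 %*% pmax(weights$W1 %*% mx, 0)
  array(sigmoid_fn(a), c(C, 1, 1))
}

#' Spatial attention weights (SAM)
#'
#' The channel-wise average and maximum maps (each 1 x H x W) are stacked
#' into a 2 x H x W tensor, convolved with a single 7 x 7 kernel ("same"
#' padding) down to one channel, and squashed by a sigmoid.
#'
#' @param f C x H x W feature map (typically the channel-attention output).
#' @param weights list with `K` (7 x 7 x 2 kernel, see [sam_init()]).
#' @param seed seed for default weights.
#' @return 1 x H x W array of spatial gates.
#' @export
sam_weights <- function(f, weights = NULL, seed = 0L) {
  f <- as_chw(f)
  if (is.null(weights)) weights <- sam_init(seed)
  d <- dim(f)
  fm <- f
  dim(fm) <- c(d[1], d[2] * d[3])
  s2 <- array(0, c(2, d[2], d[3], 1))
  s2[1, , , 1] <- colMeans(fm)
  s2[2, , , 1] <- apply(fm, 2, max)
  Wm <- matrix(0, 1, 2 * 49) # conv2d weight layout: c + C*(ky + KH*kx)
  for (kx in 1:7) for (ky in 1:7) for (c in 1:2) {
    Wm[1, c + 2 * ((ky - 1) + 7 * (kx - 1))] <- weights$K[ky, kx, c]
  }
  conv <- conv2d(local_rng(0L), 2, 1, k = 7L)
  conv$par$W <- Wm
  a <- conv$forward(s2)
  array(sigmoid_fn(a), c(1, d[2], d[3]))
}

#' Apply the convolutional block attention module (CBAM)
#'
#' Sequential channel and spatial attention: `F' = Mc(F) * F` (gates
#' broadcast over space) followed by `F'' = Ms(F') * F'` (gates broadcast
#' over channels). Output shape equals input shape, and because both gates
#' are sigmoid outputs the result is elementwise no larger in magnitude than
#' the input.
#'
#' @param f C x H x W feature map.
#' @param reduction channel bottleneck ratio.
#' @param cam,sam weight lists (see [cam_init()], [sam_init()]); random
#'   seeded defaults when `NULL`.
#' @param seed seed for default weights.
#' @return C x H x W array.
#' @export
cbam_apply <- function(f, reduction = 8L, cam = NULL, sam = NULL, seed = 0L) {
  f <- as_chw(f)
  mc <- cam_weights(f, reduction, cam, seed)
  fp <- f * as.vector(mc)
  ms <- sam_weights(fp, sam, seed)
  d <- dim(f)
  fpp <- fp * array(rep(as.vector(ms), each = d[1]), d)
  fpp
}

#' Apply a strip-pooling layer
#'
#' Mean-pools the feature map to an H x 1 and a 1 x W strip, transforms each
#' strip with a 1-D convolution of kernel length `D` ("same" padding),
#' expands both transforms back to H x W and sums them, then applies a 1 x 1
#' convolution and a sigmoid; the resulting gate multiplies the input
#' elementwise. Captures long, thin structures (field edges, lanes,
#' ditches) that square pooling windows dilute.
#'
#' @param f C x H x W feature map.
#' @param weights list with `Kh`, `Kv`, `W`, `b` (see [spl_init()]).
#' @param D odd 1-D kernel length for default weights.
#' @param seed seed for default weights.
#' @return C x H x W array, same shape as the input.
#' @export
strip_pooling <- function(f, weights = NULL, D = 3L, seed = 0L) {
  f <- as_chw(f)
  d <- dim(f)
  C <- d[1]; H <- d[2]; W <- d[3]
  if (is.null(weights)) weights <- spl_init(C, D, seed)
  D <- dim(weights$Kh)[3]
  half <- (D - 1L) %/% 2L
  hp <- apply(f, c(1, 2), mean)                # C x H
  vp <- apply(f, c(1, 3), mean)                # C x W
  conv1d <- function(strip, K) {               # strip: C x L, K: C x C x D
    L <- ncol(strip)
    out <- matrix(0, nrow(strip), L)
    for (tpos in seq_len(D)) {
      shift <- tpos - 1L - half
      src <- seq_len(L) + shift
      ok <- src >= 1 & src <= L
      out[, ok] <- out[, ok] + K[, , tpos] %*% strip[, src[ok]]
    }
    out
  }
  hc <- conv1d(hp, weights$Kh)                 # C x H
  vc <- conv1d(vp, weights$Kv)                 # C x W
  s <- array(0, d)
  for (w in seq_len(W)) s[, , w] <- hc
  for (h in seq_len(H)) s[, h, ] <- s[, h, ] + vc
  sm <- s
  dim(sm) <- c(C, H * W)
  g <- sigmoid_fn(weights$W %*% sm + weights$b)
  array(as.vector(g), d) * f
}
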