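# AttMobile-DeeplabV3+: MobileNetV2 backbone (optionally with a CBAM block
# on its final feature map), an ASPP head (optionally with a strip-pooling
# branch) and a DeeplabV3+ decoder.

# broadcast a (C, N) matrix over the spatial dims of a (C, H, W, N) tensor
bcast_cn <- function(m, H, W) {
  C <- nrow(m); N <- ncol(m)
  tensor4(m[, rep(seq_len(N), each = H * W)], C, H, W, N)
}

# broadcast a (H*W*N)-vector map over channels, as a (C, H*W*N) matrix
bcast_hw <- function(v, C) {
  matrix(rep(v, each = C), C, length(v))
}

# spread a (C, H, 1, N) strip over W columns -> (C, H, W, N)
spread_cols <- function(strip, W) {
  d <- dim(strip) # (C, H, 1, N)
  v <- array(strip, c(d[1] * d[2], d[4]))
  out <- array(0, c(d[1], d[2], W, d[4]))
  for (n in seq_len(d[4])) out[, , , n] <- rep(v[, n], W)
  out
}

# spread a (C, 1, W, N) strip over H rows -> (C, H, W, N)
spread_rows <- function(strip, H) {
  d <- dim(strip) # (C, 1, W, N)
  m3 <- array(strip, c(d[1], d[3], d[4]))
  out <- array(0, c(d[1], H, d[3], d[4]))
  for (n in seq_len(d[4])) {
    out[, , , n] <- m3[, rep(seq_len(d[3]), each = H), n]
  }
  out
}

# mean over the W axis -> (C, H, 1, N)
pool_cols <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1] * d[2], d[3], d[4])
  hp <- vapply(seq_len(d[4]),
               function(n) rowMeans(xr[, , n, drop = FALSE]),
               numeric(d[1] * d[2]))
  tensor4(hp, d[1], d[2], 1, d[4])
}

# mean over the H axis -> (C, 1, W, N)
pool_rows <- function(x) {
  d <- dim(x)
  xv <- aperm(x, c(1, 3, 4, 2))
  dim(xv) <- c(d[1] * d[3] * d[4], d[2])
  tensor4(rowMeans(xv), d[1], 1, d[3], d[4])
}

# ---- CBAM ------------------------------------------------------------------

cbam_block <- function(rng, C, reduction = 8L) {
  if (reduction >= C) stop("cbam reduction must be smaller than the channel count")
  if (C %% reduction != 0) stop("cbam reduction must divide the channel count")
  m <- mod_new("cbam")
  Cr <- C %/% reduction
  m$par$W1 <- matrix(he_init(rng, Cr * C, C), Cr, C)
  m$par$W2 <- matrix(he_init(rng, C * Cr, Cr), C, Cr)
  m$children <- list(sconv = conv2d(rng, 2, 1, k = 7L))
  m$meta <- list(C = C, reduction = reduction)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
    xm <- x
    dim(xm) <- c(C, H * W, N)
    avg <- vapply(seq_len(N), function(n) rowMeans(xm[, , n, drop = FALSE]),
                  numeric(C))
    dim(avg) <- c(C, N)
    amx <- vapply(seq_len(N), function(n) max.col(xm[, , n], ties.method = "first"),
                  integer(C))
    dim(amx) <- c(C, N)
    mxv <- matrix(xm[cbind(rep(seq_len(C), N), as.vector(amx),
                           rep(seq_len(N), each = C))], C, N)
    h_avg <- m$par$W1 %*% avg; ha <- pmax(h_avg, 0)
    h_max <- m$par$W1 %*% mxv; hm <- pmax(h_max, 0)
    a <- m$par$W2 %*% ha + m$par$W2 %*% hm
    Mc <- sigmoid_fn(a)                      # (C, N)
    G1 <- bcast_cn(Mc, H, W)
    xp <- x * G1
    xpm <- xp
    dim(xpm) <- c(C, H * W * N)
    sa <- colMeans(xpm)
    sidx <- max.col(t(xpm), ties.method = "first")
    smx <- xpm[cbind(sidx, seq_along(sidx))]
    s2 <- array(0, c(2, H, W, N))
    s2[1, , , ] <- sa
    s2[2, , , ] <- smx
    as_ <- m$children$sconv$forward(s2, training)
    Ms <- sigmoid_fn(as_)                    # (1, H, W, N)
    y <- tensor4(xpm * bcast_hw(as.vector(Ms), C), C, H, W, N)
    m$cache <- list(d = d, x = x, avg = avg, amx = amx, mxv = mxv,
                    ha = ha, hm = hm, h_avg = h_avg, h_max = h_max,
                    Mc = Mc, G1 = G1, xp = xp, sidx = sidx, Ms = Ms)
    y
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d <- cc$d
    C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
    HW <- H * W
    dym <- dy; dim(dym) <- c(C, HW * N)
    xpm <- cc$xp; dim(xpm) <- c(C, HW * N)
    ms <- as.vector(cc$Ms)
    dxp <- dym * bcast_hw(ms, C)
    dMs <- colSums(dym * xpm)
    das <- dMs * ms * (1 - ms)
    ds2 <- m$children$sconv$backward(tensor4(das, 1, H, W, N))
    dsa <- as.vector(ds2[1, , , ])
    dsmx <- as.vector(ds2[2, , , ])
    dxp <- dxp + bcast_hw(dsa / C, C)
    sc <- cbind(cc$sidx, seq_len(HW * N))
    dxp[sc] <- dxp[sc] + dsmx
    # channel gate
    dxp4 <- tensor4(dxp, C, H, W, N)
    dx <- dxp4 * cc$G1
    prod3 <- dxp4 * cc$x
    dim(prod3) <- c(C, HW, N)
    dMc <- vapply(seq_len(N), function(n) rowSums(prod3[, , n, drop = FALSE]),
                  numeric(C))
    dim(dMc) <- c(C, N)
    da <- dMc * cc$Mc * (1 - cc$Mc)
    dha <- crossprod(m$par$W2, da) * (cc$h_avg > 0)
    dhm <- crossprod(m$par$W2, da) * (cc$h_max > 0)
    m$grad$W2 <- m$grad$W2 + tcrossprod(da, cc$ha) + tcrossprod(da, cc$hm)
    m$grad$W1 <- m$grad$W1 + tcrossprod(dha, cc$avg) + tcrossprod(dhm, cc$mxv)
    davg <- crossprod(m$par$W1, dha)
    dmxv <- crossprod(m$par$W1, dhm)
    dxm <- dx
    dim(dxm) <- c(C, HW, N)
    for (n in seq_len(N)) {
      slab <- dxm[, , n]
      slab <- slab + davg[, n] / HW
      mc <- cbind(seq_len(C), cc$amx[, n])
      slab[mc] <- slab[mc] + dmxv[, n]
      dxm[, , n] <- slab
    }
    tensor4(dxm, C, H, W, N)
  }
  m
}

# ---- strip pooling gate ----------------------------------------------------

# Strip pooling: mean-pool to H x 1 and 1 x W strips, run a 1-D convolution
# (kernel length D, with batch norm) along each strip, expand both back to
# H x W and sum, then a 1x1 convolution + sigmoid produce the gate that
# multiplies the input elementwise.
spl_gate <- function(rng, C, D = 3L) {
  m <- mod_new("spl_gate")
  m$children <- list(
    hconv = conv2d(rng, C, C, k = c(D, 1L)),
    hbn = batchnorm(C),
    vconv = conv2d(rng, C, C, k = c(1L, D)),
    vbn = batchnorm(C),
    gconv = conv2d(rng, C, C, k = 1L, bias = TRUE)
  )
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    ch <- m$children
    hp <- pool_cols(x)
    vp <- pool_rows(x)
    hc <- ch$hbn$forward(ch$hconv$forward(hp, training), training)
    vc <- ch$vbn$forward(ch$vconv$forward(vp, training), training)
    s <- spread_cols(hc, d[3]) + spread_rows(vc, d[2])
    a <- ch$gconv$forward(s, training)
    g <- sigmoid_fn(a)
    m$cache <- list(d = d, x = x, g = g)
    x * g
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d <- cc$d
    ch <- m$children
    dx <- dy * cc$g
    da <- (dy * cc$x) * cc$g * (1 - cc$g)
    ds <- ch$gconv$backward(da)
    deh <- pool_cols(ds) * d[3]   # sum over the broadcast W axis
    dev <- pool_rows(ds) * d[2]   # sum over the broadcast H axis
    dhp <- ch$hconv$backward(ch$hbn$backward(deh))
    dvp <- ch$vconv$backward(ch$vbn$backward(dev))
    dx + spread_cols(dhp, d[3]) / d[3] + spread_rows(dvp, d[2]) / d[2]
  }
  m
}

# ---- ASPP ------------------------------------------------------------------

aspp_module <- function(rng, cin, out = 256L, rates = c(6L, 12L, 18L),
                        spl_mid = NULL, spl_out = 192L, spl_D = 3L) {
  m <- mod_new("aspp")
  branches <- list(
    b0 = conv_bn_act(rng, cin, out, k = 1L),
    b1 = conv_bn_act(rng, cin, out, k = 3L, dilation = rates[1]),
    b2 = conv_bn_act(rng, cin, out, k = 3L, dilation = rates[2]),
    b3 = conv_bn_act(rng, cin, out, k = 3L, dilation = rates[3]),
    pool = conv_bn_act(rng, cin, out, k = 1L)
  )
  widths <- rep(out, 5)
  if (!is.null(spl_mid)) {
    branches$spl_reduce <- conv_bn_act(rng, cin, spl_mid, k = 1L)
    branches$spl <- spl_gate(rng, spl_mid, spl_D)
    branches$spl_out <- conv_bn_act(rng, spl_mid, spl_out, k = 1L)
    widths <- c(widths, spl_out)
  }
  branches$proj <- conv_bn_act(rng, sum(widths), out, k = 1L)
  m$children <- branches
  m$meta <- list(widths = widths, has_spl = !is.null(spl_mid))
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    ch <- m$children
    outs <- list(ch$b0$forward(x, training), ch$b1$forward(x, training),
                 ch$b2$forward(x, training), ch$b3$forward(x, training))
    # image pooling branch: global mean -> 1x1 conv -> broadcast back
    gp <- x
    dim(gp) <- c(d[1], d[2] * d[3], d[4])
    gpm <- vapply(seq_len(d[4]),
                  function(n) rowMeans(gp[, , n, drop = FALSE]), numeric(d[1]))
    pb <- ch$pool$forward(tensor4(gpm, d[1], 1, 1, d[4]), training)
    outs[[5]] <- bcast_cn(array(pb, c(dim(pb)[1], d[4])), d[2], d[3])
    if (m$meta$has_spl) {
      r <- ch$spl_reduce$forward(x, training)
      outs[[6]] <- ch$spl_out$forward(ch$spl$forward(r, training), training)
    }
    m$cache <- list(d = d, pb_dim = dim(pb))
    y <- array(0, c(sum(m$meta$widths), d[2], d[3], d[4]))
    at <- 0
    for (o in outs) {
      cw <- dim(o)[1]
      y[at + seq_len(cw), , , ] <- o
      at <- at + cw
    }
    ch$proj$forward(y, training)
  }
  m$backward <- function(dy) {
    ch <- m$children
    d <- m$cache$d
    dcat <- ch$proj$backward(dy)
    w <- m$meta$widths
    at <- 0
    parts <- list()
    for (i in seq_along(w)) {
      parts[[i]] <- dcat[at + seq_len(w[i]), , , , drop = FALSE]
      at <- at + w[i]
    }
    dx <- ch$b0$backward(parts[[1]]) + ch$b1$backward(parts[[2]]) +
      ch$b2$backward(parts[[3]]) + ch$b3$backward(parts[[4]])
    # pool branch: broadcast adjoint is a spatial sum, pooling adjoint a spread
    dp <- parts[[5]]
    dim(dp) <- c(w[5], d[2] * d[3], d[4])
    dpb <- vapply(seq_len(d[4]),
                  function(n) rowSums(dp[, , n, drop = FALSE]), numeric(w[5]))
    dgp <- ch$pool$backward(tensor4(dpb, w[5], 1, 1, d[4]))
    dgp <- array(dgp, c(d[1], d[4]))
    dx <- dx + bcast_cn(dgp / (d[2] * d[3]), d[2], d[3])
    if (m$meta$has_spl) {
      dr <- ch$spl$backward(ch$spl_out$backward(parts[[6]]))
      dx <- dx + ch$spl_reduce$backward(dr)
    }
    dx
  }
  m
}

# ---- backbone --------------------------------------------------------------

# MobileNetV2 feature extractor at output stride 16: the stride-2 of the
# 160-channel stage is replaced by dilation 2. The 24-channel stage output
# (stride 4) is exposed as the decoder's low-level feature.
mobilenetv2_backbone <- function(rng) {
  m <- mod_new("backbone")
  spec <- list(
    # cin, cout, expand, stride, dilation
    c(16, 24, 6, 2, 1), c(24, 24, 6, 1, 1),
    c(24, 32, 6, 2, 1), c(32, 32, 6, 1, 1), c(32, 32, 6, 1, 1),
    c(32, 64, 6, 2, 1), c(64, 64, 6, 1, 1), c(64, 64, 6, 1, 1), c(64, 64, 6, 1, 1),
    c(64, 96, 6, 1, 1), c(96, 96, 6, 1, 1), c(96, 96, 6, 1, 1),
    c(96, 160, 6, 1, 2), c(160, 160, 6, 1, 2), c(160, 160, 6, 1, 2),
    c(160, 320, 6, 1, 2))
  blocks <- list(conv_bn_act(rng, 3, 32, k = 3L, stride = 2L),
                 inverted_residual(rng, 32, 16, 1, 1))
  for (s in spec) {
    blocks <- c(blocks, list(inverted_residual(rng, s[1], s[2], s[3], s[4], s[5])))
  }
  m$children <- blocks
  m$meta <- list(low_idx = 4L, low_channels = 24L, out_channels = 320L)
  m$forward <- function(x, training = FALSE) {
    low <- NULL
    for (i in seq_along(m$children)) {
      x <- m$children[[i]]$forward(x, training)
      if (i == m$meta$low_idx) low <- x
    }
    list(low = low, high = x)
  }
  m$backward <- function(dhigh, dlow) {
    dy <- dhigh
    for (i in rev(seq_along(m$children))) {
      if (i == m$meta$low_idx) dy <- dy + dlow
      dy <- m$children[[i]]$backward(dy)
    }
    dy
  }
  m
}

# ---- decoder ---------------------------------------------------------------

decoder_module <- function(rng, low_in = 24L, low_width = 48L, head = 256L,
                           num_classes = 3L) {
  m <- mod_new("decoder")
  m$children <- list(
    lowproj = conv_bn_act(rng, low_in, low_width, k = 1L),
    up = bilinear_module(),
    refine1 = conv_bn_act(rng, head + low_width, head, k = 3L),
    refine2 = conv_bn_act(rng, head, head, k = 3L),
    cls = conv2d(rng, head, num_classes, k = 1L, bias = TRUE)
  )
  m$meta <- list(low_width = low_width, head = head)
  m$forward <- function(low, aspp_out, training = FALSE) {
    ch <- m$children
    lp <- ch$lowproj$forward(low, training)
    dl <- dim(lp)
    au <- ch$up$forward(aspp_out, dl[2], dl[3])
    y <- array(0, c(m$meta$head + m$meta$low_width, dl[2], dl[3], dl[4]))
    y[seq_len(m$meta$head), , , ] <- au
    y[m$meta$head + seq_len(m$meta$low_width), , , ] <- lp
    y <- ch$refine2$forward(ch$refine1$forward(y, training), training)
    ch$cls$forward(y, training)
  }
  m$backward <- function(dy) {
    ch <- m$children
    dcat <- ch$refine1$backward(ch$refine2$backward(ch$cls$backward(dy)))
    dau <- dcat[seq_len(m$meta$head), , , , drop = FALSE]
    dlp <- dcat[m$meta$head + seq_len(m$meta$low_width), , , , drop = FALSE]
    daspp <- ch$up$backward(dau)
    dlow <- ch$lowproj$backward(dlp)
    list(low = dlow, aspp = daspp)
  }
  m
}

# ---- the network -----------------------------------------------------------

#' Network configuration
#'
#' Describes one of the four architecture variants: `"baseline"` (plain
#' MobileNetV2 backbone, standard ASPP), `"attention_only"` (adds one CBAM
#' block on the backbone's final 320-channel feature map),
#' `"aspp_only"` (adds the strip-pooling branch to the ASPP) and `"full"`
#' (both additions).
#'
#' @param num_classes output classes (3: Background, Crop, Soil).
#' @param input_size nominal input side in pixels; must be divisible by 16
#'   (the output stride). Any input whose sides are divisible by 16 is
#'   accepted at run time.
#' @param variant one of `"baseline"`, `"attention_only"`, `"aspp_only"`,
#'   `"full"`.
#' @param cbam_reduction channel-attention bottleneck ratio.
#' @param spl_mid_channels working width of the strip-pooling ASPP branch.
#' @param spl_out_channels output width the strip-pooling branch contributes
#'   to the ASPP concatenation.
#' @param spl_kernel_D odd length of the 1-D strip convolutions.
#' @param atrous_rates dilation rates of the three atrous ASPP branches.
#' @param decoder_low_width channel width of the decoder's low-level
#'   projection.
#' @param seed RNG seed for weight initialization.
#' @export
network_config <- function(num_classes = 3L, input_size = 1024L,
                           variant = c("full", "baseline", "attention_only",
                                       "aspp_only"),
                           cbam_reduction = 8L, spl_mid_channels = 128L,
                           spl_out_channels = 192L,
                           spl_kernel_D = 3L, atrous_rates = c(6L, 12L, 18L),
                           decoder_low_width = 49L, seed = 0L) {
  variant <- match.arg(variant)
  if (input_size %% 16 != 0) stop("input_size must be divisible by 16")
  if (spl_kernel_D %% 2 == 0) stop("spl_kernel_D must be odd")
  structure(list(num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size), variant = variant,
                 cbam_reduction = as.integer(cbam_reduction),
                 spl_mid_channels = as.integer(spl_mid_channels),
                 spl_out_channels = as.integer(spl_out_channels),
                 spl_kernel_D = as.integer(spl_kernel_D),
                 atrous_rates = as.integer(atrous_rates),
                 decoder_low_width = as.integer(decoder_low_width),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build the segmentation network
#'
#' Constructs the encoder-decoder network described by a [network_config()]:
#' a MobileNetV2 inverted-residual backbone at output stride 16, an ASPP head
#' over its final feature map and a DeeplabV3+ decoder that fuses the
#' stride-4 low-level feature, classifies at stride 4 and bilinearly
#' upsamples the class scores to the input size. Depending on the variant, a
#' CBAM block refines the backbone output and/or a strip-pooling branch
#' joins the ASPP.
#'
#' @param config a [network_config()].
#' @return object of class `attmobile_network`.
#' @export
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  rng <- local_rng(config$seed)
  net <- mod_new("attmobile_network")
  net$config <- config
  backbone <- mobilenetv2_backbone(rng)
  cbam <- if (config$variant %in% c("attention_only", "full")) {
    cbam_block(rng, backbone$meta$out_channels, config$cbam_reduction)
  }
  spl_mid <- if (config$variant %in% c("aspp_only", "full")) {
    config$spl_mid_channels
  }
  aspp <- aspp_module(rng, backbone$meta$out_channels, 256L,
                      config$atrous_rates, spl_mid, config$spl_out_channels,
                      config$spl_kernel_D)
  decoder <- decoder_module(rng, backbone$meta$low_channels,
                            config$decoder_low_width, 256L,
                            config$num_classes)
  up <- bilinear_module()
  net$children <- c(list(backbone = backbone), if (!is.null(cbam)) list(cbam = cbam),
                    list(aspp = aspp, decoder = decoder, up = up))
  net$forward <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[2] %% 16 != 0 || d[3] %% 16 != 0) {
      stop("input height and width must be divisible by 16; pad the image first")
    }
    ch <- net$children
    bb <- ch$backbone$forward(x, training)
    high <- bb$high
    if (!is.null(ch$cbam)) high <- ch$cbam$forward(high, training)
    a <- ch$aspp$forward(high, training)
    logits4 <- ch$decoder$forward(bb$low, a, training)
    ch$up$forward(logits4, d[2], d[3])
  }
  net$backward <- function(dy) {
    ch <- net$children
    d4 <- ch$up$backward(dy)
    dd <- ch$decoder$backward(d4)
    dhigh <- ch$aspp$backward(dd$aspp)
    if (!is.null(ch$cbam)) dhigh <- ch$cbam$backward(dhigh)
    ch$backbone$backward(dhigh, dd$low)
  }
  class(net) <- c("attmobile_network", "environment")
  net
}

#' Count trainable parameters, in millions
#'
#' Exhaustively sums the lengths of every trainable parameter array
#' (convolution weights, biases, and batch-normalization scale and shift
#' terms) and reports millions rounded half-up to 3 decimals.
#'
#' @param network a built network, or a `network_config` (which is built
#'   first).
#' @param exact if `TRUE`, return the raw integer count instead.
#' @return numeric scalar.
#' @export
count_parameters <- function(network, exact = FALSE) {
  if (inherits(network, "network_config")) network <- build_model(network)
  n <- mod_n_params(network)
  if (exact) return(n)
  floor(n / 1e6 * 1000 + 0.5) / 1000
}

#' Segment an image into a label mask
#'
#' Runs the network on an RGB image (values 0-255, height and width
#' divisible by 16) in evaluation mode and takes the per-pixel argmax of the
#' class scores, breaking exact ties toward the lowest class index.
#'
#' @param network a trained [build_model()] network.
#' @param image H x W x 3 array.
#' @return integer label mask (H x W).
#' @export
predict_mask <- function(network, image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) stop("image must be H x W x 3")
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("image height and width must be divisible by 16; pad the image first")
  }
  x <- normalize_image(image)
  logits <- network$forward(x, training = FALSE)
  scores_to_mask(logits)
}

normalize_image <- function(image) {
  x <- aperm(image, c(3, 1, 2)) / 127.5 - 1
  tensor4(x, 3, dim(image)[1], dim(image)[2], 1)
}

# argmax over the class axis of a (K, H, W, 1) score tensor, ties to the
# lowest class index
scores_to_mask <- function(logits) {
  d <- dim(logits)
  sm <- logits
  dim(sm) <- c(d[1], d[2] * d[3])
  idx <- max.col(t(sm), ties.method = "first")
  matrix(as.integer(idx - 1L), d[2], d[3])
}

#' @export
print.attmobile_network <- function(x, ...) {
  cat("AttMobile-DeeplabV3+ segmentation network\n")
  cat("  variant:    ", x$config$variant, "\n", sep = "")
  cat("  classes:    ", x$config$num_classes, "\n", sep = "")
  cat("  parameters: ", format(count_parameters(x, exact = TRUE), big.mark = ","),
      " (", sprintf("%.3f", count_parameters(x)), " M)\n", sep = "")
  invisible(x)
}

#' Save or load network weights
#'
#' The checkpoint holds every parameter array, the batch-normalization
#' running statistics and the network configuration.
#'
#' @param network a built network.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(network, path) {
  state <- list(config = unclass(network$config), params = mod_state(network))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  net <- build_model(structure(state$config, class = "network_config"))
  mod_load_state(net, state$params)
  net
}

mod_state <- function(m) {
  st <- list(par = m$par)
  if (!is.null(m$running_mean)) {
    st$running_mean <- m$running_mean
    st$running_var <- m$running_var
  }
  st$children <- lapply(m$children, mod_state)
  st
}

mod_load_state <- function(m, st) {
  m$par <- st$par
  if (!is.null(st$running_mean)) {
    m$running_mean <- st$running_mean
    m$running_var <- st$running_var
  }
  for (i in seq_along(m$children)) mod_load_state(m$children[[i]], st$children[[i]])
  invisible(m)
}
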