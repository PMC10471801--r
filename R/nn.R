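# Minimal feed-forward network framework used by the segmentation model.
#
# Tensors are numeric arrays with dim (C, H, W, N) — channels fastest, which
# lets the compiled im2col kernel copy channel blocks contiguously and turns
# every 1x1 convolution into a plain BLAS matrix product. Each layer is an
# environment holding parameters (`par`), their gradients (`grad`), a
# forward closure (caching what backward needs) and a backward closure.

tensor4 <- function(x, C, H, W, N) {
  dim(x) <- c(C, H, W, N)
  x
}

mod_new <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- list()
  e$grad <- list()
  e$children <- list()
  e
}

# recursive parameter walk; returns list of refs (env, name)
mod_param_refs <- function(m) {
  refs <- lapply(names(m$par), function(nm) list(env = m, name = nm))
  for (ch in m$children) refs <- c(refs, mod_param_refs(ch))
  refs
}

mod_zero_grads <- function(m) {
  for (nm in names(m$par)) m$grad[[nm]] <- m$par[[nm]] * 0
  for (ch in m$children) mod_zero_grads(ch)
  invisible(m)
}

mod_n_params <- function(m) {
  n <- sum(vapply(m$par, length, numeric(1)))
  n + sum(vapply(m$children, mod_n_params, numeric(1)))
}

he_init <- function(rng, n, fan_in) rng$norm(n, 0, sqrt(2 / fan_in))

# ---- convolution ----------------------------------------------------------

conv2d <- function(rng, cin, cout, k = 1L, stride = 1L, pad = NULL,
                   dilation = 1L, bias = FALSE) {
  m <- mod_new("conv2d")
  k <- rep(as.integer(k), length.out = 2)       # (KH, KW)
  stride <- rep(as.integer(stride), length.out = 2)
  dilation <- rep(as.integer(dilation), length.out = 2)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L * dilation # "same" for odd k
  pad <- rep(as.integer(pad), length.out = 2)
  K <- cin * k[1] * k[2]
  m$par$W <- matrix(he_init(rng, cout * K, K), cout, K)
  if (bias) m$par$b <- numeric(cout)
  m$meta <- list(cin = cin, cout = cout, k = k, stride = stride, pad = pad,
                 dilation = dilation)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    m$cache <- list(x = x, d = d)
    mt <- m$meta
    plain1x1 <- all(mt$k == 1L) && all(mt$stride == 1L) && all(mt$pad == 0L)
    if (plain1x1) {
      cols <- x
      dim(cols) <- c(d[1], prod(d[2:4]))
      oh <- d[2]; ow <- d[3]
    } else {
      cols <- cpp_im2col(x, d[1], d[2], d[3], d[4], mt$k[1], mt$k[2],
                         mt$stride[1], mt$stride[2], mt$pad[1], mt$pad[2],
                         mt$dilation[1], mt$dilation[2])
      oh <- (d[2] + 2 * mt$pad[1] - mt$dilation[1] * (mt$k[1] - 1) - 1) %/% mt$stride[1] + 1
      ow <- (d[3] + 2 * mt$pad[2] - mt$dilation[2] * (mt$k[2] - 1) - 1) %/% mt$stride[2] + 1
    }
    y <- m$par$W %*% cols
    if (!is.null(m$par$b)) y <- y + m$par$b
    tensor4(y, mt$cout, oh, ow, d[4])
  }
  m$backward <- function(dy) {
    mt <- m$meta
    d <- m$cache$d
    dy_mat <- dy
    dim(dy_mat) <- c(mt$cout, length(dy) / mt$cout)
    plain1x1 <- all(mt$k == 1L) && all(mt$stride == 1L) && all(mt$pad == 0L)
    if (plain1x1) {
      cols <- m$cache$x
      dim(cols) <- c(d[1], prod(d[2:4]))
    } else {
      cols <- cpp_im2col(m$cache$x, d[1], d[2], d[3], d[4], mt$k[1], mt$k[2],
                         mt$stride[1], mt$stride[2], mt$pad[1], mt$pad[2],
                         mt$dilation[1], mt$dilation[2])
    }
    m$grad$W <- m$grad$W + tcrossprod(dy_mat, cols)
    if (!is.null(m$par$b)) m$grad$b <- m$grad$b + rowSums(dy_mat)
    dcols <- crossprod(m$par$W, dy_mat)
    if (plain1x1) {
      tensor4(dcols, d[1], d[2], d[3], d[4])
    } else {
      dx <- cpp_col2im(dcols, d[1], d[2], d[3], d[4], mt$k[1], mt$k[2],
                       mt$stride[1], mt$stride[2], mt$pad[1], mt$pad[2],
                       mt$dilation[1], mt$dilation[2])
      tensor4(dx, d[1], d[2], d[3], d[4])
    }
  }
  m
}

dwconv2d <- function(rng, C, k = 3L, stride = 1L, dilation = 1L) {
  m <- mod_new("dwconv2d")
  k <- rep(as.integer(k), length.out = 2)
  stride <- rep(as.integer(stride), length.out = 2)
  dilation <- rep(as.integer(dilation), length.out = 2)
  pad <- (k - 1L) %/% 2L * dilation
  m$par$W <- matrix(he_init(rng, C * k[1] * k[2], k[1] * k[2]), C, k[1] * k[2])
  m$meta <- list(C = C, k = k, stride = stride, pad = pad, dilation = dilation)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    m$cache <- list(x = x, d = d)
    mt <- m$meta
    y <- cpp_dwconv_fwd(x, m$par$W, d[1], d[2], d[3], d[4], mt$k[1], mt$k[2],
                        mt$stride[1], mt$stride[2], mt$pad[1], mt$pad[2],
                        mt$dilation[1], mt$dilation[2])
    oh <- (d[2] + 2 * mt$pad[1] - mt$dilation[1] * (mt$k[1] - 1) - 1) %/% mt$stride[1] + 1
    ow <- (d[3] + 2 * mt$pad[2] - mt$dilation[2] * (mt$k[2] - 1) - 1) %/% mt$stride[2] + 1
    tensor4(y, d[1], oh, ow, d[4])
  }
  m$backward <- function(dy) {
    mt <- m$meta
    d <- m$cache$d
    dw <- matrix(0, nrow(m$par$W), ncol(m$par$W))
    dx <- cpp_dwconv_bwd(m$cache$x, m$par$W, dy, dw, d[1], d[2], d[3], d[4],
                         mt$k[1], mt$k[2], mt$stride[1], mt$stride[2],
                         mt$pad[1], mt$pad[2], mt$dilation[1], mt$dilation[2])
    m$grad$W <- m$grad$W + dw
    tensor4(dx, d[1], d[2], d[3], d[4])
  }
  m
}

# ---- batch normalization --------------------------------------------------

batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  m <- mod_new("batchnorm")
  m$par$gamma <- rep(1, C)
  m$par$beta <- rep(0, C)
  m$running_mean <- rep(0, C)
  m$running_var <- rep(1, C)
  m$meta <- list(C = C, eps = eps, momentum = momentum)
  m$forward <- function(x, training = FALSE) {
    d <- dim(x)
    xm <- x
    dim(xm) <- c(d[1], prod(d[2:4]))
    if (training) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      m$running_mean <- (1 - m$meta$momentum) * m$running_mean + m$meta$momentum * mu
      m$running_var <- (1 - m$meta$momentum) * m$running_var + m$meta$momentum * v
    } else {
      mu <- m$running_mean
      v <- m$running_var
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + m$meta$eps)
    xhat <- xc * istd
    m$cache <- list(xhat = xhat, istd = istd, d = d, training = training)
    y <- m$par$gamma * xhat + m$par$beta
    tensor4(y, d[1], d[2], d[3], d[4])
  }
  m$backward <- function(dy) {
    d <- m$cache$d
    dym <- dy
    dim(dym) <- c(d[1], prod(d[2:4]))
    xhat <- m$cache$xhat
    m$grad$gamma <- m$grad$gamma + rowSums(dym * xhat)
    m$grad$beta <- m$grad$beta + rowSums(dym)
    g <- m$par$gamma * m$cache$istd
    if (m$cache$training) {
      dx <- g * (dym - rowMeans(dym) - xhat * rowMeans(dym * xhat))
    } else {
      dx <- g * dym
    }
    tensor4(dx, d[1], d[2], d[3], d[4])
  }
  m
}

# ---- elementwise activations ----------------------------------------------

relu6 <- function() {
  m <- mod_new("relu6")
  m$forward <- function(x, training = FALSE) {
    m$cache <- (x > 0) & (x < 6)
    pmin(pmax(x, 0), 6)
  }
  m$backward <- function(dy) dy * m$cache
  m
}

sigmoid_fn <- function(x) 1 / (1 + exp(-x))

# ---- resize ----------------------------------------------------------------

bilinear_to <- function(x, oh, ow) {
  d <- dim(x)
  if (d[2] == oh && d[3] == ow) return(x)
  tensor4(cpp_bilinear_fwd(x, d[1], d[2], d[3], d[4], oh, ow), d[1], oh, ow, d[4])
}

bilinear_module <- function() {
  m <- mod_new("bilinear")
  m$forward <- function(x, oh, ow) {
    m$cache <- dim(x)
    bilinear_to(x, oh, ow)
  }
  m$backward <- function(dy) {
    d <- m$cache
    dd <- dim(dy)
    if (dd[2] == d[2] && dd[3] == d[3]) return(dy)
    tensor4(cpp_bilinear_bwd(dy, d[1], d[2], d[3], d[4], dd[2], dd[3]),
            d[1], d[2], d[3], d[4])
  }
  m
}

# ---- composite helpers -----------------------------------------------------

seq_module <- function(...) {
  m <- mod_new("sequential")
  m$children <- list(...)
  m$forward <- function(x, training = FALSE) {
    for (ch in m$children) x <- ch$forward(x, training)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

conv_bn_act <- function(rng, cin, cout, k = 1L, stride = 1L, dilation = 1L,
                        act = TRUE, bias = FALSE) {
  parts <- list(conv2d(rng, cin, cout, k, stride, dilation = dilation, bias = bias),
                batchnorm(cout))
  if (act) parts <- c(parts, list(relu6()))
  do.call(seq_module, parts)
}

# MobileNetV2 inverted residual: 1x1 expand -> 3x3 depthwise -> 1x1 linear
# project, with an identity shortcut when stride is 1 and cin == cout.
inverted_residual <- function(rng, cin, cout, expand, stride = 1L,
                              dilation = 1L) {
  m <- mod_new("inverted_residual")
  hidden <- cin * expand
  blocks <- list()
  if (expand != 1) blocks <- c(blocks, list(conv_bn_act(rng, cin, hidden)))
  blocks <- c(blocks, list(
    seq_module(dwconv2d(rng, hidden, 3L, stride, dilation), batchnorm(hidden), relu6()),
    seq_module(conv2d(rng, hidden, cout), batchnorm(cout))
  ))
  m$children <- list(do.call(seq_module, blocks))
  m$meta <- list(shortcut = (stride == 1L && cin == cout))
  m$forward <- function(x, training = FALSE) {
    y <- m$children[[1]]$forward(x, training)
    if (m$meta$shortcut) y + x else y
  }
  m$backward <- function(dy) {
    dx <- m$children[[1]]$backward(dy)
    if (m$meta$shortcut) dx + dy else dx
  }
  m
}
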