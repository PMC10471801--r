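# straight-line reference implementations of the attention operators,
# written with explicit loops, independent of the package internals

ref_cam <- function(f, W1, W2) {
  C <- dim(f)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(f[c, , ])
    mx[c] <- max(f[c, , ])
  }
  relu <- function(v) ifelse(v > 0, v, 0)
  a <- W2 %*% relu(W1 %*% avg) + W2 %*% relu(W1 %*% mx)
  1 / (1 + exp(-a))
}

ref_sam <- function(f, K) {
  d <- dim(f)
  sa <- apply(f, c(2, 3), mean)
  sm <- apply(f, c(2, 3), max)
  st <- array(0, c(d[2], d[3], 2))
  st[, , 1] <- sa; st[, , 2] <- sm
  out <- matrix(0, d[2], d[3])
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    acc <- 0
    for (kh in 1:7) for (kw in 1:7) for (c in 1:2) {
      hh <- h + kh - 4; ww <- w + kw - 4
      if (hh >= 1 && hh <= d[2] && ww >= 1 && ww <= d[3]) {
        acc <- acc + K[kh, kw, c] * st[hh, ww, c]
      }
    }
    out[h, w] <- 1 / (1 + exp(-acc))
  }
  out
}

ref_spl <- function(f, wts) {
  d <- dim(f)
  C <- d[1]; H <- d[2]; W <- d[3]
  D <- dim(wts$Kh)[3]; half <- (D - 1) / 2
  hp <- apply(f, c(1, 2), mean)
  vp <- apply(f, c(1, 3), mean)
  hc <- matrix(0, C, H); vc <- matrix(0, C, W)
  for (co in seq_len(C)) {
    for (t in seq_len(H)) {
      acc <- 0
      for (k in seq_len(D)) for (ci in seq_len(C)) {
        tt <- t + k - 1 - half
        if (tt >= 1 && tt <= H) acc <- acc + wts$Kh[co, ci, k] * hp[ci, tt]
      }
      hc[co, t] <- acc
    }
    for (t in seq_len(W)) {
      acc <- 0
      for (k in seq_len(D)) for (ci in seq_len(C)) {
        tt <- t + k - 1 - half
        if (tt >= 1 && tt <= W) acc <- acc + wts$Kv[co, ci, k] * vp[ci, tt]
      }
      vc[co, t] <- acc
    }
  }
  out <- array(0, d)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    s <- hc[, h] + vc[, w]
    g <- 1 / (1 + exp(-(wts$W %*% s + wts$b)))
    out[, h, w] <- f[, h, w] * as.vector(g)
  }
  out
}

test_that("channel attention matches its closed form and contracts", {
  C <- 8L
  # constant input with zero transform weights gives sigmoid(0) = 0.5
  f <- array(3.7, c(C, 4, 5))
  z <- list(W1 = matrix(0, 2, C), W2 = matrix(0, C, 2))
  expect_equal(as.vector(cam_weights(f, weights = z)), rep(0.5, C))

  set.seed(1)
  f <- array(rnorm(C * 16 * 16), c(C, 16, 16))
  w <- cam_weights(f, reduction = 4L, seed = 2)
  expect_equal(dim(w), c(C, 1, 1))
  expect_true(all(w > 0 & w < 1))
  expect_error(cam_weights(f, reduction = 8L), "reduction")

  for (s in 1:10) {
    set.seed(s)
    f <- array(rnorm(C * 6 * 5), c(C, 6, 5))
    wts <- cam_init(C, 4L, seed = s)
    expect_equal(as.vector(cam_weights(f, weights = wts)),
                 as.vector(ref_cam(f, wts$W1, wts$W2)), tolerance = 1e-5)
  }
})

test_that("spatial attention matches its closed form and contracts", {
  f <- array(1.2, c(8, 6, 6))
  z <- list(K = array(0, c(7, 7, 2)))
  expect_true(all(sam_weights(f, weights = z) == 0.5))

  set.seed(3)
  f <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  expect_equal(dim(sam_weights(f, seed = 1)), c(1, 16, 16))

  for (s in 1:10) {
    set.seed(s)
    f <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
    wts <- sam_init(seed = s)
    expect_equal(as.vector(sam_weights(f, weights = wts)),
                 as.vector(ref_sam(f, wts$K)), tolerance = 1e-5)
  }
})

test_that("CBAM gates multiply: zero weights quarter the input, zero stays zero", {
  f <- array(rnorm(8 * 5 * 5), c(8, 5, 5))
  zc <- list(W1 = matrix(0, 2, 8), W2 = matrix(0, 8, 2))
  zs <- list(K = array(0, c(7, 7, 2)))
  expect_equal(cbam_apply(f, cam = zc, sam = zs), 0.25 * f, tolerance = 1e-12)
  expect_equal(cbam_apply(array(0, c(8, 5, 5)), reduction = 2L, seed = 4),
               array(0, c(8, 5, 5)))
  out <- cbam_apply(array(rnorm(16 * 32 * 32), c(16, 32, 32)), seed = 5)
  expect_equal(dim(out), c(16, 32, 32))
})

test_that("strip pooling matches its closed form, preserves shape, and gates", {
  f <- array(2.5, c(4, 6, 7))
  z <- list(Kh = array(0, c(4, 4, 3)), Kv = array(0, c(4, 4, 3)),
            W = matrix(0, 4, 4), b = numeric(4))
  expect_equal(strip_pooling(f, weights = z), 0.5 * f, tolerance = 1e-12)

  set.seed(6)
  f <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  out <- strip_pooling(f, seed = 6)
  expect_equal(dim(out), dim(f))

  for (s in 1:10) {
    set.seed(s)
    f <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
    wts <- spl_init(3L, 3L, seed = s)
    expect_equal(strip_pooling(f, weights = wts), ref_spl(f, wts),
                 tolerance = 1e-5)
  }
})

test_that("attention gating never amplifies the input", {
  for (s in 1:5) {
    set.seed(s)
    f <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
    expect_true(all(abs(cbam_apply(f, reduction = 2L, seed = s)) <= abs(f) + 1e-12))
    expect_true(all(abs(strip_pooling(f, seed = s)) <= abs(f) + 1e-12))
  }
})

test_that("the network maps images to per-class score maps of the same size", {
  net <- build_model(network_config(variant = "full", input_size = 64L, seed = 1))
  x <- array(rnorm(3 * 64 * 64), c(3, 64, 64, 1))
  y1 <- net$forward(x, training = FALSE)
  expect_equal(dim(y1), c(3, 64, 64, 1))
  y2 <- net$forward(x, training = FALSE)
  expect_identical(y1, y2)
  expect_error(net$forward(array(0, c(3, 60, 60, 1)), FALSE), "divisible by 16")

  img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  m <- predict_mask(net, img)
  expect_equal(dim(m), c(64, 64))
  expect_true(all(m %in% 0:2))
  expect_error(predict_mask(net, img[1:60, , ]), "divisible by 16")
})

test_that("mask prediction is the per-pixel argmax with ties to the lowest class", {
  scores <- array(0, c(3, 4, 4, 1))
  scores[3, , , ] <- 5
  expect_true(all(fieldlines:::scores_to_mask(scores) == 2L))
  tie <- array(1, c(3, 2, 2, 1))        # exact three-way tie
  expect_true(all(fieldlines:::scores_to_mask(tie) == 0L))
  tie[2, , , ] <- 2; tie[3, , , ] <- 2  # two-way tie between classes 1 and 2
  expect_true(all(fieldlines:::scores_to_mask(tie) == 1L))

  set.seed(9)
  r <- array(rnorm(3 * 6 * 6), c(3, 6, 6, 1))
  got <- fieldlines:::scores_to_mask(r)
  for (h in 1:6) for (w in 1:6) {
    expect_equal(got[h, w], which.max(r[, h, w, 1]) - 1L)
  }
})

test_that("variants share the backbone and differ only by their extra blocks", {
  cb <- network_config(variant = "baseline", seed = 3)
  ca <- network_config(variant = "attention_only", seed = 3)
  nb <- build_model(cb)
  na <- build_model(ca)
  expect_null(nb$children$cbam)
  expect_false(is.null(na$children$cbam))
  bb_n <- fieldlines:::mod_n_params(nb$children$backbone)
  expect_equal(fieldlines:::mod_n_params(na$children$backbone), bb_n)
  cbam_n <- fieldlines:::mod_n_params(na$children$cbam)
  expect_equal(count_parameters(na, exact = TRUE),
               count_parameters(nb, exact = TRUE) + cbam_n)
})

test_that("checkpoints round-trip weights and predictions", {
  tf <- tempfile(fileext = ".ckpt")
  on.exit(unlink(tf))
  net <- build_model(network_config(variant = "aspp_only", input_size = 32L,
                                    seed = 11))
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  m1 <- predict_mask(net, img)
  save_checkpoint(net, tf)
  net2 <- load_checkpoint(tf)
  expect_equal(net2$config$variant, "aspp_only")
  expect_identical(predict_mask(net2, img), m1)
})
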