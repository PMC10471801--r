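test_that("Dice loss reproduces its closed forms", {
  expect_equal(dice_loss(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(dice_loss(c(0, 0, 0), c(1, 1, 1)), 1, tolerance = 1e-4)
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0)), 1 / 3)
  expect_error(dice_loss(c(1, 0), c(1, 0, 0)), "same shape")
})

test_that("Dice loss stays in [0, 1] and vanishes only on a perfect match", {
  set.seed(8)
  for (i in 1:50) {
    K <- sample(2:4, 1); n <- sample(5:40, 1)
    g <- matrix(0, K, n)
    g[cbind(sample(K, n, replace = TRUE), 1:n)] <- 1
    p <- matrix(runif(K * n), K, n)
    p <- p / rep(colSums(p), each = K)
    l <- dice_loss(p, g)
    expect_gte(l, 0)
    expect_lte(l, 1)
    if (l < 1e-12) expect_equal(p, g)
    expect_lt(dice_loss(g, g), 1e-12)
  }
})

test_that("the Dice gradient matches finite differences", {
  set.seed(5)
  p <- array(runif(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  g <- array(0, c(3, 4, 4, 2))
  g[1, , , ] <- 1
  dl <- fieldlines:::dice_loss_grad(p, g)
  expect_equal(dl$loss, dice_loss(p, g))
  eps <- 1e-6
  for (i in c(1, 17, 40)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd <- (dice_loss(pp, g) - dice_loss(pm, g)) / (2 * eps)
    expect_equal(dl$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("the cosine schedule hits its endpoints and decreases monotonically", {
  expect_identical(cosine_lr(0, 10), 5e-4)
  expect_identical(cosine_lr(10, 10), 5e-6)
  expect_equal(cosine_lr(5, 10), 2.525e-4)
  lrs <- cosine_lr(0:20, 20)
  expect_true(all(diff(lrs) < 0))
  expect_true(all(lrs[2:20] > 5e-6 & lrs[2:20] < 5e-4))
  expect_error(cosine_lr(11, 10), "t must lie")
  expect_error(train_config(epochs = 1, lr_min = 1e-3), "lr_min")
})

make_tiny_dataset <- function(n, size = 64L, from_seed = 1L) {
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(scene_config(size = c(size, size), n_plots = 1L,
                                      separation = 4, seed = from_seed + i))
    list(image = sc$image, mask = sc$mask)
  })
}

test_that("zero epochs is a no-op on the weights", {
  net <- build_model(network_config(variant = "baseline", input_size = 32L,
                                    seed = 2))
  w_before <- net$children$decoder$children$cls$par$W
  hist <- train_epochs(net, make_tiny_dataset(2), train_config(epochs = 0))
  expect_equal(nrow(hist), 0)
  expect_identical(net$children$decoder$children$cls$par$W, w_before)
  expect_error(train_epochs(net, list(train = list()), train_config(epochs = 1)),
               "empty dataset")
})

test_that("training follows the schedule, learns, and is seed-reproducible", {
  ds <- list(train = make_tiny_dataset(4), val = make_tiny_dataset(1, from_seed = 50))
  cfg <- train_config(epochs = 3, batch_size = 2, seed = 7)
  net <- build_model(network_config(variant = "baseline", input_size = 32L,
                                    seed = 2))
  hist <- train_epochs(net, ds, cfg)
  expect_equal(nrow(hist), 3)
  expect_equal(hist$lr, cosine_lr(0:2, 3))
  expect_lt(hist$train_loss[3], hist$train_loss[1])
  expect_true(all(is.finite(hist$val_loss)))

  net2 <- build_model(network_config(variant = "baseline", input_size = 32L,
                                     seed = 2))
  hist2 <- train_epochs(net2, ds, cfg)
  expect_identical(hist, hist2)
})
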