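#' Training configuration
#'
#' Defaults follow the study conditions for this architecture: mini-batches
#' of 8, Adam with first-moment decay 0.9, and a cosine-annealed learning
#' rate from 5e-4 down to 5e-6.
#'
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size.
#' @param lr_initial,lr_min cosine schedule endpoints.
#' @param momentum_beta1 Adam first-moment decay.
#' @param beta2 Adam second-moment decay.
#' @param freeze_backbone if `TRUE`, backbone parameters are not updated.
#' @param seed RNG seed driving shuffling.
#' @export
train_config <- function(epochs, batch_size = 8L, lr_initial = 5e-4,
                         lr_min = 5e-6, momentum_beta1 = 0.9, beta2 = 0.999,
                         freeze_backbone = FALSE, seed = 0L) {
  if (lr_min >= lr_initial) stop("lr_min must be below lr_initial")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_min = lr_min,
                 momentum_beta1 = momentum_beta1, beta2 = beta2,
                 freeze_backbone = freeze_backbone, seed = as.integer(seed)),
            class = "train_config")
}

#' Multi-class Dice loss
#'
#' For each class `c`, the binary Dice loss is
#' `1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2))` over all pixels, where `p`
#' are predicted class probabilities and `g` the one-hot truth; the returned
#' value is the unweighted mean over classes. A class absent from both the
#' prediction and the truth (a vanishing denominator) is vacuously perfect
#' and contributes 0; `eps` guards the division. The loss lies in `[0, 1]`
#' and is 0 exactly when the prediction matches the truth.
#'
#' @param p predicted probabilities: a vector (single class), a
#'   `classes x pixels` matrix, or a `(C, H, W, N)` array.
#' @param g one-hot ground truth, same shape.
#' @param eps denominator stabilizer.
#' @return scalar loss.
#' @export
dice_loss <- function(p, g, eps = 1e-5) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g))) {
    stop("p and g must have the same shape")
  }
  pm <- as.array(p)
  gm <- as.array(g)
  nd <- length(dim(pm))
  if (nd <= 1) {
    dim(pm) <- c(1, length(pm))
    dim(gm) <- dim(pm)
  } else if (nd > 2) {
    dim(pm) <- c(dim(pm)[1], length(pm) / dim(pm)[1])
    dim(gm) <- dim(pm)
  }
  num <- 2 * rowSums(pm * gm)
  den <- rowSums(pm^2) + rowSums(gm^2)
  mean(ifelse(den == 0, 0, 1 - num / pmax(den, eps)))
}

# loss and gradient wrt p, for the training loop
dice_loss_grad <- function(p, g, eps = 1e-5) {
  d <- dim(p)
  C <- d[1]
  pm <- p; dim(pm) <- c(C, length(p) / C)
  gm <- g; dim(gm) <- c(C, length(g) / C)
  num <- 2 * rowSums(pm * gm)
  den <- rowSums(pm^2) + rowSums(gm^2)
  empty <- den == 0
  den <- pmax(den, eps)
  loss <- mean(ifelse(empty, 0, 1 - num / den))
  # d/dp_ci [ -num_c/den_c ] = -(2 g - num/den * 2 p) / den, then / C for the
  # class mean
  dp <- -(2 * gm - (num / den) * 2 * pm) / den / C
  list(loss = loss, grad = tensor4(dp, d[1], d[2], d[3], d[4]))
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_initial - lr_min) * (1 + cos(pi * t / T)) / 2` for
#' `t` in `0..T`: the schedule starts at `lr_initial`, decreases
#' monotonically, and reaches `lr_min` exactly at `t = T`.
#'
#' @param t epoch index, `0 <= t <= total`.
#' @param total total number of epochs `T >= 1`.
#' @param lr_initial,lr_min schedule endpoints.
#' @return learning rate at `t`.
#' @export
cosine_lr <- function(t, total, lr_initial = 5e-4, lr_min = 5e-6) {
  if (total < 1) stop("total must be >= 1")
  if (any(t < 0) || any(t > total)) stop("t must lie in [0, total]")
  lr_min + 0.5 * (lr_initial - lr_min) * (1 + cos(pi * t / total))
}

# one-hot encode an integer mask to a (C, H, W) slab
one_hot <- function(mask, num_classes) {
  H <- nrow(mask); W <- ncol(mask)
  g <- array(0, c(num_classes, H, W))
  idx <- cbind(as.vector(mask) + 1L,
               rep(seq_len(H), W) + 0L,
               rep(seq_len(W), each = H))
  g[idx] <- 1
  g
}

softmax_c <- function(x) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], length(x) / d[1])
  xm <- xm - rep(apply(xm, 2, max), each = d[1])
  e <- exp(xm)
  s <- e / rep(colSums(e), each = d[1])
  tensor4(s, d[1], d[2], d[3], d[4])
}

softmax_backward <- function(s, ds) {
  d <- dim(s)
  sm <- s; dim(sm) <- c(d[1], length(s) / d[1])
  dm <- ds; dim(dm) <- c(d[1], length(ds) / d[1])
  inner <- colSums(dm * sm)
  tensor4(sm * (dm - rep(inner, each = d[1])), d[1], d[2], d[3], d[4])
}

# stack samples (list of lists with $image, $mask) into one batch tensor
stack_batch <- function(samples, num_classes) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  N <- length(samples)
  x <- array(0, c(3, H, W, N))
  g <- array(0, c(num_classes, H, W, N))
  for (i in seq_len(N)) {
    x[, , , i] <- aperm(samples[[i]]$image, c(3, 1, 2)) / 127.5 - 1
    g[, , , i] <- one_hot(samples[[i]]$mask, num_classes)
  }
  list(x = x, g = g)
}

adam_new <- function(refs, beta1, beta2, eps = 1e-8) {
  list(refs = refs,
       m = lapply(refs, function(r) r$env$par[[r$name]] * 0),
       v = lapply(refs, function(r) r$env$par[[r$name]] * 0),
       beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$refs)) {
    r <- opt$refs[[i]]
    g <- r$env$grad[[r$name]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    r$env$par[[r$name]] <- r$env$par[[r$name]] -
      lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
  }
  opt
}

# forward + loss on a list of samples in eval mode; also mIoU if requested
evaluate_samples <- function(network, samples, num_classes, batch_size = 8L,
                             miou = FALSE) {
  losses <- numeric(0)
  cm <- matrix(0L, num_classes, num_classes)
  for (at in seq(1, length(samples), by = batch_size)) {
    chunk <- samples[at:min(at + batch_size - 1, length(samples))]
    b <- stack_batch(chunk, num_classes)
    logits <- network$forward(b$x, training = FALSE)
    probs <- softmax_c(logits)
    losses <- c(losses, dice_loss(probs, b$g))
    if (miou) {
      for (i in seq_along(chunk)) {
        pm <- scores_to_mask(logits[, , , i, drop = FALSE])
        cm <- cm + unclass(confusion_matrix(pm, chunk[[i]]$mask,
                                            num_classes - 1L))
      }
    }
  }
  list(loss = mean(losses), miou = if (miou) iou(cm)$mean else NA_real_)
}

#' Train the segmentation network
#'
#' Mini-batch optimization of the multi-class Dice loss with Adam and a
#' per-epoch cosine-annealed learning rate (epoch `e` of `T` uses
#' `cosine_lr(e - 1, T)`). Shuffling is driven by the configuration seed, so
#' a fixed seed reproduces the run.
#'
#' @param network a [build_model()] network (modified in place).
#' @param dataset list with `train` and optionally `val`: each a list of
#'   samples, where a sample is a list with `image` (H x W x 3, 0-255) and
#'   `mask` (H x W integer matrix).
#' @param config a [train_config()].
#' @return object of class `train_history`: data.frame with one row per
#'   epoch (`epoch`, `train_loss`, `val_loss`, `lr`, `val_miou`).
#' @export
train_epochs <- function(network, dataset, config) {
  stopifnot(inherits(config, "train_config"))
  if (is.null(dataset$train)) dataset <- list(train = dataset)
  train <- dataset$train
  if (length(train) == 0) stop("empty dataset")
  num_classes <- network$config$num_classes
  rng <- local_rng(config$seed)
  refs <- if (config$freeze_backbone) {
    unlist(lapply(names(network$children)[names(network$children) != "backbone"],
                  function(nm) mod_param_refs(network$children[[nm]])),
           recursive = FALSE)
  } else {
    mod_param_refs(network)
  }
  opt <- adam_new(refs, config$momentum_beta1, config$beta2)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0),
                     val_miou = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    lr <- cosine_lr(epoch - 1, config$epochs, config$lr_initial, config$lr_min)
    perm <- rng$perm(length(train))
    batch_losses <- numeric(0)
    for (at in seq(1, length(train), by = config$batch_size)) {
      sel <- perm[at:min(at + config$batch_size - 1, length(train))]
      b <- stack_batch(train[sel], num_classes)
      mod_zero_grads(network)
      logits <- network$forward(b$x, training = TRUE)
      probs <- softmax_c(logits)
      dl <- dice_loss_grad(probs, b$g)
      if (!is.finite(dl$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at sample ", at, "); lower the learning rate")
      }
      batch_losses <- c(batch_losses, dl$loss)
      network$backward(softmax_backward(probs, dl$grad))
      opt <- adam_step(opt, lr)
    }
    val <- if (!is.null(dataset$val) && length(dataset$val) > 0) {
      evaluate_samples(network, dataset$val, num_classes,
                       config$batch_size, miou = TRUE)
    } else {
      list(loss = NA_real_, miou = NA_real_)
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = val$loss, lr = lr,
                                   val_miou = val$miou))
  }
  class(hist) <- c("train_history", "data.frame")
  hist
}

#' @export
print.train_history <- function(x, ...) {
  cat("Training history (", nrow(x), " epochs)\n", sep = "")
  print.data.frame(format(x, digits = 4))
  invisible(x)
}
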