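## Small convolutional network ------------------------------------------------
##
## A compact 3-conv-block binary classifier implemented directly on BLAS
## matrix products (im2col convolutions), with ReLU activations, 2x2 max
## pooling, global average pooling, a sigmoid output, binary cross-entropy
## loss, Adam, and a reduce-on-plateau learning-rate scheduler. Designed to
## train in seconds on a CPU at the image sizes this package uses; it is not
## a general deep-learning framework.
##
## Tensor layout: 4-D arrays (batch, height, width, channels).

## Average-pool by an integer factor (used to bring 224x224 inputs down to
## the network's 56x56 working resolution).
avg_pool_factor <- function(x, f) {
  d <- dim(x)
  h2 <- d[2] %/% f; w2 <- d[3] %/% f
  x <- x[, seq_len(h2 * f), seq_len(w2 * f), , drop = FALSE]
  out <- array(0, c(d[1], h2, w2, d[4]))
  for (i in seq_len(f)) for (j in seq_len(f)) {
    out <- out + x[, seq(i, by = f, length.out = h2),
                   seq(j, by = f, length.out = w2), , drop = FALSE]
  }
  out / f^2
}

## im2col for 3x3 same-padding convolution: returns (B*H*W) x (9*Cin).
im2col3 <- function(x) {
  d <- dim(x)  # B H W C
  xp <- array(0, c(d[1], d[2] + 2, d[3] + 2, d[4]))
  xp[, 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
  blocks <- vector("list", 9)
  k <- 0
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1
    sl <- xp[, dy + seq_len(d[2]), dx + seq_len(d[3]), , drop = FALSE]
    blocks[[k]] <- matrix(sl, nrow = d[1] * d[2] * d[3])
  }
  do.call(cbind, blocks)
}

col2im3 <- function(dcol, d) {
  dxp <- array(0, c(d[1], d[2] + 2, d[3] + 2, d[4]))
  k <- 0
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1
    block <- array(dcol[, ((k - 1) * d[4] + 1):(k * d[4])],
                   c(d[1], d[2], d[3], d[4]))
    dxp[, dy + seq_len(d[2]), dx + seq_len(d[3]), ] <-
      dxp[, dy + seq_len(d[2]), dx + seq_len(d[3]), , drop = FALSE] + block
  }
  dxp[, 2:(d[2] + 1), 2:(d[3] + 1), , drop = FALSE]
}

conv3_forward <- function(x, W, b) {
  d <- dim(x)
  xcol <- im2col3(x)
  y <- xcol %*% W
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(d[1], d[2], d[3], ncol(W))), xcol = xcol, xdim = d)
}

conv3_backward <- function(cache, W, dy) {
  d <- dim(dy)
  dym <- matrix(dy, nrow = d[1] * d[2] * d[3])
  dW <- crossprod(cache$xcol, dym)
  db <- colSums(dym)
  dcol <- dym %*% t(W)
  dx <- col2im3(dcol, cache$xdim)
  list(dx = dx, dW = dW, db = db)
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[2] %/% 2; w2 <- d[3] %/% 2
  s <- function(i, j) x[, seq(i, by = 2, length.out = h2),
                        seq(j, by = 2, length.out = w2), , drop = FALSE]
  a <- s(1, 1); b <- s(1, 2); cc <- s(2, 1); dd <- s(2, 2)
  y <- pmax(a, b, cc, dd)
  list(y = y, arg = list(a == y, b == y & a != y,
                         cc == y & a != y & b != y,
                         dd == y & a != y & b != y & cc != y),
       xdim = d)
}

maxpool2_backward <- function(cache, dy) {
  d <- cache$xdim
  h2 <- d[2] %/% 2; w2 <- d[3] %/% 2
  dx <- array(0, d)
  put <- function(k, i, j) {
    dx[, seq(i, by = 2, length.out = h2),
       seq(j, by = 2, length.out = w2), ] <<-
      dx[, seq(i, by = 2, length.out = h2),
         seq(j, by = 2, length.out = w2), , drop = FALSE] +
      dy * cache$arg[[k]]
  }
  put(1, 1, 1); put(2, 1, 2); put(3, 2, 1); put(4, 2, 2)
  dx
}

cnn_init <- function(channels = c(8L, 16L, 32L), seed = 1L) {
  set.seed(seed)
  he <- function(fan_in, nr, nc)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  cin <- c(1L, channels[1], channels[2])
  params <- list()
  for (l in 1:3) {
    params[[paste0("W", l)]] <- he(9 * cin[l], 9 * cin[l], channels[l])
    params[[paste0("b", l)]] <- rep(0, channels[l])
  }
  params$Wd <- matrix(stats::rnorm(channels[3], sd = sqrt(2 / channels[3])),
                      ncol = 1)
  params$bd <- 0
  params
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  caches <- list()
  h <- x
  for (l in 1:3) {
    cv <- conv3_forward(h, params[[paste0("W", l)]],
                        params[[paste0("b", l)]])
    r <- pmax(cv$y, 0)
    mp <- maxpool2_forward(r)
    if (keep_cache)
      caches[[l]] <- list(conv = cv, relu_mask = cv$y > 0, pool = mp)
    h <- mp$y
  }
  d <- dim(h)
  hm <- matrix(h, nrow = d[1])                     # B x (H*W*C)
  ## global max pooling: suited to "is a strong local activation present"
  gmp <- matrix(0, d[1], d[4])
  argmax <- matrix(0L, d[1], d[4])
  for (c in seq_len(d[4])) {
    cols <- ((c - 1) * d[2] * d[3] + 1):(c * d[2] * d[3])
    sub <- hm[, cols, drop = FALSE]
    am <- max.col(sub, ties.method = "first")
    gmp[, c] <- sub[cbind(seq_len(d[1]), am)]
    argmax[, c] <- am
  }
  z <- as.numeric(gmp %*% params$Wd + params$bd)
  list(z = z, prob = 1 / (1 + exp(-z)), gap = gmp, argmax = argmax,
       hdim = d, caches = caches)
}

cnn_backward <- function(params, fwd, y) {
  B <- length(y)
  dz <- (fwd$prob - y) / B
  grads <- list(Wd = crossprod(fwd$gap, dz), bd = sum(dz))
  dgap <- dz %*% t(params$Wd)                      # B x C
  d <- fwd$hdim
  dh <- array(0, d)
  hw <- d[2] * d[3]
  dhm <- matrix(0, d[1], hw * d[4])
  for (c in seq_len(d[4]))
    dhm[cbind(seq_len(d[1]), (c - 1) * hw + fwd$argmax[, c])] <- dgap[, c]
  dh <- array(dhm, d)
  for (l in 3:1) {
    ca <- fwd$caches[[l]]
    dr <- maxpool2_backward(ca$pool, dh)
    dconv <- dr * ca$relu_mask
    bk <- conv3_backward(ca$conv, params[[paste0("W", l)]], dconv)
    grads[[paste0("W", l)]] <- bk$dW
    grads[[paste0("b", l)]] <- bk$db
    dh <- bk$dx
  }
  grads
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks a loss; when it fails to improve for `patience` consecutive
#' epochs the learning rate is multiplied by `factor` (never below
#' `min_lr`) and the counter resets.
#'
#' @param lr Initial learning rate.
#' @param factor Reduction factor in (0, 1).
#' @param patience Epochs without improvement before reducing.
#' @param min_lr Lower bound on the learning rate.
#' @return A scheduler object; advance it with [scheduler_step()].
#' @export
plateau_scheduler <- function(lr, factor = 0.8, patience = 10,
                              min_lr = 1e-7) {
  stopifnot(factor > 0, factor < 1, min_lr <= lr)
  structure(list(lr = lr, factor = factor, patience = patience,
                 min_lr = min_lr, best = Inf, wait = 0, reductions = 0),
            class = "plateau_scheduler")
}

#' Advance a plateau scheduler by one epoch
#' @param sched A [plateau_scheduler()].
#' @param loss The epoch's monitored loss.
#' @return The updated scheduler (fields `lr`, `reductions`, `wait`).
#' @export
scheduler_step <- function(sched, loss) {
  if (loss < sched$best - 1e-12) {
    sched$best <- loss
    sched$wait <- 0
  } else {
    sched$wait <- sched$wait + 1
    if (sched$wait >= sched$patience) {
      sched$lr <- max(sched$min_lr, sched$lr * sched$factor)
      sched$reductions <- sched$reductions + 1
      sched$wait <- 0
    }
  }
  sched
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Train the network. x: (N, H, W, 1) array at working resolution; y in 0/1.
cnn_train <- function(x, y, epochs, batch_size, lr, factor = 0.8,
                      patience = 10, min_lr = 1e-7, val_frac = 0.15,
                      seed = 1L, channels = c(8L, 16L, 32L),
                      verbose = FALSE) {
  n <- dim(x)[1]
  set.seed(seed)
  params <- cnn_init(channels, seed = seed)
  state <- adam_init(params)
  n_val <- max(2L, round(val_frac * n))
  val_ix <- sample.int(n, n_val)
  tr_ix <- setdiff(seq_len(n), val_ix)
  xval <- x[val_ix, , , , drop = FALSE]
  yval <- y[val_ix]
  sched <- plateau_scheduler(lr, factor, patience, min_lr)
  best <- list(loss = Inf, params = params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(tr_ix)
    tl <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1, length(ord))]
      xb <- x[ix, , , , drop = FALSE]
      fwd <- cnn_forward(params, xb, keep_cache = TRUE)
      grads <- cnn_backward(params, fwd, y[ix])
      upd <- adam_step(params, grads, state, sched$lr)
      params <- upd$params; state <- upd$state
      tl <- tl + bce_loss(fwd$prob, y[ix]); nb <- nb + 1
    }
    vp <- cnn_forward(params, xval)$prob
    vl <- bce_loss(vp, yval)
    if (vl < best$loss) best <- list(loss = vl, params = params)
    sched <- scheduler_step(sched, vl)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl / nb,
                                         val_loss = vl, lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.2g",
                      ep, tl / nb, vl, sched$lr))
  }
  list(params = best$params, best_val_loss = best$loss, history = history,
       channels = channels)
}

cnn_predict <- function(model, x, batch_size = 128L) {
  n <- dim(x)[1]
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1, n)
    out[ix] <- cnn_forward(model$params, x[ix, , , , drop = FALSE])$prob
  }
  out
}
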