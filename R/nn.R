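# Self-contained dense neural-network engine: batch-norm input layer, dense
# hidden layers, sigmoid output; binary cross-entropy training with Nadam or
# RMSProp. Small fixed topologies (tens of units) aimed at microcontroller
# deployment, so plain R matrix algebra is entirely adequate.

NN_BN_EPS <- 1e-3

act_fun <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         selu = 1.0507009873554805 * ifelse(z > 0, z, 1.6732632423543772 * (exp(z) - 1)),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation: ", act))
}

act_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         tanh = 1 - a^2,
         selu = ifelse(z > 0, 1.0507009873554805,
                       1.0507009873554805 * 1.6732632423543772 * exp(z)),
         sigmoid = a * (1 - a),
         linear = matrix(1, nrow(z), ncol(z)),
         stop("unknown activation: ", act))
}

# Glorot-uniform initialization, Keras-style
nn_init <- function(layer_sizes, activations, n_in, seed) {
  set.seed(seed)
  layers <- list(list(type = "batchnorm",
                      gamma = rep(1, n_in), beta = rep(0, n_in),
                      mean = rep(0, n_in), var = rep(1, n_in), eps = NN_BN_EPS))
  d_prev <- n_in
  for (i in seq_along(layer_sizes)) {
    d <- layer_sizes[i]
    lim <- sqrt(6 / (d_prev + d))
    layers[[length(layers) + 1L]] <- list(
      type = "dense",
      W = matrix(runif(d_prev * d, -lim, lim), nrow = d_prev, ncol = d),
      b = rep(0, d),
      activation = activations[i])
    d_prev <- d
  }
  structure(list(layers = layers, n_in = n_in), class = "wo_nn")
}

# forward pass; training = TRUE uses batch statistics in the batch-norm layer
# and returns the per-layer cache needed by backprop
nn_forward <- function(net, X, training = FALSE) {
  cache <- list()
  A <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "batchnorm") {
      if (training) {
        mu <- colMeans(A)
        v <- colMeans(sweep(A, 2, mu)^2)
      } else {
        mu <- ly$mean
        v <- ly$var
      }
      inv_sd <- 1 / sqrt(v + ly$eps)
      xhat <- sweep(sweep(A, 2, mu), 2, inv_sd, `*`)
      out <- sweep(sweep(xhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
      cache[[i]] <- list(x = A, xhat = xhat, mu = mu, var = v, inv_sd = inv_sd)
      A <- out
    } else {
      Z <- sweep(A %*% ly$W, 2, ly$b, `+`)
      out <- act_fun(Z, ly$activation)
      cache[[i]] <- list(a_prev = A, z = Z, a = out)
      A <- out
    }
  }
  list(out = A, cache = cache)
}

# backprop of the mean binary cross-entropy; returns per-layer gradients
nn_backward <- function(net, cache, y) {
  n_layers <- length(net$layers)
  grads <- vector("list", n_layers)
  p <- cache[[n_layers]]$a
  m <- length(y)
  dZ <- (p - matrix(y, ncol = 1)) / m  # sigmoid + BCE shortcut
  dA <- NULL
  for (i in rev(seq_len(n_layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "dense") {
      if (i < n_layers) {
        dZ <- dA * act_grad(cc$z, cc$a, ly$activation)
      }
      grads[[i]] <- list(W = crossprod(cc$a_prev, dZ), b = colSums(dZ))
      dA <- dZ %*% t(ly$W)
    } else {
      dout <- dA
      mb <- nrow(cc$x)
      dgamma <- colSums(dout * cc$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, ly$gamma, `*`)
      xc <- sweep(cc$x, 2, cc$mu)
      dvar <- colSums(dxhat * xc) * (-0.5) * cc$inv_sd^3
      dmu <- -colSums(dxhat) * cc$inv_sd + dvar * colMeans(-2 * xc)
      dx <- sweep(dxhat, 2, cc$inv_sd, `*`) +
        sweep(xc, 2, 2 * dvar / mb, `*`) +
        matrix(dmu / mb, nrow = mb, ncol = length(dmu), byrow = TRUE)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dA <- dx
    }
  }
  grads
}

make_optimizer <- function(name, lr = 0.001) {
  name <- match.arg(tolower(name), c("nadam", "rmsprop"))
  st <- new.env(parent = emptyenv())
  st$t <- 0
  list(
    name = name,
    step = function(param, grad, key) {
      if (is.null(st[[key]])) {
        st[[key]] <- list(m = array(0, dim = dim(param) %||% length(param)),
                          v = array(0, dim = dim(param) %||% length(param)))
      }
      s <- st[[key]]
      if (name == "rmsprop") {
        s$v <- 0.9 * s$v + 0.1 * grad^2
        upd <- lr * grad / (sqrt(s$v) + 1e-7)
      } else {
        b1 <- 0.9; b2 <- 0.999
        s$m <- b1 * s$m + (1 - b1) * grad
        s$v <- b2 * s$v + (1 - b2) * grad^2
        mhat <- s$m / (1 - b1^(st$t + 1))
        vhat <- s$v / (1 - b2^(st$t + 1))
        upd <- lr * (b1 * mhat + (1 - b1) * grad / (1 - b1^(st$t + 1))) /
          (sqrt(vhat) + 1e-7)
      }
      st[[key]] <- s
      param - upd
    },
    tick = function() st$t <- st$t + 1
  )
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Train with minibatches; one fold of a k-fold split is held out for early
# stopping (epoch selection); batch-norm running statistics are updated with
# momentum as in common deep-learning practice, and the best-epoch weights
# are restored.
nn_train <- function(net, X, y, optimizer = "nadam", lr = 0.001,
                     batch_size = 32L, epochs = 200L, patience = 20L,
                     k_folds = 4L, seed = 1L, bn_momentum = 0.99) {
  set.seed(seed)
  n <- nrow(X)
  fold <- sample(rep_len(seq_len(k_folds), n))
  val_idx <- which(fold == 1L)
  tr_idx <- which(fold != 1L)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  opt <- make_optimizer(optimizer, lr)
  best <- list(loss = Inf, layers = net$layers, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(nrow(Xtr))
    starts <- seq.int(1L, length(ord), by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next  # batch statistics need >= 2 rows
      fw <- nn_forward(net, Xtr[idx, , drop = FALSE], training = TRUE)
      gr <- nn_backward(net, fw$cache, ytr[idx])
      opt$tick()
      for (i in seq_along(net$layers)) {
        ly <- net$layers[[i]]
        if (ly$type == "dense") {
          ly$W <- opt$step(ly$W, gr[[i]]$W, paste0("W", i))
          ly$b <- opt$step(ly$b, gr[[i]]$b, paste0("b", i))
        } else {
          ly$gamma <- opt$step(ly$gamma, gr[[i]]$gamma, paste0("g", i))
          ly$beta <- opt$step(ly$beta, gr[[i]]$beta, paste0("e", i))
          cc <- fw$cache[[i]]
          ly$mean <- bn_momentum * ly$mean + (1 - bn_momentum) * cc$mu
          ly$var <- bn_momentum * ly$var + (1 - bn_momentum) * cc$var
        }
        net$layers[[i]] <- ly
      }
    }
    val_p <- nn_forward(net, Xval)$out
    vloss <- bce_loss(as.numeric(val_p), yval)
    history <- c(history, vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, layers = net$layers, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  net$layers <- best$layers
  net$training <- list(optimizer = optimizer, lr = lr, batch_size = batch_size,
                       epochs_run = length(history), best_epoch = best$epoch,
                       val_loss = best$loss, k_folds = k_folds, seed = seed,
                       history = history)
  net
}

#' Forward pass of a trained dense network
#'
#' Pure function of the stored parameters and the input: batch normalization
#' with the training-set running statistics, the dense chain, and the sigmoid
#' output unit. Returns the probability-like score of the positive class
#' (Pre-levodopa / OFF).
#'
#' @param model A `wo_model` of a dense-NN family (or a raw `wo_nn`).
#' @param x Numeric vector of length `n_in`, or a matrix with one row per
#'   observation.
#' @return Numeric score(s) in (0, 1).
#' @export
forward_dense <- function(model, x) {
  net <- if (inherits(model, "wo_model")) model$fit else model
  if (!inherits(net, "wo_nn")) {
    stop("forward_dense applies to dense-NN models only", call. = FALSE)
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != net$n_in) {
    stop(sprintf("input has %d features; network expects %d", ncol(x), net$n_in),
         call. = FALSE)
  }
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  as.numeric(nn_forward(net, x)$out)
}
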