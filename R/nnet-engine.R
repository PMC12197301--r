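# Minimal convolutional-network engine: 3x3 same-padding convolutions,
# 2x2 max pooling, fully-connected layers, ReLU activations, a sigmoid
# output trained with binary cross-entropy and Adam. Written with
# im2col + BLAS matrix products; gradients are verified against numeric
# differentiation in the test suite. Single-threaded and deterministic
# given a seed.

# im2col linear-index map for a 3x3 same-padding convolution over an
# (h, w, c) array padded by 1. Rows: output pixels (column-major order);
# columns: (di, dj, channel) offsets matching the weight layout.
im2col_index <- function(h, w, c, k = 3L) {
  hp <- h + 2L
  wp <- w + 2L
  i <- rep(seq_len(h), times = w)
  j <- rep(seq_len(w), each = h)
  off <- expand.grid(di = seq_len(k), dj = seq_len(k), ch = seq_len(c))
  idx <- matrix(0L, h * w, k * k * c)
  for (q in seq_len(nrow(off))) {
    idx[, q] <- (i + off$di[q] - 1L) + (j + off$dj[q] - 2L) * hp +
      (off$ch[q] - 1L) * hp * wp
  }
  idx
}

# 2x2 disjoint-window pooling index: n_out x 4 linear indices in the
# (h, w) plane.
pool_index <- function(h, w) {
  ho <- h %/% 2L
  wo <- w %/% 2L
  i <- rep(seq_len(ho), times = wo)
  j <- rep(seq_len(wo), each = ho)
  base_i <- 2L * (i - 1L) + 1L
  base_j <- 2L * (j - 1L) + 1L
  cbind(base_i + (base_j - 1L) * h,
        base_i + 1L + (base_j - 1L) * h,
        base_i + base_j * h,
        base_i + 1L + base_j * h)
}

nn_layer_conv <- function(in_shape, out_c, k = 3L) {
  h <- in_shape[1]; w <- in_shape[2]; c <- in_shape[3]
  fan_in <- k * k * c
  list(type = "conv", h = h, w = w, c = c, out_c = out_c, k = k,
       idx = im2col_index(h, w, c, k),
       W = matrix(rnorm(fan_in * out_c, sd = sqrt(2 / fan_in)),
                  fan_in, out_c),
       b = numeric(out_c),
       out_shape = c(h, w, out_c), trainable = TRUE)
}

nn_layer_pool <- function(in_shape) {
  h <- in_shape[1]; w <- in_shape[2]; c <- in_shape[3]
  list(type = "pool", h = h, w = w, c = c,
       idx = pool_index(h, w),
       out_shape = c(h %/% 2L, w %/% 2L, c), trainable = FALSE)
}

nn_layer_dense <- function(n_in, n_out, activation = "relu") {
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       W = matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out),
       out_shape = n_out, trainable = TRUE)
}

# Build a sequential model. `spec` is a list of lists with $type in
# conv/pool/dense; dense layers follow an implicit flatten. The final
# dense layer must have 1 unit and gets a sigmoid output.
nn_build <- function(input_shape, spec, seed = 1L) {
  set.seed(seed)
  layers <- list()
  shape <- input_shape
  for (s in spec) {
    layer <- switch(s$type,
      conv = nn_layer_conv(shape, s$channels, k = s$k %||% 3L),
      pool = nn_layer_pool(shape),
      dense = nn_layer_dense(prod(shape), s$units,
                             activation = s$activation %||% "relu"))
    shape <- layer$out_shape
    layers[[length(layers) + 1]] <- layer
  }
  stopifnot(tail(layers, 1)[[1]]$type == "dense",
            tail(layers, 1)[[1]]$n_out == 1)
  layers[[length(layers)]]$activation <- "sigmoid"
  structure(list(layers = layers, input_shape = input_shape, seed = seed),
            class = "salivaflow_nn")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward pass for one image (h x w x c array). Returns the sigmoid
# probability and, when `keep = TRUE`, the per-layer caches for backprop.
nn_forward <- function(model, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(model$layers))
  a <- x
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      xp <- array(0, c(l$h + 2L, l$w + 2L, l$c))
      xp[2:(l$h + 1L), 2:(l$w + 1L), ] <- a
      cols <- matrix(as.vector(xp)[as.vector(l$idx)], nrow = l$h * l$w)
      z <- cols %*% l$W + rep(l$b, each = l$h * l$w)
      out <- z * (z > 0)
      if (keep) caches[[li]] <- list(cols = cols, mask = z > 0)
      a <- out
    } else if (l$type == "pool") {
      xv <- as.vector(a)
      plane <- l$h * l$w
      n_out <- nrow(l$idx)
      gath <- lapply(1:4, function(q) {
        matrix(xv[rep(l$idx[, q], l$c) +
                    rep((seq_len(l$c) - 1L) * plane, each = n_out)],
               n_out, l$c)
      })
      mx <- pmax(gath[[1]], gath[[2]], gath[[3]], gath[[4]])
      if (keep) {
        chosen <- matrix(rep(l$idx[, 1], l$c), n_out, l$c)
        taken <- gath[[1]] == mx
        for (q in 2:4) {
          new <- (gath[[q]] == mx) & !taken
          chosen[new] <- matrix(rep(l$idx[, q], l$c), n_out, l$c)[new]
          taken <- taken | new
        }
        chosen <- chosen + rep((seq_len(l$c) - 1L) * plane, each = n_out)
        caches[[li]] <- list(chosen = chosen)
      }
      a <- mx
    } else { # dense
      v <- as.vector(a)
      z <- drop(v %*% l$W) + l$b
      out <- if (l$activation == "sigmoid") 1 / (1 + exp(-z)) else z * (z > 0)
      if (keep) caches[[li]] <- list(x = v, z = z)
      a <- out
    }
  }
  list(prob = as.numeric(a), caches = caches)
}

# Backward pass for one image given forward caches and the target label
# (0/1). Returns the per-layer gradient list (NULL for layers without
# parameters). Uses the combined sigmoid + binary cross-entropy gradient.
nn_backward <- function(model, fwd, y) {
  L <- length(model$layers)
  grads <- vector("list", L)
  delta <- fwd$prob - y     # d(loss)/d(logit) of the sigmoid output
  for (li in rev(seq_len(L))) {
    l <- model$layers[[li]]
    cache <- fwd$caches[[li]]
    if (l$type == "dense") {
      dz <- if (l$activation == "sigmoid") delta else delta * (cache$z > 0)
      grads[[li]] <- list(W = outer(cache$x, dz), b = dz)
      delta <- drop(l$W %*% dz)
    } else if (l$type == "pool") {
      plane_out <- prod(l$out_shape[1:2])
      dout <- matrix(delta, plane_out, l$c)
      dx <- numeric(l$h * l$w * l$c)
      dx[as.vector(cache$chosen)] <- as.vector(dout)
      delta <- dx
    } else { # conv
      dout <- matrix(delta, l$h * l$w, l$out_c) * cache$mask
      grads[[li]] <- list(W = crossprod(cache$cols, dout), b = colSums(dout))
      dcols <- dout %*% t(l$W)
      agg <- rowsum(as.vector(dcols), group = as.vector(l$idx))
      hp <- l$h + 2L; wp <- l$w + 2L
      dxp <- numeric(hp * wp * l$c)
      dxp[as.numeric(rownames(agg))] <- agg
      dxp <- array(dxp, c(hp, wp, l$c))
      delta <- dxp[2:(l$h + 1L), 2:(l$w + 1L), , drop = FALSE]
    }
  }
  grads
}

nn_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

nn_n_params <- function(model, trainable_only = FALSE) {
  sum(map_dbl(model$layers, function(l) {
    if (is.null(l$W) || (trainable_only && !isTRUE(l$trainable))) return(0)
    length(l$W) + length(l$b)
  }))
}

nn_layer_counts <- function(model) {
  types <- map_chr_(model$layers, "type")
  c(conv = sum(types == "conv"), pool = sum(types == "pool"),
    dense = sum(types == "dense"))
}

map_chr_ <- function(x, field) vapply(x, function(e) e[[field]], character(1))

# One Adam training run over a list of images (arrays) and 0/1 labels.
# Deterministic given `seed`. Returns the updated model and a history
# tibble with per-epoch loss and training accuracy.
nn_train <- function(model, images, labels, epochs = 30, batch_size = 32,
                     learning_rate = 1e-3, seed = 1L,
                     beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  stopifnot(length(images) == length(labels), length(unique(labels)) == 2)
  set.seed(seed)
  n <- length(images)
  # Adam state per trainable layer
  state <- lapply(model$layers, function(l) {
    if (is.null(l$W) || !isTRUE(l$trainable)) return(NULL)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  t_step <- 0
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, n)]
      bs <- length(batch)
      acc_grads <- NULL
      for (ix in batch) {
        fwd <- nn_forward(model, images[[ix]], keep = TRUE)
        g <- nn_backward(model, fwd, labels[ix])
        ep_loss <- ep_loss + nn_loss(fwd$prob, labels[ix])
        ep_correct <- ep_correct + ((fwd$prob >= 0.5) == (labels[ix] == 1))
        if (is.null(acc_grads)) {
          acc_grads <- g
        } else {
          for (li in seq_along(g)) {
            if (!is.null(g[[li]])) {
              acc_grads[[li]]$W <- acc_grads[[li]]$W + g[[li]]$W
              acc_grads[[li]]$b <- acc_grads[[li]]$b + g[[li]]$b
            }
          }
        }
      }
      t_step <- t_step + 1
      for (li in seq_along(model$layers)) {
        if (is.null(state[[li]]) || is.null(acc_grads[[li]])) next
        gW <- acc_grads[[li]]$W / bs
        gb <- acc_grads[[li]]$b / bs
        st <- state[[li]]
        st$mW <- beta1 * st$mW + (1 - beta1) * gW
        st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
        st$mb <- beta1 * st$mb + (1 - beta1) * gb
        st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
        mW_hat <- st$mW / (1 - beta1^t_step)
        vW_hat <- st$vW / (1 - beta2^t_step)
        mb_hat <- st$mb / (1 - beta1^t_step)
        vb_hat <- st$vb / (1 - beta2^t_step)
        model$layers[[li]]$W <- model$layers[[li]]$W -
          learning_rate * mW_hat / (sqrt(vW_hat) + adam_eps)
        model$layers[[li]]$b <- model$layers[[li]]$b -
          learning_rate * mb_hat / (sqrt(vb_hat) + adam_eps)
        state[[li]] <- st
      }
    }
    history[[ep]] <- tibble(epoch = ep, loss = ep_loss / n,
                            accuracy = ep_correct / n)
  }
  list(model = model, history = bind_rows(history))
}
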