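# Minimal 1-D convolutional network engine on base R linear algebra.
# Convolutions are im2col + BLAS matrix products; activations are stored as
# 3-D arrays dim c(batch, time, channels).  Each layer is a plain list; the
# forward pass returns (possibly updated) layers so BatchNorm running
# statistics stay value-semantic and a "best epoch" snapshot is just a copy
# of the layer list.

bcast <- function(v, m) rep(v, each = m)  # per-column broadcast over M rows

layer_conv <- function(k, cin, cout, first = FALSE) {
  list(type = "conv", k = k, cin = cin, cout = cout, first = first,
       W = matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                  k * cin, cout),
       b = numeric(cout))
}
layer_bn <- function(c, act = FALSE, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", c = c, act = act, momentum = momentum, eps = eps,
       gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c))
}
layer_relu <- function() list(type = "relu")
layer_pool <- function(p, kind) list(type = "pool", p = p, kind = kind)
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_gap <- function() list(type = "gap")
layer_dense <- function(cin, cout) {
  list(type = "dense",
       W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}
layer_leadconv <- function(n_leads, cin, cout) {
  list(type = "leadconv", n_leads = n_leads, cin = cin, cout = cout,
       W = matrix(stats::rnorm(n_leads * cin * cout, 0, sqrt(2 / (n_leads * cin))),
                  n_leads * cin, cout),
       b = numeric(cout))
}
layer_resblock <- function(k, cin, cout) {
  list(type = "resblock", cin = cin, cout = cout,
       conv1 = layer_conv(k, cin, cout), bn1 = layer_bn(cout, act = TRUE),
       conv2 = layer_conv(k, cout, cout), bn2 = layer_bn(cout),
       proj = if (cin != cout) layer_conv(1L, cin, cout) else NULL)
}

conv_fw <- function(l, x) {
  y <- .conv1d_fw(x, l$W, l$b, l$k)
  list(out = y, cache = x)
}

conv_bw <- function(l, cache, dout) {
  r <- .conv1d_bw(cache, l$W, dout, l$k, need_dx = !isTRUE(l$first))
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

bn_fw <- function(l, x, train) {
  act <- isTRUE(l$act)  # ReLU fused into the kernel
  if (train) {
    r <- .bn_fw_train(x, l$gamma, l$beta, l$eps, act)
    l$running_mean <- l$momentum * l$running_mean + (1 - l$momentum) * r$mean
    l$running_var <- l$momentum * l$running_var + (1 - l$momentum) * r$var
    list(out = r$y,
         cache = list(x = x, mean = r$mean, inv = r$inv,
                      y = if (act) r$y),
         layer = l)
  } else {
    list(out = .bn_fw_eval(x, l$gamma, l$beta, l$running_mean, l$running_var,
                           l$eps, act),
         cache = NULL, layer = l)
  }
}

bn_bw <- function(l, cache, dout) {
  r <- .bn_bw(cache$x, cache$mean, cache$inv, l$gamma, dout, cache$y)
  list(dx = r$dx, grads = list(gamma = r$gamma, beta = r$beta))
}

pool_fw <- function(l, x) {
  r <- .pool_fw(x, l$p, l$kind == "max")
  list(out = r$y, cache = list(am = r$am, Tt = dim(x)[2]))
}

pool_bw <- function(l, cache, dout) {
  list(dx = .pool_bw(dout, cache$am, l$p, cache$Tt, l$kind == "max"),
       grads = NULL)
}

leadconv_fw <- function(l, x) {
  d <- dim(x); L <- l$n_leads; n <- d[1] %/% L; Tt <- d[2]; C <- d[3]
  dim(x) <- c(L, n, Tt, C)
  xp <- aperm(x, c(2, 3, 1, 4))
  dim(xp) <- c(n * Tt, L * C)
  y <- xp %*% l$W + bcast(l$b, n * Tt)
  dim(y) <- c(n, Tt, l$cout)
  list(out = y, cache = list(xp = xp, n = n, Tt = Tt, C = C))
}

leadconv_bw <- function(l, cache, dout) {
  n <- cache$n; Tt <- cache$Tt; C <- cache$C; L <- l$n_leads
  dim(dout) <- c(n * Tt, l$cout)
  grads <- list(W = crossprod(cache$xp, dout), b = colSums(dout))
  dxp <- tcrossprod(dout, l$W)
  dim(dxp) <- c(n, Tt, L, C)
  dx <- aperm(dxp, c(3, 1, 2, 4))
  dim(dx) <- c(L * n, Tt, C)
  list(dx = dx, grads = grads)
}

layer_forward <- function(l, x, train) {
  switch(l$type,
    conv = c(conv_fw(l, x), list(layer = l)),
    bn = bn_fw(l, x, train),
    relu = {
      y <- .relu_fw(x)
      list(out = y, cache = if (train) y else NULL, layer = l)
    },
    pool = c(pool_fw(l, x), list(layer = l)),
    dropout = {
      if (train && l$rate > 0) {
        mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = mask, layer = l)
      } else list(out = x, cache = NULL, layer = l)
    },
    gap = {
      d <- dim(x)
      y <- colMeans(aperm(x, c(2, 1, 3)))
      list(out = y, cache = d, layer = l)
    },
    dense = {
      y <- x %*% l$W + bcast(l$b, nrow(x))
      list(out = y, cache = x, layer = l)
    },
    leadconv = c(leadconv_fw(l, x), list(layer = l)),
    resblock = {
      r1 <- conv_fw(l$conv1, x)
      b1 <- bn_fw(l$bn1, r1$out, train); l$bn1 <- b1$layer
      r2 <- conv_fw(l$conv2, b1$out)
      b2 <- bn_fw(l$bn2, r2$out, train); l$bn2 <- b2$layer
      if (!is.null(l$proj)) {
        pr <- conv_fw(l$proj, x)
        short <- pr$out
        pc <- pr$cache
      } else { short <- x; pc <- NULL }
      out <- .relu_fw(b2$out + short)
      cache <- if (train) list(c1 = r1$cache, b1 = b1$cache,
                               c2 = r2$cache, b2 = b2$cache, pc = pc,
                               out = out)
      list(out = out, cache = cache, layer = l)
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, cache, dout) {
  switch(l$type,
    conv = conv_bw(l, cache, dout),
    bn = bn_bw(l, cache, dout),
    relu = list(dx = .relu_bw(dout, cache), grads = NULL),
    pool = pool_bw(l, cache, dout),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    },
    gap = {
      d <- cache
      dx <- aperm(array(dout / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = tcrossprod(dout, l$W),
           grads = list(W = crossprod(cache, dout), b = colSums(dout)))
    },
    leadconv = leadconv_bw(l, cache, dout),
    resblock = {
      ds <- .relu_bw(dout, cache$out)
      g2 <- bn_bw(l$bn2, cache$b2, ds)
      c2 <- conv_bw(l$conv2, cache$c2, g2$dx)
      g1 <- bn_bw(l$bn1, cache$b1, c2$dx)
      c1 <- conv_bw(l$conv1, cache$c1, g1$dx)
      dx <- c1$dx
      grads <- list(conv1 = c1$grads, bn1 = g1$grads,
                    conv2 = c2$grads, bn2 = g2$grads)
      if (!is.null(l$proj)) {
        pb <- conv_bw(l$proj, cache$pc, ds)
        dx <- dx + pb$dx
        grads$proj <- pb$grads
      } else {
        dx <- dx + ds
      }
      list(dx = dx, grads = grads)
    },
    stop("unknown layer type: ", l$type))
}

nn_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)  # keep NULL placeholders for param-free layers
  }
  grads
}

# named nested list of a layer's trainable arrays (order matters for Adam)
layer_param_names <- list(
  conv = c("W", "b"), dense = c("W", "b"), leadconv = c("W", "b"),
  bn = c("gamma", "beta"))

get_params <- function(l) {
  if (l$type == "resblock") {
    out <- list(conv1 = get_params(l$conv1), bn1 = get_params(l$bn1),
                conv2 = get_params(l$conv2), bn2 = get_params(l$bn2))
    if (!is.null(l$proj)) out$proj <- get_params(l$proj)
    return(out)
  }
  nm <- layer_param_names[[l$type]]
  if (is.null(nm)) return(NULL)
  l[nm]
}

set_params <- function(l, p) {
  if (l$type == "resblock") {
    l$conv1 <- set_params(l$conv1, p$conv1)
    l$bn1 <- set_params(l$bn1, p$bn1)
    l$conv2 <- set_params(l$conv2, p$conv2)
    l$bn2 <- set_params(l$bn2, p$bn2)
    if (!is.null(l$proj)) l$proj <- set_params(l$proj, p$proj)
    return(l)
  }
  for (nm in names(p)) l[[nm]] <- p[[nm]]
  l
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else { z <- p; z[] <- 0; z }
}

adam_rec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      r <- adam_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_update <- function(layers, grads, state, lr, t) {
  for (i in seq_along(layers)) {
    p <- get_params(layers[[i]])
    if (is.null(p)) next
    if (is.null(state[[i]])) state[[i]] <- list(m = zeros_like(p), v = zeros_like(p))
    r <- adam_rec(p, grads[[i]], state[[i]]$m, state[[i]]$v, lr, t)
    layers[[i]] <- set_params(layers[[i]], r$p)
    state[[i]]$m <- r$m
    state[[i]]$v <- r$v
  }
  list(layers = layers, state = state)
}

count_params <- function(layers) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p)) for (q in p) walk(q) else n <<- n + length(p)
  }
  for (l in layers) { p <- get_params(l); if (!is.null(p)) walk(p) }
  n
}

softmax_xent <- function(logits, yi) {
  n <- nrow(logits)
  mx <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - mx)
  s <- rowSums(e)
  p <- e / s
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yi)], 1e-12)))
  dl <- p
  dl[cbind(seq_len(n), yi)] <- dl[cbind(seq_len(n), yi)] - 1
  list(loss = loss, dlogits = dl / n, prob = p)
}

# fold an (8, 2500, n) input into the (8n, 2500, 1) per-lead sequence batch
fold_leads <- function(x) {
  d <- dim(x)
  xb <- aperm(x, c(1, 3, 2))
  dim(xb) <- c(d[1] * d[3], d[2], 1L)
  xb
}

check_input_geometry <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[1] != 8L || d[2] != 2500L) {
    stop("input must be an 8 x 2500 x n array (8 independent leads, 5 s at 500 Hz)")
  }
  x
}
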