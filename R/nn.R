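# Multi-task 3D DenseNet: architecture construction and the forward /
# backward passes.  Activations are arrays dim (D, H, W, C, B); convolution
# and pooling run through the compiled im2col/GEMM kernels.  Parameters and
# batch-norm running statistics live in an environment (net$par) keyed by
# node, so checkpoints are plain named lists.

#' Network / training hyperparameter configuration
#'
#' Defaults follow the reference architecture: growth factor 18, initial
#' 5x5x5 convolution with 8 filters, 3 dense blocks, fully connected widths
#' 512/256/128 (the final 128 being the embedding), exponential linear
#' units, He initialization, Adam with initial learning rate 1e-4 under a
#' cyclic exponentially decaying schedule, batch size 8, up to 250 epochs.
#' Layers per dense block (not fixed by the reference) defaults to 4;
#' transition layers use batch norm + 1x1x1 convolution with compression 0.5
#' + stride-2 average pooling.
#'
#' @param ... overrides for any of the defaults.
#' @return A `model_config` list.
#' @export
model_config <- function(...) {
  cfg <- list(growth = 18L, init_kernel = 5L, init_filters = 8L,
              dense_blocks = 3L, layers_per_block = 4L, compression = 0.5,
              fc_widths = c(512L, 256L, 128L), dropout = 0.2,
              batch_size = 8L, init_lr = 1e-4, lr_decay = 0.98,
              lr_cycle = 20L, max_epochs = 250L, bn_momentum = 0.9,
              class_heads = c("sex", "Da", "Db", "Dg"),
              reg_heads = c("age", "bmi", "insulin_sensitivity", "hba1c"),
              loss_weights = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$growth <= 0) stop("growth factor must be positive")
  w <- cfg$fc_widths
  if (any(diff(w) >= 0) || w[length(w)] != 128L)
    stop("fc_widths must be strictly decreasing and end at the 128-wide embedding")
  if (is.null(cfg$loss_weights))
    cfg$loss_weights <- setNames(rep(1, length(cfg$class_heads) +
                                       length(cfg$reg_heads)),
                                 c(cfg$class_heads, cfg$reg_heads))
  structure(cfg, class = "model_config")
}

# learning rate at a 0-based epoch: exponential decay modulated by a cosine
# cycle rescaled to [0.5, 1]; epoch 0 gives exactly init_lr.
lr_schedule <- function(epoch, cfg) {
  cyc <- 0.5 + 0.25 * (1 + cos(2 * pi * epoch / cfg$lr_cycle))
  cfg$init_lr * cfg$lr_decay^epoch * cyc
}

ceil2 <- function(d) as.integer(ceiling(d / 2))

#' Build the multi-task 3D dense convolutional network
#'
#' Assembles: initial 5x5x5 convolution, batch normalization, ELU, stride-2
#' max pooling; then `dense_blocks` alternating dense blocks (each layer
#' BN-ELU-3x3x3 conv producing `growth` feature maps concatenated onto its
#' input) and transition layers (BN-ELU-1x1x1 conv at compression 0.5,
#' stride-2 average pooling); then flatten and the 512/256/128 fully
#' connected stack with dropout, the 128-vector being the scan embedding.
#' Two-node softmax heads (sex and the three diabetes definitions) and
#' linear regression heads (age, BMI, insulin sensitivity, HbA1c) hang off
#' the embedding.  All kernels use He initialization; the parameter count is
#' a pure function of the configuration.
#'
#' @param cfg a [model_config()].
#' @param input_dims spatial input dimensions (vertical, sagittal, coronal).
#' @param seed RNG seed for initialization.
#' @return An `adiponet_net` (node list + parameter environment).
#' @export
build_model <- function(cfg = model_config(), input_dims, seed = 1L) {
  input_dims <- as.integer(input_dims)
  if (length(input_dims) != 3 || any(input_dims < 1))
    stop("input_dims must be 3 positive integers")
  par <- new.env(parent = emptyenv())
  param_keys <- character(0)
  state_keys <- character(0)
  kid <- 0L
  newkey <- function(what) {
    kid <<- kid + 1L
    sprintf("n%02d_%s", kid, what)
  }
  init_conv <- function(k, cin, cout) {
    Wk <- newkey("W"); bk <- newkey("b")
    par[[Wk]] <- matrix(rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
                        k^3 * cin, cout)
    par[[bk]] <- numeric(cout)
    param_keys <<- c(param_keys, Wk, bk)
    list(W = Wk, b = bk)
  }
  init_bn <- function(c) {
    ks <- lapply(c("g", "be", "rm", "rv"), newkey)
    par[[ks[[1]]]] <- rep(1, c); par[[ks[[2]]]] <- rep(0, c)
    par[[ks[[3]]]] <- rep(0, c); par[[ks[[4]]]] <- rep(1, c)
    param_keys <<- c(param_keys, ks[[1]], ks[[2]])
    state_keys <<- c(state_keys, ks[[3]], ks[[4]])
    list(gamma = ks[[1]], beta = ks[[2]], rm = ks[[3]], rv = ks[[4]])
  }
  init_fc <- function(cin, cout) {
    Wk <- newkey("W"); bk <- newkey("b")
    par[[Wk]] <- matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
    par[[bk]] <- numeric(cout)
    param_keys <<- c(param_keys, Wk, bk)
    list(W = Wk, b = bk)
  }
  nodes <- list()
  with_rng_seed(seed, {
    sp <- input_dims; ch <- 1L
    add <- function(node) nodes[[length(nodes) + 1L]] <<- node
    k0 <- cfg$init_kernel
    add(c(list(type = "conv", k = k0, pad = (k0 - 1L) %/% 2L,
               cin = ch, cout = cfg$init_filters, sp = sp),
          init_conv(k0, ch, cfg$init_filters)))
    ch <- cfg$init_filters
    add(c(list(type = "bn", c = ch, sp = sp), init_bn(ch)))
    add(list(type = "elu"))
    add(list(type = "maxpool", sp = sp, c = ch)); sp <- ceil2(sp)
    for (b in seq_len(cfg$dense_blocks)) {
      for (l in seq_len(cfg$layers_per_block)) {
        add(c(list(type = "dense_unit", k = 3L, pad = 1L, cin = ch,
                   growth = cfg$growth, sp = sp),
              list(bn = init_bn(ch)), init_conv(3L, ch, cfg$growth)))
        ch <- ch + cfg$growth
      }
      cout <- max(1L, as.integer(floor(ch * cfg$compression)))
      add(c(list(type = "bn", c = ch, sp = sp), init_bn(ch)))
      add(list(type = "elu"))
      add(c(list(type = "conv", k = 1L, pad = 0L, cin = ch, cout = cout,
                 sp = sp), init_conv(1L, ch, cout)))
      ch <- cout
      add(list(type = "avgpool", sp = sp, c = ch)); sp <- ceil2(sp)
    }
    nfeat <- prod(sp) * ch
    add(list(type = "flatten", sp = sp, c = ch, nfeat = nfeat))
    prev <- nfeat
    for (w in cfg$fc_widths) {
      add(c(list(type = "fc", cin = prev, cout = w), init_fc(prev, w)))
      add(list(type = "elu"))
      add(list(type = "dropout", rate = cfg$dropout))
      prev <- w
    }
    heads <- list()
    for (h in cfg$class_heads)
      heads[[h]] <- c(list(kind = "class"), init_fc(prev, 2L))
    for (h in cfg$reg_heads)
      heads[[h]] <- c(list(kind = "reg"), init_fc(prev, 1L))
    structure(list(cfg = cfg, input_dims = input_dims, nodes = nodes,
                   heads = heads, par = par, param_keys = param_keys,
                   state_keys = state_keys, embedding_dim = prev,
                   final_sp = sp, final_ch = ch),
              class = "adiponet_net")
  })
}

#' @export
print.adiponet_net <- function(x, ...) {
  cat("<adiponet_net> input", paste(x$input_dims, collapse = "x"),
      "| embedding", x$embedding_dim,
      "|", n_parameters(x), "parameters\n")
  invisible(x)
}

#' Total number of trainable parameters
#' @param net an `adiponet_net`.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$param_keys, function(k) length(net$par[[k]]), numeric(1))) +
    sum(vapply(net$heads, function(h)
      length(net$par[[h$W]]) + length(net$par[[h$b]]), numeric(1)))
}

#' Structural summary of the trunk
#'
#' One row per node with output spatial dims and channel counts; used to
#' inspect concatenative growth and layer widths.
#' @param net an `adiponet_net`.
#' @export
model_summary <- function(net) {
  rows <- list()
  sp <- net$input_dims; ch <- 1L
  for (nd in net$nodes) {
    ch <- switch(nd$type,
                 conv = nd$cout,
                 dense_unit = nd$cin + nd$growth,
                 fc = nd$cout,
                 flatten = nd$nfeat,
                 ch)
    if (nd$type %in% c("maxpool", "avgpool")) sp <- ceil2(sp)
    if (nd$type == "flatten") sp <- c(1L, 1L, 1L)
    rows[[length(rows) + 1L]] <-
      data.frame(type = nd$type, d = sp[1], h = sp[2], w = sp[3],
                 channels = as.integer(ch))
  }
  do.call(rbind, rows)
}

# ---- elementary layer forward/backward ------------------------------------

elu_fw <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
elu_bw <- function(dy, y) {
  d <- dy
  neg <- y < 0
  d[neg] <- dy[neg] * (y[neg] + 1)
  d
}

# channel-major matrix view of an activation array: rows = voxel x batch
to_cmat <- function(x, V, C, B) {
  dim(x) <- c(V, C, B)
  m <- aperm(x, c(1, 3, 2))
  dim(m) <- c(V * B, C)
  m
}
from_cmat <- function(m, V, C, B) {
  dim(m) <- c(V, B, C)
  x <- aperm(m, c(1, 3, 2))
  dim(x) <- c(V, C, B)
  x
}

bn_fw <- function(nd, par, x, V, B, training, momentum) {
  C <- length(par[[nd$gamma]])
  xm <- to_cmat(x, V, C, B)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu^2
    par[[nd$rm]] <- momentum * par[[nd$rm]] + (1 - momentum) * mu
    par[[nd$rv]] <- momentum * par[[nd$rv]] + (1 - momentum) * va
  } else {
    mu <- par[[nd$rm]]; va <- par[[nd$rv]]
  }
  ivar <- 1 / sqrt(va + 1e-5)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, par[[nd$gamma]], `*`), 2, par[[nd$beta]], `+`)
  list(y = from_cmat(y, V, C, B),
       cache = list(xhat = xhat, ivar = ivar, training = training, C = C))
}

bn_bw <- function(nd, par, cache, dy, V, B) {
  C <- cache$C
  dym <- to_cmat(dy, V, C, B)
  gamma <- par[[nd$gamma]]
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    dxhat <- sweep(dym, 2, gamma, `*`)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dxm <- sweep(sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, `*`),
                 2, cache$ivar, `*`)
  } else {
    dxm <- sweep(dym, 2, gamma * cache$ivar, `*`)
  }
  list(dx = from_cmat(dxm, V, C, B), dgamma = dgamma, dbeta = dbeta)
}

# ---- trunk forward ---------------------------------------------------------

# x: array (D, H, W, B); returns embedding, per-head outputs, and (optionally)
# the caches required for the backward pass.
nn_forward <- function(net, x, training = FALSE, keep_cache = TRUE) {
  d <- dim(x)
  if (length(d) == 3) { B <- 1L; dim(x) <- c(d, 1L) } else B <- d[4]
  if (!all(dim(x)[1:3] == net$input_dims))
    stop("input dims ", paste(dim(x)[1:3], collapse = "x"),
         " do not match network input ",
         paste(net$input_dims, collapse = "x"))
  par <- net$par
  mom <- net$cfg$bn_momentum
  caches <- if (keep_cache) vector("list", length(net$nodes))
  cur <- x
  dim(cur) <- c(net$input_dims, 1L, B)
  sp <- net$input_dims; ch <- 1L
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    V <- prod(sp)
    if (nd$type == "conv") {
      y <- cpp_conv3d_forward(as.double(cur), par[[nd$W]], par[[nd$b]],
                              sp, nd$cin, B, nd$k, nd$pad)
      if (keep_cache) caches[[i]] <- list(x = cur)
      cur <- y; dim(cur) <- c(sp, nd$cout, B); ch <- nd$cout
    } else if (nd$type == "bn") {
      r <- bn_fw(nd, par, cur, V, B, training, mom)
      cur <- r$y; dim(cur) <- c(sp, ch, B)
      if (keep_cache) caches[[i]] <- r$cache
    } else if (nd$type == "elu") {
      cur <- elu_fw(cur)
      if (keep_cache) caches[[i]] <- list(y = cur)
    } else if (nd$type == "maxpool") {
      r <- cpp_maxpool3d_forward(as.double(cur), sp, ch, B)
      if (keep_cache) caches[[i]] <- list(idx = r$idx, sp = sp)
      sp <- ceil2(sp)
      cur <- r$y; dim(cur) <- c(sp, ch, B)
    } else if (nd$type == "avgpool") {
      cur <- cpp_avgpool3d_forward(as.double(cur), sp, ch, B)
      if (keep_cache) caches[[i]] <- list(sp = sp)
      sp <- ceil2(sp)
      dim(cur) <- c(sp, ch, B)
    } else if (nd$type == "dense_unit") {
      r1 <- bn_fw(nd$bn, par, cur, V, B, training, mom)
      t2 <- elu_fw(r1$y)
      t3 <- cpp_conv3d_forward(as.double(t2), par[[nd$W]], par[[nd$b]],
                               sp, nd$cin, B, nd$k, nd$pad)
      y <- array(0, c(V, nd$cin + nd$growth, B))
      dim(cur) <- c(V, nd$cin, B)
      y[, seq_len(nd$cin), ] <- cur
      y[, nd$cin + seq_len(nd$growth), ] <- t3
      if (keep_cache) caches[[i]] <- list(bn = r1$cache, t2 = t2)
      cur <- y; ch <- nd$cin + nd$growth
      dim(cur) <- c(sp, ch, B)
    } else if (nd$type == "flatten") {
      m <- matrix(as.double(cur), ncol = B)
      cur <- t(m)
      if (keep_cache) caches[[i]] <- list(sp = sp, c = ch)
    } else if (nd$type == "fc") {
      y <- cur %*% par[[nd$W]]
      y <- sweep(y, 2, par[[nd$b]], `+`)
      if (keep_cache) caches[[i]] <- list(x = cur)
      cur <- y
    } else if (nd$type == "dropout") {
      if (training && nd$rate > 0) {
        mask <- matrix(runif(length(cur)) >= nd$rate, nrow(cur), ncol(cur))
        cur <- cur * mask / (1 - nd$rate)
        if (keep_cache) caches[[i]] <- list(mask = mask, rate = nd$rate)
      } else if (keep_cache) caches[[i]] <- list(mask = NULL)
    }
  }
  emb <- cur
  class_logits <- list(); class_probs <- list(); reg <- list()
  for (h in names(net$heads)) {
    hd <- net$heads[[h]]
    z <- sweep(emb %*% par[[hd$W]], 2, par[[hd$b]], `+`)
    if (hd$kind == "class") {
      zs <- z - apply(z, 1, max)
      e <- exp(zs)
      class_probs[[h]] <- e / rowSums(e)
      class_logits[[h]] <- z
    } else reg[[h]] <- z[, 1]
  }
  list(embedding = emb, class_probs = class_probs,
       class_logits = class_logits, reg = reg,
       caches = caches, B = B, training = training)
}

# Backward through the trunk given the gradient at the embedding.
# Returns gradients for all trunk parameters (named by key) and, when
# need_dx, the gradient with respect to the input volume batch.
nn_backward <- function(net, fw, d_embedding, need_dx = FALSE) {
  par <- net$par
  B <- fw$B
  grads <- new.env(parent = emptyenv())
  cur <- d_embedding
  sp <- net$final_sp
  # channel trace per node, replayed backwards
  for (i in rev(seq_along(net$nodes))) {
    nd <- net$nodes[[i]]
    cc <- fw$caches[[i]]
    if (nd$type == "fc") {
      grads[[nd$W]] <- crossprod(cc$x, cur)
      grads[[nd$b]] <- colSums(cur)
      cur <- cur %*% t(par[[nd$W]])
    } else if (nd$type == "dropout") {
      if (!is.null(cc$mask)) cur <- cur * cc$mask / (1 - cc$rate)
    } else if (nd$type == "elu") {
      cur <- elu_bw(cur, cc$y)
    } else if (nd$type == "flatten") {
      cur <- t(cur)
      dim(cur) <- c(cc$sp, cc$c, B)
      sp <- cc$sp
    } else if (nd$type == "conv") {
      if (i == 1 && !need_dx) {
        # still need parameter gradients for the first layer
        r <- cpp_conv3d_backward(as.double(cc$x), par[[nd$W]],
                                 as.double(cur), sp, nd$cin, B, nd$k, nd$pad)
        grads[[nd$W]] <- r$dw; grads[[nd$b]] <- r$db
        cur <- NULL
      } else {
        r <- cpp_conv3d_backward(as.double(cc$x), par[[nd$W]],
                                 as.double(cur), sp, nd$cin, B, nd$k, nd$pad)
        grads[[nd$W]] <- r$dw; grads[[nd$b]] <- r$db
        cur <- r$dx
        dim(cur) <- c(sp, nd$cin, B)
      }
    } else if (nd$type == "bn") {
      r <- bn_bw(nd, par, cc, cur, prod(sp), B)
      grads[[nd$gamma]] <- r$dgamma; grads[[nd$beta]] <- r$dbeta
      cur <- r$dx
      dim(cur) <- c(sp, length(r$dgamma), B)
    } else if (nd$type == "maxpool") {
      cur <- cpp_maxpool3d_backward(as.double(cur), cc$idx, cc$sp,
                                    dim(cur)[4], B)
      sp <- cc$sp
      dim(cur) <- c(sp, length(cur) / prod(sp) / B, B)
    } else if (nd$type == "avgpool") {
      cur <- cpp_avgpool3d_backward(as.double(cur), cc$sp, dim(cur)[4], B)
      sp <- cc$sp
      dim(cur) <- c(sp, length(cur) / prod(sp) / B, B)
    } else if (nd$type == "dense_unit") {
      V <- prod(sp)
      dim(cur) <- c(V, nd$cin + nd$growth, B)
      dy1 <- cur[, seq_len(nd$cin), , drop = FALSE]
      dyn <- cur[, nd$cin + seq_len(nd$growth), , drop = FALSE]
      r <- cpp_conv3d_backward(as.double(cc$t2), par[[nd$W]],
                               as.double(dyn), sp, nd$cin, B, nd$k, nd$pad)
      grads[[nd$W]] <- r$dw; grads[[nd$b]] <- r$db
      dt2 <- r$dx
      dim(dt2) <- dim(cc$t2)
      dt1 <- elu_bw(dt2, cc$t2)   # t2 is the post-ELU activation
      rb <- bn_bw(nd$bn, par, cc$bn, dt1, V, B)
      grads[[nd$bn$gamma]] <- rb$dgamma; grads[[nd$bn$beta]] <- rb$dbeta
      dx <- rb$dx
      dim(dx) <- c(V, nd$cin, B)
      cur <- dy1 + dx
      dim(cur) <- c(sp, nd$cin, B)
    }
    if (is.null(cur)) break
  }
  dx <- NULL
  if (need_dx && !is.null(cur)) {
    dx <- cur
    dim(dx) <- c(net$input_dims, B)
  }
  list(grads = grads, dx = dx)
}

# Snapshot / restore of all parameters and running statistics.
net_snapshot <- function(net) {
  keys <- c(net$param_keys, net$state_keys,
            unlist(lapply(net$heads, function(h) c(h$W, h$b))))
  setNames(lapply(keys, function(k) net$par[[k]]), keys)
}

net_restore <- function(net, snapshot) {
  for (k in names(snapshot)) net$par[[k]] <- snapshot[[k]]
  invisible(net)
}
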