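# Minimal layer stack with hand-rolled backprop: im2col convolution (stride
# 1, zero "same" padding), ReLU, 2x2 average pooling, flatten, dense. Every
# gradient is verified against finite differences in the test suite. Arrays
# are per-sample H x W x C; dense activations are plain vectors.

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

layer_conv <- function(in_ch, filters, kernel) {
  list(type = "conv", kernel = kernel, in_ch = in_ch, filters = filters,
       W = he_init(kernel * kernel * in_ch, filters, kernel * kernel * in_ch),
       b = numeric(filters))
}
layer_dense <- function(in_dim, units) {
  list(type = "dense", W = he_init(in_dim, units, in_dim), b = numeric(units))
}

im2col <- function(x, k, pad) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  padded <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
  padded[pad + seq_len(h), pad + seq_len(w), ] <- x
  cols <- matrix(0, h * w, k * k * cin)
  idx <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    idx <- idx + 1L
    cols[, idx] <- padded[ki + seq_len(h) - 1L, kj + seq_len(w) - 1L, ci]
  }
  cols
}

col2im <- function(dcols, h, w, cin, k, pad) {
  dpad <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
  idx <- 0L
  for (ci in seq_len(cin)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    idx <- idx + 1L
    ri <- ki + seq_len(h) - 1L; cj <- kj + seq_len(w) - 1L
    dpad[ri, cj, ci] <- dpad[ri, cj, ci] + matrix(dcols[, idx], h, w)
  }
  dpad[pad + seq_len(h), pad + seq_len(w), , drop = FALSE]
}

conv_forward <- function(layer, x) {
  d <- dim(x); k <- layer$kernel; pad <- k %/% 2L
  cols <- im2col(x, k, pad)
  out <- cols %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = array(out, c(d[1], d[2], layer$filters)),
       cache = list(cols = cols, dim_in = d))
}

conv_backward <- function(layer, cache, dout) {
  d <- cache$dim_in
  dmat <- matrix(dout, d[1] * d[2], layer$filters)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(layer$W)
  dx <- col2im(dcols, d[1], d[2], d[3], layer$kernel, layer$kernel %/% 2L)
  list(dW = dW, db = db, dx = dx)
}

pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stopf("2x2 average pooling needs even spatial dimensions, got %dx%d",
          d[1], d[2])
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  out <- (x[i1, j1, , drop = FALSE] + x[i2, j1, , drop = FALSE] +
          x[i1, j2, , drop = FALSE] + x[i2, j2, , drop = FALSE]) / 4
  list(out = out, cache = d)
}

pool_backward <- function(cache, dout) {
  d <- cache
  dout[rep(seq_len(d[1] %/% 2L), each = 2L),
       rep(seq_len(d[2] %/% 2L), each = 2L), , drop = FALSE] / 4
}

# ---- small CNN: conv blocks -> flatten -> dense feature layer -> head ----

cnn_init <- function(input_shape, conv_filters = c(4L, 8L, 8L), kernel = 3L,
                     feature_dim = 16L, num_classes, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    in_ch <- input_shape[3]
    h <- input_shape[1]; w <- input_shape[2]
    for (f in conv_filters) {
      layers <- c(layers, list(layer_conv(in_ch, f, kernel)),
                  list(list(type = "relu")), list(list(type = "pool")))
      in_ch <- f; h <- h %/% 2L; w <- w %/% 2L
      if (h < 1 || w < 1) stopf("too many pooling stages for input size")
    }
    flat_dim <- h * w * in_ch
    layers <- c(layers, list(list(type = "flatten")),
                list(layer_dense(flat_dim, feature_dim)),
                list(list(type = "relu")))
    structure(list(layers = layers,
                   head = layer_dense(feature_dim, num_classes),
                   input_shape = as.integer(input_shape),
                   feature_dim = as.integer(feature_dim),
                   num_classes = as.integer(num_classes)),
              class = "histosdl_cnn")
  })
}

# scale [0,255] intensities to a centred range for the network input
normalise_image <- function(img) unclass(img) / 255 - 0.5

cnn_forward <- function(net, x) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_forward(ly, x); caches[[i]] <- r$cache; x <- r$out
    } else if (ly$type == "relu") {
      caches[[i]] <- x > 0; x <- pmax(x, 0)
    } else if (ly$type == "pool") {
      r <- pool_forward(x); caches[[i]] <- r$cache; x <- r$out
    } else if (ly$type == "flatten") {
      caches[[i]] <- dim(x); x <- as.vector(x)
    } else if (ly$type == "dense") {
      caches[[i]] <- x; x <- drop(x %*% ly$W) + ly$b
    }
  }
  feature <- x
  logits <- drop(feature %*% net$head$W) + net$head$b
  list(feature = feature, logits = logits, caches = caches)
}

# dlogits: gradient at the logits; dfeature_extra: extra gradient injected
# at the feature layer (the synergic supervision path)
cnn_backward <- function(net, fwd, dlogits, dfeature_extra = NULL) {
  grads <- list(layers = vector("list", length(net$layers)))
  grads$head <- list(dW = outer(fwd$feature, dlogits), db = dlogits)
  dx <- drop(net$head$W %*% dlogits)
  if (!is.null(dfeature_extra)) dx <- dx + dfeature_extra
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]; ca <- fwd$caches[[i]]
    if (ly$type == "conv") {
      r <- conv_backward(ly, ca, dx)
      grads$layers[[i]] <- list(dW = r$dW, db = r$db); dx <- r$dx
    } else if (ly$type == "relu") {
      dx <- dx * ca
    } else if (ly$type == "pool") {
      dx <- pool_backward(ca, dx)
    } else if (ly$type == "flatten") {
      dx <- array(dx, ca)
    } else if (ly$type == "dense") {
      grads$layers[[i]] <- list(dW = outer(ca, dx), db = dx)
      dx <- drop(ly$W %*% dx)
    }
  }
  grads
}

cnn_update <- function(net, grads, lr) {
  for (i in seq_along(net$layers)) {
    g <- grads$layers[[i]]
    if (!is.null(g)) {
      net$layers[[i]]$W <- net$layers[[i]]$W - lr * g$dW
      net$layers[[i]]$b <- net$layers[[i]]$b - lr * g$db
    }
  }
  net$head$W <- net$head$W - lr * grads$head$dW
  net$head$b <- net$head$b - lr * grads$head$db
  net
}

cnn_zero_grads <- function(net) {
  grads <- list(layers = vector("list", length(net$layers)))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "dense"))
      grads$layers[[i]] <- list(dW = ly$W * 0, db = ly$b * 0)
  }
  grads$head <- list(dW = net$head$W * 0, db = net$head$b * 0)
  grads
}

grads_add <- function(a, b) {
  for (i in seq_along(a$layers)) {
    if (!is.null(b$layers[[i]])) {
      a$layers[[i]]$dW <- a$layers[[i]]$dW + b$layers[[i]]$dW
      a$layers[[i]]$db <- a$layers[[i]]$db + b$layers[[i]]$db
    }
  }
  a$head$dW <- a$head$dW + b$head$dW
  a$head$db <- a$head$db + b$head$db
  a
}

grads_scale <- function(a, s) {
  for (i in seq_along(a$layers)) {
    if (!is.null(a$layers[[i]])) {
      a$layers[[i]]$dW <- a$layers[[i]]$dW * s
      a$layers[[i]]$db <- a$layers[[i]]$db * s
    }
  }
  a$head$dW <- a$head$dW * s
  a$head$db <- a$head$db * s
  a
}

# parameter vector round-trips, used by the finite-difference checks
cnn_get_params <- function(net) {
  ps <- list()
  for (ly in net$layers) if (ly$type %in% c("conv", "dense"))
    ps <- c(ps, list(as.vector(ly$W)), list(ly$b))
  ps <- c(ps, list(as.vector(net$head$W)), list(net$head$b))
  unlist(ps)
}

cnn_set_params <- function(net, theta) {
  pos <- 0L
  take <- function(n) {
    out <- unname(theta[pos + seq_len(n)]); pos <<- pos + n; out
  }
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type %in% c("conv", "dense")) {
      net$layers[[i]]$W <- matrix(take(length(ly$W)), nrow(ly$W), ncol(ly$W))
      net$layers[[i]]$b <- take(length(ly$b))
    }
  }
  net$head$W <- matrix(take(length(net$head$W)),
                       nrow(net$head$W), ncol(net$head$W))
  net$head$b <- take(length(net$head$b))
  stopifnot(pos == length(theta))
  net
}

grads_get_vector <- function(net, grads) {
  ps <- list()
  for (i in seq_along(net$layers)) {
    g <- grads$layers[[i]]
    if (!is.null(g)) ps <- c(ps, list(as.vector(g$dW)), list(g$db))
  }
  ps <- c(ps, list(as.vector(grads$head$dW)), list(grads$head$db))
  unlist(ps)
}

# ---- synergic network: two FC+ReLU layers, then one sigmoid unit ----

snet_init <- function(in_dim, hidden = c(16L, 8L), seed = 1L) {
  with_seed(seed, {
    structure(list(l1 = layer_dense(in_dim, hidden[1]),
                   l2 = layer_dense(hidden[1], hidden[2]),
                   out = layer_dense(hidden[2], 1L),
                   in_dim = as.integer(in_dim)),
              class = "histosdl_snet")
  })
}

snet_forward <- function(sn, fab) {
  if (length(fab) != sn$in_dim)
    stopf("synergic net expects input length %d, got %d",
          sn$in_dim, length(fab))
  a1 <- drop(fab %*% sn$l1$W) + sn$l1$b; h1 <- pmax(a1, 0)
  a2 <- drop(h1 %*% sn$l2$W) + sn$l2$b;  h2 <- pmax(a2, 0)
  z <- drop(h2 %*% sn$out$W) + sn$out$b
  yhat <- clamp(sigmoid(z), 1e-7, 1 - 1e-7)
  list(yhat = yhat, cache = list(fab = fab, a1 = a1, h1 = h1,
                                 a2 = a2, h2 = h2, z = z))
}

# dz: gradient at the pre-sigmoid unit (for BCE, yhat - ys)
snet_backward <- function(sn, cache, dz) {
  g_out <- list(dW = cbind(cache$h2 * dz), db = dz)
  dh2 <- drop(sn$out$W * dz) * (cache$a2 > 0)
  g_l2 <- list(dW = outer(cache$h1, dh2), db = dh2)
  dh1 <- drop(sn$l2$W %*% dh2) * (cache$a1 > 0)
  g_l1 <- list(dW = outer(cache$fab, dh1), db = dh1)
  dfab <- drop(sn$l1$W %*% dh1)
  list(grads = list(l1 = g_l1, l2 = g_l2, out = g_out), dfab = dfab)
}

snet_update <- function(sn, grads, lr) {
  for (nm in c("l1", "l2", "out")) {
    sn[[nm]]$W <- sn[[nm]]$W - lr * grads[[nm]]$dW
    sn[[nm]]$b <- sn[[nm]]$b - lr * grads[[nm]]$db
  }
  sn
}

snet_zero_grads <- function(sn) {
  lapply(stats::setNames(c("l1", "l2", "out"), c("l1", "l2", "out")),
         function(nm) list(dW = sn[[nm]]$W * 0, db = sn[[nm]]$b * 0))
}

snet_grads_add <- function(a, b) {
  for (nm in c("l1", "l2", "out")) {
    a[[nm]]$dW <- a[[nm]]$dW + b[[nm]]$dW
    a[[nm]]$db <- a[[nm]]$db + b[[nm]]$db
  }
  a
}

snet_grads_scale <- function(a, s) {
  for (nm in c("l1", "l2", "out")) {
    a[[nm]]$dW <- a[[nm]]$dW * s
    a[[nm]]$db <- a[[nm]]$db * s
  }
  a
}

snet_get_params <- function(sn) {
  unlist(lapply(c("l1", "l2", "out"),
                function(nm) c(as.vector(sn[[nm]]$W), sn[[nm]]$b)))
}

snet_set_params <- function(sn, theta) {
  pos <- 0L
  for (nm in c("l1", "l2", "out")) {
    n <- length(sn[[nm]]$W)
    sn[[nm]]$W <- matrix(unname(theta[pos + seq_len(n)]),
                         nrow(sn[[nm]]$W), ncol(sn[[nm]]$W))
    pos <- pos + n
    n <- length(sn[[nm]]$b)
    sn[[nm]]$b <- unname(theta[pos + seq_len(n)])
    pos <- pos + n
  }
  stopifnot(pos == length(theta))
  sn
}

snet_grads_vector <- function(grads) {
  unlist(lapply(c("l1", "l2", "out"),
                function(nm) c(as.vector(grads[[nm]]$dW), grads[[nm]]$db)))
}
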