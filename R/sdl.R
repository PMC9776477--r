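#' Configuration for a synergic deep learning ensemble
#'
#' A synergic deep learning (SDL) ensemble holds `k` convolutional network
#' components trained jointly: every unordered pair of components feeds a
#' small fully-connected "synergic network" ending in a sigmoid unit, which
#' predicts whether the pair's two inputs share a class. The synergic
#' binary cross-entropy adds corrective pairwise supervision, weighted by
#' `lambda`, to each component's own cross-entropy gradient.
#'
#' The desk-scale backbone is a small 3-conv-block CNN (conv + ReLU + 2x2
#' average pool per block), then a dense feature layer (the penultimate
#' activations are the feature vectors handed to the LSTM head) and a
#' linear classification head. Backbone width/depth are configurable; the
#' synergic mechanism, not the backbone, is what this package implements.
#'
#' @param k number of CNN components (>= 2).
#' @param num_classes number of classes K (>= 2).
#' @param input_shape integer `c(H, W, C)` of the (preprocessed) images.
#' @param conv_filters filter counts per conv block; length sets the number
#'   of blocks (each halves the spatial size).
#' @param kernel odd conv kernel size.
#' @param feature_dim dimension of the feature vectors.
#' @param snet_hidden widths of the two fully-connected synergic layers.
#' @param lambda trade-off between component classification error and
#'   synergic error (>= 0; 0 disables synergic supervision).
#' @param lr learning rate, either a positive scalar or a function of the
#'   update step `z` returning a positive scalar (SGD schedule).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed governing initialisation and shuffling.
#' @return an `sdl_config` list.
#' @export
sdl_config <- function(k = 2L, num_classes = 2L,
                       input_shape = c(16L, 16L, 3L),
                       conv_filters = c(4L, 8L, 8L), kernel = 3L,
                       feature_dim = 16L, snet_hidden = c(16L, 8L),
                       lambda = 0.5, lr = 0.1, batch_size = 8L,
                       epochs = 20L, seed = 1L) {
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (!is_count(num_classes) || num_classes < 2) stopf("num_classes >= 2")
  if (lambda < 0) stopf("lambda must be >= 0")
  lr_schedule <- if (is.function(lr)) lr else function(z) lr
  if (lr_schedule(1) <= 0) stopf("learning rate must be positive")
  structure(list(k = as.integer(k), num_classes = as.integer(num_classes),
                 input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 feature_dim = as.integer(feature_dim),
                 snet_hidden = as.integer(snet_hidden),
                 lambda = lambda, lr_schedule = lr_schedule,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "sdl_config")
}

component_pairs <- function(k) {
  if (k < 2) return(matrix(integer(0), 0, 2))
  t(utils::combn(k, 2L))
}

# build untrained components + C(k,2) synergic nets from a config
sdl_init <- function(config) {
  comps <- lapply(seq_len(config$k), function(a) {
    cnn_init(config$input_shape, config$conv_filters, config$kernel,
             config$feature_dim, config$num_classes,
             seed = derive_seed(config$seed, a))
  })
  pairs <- component_pairs(config$k)
  snets <- lapply(seq_len(nrow(pairs)), function(p) {
    snet_init(2L * config$feature_dim, config$snet_hidden,
              seed = derive_seed(config$seed, 1000L + p))
  })
  list(components = comps, synergic_nets = snets, pairs = pairs)
}

#' Cross-entropy loss
#'
#' Mean over the batch of the negative log softmax probability of the true
#' class, computed with the log-sum-exp trick.
#'
#' @param logits numeric `M x K` matrix (or a K-vector for one sample).
#' @param labels integer class indices in `1..K`.
#' @return nonnegative scalar loss.
#' @examples
#' ce_loss(rbind(c(0, 0)), 1)  # log(2)
#' @export
ce_loss <- function(logits, labels) {
  if (is.vector(logits)) logits <- matrix(logits, 1)
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits)) stopf("one label per logit row")
  K <- ncol(logits)
  if (any(labels < 1 | labels > K))
    stopf("label out of range 1..%d", K)
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[cbind(seq_along(labels), labels)])
}

#' Synergic label of an input pair
#'
#' 1 when the two inputs share a class, 0 otherwise — the target of the
#' synergic networks.
#'
#' @param yA,yB class indices.
#' @return 0 or 1.
#' @export
synergic_label <- function(yA, yB) as.integer(yA == yB)

#' Synergic network forward pass
#'
#' Concatenates the two feature vectors in fixed pair order and pushes them
#' through the synergic network's two fully-connected ReLU layers and the
#' final sigmoid unit, returning the probability that the pair shares a
#' class (clamped to `[1e-7, 1 - 1e-7]`).
#'
#' @param fA,fB feature vectors of equal length.
#' @param snet a synergic network (from an [sdl_train()] fit, or internal).
#' @return scalar in (0, 1).
#' @export
synergic_forward <- function(fA, fB, snet) {
  if (length(fA) != length(fB)) stopf("feature vectors must match in length")
  snet_forward(snet, c(fA, fB))$yhat
}

#' Synergic binary cross-entropy loss
#'
#' `-(ys log yhat + (1 - ys) log(1 - yhat))`, the nonnegative loss the
#' synergic networks minimise.
#'
#' @param yhat predicted same-class probability in (0, 1) (clamped).
#' @param ys synergic label, 0 or 1.
#' @return nonnegative scalar.
#' @export
synergic_bce_loss <- function(yhat, ys) {
  yhat <- clamp(yhat, 1e-7, 1 - 1e-7)
  -(ys * log(yhat) + (1 - ys) * log(1 - yhat))
}

# ---- training ----

# Normalise a data tibble (image list-column + label) into internal form.
sdl_prepare_data <- function(data, label_col = "label", levels = NULL) {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  labels_raw <- data[[label_col]]
  if (is.null(labels_raw)) stopf("data needs a `%s` column", label_col)
  if (is.null(levels)) {
    levels <- if (is.factor(labels_raw)) base::levels(labels_raw)
              else sort(unique(as.character(labels_raw)))
  }
  y <- match(as.character(labels_raw), levels)
  if (anyNA(y)) stopf("labels outside the fitted class levels")
  x <- lapply(data$image, function(im) normalise_image(image_grid(im)))
  list(x = x, y = y, levels = levels)
}

#' Train a synergic deep learning ensemble
#'
#' Jointly trains the `k` CNN components and the `k(k-1)/2` synergic
#' networks by minibatch SGD. Per batch, each component accrues its own
#' cross-entropy gradient plus `lambda` times the gradients of the synergic
#' losses of every pair containing it (differentiated through its feature
#' vectors); each synergic network accrues its own loss gradient. Within a
#' batch every ordered sample pair `(i, j), i < j` supervises every
#' component pair.
#'
#' @param data tibble with an `image` list-column and a label column.
#' @param config an [sdl_config()]; `num_classes` must match the data.
#' @param label_col name of the label column (default `"label"`).
#' @return an object of class `sdl_fit`: trained model, class levels, and a
#'   per-epoch loss trace tibble (`epoch`, `ce_loss`, `synergic_loss`,
#'   `total_loss`).
#' @seealso [sdl_predict()], [sdl_extract_features()]
#' @export
sdl_train <- function(data, config, label_col = "label") {
  prep <- sdl_prepare_data(data, label_col)
  if (length(prep$levels) != config$num_classes)
    stopf("data has %d classes but config says %d",
          length(prep$levels), config$num_classes)
  if (length(prep$x) == 0) stopf("empty training data")
  if (length(unique(prep$y)) < 2) stopf("need >= 2 classes present")
  model <- sdl_init(config)
  out <- train_core(model$components, model$synergic_nets, model$pairs,
                    prep$x, prep$y, config)
  structure(list(components = out$components,
                 synergic_nets = out$synergic_nets,
                 pairs = model$pairs, config = config,
                 levels = prep$levels, trace = out$trace, trained = TRUE),
            class = "sdl_fit")
}

# Shared SGD loop. With a single component (or lambda = 0) this is plain
# CNN training — the synergic terms vanish identically, which the test
# suite exploits for the bitwise-reduction check.
train_core <- function(comps, snets, pairs, x, y, config) {
  k <- length(comps)
  n <- length(x)
  K <- config$num_classes
  lambda <- config$lambda
  use_syn <- lambda > 0 && k >= 2
  z <- 0L
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, 5000L + epoch), sample.int(n))
    ep_ce <- 0; ep_syn <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(batch)
      # forward every component on every sample in the batch
      fwd <- lapply(comps, function(net)
        lapply(batch, function(i) cnn_forward(net, x[[i]])))
      yb <- y[batch]
      # CE gradients at the logits
      comp_grads <- lapply(comps, cnn_zero_grads)
      dfeat <- lapply(seq_len(k), function(a)
        lapply(seq_len(B), function(i) numeric(config$feature_dim)))
      ce_batch <- 0
      dlogits <- vector("list", k)
      for (a in seq_len(k)) {
        dlogits[[a]] <- vector("list", B)
        for (i in seq_len(B)) {
          p <- softmax(fwd[[a]][[i]]$logits)
          ce_batch <- ce_batch - log(p[yb[i]])
          g <- p; g[yb[i]] <- g[yb[i]] - 1
          dlogits[[a]][[i]] <- g / B
        }
      }
      ce_batch <- ce_batch / (B * k)
      # synergic supervision over all intra-batch sample pairs
      syn_batch <- 0
      snet_grads <- NULL
      if (use_syn && B >= 2) {
        snet_grads <- lapply(snets, snet_zero_grads)
        n_sp <- B * (B - 1) / 2
        for (p in seq_len(nrow(pairs))) {
          a <- pairs[p, 1]; b <- pairs[p, 2]
          for (i in seq_len(B - 1L)) for (j in seq((i + 1L), B)) {
            fab <- c(fwd[[a]][[i]]$feature, fwd[[b]][[j]]$feature)
            sf <- snet_forward(snets[[p]], fab)
            ys <- synergic_label(yb[i], yb[j])
            syn_batch <- syn_batch + synergic_bce_loss(sf$yhat, ys)
            dz_s <- (sf$yhat - ys) / n_sp
            bk <- snet_backward(snets[[p]], sf$cache, dz_s)
            snet_grads[[p]] <- snet_grads_add(snet_grads[[p]], bk$grads)
            Fd <- config$feature_dim
            dfeat[[a]][[i]] <- dfeat[[a]][[i]] + lambda * bk$dfab[seq_len(Fd)]
            dfeat[[b]][[j]] <- dfeat[[b]][[j]] + lambda * bk$dfab[Fd + seq_len(Fd)]
          }
        }
        syn_batch <- syn_batch / (n_sp * nrow(pairs))
      }
      # component backward + accumulate
      for (a in seq_len(k)) {
        for (i in seq_len(B)) {
          extra <- if (use_syn) dfeat[[a]][[i]] else NULL
          g <- cnn_backward(comps[[a]], fwd[[a]][[i]],
                            dlogits[[a]][[i]], extra)
          comp_grads[[a]] <- grads_add(comp_grads[[a]], g)
        }
      }
      if (!is.finite(ce_batch) || !is.finite(syn_batch))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      # SGD step with the learning-rate schedule
      z <- z + 1L
      eta <- config$lr_schedule(z)
      for (a in seq_len(k)) comps[[a]] <- cnn_update(comps[[a]],
                                                     comp_grads[[a]], eta)
      if (!is.null(snet_grads)) {
        for (p in seq_along(snets))
          snets[[p]] <- snet_update(snets[[p]], snet_grads[[p]], eta)
      }
      ep_ce <- ep_ce + ce_batch; ep_syn <- ep_syn + syn_batch
      n_batches <- n_batches + 1L
    }
    trace[[epoch]] <- tibble::tibble(
      epoch = epoch,
      ce_loss = ep_ce / n_batches,
      synergic_loss = ep_syn / n_batches,
      total_loss = (ep_ce + lambda * ep_syn) / n_batches)
  }
  list(components = comps, synergic_nets = snets,
       trace = dplyr::bind_rows(trace))
}

# Full-batch loss and analytic gradients, used by the finite-difference
# gradient checks: components against CE + lambda * synergic, synergic nets
# against the synergic loss alone.
sdl_loss_and_grads <- function(comps, snets, pairs, x, y, config) {
  k <- length(comps); B <- length(x)
  lambda <- config$lambda
  fwd <- lapply(comps, function(net) lapply(x, function(xi)
    cnn_forward(net, xi)))
  comp_grads <- lapply(comps, cnn_zero_grads)
  snet_grads <- lapply(snets, snet_zero_grads)
  dfeat <- lapply(seq_len(k), function(a)
    lapply(seq_len(B), function(i) numeric(config$feature_dim)))
  ce <- 0
  dlogits <- lapply(seq_len(k), function(a) vector("list", B))
  for (a in seq_len(k)) for (i in seq_len(B)) {
    p <- softmax(fwd[[a]][[i]]$logits)
    ce <- ce - log(p[y[i]])
    g <- p; g[y[i]] <- g[y[i]] - 1
    dlogits[[a]][[i]] <- g / B
  }
  ce <- ce / (B * k)  # reported per-component mean
  syn <- 0
  n_sp <- max(1, B * (B - 1) / 2)
  if (k >= 2 && B >= 2) {
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      for (i in seq_len(B - 1L)) for (j in seq((i + 1L), B)) {
        fab <- c(fwd[[a]][[i]]$feature, fwd[[b]][[j]]$feature)
        sf <- snet_forward(snets[[p]], fab)
        ys <- synergic_label(y[i], y[j])
        syn <- syn + synergic_bce_loss(sf$yhat, ys)
        dz_s <- (sf$yhat - ys) / n_sp
        bk <- snet_backward(snets[[p]], sf$cache, dz_s)
        snet_grads[[p]] <- snet_grads_add(snet_grads[[p]], bk$grads)
        Fd <- config$feature_dim
        dfeat[[a]][[i]] <- dfeat[[a]][[i]] + lambda * bk$dfab[seq_len(Fd)]
        dfeat[[b]][[j]] <- dfeat[[b]][[j]] + lambda * bk$dfab[Fd + seq_len(Fd)]
      }
    }
    syn <- syn / n_sp
  }
  for (a in seq_len(k)) for (i in seq_len(B)) {
    g <- cnn_backward(comps[[a]], fwd[[a]][[i]], dlogits[[a]][[i]],
                      dfeat[[a]][[i]])
    comp_grads[[a]] <- grads_add(comp_grads[[a]], g)
  }
  list(ce = ce, synergic = syn,
       total = ce * k + lambda * syn,  # sum over components + weighted pairs
       comp_grads = comp_grads, snet_grads = snet_grads)
}

#' Fuse component probability vectors
#'
#' The ensemble decision rule: sum the k components' class-probability
#' vectors and take the argmax (ties broken toward the lowest class
#' index).
#'
#' @param probs `k x K` matrix, one row per component.
#' @return list with `class` (index) and `fused` (the column sums).
#' @examples
#' fuse_probabilities(rbind(c(0.6, 0.4), c(0.3, 0.7)))$class  # 2
#' @export
fuse_probabilities <- function(probs) {
  if (is.vector(probs)) probs <- matrix(probs, 1)
  fused <- colSums(probs)
  list(class = which.max(fused), fused = fused)
}

check_trained <- function(model) {
  if (!inherits(model, "sdl_fit") || !isTRUE(model$trained))
    stopf("model is not a trained `sdl_fit`")
}

#' Predict classes with a trained SDL ensemble
#'
#' Each component emits softmax class probabilities; the ensemble sums them
#' across components and predicts the argmax (ties broken toward the lowest
#' class index). The returned `.pred_*` columns are the fused probabilities
#' rescaled to sum to 1.
#'
#' @param model a trained [sdl_train()] fit.
#' @param data tibble with an `image` list-column (a single [image_grid()]
#'   is also accepted).
#' @return tibble with `.pred_class` and one `.pred_<level>` column per
#'   class.
#' @export
sdl_predict <- function(model, data) {
  check_trained(model)
  if (inherits(data, "image_grid") || is.array(data) || is.matrix(data))
    data <- tibble::tibble(image = list(data))
  x <- lapply(data$image, function(im) normalise_image(image_grid(im)))
  K <- model$config$num_classes
  per_sample <- lapply(x, function(xi) {
    fuse_probabilities(t(vapply(model$components, function(net)
      softmax(cnn_forward(net, xi)$logits), numeric(K))))
  })
  fused <- do.call(rbind, lapply(per_sample, `[[`, "fused"))
  probs <- fused / rowSums(fused)
  cls <- vapply(per_sample, `[[`, 1L, "class")
  out <- tibble::tibble(.pred_class = factor(model$levels[cls],
                                             levels = model$levels))
  colnames(probs) <- paste0(".pred_", model$levels)
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Extract SDL feature sequences
#'
#' Returns, per image, the ordered sequence of the `k` components'
#' penultimate-layer feature vectors — the input consumed by the LSTM
#' classification head.
#'
#' @inheritParams sdl_predict
#' @return tibble with a `features` list-column of `k x feature_dim`
#'   matrices (row `a` = component `a`'s feature vector).
#' @export
sdl_extract_features <- function(model, data) {
  check_trained(model)
  if (inherits(data, "image_grid") || is.array(data) || is.matrix(data))
    data <- tibble::tibble(image = list(data))
  x <- lapply(data$image, function(im) normalise_image(image_grid(im)))
  feats <- lapply(x, function(xi) {
    do.call(rbind, lapply(model$components, function(net)
      cnn_forward(net, xi)$feature))
  })
  tibble::tibble(features = feats)
}

#' @export
print.sdl_fit <- function(x, ...) {
  cat(sprintf(
    "<sdl_fit: k = %d components, %d synergic nets, %d classes, %d epochs>\n",
    x$config$k, length(x$synergic_nets), x$config$num_classes,
    x$config$epochs))
  cat(sprintf("  final losses: ce %.4f, synergic %.4f\n",
              utils::tail(x$trace$ce_loss, 1),
              utils::tail(x$trace$synergic_loss, 1)))
  invisible(x)
}

#' Save or load a pipeline checkpoint
#'
#' Serialises fitted model objects (SDL ensemble, LSTM head, class levels)
#' into a single archive file.
#'
#' @param object list or fit object to store.
#' @param path file path.
#' @return `load_checkpoint()` returns the stored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
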