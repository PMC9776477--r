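small_cfg <- function(lambda = 0.5) {
  sdl_config(k = 2, num_classes = 2, input_shape = c(8L, 8L, 1L),
             conv_filters = c(3L, 4L), feature_dim = 6L,
             snet_hidden = c(6L, 4L), lambda = lambda, lr = 0.1,
             batch_size = 4L, epochs = 4L, seed = 77)
}

random_batch <- function(n = 12, seed = 2, classes = c("a", "b")) {
  set.seed(seed)
  tibble::tibble(
    image = lapply(seq_len(n), function(i)
      image_grid(array(sample(0:255, 64, TRUE), c(8, 8, 1)))),
    label = factor(rep_len(classes, n)))
}

test_that("cross-entropy matches a hand-coded log-sum-exp oracle", {
  expect_equal(ce_loss(c(0, 0), 1), log(2))
  expect_equal(ce_loss(c(1e4, 0), 1), 0, tolerance = 1e-12)
  set.seed(3)
  Z <- matrix(rnorm(12), 4, 3)
  y <- c(1, 3, 2, 2)
  oracle <- mean(vapply(1:4, function(i) {
    p <- exp(Z[i, ]) / sum(exp(Z[i, ]))
    -log(p[y[i]])
  }, numeric(1)))
  expect_equal(ce_loss(Z, y), oracle, tolerance = 1e-10)
  expect_error(ce_loss(Z, c(1, 2, 3, 4)), "out of range")
})

test_that("synergic label is the equality predicate, exhaustively for K = 8", {
  expect_identical(synergic_label(1, 1), 1L)
  expect_identical(synergic_label(1, 2), 0L)
  for (a in 1:8) for (b in 1:8) {
    expect_identical(synergic_label(a, b), as.integer(a == b))
  }
})

test_that("synergic forward is a checked FC+sigmoid computation", {
  sn <- histosdl:::snet_init(8L, c(5L, 3L), seed = 4)
  # zero parameters give sigmoid(0) = 0.5
  sn0 <- histosdl:::snet_set_params(
    sn, numeric(length(histosdl:::snet_get_params(sn))))
  expect_equal(synergic_forward(rnorm(4), rnorm(4), sn0), 0.5)
  # matrix-multiply + sigmoid oracle
  set.seed(9)
  fA <- rnorm(4); fB <- rnorm(4)
  fab <- c(fA, fB)
  h1 <- pmax(drop(fab %*% sn$l1$W) + sn$l1$b, 0)
  h2 <- pmax(drop(h1 %*% sn$l2$W) + sn$l2$b, 0)
  yhat <- 1 / (1 + exp(-(drop(h2 %*% sn$out$W) + sn$out$b)))
  expect_equal(synergic_forward(fA, fB, sn), unname(yhat), tolerance = 1e-12)
  expect_error(synergic_forward(rnorm(3), rnorm(4), sn), "match")
})

test_that("synergic BCE has its closed-form values and clamps", {
  expect_equal(synergic_bce_loss(0.5, 1), log(2))
  expect_equal(synergic_bce_loss(0.9, 0), -log(0.1), tolerance = 1e-12)
  expect_equal(synergic_bce_loss(1, 1), -log(1 - 1e-7), tolerance = 1e-12)
  expect_gte(synergic_bce_loss(0.2, 0), 0)
})

test_that("the ensemble holds k(k-1)/2 synergic nets for k = 2..5", {
  for (k in 2:5) {
    cfg <- sdl_config(k = k, num_classes = 2, input_shape = c(8L, 8L, 1L),
                      conv_filters = c(2L), feature_dim = 4L, seed = 1)
    model <- histosdl:::sdl_init(cfg)
    expect_length(model$synergic_nets, k * (k - 1) / 2)
    expect_identical(model$pairs, t(utils::combn(k, 2L)))
  }
})

test_that("with lambda = 0 each component reduces bitwise to solo SGD", {
  data <- random_batch(12)
  cfg <- small_cfg(lambda = 0)
  fit <- sdl_train(data, cfg)
  prep <- histosdl:::sdl_prepare_data(data, "label")
  for (a in 1:2) {
    comp <- histosdl:::cnn_init(cfg$input_shape, cfg$conv_filters,
                                cfg$kernel, cfg$feature_dim,
                                cfg$num_classes,
                                seed = histosdl:::derive_seed(cfg$seed, a))
    solo <- histosdl:::train_core(list(comp), NULL,
                                  matrix(integer(0), 0, 2),
                                  prep$x, prep$y, cfg)
    expect_identical(
      histosdl:::cnn_get_params(solo$components[[1]]),
      histosdl:::cnn_get_params(fit$components[[a]]))
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- sdl_config(k = 2, num_classes = 3, input_shape = c(8L, 8L, 1L),
                    conv_filters = c(3L, 4L), feature_dim = 5L,
                    snet_hidden = c(6L, 4L), lambda = 0.7, seed = 3)
  model <- histosdl:::sdl_init(cfg)
  set.seed(42)
  x <- lapply(1:3, function(i) array(rnorm(64), c(8, 8, 1)))
  y <- c(1, 2, 3)
  comps <- model$components; snets <- model$synergic_nets
  lg <- histosdl:::sdl_loss_and_grads(comps, snets, model$pairs, x, y, cfg)
  eps <- 1e-5
  # component parameters against the full lambda-weighted loss
  total <- function(cs, ss) {
    out <- histosdl:::sdl_loss_and_grads(cs, ss, model$pairs, x, y, cfg)
    out$ce * cfg$k + cfg$lambda * out$synergic
  }
  th <- histosdl:::cnn_get_params(comps[[1]])
  g_an <- histosdl:::grads_get_vector(comps[[1]], lg$comp_grads[[1]])
  idx <- sample(length(th), 25)
  for (i in idx) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    fd <- (total(list(histosdl:::cnn_set_params(comps[[1]], tp), comps[[2]]),
                 snets) -
           total(list(histosdl:::cnn_set_params(comps[[1]], tm), comps[[2]]),
                 snets)) / (2 * eps)
    expect_equal(unname(g_an[i]), fd, tolerance = 1e-4)
  }
  # synergic-net parameters against the synergic loss (their own update)
  syn_only <- function(ss)
    histosdl:::sdl_loss_and_grads(comps, ss, model$pairs, x, y, cfg)$synergic
  ths <- histosdl:::snet_get_params(snets[[1]])
  gs_an <- histosdl:::snet_grads_vector(lg$snet_grads[[1]])
  for (i in sample(length(ths), 15)) {
    tp <- ths; tp[i] <- tp[i] + eps
    tm <- ths; tm[i] <- tm[i] - eps
    fd <- (syn_only(list(histosdl:::snet_set_params(snets[[1]], tp))) -
           syn_only(list(histosdl:::snet_set_params(snets[[1]], tm)))) /
      (2 * eps)
    expect_equal(unname(gs_an[i]), fd, tolerance = 1e-4)
  }
})

test_that("training descends on a separable synthetic set", {
  man <- generate_dataset(synth_config(two_class_spec(c(15L, 15L)),
                                       image_size = c(16L, 16L), seed = 11))
  man$label <- factor(man$subclass)
  cfg <- sdl_config(k = 2, num_classes = 2, input_shape = c(16L, 16L, 3L),
                    lambda = 0.5, lr = 0.1, batch_size = 8L, epochs = 8L,
                    seed = 5)
  fit <- sdl_train(man, cfg)
  expect_lt(utils::tail(fit$trace$ce_loss, 1), fit$trace$ce_loss[1])
  expect_true(all(is.finite(fit$trace$total_loss)))
  pred <- sdl_predict(fit, man)
  expect_equal(mean(pred$.pred_class == man$label), 1)
})

test_that("prediction fuses component probabilities by summed argmax", {
  expect_equal(fuse_probabilities(rbind(c(0.9, 0.1), c(0.8, 0.2)))$class, 1)
  expect_equal(fuse_probabilities(rbind(c(0.6, 0.4), c(0.3, 0.7)))$class, 2)
  set.seed(8)
  probs <- matrix(runif(12), 3, 4)
  out <- fuse_probabilities(probs)
  expect_equal(out$fused, colSums(probs))
  expect_equal(out$class, which.max(colSums(probs)))
  # permutation of component order leaves the fused sums unchanged
  expect_equal(fuse_probabilities(probs[c(3, 1, 2), ])$fused, out$fused)
  # exact tie breaks toward the lowest class index
  expect_equal(fuse_probabilities(rbind(c(0.5, 0.5)))$class, 1)
})

test_that("feature extraction is deterministic with k rows per image", {
  data <- random_batch(8)
  for (k in 2:3) {
    cfg <- sdl_config(k = k, num_classes = 2, input_shape = c(8L, 8L, 1L),
                      conv_filters = c(3L), feature_dim = 6L,
                      batch_size = 4L, epochs = 2L, seed = 9)
    fit <- sdl_train(data, cfg)
    f1 <- sdl_extract_features(fit, data[1, ])
    f2 <- sdl_extract_features(fit, data[1, ])
    expect_identical(f1$features, f2$features)
    expect_identical(dim(f1$features[[1]]), c(k, 6L))
  }
})

test_that("untrained models and bad inputs error cleanly", {
  expect_error(sdl_predict(list(), tibble::tibble()), "trained")
  data <- random_batch(6)
  expect_error(sdl_train(data[0, ], small_cfg()), "empty|classes")
  one_class <- data; one_class$label <- factor(rep("a", 6))
  expect_error(sdl_train(one_class, small_cfg()), "classes")
  expect_error(sdl_config(k = 1), "k must be")
  expect_error(sdl_config(lambda = -1), "lambda")
})
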