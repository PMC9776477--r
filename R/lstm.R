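#' LSTM parameters
#'
#' A single vanilla LSTM cell plus a linear classification head. The four
#' gates (forget, input, candidate, output) each hold a weight matrix over
#' the concatenation `[h_{t-1}, x_t]` and a bias vector; the head maps the
#' final hidden state to K class scores.
#'
#' @param input_size length of each input feature vector `x_t`.
#' @param hidden_size hidden/cell state dimension.
#' @param num_classes K.
#' @param seed integer seed for the Gaussian initialisation.
#' @param init_sd standard deviation of the initial weights; `0` gives the
#'   all-zero network (useful for closed-form checks).
#' @return an `lstm_params` list with elements `Wf, Wi, Wc, Wo`
#'   (`hidden_size x (hidden_size + input_size)`), `bf, bi, bc, bo`,
#'   `Wh` (`num_classes x hidden_size`), `bh`.
#' @export
lstm_params <- function(input_size, hidden_size = 16L, num_classes = 2L,
                        seed = 1L, init_sd = NULL) {
  d <- hidden_size + input_size
  if (is.null(init_sd)) init_sd <- 1 / sqrt(d)
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  with_seed(seed, {
    structure(list(
      Wf = mk(hidden_size, d), Wi = mk(hidden_size, d),
      Wc = mk(hidden_size, d), Wo = mk(hidden_size, d),
      bf = numeric(hidden_size), bi = numeric(hidden_size),
      bc = numeric(hidden_size), bo = numeric(hidden_size),
      Wh = mk(num_classes, hidden_size), bh = numeric(num_classes),
      input_size = as.integer(input_size),
      hidden_size = as.integer(hidden_size),
      num_classes = as.integer(num_classes)), class = "lstm_params")
  })
}

#' One LSTM time step
#'
#' The standard gated update: forget gate `f_t = sigmoid(Wf [h_{t-1}, x_t]
#' + bf)`, input gate `i_t` likewise, candidate `C~_t = tanh(Wc [...] +
#' bc)`, cell `C_t = f_t * C_{t-1} + i_t * C~_t`, output gate `o_t`, hidden
#' `h_t = o_t * tanh(C_t)`.
#'
#' @param x_t input vector of length `input_size`.
#' @param state list with `C` and `h` vectors (zeros at t = 0), e.g.
#'   [lstm_zero_state()].
#' @param params an [lstm_params()].
#' @return list `C`, `h` (plus a `cache` attribute used by training).
#' @export
lstm_step <- function(x_t, state, params) {
  if (length(x_t) != params$input_size)
    stopf("x_t has length %d, expected %d", length(x_t), params$input_size)
  if (length(state$h) != params$hidden_size)
    stopf("hidden state has length %d, expected %d",
          length(state$h), params$hidden_size)
  z <- c(state$h, x_t)
  f <- sigmoid(drop(params$Wf %*% z) + params$bf)
  i <- sigmoid(drop(params$Wi %*% z) + params$bi)
  ctilde <- tanh(drop(params$Wc %*% z) + params$bc)
  C <- f * state$C + i * ctilde
  o <- sigmoid(drop(params$Wo %*% z) + params$bo)
  h <- o * tanh(C)
  out <- list(C = C, h = h)
  attr(out, "cache") <- list(z = z, f = f, i = i, ctilde = ctilde,
                             o = o, C = C, C_prev = state$C)
  out
}

#' @rdname lstm_step
#' @export
lstm_zero_state <- function(params) {
  list(C = numeric(params$hidden_size), h = numeric(params$hidden_size))
}

lstm_forward <- function(features, params) {
  state <- lstm_zero_state(params)
  caches <- vector("list", nrow(features))
  for (t in seq_len(nrow(features))) {
    state <- lstm_step(features[t, ], state, params)
    caches[[t]] <- attr(state, "cache")
  }
  scores <- softmax(drop(params$Wh %*% state$h) + params$bh)
  list(scores = scores, h = state$h, caches = caches)
}

#' Classify a feature sequence with an LSTM head
#'
#' Runs [lstm_step()] over the rows of `features` (t = 1..k), applies the
#' linear head and softmax to the final hidden state, and predicts the
#' argmax class (ties broken toward the lowest index).
#'
#' @param features `k x input_size` matrix — one row per time step (the k
#'   SDL component feature vectors, in component order).
#' @param params an [lstm_params()].
#' @return list with `class` (index) and `scores` (softmax K-vector).
#' @export
lstm_classify <- function(features, params) {
  if (is.vector(features)) features <- matrix(features, 1)
  if (nrow(features) == 0) stopf("empty feature sequence")
  fw <- lstm_forward(features, params)
  list(class = which.max(fw$scores), scores = fw$scores)
}

# loss + full analytic gradient (BPTT); loss = "squared" is the mean
# squared distance between the softmax output and the one-hot target,
# "ce" the usual cross-entropy
lstm_loss_and_grads <- function(params, features_list, y, loss = "squared") {
  N <- length(features_list)
  K <- params$num_classes
  g <- lapply(params[c("Wf", "Wi", "Wc", "Wo", "Wh")], function(m) m * 0)
  gb <- lapply(params[c("bf", "bi", "bc", "bo", "bh")], function(v) v * 0)
  Hd <- params$hidden_size
  total <- 0
  for (n in seq_len(N)) {
    fw <- lstm_forward(features_list[[n]], params)
    s <- fw$scores
    onehot <- numeric(K); onehot[y[n]] <- 1
    if (loss == "squared") {
      total <- total + sum((s - onehot)^2) / N
      ds <- 2 * (s - onehot) / N
      dzs <- s * (ds - sum(ds * s))       # through softmax
    } else {
      total <- total - log(s[y[n]]) / N
      dzs <- (s - onehot) / N
    }
    g$Wh <- g$Wh + outer(dzs, fw$h)
    gb$bh <- gb$bh + dzs
    dh <- drop(crossprod(params$Wh, dzs))
    dC <- numeric(Hd)
    for (t in rev(seq_along(fw$caches))) {
      ca <- fw$caches[[t]]
      tC <- tanh(ca$C)
      do <- dh * tC
      dC <- dC + dh * ca$o * (1 - tC^2)
      df <- dC * ca$C_prev
      di <- dC * ca$ctilde
      dct <- dC * ca$i
      da_f <- df * ca$f * (1 - ca$f)
      da_i <- di * ca$i * (1 - ca$i)
      da_c <- dct * (1 - ca$ctilde^2)
      da_o <- do * ca$o * (1 - ca$o)
      g$Wf <- g$Wf + outer(da_f, ca$z); gb$bf <- gb$bf + da_f
      g$Wi <- g$Wi + outer(da_i, ca$z); gb$bi <- gb$bi + da_i
      g$Wc <- g$Wc + outer(da_c, ca$z); gb$bc <- gb$bc + da_c
      g$Wo <- g$Wo + outer(da_o, ca$z); gb$bo <- gb$bo + da_o
      dz <- drop(crossprod(params$Wf, da_f) + crossprod(params$Wi, da_i) +
                 crossprod(params$Wc, da_c) + crossprod(params$Wo, da_o))
      dh <- dz[seq_len(Hd)]
      dC <- dC * ca$f
    }
  }
  list(loss = total, grads = c(g, gb))
}

lstm_apply_grads <- function(params, grads, lr) {
  for (nm in c("Wf", "Wi", "Wc", "Wo", "Wh", "bf", "bi", "bc", "bo", "bh"))
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

lstm_get_params <- function(params) {
  unlist(params[c("Wf", "Wi", "Wc", "Wo", "Wh",
                  "bf", "bi", "bc", "bo", "bh")])
}

lstm_set_params <- function(params, theta) {
  pos <- 0L
  for (nm in c("Wf", "Wi", "Wc", "Wo", "Wh", "bf", "bi", "bc", "bo", "bh")) {
    n <- length(params[[nm]])
    v <- unname(theta[pos + seq_len(n)])
    params[[nm]] <- if (is.matrix(params[[nm]]))
      matrix(v, nrow(params[[nm]]), ncol(params[[nm]])) else v
    pos <- pos + n
  }
  stopifnot(pos == length(theta))
  params
}

#' Train the LSTM classification head
#'
#' Minimises, by minibatch SGD with backpropagation through time, the
#' squared distance between the softmax output and the one-hot target
#' (mean over samples); cross-entropy is available via `loss = "ce"` for
#' practical training.
#'
#' @param data tibble with a `features` list-column (from
#'   [sdl_extract_features()]; `k x input_size` matrices) and a label
#'   column.
#' @param hidden_size hidden dimension.
#' @param lr SGD learning rate (a zero rate leaves the parameters
#'   untouched).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param loss `"squared"` (default) or `"ce"`.
#' @param seed integer seed (initialisation and shuffling).
#' @param label_col label column name.
#' @return an `lstm_fit`: trained `params`, class `levels`, and a loss
#'   `trace` tibble.
#' @export
lstm_train <- function(data, hidden_size = 16L, lr = 0.5, epochs = 100L,
                       batch_size = 16L, loss = c("squared", "ce"),
                       seed = 1L, label_col = "label") {
  loss <- match.arg(loss)
  stopifnot(is.data.frame(data), "features" %in% names(data))
  labels_raw <- data[[label_col]]
  levels <- if (is.factor(labels_raw)) base::levels(labels_raw)
            else sort(unique(as.character(labels_raw)))
  if (length(levels) < 2) stopf("need >= 2 classes present")
  y <- match(as.character(labels_raw), levels)
  feats <- lapply(data$features, function(f) {
    if (is.vector(f)) matrix(f, 1) else as.matrix(f)
  })
  params <- lstm_params(ncol(feats[[1]]), hidden_size, length(levels),
                        seed = derive_seed(seed, 1L))
  n <- length(feats)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 6000L + ep), sample.int(n))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      lg <- lstm_loss_and_grads(params, feats[batch], y[batch], loss)
      if (!is.finite(lg$loss)) stopf("LSTM training diverged at epoch %d", ep)
      params <- lstm_apply_grads(params, lg$grads, lr)
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    trace[ep] <- ep_loss / nb
  }
  structure(list(params = params, levels = levels,
                 trace = tibble::tibble(epoch = seq_len(epochs),
                                        loss = trace),
                 loss = loss, trained = TRUE),
            class = "lstm_fit")
}

#' Predict with a trained LSTM head
#'
#' @param model an [lstm_train()] fit.
#' @param data tibble with a `features` list-column.
#' @return tibble with `.pred_class` and `.pred_<level>` score columns.
#' @export
lstm_predict <- function(model, data) {
  stopifnot(inherits(model, "lstm_fit"))
  K <- model$params$num_classes
  scores <- t(vapply(data$features, function(f) {
    lstm_classify(as.matrix(f), model$params)$scores
  }, numeric(K)))
  cls <- apply(scores, 1, which.max)
  out <- tibble::tibble(.pred_class = factor(model$levels[cls],
                                             levels = model$levels))
  colnames(scores) <- paste0(".pred_", model$levels)
  dplyr::bind_cols(out, tibble::as_tibble(scores))
}

#' @export
print.lstm_fit <- function(x, ...) {
  cat(sprintf("<lstm_fit: hidden %d, %d classes, %s loss, final %.5f>\n",
              x$params$hidden_size, x$params$num_classes, x$loss,
              utils::tail(x$trace$loss, 1)))
  invisible(x)
}
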