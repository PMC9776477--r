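# Shared fixtures and independent oracles, all generated in code.

# a separable two-class texture spec (bright sparse vs dark dense)
two_class_spec <- function(count = c(45L, 45L)) {
  tibble::tibble(
    name = c("ben", "mal"), superclass = c("benign", "malignant"),
    count = count,
    base_r = c(230, 150), base_g = c(195, 110), base_b = c(215, 170),
    density = c(1.2, 5.0), radius = c(1.8, 2.5), bg_len = c(4, 4))
}

rand_image <- function(h = 16, w = 16, ch = 1, seed = 1) {
  set.seed(seed)
  image_grid(array(sample(0:255, h * w * ch, replace = TRUE), c(h, w, ch)))
}

# denoising fixture: smooth, dark textures where impulse corruption is the
# dominant error source (the zero-padded median biases bright borders
# toward 0 and erodes fine high-frequency blob texture, so the L1 noise-
# reduction property is asserted where a practitioner would apply the
# filter: on images whose structure is coarser than the 3x3 kernel)
smooth_dark_spec <- function(count = c(3L, 3L)) {
  tibble::tibble(
    name = c("ben", "mal"), superclass = c("benign", "malignant"),
    count = count,
    base_r = c(60, 35), base_g = c(45, 25), base_b = c(70, 45),
    density = c(0.3, 0.6), radius = c(3, 3.5), bg_len = c(6, 8))
}

# brute-force median filter: explicit window gather + sort, per pixel
oracle_median_filter <- function(img, k) {
  d <- dim(img)
  p <- k %/% 2
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    m <- unclass(img)[, , ch]
    pm <- matrix(0, d[1] + 2 * p, d[2] + 2 * p)
    pm[p + seq_len(d[1]), p + seq_len(d[2])] <- m
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      w <- sort(as.vector(pm[i:(i + k - 1), j:(j + k - 1)]))
      out[i, j, ch] <- w[(k * k + 1) / 2]
    }
  }
  out
}

# scalar-loop LSTM step: every dot product written out by hand
oracle_lstm_step <- function(x, C_prev, h_prev, p) {
  Hd <- p$hidden_size
  z <- c(h_prev, x)
  gate <- function(W, b, act) {
    out <- numeric(Hd)
    for (j in seq_len(Hd)) {
      s <- b[j]
      for (m in seq_along(z)) s <- s + W[j, m] * z[m]
      out[j] <- act(s)
    }
    out
  }
  sig <- function(v) 1 / (1 + exp(-v))
  f <- gate(p$Wf, p$bf, sig)
  i <- gate(p$Wi, p$bi, sig)
  ct <- gate(p$Wc, p$bc, tanh)
  o <- gate(p$Wo, p$bo, sig)
  C <- f * C_prev + i * ct
  list(C = C, h = o * tanh(C))
}

# record every position a fitness function is asked to evaluate
recording_fitness <- function(f) {
  env <- new.env()
  env$positions <- list()
  fn <- function(x) {
    env$positions[[length(env$positions) + 1L]] <- x
    f(x)
  }
  list(fn = fn, env = env)
}

sphere <- function(x) sum(x^2)
shifted_sphere <- function(x) sum((x - 1.5)^2)
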