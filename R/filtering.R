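#' Median of a kernel window
#'
#' The order statistic used by the median filter: the middle element of the
#' sorted window when `n` is odd, and the mean of the two middle elements
#' when `n` is even. For the default odd-sized kernels the result is always
#' a value present in the window — unlike a Gaussian or box filter, which can
#' introduce intensities absent from the original image.
#'
#' @param values numeric vector of window intensities (length >= 1).
#' @return the median intensity (scalar).
#' @examples
#' median_of_window(c(5, 1, 9, 3, 7))  # 5
#' median_of_window(c(2, 4, 6, 8))     # 5, the even-n branch
#' @export
median_of_window <- function(values) {
  if (length(values) == 0) stopf("empty kernel window")
  if (anyNA(values)) stopf("kernel window contains NA")
  s <- sort(values)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

#' Median-filter an image
#'
#' Replaces every pixel with the median of the `size x size` window centred
#' on it, after zero padding the image by `floor(size / 2)` rows/columns on
#' each side. Channels are filtered independently. This is the classical
#' nonlinear denoiser for salt-and-pepper (impulse) noise: extreme 0/255
#' outliers rarely survive as the window median.
#'
#' @param img an [image_grid()] (or matrix/array coercible to one).
#' @param size odd kernel size (default 3).
#' @return filtered `image_grid`, same dimensions as the input.
#' @examples
#' img <- image_grid(matrix(c(1, 2, 3, 4), 2, 2))
#' median_filter(img, 3)  # all zeros: each padded window is majority zero
#' @export
median_filter <- function(img, size = 3) {
  img <- image_grid(img)
  if (!is_count(size) || size < 1 || size %% 2L == 0L)
    stopf("kernel size must be a positive odd integer, got %s", format(size))
  size <- as.integer(size)
  pad <- size %/% 2L
  d <- dim(img)
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- median_filter_channel(unclass(img)[, , ch], size, pad)
  }
  image_grid(out)
}

# One channel: zero-pad, gather the k^2 shifted planes into an
# n_pixels x k^2 matrix, take row-wise medians.
median_filter_channel <- function(m, size, pad) {
  h <- nrow(m); w <- ncol(m)
  padded <- matrix(0, h + 2L * pad, w + 2L * pad)
  padded[pad + seq_len(h), pad + seq_len(w)] <- m
  windows <- matrix(0, h * w, size * size)
  col <- 0L
  for (dj in seq_len(size)) {
    for (di in seq_len(size)) {
      col <- col + 1L
      windows[, col] <- padded[di + seq_len(h) - 1L, dj + seq_len(w) - 1L]
    }
  }
  med <- apply(windows, 1L, function(v) {
    s <- sort.int(v, method = "quick")
    n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
  })
  # odd-window medians of integers are integers; round half up defensively
  matrix(round_half_up(med, 0), h, w)
}
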