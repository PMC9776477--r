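#' Synthetic histopathology-like dataset configuration
#'
#' Describes a seeded generator for a multi-class, class-imbalanced image
#' dataset with class-distinct texture statistics, so that every pipeline
#' stage runs with no external download. Each class draws images from its
#' own texture model: a correlated Gaussian background around a class base
#' colour, plus Poisson-placed elliptical "nuclei" blobs of class-specific
#' density and size, with optional salt-and-pepper corruption.
#'
#' The default `classes` table mirrors the shape of a well-known
#' breast-histopathology benchmark: 8 subclasses (A, F, PT, TA benign; DC,
#' LC, MC, PC malignant) with the benchmark's class imbalance, scaled down
#' tenfold (11, 24, 12, 13, 79, 14, 17, 14 images; 182 total).
#'
#' @param classes tibble with columns `name`, `superclass`, `count`, and
#'   texture columns `base_r`, `base_g`, `base_b` (background colour,
#'   0-255), `density` (expected blobs per 100 pixels), `radius` (mean blob
#'   radius, px), `bg_len` (background correlation length, px). Defaults to
#'   the scaled 8-class layout.
#' @param image_size integer `c(H, W)`.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param noise salt-and-pepper fraction in `[0, 1)` applied to every image.
#' @param seed integer seed; the dataset is fully determined by it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(classes = default_class_spec(),
                         image_size = c(32L, 32L),
                         channels = 3L,
                         noise = 0,
                         seed = 1L) {
  classes <- tibble::as_tibble(classes)
  needed <- c("name", "superclass", "count")
  if (!all(needed %in% names(classes)))
    stopf("`classes` needs columns %s", paste(needed, collapse = ", "))
  if (anyDuplicated(classes$name)) stopf("duplicate class names")
  if (any(classes$count < 1)) stopf("class counts must be >= 1")
  if (noise < 0 || noise >= 1) stopf("noise fraction must be in [0, 1)")
  if (!channels %in% c(1L, 3L)) stopf("channels must be 1 or 3")
  # fill texture defaults for user-supplied specs lacking them
  tex_defaults <- default_class_spec()
  for (col in c("base_r", "base_g", "base_b", "density", "radius", "bg_len")) {
    if (!col %in% names(classes)) {
      idx <- (seq_len(nrow(classes)) - 1L) %% nrow(tex_defaults) + 1L
      classes[[col]] <- tex_defaults[[col]][idx]
    }
  }
  tex <- as.matrix(classes[, c("base_r", "base_g", "base_b",
                               "density", "radius", "bg_len")])
  if (anyDuplicated(tex) > 0)
    stopf("distinct classes must have distinct texture parameters")
  structure(list(classes = classes,
                 image_size = as.integer(image_size),
                 channels = as.integer(channels),
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_class_spec <- function() {
  tibble::tibble(
    name       = c("A", "F", "PT", "TA", "DC", "LC", "MC", "PC"),
    superclass = rep(c("benign", "malignant"), each = 4L),
    count      = c(11L, 24L, 12L, 13L, 79L, 14L, 17L, 14L),
    base_r     = c(235, 225, 240, 220, 150, 165, 180, 140),
    base_g     = c(205, 185, 215, 175, 110, 140, 120, 150),
    base_b     = c(225, 210, 230, 200, 170, 185, 160, 175),
    density    = c(1.0, 2.2, 0.6, 3.0, 5.5, 3.8, 4.6, 2.8),
    radius     = c(1.5, 2.0, 3.0, 1.2, 2.5, 1.8, 3.2, 2.2),
    bg_len     = c(3, 5, 7, 2, 4, 6, 3, 8)
  )
}

#' Generate a synthetic image dataset
#'
#' Draws every image from its class texture model under `cfg$seed` (the same
#' config always yields byte-identical images). With `out_dir` the images
#' are written as PNG plus a `manifest.csv` (`path,subclass,superclass`);
#' without it the images are kept in-memory in the `image` list-column.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional output directory.
#' @return tibble manifest: `path`, `subclass`, `superclass`, and an
#'   `image` list-column of [image_grid()]s.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  rows <- purrr::pmap(
    list(seq_len(nrow(cfg$classes))),
    function(ci) {
      cls <- cfg$classes[ci, ]
      purrr::map(seq_len(cls$count), function(j) {
        img <- synth_image(cls, cfg, derive_seed(cfg$seed, ci * 100000L + j))
        list(name = cls$name, superclass = cls$superclass, idx = j, image = img)
      })
    }
  )
  rows <- purrr::flatten(rows)
  manifest <- tibble::tibble(
    path = purrr::map_chr(rows, ~ sprintf("%s_%03d.png", .x$name, .x$idx)),
    subclass = purrr::map_chr(rows, "name"),
    superclass = purrr::map_chr(rows, "superclass"),
    image = purrr::map(rows, "image")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, manifest$path)
    purrr::walk2(manifest$image, manifest$path, write_image)
    readr::write_csv(manifest[, c("path", "subclass", "superclass")],
                     file.path(out_dir, "manifest.csv"))
  }
  manifest
}

# one image from a class's texture model
synth_image <- function(cls, cfg, seed) {
  h <- cfg$image_size[1]; w <- cfg$image_size[2]; nc <- cfg$channels
  base <- c(cls$base_r, cls$base_g, cls$base_b)
  if (nc == 1L) base <- sum(base * c(0.299, 0.587, 0.114))
  with_seed(seed, {
    bg <- smooth_field(h, w, cls$bg_len)        # zero-mean, unit-ish sd
    img <- array(0, c(h, w, nc))
    for (ch in seq_len(nc)) img[, , ch] <- base[ch] + 18 * bg
    n_blobs <- stats::rpois(1, cls$density * h * w / 100)
    if (n_blobs > 0) {
      cy <- stats::runif(n_blobs, 1, h); cx <- stats::runif(n_blobs, 1, w)
      rr <- pmax(0.6, stats::rgamma(n_blobs, shape = 6,
                                    scale = cls$radius / 6))
      ecc <- stats::runif(n_blobs, 0.6, 1)
      ang <- stats::runif(n_blobs, 0, pi)
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      blob_col <- if (nc == 1L) 60 else c(90, 50, 120)  # nucleus stain
      for (b in seq_len(n_blobs)) {
        dy <- yy - cy[b]; dx <- xx - cx[b]
        u <- cos(ang[b]) * dx + sin(ang[b]) * dy
        v <- -sin(ang[b]) * dx + cos(ang[b]) * dy
        inside <- (u / rr[b])^2 + (v / (rr[b] * ecc[b]))^2 <= 1
        if (!any(inside)) next
        for (ch in seq_len(nc)) {
          plane <- img[, , ch]
          plane[inside] <- 0.25 * plane[inside] + 0.75 * blob_col[ch]
          img[, , ch] <- plane
        }
      }
    }
    out <- image_grid(clamp(round(img), 0, 255))
    if (cfg$noise > 0) out <- inject_salt_pepper(out, cfg$noise,
                                                 derive_seed(seed, 77L))
    out
  })
}

# correlated Gaussian background: white noise smoothed by a separable
# moving average of width `len`, renormalised to unit sd
smooth_field <- function(h, w, len) {
  len <- max(1L, as.integer(round(len)))
  z <- matrix(stats::rnorm((h + 2 * len) * (w + 2 * len)),
              h + 2 * len, w + 2 * len)
  k <- rep(1 / len, len)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(t(z), 2, function(col) stats::filter(col, k, sides = 2)))
  z <- z[len + seq_len(h), len + seq_len(w)]
  z[is.na(z)] <- 0
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Inject salt-and-pepper noise
#'
#' Sets exactly `round(fraction * H * W)` pixel positions per channel to 0
#' or 255 (equal probability), positions drawn without replacement under
#' `seed`. This is the impulse-noise fixture the median filter targets.
#'
#' @param img an [image_grid()].
#' @param fraction corrupted fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return corrupted `image_grid`.
#' @export
inject_salt_pepper <- function(img, fraction, seed = 1L) {
  img <- image_grid(img)
  if (fraction < 0 || fraction >= 1) stopf("fraction must be in [0, 1)")
  d <- dim(img)
  n <- round(fraction * d[1] * d[2])
  if (n == 0) return(img)
  out <- unclass(img)
  with_seed(seed, {
    for (ch in seq_len(d[3])) {
      pos <- sample.int(d[1] * d[2], n)
      vals <- sample(c(0, 255), n, replace = TRUE)
      plane <- out[, , ch]
      plane[pos] <- vals
      out[, , ch] <- plane
    }
  })
  image_grid(out)
}

#' Stratified train/validation/test split
#'
#' Splits a manifest by subclass with seeded shuffling, preserving class
#' ratios within +/- 1 image per class.
#'
#' @param manifest tibble with a `subclass` column.
#' @param props named proportions summing to 1
#'   (default `c(train = .7, val = .15, test = .15)`).
#' @param seed integer seed.
#' @return the manifest with an added `split` factor column.
#' @export
split_dataset <- function(manifest,
                          props = c(train = 0.7, val = 0.15, test = 0.15),
                          seed = 1L) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  manifest <- tibble::as_tibble(manifest)
  split <- character(nrow(manifest))
  with_seed(seed, {
    for (cls in sort(unique(manifest$subclass))) {
      idx <- which(manifest$subclass == cls)
      # canonical order first: the split depends on the seed, never on the
      # manifest's row (filesystem) ordering
      if (!is.null(manifest$path)) idx <- idx[order(manifest$path[idx])]
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      cuts <- round(cumsum(props) * n)
      starts <- c(0L, cuts[-length(cuts)]) + 1L
      for (s in seq_along(props)) {
        if (starts[s] <= cuts[s])
          split[idx[starts[s]:cuts[s]]] <- names(props)[s]
      }
    }
  })
  manifest$split <- factor(split, levels = names(props))
  manifest
}

#' Read a dataset manifest CSV
#'
#' Loads a `path,subclass,superclass` manifest and the images it points to.
#'
#' @param path manifest CSV path; relative image paths resolve against its
#'   directory.
#' @return tibble manifest with an `image` list-column.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("path", "subclass", "superclass") %in% names(man)))
    stopf("manifest must have columns path, subclass, superclass")
  base <- dirname(path)
  full <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  man$image <- purrr::map(full, read_image)
  tibble::as_tibble(man)
}
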