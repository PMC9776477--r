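# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base [round()] rounds half to even; metric tables in the field are
#' conventionally reported with half-up rounding, so reports use this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Deterministic 32-bit sub-seed from a base seed and an integer tag, so each
# component/stage gets its own reproducible stream without seed collisions.
derive_seed <- function(seed, tag) {
  s <- (as.numeric(seed) * 2654435761 + as.numeric(tag) * 40503) %% 2147483647
  as.integer(s)
}

# run expr with a temporarily-set RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}
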