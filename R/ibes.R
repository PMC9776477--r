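#' Control parameters for bald eagle search
#'
#' Bald eagle search (BES) is a population metaheuristic with three phases
#' per iteration — select space, search space (spiral), swoop — each
#' proposing per-eagle candidate positions accepted greedily. The improved
#' variant (IBES) adds oppositional-based learning (OBL): the bound-mirrored
#' opposite of a candidate is evaluated and kept when fitter.
#'
#' @param alpha control gain of the select phase, in `[1.5, 2]`.
#' @param a_control corner/spiral control variable, in `[5, 10]`.
#' @param R search-cycle variable of the spiral, in `[0.5, 2]`.
#' @param n_pop population size (>= 2).
#' @param max_iter iteration count (>= 1).
#' @param seed integer seed for the whole optimisation run.
#' @param c_continuous draw the swoop centring factors `c1, c2` as
#'   continuous U(1, 2) (default, matching the BES literature); `FALSE`
#'   draws them as integers in `{1, 2}`.
#' @return a `bes_params` list.
#' @export
bes_params <- function(alpha = 2, a_control = 10, R = 1.5,
                       n_pop = 20L, max_iter = 50L, seed = 1L,
                       c_continuous = TRUE) {
  if (alpha < 1.5 || alpha > 2) stopf("alpha must lie in [1.5, 2]")
  if (a_control < 5 || a_control > 10) stopf("a_control must lie in [5, 10]")
  if (R < 0.5 || R > 2) stopf("R must lie in [0.5, 2]")
  if (!is_count(n_pop) || n_pop < 2) stopf("n_pop must be an integer >= 2")
  if (!is_count(max_iter) || max_iter < 1) stopf("max_iter must be >= 1")
  structure(list(alpha = alpha, a_control = a_control, R = R,
                 n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
                 seed = as.integer(seed), c_continuous = c_continuous),
            class = "bes_params")
}

check_bounds <- function(lb, ub) {
  if (length(lb) != length(ub) || any(!is.finite(lb)) || any(!is.finite(ub)))
    stopf("lb and ub must be finite vectors of equal length")
  if (any(lb >= ub)) stopf("every lower bound must be below its upper bound")
}

# evaluate fitness with bound clipping and NaN guard; records history
eval_fitness <- function(f, x, lb, ub, env = NULL, phase = NA_character_,
                         iteration = NA_integer_) {
  x <- clamp(x, lb, ub)
  fx <- f(x)
  if (!is.finite(fx))
    stopf("fitness returned a non-finite value at position (%s)",
          paste(signif(x, 6), collapse = ", "))
  if (!is.null(env)) {
    env$history[[length(env$history) + 1L]] <-
      list(phase = phase, iteration = iteration, position = x, fitness = fx)
  }
  fx
}

#' Oppositional-based learning
#'
#' `obl_opposite()` mirrors a position across the centre of the search box:
#' component-wise `lb + ub - x` (an involution; positions outside the box
#' are clipped first). `obl_select()` evaluates the opposite and returns
#' whichever of `x` and its opposite has the strictly better (lower)
#' fitness.
#'
#' @param x position vector.
#' @param lb,ub bound vectors (`lb < ub` component-wise).
#' @return `obl_opposite()`: the opposite position. `obl_select()`: the
#'   chosen position.
#' @examples
#' obl_opposite(0.3, 0, 1)  # 0.7
#' @export
obl_opposite <- function(x, lb, ub) {
  check_bounds(lb, ub)
  lb + ub - clamp(x, lb, ub)
}

#' @rdname obl_opposite
#' @param f fitness function mapping a position to a scalar (lower better).
#' @export
obl_select <- function(x, f, lb, ub) {
  xo <- obl_opposite(x, lb, ub)
  if (f(xo) < f(x)) xo else x
}

# internal variant reusing the known fitness of x
obl_select_known <- function(x, fx, f, lb, ub, env, phase, iteration) {
  xo <- obl_opposite(x, lb, ub)
  fo <- eval_fitness(f, xo, lb, ub, env, phase, iteration)
  if (fo < fx) list(x = xo, fx = fo) else list(x = x, fx = fx)
}

#' Initialise an eagle swarm
#'
#' Draws `n_pop` positions uniformly inside the bounds and evaluates them;
#' with `obl = TRUE` also evaluates every position's opposite and keeps the
#' better of each pair (the OBL-augmented initialisation).
#'
#' @param f fitness function (lower is better).
#' @param lb,ub bound vectors.
#' @param params a [bes_params()].
#' @param obl apply oppositional-based learning to the initial population.
#' @return a swarm list: `positions` (`n_pop x D`), `fitnesses`, `p_best`,
#'   `f_best`, `lb`, `ub`.
#' @export
init_swarm <- function(f, lb, ub, params, obl = TRUE) {
  check_bounds(lb, ub)
  D <- length(lb)
  P <- matrix(stats::runif(params$n_pop * D), params$n_pop, D)
  P <- sweep(sweep(P, 2, ub - lb, `*`), 2, lb, `+`)
  swarm_from_positions(P, f, lb, ub, obl, env = NULL)
}

swarm_from_positions <- function(P, f, lb, ub, obl, env) {
  fit <- apply(P, 1, function(x)
    eval_fitness(f, x, lb, ub, env, "init", 0L))
  if (obl) {
    for (i in seq_len(nrow(P))) {
      sel <- obl_select_known(P[i, ], fit[i], f, lb, ub, env, "init-obl", 0L)
      P[i, ] <- sel$x; fit[i] <- sel$fx
    }
  }
  best <- which.min(fit)
  list(positions = P, fitnesses = fit,
       p_best = P[best, ], f_best = fit[best], lb = lb, ub = ub)
}

# vapply over eagles returns a D x n matrix for D > 1 but a plain vector
# for D = 1; normalise to an n x D candidate matrix
as_candidates <- function(v, D) if (is.matrix(v)) t(v) else matrix(v, ncol = D)

# greedy per-eagle acceptance shared by the three phases
accept_candidates <- function(swarm, cand, f, obl, env, phase, iteration) {
  for (i in seq_len(nrow(cand))) {
    xc <- clamp(cand[i, ], swarm$lb, swarm$ub)
    fc <- eval_fitness(f, xc, swarm$lb, swarm$ub, env, phase, iteration)
    if (obl) {
      sel <- obl_select_known(xc, fc, f, swarm$lb, swarm$ub, env,
                              paste0(phase, "-obl"), iteration)
      xc <- sel$x; fc <- sel$fx
    }
    if (fc < swarm$fitnesses[i]) {
      swarm$positions[i, ] <- xc
      swarm$fitnesses[i] <- fc
    }
    if (fc < swarm$f_best) {
      swarm$p_best <- xc
      swarm$f_best <- fc
    }
  }
  swarm
}

#' The three bald-eagle-search phases
#'
#' Each phase proposes one candidate per eagle and accepts it greedily
#' (candidate replaces the eagle iff its fitness improves on the eagle's;
#' the global best is updated whenever beaten). All candidates are clipped
#' to the bounds before evaluation. Random draws come from the global RNG
#' in a fixed, documented order.
#'
#' \describe{
#'   \item{`select_space()`}{`P_new(i) = P_best + alpha * r_i * (P_mean -
#'     P_i)` with `r_i ~ U(0,1)` (one `runif(n_pop)` draw).}
#'   \item{`search_space()`}{spiral update `P_new(i) = P_i + y_i * (P_i -
#'     P_{i+1}) + x_i * (P_i - P_mean)` with neighbour `i + 1` cyclic;
#'     `theta_i = a * pi * u1_i`, `r_i = theta_i * R * u2_i`,
#'     `xr_i = r_i * sin(theta_i)`, `yr_i = r_i * cos(theta_i)`, each
#'     normalised by its vector's max absolute value (draws: `u1`, then
#'     `u2`, each `runif(n_pop)`).}
#'   \item{`swoop()`}{`P_new(i) = u_i * P_best + x1_i * (P_i - c1_i *
#'     P_mean) + y1_i * (P_i - c2_i * P_best)` with `theta_i = a * pi *
#'     u1_i`, `r_i = theta_i`, `xr_i = r_i * sinh(theta_i)`, `yr_i = r_i *
#'     cosh(theta_i)` normalised as in the search phase, and `u, c1, c2`
#'     drawn per eagle (`c1, c2 ~ U(1, 2)`; draws: `u1`, `u`, `c1`, `c2`).
#'     `theta` is capped at `700 / pi` so `sinh`/`cosh` cannot overflow.}
#' }
#'
#' @param swarm a swarm from [init_swarm()].
#' @param f fitness function.
#' @param params a [bes_params()].
#' @param obl apply [obl_select()] to each candidate before acceptance.
#' @return the updated swarm.
#' @name bes_phases
NULL

#' @rdname bes_phases
#' @export
select_space <- function(swarm, f, params, obl = FALSE) {
  n <- nrow(swarm$positions)
  p_mean <- colMeans(swarm$positions)
  r <- stats::runif(n)
  cand <- as_candidates(vapply(seq_len(n), function(i) {
    swarm$p_best + params$alpha * r[i] * (p_mean - swarm$positions[i, ])
  }, numeric(ncol(swarm$positions))), ncol(swarm$positions))
  accept_candidates(swarm, cand, f, obl, attr(swarm, "env"),
                    "select", attr(swarm, "iter") %||% NA_integer_)
}

# normalise by max |v|; all-zero vector stays zero (documented degenerate)
norm_by_max <- function(v) {
  m <- max(abs(v))
  if (m == 0) v else v / m
}

#' @rdname bes_phases
#' @export
search_space <- function(swarm, f, params, obl = FALSE) {
  n <- nrow(swarm$positions)
  D <- ncol(swarm$positions)
  p_mean <- colMeans(swarm$positions)
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  theta <- params$a_control * pi * u1
  r <- theta * params$R * u2
  x <- norm_by_max(r * sin(theta))
  y <- norm_by_max(r * cos(theta))
  nxt <- c(seq_len(n)[-1], 1L)  # cyclic neighbour
  cand <- as_candidates(vapply(seq_len(n), function(i) {
    Pi <- swarm$positions[i, ]
    Pi + y[i] * (Pi - swarm$positions[nxt[i], ]) + x[i] * (Pi - p_mean)
  }, numeric(D)), D)
  accept_candidates(swarm, cand, f, obl, attr(swarm, "env"),
                    "search", attr(swarm, "iter") %||% NA_integer_)
}

#' @rdname bes_phases
#' @export
swoop <- function(swarm, f, params, obl = FALSE) {
  n <- nrow(swarm$positions)
  D <- ncol(swarm$positions)
  p_mean <- colMeans(swarm$positions)
  u1 <- stats::runif(n)
  theta <- pmin(params$a_control * pi * u1, 700 / pi)
  r <- theta
  x1 <- norm_by_max(r * sinh(theta))
  y1 <- norm_by_max(r * cosh(theta))
  u <- stats::runif(n)
  if (params$c_continuous) {
    c1 <- stats::runif(n, 1, 2); c2 <- stats::runif(n, 1, 2)
  } else {
    c1 <- sample(1:2, n, replace = TRUE); c2 <- sample(1:2, n, replace = TRUE)
  }
  cand <- as_candidates(vapply(seq_len(n), function(i) {
    Pi <- swarm$positions[i, ]
    u[i] * swarm$p_best + x1[i] * (Pi - c1[i] * p_mean) +
      y1[i] * (Pi - c2[i] * swarm$p_best)
  }, numeric(D)), D)
  accept_candidates(swarm, cand, f, obl, attr(swarm, "env"),
                    "swoop", attr(swarm, "iter") %||% NA_integer_)
}

#' Optimise a fitness function with improved bald eagle search
#'
#' Runs the OBL-augmented initialisation (population plus its opposites,
#' keeping the better of each pair), then `max_iter` iterations of select
#' -> search -> swoop with greedy per-eagle acceptance. The `obl` schedule
#' controls where oppositional learning applies: to every candidate
#' (`"per-candidate"`, the default), to the initial population only
#' (`"init-only"`), or not at all (`"off"`, plain BES).
#'
#' @param f fitness function mapping a D-vector to a finite scalar (lower
#'   is better). Evaluations only ever occur inside the bounds.
#' @param lb,ub bound vectors.
#' @param params a [bes_params()].
#' @param obl OBL schedule: `"per-candidate"`, `"init-only"`, or `"off"`.
#' @return an `ibes_result`: `best_position`, `best_fitness`, `trace`
#'   (tibble `iteration`, `f_best` — length `max_iter + 1`, monotone
#'   non-increasing), `history` (tibble of every evaluation: `phase`,
#'   `iteration`, `fitness`, position columns `x1..xD`), `n_evals`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ibes_optimize(sphere, c(-5, -5), c(5, 5),
#'                      bes_params(n_pop = 10, max_iter = 25, seed = 42))
#' res$best_fitness
#' @export
ibes_optimize <- function(f, lb, ub, params,
                          obl = c("per-candidate", "init-only", "off")) {
  obl <- match.arg(obl)
  check_bounds(lb, ub)
  env <- new.env()
  env$history <- list()
  with_seed(params$seed, {
    D <- length(lb)
    P <- matrix(stats::runif(params$n_pop * D), params$n_pop, D)
    P <- sweep(sweep(P, 2, ub - lb, `*`), 2, lb, `+`)
    swarm <- swarm_from_positions(P, f, lb, ub, obl != "off", env)
    per_cand <- obl == "per-candidate"
    trace <- numeric(params$max_iter + 1L)
    trace[1] <- swarm$f_best
    for (it in seq_len(params$max_iter)) {
      attr(swarm, "env") <- env
      attr(swarm, "iter") <- it
      swarm <- select_space(swarm, f, params, obl = per_cand)
      attr(swarm, "env") <- env; attr(swarm, "iter") <- it
      swarm <- search_space(swarm, f, params, obl = per_cand)
      attr(swarm, "env") <- env; attr(swarm, "iter") <- it
      swarm <- swoop(swarm, f, params, obl = per_cand)
      trace[it + 1L] <- swarm$f_best
    }
    hist <- history_tibble(env$history, D)
    structure(list(best_position = swarm$p_best,
                   best_fitness = swarm$f_best,
                   trace = tibble::tibble(iteration = 0:params$max_iter,
                                          f_best = trace),
                   history = hist, n_evals = nrow(hist),
                   params = params, obl = obl),
              class = "ibes_result")
  })
}

history_tibble <- function(history, D) {
  if (length(history) == 0)
    return(tibble::tibble(phase = character(), iteration = integer(),
                          fitness = numeric()))
  pos <- do.call(rbind, lapply(history, `[[`, "position"))
  colnames(pos) <- paste0("x", seq_len(D))
  dplyr::bind_cols(
    tibble::tibble(phase = vapply(history, `[[`, "", "phase"),
                   iteration = vapply(history, function(h)
                     as.integer(h$iteration), 1L),
                   fitness = vapply(history, `[[`, 1, "fitness")),
    tibble::as_tibble(pos))
}

#' @export
print.ibes_result <- function(x, ...) {
  cat(sprintf("<ibes_result: f_best = %.6g after %d evaluations (obl = %s)>\n",
              x$best_fitness, x$n_evals, x$obl))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classifier error-rate fitness
#'
#' The percentage of misclassified samples — the quantity the optimizer
#' minimises when tuning classifier hyperparameters.
#'
#' @param truth true labels.
#' @param estimate predicted labels.
#' @return percentage in `[0, 100]`.
#' @examples
#' fitness_error_rate(c(1, 1, 2), c(1, 2, 2))  # 33.33...
#' @export
fitness_error_rate <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) == 0)
    stopf("truth and estimate must be equal-length, nonempty")
  100 * mean(as.character(truth) != as.character(estimate))
}

#' Define a hyperparameter search space
#'
#' One row per tunable parameter. `scale = "log10"` searches the exponent
#' (bounds given on the log10 scale, decoded as `10^x`); `type = "integer"`
#' rounds half-up after descaling.
#'
#' @param name,lb,ub,scale,type equal-length vectors (scale in
#'   `c("linear", "log10")`, type in `c("real", "integer")`).
#' @return tibble search space.
#' @export
search_space_spec <- function(name, lb, ub, scale = "linear", type = "real") {
  tibble::tibble(name = name, lb = lb, ub = ub,
                 scale = rep_len(scale, length(name)),
                 type = rep_len(type, length(name)))
}

#' Decode an optimizer position into hyperparameters
#'
#' @param position numeric vector, one entry per search-space row.
#' @param space a [search_space_spec()] tibble.
#' @return named list of decoded parameter values.
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == nrow(space))
  vals <- purrr::pmap(list(position, space$scale, space$type),
                      function(v, sc, ty) {
    if (sc == "log10") v <- 10^v
    if (ty == "integer") v <- as.integer(round_half_up(v, 0))
    v
  })
  stats::setNames(vals, space$name)
}

#' Tune SDL hyperparameters with improved bald eagle search
#'
#' Minimises the classifier error rate ([fitness_error_rate()]) over a
#' hyperparameter search space. By default each position decodes into
#' overrides of `base_config`, a reduced-epoch SDL ensemble is trained on
#' each stratified cross-validation fold, and the mean held-out error rate
#' (percent) is the fitness; a custom `fitness` closure over the decoded
#' parameter list can replace that (used, e.g., with surrogate surfaces).
#' Positions that fail to decode into a trainable configuration score the
#' worst fitness (100) with a warning so the search continues.
#'
#' @param data tibble with `image` list-column and label column (ignored
#'   when `fitness` is supplied).
#' @param space a [search_space_spec()] tibble.
#' @param params a [bes_params()].
#' @param base_config an [sdl_config()] supplying the untuned fields.
#' @param folds number of stratified cross-validation folds.
#' @param fitness optional `function(decoded_params) -> percentage`.
#' @param label_col label column name.
#' @param obl OBL schedule passed to [ibes_optimize()].
#' @return a `tune_result`: `best_params` (decoded named list),
#'   `best_fitness`, `result` (the full `ibes_result`), and `report` — a
#'   tibble logging every evaluated position with its decoded values and
#'   fitness.
#' @export
tune_hyperparameters <- function(data, space, params,
                                 base_config = NULL, folds = 3L,
                                 fitness = NULL, label_col = "label",
                                 obl = "per-candidate") {
  if (is.null(fitness)) {
    if (is.null(base_config)) stopf("supply `base_config` or `fitness`")
    folds_idx <- with_seed(derive_seed(params$seed, 999L),
                           make_cv_folds(data[[label_col]], folds))
    fitness <- function(decoded) {
      cfg <- base_config
      for (nm in names(decoded)) cfg[[nm]] <- decoded[[nm]]
      if (!is.function(cfg$lr_schedule)) {
        lr <- cfg$lr_schedule
        cfg$lr_schedule <- function(z) lr
      }
      errs <- vapply(seq_along(folds_idx), function(fi) {
        hold <- folds_idx[[fi]]
        fit <- sdl_train(data[-hold, ], cfg, label_col)
        pred <- sdl_predict(fit, data[hold, ])
        fitness_error_rate(data[[label_col]][hold], pred$.pred_class)
      }, numeric(1))
      mean(errs)
    }
  }
  f_pos <- function(pos) {
    decoded <- decode_position(pos, space)
    out <- tryCatch(fitness(decoded), error = function(e) {
      warning("fitness evaluation failed (", conditionMessage(e),
              "); scoring worst fitness", call. = FALSE)
      100
    })
    out
  }
  res <- ibes_optimize(f_pos, space$lb, space$ub, params, obl = obl)
  report <- res$history
  decoded_cols <- purrr::map(seq_len(nrow(report)), function(i) {
    pos <- as.numeric(report[i, paste0("x", seq_len(nrow(space)))])
    decode_position(pos, space)
  })
  for (nm in space$name)
    report[[paste0("param_", nm)]] <-
      purrr::map_dbl(decoded_cols, ~ as.numeric(.x[[nm]]))
  structure(list(best_params = decode_position(res$best_position, space),
                 best_fitness = res$best_fitness,
                 result = res, report = report),
            class = "tune_result")
}

# stratified fold assignment; errors when a class has fewer samples than
# would leave every fold usable
make_cv_folds <- function(labels, folds) {
  n <- length(labels)
  if (n < folds) stopf("fewer samples (%d) than folds (%d)", n, folds)
  assign <- integer(n)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  lapply(seq_len(folds), function(fi) which(assign == fi))
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result: best fitness %.4g over %d evaluations>\n",
              x$best_fitness, nrow(x$report)))
  cat("  best params:",
      paste(names(x$best_params),
            signif(unlist(x$best_params), 5), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}
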