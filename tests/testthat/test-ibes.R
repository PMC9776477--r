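test_that("opposition is an involution that stays in bounds", {
  expect_equal(obl_opposite(0.3, 0, 1), 0.7)
  mid <- c(0.5, 2.5)
  expect_equal(obl_opposite(mid, c(0, 0), c(1, 5)), mid)  # fixed point
  set.seed(4)
  for (i in 1:20) {
    lb <- runif(3, -10, 0); ub <- runif(3, 1, 10)
    x <- lb + runif(3) * (ub - lb)
    xo <- obl_opposite(x, lb, ub)
    expect_true(all(xo >= lb & xo <= ub))
    expect_equal(obl_opposite(xo, lb, ub), x, tolerance = 1e-12)
  }
  # out-of-bounds input is clipped first
  expect_equal(obl_opposite(2, 0, 1), 0)
})

test_that("obl_select keeps the strictly fitter of a point and its opposite", {
  f_to_ub <- function(x) 1 - x  # distance to ub on [0, 1]
  expect_equal(obl_select(0.2, f_to_ub, 0, 1), 0.8)
  f_sym <- function(x) abs(x - 0.5)
  expect_equal(obl_select(0.2, f_sym, 0, 1), 0.2)  # tie keeps x
  # exhaustive-comparison oracle over a random fitness table
  set.seed(7)
  grid <- seq(0.05, 0.95, by = 0.1)
  vals <- runif(10)
  f_tab <- function(x) vals[which.min(abs(grid - x))]
  for (x in grid) {
    xo <- 1 - x
    expected <- if (f_tab(xo) < f_tab(x)) xo else x
    expect_equal(obl_select(x, f_tab, 0, 1), expected)
  }
})

test_that("select phase follows its update rule and accepts greedily", {
  # all positions at the mean: candidates equal P_best regardless of r
  f <- function(x) sum(x^2)
  rec <- recording_fitness(f)
  swarm <- list(positions = matrix(2, 4, 2), fitnesses = rep(8, 4),
                p_best = c(-1, 1), f_best = 2,
                lb = c(-5, -5), ub = c(5, 5))
  set.seed(1)
  out <- select_space(swarm, rec$fn, bes_params(n_pop = 4, seed = 1))
  for (p in rec$env$positions) expect_equal(p, c(-1, 1))
  expect_true(all(out$fitnesses <= swarm$fitnesses))
  expect_lte(out$f_best, swarm$f_best)

  # scalar replay oracle with a spread-out swarm
  set.seed(33)
  P <- matrix(runif(8, -4, 4), 4, 2)
  fit <- apply(P, 1, f)
  swarm <- list(positions = P, fitnesses = fit,
                p_best = P[which.min(fit), ], f_best = min(fit),
                lb = c(-5, -5), ub = c(5, 5))
  params <- bes_params(alpha = 1.8, n_pop = 4, seed = 1)
  rec <- recording_fitness(f)
  set.seed(99)
  select_space(swarm, rec$fn, params)
  set.seed(99)
  r <- runif(4)
  pmean <- colMeans(P)
  for (i in 1:4) {
    cand <- swarm$p_best + params$alpha * r[i] * (pmean - P[i, ])
    expect_equal(rec$env$positions[[i]],
                 pmin(pmax(cand, swarm$lb), swarm$ub), tolerance = 1e-12)
  }
})

test_that("search phase matches a step-by-step scalar oracle", {
  f <- function(x) sum((x - 1)^2)
  set.seed(21)
  P <- matrix(runif(10, -4, 4), 5, 2)
  fit <- apply(P, 1, f)
  swarm <- list(positions = P, fitnesses = fit,
                p_best = P[which.min(fit), ], f_best = min(fit),
                lb = c(-6, -6), ub = c(6, 6))
  params <- bes_params(a_control = 7, R = 1.2, n_pop = 5, seed = 1)
  rec <- recording_fitness(f)
  set.seed(5)
  search_space(swarm, rec$fn, params)
  set.seed(5)
  u1 <- runif(5); u2 <- runif(5)
  theta <- params$a_control * pi * u1
  r <- theta * params$R * u2
  xr <- r * sin(theta); yr <- r * cos(theta)
  x <- xr / max(abs(xr)); y <- yr / max(abs(yr))
  pmean <- colMeans(P)
  for (i in 1:5) {
    nxt <- if (i == 5) 1 else i + 1  # cyclic neighbour
    cand <- P[i, ] + y[i] * (P[i, ] - P[nxt, ]) + x[i] * (P[i, ] - pmean)
    expect_equal(rec$env$positions[[i]],
                 pmin(pmax(cand, swarm$lb), swarm$ub), tolerance = 1e-12)
  }
  # identical positions: all difference vectors vanish
  same <- list(positions = matrix(1.5, 3, 2), fitnesses = rep(4.5, 3),
               p_best = c(1.5, 1.5), f_best = 0.5,
               lb = c(-6, -6), ub = c(6, 6))
  rec2 <- recording_fitness(f)
  set.seed(2)
  search_space(same, rec2$fn, bes_params(n_pop = 3, seed = 1))
  for (p in rec2$env$positions) expect_equal(p, c(1.5, 1.5))
})

test_that("swoop phase matches its sinh/cosh oracle", {
  f <- function(x) sum(x^2)
  set.seed(13)
  P <- matrix(runif(8, -3, 3), 4, 2)
  fit <- apply(P, 1, f)
  swarm <- list(positions = P, fitnesses = fit,
                p_best = P[which.min(fit), ], f_best = min(fit),
                lb = c(-5, -5), ub = c(5, 5))
  params <- bes_params(a_control = 6, n_pop = 4, seed = 1)
  rec <- recording_fitness(f)
  set.seed(17)
  swoop(swarm, rec$fn, params)
  set.seed(17)
  u1 <- runif(4)
  theta <- pmin(params$a_control * pi * u1, 700 / pi)
  r <- theta
  xr <- r * sinh(theta); yr <- r * cosh(theta)
  x1 <- xr / max(abs(xr)); y1 <- yr / max(abs(yr))
  u <- runif(4); c1 <- runif(4, 1, 2); c2 <- runif(4, 1, 2)
  pmean <- colMeans(P)
  for (i in 1:4) {
    cand <- u[i] * swarm$p_best + x1[i] * (P[i, ] - c1[i] * pmean) +
      y1[i] * (P[i, ] - c2[i] * swarm$p_best)
    expect_equal(rec$env$positions[[i]],
                 pmin(pmax(cand, swarm$lb), swarm$ub), tolerance = 1e-12)
  }
  # cosh dominates sinh for theta >= 0
  expect_true(all(abs(yr) >= abs(xr)))
})

test_that("best fitness never increases across phases and iterations", {
  for (s in 1:20) {
    shift <- (s %% 5) - 2
    g <- function(x) sum((x - shift)^2) + 0.5 * sum(abs(x))
    res <- ibes_optimize(g, rep(-4, 3), rep(6, 3),
                         bes_params(n_pop = 6, max_iter = 12, seed = 100 + s))
    expect_true(all(diff(res$trace$f_best) <= 0))
    expect_equal(nrow(res$trace), 13)
    expect_equal(res$best_fitness, min(res$history$fitness))
  }
})

test_that("every evaluated position lies within the bounds", {
  res <- ibes_optimize(sphere, c(-1, -2), c(0.5, 3),
                       bes_params(n_pop = 8, max_iter = 10, seed = 3))
  expect_true(all(res$history$x1 >= -1 & res$history$x1 <= 0.5))
  expect_true(all(res$history$x2 >= -2 & res$history$x2 <= 3))
})

test_that("the optimizer converges on the sphere function", {
  res <- ibes_optimize(sphere, c(-5, -5), c(5, 5),
                       bes_params(n_pop = 10, max_iter = 50, seed = 7))
  expect_lt(res$best_fitness, 1e-2)
})

test_that("a constant fitness yields a flat trace", {
  res <- ibes_optimize(function(x) 3, c(0, 0), c(1, 1),
                       bes_params(n_pop = 4, max_iter = 5, seed = 2))
  expect_true(all(res$trace$f_best == 3))
})

test_that("non-finite fitness fails loudly with the offending position", {
  f <- function(x) if (x[1] > 0.9) NaN else sum(x^2)
  expect_error(
    ibes_optimize(f, c(0, 0), c(1, 1),
                  bes_params(n_pop = 6, max_iter = 5, seed = 1)),
    "non-finite")
})

test_that("opposition-based learning improves on plain BES at equal budget", {
  on <- vapply(1:10, function(s)
    ibes_optimize(shifted_sphere, c(-5, -5), c(5, 5),
                  bes_params(n_pop = 10, max_iter = 10, seed = s),
                  obl = "per-candidate")$best_fitness, numeric(1))
  off <- vapply(1:10, function(s)
    ibes_optimize(shifted_sphere, c(-5, -5), c(5, 5),
                  bes_params(n_pop = 10, max_iter = 20, seed = s),
                  obl = "off")$best_fitness, numeric(1))
  expect_lt(mean(on), mean(off))
})

test_that("disabling OBL reproduces plain BES exactly", {
  # init-only and off share the same RNG stream after initialisation, so
  # the OBL delta is isolated to the initial opposition sweep
  a <- ibes_optimize(sphere, c(-2, -2), c(2, 2),
                     bes_params(n_pop = 5, max_iter = 4, seed = 9),
                     obl = "off")
  b <- ibes_optimize(sphere, c(-2, -2), c(2, 2),
                     bes_params(n_pop = 5, max_iter = 4, seed = 9),
                     obl = "off")
  expect_identical(a$trace, b$trace)  # same seed, same trace
  expect_false(any(grepl("obl", a$history$phase)))
  # plain BES budget: n_pop initial + 3 phases x n_pop per iteration
  expect_equal(a$n_evals, 5 * (1 + 3 * 4))
})

test_that("error-rate fitness is the misclassification percentage", {
  expect_equal(fitness_error_rate(rep(1, 10), c(rep(1, 7), rep(2, 3))), 30)
  expect_equal(fitness_error_rate(c("a", "b"), c("a", "b")), 0)
  expect_equal(fitness_error_rate(c(1, 1), c(2, 2)), 100)
  expect_error(fitness_error_rate(1, c(1, 2)), "equal-length")
})

test_that("position decoding honours scale and integer rounding", {
  space <- search_space_spec(c("lr", "epochs", "lambda"),
                             lb = c(-3, 2, 0), ub = c(-1, 10, 1),
                             scale = c("log10", "linear", "linear"),
                             type = c("real", "integer", "real"))
  dec <- decode_position(c(-2, 4.5, 0.25), space)
  expect_equal(dec$lr, 1e-2)
  expect_identical(dec$epochs, 5L)  # round half up
  expect_equal(dec$lambda, 0.25)
})

test_that("tuning recovers the minimum of a surrogate quadratic surface", {
  space <- search_space_spec("lambda", lb = 0, ub = 1)
  res <- tune_hyperparameters(
    data = NULL, space = space,
    params = bes_params(n_pop = 6, max_iter = 6, seed = 11),
    fitness = function(p) (p$lambda - 0.5)^2)
  expect_lt(abs(res$best_params$lambda - 0.5), 0.05)
  expect_true(all(c("phase", "iteration", "fitness", "param_lambda")
                  %in% names(res$report)))
})

test_that("tuning bookkeeping: init evaluations double under OBL", {
  space <- search_space_spec("w", lb = 0, ub = 1)
  res <- tune_hyperparameters(
    data = NULL, space = space,
    params = bes_params(n_pop = 4, max_iter = 3, seed = 2),
    fitness = function(p) (p$w - 0.3)^2, obl = "init-only")
  rep <- res$report
  expect_equal(sum(rep$phase == "init"), 4)
  expect_equal(sum(rep$phase == "init-obl"), 4)
  for (it in 1:3) {
    expect_equal(sum(rep$iteration == it & rep$phase == "select"), 4)
    expect_equal(sum(rep$iteration == it & rep$phase == "search"), 4)
    expect_equal(sum(rep$iteration == it & rep$phase == "swoop"), 4)
  }
  expect_equal(nrow(rep), 8 + 3 * 12)
})

test_that("a degenerate search space still completes", {
  space <- search_space_spec("w", lb = 0.5, ub = 0.5 + 1e-9)
  res <- tune_hyperparameters(
    data = NULL, space = space,
    params = bes_params(n_pop = 4, max_iter = 2, seed = 3),
    fitness = function(p) p$w)
  expect_equal(res$best_params$w, 0.5, tolerance = 1e-6)
})

test_that("a failing fitness scores worst so the search continues", {
  space <- search_space_spec("w", lb = 0, ub = 1)
  w <- testthat::capture_warnings(
    res <- tune_hyperparameters(
      data = NULL, space = space,
      params = bes_params(n_pop = 4, max_iter = 1, seed = 4),
      fitness = function(p) if (p$w > 0.5) stop("boom") else p$w))
  expect_true(any(grepl("worst fitness", w)))
  expect_lte(res$best_fitness, 100)
})

test_that("parameter ranges are validated", {
  expect_error(bes_params(alpha = 1), "alpha")
  expect_error(bes_params(a_control = 3), "a_control")
  expect_error(bes_params(R = 3), "R must")
  expect_error(bes_params(n_pop = 1), "n_pop")
})
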