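test_that("Box-Behnken designs have the canonical structure and balance", {
  d6 <- bbd_points(6, rep(0, 6), rep(1, 6))
  expect_equal(nrow(d6$coded), 49)
  # exactly one all-zero center row
  expect_equal(sum(rowSums(abs(d6$coded)) == 0), 1)
  # every row has 0 or 3 non-zero coded entries
  expect_true(all(rowSums(d6$coded != 0) %in% c(0, 3)))
  # per-factor level counts: 12 at +1, 12 at -1, 25 at 0
  for (j in 1:6) {
    expect_equal(sum(d6$coded[, j] == 1), 12)
    expect_equal(sum(d6$coded[, j] == -1), 12)
    expect_equal(sum(d6$coded[, j] == 0), 25)
  }
  d3 <- bbd_points(3, rep(0, 3), rep(1, 3))
  expect_equal(nrow(d3$coded), 13)
  # physical mapping and clipping
  d <- bbd_points(3, c(10, 10, 10), c(5, 5, 5))
  expect_equal(range(d$physical), c(5, 15))
  expect_warning(bbd_points(3, c(10, 10, 10), c(5, 5, 5),
                            bounds = list(lower = 6, upper = 14)), "clipped")
})

test_that("the response surface fit recovers a known quadratic exactly", {
  des <- bbd_points(6, rep(0, 6), rep(1, 6))
  k <- 6
  p <- 1 + 2 * k + k * (k - 1) / 2
  set.seed(31)
  beta <- rnorm(p)
  M <- cmgraft:::quad_model_matrix(des$coded)
  y <- drop(M %*% beta)
  fit <- fit_rsm(des$coded, y)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-9)
  # constant responses: intercept only
  fc <- fit_rsm(des$coded, rep(2.5, 49))
  expect_equal(unname(fc$coefficients[1]), 2.5, tolerance = 1e-12)
  expect_lt(max(abs(fc$coefficients[-1])), 1e-12)
  expect_error(fit_rsm(des$coded, c(rep(NA, 30), y[31:49])), "rank")
})

test_that("coefficient noise scales with the response noise level", {
  des <- bbd_points(6, rep(0, 6), rep(1, 6))
  sd_of_linear <- function(sigma, seed) {
    set.seed(seed)
    reps <- replicate(60, {
      y <- 1 + des$coded[, 1] + sigma * rnorm(49)
      fit_rsm(des$coded, y)$coefficients[2]
    })
    sd(reps)
  }
  s1 <- sd_of_linear(0.01, 1)
  s2 <- sd_of_linear(0.02, 1)
  expect_equal(s2 / s1, 2, tolerance = 0.25)
})

test_that("the descent step finds box minimizers and shrinks the trust region", {
  # convex bowl with interior minimum at coded (0.3, -0.2, 0.1, 0, 0.25, -0.4)
  xstar <- c(0.3, -0.2, 0.1, 0, 0.25, -0.4)
  des <- bbd_points(6, rep(0, 6), rep(1, 6))
  y <- apply(des$coded, 1, function(x) sum((x - xstar)^2))
  fit <- fit_rsm(des$coded, y)
  step <- descend(fit, rep(0, 6), rep(1, 6), gamma = 0.7)
  expect_equal(step$coded_step, xstar, tolerance = 1e-6)
  expect_equal(step$half_ranges, rep(0.7, 6))
  # linear surface: minimizer sits on the box boundary along -gradient
  g <- c(1, -2, 0.5, -0.5, 2, -1)
  ylin <- drop(des$coded %*% g)
  fitl <- fit_rsm(des$coded, ylin)
  stepl <- descend(fitl, rep(0, 6), rep(1, 6), gamma = 0.7)
  expect_equal(stepl$coded_step, -sign(g), tolerance = 1e-5)
  # geometric shrinkage with a floor
  h <- rep(1, 6)
  for (i in 1:12) h <- descend(fit, rep(0, 6), h, gamma = 0.7,
                               floor_half = rep(0.05, 6))$half_ranges
  expect_equal(h, pmax(rep(0.7^12, 6), 0.05))
})

test_that("main-effects screening ranks factors by their true influence", {
  space <- list(names = paste0("f", 1:7),
                lower = rep(-1, 7), upper = rep(1, 7))
  coefs <- c(5, 3, 0, 1, 0.5, 2, 4)
  lin <- function(x) sum(coefs * as.numeric(x))
  scr <- main_effects_screen(lin, space)
  expect_equal(scr$effects$factor[1:2], c("f1", "f7"))
  expect_equal(scr$selected,
               space$names[order(abs(coefs), decreasing = TRUE)][1:6])
  # an ignored factor has a null effect and ranks last
  expect_equal(scr$effects$factor[7], "f3")
  expect_lt(abs(scr$effects$effect[7]), 1e-12)
  # a pure two-factor interaction has no main effect in a full factorial
  inter <- function(x) as.numeric(x)[1] * as.numeric(x)[2]
  scr2 <- main_effects_screen(inter, space)
  expect_lt(max(abs(scr2$effects$effect)), 1e-12)
  # failure handling: abort when more than 20% of runs fail
  flaky <- function(x) if (as.numeric(x)[1] > 0) stop("boom") else 1
  expect_error(main_effects_screen(flaky, space), "failed")
})

test_that("optimization on an analytic quadratic converges to the argmin deterministically", {
  q <- fixture_quadratic_evaluator()
  res <- optimize_graft(q$f, q$space, target = q$minimum, starts = 2L, seed = 7L)
  best <- res[[1]]
  expect_true(best$converged)
  expect_lte(best$cycles_used, 10)
  width <- q$space$upper - q$space$lower
  expect_true(all(abs(best$best_design - q$argmin) <= 0.01 * width))
  expect_lt(best$objective, 1e-6)
  # determinism contract: identical seeds give identical traces
  res2 <- optimize_graft(q$f, q$space, target = q$minimum, starts = 2L, seed = 7L)
  expect_identical(lapply(res, `[[`, "trace"), lapply(res2, `[[`, "trace"))
  # trust region never grows
  expect_true(all(diff(res[[1]]$trace$cycle) == 1))
})
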