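test_that("polynomial fitting handles the degenerate and exact cases", {
  # two points, order 1: the interpolating line
  ser2 <- tibble::tibble(time = c(0, 2), value = c(1, 5))
  f <- fit_polynomial(ser2, 1)
  expect_equal(f$predict(c(0, 1, 2)), c(1, 3, 5), tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)

  # order 0 is the mean
  ser <- tibble::tibble(time = 1:5, value = c(2, 4, 6, 3, 5))
  expect_equal(unname(f0 <- fit_polynomial(ser, 0)$predict(3)), 4)

  expect_error(fit_polynomial(ser, 5), "at least")
  expect_error(
    fit_polynomial(tibble::tibble(time = c(1, 1, 2), value = 1:3), 1),
    "duplicate")
})

test_that("zero-residual fits reproduce the data at the sample times", {
  set.seed(3)
  tt <- sort(stats::runif(8, 0, 4))
  y <- 2 - tt + 0.5 * tt^3
  f <- fit_polynomial(tibble::tibble(time = tt, value = y), 3)
  expect_equal(f$predict(tt), y, tolerance = 1e-9)
})

test_that("AIC order selection penalises superfluous terms", {
  tt <- seq(0, 5, length.out = 20)
  y <- 1 + 2 * tt - 0.3 * tt^2 + 0.1 * tt^3
  best <- select_polynomial_order(tibble::tibble(time = tt, value = y),
                                  candidates = 1:8)
  expect_equal(best$order, 3L)

  # constant series: lowest candidate wins, adjusted R2 is 0 by convention
  const <- tibble::tibble(time = tt, value = rep(2, 20))
  b0 <- select_polynomial_order(const, candidates = 0:4)
  expect_equal(b0$order, 0L)
  expect_equal(b0$score_adj_r2, 0)
})

test_that("a 6th-order polynomial describes noise-free branched data well", {
  case <- make_branched_case(noise_cv = 0)
  r2 <- vapply(case$model$species, function(sp) {
    fit_polynomial(tibble::tibble(time = case$data$time,
                                  value = case$data[[sp]]), 6)$score_adj_r2
  }, numeric(1))
  # X1 carries the sharpest transient and fits worst; the rest are
  # near-interpolating
  expect_true(all(r2 > 0.85))
  expect_gt(stats::median(r2), 0.97)
})

test_that("the Hill smoother recovers exact saturating data", {
  tt <- seq(0, 10, length.out = 25)
  y <- 2 * tt^2 / (1 + tt^2)
  f <- fit_hill(tibble::tibble(time = tt, value = y))
  expect_equal(unname(f$coefficients[c("k1", "k2", "n")]), c(2, 1, 2),
               tolerance = 1e-6)
  # a strictly decreasing series does not suit the saturating form
  dec <- tibble::tibble(time = tt, value = rev(seq(1, 5, length.out = 25)))
  bad <- tryCatch(fit_hill(dec), error = function(e) e)
  if (inherits(bad, "error")) {
    expect_match(conditionMessage(bad), "converge|saturating")
  } else {
    expect_lt(bad$score_adj_r2, 0.5)
  }
})

test_that("the Hill smoother tolerates moderate noise", {
  # k1=5, k2=3, n=1, 5% proportional noise, 20 points: median relative
  # parameter deviation across seeds stays in the ~10% regime
  errs <- vapply(1:30, function(s) {
    set.seed(s)
    tt <- seq(0, 10, length.out = 20)
    y0 <- 5 * tt / (3 + tt)
    y <- pmax(y0 + stats::rnorm(20, 0, 0.05 * y0), 0)
    f <- fit_hill(tibble::tibble(time = tt, value = y))
    k <- f$coefficients
    mean(abs(c(k[["k1"]] - 5, k[["k2"]] - 3, k[["n"]] - 1) / c(5, 3, 1)))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("central differences are exact for quadratics and second order", {
  tt <- seq(0, 3, by = 0.25)
  expect_equal(central_slopes(tt, tt^2), 2 * tt, tolerance = 1e-12)
  expect_equal(central_slopes(tt, rep(4, length(tt))),
               rep(0, length(tt)))
  expect_error(central_slopes(c(0, 1), c(1, 2)), "at least 3")

  h <- 0.01
  tt <- seq(0, 2, by = h)
  err <- max(abs(central_slopes(tt, sin(tt)) - cos(tt)))
  expect_lt(err, h^2)

  # order-2 convergence: refining the grid by 2 shrinks the error ~4x
  err_h <- function(h) {
    tt <- seq(0, 2, by = h)
    max(abs(central_slopes(tt, exp(tt)) - exp(tt)))
  }
  expect_gt(err_h(0.02) / err_h(0.01), 3.3)

  # nonuniform grids are handled (still exact for quadratics)
  tnu <- cumsum(c(0, stats::runif(10, 0.1, 0.5)))
  expect_equal(central_slopes(tnu, 3 * tnu^2 - tnu), 6 * tnu - 1,
               tolerance = 1e-10)
})

test_that("central differencing is linear in its input", {
  set.seed(11)
  tt <- sort(stats::runif(12, 0, 5))
  y1 <- stats::rnorm(12); y2 <- stats::rnorm(12)
  a <- 2.3; b <- -0.7
  expect_equal(central_slopes(tt, a * y1 + b * y2),
               a * central_slopes(tt, y1) + b * central_slopes(tt, y2),
               tolerance = 1e-11)
})

test_that("analytical slopes equal dense-grid finite differences", {
  bm <- branched_model()
  sim <- simulate_gma(bm, seq(0, 2, length.out = 2001))
  sl <- analytical_slopes(bm, sim$trajectory)
  h <- 1e-3
  for (sp in bm$species) {
    num <- central_slopes(sim$trajectory$time, sim$trajectory[[sp]])
    inner <- 2:2000
    expect_lt(max(abs(num[inner] - sl[[sp]][inner])),
              1e-4 * max(1, max(abs(sl[[sp]]))))
  }
  # at a steady state the slopes vanish
  m <- toy_in_out_model(a = 3, b = 3, f = 1)
  traj <- tibble::tibble(time = c(0, 1), A = c(1, 1))
  expect_equal(analytical_slopes(m, traj)$A, c(0, 0))
})

test_that("smooth_timecourse returns slopes for measured species only", {
  case <- make_branched_case(noise_cv = 0.1, missing = "X3", seed = 2)
  sm <- smooth_timecourse(case$data, method = "polynomial", candidates = 6)
  expect_true(all(is.na(sm$slopes$X3)))
  expect_false(anyNA(sm$slopes$X1))
  expect_named(sm$fits, c("X1", "X2", "X4"))
  expect_equal(sm$fits$X1$order, 6L)
})
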