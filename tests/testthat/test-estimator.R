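# A tiny full-data problem reused across blocks: in/out toy with
# analytical slopes, where every stage of the chain is exact.
toy_problem <- function(objective = "slope", f = 0.6) {
  toy <- toy_in_out_model(a = 2, b = 1, f = f, A0 = 0.2)
  sim <- simulate_gma(toy, seq(0, 4, length.out = 15))
  sl <- analytical_slopes(toy, sim$trajectory)
  bounds <- tibble::tibble(flux = c("vin", "vout", "vout"),
                           parameter = c("gamma", "gamma", "A"),
                           lower = c(0, 0, 0), upper = c(10, 10, 2))
  estimation_problem(toy, sim$trajectory, slopes = sl,
                     partition = flux_partition(toy, "vin"),
                     objective = objective, bounds = bounds,
                     truth = flux_parameters(toy)$value)
}

test_that("phi_C matches hand arithmetic on a frozen model", {
  # a model frozen at X == 1 (zero net flux), data (1, 3) at two times:
  # Phi_C = (0 + 4) / 2 = 2
  frozen <- gma_model("A", c("u", "w"), S = matrix(c(1, -1), 1, 2),
                      gamma = c(1, 1), orders = matrix(0, 2, 1,
                        dimnames = list(NULL, "A")),
                      x0 = c(A = 1),
                      structure = matrix(FALSE, 2, 1,
                                         dimnames = list(NULL, "A")))
  data <- tibble::tibble(time = c(0, 1), A = c(1, 3))
  expect_equal(phi_C(frozen, data), 2, tolerance = 1e-8)
})

test_that("phi_C is ~0 at the truth and the penalty on integration failure", {
  case <- make_branched_case(noise_cv = 0)
  expect_lt(phi_C(case$model, case$data), 1e-12)
  exploded <- set_flux_parameters(case$model, c(20, 40), "v1")
  expect_equal(phi_C(exploded, case$data, penalty = 1e3,
                     sim_control = list(maxsteps = 500, wall = 5)),
               1e3)
})

test_that("phi_S vanishes at the truth and scales quadratically", {
  case <- make_branched_case(noise_cv = 0)
  sl <- analytical_slopes(case$model, case$truth_data)
  expect_lt(phi_S(case$model, case$data, sl), 1e-24)

  # doubling every slope residual quadruples the objective
  sl1 <- sl; sl2 <- sl
  for (sp in case$model$species) {
    sl1[[sp]] <- sl[[sp]] + 0.1
    sl2[[sp]] <- sl[[sp]] + 0.2
  }
  p1 <- phi_S(case$model, case$data, sl1)
  p2 <- phi_S(case$model, case$data, sl2)
  expect_equal(p2 / p1, 4, tolerance = 1e-10)
})

test_that("the incremental chain is exact at the true independent parameters", {
  pb <- branched_problem("slope")
  p_true <- flux_parameters(pb$case$model, c("v1", "v6"))$value
  det <- incremental_objective(p_true, pb$problem, detail = TRUE)
  expect_lt(det$phi, 1e-20)
  expect_lt(parameter_error(det$params$value, pb$case$truth), 1e-8)
})

test_that("infeasible independent parameters draw the penalty", {
  pb <- branched_problem("slope")
  # gamma_1 = 0 kills the input flux: the dependent solve then forces
  # v2/v5 negative over most of the transient
  det <- incremental_objective(c(0, -0.8, 6, 0.8), pb$problem,
                               detail = TRUE)
  expect_equal(det$phi, pb$case$penalty)
  expect_false(det$feasible)
})

test_that("the missing-data objective reduces to the full-data one", {
  pb <- branched_problem("slope")
  set.seed(31)
  for (i in 1:20) {
    p_I <- c(stats::runif(1, 0, 25), stats::runif(1, -2, 0),
             stats::runif(1, 0, 25), stats::runif(1, 0, 2))
    a <- incremental_objective(p_I, pb$problem)
    b <- incremental_objective_missing(p_I, pb$problem)
    expect_identical(a, b)
  }
})

test_that("the missing-X3 chain is near-exact at the truth", {
  pb <- branched_problem("slope", missing = "X3")
  theta <- c(flux_parameters(pb$case$model, c("v1", "v3", "v4"))$value,
             unname(pb$case$model$x0["X3"]))  # true X3(0)
  det <- incremental_objective_missing(theta, pb$problem, detail = TRUE)
  expect_lt(det$phi, 1e-3)
  # X3 reconstruction only sees interpolated measured profiles, so the
  # chain is near-exact, not exact
  expect_lt(parameter_error(det$params$value, pb$case$truth), 2)
})

test_that("estimators search exactly the advertised dimensions", {
  pb <- branched_problem("slope")
  fit <- estimate_incremental(pb$problem, runs = 1, seed = 1,
                              control = list(pop = 10, maxiter = 3,
                                             polish = FALSE))
  expect_length(fit$par, 4)   # gamma1, f13, gamma6, f64

  pb3 <- branched_problem("slope", missing = "X3")
  fit3 <- estimate_incremental(pb3$problem, runs = 1, seed = 1,
                               control = list(pop = 10, maxiter = 3,
                                              polish = FALSE))
  expect_length(fit3$par, 8)  # 7 independent parameters + X3(0)

  fitS <- estimate_simultaneous(pb$problem, runs = 1, seed = 1,
                                control = list(pop = 10, maxiter = 2,
                                               polish = FALSE))
  expect_length(fitS$par, 13)
})

test_that("repeated estimation with the same seed is bit-reproducible", {
  prob <- toy_problem()
  ctl <- list(pop = 12, maxiter = 10, polish = FALSE)
  f1 <- estimate_incremental(prob, runs = 1, seed = 7, control = ctl)
  f2 <- estimate_incremental(prob, runs = 1, seed = 7, control = ctl)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$phi, f2$phi)
})

test_that("a zero-generation budget returns the initial best, not converged", {
  prob <- toy_problem()
  fit <- estimate_incremental(prob, runs = 1, seed = 3,
                              control = list(pop = 15, maxiter = 0,
                                             polish = FALSE))
  expect_false(any(fit$runs$converged))
  expect_equal(fit$runs$iterations, 0)
  expect_equal(nrow(fit$trace), 1)
})

test_that("incremental estimation matches a dense grid search on a 1-dof toy", {
  prob <- toy_problem("slope")
  fit <- estimate_incremental(prob, runs = 2, seed = 1,
                              control = list(pop = 15, maxiter = 60))
  # brute-force the single independent parameter (vin's gamma)
  grid <- seq(0.5, 5, by = 0.005)
  phi_grid <- vapply(grid, function(g) incremental_objective(g, prob),
                     numeric(1))
  g_star <- grid[which.min(phi_grid)]
  expect_lt(abs(fit$par[1] - g_star), 0.01)
  # and the chain recovers the truth (a = 2) on analytical slopes
  expect_lt(abs(fit$par[1] - 2), 1e-3)
})

test_that("simultaneous and incremental agree on a small exact problem", {
  prob <- toy_problem("slope")
  inc <- estimate_incremental(prob, runs = 2, seed = 1,
                              control = list(pop = 15, maxiter = 60))
  sim <- estimate_simultaneous(prob, runs = 2, seed = 1,
                               control = list(pop = 30, maxiter = 150))
  expect_lt(inc$phi, 1e-8)
  expect_lt(sim$phi, 1e-6)
  expect_equal(inc$params$value, sim$params$value, tolerance = 0.05)
})

test_that("achieved objectives are recomputable from the returned parameters", {
  pb <- branched_problem("slope")
  fit <- estimate_incremental(pb$problem, runs = 1, seed = 2,
                              control = list(pop = 15, maxiter = 30))
  expect_equal(phi_S(fit$model, pb$problem$data, pb$problem$slopes),
               fit$phi_S, tolerance = 1e-12)
  expect_equal(phi_C(fit$model, pb$problem$data, penalty = 1e3),
               fit$phi_C, tolerance = 1e-9)
})

test_that("parameter_error implements mean absolute relative deviation", {
  expect_equal(parameter_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(parameter_error(c(1.1, 2.2, 3.3), c(1, 2, 3)), 10,
               tolerance = 1e-10)
  # zero-truth components fall back to absolute deviation
  expect_equal(parameter_error(c(0.5, 2), c(0, 2)), 25)
  expect_error(parameter_error(1:3, 1:2))
})

test_that("tidy and glance summarise a fit", {
  prob <- toy_problem()
  fit <- estimate_incremental(prob, runs = 2, seed = 1,
                              control = list(pop = 10, maxiter = 10,
                                             polish = FALSE))
  td <- tidy(fit)
  expect_true(all(c("flux", "parameter", "estimate", "role",
                    "rel_error_pct") %in% names(td)))
  expect_equal(sum(td$role == "independent"), 1)
  gl <- glance(fit)
  expect_equal(gl$n_runs, 2)
  expect_equal(gl$n_par_searched, 1)
  expect_equal(gl$phi, fit$phi)
})
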