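test_that("power-law fluxes evaluate term by term", {
  m <- gma_model("A", "v", S = matrix(1, 1, 1), gamma = 2,
                 orders = matrix(0.5, 1, 1, dimnames = list("v", "A")),
                 x0 = c(A = 1))
  expect_equal(unname(eval_fluxes(m, c(A = 4))), 2 * 4^0.5)

  # all orders zero: constant input flux, empty product = 1
  m0 <- toy_in_out_model(a = 3.7)
  expect_equal(unname(eval_fluxes(m0, c(A = 99))[["vin"]]), 3.7)

  # branched model at its initial state, against a hand calculation of
  # each power-law term
  bm <- branched_model()
  x0 <- bm$x0  # (1.4, 2.7, 1.2, 0.4)
  v_hand <- c(
    v1 = 12 * 1.2^-0.8,
    v2 = 8 * 1.4^0.5,
    v3 = 3 * 2.7^0.75,
    v4 = 5 * 1.2^0.5 * 0.4^0.2,
    v5 = 2 * 1.4^0.5,
    v6 = 6 * 0.4^0.8
  )
  expect_equal(eval_fluxes(bm, x0), v_hand, tolerance = 1e-12)
})

test_that("nonpositive concentration with a non-integer order is a domain error", {
  bm <- branched_model()
  expect_error(eval_fluxes(bm, c(X1 = -1, X2 = 1, X3 = 1, X4 = 1)),
               "v2.*X1|X1.*v2")
})

test_that("the right-hand side is S times the flux vector", {
  # influx = efflux at steady state
  m <- toy_in_out_model(a = 3, b = 3, f = 1)
  expect_equal(unname(eval_rhs(m, c(A = 1))), 0)

  # S = identity passes fluxes through
  mi <- gma_model(c("A", "B"), c("u", "w"), S = diag(2),
                  gamma = c(2, 5),
                  orders = matrix(c(1, 0, 0, 1), 2, 2,
                                  dimnames = list(c("u", "w"),
                                                  c("A", "B"))),
                  x0 = c(A = 1, B = 1))
  x <- c(A = 1.3, B = 0.7)
  expect_equal(eval_rhs(mi, x), eval_fluxes(mi, x),
               ignore_attr = TRUE)

  # mass-balance identity at random states, machine precision
  bm <- branched_model()
  set.seed(42)
  for (i in 1:20) {
    x <- stats::runif(4, 0.1, 5)
    names(x) <- bm$species
    expect_equal(eval_rhs(bm, x), drop(bm$S %*% eval_fluxes(bm, x)),
                 tolerance = 1e-14)
  }
})

test_that("power laws scale as c^f when one regressor is scaled by c", {
  bm <- branched_model()
  set.seed(7)
  for (i in 1:10) {
    x <- stats::runif(4, 0.2, 4); names(x) <- bm$species
    cc <- stats::runif(1, 0.5, 3)
    x2 <- x; x2["X3"] <- cc * x["X3"]
    v1 <- eval_fluxes(bm, x); v2 <- eval_fluxes(bm, x2)
    expect_equal(v2[["v1"]], v1[["v1"]] * cc^-0.8, tolerance = 1e-12)
    expect_equal(v2[["v4"]], v1[["v4"]] * cc^0.5, tolerance = 1e-12)
    expect_equal(v2[["v2"]], v1[["v2"]], tolerance = 1e-12)  # untouched
  }
})

test_that("simulation matches the closed form for exponential decay", {
  # dA/dt = -A  =>  A(t) = exp(-t)
  m <- gma_model("A", "v", S = matrix(-1, 1, 1), gamma = 1,
                 orders = matrix(1, 1, 1, dimnames = list("v", "A")),
                 x0 = c(A = 1))
  sim <- simulate_gma(m, seq(0, 1, length.out = 11))
  expect_equal(sim$status, "ok")
  expect_equal(sim$trajectory$A[11], exp(-1), tolerance = 1e-7)
})

test_that("simulated slopes agree with the model right-hand side to O(h^2)", {
  bm <- branched_model()
  h <- 1e-3
  sim <- simulate_gma(bm, seq(0, 0.5, by = h))
  expect_equal(sim$status, "ok")
  X <- as.matrix(sim$trajectory[bm$species])
  K <- nrow(X)
  for (sp in bm$species) {
    num <- (X[3:K, sp] - X[1:(K - 2), sp]) / (2 * h)
    ana <- vapply(2:(K - 1), function(k) {
      eval_rhs(bm, X[k, ])[[sp]]
    }, numeric(1))
    expect_lt(max(abs(num - ana)), 10 * h^2 * max(abs(ana)))
  }
})

test_that("stiffness exhausts the step budget as a status, not an error", {
  bm <- branched_model()
  # an extreme kinetic order makes the system explode
  bad <- set_flux_parameters(bm, c(12, 40), "v1")  # X3 order 40
  sim <- simulate_gma(bad, seq(0, 6, length.out = 10),
                      maxsteps = 500, wall = 5)
  expect_equal(sim$status, "integration_failed")
  expect_null(sim$trajectory)
  expect_match(sim$failure_reason, ".")
})

test_that("simulate validates its grid and initial state", {
  bm <- branched_model()
  expect_error(simulate_gma(bm, c(0, 0, 1)), "strictly increasing")
  expect_error(simulate_gma(bm, c(1, 0.5)), "strictly increasing")
  expect_error(simulate_gma(bm, 0:5, x0 = c(X1 = -1, X2 = 1, X3 = 1,
                                            X4 = 1)),
               "negative")
})

test_that("off-line variables enter fluxes through their interpolants", {
  prof <- data.frame(time = c(0, 1, 2, 4), value = c(2, 3, 5, 4))
  m <- gma_model(
    "A", "v", S = matrix(1, 1, 1), gamma = 2,
    orders = matrix(c(0.5, 1), 1, 2,
                    dimnames = list("v", c("A", "E"))),
    x0 = c(A = 1), offline = list(E = prof)
  )
  # at a tabulated node the interpolant passes through the value
  expect_equal(unname(eval_fluxes(m, c(A = 4), t = 2)), 2 * 2 * 5)
  # constant extrapolation beyond the table
  expect_equal(unname(eval_fluxes(m, c(A = 4), t = 10)), 2 * 2 * 4)
})

test_that("model parameter layout round-trips through set_flux_parameters", {
  bm <- branched_model()
  p <- flux_parameters(bm)
  expect_equal(nrow(p), 13)  # 6 rate constants + 7 kinetic orders
  scrambled <- set_flux_parameters(bm, rev(seq_len(13)))
  expect_equal(flux_parameters(scrambled)$value, rev(seq_len(13)))
  back <- set_flux_parameters(scrambled, p$value)
  expect_equal(flux_parameters(back), p)
})

test_that("gma_model validates structure", {
  expect_error(
    gma_model(c("A", "B"), c("u", "w"),
              S = matrix(c(1, 1, 2, 2), 2, 2),  # rank 1
              gamma = c(1, 1),
              orders = matrix(1, 2, 1, dimnames = list(NULL, "A")),
              x0 = c(A = 1, B = 1)),
    "row rank")
  expect_error(
    gma_model("A", "v", S = matrix(1, 1, 1), gamma = 1,
              orders = matrix(1, 1, 1, dimnames = list("v", "Zz")),
              x0 = c(A = 1)),
    "Zz")
  expect_error(
    gma_model("A", "v", S = matrix(1, 1, 1), gamma = -2,
              orders = matrix(1, 1, 1, dimnames = list("v", "A")),
              x0 = c(A = 1)),
    "nonnegative")
})
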