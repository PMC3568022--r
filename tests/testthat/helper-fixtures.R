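# Small fixture models built in code.

# one species, constant input (gamma = a) and first-order-like efflux
# (gamma = b, order f on A):  dA/dt = a - b * A^f
toy_in_out_model <- function(a = 2, b = 1, f = 1, A0 = 1) {
  gma_model(
    species = "A", fluxes = c("vin", "vout"),
    S = matrix(c(1, -1), 1, 2),
    gamma = c(a, b),
    orders = matrix(c(0, f), 2, 1, dimnames = list(c("vin", "vout"), "A")),
    x0 = c(A = A0),
    structure = matrix(c(FALSE, TRUE), 2, 1,
                       dimnames = list(c("vin", "vout"), "A"))
  )
}

# random GMA flux structure for regression tests: r regressors, orders in
# [-2, 2] bounded away from 0, gamma in [0.5, 10], positive random states
random_flux_data <- function(K = 12, r = 2, seed = 1) {
  set.seed(seed)
  gamma <- stats::runif(1, 0.5, 10)
  f <- stats::runif(r, 0.3, 2) * sample(c(-1, 1), r, replace = TRUE)
  X <- matrix(stats::runif(K * r, 0.2, 5), K, r,
              dimnames = list(NULL, paste0("X", seq_len(r))))
  v <- gamma * apply(sweep(log(X), 2, f, "*"), 1, function(z) exp(sum(z)))
  list(gamma = gamma, f = f, X = X, v = v)
}

# analytical-slope estimation problem for the branched case
branched_problem <- function(objective = "slope", noise_cv = 0,
                             missing = character(), smoothing = "analytical",
                             poly_order = 6, seed = 1) {
  case <- make_branched_case(noise_cv = noise_cv, missing = missing,
                             seed = seed)
  prob <- inckin:::prepare_problem(case, objective = objective,
                                   smoothing = smoothing,
                                   poly_order = poly_order,
                                   independent = case$independent)
  list(case = case, problem = prob)
}
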