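#' The generic branched-pathway benchmark model
#'
#' A four-metabolite, six-flux branched pathway with feedback inhibition
#' of the input flux by X3 and activation of the X3 efflux by X4 -- the
#' classical didactic GMA benchmark.  The model carries thirteen kinetic
#' parameters (six rate constants, seven kinetic orders):
#' \deqn{v_1 = 12 X_3^{-0.8},\; v_2 = 8 X_1^{0.5},\; v_3 = 3 X_2^{0.75},}
#' \deqn{v_4 = 5 X_3^{0.5} X_4^{0.2},\; v_5 = 2 X_1^{0.5},\; v_6 = 6 X_4^{0.8},}
#' with balances `X1: v1 - v2 - v5` (the X1 efflux splits 8:2 between the
#' main chain and the branch), `X2: v2 - v3`, `X3: v3 - v4`,
#' `X4: v5 - v6` and initial state `(1.4, 2.7, 1.2, 0.4)`.
#'
#' @return a [gma_model()] with the true parameters.
#' @export
branched_model <- function() {
  species <- paste0("X", 1:4)
  fluxes <- paste0("v", 1:6)
  S <- rbind(
    c( 1, -1,  0,  0, -1,  0),
    c( 0,  1, -1,  0,  0,  0),
    c( 0,  0,  1, -1,  0,  0),
    c( 0,  0,  0,  0,  1, -1)
  )
  orders <- matrix(0, 6, 4, dimnames = list(fluxes, species))
  orders["v1", "X3"] <- -0.8
  orders["v2", "X1"] <- 0.5
  orders["v3", "X2"] <- 0.75
  orders["v4", "X3"] <- 0.5
  orders["v4", "X4"] <- 0.2
  orders["v5", "X1"] <- 0.5
  orders["v6", "X4"] <- 0.8
  gma_model(species, fluxes, S,
            gamma = c(12, 8, 3, 5, 2, 6),
            orders = orders,
            x0 = c(X1 = 1.4, X2 = 2.7, X3 = 1.2, X4 = 0.4))
}

#' Published-style parameter bounds for the branched pathway
#'
#' Rate constants in `[0, 25]`; kinetic orders bounded in magnitude by 2
#' with their signs (activation/inhibition) known a priori, so the single
#' inhibitory order (X3 in v1) is searched in `[-2, 0]` and all others in
#' `[0, 2]`.
#'
#' @return tibble with columns `flux`, `parameter`, `lower`, `upper`.
#' @export
branched_bounds <- function() {
  model <- branched_model()
  layout <- flux_parameters(model)
  layout$lower <- ifelse(layout$parameter == "gamma", 0, 0)
  layout$upper <- ifelse(layout$parameter == "gamma", 25, 2)
  inhib <- layout$flux == "v1" & layout$parameter == "X3"
  layout$lower[inhib] <- -2
  layout$upper[inhib] <- 0
  layout[c("flux", "parameter", "lower", "upper")]
}

#' Generate an in-silico branched-pathway dataset
#'
#' Integrates the true branched model on a uniform grid, then (optionally)
#' corrupts each sample with i.i.d. additive Gaussian noise whose standard
#' deviation is `noise_cv` times the true value (a fixed coefficient of
#' variation), truncating negative draws at zero, and (optionally) masks
#' whole metabolite columns as unmeasured.  Deterministic for a given
#' seed.
#'
#' The default grid -- 30 uniform points on `[0, 6]` -- covers the
#' transient (about a third of the window) and the approach to steady
#' state; the 6th-order polynomial used by the benchmark runs is among
#' the top AIC choices for noisy data on this window.
#'
#' @param noise_cv coefficient of variation of the additive noise
#'   (0 = noise-free, 0.10 = the standard noisy setting).
#' @param missing character vector of species to mask (e.g. `"X3"`).
#' @param seed integer seed for the noise draws.
#' @param K number of sample points.
#' @param t_end time horizon.
#' @return list with `model` (true model), `data` (tibble `time` +
#'   species, noisy/masked), `truth_data` (noise-free tibble), `truth`
#'   (true parameter vector in [flux_parameters()] layout), `bounds`
#'   ([branched_bounds()]), `penalty` (`1e3`), `x0_bounds` (`c(0, 5)`).
#' @export
make_branched_case <- function(noise_cv = 0, missing = character(),
                               seed = 1, K = 30, t_end = 6) {
  model <- branched_model()
  times <- seq(0, t_end, length.out = K)
  sim <- simulate_gma(model, times)
  if (sim$status != "ok") stop("true-model integration failed", call. = FALSE)
  truth_data <- sim$trajectory
  data <- truth_data
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    for (sp in model$species) {
      x <- truth_data[[sp]]
      data[[sp]] <- pmax(x + stats::rnorm(length(x), 0, noise_cv * x), 0)
    }
  }
  for (sp in missing) data[[sp]] <- NA_real_
  # published choices: {v1,v6} with full data, {v1,v3,v4} when X3 is missing;
  # other masking patterns fall back to the automatic ranking
  independent <- if (!length(missing)) c("v1", "v6")
    else if (identical(sort(missing), "X3")) c("v1", "v3", "v4")
    else NULL
  list(model = model, data = data, truth_data = truth_data,
       truth = flux_parameters(model)$value,
       bounds = branched_bounds(), penalty = 1e3, x0_bounds = c(0, 5),
       independent = independent)
}

#' A synthetic surrogate of the L. lactis glycolytic GMA model
#'
#' The second benchmark exercises the method's full feature set -- nine
#' fluxes over six metabolites (degrees of freedom 3) with off-line
#' variables (extracellular glucose, ATP and inorganic phosphate) entering
#' the fluxes through interpolated profiles.  The in vivo NMR dataset
#' behind the original model is external, so this case is a clearly
#' flagged *synthetic surrogate*: the glycolytic structure (PTS uptake,
#' PFK, a lumped FBP-to-triose step, a lumped lower-glycolysis step,
#' pyruvate kinase with FBP activation, lactate dehydrogenase with FBP
#' activation, two pyruvate drains for the mixed-acid branches and
#' lactate export)
#' with nominal parameters chosen inside the published-style bounds to
#' give smooth, non-stiff dynamics.  Its numbers are not a reproduction
#' target; its role is structural.
#'
#' Species: `G6P`, `FBP`, `PGA3`, `PEP`, `Pyr`, `Lac`.
#' The independent set `{v4, v7, v9}` leaves an invertible dependent
#' block and is the partition used by the packaged runs.
#'
#' @return a [gma_model()] with the surrogate's nominal parameters.
#' @export
lactis_model <- function() {
  species <- c("G6P", "FBP", "PGA3", "PEP", "Pyr", "Lac")
  fluxes <- paste0("v", 1:9)
  #        v1  v2  v3  v4  v5  v6  v7  v8  v9
  S <- rbind(
    c(  1, -1,  0,  0,  0,  0,  0,  0,  0),  # G6P
    c(  0,  1, -1,  0,  0,  0,  0,  0,  0),  # FBP
    c(  0,  0,  2, -1,  0,  0,  0,  0,  0),  # PGA3
    c( -1,  0,  0,  1, -1,  0,  0,  0,  0),  # PEP
    c(  1,  0,  0,  0,  1, -1, -1, -1,  0),  # Pyr
    c(  0,  0,  0,  0,  0,  1,  0,  0, -1)   # Lac
  )
  regs <- c(species, "Glu", "ATP", "Pi")
  orders <- matrix(0, 9, length(regs), dimnames = list(fluxes, regs))
  orders["v1", c("Glu", "PEP")] <- c(0.6, 0.4)   # PTS uptake
  orders["v2", c("G6P", "ATP")] <- c(0.7, 0.4)   # PFK
  orders["v3", c("FBP", "Pi")] <- c(0.6, 0.3)    # FBP -> 2 x triose/PGA
  orders["v4", "PGA3"] <- 0.8                    # lower glycolysis lump
  orders["v5", c("PEP", "FBP")] <- c(0.7, 0.3)   # pyruvate kinase
  orders["v6", c("Pyr", "FBP")] <- c(0.8, 0.2)   # LDH
  orders["v7", "Pyr"] <- 0.6                     # acetate-branch drain
  orders["v8", c("Pyr", "Pi")] <- c(0.5, 0.3)    # formate/ethanol branch
  orders["v9", "Lac"] <- 0.7                     # lactate export
  gamma <- c(v1 = 2.0, v2 = 3.0, v3 = 2.5, v4 = 3.0, v5 = 2.0,
             v6 = 2.5, v7 = 0.8, v8 = 0.4, v9 = 0.6)
  offline <- list(
    Glu = data.frame(time = c(0, 5, 10, 15, 20, 25, 30),
                     value = c(20, 15, 9, 4.5, 1.8, 0.6, 0.2)),
    ATP = data.frame(time = c(0, 5, 10, 15, 20, 25, 30),
                     value = c(1.0, 2.2, 2.6, 2.2, 1.5, 0.9, 0.6)),
    Pi = data.frame(time = c(0, 5, 10, 15, 20, 25, 30),
                    value = c(10, 7.5, 5.5, 4.5, 5.0, 6.5, 8.0))
  )
  gma_model(species, fluxes, S, gamma = gamma, orders = orders,
            x0 = c(G6P = 1.0, FBP = 0.8, PGA3 = 0.5, PEP = 1.2,
                   Pyr = 0.4, Lac = 0.1),
            offline = offline)
}

#' Published-style bounds for the lactococcal surrogate
#'
#' Rate constants in `[0, 50]`; independent kinetic orders (signs known a
#' priori) in `[0, 5]`; dependent kinetic orders in `[-5, 5]`.
#'
#' @param independent flux names of the independent set (default
#'   `c("v4", "v7", "v9")`).
#' @return tibble with columns `flux`, `parameter`, `lower`, `upper`.
#' @export
lactis_bounds <- function(independent = c("v4", "v7", "v9")) {
  model <- lactis_model()
  layout <- flux_parameters(model)
  is_gamma <- layout$parameter == "gamma"
  is_ind <- layout$flux %in% independent
  layout$lower <- ifelse(is_gamma, 0, ifelse(is_ind, 0, -5))
  layout$upper <- ifelse(is_gamma, 50, 5)
  layout[c("flux", "parameter", "lower", "upper")]
}

#' Generate the synthetic lactococcal surrogate dataset
#'
#' Simulates [lactis_model()] on a uniform grid over a 30-minute window
#' (the time scale of a glucose pulse experiment) and optionally adds
#' proportional Gaussian noise as in [make_branched_case()].
#'
#' @param noise_cv coefficient of variation of the additive noise.
#' @param seed integer seed.
#' @param K number of sample points.
#' @param t_end time horizon (minutes).
#' @return list with the same shape as [make_branched_case()], plus
#'   `independent = c("v4","v7","v9")` and `penalty = 1e5`.
#' @export
make_lactis_case <- function(noise_cv = 0, seed = 1, K = 25, t_end = 30) {
  model <- lactis_model()
  times <- seq(0, t_end, length.out = K)
  sim <- simulate_gma(model, times, wall = 30)
  if (sim$status != "ok") stop("surrogate integration failed", call. = FALSE)
  truth_data <- sim$trajectory
  data <- truth_data
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    for (sp in model$species) {
      x <- truth_data[[sp]]
      data[[sp]] <- pmax(x + stats::rnorm(length(x), 0, noise_cv * x), 0)
    }
  }
  list(model = model, data = data, truth_data = truth_data,
       truth = flux_parameters(model)$value,
       bounds = lactis_bounds(), penalty = 1e5, x0_bounds = c(0, 5),
       independent = c("v4", "v7", "v9"))
}

#' Run one benchmark row
#'
#' Prepares the estimation problem for a generated case (smoothing and
#' slope estimation included), runs the requested estimator and returns a
#' one-row report in the benchmark-table layout: mean and standard
#' deviation over the repeated runs of the parameter error and both
#' objectives, plus evaluation counts.  Wall-clock time is reported but
#' is machine-dependent and never asserted.
#'
#' @param case a list from [make_branched_case()] or [make_lactis_case()].
#' @param method `"incremental"` or `"simultaneous"`.
#' @param objective `"concentration"` or `"slope"`.
#' @param runs,seed,control passed to the estimator.
#' @param smoothing `"polynomial"` (order fixed by `poly_order`),
#'   `"none"` (raw finite differences), or `"analytical"` (slopes from
#'   the true model's right-hand side -- the idealized-slope setting).
#' @param poly_order polynomial degree used when `smoothing =
#'   "polynomial"` (the benchmark runs use 6).
#' @param independent optional independent flux set (default: the case's
#'   preset, else the top-ranked partition).
#' @return list with `fit` (the `estimation_fit`) and `row` (one-row
#'   tibble).
#' @export
run_benchmark <- function(case, method = c("incremental", "simultaneous"),
                          objective = c("concentration", "slope"),
                          runs = 5, seed = 1, control = list(),
                          smoothing = c("polynomial", "none", "analytical"),
                          poly_order = 6, independent = NULL) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  smoothing <- match.arg(smoothing)
  prep <- prepare_problem(case, objective, smoothing, poly_order,
                          independent)
  fit <- switch(method,
    incremental = estimate_incremental(prep, runs = runs, seed = seed,
                                       control = control),
    simultaneous = estimate_simultaneous(prep, runs = runs, seed = seed,
                                         control = control)
  )
  r <- fit$runs
  row <- tibble::tibble(
    method = method, objective = objective, status = fit$status,
    parameter_error = fit$parameter_error,
    parameter_error_mean = mean(r$parameter_error),
    parameter_error_sd = stats::sd(r$parameter_error),
    phi_C = fit$phi_C, phi_C_mean = mean(r$phi_C),
    phi_C_sd = stats::sd(r$phi_C),
    phi_S = fit$phi_S, phi_S_mean = mean(r$phi_S),
    phi_S_sd = stats::sd(r$phi_S),
    n_evals = fit$n_evals, cpu_sec_mean = mean(r$cpu_sec)
  )
  list(fit = fit, row = row)
}

# Build the estimation_problem for a generated benchmark case.
prepare_problem <- function(case, objective, smoothing, poly_order,
                            independent = NULL) {
  model <- case$model
  data <- case$data
  if (smoothing == "analytical") {
    sl <- analytical_slopes(model, case$truth_data)
    smoothed <- data
  } else if (smoothing == "polynomial") {
    sm <- smooth_timecourse(data, method = "polynomial",
                            candidates = poly_order)
    smoothed <- sm$smoothed
    sl <- sm$slopes
  } else {
    sm <- smooth_timecourse(data, method = "none")
    smoothed <- sm$smoothed
    sl <- sm$slopes
  }
  unmeasured <- model$species[vapply(model$species,
                                     function(s) all(is.na(data[[s]])),
                                     logical(1))]
  if (length(unmeasured)) {
    for (s in unmeasured) sl[[s]] <- NA_real_
  }
  independent <- independent %||% case$independent
  part <- if (is.null(independent)) {
    enumerate_partitions(model, unmeasured)$partition[[1]]
  } else {
    flux_partition(model, independent, unmeasured)
  }
  estimation_problem(model, data, slopes = sl, partition = part,
                     objective = objective, bounds = case$bounds,
                     penalty = case$penalty, x0_bounds = case$x0_bounds,
                     truth = case$truth, smoothed = smoothed)
}
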