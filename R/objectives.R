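#' Define a parameter-estimation problem
#'
#' Bundles everything the estimators need: the model structure (topology
#' and flux regressor structure; current parameter values are mere
#' placeholders), the measured time-course table, the time-slopes, the
#' flux partition, the objective choice, parameter bounds and the penalty
#' constant that replaces the objective whenever integration fails or the
#' dependent-flux chain turns infeasible.
#'
#' Two objectives are supported: the *concentration error*
#' `Phi_C = (1/mK) sum_k ||X_m(t_k) - X(t_k, p)||^2`, which requires
#' integrating the ODE model, and the *slope error*
#' `Phi_S = (1/mK) sum_k ||Xdot_m(t_k) - S v(X_m(t_k), p)||^2`, which does
#' not.  Unmeasured species are excluded from both the sum and the
#' normaliser (`m` counts measured species only).
#'
#' @param model a [gma_model()] giving the structure.
#' @param data tibble with `time` plus one column per species; an all-`NA`
#'   column marks an unmeasured metabolite.  Values are the raw measured
#'   concentrations.
#' @param slopes tibble like `data` holding the estimated time-slopes of
#'   the measured species (e.g. from [smooth_timecourse()] or
#'   [analytical_slopes()]).
#' @param smoothed tibble like `data` with the smoothed concentrations;
#'   used wherever the method evaluates fluxes at "the data" (the
#'   dependent-flux chain, Phi_S, the external drivers of the unmeasured
#'   subsystem).  Defaults to `data` itself.  Phi_C always compares the
#'   integrated trajectory to the raw `data`.
#' @param partition a [flux_partition()]; `NULL` picks the top-ranked
#'   admissible partition from [enumerate_partitions()].
#' @param objective `"concentration"` (Phi_C) or `"slope"` (Phi_S).
#' @param bounds tibble with columns `flux`, `parameter`, `lower`,
#'   `upper` covering every kinetic parameter.
#' @param penalty large objective value assigned to failed integrations
#'   and infeasible dependent-flux chains.
#' @param x0_bounds two-element numeric `c(lower, upper)` for the
#'   estimated initial conditions of unmeasured species.
#' @param truth optional full true parameter vector (layout of
#'   [flux_parameters()] over all fluxes) for benchmark error scoring.
#' @param eps positivity floor used before logarithms and power laws.
#' @param sim_control list of [simulate_gma()] guard settings
#'   (`rtol`, `atol`, `maxsteps`, `wall`).
#' @return an object of class `estimation_problem`.
#' @export
estimation_problem <- function(model, data, slopes = NULL, partition = NULL,
                               objective = c("concentration", "slope"),
                               bounds, penalty = 1e3,
                               x0_bounds = c(0, 5), truth = NULL,
                               eps = 1e-9, sim_control = list(),
                               smoothed = NULL) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(data), "time" %in% names(data))
  miss_sp <- setdiff(model$species, names(data))
  if (length(miss_sp)) {
    stop("`data` lacks a column for species: ",
         paste(miss_sp, collapse = ", "), call. = FALSE)
  }
  times <- data$time
  if (any(diff(times) <= 0)) stop("`data` times must be strictly increasing",
                                  call. = FALSE)
  unmeasured <- model$species[vapply(model$species,
                                     function(s) all(is.na(data[[s]])),
                                     logical(1))]
  measured <- setdiff(model$species, unmeasured)
  if (any(is.na(data[measured]))) {
    stop("partially missing species columns are not supported: a species ",
         "is either measured at all time points or unmeasured", call. = FALSE)
  }
  if (is.null(partition)) {
    partition <- enumerate_partitions(model, unmeasured)$partition[[1]]
  }
  if (!setequal(partition$unmeasured, unmeasured)) {
    stop("partition and data disagree on the unmeasured species",
         call. = FALSE)
  }
  if (is.null(smoothed)) smoothed <- data
  stopifnot(is.data.frame(smoothed), "time" %in% names(smoothed))
  if (any(is.na(smoothed[measured]))) {
    stop("`smoothed` must provide values for every measured species",
         call. = FALSE)
  }
  if (is.null(slopes)) {
    if (objective == "slope") {
      stop("the slope objective needs `slopes`", call. = FALSE)
    }
    sm <- smooth_timecourse(smoothed, method = "none")
    slopes <- sm$slopes
  }
  stopifnot(is.data.frame(slopes), "time" %in% names(slopes))
  need <- c("flux", "parameter", "lower", "upper")
  if (!all(need %in% names(bounds))) {
    stop("`bounds` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  sim_defaults <- list(rtol = 1e-8, atol = 1e-10, maxsteps = 1e5, wall = 10)
  sim_control <- utils::modifyList(sim_defaults, sim_control)

  structure(
    list(model = model, data = tibble::as_tibble(data),
         slopes = tibble::as_tibble(slopes),
         partition = partition, objective = objective,
         bounds = tibble::as_tibble(bounds), penalty = penalty,
         x0_bounds = x0_bounds, truth = truth, eps = eps,
         times = times, measured = measured, unmeasured = unmeasured,
         X_M = as.matrix(data[measured]),
         smoothed = tibble::as_tibble(smoothed),
         X_S = as.matrix(smoothed[measured]),
         slopes_M = as.matrix(slopes[measured]),
         interps = stats::setNames(lapply(measured, function(s) {
           stats::splinefun(times, smoothed[[s]], method = "monoH.FC")
         }), measured),
         sim_control = sim_control),
    class = "estimation_problem"
  )
}

#' @export
print.estimation_problem <- function(x, ...) {
  cat("<estimation_problem> ", x$objective, " objective, ",
      nrow(x$data), " time points\n  I = {",
      paste(x$partition$independent, collapse = ", "), "}",
      if (length(x$unmeasured))
        paste0(", unmeasured: ", paste(x$unmeasured, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# lower/upper vectors for the flux_parameters layout of `fluxes`
bounds_vectors <- function(problem, fluxes) {
  layout <- flux_parameters(problem$model, fluxes)
  lo <- numeric(nrow(layout)); hi <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    row <- problem$bounds[problem$bounds$flux == layout$flux[i] &
                            problem$bounds$parameter == layout$parameter[i], ]
    if (nrow(row) != 1) {
      stop("bounds must give exactly one row for ", layout$flux[i], ":",
           layout$parameter[i], call. = FALSE)
    }
    lo[i] <- row$lower; hi[i] <- row$upper
  }
  list(lower = lo, upper = hi, layout = layout)
}

#' Mean squared concentration error (Phi_C)
#'
#' Integrates the model over the data grid and returns the mean squared
#' deviation from the measured concentrations, averaged over measured
#' species and time points.  A failed integration returns `penalty` --
#' failure is data, not an exception, so a global optimizer can steer away
#' from stiffness-inducing parameter combinations.
#'
#' @param model a fully parameterised [gma_model()].
#' @param data tibble with `time` and species columns (all-`NA` column =
#'   unmeasured, excluded from the error and the normaliser).
#' @param penalty value returned on integration failure.
#' @param x0 initial state (defaults to the first data row for measured
#'   species and the model's `x0` for unmeasured ones).
#' @param sim_control list of [simulate_gma()] settings.
#' @return nonnegative scalar.
#' @export
phi_C <- function(model, data, penalty = 1e3, x0 = NULL,
                  sim_control = list()) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  measured <- intersect(model$species, names(data))
  measured <- measured[vapply(measured, function(s) !all(is.na(data[[s]])),
                              logical(1))]
  if (!length(measured)) stop("no measured species in `data`", call. = FALSE)
  if (is.null(x0)) {
    x0 <- model$x0
    x0[measured] <- as.numeric(data[1, measured])
  }
  sc <- utils::modifyList(list(rtol = 1e-8, atol = 1e-10, maxsteps = 1e5,
                               wall = 10), sim_control)
  sim <- simulate_gma(model, data$time, x0 = x0, rtol = sc$rtol,
                      atol = sc$atol, maxsteps = sc$maxsteps, wall = sc$wall)
  if (sim$status != "ok") return(penalty)
  pred <- as.matrix(sim$trajectory[measured])
  obs <- as.matrix(data[measured])
  mean((obs - pred)^2)
}

#' Mean squared slope error (Phi_S)
#'
#' Evaluates the fluxes at the measured (smoothed) concentrations --
#' no integration -- and returns the mean squared deviation between the
#' estimated slopes and `S v`, over measured species and time points.
#' Concentrations are floored at `eps` before the power laws so that the
#' optimizer loop never throws on a stray nonpositive value.
#'
#' @param model a fully parameterised [gma_model()].
#' @param data tibble of (smoothed) concentrations; unmeasured species
#'   columns must carry their reconstructed values or be absent from both
#'   the error and the flux evaluation only if no flux needs them.
#' @param slopes tibble of slope estimates for the measured species.
#' @param eps positivity floor.
#' @return nonnegative scalar.
#' @export
phi_S <- function(model, data, slopes, eps = 1e-9) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  measured <- intersect(model$species, names(slopes))
  measured <- measured[vapply(measured, function(s) !all(is.na(slopes[[s]])),
                              logical(1))]
  if (!length(measured)) stop("no measured slopes", call. = FALSE)
  X <- as.matrix(data[model$species])
  if (any(is.na(X))) {
    stop("`data` must provide concentrations for every species entering ",
         "the fluxes (reconstruct unmeasured ones first)", call. = FALSE)
  }
  V <- eval_fluxes_grid(model, pmax(X, eps), data$time, check = FALSE)
  pred <- V %*% t(model$S[measured, , drop = FALSE])
  obs <- as.matrix(slopes[measured])
  mean((obs - pred)^2)
}

## ---- the incremental chain ------------------------------------------------

# Shared engine: given independent parameters (and unmeasured initial
# conditions), run the incremental chain and return the objective value,
# optionally with full detail.
incremental_eval <- function(theta, problem, detail = FALSE) {
  part <- problem$partition
  model <- problem$model
  u <- length(problem$unmeasured)
  ind <- part$independent
  n_pI <- sum(flux_n_params(model, ind))
  if (length(theta) != n_pI + u) {
    stop("expected ", n_pI + u, " values (", n_pI, " independent ",
         "parameters + ", u, " unmeasured initial conditions), got ",
         length(theta), call. = FALSE)
  }
  p_I <- theta[seq_len(n_pI)]
  xU0 <- if (u) theta[n_pI + seq_len(u)] else numeric()
  names(xU0) <- problem$unmeasured

  pen <- function(reason) {
    if (detail) list(phi = problem$penalty, feasible = FALSE,
                     reason = reason) else problem$penalty
  }

  model_I <- if (n_pI) set_flux_parameters(model, p_I, ind) else model
  times <- problem$times
  K <- length(times)

  # unmeasured metabolites: simulate the U-subsystem driven by the
  # interpolated measured profiles; only independent fluxes can appear in
  # an unmeasured balance (enforced by flux_partition)
  if (u) {
    X_U <- simulate_unmeasured(model_I, problem, xU0, fluxes = ind)
    if (is.null(X_U)) return(pen("U-subsystem integration failed"))
  } else {
    X_U <- matrix(0, K, 0)
  }

  X_full <- matrix(NA_real_, K, n_species(model),
                   dimnames = list(NULL, model$species))
  X_full[, problem$measured] <- problem$X_S
  if (u) X_full[, problem$unmeasured] <- X_U
  X_full <- pmax(X_full, problem$eps)

  V_all_I <- eval_fluxes_grid(model_I, X_full, times, check = FALSE)
  v_I <- V_all_I[, ind, drop = FALSE]

  V_D <- if (u || length(part$dependent) < length(part$measured)) {
    dependent_fluxes_missing(part, problem$slopes_M, v_I)
  } else {
    dependent_fluxes(part, problem$slopes_M, v_I)
  }

  # flux-by-flux log-linear regression of the dependent parameters
  regressors <- cbind(X_full, offline_values(model, times))
  fits <- list()
  model_full <- model_I
  for (fl in part$dependent) {
    regs <- colnames(model$orders)[model$structure[fl, ]]
    vj <- V_D[, fl]
    n_nonpos <- sum(!(is.finite(vj) & vj > problem$eps))
    if (n_nonpos / K > 0.5) {
      return(pen(paste0("dependent flux ", fl, " nonpositive at ",
                        n_nonpos, "/", K, " time points")))
    }
    b <- problem$bounds[problem$bounds$flux == fl, ]
    fit <- tryCatch(
      suppressWarnings(
        fit_flux_loglinear(vj, regressors[, regs, drop = FALSE],
                           bounds = b, eps = problem$eps)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(pen(paste0("regression of ", fl, " failed")))
    fits[[fl]] <- fit
    model_full <- set_flux_parameters(
      model_full, c(fit$gamma, fit$orders), fl)
  }

  data_eval <- problem$smoothed
  if (u) for (s in problem$unmeasured) data_eval[[s]] <- X_full[, s]

  phi <- if (problem$objective == "concentration") {
    x0 <- model$x0
    x0[problem$measured] <- as.numeric(problem$data[1, problem$measured])
    if (u) x0[problem$unmeasured] <- xU0
    phi_C(model_full, problem$data, penalty = problem$penalty, x0 = x0,
          sim_control = problem$sim_control)
  } else {
    phi_S(model_full, data_eval, problem$slopes, eps = problem$eps)
  }

  if (!detail) return(phi)
  list(phi = phi, feasible = TRUE, model = model_full,
       regressions = fits, v_I = v_I, v_D = V_D, x_u0 = xU0,
       X_U = if (u) X_U else NULL,
       params = flux_parameters(model_full))
}

# Integrate Xdot_U = S_U v(X_M(t), X_U, p) with interpolated measured
# profiles.  `fluxes` restricts the evaluation to the fluxes allowed to
# appear in the unmeasured balances (the independent set during the
# incremental chain; all fluxes for the simultaneous baseline).
#
# The drivers are interpolants whose error dwarfs any tight solver
# tolerance, so the subsystem is integrated with classical fixed-step
# RK4 on a refined grid (4 substeps per sampling interval) instead of an
# adaptive stiff solver; a state that turns non-finite or explodes is
# reported as failure (NULL), which the caller maps to the penalty.
simulate_unmeasured <- function(model, problem, xU0, fluxes) {
  meas <- problem$measured
  unmeas <- problem$unmeasured
  times <- problem$times
  S_U <- unname(problem$partition$S_U[, fluxes, drop = FALSE])
  sp_order <- model$species
  meas_idx <- match(meas, sp_order)
  unmeas_idx <- match(unmeas, sp_order)
  F_sp <- unname(model$orders[fluxes, sp_order, drop = FALSE])
  gam_f <- unname(model$gamma[fluxes])
  off <- model$offline
  has_off <- length(off) > 0
  F_off <- if (has_off) {
    unname(model$orders[fluxes, names(off), drop = FALSE])
  } else NULL

  # all RK4 stage times are known in advance: evaluate every driver once
  n_sub <- 4L
  K <- length(times)
  n_stage <- 2L * n_sub  # half-step resolution within each interval
  tt <- unlist(lapply(seq_len(K - 1), function(k) {
    times[k] + (0:n_stage) * (times[k + 1] - times[k]) / n_stage
  }))
  D <- vapply(problem$interps, function(f) pmax(f(tt), 1e-12),
              numeric(length(tt)))
  W <- if (has_off) {
    log(vapply(off, function(f) pmax(f(tt), 1e-12), numeric(length(tt))))
  } else NULL

  x_buf <- numeric(length(sp_order))
  rhs <- function(j, xU) {   # j indexes a row of the stage-time tables
    x_buf[meas_idx] <- D[j, ]
    x_buf[unmeas_idx] <- xU
    x_buf <- pmax(x_buf, 1e-12)
    lnv <- F_sp %*% log(x_buf)
    if (has_off) lnv <- lnv + F_off %*% W[j, ]
    drop(S_U %*% (gam_f * exp(lnv)))
  }

  u <- length(xU0)
  out <- matrix(NA_real_, K, u)
  x <- as.numeric(xU0)
  out[1, ] <- x
  for (k in seq_len(K - 1)) {
    h <- (times[k + 1] - times[k]) / n_sub
    base <- (k - 1L) * (n_stage + 1L)
    for (s in seq_len(n_sub)) {
      j0 <- base + 2L * (s - 1L) + 1L
      k1 <- rhs(j0, x)
      k2 <- rhs(j0 + 1L, x + h / 2 * k1)
      k3 <- rhs(j0 + 1L, x + h / 2 * k2)
      k4 <- rhs(j0 + 2L, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (any(!is.finite(x)) || any(abs(x) > 1e8)) return(NULL)
    }
    out[k + 1L, ] <- x
  }
  colnames(out) <- unmeas
  out
}

#' Incremental objective (full data)
#'
#' One evaluation of the incremental loop: given trial independent
#' parameters `p_I`, compute the independent fluxes at the measured
#' concentrations, solve the dependent fluxes from the slopes, regress
#' the dependent parameters flux-by-flux in log scale, assemble the full
#' parameter vector and score it with the problem's objective.
#' Infeasibility anywhere in the chain (a dependent flux nonpositive at
#' more than half the time points, an estimability failure, a failed
#' integration under Phi_C) yields the penalty value.
#'
#' @param p_I numeric vector of independent parameters in
#'   [flux_parameters()] layout over the independent fluxes.
#' @param problem an [estimation_problem()] without unmeasured species.
#' @param detail return the assembled model and diagnostics instead of
#'   the bare objective value.
#' @return scalar objective, or a detail list when `detail = TRUE`.
#' @export
incremental_objective <- function(p_I, problem, detail = FALSE) {
  if (length(problem$unmeasured)) {
    stop("problem has unmeasured species; use ",
         "incremental_objective_missing()", call. = FALSE)
  }
  incremental_eval(p_I, problem, detail = detail)
}

#' Incremental objective with unmeasured metabolites
#'
#' As [incremental_objective()], but the trial vector carries the initial
#' conditions of the unmeasured species after the independent parameters.
#' The unmeasured profiles are reconstructed by integrating their balances
#' (which by construction involve independent fluxes only) with the
#' measured concentrations interpolated as external drivers; the
#' dependent fluxes then come from the measured-row pseudo-inverse solve.
#' With no unmeasured species this reduces exactly to
#' [incremental_objective()].
#'
#' @param theta numeric vector `c(p_I, X_U(t0))`.
#' @inheritParams incremental_objective
#' @return scalar objective, or a detail list when `detail = TRUE`.
#' @export
incremental_objective_missing <- function(theta, problem, detail = FALSE) {
  incremental_eval(theta, problem, detail = detail)
}

#' Mean absolute relative parameter error, in percent
#'
#' The benchmark error score: the mean over all rate constants and kinetic
#' orders of `|est - true| / |true|`, times 100.  Components whose true
#' value is zero contribute their absolute deviation instead (relative
#' error is undefined there).
#'
#' @param p_est,p_true equal-length numeric vectors.
#' @return scalar percentage.
#' @export
parameter_error <- function(p_est, p_true) {
  stopifnot(length(p_est) == length(p_true))
  dev <- ifelse(p_true != 0, abs((p_est - p_true) / p_true),
                abs(p_est - p_true))
  100 * mean(dev)
}
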