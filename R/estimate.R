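#' Incremental (two-stage) parameter estimation
#'
#' Minimises the chosen objective over the independent parameters only
#' (plus the initial conditions of any unmeasured metabolites), with the
#' dependent parameters recovered inside every objective evaluation by the
#' slope-based flux decomposition and per-flux log-linear regression.  The
#' search space therefore has `sum of |p_I|` (+ number of unmeasured
#' species) dimensions, not the full parameter count.
#'
#' The global search is the seeded differential-evolution optimizer
#' [de_optimize()].  The estimation is repeated `runs` times with
#' consecutive seeds; the best run is reported along with a per-run
#' summary, mirroring the usual repeat-to-trust-the-global-optimum
#' practice.
#'
#' @param problem an [estimation_problem()].
#' @param runs number of repeated optimizations (default 5).
#' @param seed base seed; run `r` uses `seed + r - 1`.
#' @param control list of [de_optimize()] settings
#'   (`pop`, `maxiter`, `reltol`, `stall`, `wall`, `polish`).
#' @return an object of class `estimation_fit`.
#' @export
estimate_incremental <- function(problem, runs = 5, seed = 1,
                                 control = list()) {
  part <- problem$partition
  bv <- bounds_vectors(problem, part$independent)
  u <- length(problem$unmeasured)
  lower <- c(bv$lower, rep(problem$x0_bounds[1], u))
  upper <- c(bv$upper, rep(problem$x0_bounds[2], u))
  fn <- function(theta) incremental_eval(theta, problem)

  # Two-phase warm start for the concentration objective: the slope
  # objective needs no ODE integration and its minimiser lies in the same
  # region of the independent-parameter space, so it is first optimised
  # cheaply and its optimum is planted in the initial population of every
  # concentration-error run (slope-based estimates as starting values for
  # concentration-based fitting).
  warm <- isTRUE(control$warm_start %||%
                   (problem$objective == "concentration"))
  control$warm_start <- NULL
  init <- NULL
  if (warm && problem$objective == "concentration") {
    sprob <- problem
    sprob$objective <- "slope"
    sfn <- function(theta) incremental_eval(theta, sprob)
    sopt <- de_optimize(sfn, lower, upper, seed = seed,
                        pop = max(10L * length(lower), 20L),
                        maxiter = 100, stall = 8, trace = FALSE)
    if (sopt$value < problem$penalty) init <- matrix(sopt$par, 1)
  }

  run_estimation(problem, fn, lower, upper, runs, seed, control,
                 method = "incremental", init = init,
                 assemble = function(theta) {
                   incremental_eval(theta, problem, detail = TRUE)
                 })
}

#' Simultaneous (single-step) estimation baseline
#'
#' Minimises the same objective over the *entire* parameter vector (every
#' rate constant and kinetic order, plus unmeasured initial conditions),
#' with the same optimizer, penalties and bounds.  This is the baseline
#' against which the incremental method's reduction in search-space
#' dimension and objective-evaluation count is measured.
#'
#' @inheritParams estimate_incremental
#' @return an object of class `estimation_fit`.
#' @export
estimate_simultaneous <- function(problem, runs = 5, seed = 1,
                                  control = list()) {
  model <- problem$model
  bv <- bounds_vectors(problem, model$fluxes)
  u <- length(problem$unmeasured)
  lower <- c(bv$lower, rep(problem$x0_bounds[1], u))
  upper <- c(bv$upper, rep(problem$x0_bounds[2], u))
  n_p <- length(bv$lower)

  eval_full <- function(theta, detail = FALSE) {
    m_full <- set_flux_parameters(model, theta[seq_len(n_p)])
    xU0 <- if (u) theta[n_p + seq_len(u)] else numeric()
    names(xU0) <- problem$unmeasured
    pen <- function(reason) {
      if (detail) list(phi = problem$penalty, feasible = FALSE,
                       reason = reason) else problem$penalty
    }
    if (problem$objective == "concentration") {
      x0 <- model$x0
      x0[problem$measured] <- as.numeric(problem$data[1, problem$measured])
      if (u) x0[problem$unmeasured] <- xU0
      phi <- phi_C(m_full, problem$data, penalty = problem$penalty,
                   x0 = x0, sim_control = problem$sim_control)
    } else {
      data_eval <- problem$smoothed
      if (u) {
        X_U <- simulate_unmeasured(m_full, problem, xU0,
                                   fluxes = model$fluxes)
        if (is.null(X_U)) return(pen("U-subsystem integration failed"))
        for (s in problem$unmeasured) data_eval[[s]] <- X_U[, s]
      }
      phi <- phi_S(m_full, data_eval, problem$slopes, eps = problem$eps)
    }
    if (!detail) return(phi)
    list(phi = phi, feasible = TRUE, model = m_full, regressions = NULL,
         x_u0 = xU0, params = flux_parameters(m_full))
  }

  run_estimation(problem, eval_full, lower, upper, runs, seed, control,
                 method = "simultaneous",
                 assemble = function(theta) eval_full(theta, detail = TRUE))
}

# Shared repeat-run driver for both estimators.
run_estimation <- function(problem, fn, lower, upper, runs, seed, control,
                           method, assemble, init = NULL) {
  stopifnot(runs >= 1)
  ctl <- utils::modifyList(
    list(pop = NULL, maxiter = 200, reltol = 1e-4, stall = 5,
         F = 0.8, CR = 0.9, wall = Inf, polish = TRUE, trace = TRUE),
    control)
  run_rows <- list()
  best <- NULL
  for (r in seq_len(runs)) {
    t0 <- proc.time()[["elapsed"]]
    opt <- de_optimize(fn, lower, upper, seed = seed + r - 1,
                       pop = ctl$pop, maxiter = ctl$maxiter,
                       reltol = ctl$reltol, stall = ctl$stall,
                       F = ctl$F, CR = ctl$CR, wall = ctl$wall,
                       polish = ctl$polish, trace = ctl$trace,
                       init = init)
    elapsed <- proc.time()[["elapsed"]] - t0
    det <- assemble(opt$par)
    scores <- score_fit(problem, det)
    run_rows[[r]] <- tibble::tibble(
      run = r, seed = seed + r - 1, phi = opt$value,
      phi_C = scores$phi_C, phi_S = scores$phi_S,
      parameter_error = scores$err, n_evals = opt$n_evals,
      iterations = opt$iterations, converged = opt$converged,
      cpu_sec = elapsed, feasible = det$feasible %||% TRUE
    )
    if (is.null(best) || opt$value < best$opt$value) {
      best <- list(opt = opt, detail = det, scores = scores, run = r)
    }
  }
  runs_tbl <- dplyr::bind_rows(run_rows)
  status <- if (best$opt$value >= problem$penalty) "estimation_failed" else "ok"
  structure(
    list(method = method, objective = problem$objective, status = status,
         par = best$opt$par, model = best$detail$model,
         params = best$detail$params, x_u0 = best$detail$x_u0,
         phi = best$opt$value, phi_C = best$scores$phi_C,
         phi_S = best$scores$phi_S,
         parameter_error = best$scores$err,
         regressions = best$detail$regressions,
         trace = best$opt$trace, best_run = best$run,
         runs = runs_tbl, n_evals = sum(runs_tbl$n_evals),
         partition = problem$partition, problem = problem),
    class = "estimation_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Both objectives and the benchmark error at an assembled solution.
score_fit <- function(problem, det) {
  if (is.null(det$model)) {
    return(list(phi_C = problem$penalty, phi_S = problem$penalty,
                err = NA_real_))
  }
  u <- length(problem$unmeasured)
  x0 <- problem$model$x0
  x0[problem$measured] <- as.numeric(problem$data[1, problem$measured])
  if (u) x0[problem$unmeasured] <- det$x_u0
  pC <- phi_C(det$model, problem$data, penalty = problem$penalty, x0 = x0,
              sim_control = problem$sim_control)
  data_eval <- problem$smoothed
  if (u) {
    if (!is.null(det$X_U)) {
      for (s in problem$unmeasured) data_eval[[s]] <- det$X_U[, s]
      pS <- phi_S(det$model, data_eval, problem$slopes, eps = problem$eps)
    } else {
      X_U <- simulate_unmeasured(det$model, problem, det$x_u0,
                                 fluxes = problem$model$fluxes)
      if (is.null(X_U)) {
        pS <- problem$penalty
      } else {
        for (s in problem$unmeasured) data_eval[[s]] <- X_U[, s]
        pS <- phi_S(det$model, data_eval, problem$slopes, eps = problem$eps)
      }
    }
  } else {
    pS <- phi_S(det$model, data_eval, problem$slopes, eps = problem$eps)
  }
  err <- if (!is.null(problem$truth) && !is.null(det$params)) {
    parameter_error(det$params$value, problem$truth)
  } else NA_real_
  list(phi_C = pC, phi_S = pS, err = err)
}

#' @export
print.estimation_fit <- function(x, ...) {
  cat("<estimation_fit> ", x$method, " / ", x$objective,
      " objective -- ", x$status, "\n", sep = "")
  cat("  best of ", nrow(x$runs), " runs: Phi = ", signif(x$phi, 5),
      "  (Phi_C = ", signif(x$phi_C, 5),
      ", Phi_S = ", signif(x$phi_S, 5), ")\n", sep = "")
  if (!is.na(x$parameter_error)) {
    cat("  parameter error = ", signif(x$parameter_error, 4), "%\n",
        sep = "")
  }
  cat("  objective evaluations: ", x$n_evals, " (all runs)\n", sep = "")
  invisible(x)
}
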