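#' Integrate a GMA model over a time grid
#'
#' Integrates `dX/dt = S v(X, p)` with a stiff-capable implicit solver
#' (`deSolve::lsoda`).  Power-law models are notoriously stiff for
#' unfortunate parameter combinations, and during global optimization such
#' combinations are routinely visited; an integration that exhausts its
#' internal step budget (or the wall-clock guard) is therefore *not an
#' error* here.  It is reported as data (`status = "integration_failed"`)
#' so that the estimation objective can map it to its large penalty value.
#'
#' States are floored at `1e-12` inside the right-hand side before the
#' power laws are evaluated.  This is a numerical guard against integrator
#' overshoot into negative concentrations (where non-integer powers are
#' undefined), not part of the model semantics.
#'
#' @param model a [gma_model()].
#' @param times strictly increasing numeric grid; the first element is the
#'   initial time.
#' @param x0 initial concentrations (defaults to the model's).
#' @param rtol,atol relative / absolute integration tolerances.
#' @param maxsteps internal step budget per output interval; exhausting it
#'   yields `integration_failed`.
#' @param wall wall-clock guard in seconds for the whole integration.
#' @return A list of class `gma_simulation` with elements `status`
#'   (`"ok"` or `"integration_failed"`), `trajectory` (tibble with `time`
#'   and one column per species; present iff ok) and `failure_reason`.
#' @export
simulate_gma <- function(model, times, x0 = model$x0,
                         rtol = 1e-8, atol = 1e-10,
                         maxsteps = 1e5, wall = 10) {
  times <- as.numeric(times)
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("`times` must be a strictly increasing grid of length >= 2",
         call. = FALSE)
  }
  x0 <- state_vector(model, x0)
  if (any(x0 < 0)) stop("negative initial concentrations", call. = FALSE)

  rhs <- make_fast_rhs(model)

  msgs <- character()
  out <- tryCatch({
    setTimeLimit(elapsed = wall, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    res <- NULL
    # capture.output also swallows the solver's C-level diagnostics
    utils::capture.output(
      res <- withCallingHandlers(
        deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                     method = "lsoda", rtol = rtol, atol = atol,
                     maxsteps = maxsteps),
        warning = function(w) {
          msgs <<- c(msgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      ))
    res
  }, error = function(e) e)

  fail <- function(reason) {
    structure(list(status = "integration_failed", trajectory = NULL,
                   failure_reason = reason, times = times),
              class = "gma_simulation")
  }
  if (inherits(out, "error")) {
    return(fail(conditionMessage(out)))
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    return(fail(paste0("solver istate ", istate, ": ",
                       paste(msgs, collapse = "; "))))
  }
  if (nrow(out) < length(times) || any(!is.finite(out[, -1]))) {
    return(fail("non-finite or truncated trajectory"))
  }
  traj <- tibble::as_tibble(as.data.frame(out))
  names(traj) <- c("time", model$species)
  structure(list(status = "ok", trajectory = traj, failure_reason = NULL,
                 times = times),
            class = "gma_simulation")
}

# Lean closure for the integrator: v = gamma * exp(F ln x), dx = S v, with
# the 1e-12 concentration floor applied first.  Avoids the bookkeeping of
# eval_fluxes_grid inside the innermost loop.
make_fast_rhs <- function(model) {
  S <- unname(model$S)
  F_sp <- unname(model$orders[, model$species, drop = FALSE])
  off <- model$offline
  has_off <- length(off) > 0
  F_off <- if (has_off) {
    unname(model$orders[, names(off), drop = FALSE])
  } else NULL
  gam <- unname(model$gamma)
  function(t, x, parms) {
    x <- pmax(x, 1e-12)
    lnv <- F_sp %*% log(x)
    if (has_off) {
      w <- pmax(vapply(off, function(f) f(t), numeric(1)), 1e-12)
      lnv <- lnv + F_off %*% log(w)
    }
    list(drop(S %*% (gam * exp(lnv))))
  }
}

#' @export
print.gma_simulation <- function(x, ...) {
  if (x$status == "ok") {
    cat("<gma_simulation> ok, ", nrow(x$trajectory), " time points\n",
        sep = "")
  } else {
    cat("<gma_simulation> integration failed: ", x$failure_reason, "\n",
        sep = "")
  }
  invisible(x)
}

#' Slopes along a simulated trajectory from the model right-hand side
#'
#' Evaluates `S v(X(t_k), p)` at every row of a trajectory: the analytical
#' (model-implied) concentration time-slopes.  With the true parameters
#' these are the idealized slopes under which the incremental estimator is
#' exact.
#'
#' @param model a [gma_model()].
#' @param trajectory tibble with `time` and one column per model species
#'   (e.g. `simulate_gma(...)$trajectory`).
#' @return tibble with `time` and one slope column per species.
#' @export
analytical_slopes <- function(model, trajectory) {
  missing <- setdiff(model$species, names(trajectory))
  if (length(missing)) {
    stop("trajectory lacks species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(trajectory[model$species])
  V <- eval_fluxes_grid(model, X, trajectory$time)
  D <- V %*% t(model$S)
  out <- tibble::as_tibble(as.data.frame(D))
  names(out) <- model$species
  dplyr::bind_cols(tibble::tibble(time = trajectory$time), out)
}
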