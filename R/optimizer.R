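#' Seeded bounded global optimization by differential evolution
#'
#' A compact differential-evolution optimizer (rand/1/bin) with box
#' constraints, used as the global search engine of the estimators.  The
#' population default of `15 * d` follows common DE practice.  Iteration
#' stops when the best objective has improved by less than `reltol`
#' (relative; default 0.01%) over the last `stall` generations, when
#' `maxiter` generations are exhausted, or when `wall` seconds have
#' elapsed.  A final local polish (Nelder-Mead restarts from the best few
#' well-separated members, counted in the evaluation budget) sharpens the
#' optimum; like enhanced scatter-search methods, the global phase is
#' paired with a local solver.
#'
#' Fully deterministic for a given `seed`.
#'
#' @param fn objective, a function of a numeric vector returning a finite
#'   scalar (large penalty values are fine and expected).
#' @param lower,upper numeric bound vectors of equal length d.
#' @param seed integer RNG seed.
#' @param pop population size (default `max(15 * d, 20)`).
#' @param maxiter maximum generations.
#' @param reltol relative improvement threshold (default `1e-4`, i.e.
#'   0.01%).
#' @param stall generations without sufficient improvement before stopping.
#' @param F,CR differential weight and crossover probability.
#' @param wall wall-clock cap in seconds.
#' @param polish logical; run the local polish step.
#' @param trace logical; record the per-generation best value.
#' @param init optional matrix of start points (one per row) embedded in
#'   the initial population after clipping to the bounds -- used e.g. to
#'   seed the search with the optimum of a cheaper surrogate objective.
#' @return list with `par`, `value`, `n_evals`, `iterations`, `converged`,
#'   `trace` (tibble `iteration`, `best`), `message`.
#' @export
de_optimize <- function(fn, lower, upper, seed = 1, pop = NULL,
                        maxiter = 200, reltol = 1e-4, stall = 5,
                        F = 0.8, CR = 0.9, wall = Inf, polish = TRUE,
                        trace = TRUE, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), d >= 1)
  if (is.null(pop)) pop <- max(15L * d, 20L)
  pop <- max(as.integer(pop), 5L)
  set.seed(as.integer(seed))
  t0 <- proc.time()[["elapsed"]]

  n_evals <- 0L
  BIG <- 1e12  # large-but-safe cap: DBL_MAX-scale values break L-BFGS-B
  evalf <- function(x) {
    n_evals <<- n_evals + 1L
    val <- fn(x)
    if (!is.finite(val) || val > BIG) val <- BIG
    val
  }

  span <- upper - lower
  P <- matrix(stats::runif(pop * d), pop, d)
  P <- sweep(sweep(P, 2, span, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), pop)
    P[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 rep(lower, each = k)),
                            rep(upper, each = k))
  }
  fvals <- apply(P, 1, evalf)
  best_i <- which.min(fvals)
  best_hist <- min(fvals)
  tr <- list(tibble::tibble(iteration = 0L, best = best_hist))

  iter <- 0L
  converged <- FALSE
  msg <- "maxiter reached"
  while (iter < maxiter) {
    iter <- iter + 1L
    for (i in seq_len(pop)) {
      r <- sample(seq_len(pop)[-i], 3L)
      mutant <- P[r[1], ] + F * (P[r[2], ] - P[r[3], ])
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < CR
      cross[jrand] <- TRUE
      cand <- ifelse(cross, mutant, P[i, ])
      cand <- pmin(pmax(cand, lower), upper)
      fc <- evalf(cand)
      if (fc <= fvals[i]) {
        P[i, ] <- cand
        fvals[i] <- fc
      }
    }
    best <- min(fvals)
    best_hist <- c(best_hist, best)
    if (trace) {
      tr[[length(tr) + 1L]] <- tibble::tibble(iteration = iter, best = best)
    }
    if (iter >= stall) {
      ref <- best_hist[length(best_hist) - stall]
      impr <- (ref - best) / max(abs(ref), .Machine$double.eps)
      if (impr < reltol) {
        converged <- TRUE
        msg <- sprintf("relative improvement < %g over %d generations",
                       reltol, stall)
        break
      }
    }
    if (proc.time()[["elapsed"]] - t0 > wall) {
      msg <- "wall-clock cap reached"
      break
    }
  }

  best_i <- which.min(fvals)
  par <- P[best_i, ]
  val <- fvals[best_i]

  if (polish && val < 1e12) {
    # polish the best few well-separated members: the population may
    # straddle several basins and the global one need not hold the
    # current best point
    ord <- order(fvals)
    starts <- list(P[ord[1], ])
    for (i in ord[-1]) {
      if (length(starts) >= 3) break
      sep <- vapply(starts, function(s) {
        sqrt(sum(((P[i, ] - s) / pmax(upper - lower, 1e-12))^2))
      }, numeric(1))
      if (all(sep > 0.05) && fvals[i] < 1e12) {
        starts[[length(starts) + 1L]] <- P[i, ]
      }
    }
    # Nelder-Mead on a clamped objective: derivative-free, and robust to
    # the flat penalty plateaus that break line-search methods
    clamped <- function(x) {
      xc <- pmin(pmax(x, lower), upper)
      evalf(xc) + sum(((x - xc) / pmax(span, 1e-12))^2) * 1e6
    }
    nm_budget <- min(200L * d, 800L)
    local_opt <- function(s0) {
      if (d == 1) {
        return(tryCatch(
          stats::optim(s0, clamped, method = "Brent", lower = lower,
                       upper = upper),
          error = function(e) NULL))
      }
      opt <- tryCatch(
        stats::optim(s0, clamped, method = "Nelder-Mead",
                     control = list(maxit = nm_budget, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(opt) && is.finite(opt$value) && d <= 4) {
        # one restart tightens the simplex (cheap only in low dimension)
        opt <- tryCatch(
          stats::optim(opt$par, clamped, method = "Nelder-Mead",
                       control = list(maxit = nm_budget, reltol = 1e-12)),
          error = function(e) opt
        )
      }
      opt
    }
    for (s in starts) {
      opt <- local_opt(s)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < val) {
        par <- pmin(pmax(opt$par, lower), upper)
        val <- evalf(par)
      }
    }
  }

  list(par = unname(par), value = val, n_evals = n_evals,
       iterations = iter, converged = converged,
       trace = if (trace) dplyr::bind_rows(tr) else NULL,
       message = msg)
}
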