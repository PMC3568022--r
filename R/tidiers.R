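#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an estimation fit
#'
#' One row per kinetic parameter of the best run: the estimate, whether
#' the parameter was searched (independent) or regressed (dependent), and
#' -- when the problem carries a ground truth -- the true value and the
#' relative error in percent.
#'
#' @param x an `estimation_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy estimation_fit
#' @export
tidy.estimation_fit <- function(x, ...) {
  out <- x$params
  ind <- x$partition$independent
  out$role <- if (x$method == "simultaneous") "searched" else
    ifelse(out$flux %in% ind, "independent", "dependent")
  names(out)[names(out) == "value"] <- "estimate"
  if (!is.null(x$problem$truth)) {
    out$truth <- x$problem$truth
    out$rel_error_pct <- 100 * ifelse(
      out$truth != 0, abs((out$estimate - out$truth) / out$truth),
      abs(out$estimate - out$truth))
  }
  if (length(x$x_u0)) {
    extra <- tibble::tibble(
      flux = NA_character_,
      parameter = paste0(names(x$x_u0), "(t0)"),
      estimate = as.numeric(x$x_u0),
      role = "initial_condition")
    out <- dplyr::bind_rows(out, extra)
  }
  tibble::as_tibble(out)
}

#' One-row summary of an estimation fit
#'
#' @param x an `estimation_fit`.
#' @param ... unused.
#' @return a tibble with the achieved objectives, the parameter error
#'   (when a truth is known), the search-space dimension, evaluation
#'   counts and the across-run mean and standard deviation of the
#'   objective.
#' @method glance estimation_fit
#' @export
glance.estimation_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, objective = x$objective, status = x$status,
    phi = x$phi, phi_C = x$phi_C, phi_S = x$phi_S,
    parameter_error = x$parameter_error,
    n_par_searched = length(x$par),
    n_runs = nrow(x$runs), n_evals = x$n_evals,
    phi_mean = mean(x$runs$phi), phi_sd = stats::sd(x$runs$phi),
    converged = all(x$runs$converged)
  )
}

#' Tidy a flux regression
#'
#' @param x a `flux_regression`.
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @method tidy flux_regression
#' @export
tidy.flux_regression <- function(x, ...) {
  tibble::tibble(
    parameter = c("gamma", names(x$orders)),
    estimate = c(x$gamma, unname(x$orders)),
    at_bound = c("(Intercept)", names(x$orders)) %in% x$bounds_active
  )
}

#' One-row summary of a flux regression
#'
#' @param x a `flux_regression`.
#' @param ... unused.
#' @return a tibble.
#' @method glance flux_regression
#' @export
glance.flux_regression <- function(x, ...) {
  tibble::tibble(
    residual_ss = x$residual_ss, design_rank = x$design_rank,
    n_used = x$n_used, clipped_points = x$clipped_points,
    status = x$status
  )
}
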