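#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' @param object a `gma_simulation` with `status == "ok"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot gma_simulation
#' @export
autoplot.gma_simulation <- function(object, ...) {
  if (object$status != "ok") {
    stop("cannot plot a failed integration", call. = FALSE)
  }
  long <- tidyr::pivot_longer(object$trajectory, -"time",
                              names_to = "species",
                              values_to = "concentration")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration")
}

#' Plot a smoother fit over its data
#'
#' @param object a `smoother_fit`.
#' @param series the data frame (`time`, `value`) it was fitted to.
#' @param n number of curve evaluation points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot smoother_fit
#' @export
autoplot.smoother_fit <- function(object, series, n = 200, ...) {
  grid <- seq(object$range[1], object$range[2], length.out = n)
  curve <- tibble::tibble(time = grid, value = object$predict(grid))
  ggplot2::ggplot(series, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point(shape = 4) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(x = "time", y = "value",
                  title = paste0(object$kind, " smoother"))
}

#' Plot data against the fitted model's prediction
#'
#' Measured concentrations (crosses) with the trajectory of the model
#' assembled from the estimated parameters (line), one facet per
#' species.  Unmeasured species show the prediction only.
#'
#' @param object an `estimation_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot estimation_fit
#' @export
autoplot.estimation_fit <- function(object, ...) {
  problem <- object$problem
  x0 <- problem$model$x0
  x0[problem$measured] <- as.numeric(problem$data[1, problem$measured])
  if (length(problem$unmeasured)) x0[problem$unmeasured] <- object$x_u0
  sim <- simulate_gma(object$model, problem$times, x0 = x0)
  obs <- tidyr::pivot_longer(problem$data, -"time", names_to = "species",
                             values_to = "concentration")
  p <- ggplot2::ggplot(obs, ggplot2::aes(.data$time, .data$concentration)) +
    ggplot2::geom_point(shape = 4, na.rm = TRUE)
  if (sim$status == "ok") {
    pred <- tidyr::pivot_longer(sim$trajectory, -"time",
                                names_to = "species",
                                values_to = "concentration")
    p <- p + ggplot2::geom_line(data = pred, colour = "steelblue")
  }
  p + ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time", y = "concentration")
}

#' Optimizer convergence trace
#'
#' Best objective value per generation of the best run.
#'
#' @param fit an `estimation_fit`.
#' @return a ggplot.
#' @export
plot_trace <- function(fit) {
  stopifnot(inherits(fit, "estimation_fit"), !is.null(fit$trace))
  ggplot2::ggplot(fit$trace, ggplot2::aes(.data$iteration, .data$best)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best objective")
}
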