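#' Fit a polynomial smoother to one concentration series
#'
#' Ordinary least-squares polynomial of the given degree, fitted on an
#' orthogonal-polynomial basis for numerical stability.  The smoother is
#' consumed through its `predict` closure; downstream slope estimation
#' uses finite differences of the smoothed values, never analytic
#' differentiation of the polynomial.
#'
#' @param series data frame with columns `time` and `value` (K rows).
#' @param order polynomial degree, `0 <= order <= K - 1`.
#' @return An object of class `smoother_fit` with fields `kind`
#'   (`"polynomial"`), `order`, `coefficients`, `score_aic` (small-sample
#'   corrected when K is small, see [select_polynomial_order()]),
#'   `score_adj_r2`, `predict`.
#' @export
fit_polynomial <- function(series, order) {
  series <- check_series(series)
  K <- nrow(series)
  order <- as.integer(order)
  if (order < 0) stop("`order` must be >= 0", call. = FALSE)
  if (K < order + 1) {
    stop("need at least ", order + 1, " points for a degree-", order,
         " polynomial, got ", K, call. = FALSE)
  }
  if (anyDuplicated(series$time)) {
    stop("duplicate time points make the polynomial design rank-deficient",
         call. = FALSE)
  }
  if (order == 0) {
    fit <- stats::lm(value ~ 1, data = series)
  } else {
    fit <- stats::lm(value ~ poly(time, degree = order), data = series)
  }
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((series$value - mean(series$value))^2)
  adj_r2 <- if (tss > 0 && K > order + 1) {
    1 - (rss / (K - order - 1)) / (tss / (K - 1))
  } else if (tss > 0) NA_real_ else 0  # constant series: R2 undefined -> 0
  k_par <- order + 2  # coefficients + residual variance
  # Guard: an (effectively) exact fit has RSS at rounding-noise level; pin
  # it to a common floor so AIC comparisons between exact fits are decided
  # by the parameter penalty, not by 1e-30-scale noise.
  rss_eff <- max(rss, 1e-12 * max(tss, 1) / K)
  aic <- K * log(rss_eff / K) + 2 * k_par
  if (K / k_par < 40) {            # small-sample correction
    aic <- aic + 2 * k_par * (k_par + 1) / max(K - k_par - 1, 1e-8)
  }
  pred_fun <- function(t) {
    unname(stats::predict(fit, newdata = data.frame(time = t)))
  }
  structure(
    list(kind = "polynomial", order = order,
         coefficients = stats::coef(fit),
         score_aic = aic, score_adj_r2 = adj_r2,
         rss = rss, range = range(series$time), predict = pred_fun),
    class = "smoother_fit"
  )
}

#' Select a polynomial smoothing order by AIC and adjusted R-squared
#'
#' Fits every candidate degree and returns the one with the smallest AIC
#' (the small-sample corrected AICc is used whenever `K / (order + 2) <
#' 40`, which is the typical regime for tens of time points).  Ties are
#' broken by higher adjusted R-squared, then by lower order.
#'
#' @param series data frame with columns `time`, `value`.
#' @param candidates integer vector of candidate degrees.
#' @return the winning `smoother_fit` (its `order` field gives the degree).
#' @export
select_polynomial_order <- function(series, candidates = 2:8) {
  series <- check_series(series)
  K <- nrow(series)
  candidates <- sort(unique(as.integer(candidates)))
  candidates <- candidates[candidates <= K - 2]
  if (!length(candidates)) {
    stop("no candidate order leaves a residual degree of freedom (K = ",
         K, ")", call. = FALSE)
  }
  fits <- lapply(candidates, function(d) fit_polynomial(series, d))
  aic <- vapply(fits, `[[`, numeric(1), "score_aic")
  adj <- vapply(fits, `[[`, numeric(1), "score_adj_r2")
  adj[is.na(adj)] <- 0
  best <- order(aic, -adj, candidates)[1]
  fits[[best]]
}

#' Fit a saturating Hill-type smoother
#'
#' Fits `k1 * t^n / (k2 + t^n)` by bounded nonlinear least squares
#' (Levenberg-Marquardt), multi-starting over Hill coefficients
#' `n in {0.5, 1, 2, 4}` to avoid local minima.  This form suits
#' monotonically saturating series such as a product accumulation curve;
#' on decreasing series it fits poorly by construction.
#'
#' @param series data frame with columns `time`, `value`; times and values
#'   must be nonnegative.
#' @return `smoother_fit` with `kind = "hill"` and `coefficients`
#'   `(k1, k2, n)`, all positive.
#' @export
fit_hill <- function(series) {
  series <- check_series(series)
  if (any(series$time < 0) || any(series$value < 0)) {
    stop("Hill smoothing expects nonnegative times and values",
         call. = FALSE)
  }
  K <- nrow(series)
  if (K < 4) stop("need at least 4 points for the 3-parameter Hill form",
                  call. = FALSE)
  t_pos <- series$time[series$time > 0]
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4)) {
    start <- list(k1 = max(series$value, 1e-3),
                  k2 = max(stats::median(t_pos)^n0, 1e-3), n = n0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ k1 * time^n / (k2 + time^n),
        data = series, start = start,
        lower = c(k1 = 1e-10, k2 = 1e-10, n = 1e-10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("Hill smoother failed to converge from any start; the series may ",
         "not be saturating-increasing", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  tss <- sum((series$value - mean(series$value))^2)
  adj_r2 <- if (tss > 0) 1 - (best$rss / (K - 3)) / (tss / (K - 1)) else 0
  k_par <- 4
  aic <- K * log(max(best$rss, 1e-12 * max(tss, 1) / K) / K) + 2 * k_par +
    if (K / k_par < 40) 2 * k_par * (k_par + 1) / max(K - k_par - 1, 1e-8) else 0
  pred_fun <- function(t) cf[["k1"]] * t^cf[["n"]] / (cf[["k2"]] + t^cf[["n"]])
  structure(
    list(kind = "hill", order = NA_integer_, coefficients = cf,
         score_aic = aic, score_adj_r2 = adj_r2, rss = best$rss,
         range = range(series$time), predict = pred_fun),
    class = "smoother_fit"
  )
}

#' @export
print.smoother_fit <- function(x, ...) {
  cat("<smoother_fit> ", x$kind,
      if (x$kind == "polynomial") paste0(" (order ", x$order, ")"),
      ", adj R2 = ", signif(x$score_adj_r2, 4),
      ", AIC = ", signif(x$score_aic, 5), "\n", sep = "")
  invisible(x)
}

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("time", "value") %in% names(series))) {
    stop("`series` must be a data frame with `time` and `value` columns",
         call. = FALSE)
  }
  series <- series[stats::complete.cases(series[c("time", "value")]),
                   c("time", "value")]
  if (is.unsorted(series$time)) series <- series[order(series$time), ]
  tibble::as_tibble(series)
}

#' Central-difference time-slopes on a (possibly nonuniform) grid
#'
#' Interior points use the three-point central difference (the derivative
#' of the local interpolating quadratic, exact for quadratics, O(h^2)
#' accurate); the two endpoints use the matching one-sided three-point
#' formulas.  The operator is linear in `values`.
#'
#' @param times strictly increasing numeric vector, length K >= 3.
#' @param values numeric vector of the same length.
#' @return numeric vector of K slope estimates.
#' @export
central_slopes <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  K <- length(times)
  if (K < 3) stop("need at least 3 points for 3-point differences",
                  call. = FALSE)
  if (length(values) != K) stop("`times` and `values` lengths differ",
                                call. = FALSE)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  d <- numeric(K)
  stencil_deriv <- function(ta, tb, tc, ya, yb, yc, x) {
    ya * (2 * x - tb - tc) / ((ta - tb) * (ta - tc)) +
      yb * (2 * x - ta - tc) / ((tb - ta) * (tb - tc)) +
      yc * (2 * x - ta - tb) / ((tc - ta) * (tc - tb))
  }
  for (k in seq_len(K)) {
    i <- if (k == 1) 1L else if (k == K) K - 2L else k - 1L
    d[k] <- stencil_deriv(times[i], times[i + 1], times[i + 2],
                          values[i], values[i + 1], values[i + 2],
                          times[k])
  }
  d
}

#' Smooth a time-course table and estimate slopes
#'
#' Applies a smoother to every species column of a time-course tibble and
#' returns the smoothed values and the central-difference slopes on the
#' original grid.  Polynomial order is selected per species by
#' [select_polynomial_order()] (pass a single candidate to impose one
#' shared order, as in the branched-pathway runs where a 6th-order
#' polynomial is used for every metabolite).  Columns that are entirely
#' missing (unmeasured metabolites) are passed through as `NA`.
#'
#' @param data tibble with a `time` column and one column per species;
#'   `NA` cells mark missing observations.
#' @param method `"polynomial"`, `"hill"`, or `"none"` (no smoothing:
#'   slopes are finite differences of the raw values).
#' @param candidates candidate polynomial degrees.
#' @return list with `smoothed` (tibble like `data`), `slopes` (tibble
#'   like `data`), and `fits` (named list of `smoother_fit`, or `NULL`
#'   for method `"none"`).
#' @export
smooth_timecourse <- function(data, method = c("polynomial", "hill", "none"),
                              candidates = 2:8) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), "time" %in% names(data))
  species <- setdiff(names(data), "time")
  smoothed <- data
  fits <- list()
  for (sp in species) {
    y <- data[[sp]]
    if (all(is.na(y))) next
    if (method == "none") { smoothed[[sp]] <- y; next }
    ser <- tibble::tibble(time = data$time, value = y)
    fit <- switch(method,
      polynomial = if (length(candidates) == 1) {
        fit_polynomial(ser, candidates)
      } else {
        select_polynomial_order(ser, candidates)
      },
      hill = fit_hill(ser)
    )
    fits[[sp]] <- fit
    smoothed[[sp]] <- fit$predict(data$time)
  }
  slopes <- data
  for (sp in species) {
    y <- smoothed[[sp]]
    slopes[[sp]] <- if (all(is.na(y))) NA_real_ else central_slopes(data$time, y)
  }
  list(smoothed = tibble::as_tibble(smoothed),
       slopes = tibble::as_tibble(slopes),
       fits = if (method == "none") NULL else fits)
}
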