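#' Select usable time points for log-linear flux regression
#'
#' Power-law regression works on logarithms, so nonpositive values cannot
#' enter.  The two kinds of nonpositivity are treated differently: a
#' nonpositive *flux* estimate signals infeasibility (fluxes of
#' irreversible reactions are constrained positive), so such time points
#' are dropped and counted; a tiny or nonpositive *concentration* is a
#' numerical artifact, so concentrations are floored at `eps`.
#'
#' @param v numeric vector of flux values at the time points.
#' @param X numeric matrix of regressor concentrations (K x r).
#' @param eps positive floor (default `1e-9`).
#' @return list with `idx` (usable indices), `clipped` (number dropped),
#'   `X` (floored regressor matrix).
#' @export
usable_points <- function(v, X, eps = 1e-9) {
  X <- as.matrix(X)
  idx <- which(is.finite(v) & v > eps)
  list(idx = idx, clipped = length(v) - length(idx),
       X = pmax(X, eps))
}

#' Fit one power-law flux by log-linear least squares
#'
#' Regresses `ln v_j` on the logarithms of the regressor concentrations
#' with intercept `ln gamma_j`, the classical GMA identity that makes the
#' per-flux regressions linear.  If the ordinary solution violates the
#' parameter bounds it is re-solved as a bound-constrained least-squares
#' problem (projected start, L-BFGS-B on the quadratic).  A rank-deficient
#' log-concentration design -- e.g. two proportional regressor series, the
#' redundancy that plagues this regression -- is flagged and the
#' minimum-norm solution returned with `status = "rank_deficient"`.
#'
#' @param v numeric vector of flux values at the K time points.
#' @param X K x r matrix of regressor concentrations, columns named by
#'   regressor.
#' @param bounds optional data frame with columns `parameter`
#'   (`"gamma"` or a regressor name), `lower`, `upper`.
#' @param eps positivity floor, see [usable_points()].
#' @return An object of class `flux_regression`: fields `gamma`, `orders`
#'   (named), `residual_ss` (log scale, over usable points),
#'   `design_rank`, `clipped_points`, `bounds_active`, `status`
#'   (`"ok"`, `"rank_deficient"`).
#' @export
fit_flux_loglinear <- function(v, X, bounds = NULL, eps = 1e-9) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  }
  up <- usable_points(v, X, eps)
  r <- ncol(X)
  n_par <- r + 1L
  if (length(up$idx) <= n_par) {
    stop("estimability error: ", length(up$idx), " usable time points for ",
         n_par, " parameters", call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, log(up$X[up$idx, , drop = FALSE]))
  y <- log(v[up$idx])

  qr_A <- qr(A)
  status <- "ok"
  if (qr_A$rank < ncol(A)) {
    status <- "rank_deficient"
    warning("log-concentration design is rank deficient (rank ",
            qr_A$rank, " < ", ncol(A), "); returning the minimum-norm ",
            "solution", call. = FALSE)
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_A, y)
  }
  names(beta) <- c("(Intercept)", colnames(X))

  lower <- c(-Inf, rep(-Inf, r)); upper <- c(Inf, rep(Inf, r))
  names(lower) <- names(upper) <- names(beta)
  if (!is.null(bounds)) {
    for (i in seq_len(nrow(bounds))) {
      pn <- bounds$parameter[i]
      key <- if (pn == "gamma") "(Intercept)" else pn
      if (!key %in% names(beta)) next
      lo <- bounds$lower[i]; hi <- bounds$upper[i]
      if (pn == "gamma") {   # bounds act on gamma, intercept is ln gamma
        lo <- log(max(lo, 1e-300)); hi <- log(hi)
      }
      lower[key] <- lo; upper[key] <- hi
    }
  }

  bounds_active <- character()
  if (any(beta < lower - 1e-12) || any(beta > upper + 1e-12)) {
    obj <- function(b) sum((A %*% b - y)^2)
    grad <- function(b) drop(2 * t(A) %*% (A %*% b - y))
    start <- pmin(pmax(beta, lower), upper)
    start[!is.finite(start)] <- 0
    opt <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    beta <- opt$par
    names(beta) <- c("(Intercept)", colnames(X))
    at_lo <- abs(beta - lower) < 1e-8
    at_hi <- abs(beta - upper) < 1e-8
    bounds_active <- names(beta)[at_lo | at_hi]
  }

  res <- drop(A %*% beta - y)
  structure(
    list(gamma = exp(beta[["(Intercept)"]]),
         orders = beta[-1],
         residual_ss = sum(res^2),
         design_rank = qr_A$rank,
         clipped_points = up$clipped,
         n_used = length(up$idx),
         bounds_active = bounds_active,
         status = status),
    class = "flux_regression"
  )
}

#' @export
print.flux_regression <- function(x, ...) {
  cat("<flux_regression> gamma = ", signif(x$gamma, 6), ", orders: ",
      paste(names(x$orders), signif(x$orders, 6), sep = " = ",
            collapse = ", "),
      "\n  log-scale RSS = ", signif(x$residual_ss, 4),
      ", used ", x$n_used, " points (", x$clipped_points, " clipped), ",
      "status ", x$status, "\n", sep = "")
  invisible(x)
}
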