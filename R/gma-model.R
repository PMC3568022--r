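#' Construct a generalized mass action (GMA) model
#'
#' A GMA model couples the mass balance `dX/dt = S v(X, p)` with power-law
#' flux functions `v_j = gamma_j * prod_i X_i^{f_ji}`.  `S` is the m x n
#' stoichiometric matrix for `m` metabolites taking part in `n` fluxes,
#' `gamma_j >= 0` is the rate constant of flux `j` and `f_ji` the kinetic
#' order of regressor `i` in flux `j` (positive: substrate or activator,
#' negative: inhibitor).  Regressors may be model species or *off-line
#' variables*: externally measured quantities (e.g. extracellular glucose,
#' ATP, Pi) that enter fluxes through interpolated time profiles rather
#' than through a mass balance.
#'
#' The sparsity pattern of `orders` is structural: a zero entry means the
#' regressor does not appear in the flux at all, and flux-by-flux
#' regression estimates only the structurally present orders.  A
#' structurally present order whose value happens to be zero can be forced
#' with `structure`.
#'
#' @param species character vector of m species names.
#' @param fluxes character vector of n flux names.
#' @param S numeric m x n stoichiometric matrix (rows = species, columns =
#'   fluxes).  Must have full row rank: a rank-deficient `S` means a
#'   redundant mass balance and the flux decomposition is not defined.
#' @param gamma numeric vector of n nonnegative rate constants.
#' @param orders numeric n x r matrix of kinetic orders; column names are
#'   regressor names (species and/or off-line variables), row names flux
#'   names.  Missing columns are treated as all-zero.
#' @param x0 named numeric vector of m nonnegative initial concentrations.
#' @param offline named list of off-line variable profiles; each element is
#'   either a function of time or a data frame with columns `time`,
#'   `value` (interpolated by a shape-preserving monotone cubic, with
#'   constant extrapolation beyond the tabulated range).
#' @param structure optional logical n x r matrix marking structurally
#'   present orders; defaults to `orders != 0`.
#'
#' @return An object of class `gma_model`.
#' @export
gma_model <- function(species, fluxes, S, gamma, orders, x0,
                      offline = list(), structure = NULL) {
  species <- as.character(species)
  fluxes <- as.character(fluxes)
  m <- length(species)
  n <- length(fluxes)
  S <- as.matrix(S)
  if (!identical(dim(S), c(m, n))) {
    stop("`S` must be ", m, " x ", n, " (species x fluxes)", call. = FALSE)
  }
  dimnames(S) <- list(species, fluxes)
  if (qr(S)$rank < m) {
    stop("`S` must have full row rank: a redundant mass balance was found",
         call. = FALSE)
  }
  gamma <- as.numeric(gamma)
  if (length(gamma) != n || any(gamma < 0) || any(!is.finite(gamma))) {
    stop("`gamma` must be ", n, " finite nonnegative rate constants",
         call. = FALSE)
  }
  names(gamma) <- fluxes

  offline_names <- names(offline)
  regressors <- c(species, offline_names)
  if (anyDuplicated(regressors)) {
    stop("species and off-line variable names must be distinct", call. = FALSE)
  }
  F_mat <- matrix(0, n, length(regressors),
                  dimnames = list(fluxes, regressors))
  orders <- as.matrix(orders)
  if (is.null(colnames(orders))) {
    stop("`orders` must have regressor column names", call. = FALSE)
  }
  unknown <- setdiff(colnames(orders), regressors)
  if (length(unknown)) {
    stop("kinetic-order regressor(s) not a species or off-line variable: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  F_mat[, colnames(orders)] <- orders

  if (is.null(structure)) {
    struct <- F_mat != 0
  } else {
    struct <- matrix(FALSE, n, length(regressors),
                     dimnames = dimnames(F_mat))
    structure <- as.matrix(structure)
    struct[, colnames(structure)] <- structure
    if (any(F_mat[!struct] != 0)) {
      stop("`orders` has nonzero entries outside `structure`", call. = FALSE)
    }
  }

  x0 <- as.numeric(x0[species])
  if (length(x0) != m || any(is.na(x0)) || any(x0 < 0)) {
    stop("`x0` must give a nonnegative initial concentration for every species",
         call. = FALSE)
  }
  names(x0) <- species

  offline_funs <- lapply(offline, as_offline_profile)

  structure(
    list(species = species, fluxes = fluxes, S = S, gamma = gamma,
         orders = F_mat, structure = struct, x0 = x0,
         offline = offline_funs),
    class = "gma_model"
  )
}

# Shape-preserving interpolant (monotone Fritsch-Carlson cubic) with
# constant extrapolation outside the tabulated range.
as_offline_profile <- function(x) {
  if (is.function(x)) return(x)
  if (!is.data.frame(x) || !all(c("time", "value") %in% names(x))) {
    stop("off-line variables must be functions or data frames with ",
         "`time` and `value` columns", call. = FALSE)
  }
  tt <- x$time
  vv <- x$value
  f <- stats::splinefun(tt, vv, method = "monoH.FC")
  lo <- min(tt); hi <- max(tt)
  function(t) f(pmin(pmax(t, lo), hi))
}

#' @export
print.gma_model <- function(x, ...) {
  cat("<gma_model> ", length(x$species), " species, ",
      length(x$fluxes), " fluxes", sep = "")
  if (length(x$offline)) {
    cat(", off-line: ", paste(names(x$offline), collapse = ", "), sep = "")
  }
  cat("\n  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  np <- sum(x$structure) + length(x$fluxes)
  cat("  parameters: ", np, " (", length(x$fluxes), " rate constants, ",
      sum(x$structure), " kinetic orders)\n", sep = "")
  invisible(x)
}

#' Number of species / fluxes of a GMA model
#' @param model a [gma_model()].
#' @return integer count.
#' @export
n_species <- function(model) length(model$species)

#' @rdname n_species
#' @export
n_fluxes <- function(model) length(model$fluxes)

# Off-line variable values at a vector of times, as a length(times) x u
# matrix (u = number of off-line variables, possibly 0).
offline_values <- function(model, times) {
  u <- length(model$offline)
  out <- matrix(NA_real_, length(times), u,
                dimnames = list(NULL, names(model$offline)))
  for (j in seq_len(u)) out[, j] <- model$offline[[j]](times)
  out
}

#' Evaluate the power-law fluxes at one state
#'
#' Computes `v_j = gamma_j * prod_i X_i^{f_ji}` for every flux, with
#' off-line variables evaluated at `t` through their interpolants.  A flux
#' in which every kinetic order is zero evaluates to its rate constant (a
#' constant input flux).
#'
#' @param model a [gma_model()].
#' @param x named (or species-ordered) numeric concentration vector.
#' @param t time at which off-line variables are evaluated.
#' @return named numeric vector of n flux values.
#' @export
eval_fluxes <- function(model, x, t = 0) {
  x <- state_vector(model, x)
  regs <- c(x, drop(offline_values(model, t)))
  check_power_domain(model, regs)
  drop(eval_fluxes_grid(model, matrix(x, 1, dimnames = list(NULL, model$species)),
                        t, check = FALSE))
}

state_vector <- function(model, x) {
  if (!is.null(names(x))) {
    missing <- setdiff(model$species, names(x))
    if (length(missing)) {
      stop("state is missing species: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- x[model$species]
  }
  if (length(x) != length(model$species)) {
    stop("state must have one concentration per species", call. = FALSE)
  }
  as.numeric(x)
}

# Nonpositive regressor raised to a non-integer order is undefined over the
# reals; identify the offending flux and regressor.
check_power_domain <- function(model, regs) {
  F_mat <- model$orders
  bad <- which(regs <= 0)
  for (i in bad) {
    f <- F_mat[, i]
    j <- which(f != 0 & f != round(f))
    if (length(j)) {
      stop("flux `", model$fluxes[j[1]], "`: regressor `",
           colnames(F_mat)[i], "` is nonpositive (", regs[i],
           ") with non-integer kinetic order ", f[j[1]], call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Vectorised flux evaluation over a grid: X is K x m (columns = species),
# times length K (or 1).  Returns K x n flux matrix.  Callers inside
# optimizer loops floor concentrations themselves and pass check = FALSE.
eval_fluxes_grid <- function(model, X, times = 0, check = TRUE) {
  X <- as.matrix(X)
  K <- nrow(X)
  off <- offline_values(model, if (length(times) == 1) rep(times, K) else times)
  R <- cbind(X, off)
  colnames(R) <- c(model$species, names(model$offline))
  if (check) {
    for (k in seq_len(K)) check_power_domain(model, R[k, ])
  }
  lnR <- suppressWarnings(log(R))
  lnR[!is.finite(lnR)] <- 0  # only hit where the order is an integer; see below
  F_mat <- model$orders
  # integer orders on nonpositive regressors: evaluate by direct powers
  V <- exp(sweep(lnR %*% t(F_mat), 2, log_gamma(model), "+"))
  int_cols <- which(apply(F_mat, 2, function(f) any(f != 0)) &
                      apply(R <= 0, 2, any))
  if (length(int_cols)) {
    # redo affected entries with direct products (integer orders only)
    for (k in which(apply(R[, int_cols, drop = FALSE] <= 0, 1, any))) {
      V[k, ] <- model$gamma *
        apply(t(R[k, ])[rep(1, nrow(F_mat)), , drop = FALSE]^F_mat, 1, prod)
    }
  }
  colnames(V) <- model$fluxes
  V
}

log_gamma <- function(model) {
  lg <- log(model$gamma)
  lg[model$gamma == 0] <- -Inf
  lg
}

#' Evaluate the mass-balance right-hand side
#'
#' Returns `S v(x, p)`, the vector of concentration time-slopes implied by
#' the model at state `x`.  Used both by the simulator and as the
#' analytical-slope oracle for the incremental estimator.
#'
#' @inheritParams eval_fluxes
#' @return named numeric vector of m slopes.
#' @export
eval_rhs <- function(model, x, t = 0) {
  v <- eval_fluxes(model, x, t)
  drop(model$S %*% v)
}

## ---- parameter layout -----------------------------------------------------

#' Tidy view of a model's kinetic parameters
#'
#' One row per parameter in the canonical layout used by the estimators:
#' for each flux, the rate constant (`parameter = "gamma"`) followed by its
#' structural kinetic orders in regressor-column order.
#'
#' @param model a [gma_model()].
#' @param fluxes optional subset of flux names (layout order preserved).
#' @return tibble with columns `flux`, `parameter`, `value`.
#' @export
flux_parameters <- function(model, fluxes = model$fluxes) {
  fluxes <- match.arg(fluxes, model$fluxes, several.ok = TRUE)
  rows <- lapply(fluxes, function(fl) {
    regs <- colnames(model$orders)[model$structure[fl, ]]
    tibble::tibble(
      flux = fl,
      parameter = c("gamma", regs),
      value = unname(c(model$gamma[fl], model$orders[fl, regs]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Replace kinetic parameters of selected fluxes
#'
#' @param model a [gma_model()].
#' @param p numeric vector in the [flux_parameters()] layout for `fluxes`.
#' @param fluxes flux names whose parameters are replaced.
#' @return the modified model.
#' @export
set_flux_parameters <- function(model, p, fluxes = model$fluxes) {
  p <- as.numeric(p)
  idx <- 0L
  for (fl in fluxes) {
    j <- match(fl, model$fluxes)
    if (is.na(j)) stop("unknown flux: ", fl, call. = FALSE)
    regs <- which(model$structure[j, ])
    k <- length(regs)
    if (idx + 1L + k > length(p)) {
      stop("parameter vector too short for the requested fluxes",
           call. = FALSE)
    }
    model$gamma[j] <- p[idx + 1L]
    if (k) model$orders[j, regs] <- p[idx + 1L + seq_len(k)]
    idx <- idx + 1L + k
  }
  if (idx != length(p)) {
    stop("expected ", idx, " parameters, got ", length(p), call. = FALSE)
  }
  model
}

# Number of parameters carried by each flux (gamma + structural orders).
flux_n_params <- function(model, fluxes = model$fluxes) {
  vapply(fluxes, function(fl) 1L + sum(model$structure[fl, ]), integer(1))
}
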