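#' Degrees of freedom of the dynamic flux estimation
#'
#' At each time point the mass balance `Xdot = S v` pins down only `m`
#' linear combinations of the `n` fluxes, leaving `n - m` degrees of
#' freedom (S is required to have full row rank).  Every unmeasured
#' metabolite removes one usable balance, raising the count by one.
#'
#' @param model a [gma_model()].
#' @param unmeasured character vector of unmeasured species names.
#' @return integer, `n - m + length(unmeasured)`.
#' @export
compute_dof <- function(model, unmeasured = character()) {
  unmeasured <- match_species(model, unmeasured)
  m <- n_species(model)
  if (length(unmeasured) >= m) {
    stop("all species unmeasured: no measured mass balance is left",
         call. = FALSE)
  }
  n_fluxes(model) - m + length(unmeasured)
}

match_species <- function(model, x) {
  x <- as.character(x)
  bad <- setdiff(x, model$species)
  if (length(bad)) {
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Build a flux partition
#'
#' Splits the fluxes into an independent set I (whose parameters are
#' searched by the optimizer) and the complementary dependent set D
#' (computed algebraically from the measured slopes).  In the full-data
#' case `|D| = m` and the submatrix `S_D` must be invertible.  With
#' unmeasured metabolites, I must contain every flux that appears in an
#' unmeasured species' balance, and the measured-row block `S_D,M` must
#' have full column rank (it is inverted -- or pseudo-inverted when
#' rectangular -- in the dependent-flux solve).
#'
#' Invertibility is judged by a relative condition-number threshold of
#' `1e10` rather than exact singularity, since stoichiometric entries may
#' be user-scaled.
#'
#' @param model a [gma_model()].
#' @param independent character vector of independent flux names.
#' @param unmeasured character vector of unmeasured species names.
#' @return An object of class `flux_partition`.
#' @export
flux_partition <- function(model, independent, unmeasured = character()) {
  independent <- as.character(independent)
  bad <- setdiff(independent, model$fluxes)
  if (length(bad)) {
    stop("unknown flux(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unmeasured <- match_species(model, unmeasured)
  measured <- setdiff(model$species, unmeasured)
  dependent <- setdiff(model$fluxes, independent)

  # every flux touching an unmeasured balance must be independent
  if (length(unmeasured)) {
    S_U <- model$S[unmeasured, , drop = FALSE]
    needed <- model$fluxes[colSums(S_U != 0) > 0]
    missing <- setdiff(needed, independent)
    if (length(missing)) {
      stop("flux(es) appearing in an unmeasured balance must be ",
           "independent: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  S_I <- model$S[, independent, drop = FALSE]
  S_D <- model$S[, dependent, drop = FALSE]
  S_IM <- S_I[measured, , drop = FALSE]
  S_DM <- S_D[measured, , drop = FALSE]

  if (length(dependent) > length(measured)) {
    stop("structural error: ", length(dependent), " dependent fluxes but ",
         "only ", length(measured), " measured balances -- enlarge the ",
         "independent set", call. = FALSE)
  }
  if (ncol(S_DM)) {
    sv <- svd(S_DM)$d
    if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
      stop("structural error: S_D (measured rows) is rank deficient for ",
           "I = {", paste(independent, collapse = ", "), "}; condition ",
           "number exceeds 1e10", call. = FALSE)
    }
  }

  structure(
    list(model_species = model$species, model_fluxes = model$fluxes,
         independent = independent, dependent = dependent,
         measured = measured, unmeasured = unmeasured,
         S_I = S_I, S_D = S_D, S_IM = S_IM, S_DM = S_DM,
         S_M = model$S[measured, , drop = FALSE],
         S_U = model$S[unmeasured, , drop = FALSE],
         n_dof = length(independent)),
    class = "flux_partition"
  )
}

#' @export
print.flux_partition <- function(x, ...) {
  cat("<flux_partition> I = {", paste(x$independent, collapse = ", "),
      "}, D = {", paste(x$dependent, collapse = ", "), "}\n", sep = "")
  if (length(x$unmeasured)) {
    cat("  unmeasured: ", paste(x$unmeasured, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Enumerate admissible flux partitions, best first
#'
#' Exhaustively searches the `choose(n, n_dof)` candidate independent
#' sets (forcing the fluxes of unmeasured balances in), keeps those whose
#' dependent block passes the rank test, and ranks them by the selection
#' criteria for the independent fluxes: fewest independent parameters
#' first, then the most prior-known independent parameters, then
#' lexicographic flux order (the deterministic tie-break).  Exhaustive
#' search is adequate for the tens of fluxes typical of pathway models.
#'
#' @param model a [gma_model()].
#' @param unmeasured character vector of unmeasured species.
#' @param prior_known optional tibble with columns `flux`, `parameter`
#'   naming independent parameters whose values are known a priori.
#' @param max_keep maximum number of partitions to return.
#' @return tibble with columns `independent` (list), `n_params`,
#'   `n_known`, `cond_SD`, `partition` (list of `flux_partition`), ranked
#'   best first.
#' @export
enumerate_partitions <- function(model, unmeasured = character(),
                                 prior_known = NULL, max_keep = Inf) {
  unmeasured <- match_species(model, unmeasured)
  dof <- compute_dof(model, unmeasured)
  fluxes <- model$fluxes
  forced <- if (length(unmeasured)) {
    fluxes[colSums(model$S[unmeasured, , drop = FALSE] != 0) > 0]
  } else character()
  if (length(forced) > dof) {
    stop("structural error: ", length(forced), " fluxes are forced into I ",
         "by unmeasured balances but the degree of freedom is only ", dof,
         call. = FALSE)
  }
  free <- setdiff(fluxes, forced)
  if (dof == 0) {
    part <- flux_partition(model, character(), unmeasured)
    return(tibble::tibble(independent = list(character()), n_params = 0L,
                          n_known = 0L, cond_SD = cond_number(part$S_DM),
                          partition = list(part)))
  }
  picks <- utils::combn(free, dof - length(forced), simplify = FALSE)
  npar <- flux_n_params(model)
  known_count <- function(ind) {
    if (is.null(prior_known)) return(0L)
    sum(prior_known$flux %in% ind)
  }
  rows <- list()
  for (pick in picks) {
    ind <- fluxes[fluxes %in% c(forced, pick)]  # canonical flux order
    part <- tryCatch(flux_partition(model, ind, unmeasured),
                     error = function(e) NULL)
    if (is.null(part)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      independent = list(ind),
      n_params = sum(npar[ind]),
      n_known = known_count(ind),
      cond_SD = cond_number(part$S_DM),
      partition = list(part)
    )
  }
  if (!length(rows)) {
    stop("structural error: no independent set of size ", dof,
         " leaves an invertible dependent block S_D", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  key <- vapply(out$independent, function(i) {
    paste(sprintf("%04d", match(i, fluxes)), collapse = " ")
  }, character(1))
  out <- out[order(out$n_params, -out$n_known, key), ]
  utils::head(out, max_keep)
}

cond_number <- function(M) {
  if (!length(M)) return(1)
  sv <- svd(M)$d
  if (sv[length(sv)] <= 0) Inf else sv[1] / sv[length(sv)]
}

#' Dependent fluxes from measured slopes (full data)
#'
#' Solves, at every time point, the m x m linear system
#' `S_D v_D(t_k) = Xdot(t_k) - S_I v_I(t_k)`, the algebraic core of the
#' incremental method.  `S_D` is factored once.  The stacked flux vector
#' `[v_I; v_D]` then reproduces the measured slopes exactly.
#'
#' @param partition a full-data [flux_partition()].
#' @param slopes K x m matrix of measured slopes (columns in model species
#'   order).
#' @param v_I K x |I| matrix of independent flux values.
#' @return K x |D| matrix of dependent flux values.
#' @export
dependent_fluxes <- function(partition, slopes, v_I) {
  if (length(partition$unmeasured)) {
    stop("partition has unmeasured species; use dependent_fluxes_missing()",
         call. = FALSE)
  }
  slopes <- as.matrix(slopes); v_I <- as.matrix(v_I)
  check_decomp_dims(partition, slopes, v_I)
  rhs <- t(slopes) - if (ncol(v_I)) partition$S_I %*% t(v_I) else 0
  V_D <- t(solve(partition$S_D, rhs))
  colnames(V_D) <- partition$dependent
  V_D
}

#' Dependent fluxes from measured slopes (unmeasured metabolites)
#'
#' The measured-row analogue
#' `v_D(t_k) = S_D,M^+ [Xdot_M(t_k) - S_I,M v_I(t_k)]`, solved by QR least
#' squares.  When `S_D,M` is square and invertible this equals the exact
#' solve; when rectangular (more measured balances than dependent fluxes)
#' it is the pseudo-inverse solution and the residual of the overdetermined
#' system is reported in the `"lsq_residual"` attribute (one norm per time
#' point) as a consistency diagnostic.
#'
#' @param partition a [flux_partition()] (any measurement pattern).
#' @param slopes_M K x |M| matrix of measured-species slopes.
#' @param v_I K x |I| matrix of independent flux values.
#' @return K x |D| matrix of dependent flux values.
#' @export
dependent_fluxes_missing <- function(partition, slopes_M, v_I) {
  slopes_M <- as.matrix(slopes_M); v_I <- as.matrix(v_I)
  if (ncol(slopes_M) != length(partition$measured)) {
    stop("`slopes_M` must have one column per measured species",
         call. = FALSE)
  }
  if (ncol(v_I) != length(partition$independent)) {
    stop("`v_I` must have one column per independent flux", call. = FALSE)
  }
  rhs <- t(slopes_M) - if (ncol(v_I)) partition$S_IM %*% t(v_I) else 0
  qr_DM <- qr(partition$S_DM)
  if (qr_DM$rank < ncol(partition$S_DM)) {
    stop("structural error: S_D,M lost full column rank", call. = FALSE)
  }
  V_D <- t(qr.coef(qr_DM, rhs))
  colnames(V_D) <- partition$dependent
  resid <- partition$S_DM %*% t(V_D) - rhs
  attr(V_D, "lsq_residual") <- sqrt(colSums(resid^2))
  V_D
}

check_decomp_dims <- function(partition, slopes, v_I) {
  if (ncol(slopes) != length(partition$model_species)) {
    stop("`slopes` must have one column per species", call. = FALSE)
  }
  if (ncol(v_I) != length(partition$independent)) {
    stop("`v_I` must have one column per independent flux", call. = FALSE)
  }
  if (nrow(slopes) != nrow(v_I)) {
    stop("`slopes` and `v_I` must cover the same time points", call. = FALSE)
  }
  invisible(TRUE)
}
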