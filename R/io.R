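#' Read a time-course concentration table
#'
#' Delimited text with a header: a `time` column plus one column per
#' species.  Empty cells are missing observations; a column that is empty
#' throughout marks an unmeasured metabolite.  Rows are sorted by time
#' (with a warning if the file was unsorted); duplicate times and
#' non-numeric cells are errors that identify the offending row/column.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return tibble with `time` first.
#' @export
read_timecourse <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (!"time" %in% names(raw)) {
    stop("parse error: header must contain a `time` column", call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  for (cn in names(out)) {
    vals <- out[[cn]]
    vals[vals == ""] <- NA
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad)) {
      stop("parse error: non-numeric cell at row ", bad[1], ", column `",
           cn, "` (", vals[bad[1]], ")", call. = FALSE)
    }
    out[[cn]] <- num
  }
  if (anyNA(out$time)) {
    stop("parse error: missing value in the `time` column", call. = FALSE)
  }
  if (anyDuplicated(out$time)) {
    stop("parse error: duplicate time ",
         out$time[anyDuplicated(out$time)], call. = FALSE)
  }
  if (is.unsorted(out$time)) {
    warning("times were not sorted; sorting", call. = FALSE)
    out <- out[order(out$time), ]
  }
  dplyr::relocate(out, "time")
}

#' Write a time-course table
#'
#' @param data tibble with `time` and species columns.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(data, path, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a declarative GMA model specification
#'
#' A human-writable YAML format: `species`, `initial_conditions`,
#' `fluxes` (per flux: `gamma` and a map of kinetic `orders`),
#' `stoichiometry` as a list of `[species, flux, coefficient]` triples,
#' optional `offline` variable tables (`time`/`value` arrays) and
#' optional `bounds` rows.  [write_gma_model()] produces the same format;
#' the two round-trip.
#'
#' @param path YAML file path.
#' @return list with elements `model` (a [gma_model()]) and `bounds`
#'   (tibble or `NULL`).
#' @export
read_gma_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("species", "fluxes", "stoichiometry", "initial_conditions")
  miss <- setdiff(need, names(y))
  if (length(miss)) {
    stop("model spec lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  species <- as.character(y$species)
  flux_names <- names(y$fluxes)
  S <- matrix(0, length(species), length(flux_names),
              dimnames = list(species, flux_names))
  for (tr in y$stoichiometry) {
    S[tr[[1]], tr[[2]]] <- as.numeric(tr[[3]])
  }
  offline <- lapply(y$offline %||% list(), function(tbl) {
    data.frame(time = as.numeric(tbl$time), value = as.numeric(tbl$value))
  })
  regs <- c(species, names(offline))
  orders <- matrix(0, length(flux_names), length(regs),
                   dimnames = list(flux_names, regs))
  gamma <- numeric(length(flux_names))
  for (j in seq_along(flux_names)) {
    fl <- y$fluxes[[j]]
    gamma[j] <- as.numeric(fl$gamma)
    for (rn in names(fl$orders %||% list())) {
      orders[j, rn] <- as.numeric(fl$orders[[rn]])
    }
  }
  x0 <- unlist(y$initial_conditions)[species]
  model <- gma_model(species, flux_names, S, gamma, orders, x0,
                     offline = offline)
  bounds <- if (!is.null(y$bounds)) {
    dplyr::bind_rows(lapply(y$bounds, function(b) {
      tibble::tibble(flux = b$flux, parameter = b$parameter,
                     lower = as.numeric(b$lower),
                     upper = as.numeric(b$upper))
    }))
  } else NULL
  list(model = model, bounds = bounds)
}

#' Write a GMA model specification
#'
#' @param model a [gma_model()].
#' @param path output YAML path.
#' @param bounds optional bounds tibble to embed.
#' @return `path`, invisibly.
#' @export
write_gma_model <- function(model, path, bounds = NULL) {
  fluxes <- lapply(model$fluxes, function(fl) {
    regs <- colnames(model$orders)[model$structure[fl, ]]
    list(gamma = unname(model$gamma[fl]),
         orders = as.list(stats::setNames(model$orders[fl, regs], regs)))
  })
  names(fluxes) <- model$fluxes
  stoich <- list()
  for (sp in model$species) for (fl in model$fluxes) {
    if (model$S[sp, fl] != 0) {
      stoich[[length(stoich) + 1L]] <- list(sp, fl,
                                            unname(model$S[sp, fl]))
    }
  }
  y <- list(
    species = as.list(model$species),
    initial_conditions = as.list(model$x0),
    fluxes = fluxes,
    stoichiometry = stoich
  )
  if (length(model$offline)) {
    stop("writing off-line variables requires tabulated profiles; ",
         "models built from functions cannot be serialised", call. = FALSE)
  }
  if (!is.null(bounds)) {
    y$bounds <- lapply(seq_len(nrow(bounds)), function(i) {
      as.list(bounds[i, c("flux", "parameter", "lower", "upper")])
    })
  }
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Serialise an estimation result
#'
#' Writes a JSON result (full numeric precision, round-trip readable via
#' [read_result()]), a human-readable text report and the optimizer trace
#' as a delimited log, all sharing `stem`.
#'
#' @param fit an `estimation_fit`.
#' @param stem output path stem; writes `<stem>.json`, `<stem>.txt`,
#'   `<stem>_trace.csv`.
#' @return named character vector of the paths written, invisibly.
#' @export
write_result <- function(fit, stem) {
  paths <- c(json = paste0(stem, ".json"), report = paste0(stem, ".txt"),
             trace = paste0(stem, "_trace.csv"))
  payload <- list(
    method = fit$method, objective = fit$objective, status = fit$status,
    phi = fit$phi, phi_C = fit$phi_C, phi_S = fit$phi_S,
    parameter_error = fit$parameter_error,
    n_evals = fit$n_evals, best_run = fit$best_run,
    par = fit$par,
    params = fit$params,
    x_u0 = as.list(fit$x_u0 %||% stats::setNames(list(), character())),
    runs = fit$runs
  )
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = I(17), na = "null")
  rep <- utils::capture.output(print(fit))
  writeLines(c(rep, "", "parameters:",
               utils::capture.output(print.data.frame(
                 as.data.frame(fit$params)))),
             paths[["report"]])
  if (!is.null(fit$trace)) {
    utils::write.csv(fit$trace, paths[["trace"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read back a serialised estimation result
#'
#' @param path a `.json` file written by [write_result()].
#' @return list with the numeric fields restored at full precision
#'   (`params` and `runs` as tibbles).
#' @export
read_result <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$params <- tibble::as_tibble(out$params)
  out$runs <- tibble::as_tibble(out$runs)
  out$par <- as.numeric(out$par)
  out
}
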