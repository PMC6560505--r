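#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Columns every NONMEM-style dataset must carry (MDV is derived when absent).
.pk_required_cols <- c("ID", "TIME", "DV", "AMT", "EVID")
.pk_reserved_cols <- c(.pk_required_cols, "MDV")

#' Construct a PK dataset tibble
#'
#' A `pk_dataset` is an ordinary long-format tibble in NONMEM convention:
#' one row per event, with `ID`, `TIME` (h), `AMT` (mg, dose rows), `DV`
#' (mg/L, observation rows), `EVID` (1 = dose, 0 = observation) and `MDV`
#' (1 = DV missing). Any further column is treated as a subject-constant
#' covariate (e.g. `WT` in kg or a binary `COV`). Only EVID 0 and 1 are
#' supported; times are absolute hours from first dose.
#'
#' @param data data frame with at least ID, TIME, DV, AMT, EVID.
#' @param design_label optional free-text label describing the design.
#' @return a tibble of class `pk_dataset`, rows ordered by ID (input order
#'   of first appearance) then TIME.
#' @export
pk_dataset <- function(data, design_label = NULL) {
  data <- as_tibble(data)
  missing_cols <- setdiff(.pk_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mixvpc_format_error")
  }
  if (!"MDV" %in% names(data)) {
    data$MDV <- ifelse(data$EVID == 1L | is.na(data$DV), 1L, 0L)
  }
  bad_time <- which(!is.finite(data$TIME) | data$TIME < 0)
  if (length(bad_time) > 0) {
    abort(paste0("TIME must be finite and >= 0; first offending row: ",
                 bad_time[1]),
          class = "mixvpc_validation_error")
  }
  if (!all(data$EVID %in% c(0L, 1L))) {
    abort("only EVID 0 (observation) and 1 (dose) records are supported",
          class = "mixvpc_validation_error")
  }
  bad_amt <- which(data$EVID == 1L & (is.na(data$AMT) | data$AMT <= 0))
  if (length(bad_amt) > 0) {
    abort(paste0("dose rows must have AMT > 0; first offending row: ",
                 bad_amt[1]),
          class = "mixvpc_validation_error")
  }
  cov_cols <- setdiff(names(data), c(.pk_reserved_cols, "ROUTE", "REP"))
  for (cc in cov_cols) {
    n_distinct_within <- data |>
      group_by(.data$ID) |>
      summarise(n = n_distinct(.data[[cc]]), .groups = "drop")
    if (any(n_distinct_within$n > 1)) {
      abort(paste0("covariate '", cc, "' varies within subject; ",
                   "time-varying covariates are not supported"),
            class = "mixvpc_validation_error")
    }
  }
  data$ID <- as.character(data$ID)
  id_order <- unique(data$ID)
  data <- data |>
    arrange(match(.data$ID, id_order), .data$TIME, desc(.data$EVID))
  structure(data,
            class = c("pk_dataset", class(tibble())),
            design_label = design_label %||% attr(data, "design_label"))
}

#' Read a NONMEM-style CSV dataset
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping the canonical
#'   names to the file's column names, e.g. `c(DV = "CONC")`.
#' @return a [pk_dataset] tibble.
#' @export
read_pk_dataset <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  pk_dataset(raw)
}

#' Write a PK dataset to CSV
#'
#' @param data a [pk_dataset] (or compatible data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Split a dataset into per-subject dose and observation records
#'
#' Internal workhorse used by the likelihood and simulation code: turns the
#' long table into a list with one element per subject holding numeric
#' vectors (fast to iterate over during estimation).
#' @param data a [pk_dataset].
#' @return list of subjects; each has `id`, `dose_times`, `dose_amts`,
#'   `obs_times`, `obs_values`, `covariates` (named list).
#' @keywords internal
split_subjects <- function(data) {
  id <- as.character(data$ID)
  time <- data$TIME
  amt <- data$AMT
  dv <- data$DV
  evid <- data$EVID
  mdv <- if ("MDV" %in% names(data)) data$MDV else ifelse(evid == 1L, 1L, 0L)
  cov_cols <- setdiff(names(data), c(.pk_reserved_cols, "ROUTE", "REP"))
  cov_data <- lapply(cov_cols, function(cc) data[[cc]])
  names(cov_data) <- cov_cols
  ids <- unique(id)
  rows_by_id <- split(seq_along(id), factor(id, levels = ids))
  lapply(ids, function(i) {
    rows <- rows_by_id[[i]]
    is_dose <- evid[rows] == 1L
    is_obs <- evid[rows] == 0L & mdv[rows] == 0L
    list(id = i,
         dose_times = time[rows][is_dose], dose_amts = amt[rows][is_dose],
         obs_times = time[rows][is_obs], obs_values = dv[rows][is_obs],
         covariates = lapply(cov_data, function(v) v[rows[1]]))
  })
}

#' Residual error specification
#'
#' @param proportional proportional error variance (unitless), or NULL.
#' @param additive additive error variance ((mg/L)^2), or NULL.
#' @return named list with elements `model` (one of "proportional",
#'   "additive", "combined") and the variances.
#' @export
residual_spec <- function(proportional = NULL, additive = NULL) {
  if (is.null(proportional) && is.null(additive)) {
    abort("at least one of proportional/additive variance is required")
  }
  for (v in c(proportional, additive)) {
    if (!is.finite(v) || v < 0) {
      abort("residual variances must be finite and >= 0",
            class = "mixvpc_domain_error")
    }
  }
  model <- if (!is.null(proportional) && !is.null(additive)) "combined"
           else if (!is.null(proportional)) "proportional" else "additive"
  structure(list(model = model,
                 proportional = proportional %||% 0,
                 additive = additive %||% 0),
            class = "residual_spec")
}

#' Population parameters of a (possibly) mixture model
#'
#' Container for the typical values, mixing proportions and variance
#' components of a K-component mixture nonlinear mixed-effects model.
#' The mixture parameter (e.g. CL) has one typical value per component
#' (theta_component); all other structural parameters are shared.
#'
#' @param theta_component named list; each element a numeric vector of
#'   length K with per-component typical values (e.g. `list(CL = c(20, 80))`).
#'   May be empty (non-mixture model).
#' @param theta_shared named numeric vector of shared typical values
#'   (e.g. `c(ka = 1, V = 100)`).
#' @param pmix numeric probability vector over the K components; must sum
#'   to 1. Use `1` for a single-component model.
#' @param omega named numeric vector of random-effect variances (lognormal
#'   interindividual variability on the named parameters).
#' @param sigma a [residual_spec].
#' @return object of class `mix_params`.
#' @export
mixture_parameters <- function(theta_component = list(), theta_shared = numeric(),
                               pmix = 1, omega = numeric(), sigma) {
  if (abs(sum(pmix) - 1) > 1e-12 || any(pmix < 0) || any(pmix > 1)) {
    abort("pmix entries must lie in [0,1] and sum to 1 (tolerance 1e-12)",
          class = "mixvpc_domain_error")
  }
  K <- length(pmix)
  for (nm in names(theta_component)) {
    v <- theta_component[[nm]]
    if (length(v) != K) {
      abort(paste0("theta_component$", nm, " must have one value per component"),
            class = "mixvpc_domain_error")
    }
    if (any(!is.finite(v) | v <= 0)) {
      abort("typical values must be positive and finite",
            class = "mixvpc_domain_error")
    }
  }
  if (length(theta_shared) && any(!is.finite(theta_shared) | theta_shared <= 0)) {
    abort("typical values must be positive and finite",
          class = "mixvpc_domain_error")
  }
  if (length(omega) && any(!is.finite(omega) | omega <= 0)) {
    abort("omega variances must be positive and finite",
          class = "mixvpc_domain_error")
  }
  stopifnot(inherits(sigma, "residual_spec"))
  structure(list(theta_component = theta_component,
                 theta_shared = theta_shared,
                 pmix = as.numeric(pmix),
                 omega = omega, sigma = sigma),
            class = "mix_params")
}

#' @export
print.mix_params <- function(x, ...) {
  cat("<mix_params> ", length(x$pmix), " component(s)\n", sep = "")
  if (length(x$theta_component)) {
    for (nm in names(x$theta_component)) {
      cat("  ", nm, " (by component): ",
          paste(signif(x$theta_component[[nm]], 4), collapse = " / "), "\n",
          sep = "")
    }
  }
  if (length(x$theta_shared)) {
    cat("  shared:", paste(names(x$theta_shared),
                           signif(x$theta_shared, 4),
                           sep = "=", collapse = ", "), "\n")
  }
  cat("  pmix:", paste(signif(x$pmix, 4), collapse = " / "), "\n")
  if (length(x$omega)) {
    cat("  omega:", paste(names(x$omega), signif(x$omega, 4),
                          sep = "=", collapse = ", "), "\n")
  }
  cat("  sigma:", x$sigma$model,
      "prop =", signif(x$sigma$proportional, 4),
      "add =", signif(x$sigma$additive, 4), "\n")
  invisible(x)
}

#' The typical-value set of one mixture component
#'
#' Merges per-component and shared typical values into a single named list
#' for component `k`.
#' @param params a [mixture_parameters] object.
#' @param k component index.
#' @return named list of typical values.
#' @export
component_theta <- function(params, k) {
  th <- as.list(params$theta_shared)
  for (nm in names(params$theta_component)) {
    th[[nm]] <- params$theta_component[[nm]][k]
  }
  th
}

#' Serialize / read mixture parameters as YAML
#'
#' @param params a `mix_params` object.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `path` invisibly; `read_params()` returns the `mix_params`.
#' @export
write_params <- function(params, path) {
  x <- list(theta_component = lapply(params$theta_component, as.numeric),
            theta_shared = as.list(params$theta_shared),
            pmix = as.numeric(params$pmix),
            omega = as.list(params$omega),
            sigma = list(model = params$sigma$model,
                         proportional = params$sigma$proportional,
                         additive = params$sigma$additive))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  sig <- x$sigma
  sigma <- residual_spec(
    proportional = if (sig$proportional > 0 || sig$model %in% c("proportional", "combined")) sig$proportional else NULL,
    additive = if (sig$additive > 0 || sig$model %in% c("additive", "combined")) sig$additive else NULL)
  mixture_parameters(theta_component = lapply(x$theta_component, as.numeric),
                     theta_shared = unlist(x$theta_shared) %||% numeric(),
                     pmix = as.numeric(x$pmix),
                     omega = unlist(x$omega) %||% numeric(),
                     sigma = sigma)
}

#' Write / read a phm-like table of individual mixture records
#'
#' The phm-like table is the per-individual, per-component summary of the
#' mixture evaluation: the individual objective function value (`IOFV`,
#' -2 log marginal likelihood for that component), the relative individual
#' likelihood (`IL`), the posterior subpopulation probability (`IPmix`) and
#' the most likely subpopulation (`MIXEST`). One row per (ID, SUBPOP);
#' numeric values round-trip at 12 significant digits.
#'
#' @param records a records tibble as produced by [evaluate_mixture()]
#'   (columns ID, SUBPOP, IOFV, IL, IPmix, MIXEST).
#' @param path output CSV path.
#' @return `path` invisibly; `read_phm()` returns the records tibble.
#' @export
write_phm <- function(records, path) {
  if (is.null(records) || nrow(records) == 0) {
    abort("cannot write an empty phm table", class = "mixvpc_usage_error")
  }
  out <- records |>
    transmute(ID = .data$ID,
              SUBPOP = .data$SUBPOP,
              IOFV = formatC(.data$IOFV, digits = 12, format = "g"),
              IL = formatC(.data$IL, digits = 12, format = "g"),
              IPmix = formatC(.data$IPmix, digits = 12, format = "g"),
              MIXEST = .data$MIXEST)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_phm
#' @export
read_phm <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(ID = readr::col_character())) |>
    mutate(SUBPOP = as.integer(.data$SUBPOP), MIXEST = as.integer(.data$MIXEST))
}
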