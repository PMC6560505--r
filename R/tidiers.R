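#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted mixture model
#'
#' One row per estimated quantity: component-specific typical values,
#' shared typical values, mixing proportions, random-effect variances and
#' residual variances.
#'
#' @param x a `mixfit`.
#' @param ... unused.
#' @return tibble with columns `term`, `component` (NA for shared terms),
#'   `estimate`.
#' @method tidy mixfit
#' @export
tidy.mixfit <- function(x, ...) {
  p <- x$params
  rows <- list()
  for (nm in names(p$theta_component)) {
    rows[[length(rows) + 1]] <- tibble(term = nm,
                                       component = seq_along(p$theta_component[[nm]]),
                                       estimate = p$theta_component[[nm]])
  }
  if (length(p$theta_shared)) {
    rows[[length(rows) + 1]] <- tibble(term = names(p$theta_shared),
                                       component = NA_integer_,
                                       estimate = unname(p$theta_shared))
  }
  if (length(p$pmix) > 1) {
    rows[[length(rows) + 1]] <- tibble(term = "pmix",
                                       component = seq_along(p$pmix),
                                       estimate = p$pmix)
  }
  if (length(p$omega)) {
    rows[[length(rows) + 1]] <- tibble(term = paste0("omega.", names(p$omega)),
                                       component = NA_integer_,
                                       estimate = unname(p$omega))
  }
  sig <- c(if (p$sigma$model %in% c("proportional", "combined"))
             c(sigma.prop = p$sigma$proportional),
           if (p$sigma$model %in% c("additive", "combined"))
             c(sigma.add = p$sigma$additive))
  rows[[length(rows) + 1]] <- tibble(term = names(sig),
                                     component = NA_integer_,
                                     estimate = unname(sig))
  bind_rows(rows)
}

#' One-line summary of a fitted mixture model
#'
#' @param x a `mixfit`.
#' @param ... unused.
#' @return one-row tibble: ofv, converged, n_subjects, n_components,
#'   pmix_1 (dominant-first not applied; component order is canonical),
#'   best_start, n_function_evals, boundary.
#' @method glance mixfit
#' @export
glance.mixfit <- function(x, ...) {
  tibble(ofv = x$ofv, converged = x$converged, n_subjects = x$n_subjects,
         n_components = length(x$params$pmix),
         pmix_1 = x$params$pmix[1],
         best_start = x$best_start,
         n_function_evals = x$n_function_evals,
         boundary = x$boundary)
}

#' Tidy a VPC result
#'
#' @param x a `vpc_result`.
#' @param ... unused.
#' @return the bands tibble: one row per stratum, bin and percentile with
#'   observed value, simulation CI and outside flag.
#' @method tidy vpc_result
#' @export
tidy.vpc_result <- function(x, ...) as_tibble(x$bands)

#' Per-stratum VPC summary
#'
#' @param x a `vpc_result`.
#' @param ... unused.
#' @return tibble with one row per stratum: number of (bin x percentile)
#'   cells with an available band, number of cells where the observed
#'   percentile falls outside its CI, and the outside rate.
#' @method glance vpc_result
#' @export
glance.vpc_result <- function(x, ...) {
  x$bands |>
    group_by(.data$stratum) |>
    summarise(cells = sum(!is.na(.data$lo) & !is.na(.data$obs)),
              outside = sum(.data$outside, na.rm = TRUE),
              outside_rate = .data$outside / pmax(.data$cells, 1),
              .groups = "drop")
}

#' Export a VPC result to CSV / JSON
#'
#' CSV holds one row per stratum x bin x percentile (observed value,
#' CI bounds, bin size); JSON adds the allocation summary and
#' configuration.
#'
#' @param x a `vpc_result`.
#' @param path output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_vpc <- function(x, path) {
  if (grepl("\\.json$", path)) {
    payload <- list(strategy = x$strategy,
                    bands = x$bands,
                    allocation = if (!is.null(x$allocation))
                      list(table = as_tibble(x$allocation),
                           bias_pp = attr(x$allocation, "bias_pp")),
                    config = x$config[c("percentiles", "ci_level",
                                        "n_replicates", "bin_mode",
                                        "strategy", "seed")])
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    readr::write_csv(x$bands, path, progress = FALSE)
  }
  invisible(path)
}
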