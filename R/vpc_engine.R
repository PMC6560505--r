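#' VPC configuration
#'
#' @param percentiles strictly increasing percentiles in (0, 100);
#'   default 5/50/95.
#' @param ci_level simulation confidence band level (default 0.95).
#' @param n_replicates number of simulated replicates R (default 200;
#'   at least 20 for meaningful bands).
#' @param bin_mode `"nominal"` (one bin per distinct design time; the
#'   default, suitable for fixed sampling designs) or `"quantile"`
#'   (equal-count bins for irregular data).
#' @param n_bins bin count for quantile binning.
#' @param strategy `"none"` (traditional), `"mixest"` or `"randomized"`.
#' @param seed integer seed driving replicate simulation and any
#'   randomized allocation.
#' @return object of class `vpc_config`.
#' @export
vpc_config <- function(percentiles = c(5, 50, 95), ci_level = 0.95,
                       n_replicates = 200L, bin_mode = c("nominal", "quantile"),
                       n_bins = 8L, strategy = c("none", "mixest", "randomized"),
                       seed = 1L) {
  bin_mode <- match.arg(bin_mode)
  strategy <- match.arg(strategy)
  if (any(diff(percentiles) <= 0) || any(percentiles <= 0) ||
      any(percentiles >= 100)) {
    rlang::abort("percentiles must be strictly increasing in (0, 100)",
                 class = "mixvpc_usage_error")
  }
  if (n_replicates < 20) {
    rlang::abort("at least 20 replicates are required for CI output",
                 class = "mixvpc_usage_error")
  }
  structure(list(percentiles = percentiles, ci_level = ci_level,
                 n_replicates = as.integer(n_replicates),
                 bin_mode = bin_mode, n_bins = as.integer(n_bins),
                 strategy = strategy, seed = as.integer(seed)),
            class = "vpc_config")
}

#' Bin observations by time
#'
#' Nominal mode gives one bin per distinct design time (exact match within
#' 1e-9 h); quantile mode gives `n_bins` equal-count bins with left-closed,
#' right-open intervals (the last bin closed).
#'
#' @param times,values observation times and values.
#' @param config a [vpc_config].
#' @param breaks optional pre-computed quantile-bin breaks (so simulated
#'   replicates can reuse the observed data's bins).
#' @return list with `bins` (tibble: bin, lo, hi, mid, n) and `idx` (bin
#'   index per observation).
#' @export
bin_observations <- function(times, values, config, breaks = NULL) {
  if (length(times) == 0) {
    rlang::abort("at least one observation is required",
                 class = "mixvpc_usage_error")
  }
  if (config$bin_mode == "nominal") {
    ut <- sort(unique(round(times / 1e-9) * 1e-9))
    idx <- match(round(times / 1e-9) * 1e-9, ut)
    bins <- tibble(bin = seq_along(ut), lo = ut, hi = ut, mid = ut,
                   n = tabulate(idx, length(ut)))
  } else {
    nb <- config$n_bins
    if (is.null(breaks)) {
      if (nb > length(unique(times))) {
        rlang::abort("more quantile bins than distinct observation times",
                     class = "mixvpc_usage_error")
      }
      breaks <- unique(stats::quantile(times, probs = seq(0, 1, length.out = nb + 1),
                                       type = 7, names = FALSE))
    }
    nb <- length(breaks) - 1
    idx <- findInterval(times, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    bins <- tibble(bin = seq_len(nb), lo = breaks[-length(breaks)],
                   hi = breaks[-1], mid = mids, n = tabulate(idx, nb))
  }
  list(bins = bins, idx = idx, breaks = breaks)
}

# linear-interpolation (type 7) percentiles of a vector
obs_percentiles <- function(x, percentiles) {
  stats::quantile(x, probs = percentiles / 100, type = 7, names = FALSE)
}

#' Observed percentiles with simulation-based confidence bands
#'
#' Bins the observed data, computes the requested percentiles per bin, and
#' derives, for every (bin, percentile) cell, the empirical confidence
#' interval of that percentile across simulated replicates (each replicate
#' binned identically to the observed data). Cells where any replicate has
#' an empty bin get an unavailable (NA) band rather than an error.
#'
#' @param obs tibble/data frame with columns `time`, `value` (observed).
#' @param sims list of such tibbles, one per replicate.
#' @param config a [vpc_config].
#' @return tibble: bin, t_mid, n_obs, percentile, obs, lo, mid, hi,
#'   outside (logical; observed value outside \[lo, hi\]).
#' @export
percentile_bands <- function(obs, sims, config) {
  ob <- bin_observations(obs$time, obs$value, config)
  nb <- nrow(ob$bins)
  pr <- config$percentiles
  np <- length(pr)
  obs_q <- matrix(NA_real_, nb, np)
  for (b in seq_len(nb)) {
    v <- obs$value[ob$idx == b]
    if (length(v) > 0) obs_q[b, ] <- obs_percentiles(v, pr)
  }
  R <- length(sims)
  sim_q <- array(NA_real_, c(R, nb, np))
  for (r in seq_len(R)) {
    sb <- bin_observations(sims[[r]]$time, sims[[r]]$value, config,
                           breaks = ob$breaks)
    # nominal mode: bins are per distinct time; align replicate bins to the
    # observed bin layout by time value
    map <- if (config$bin_mode == "nominal") {
      match(round(sb$bins$mid, 9), round(ob$bins$mid, 9))
    } else sb$bins$bin
    for (b2 in seq_len(nrow(sb$bins))) {
      target <- map[b2]
      if (is.na(target)) next
      v <- sims[[r]]$value[sb$idx == b2]
      if (length(v) > 0) sim_q[r, target, ] <- obs_percentiles(v, pr)
    }
  }
  a <- (1 - config$ci_level) / 2
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    cells <- tibble(bin = b, t_mid = ob$bins$mid[b], n_obs = ob$bins$n[b],
                    percentile = pr, obs = obs_q[b, ],
                    lo = NA_real_, mid = NA_real_, hi = NA_real_)
    for (j in seq_len(np)) {
      vals <- sim_q[, b, j]
      if (!anyNA(vals)) {
        cells$lo[j] <- stats::quantile(vals, a, type = 7, names = FALSE)
        cells$mid[j] <- stats::quantile(vals, 0.5, type = 7, names = FALSE)
        cells$hi[j] <- stats::quantile(vals, 1 - a, type = 7, names = FALSE)
      }
    }
    out[[b]] <- cells
  }
  bind_rows(out) |>
    mutate(outside = !is.na(.data$obs) & !is.na(.data$lo) &
             (.data$obs < .data$lo | .data$obs > .data$hi))
}

obs_tv <- function(data, ids = NULL) {
  d <- as_tibble(data) |> filter(.data$EVID == 0L, .data$MDV == 0L)
  if (!is.null(ids)) d <- d |> filter(.data$ID %in% ids)
  tibble(ID = d$ID, time = d$TIME, value = d$DV)
}

new_vpc_result <- function(bands, allocation, config, strategy, extra = list()) {
  structure(c(list(bands = bands, allocation = allocation, config = config,
                   strategy = strategy), extra),
            class = "vpc_result")
}

#' Traditional (single-panel) visual predictive check
#'
#' Simulates `R` replicates of the dataset from the model parameters and
#' compares observed percentiles per time bin against the simulation-based
#' confidence bands, pooling all individuals into one stratum.
#'
#' @param data a [pk_dataset].
#' @param fit a `mixfit` object (or a list with `params` and `model`).
#' @param config a [vpc_config].
#' @return a `vpc_result`: `bands` tibble (with `stratum = "all"`),
#'   no allocation annotation.
#' @export
traditional_vpc <- function(data, fit, config = vpc_config()) {
  sims <- simulate_replicates(fit$params, data, fit$model,
                              config$n_replicates, config$seed)
  bands <- percentile_bands(obs_tv(data), lapply(sims, obs_tv), config) |>
    mutate(stratum = "all", .before = 1)
  new_vpc_result(bands, NULL, config, "none",
                 extra = list(n_obs_total = nrow(obs_tv(data))))
}

#' Mixture-model-specific visual predictive check
#'
#' The mixture VPC pipeline: (1) simulate `R` replicates from the fitted
#' parameters over the original design; (2) evaluate the model at those
#' fixed parameters on the original data and on every replicate to obtain
#' posterior subpopulation probabilities (the MAXEVAL = 0 analog); (3)
#' allocate observed and simulated individuals to subpopulations with the
#' MIXEST or the randomized IP_mix strategy (observed individuals once per
#' run, each replicate independently); (4) bin and band each
#' subpopulation's data separately; (5) attach the PMIX/ORIGID/SIMID
#' allocation summary.
#'
#' @param data a [pk_dataset].
#' @param fit a `mixfit` with a >= 2 component mixture.
#' @param config a [vpc_config] with `strategy` `"mixest"` or
#'   `"randomized"`.
#' @param settings [likelihood_settings()] for the evaluation step.
#' @param true_pmix optional true proportions for the bias-vs-truth
#'   annotation.
#' @return a `vpc_result`: `bands` tibble with one stratum per
#'   subpopulation, plus the [allocation_summary()] annotation.
#' @export
mixture_vpc <- function(data, fit, config = vpc_config(strategy = "mixest"),
                        settings = NULL, true_pmix = NULL) {
  if (length(fit$params$pmix) < 2) {
    rlang::abort("mixture VPC requires a >= 2 component fit",
                 class = "mixvpc_usage_error")
  }
  if (config$strategy == "none") {
    rlang::abort("choose strategy 'mixest' or 'randomized' for a mixture VPC",
                 class = "mixvpc_usage_error")
  }
  settings <- settings %||% fit$settings %||% likelihood_settings()
  K <- length(fit$params$pmix)
  sims <- simulate_replicates(fit$params, data, fit$model,
                              config$n_replicates, config$seed)
  obs_records <- fit$records %||%
    evaluate_mixture(data, fit$params, fit$model, settings)
  sim_records <- lapply(sims, evaluate_mixture, params = fit$params,
                        model = fit$model, settings = settings)

  alloc_seed <- derive_seed(config$seed, 1e6)
  obs_assign <- assign_by_strategy(obs_records, config$strategy,
                                   derive_seed(alloc_seed, 0))
  sim_assign <- lapply(seq_along(sim_records), function(r) {
    assign_by_strategy(sim_records[[r]], config$strategy,
                       derive_seed(alloc_seed, r))
  })

  strata <- vector("list", K)
  for (k in seq_len(K)) {
    obs_ids <- obs_assign$ID[obs_assign$COMP == k]
    if (length(obs_ids) == 0) {
      rlang::warn(paste0("no observed individuals allocated to subpopulation ",
                         k, "; panel suppressed"))
      next
    }
    o <- obs_tv(data, obs_ids)
    s <- lapply(seq_along(sims), function(r) {
      obs_tv(sims[[r]], sim_assign[[r]]$ID[sim_assign[[r]]$COMP == k])
    })
    strata[[k]] <- percentile_bands(o, s, config) |>
      mutate(stratum = paste0("subpop ", k), .before = 1)
  }
  alloc <- allocation_summary(obs_records, sim_records, fit$params$pmix,
                              strategy = config$strategy, seed = alloc_seed,
                              true_pmix = true_pmix)
  new_vpc_result(bind_rows(strata), alloc, config, config$strategy,
                 extra = list(n_obs_total = nrow(obs_tv(data)),
                              obs_records = obs_records,
                              obs_assign = obs_assign))
}

#' IP_mix separation diagnostic
#'
#' Histogram of the posterior probability of belonging to subpopulation 1
#' across individuals (20 equal bins on \[0, 1\]), plus a scalar separation
#' index: the fraction of individuals whose largest posterior membership
#' probability is at least 0.8. Mass near 0.5 marks individuals whose data
#' cannot discriminate the subpopulations.
#'
#' @param records phm-like tibble from [evaluate_mixture()].
#' @return tibble (bin, lo, hi, count) of class `mix_separation` with
#'   attribute `separation_index`.
#' @export
separation_histogram <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    rlang::abort("records must be non-empty", class = "mixvpc_usage_error")
  }
  per_id <- records |>
    group_by(.data$ID) |>
    summarise(ip1 = .data$IPmix[.data$SUBPOP == 1],
              ipmax = max(.data$IPmix), .groups = "drop")
  edges <- seq(0, 1, length.out = 21)
  idx <- pmin(pmax(findInterval(per_id$ip1, edges, rightmost.closed = TRUE),
                   1L), 20L)
  out <- tibble(bin = 1:20, lo = edges[-21], hi = edges[-1],
                count = tabulate(idx, 20))
  structure(out, class = c("mix_separation", class(tibble())),
            separation_index = mean(per_id$ipmax >= 0.8),
            n = nrow(per_id))
}

#' @export
print.vpc_result <- function(x, ...) {
  g <- glance(x)
  cat("<vpc_result> strategy:", x$strategy, "\n")
  print(as_tibble(g))
  if (!is.null(x$allocation)) print(x$allocation)
  invisible(x)
}
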