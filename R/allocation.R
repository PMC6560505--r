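#' Most-likely-subpopulation (MIXEST) assignment
#'
#' Assigns every individual to the subpopulation with the largest posterior
#' membership probability; ties break to the lowest component index.
#' Deterministic, and therefore prone to shrinkage toward the dominant
#' subpopulation when individual data are uninformative.
#'
#' @param records phm-like tibble from [evaluate_mixture()] (long: one row
#'   per ID and SUBPOP).
#' @return tibble with columns `ID`, `COMP`.
#' @export
mixest_assign <- function(records) {
  records |>
    group_by(.data$ID) |>
    arrange(.data$SUBPOP, .by_group = TRUE) |>
    summarise(COMP = .data$SUBPOP[which.max(.data$IPmix)], .groups = "drop")
}

#' Randomized IP_mix-based assignment
#'
#' Draws each individual's subpopulation from its posterior membership
#' probabilities, so that the expected per-component share equals the mean
#' posterior probability (an unbiased allocation).
#'
#' @inheritParams mixest_assign
#' @param seed integer seed for the allocation stream.
#' @return tibble with columns `ID`, `COMP`.
#' @export
randomized_assign <- function(records, seed) {
  set.seed(seed)
  records |>
    group_by(.data$ID) |>
    arrange(.data$SUBPOP, .by_group = TRUE) |>
    summarise(COMP = sample(.data$SUBPOP, 1, prob = .data$IPmix),
              .groups = "drop")
}

assign_by_strategy <- function(records, strategy, seed) {
  switch(strategy,
         mixest = mixest_assign(records),
         randomized = randomized_assign(records, seed),
         rlang::abort(paste0("unknown allocation strategy: ", strategy),
                      class = "mixvpc_usage_error"))
}

pct_by_component <- function(assign, K) {
  n <- nrow(assign)
  vapply(seq_len(K), function(k) 100 * sum(assign$COMP == k) / n, numeric(1))
}

#' Allocation summary statistics (PMIX / ORIGID / SIMID)
#'
#' Allocates the observed individuals once and every simulated replicate
#' independently, and summarises the per-component shares: `ORIGID` is the
#' percentage of original-data individuals per subpopulation, `SIMID` the
#' mean percentage across replicates, and `PMIX` the estimated population
#' mixing percentage. The allocation bias (in percentage points) is
#' `ORIGID - PMIX` for the dominant component (the one with the largest
#' estimated mixing proportion); a clearly positive value flags
#' shrinkage-type over-allocation under the MIXEST strategy.
#'
#' @param obs_records phm-like tibble for the original data.
#' @param sim_records_list list of phm-like tibbles, one per simulated
#'   replicate.
#' @param pmix_hat estimated mixing proportions.
#' @param strategy `"mixest"` or `"randomized"`.
#' @param seed allocation seed (randomized strategy; the observed data and
#'   each replicate get independent substreams).
#' @param true_pmix optional true proportions; when given, the bias against
#'   the truth is attached as well.
#' @return tibble (component, pmix_pct, origid_pct, simid_pct) of class
#'   `allocation_summary`, with attributes `bias_pp` (vs estimated PMIX),
#'   `bias_pp_true` (vs truth, if requested), `strategy` and `seed`.
#' @export
allocation_summary <- function(obs_records, sim_records_list, pmix_hat,
                               strategy = c("mixest", "randomized"),
                               seed = 1L, true_pmix = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(obs_records) || nrow(obs_records) == 0) {
    rlang::abort("obs_records must be non-empty", class = "mixvpc_usage_error")
  }
  if (length(sim_records_list) == 0) {
    rlang::abort("at least one simulated replicate is required",
                 class = "mixvpc_usage_error")
  }
  K <- length(pmix_hat)
  obs_assign <- assign_by_strategy(obs_records, strategy, derive_seed(seed, 0))
  origid <- pct_by_component(obs_assign, K)
  simid_mat <- vapply(seq_along(sim_records_list), function(r) {
    a <- assign_by_strategy(sim_records_list[[r]], strategy,
                            derive_seed(seed, r))
    pct_by_component(a, K)
  }, numeric(K))
  simid <- rowMeans(matrix(simid_mat, nrow = K))
  dom <- which.max(pmix_hat)
  out <- tibble(component = seq_len(K),
                pmix_pct = 100 * pmix_hat,
                origid_pct = origid,
                simid_pct = simid)
  structure(out,
            class = c("allocation_summary", class(tibble())),
            bias_pp = origid[dom] - 100 * pmix_hat[dom],
            bias_pp_true = if (!is.null(true_pmix))
              origid[which.max(true_pmix)] - 100 * max(true_pmix),
            dominant = dom, strategy = strategy, seed = seed)
}

#' @export
print.allocation_summary <- function(x, ...) {
  cat("<allocation_summary> strategy:", attr(x, "strategy"),
      " bias:", sprintf("%+.2f pp", attr(x, "bias_pp")),
      "(dominant component", attr(x, "dominant"), ")\n")
  NextMethod()
}
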