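#' One-compartment oral-absorption concentration profile
#'
#' Closed-form concentration for a one-compartment model with first-order
#' absorption and elimination, by superposition over doses:
#' \deqn{C(t) = \sum_d \frac{D_d k_a}{V (k_a - k_e)}
#'   \left(e^{-k_e (t - t_d)} - e^{-k_a (t - t_d)}\right),\quad k_e = CL/V,}
#' with zero contribution from doses not yet given. The degenerate case
#' \eqn{k_a \approx k_e} (relative difference below 1e-8) uses the limit
#' form \eqn{D k_a (t-t_d) e^{-k_a (t-t_d)} / V} to avoid catastrophic
#' cancellation.
#'
#' @param params named list/vector with `ka` (1/h), `CL` (L/h), `V` (L).
#' @param dose_times,dose_amts dose times (h) and amounts (mg).
#' @param t times (h) at which to evaluate; vectorized.
#' @return concentrations (mg/L), same length as `t`.
#' @export
conc_1cmt_oral <- function(params, dose_times, dose_amts, t) {
  ka <- params[["ka"]]; CL <- params[["CL"]]; V <- params[["V"]]
  if (any(!is.finite(c(ka, CL, V))) || any(c(ka, CL, V) <= 0)) {
    rlang::abort("ka, CL and V must be positive and finite",
                 class = "mixvpc_domain_error")
  }
  ke <- CL / V
  conc <- numeric(length(t))
  for (d in seq_along(dose_times)) {
    dt <- t - dose_times[d]
    on <- dt > 0
    if (!any(on)) next
    dd <- dt[on]
    if (abs(ka - ke) < 1e-8 * ka) {
      conc[on] <- conc[on] + dose_amts[d] * ka * dd * exp(-ka * dd) / V
    } else {
      conc[on] <- conc[on] + dose_amts[d] * ka / (V * (ka - ke)) *
        (exp(-ke * dd) - exp(-ka * dd))
    }
  }
  pmax(conc, 0)
}

#' Two-compartment model with parallel linear and Michaelis-Menten elimination
#'
#' Numerically integrates
#' \deqn{dA_1/dt = -(CL_{lin}/V_1) A_1 - V_{max} C/(K_m + C)
#'   - (Q/V_1) A_1 + (Q/V_2) A_2}
#' \deqn{dA_2/dt = (Q/V_1) A_1 - (Q/V_2) A_2, \qquad C = A_1/V_1,}
#' with intravenous bolus doses into the central compartment. The
#' disposition parameters `CLlin`, `Vmax`, `V1` and `V2` are scaled
#' linearly with body weight relative to 70 kg before integration.
#' Integration is piecewise between dose events (lsoda, rtol 1e-8,
#' atol 1e-10), using the package's compiled right-hand side.
#'
#' @param params named list/vector with `CLlin` (L/h), `Vmax` (mg/h),
#'   `Km` (mg/L), `V1` (L), `V2` (L), `Q` (L/h) and optionally `WT` (kg,
#'   default 70 = no scaling).
#' @param dose_times,dose_amts bolus times (h) and amounts (mg).
#' @param t output times (h); vectorized, need not be sorted.
#' @return concentrations A1/V1 (mg/L) at `t`.
#' @export
conc_2cmt_parallel <- function(params, dose_times, dose_amts, t) {
  p <- params
  need <- c("CLlin", "Vmax", "Km", "V1", "V2", "Q")
  vals <- vapply(need, function(nm) p[[nm]], numeric(1))
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals[c("Km", "V1", "V2")] <= 0)) {
    rlang::abort("structural parameters must be finite and positive",
                 class = "mixvpc_domain_error")
  }
  wt <- p[["WT"]] %||% 70
  sc <- wt / 70
  parms <- c(CLlin = vals[["CLlin"]] * sc, Vmax = vals[["Vmax"]] * sc,
             Km = vals[["Km"]], V1 = vals[["V1"]] * sc,
             V2 = vals[["V2"]] * sc, Q = vals[["Q"]])

  ord <- order(t)
  ts <- t[ord]
  conc <- numeric(length(ts))
  if (length(dose_times) == 0 || all(ts <= min(dose_times))) {
    conc_out <- numeric(length(t))
    return(conc_out)
  }
  d_ord <- order(dose_times)
  dose_times <- dose_times[d_ord]; dose_amts <- dose_amts[d_ord]

  grid <- sort(unique(c(dose_times, ts[ts >= dose_times[1]])))
  ev <- data.frame(var = "A1", time = dose_times, value = dose_amts,
                   method = "add")
  use_dll <- is.loaded("derivs_par2", PACKAGE = "mixvpc")
  y0 <- c(A1 = 0, A2 = 0)
  sol <- if (use_dll) {
    deSolve::lsoda(y = y0, times = grid, func = "derivs_par2",
                   parms = unname(parms), dllname = "mixvpc",
                   initfunc = "init_par2",
                   events = list(data = ev),
                   rtol = 1e-8, atol = 1e-10)
  } else {
    rhs <- function(t, y, p) {
      C <- y[1] / p[["V1"]]
      mm <- p[["Vmax"]] * C / (p[["Km"]] + C)
      list(c(-(p[["CLlin"]] / p[["V1"]]) * y[1] - mm -
               (p[["Q"]] / p[["V1"]]) * y[1] + (p[["Q"]] / p[["V2"]]) * y[2],
             (p[["Q"]] / p[["V1"]]) * y[1] - (p[["Q"]] / p[["V2"]]) * y[2]))
    }
    deSolve::lsoda(y = y0, times = grid, func = rhs, parms = parms,
                   events = list(data = ev), rtol = 1e-8, atol = 1e-10)
  }
  if (attr(sol, "istate")[1] < 0) {
    rlang::abort("ODE solver failed to meet tolerance",
                 class = "mixvpc_numerical_error")
  }
  a1 <- sol[, "A1"]
  idx <- match(ts, grid)
  conc[!is.na(idx)] <- a1[idx[!is.na(idx)]] / parms[["V1"]]
  # times strictly before the first dose are zero by causality
  conc[ts < dose_times[1]] <- 0
  out <- numeric(length(t))
  out[ord] <- pmax(conc, 0)
  out
}

#' Predict concentrations for a named structural model
#'
#' Dispatches to [conc_1cmt_oral()] or [conc_2cmt_parallel()] based on the
#' model id used throughout the package.
#' @param model_id `"onecmt_oral"` or `"twocmt_parallel"`.
#' @param params named list of individual parameter values (post random
#'   effects), including `WT` where applicable.
#' @param dose_times,dose_amts,t as in the underlying functions.
#' @return concentrations (mg/L).
#' @export
predict_conc <- function(model_id, params, dose_times, dose_amts, t) {
  switch(model_id,
         onecmt_oral = conc_1cmt_oral(params, dose_times, dose_amts, t),
         twocmt_parallel = conc_2cmt_parallel(params, dose_times, dose_amts, t),
         rlang::abort(paste0("unknown structural model: ", model_id),
                      class = "mixvpc_usage_error"))
}

#' Residual error model
#'
#' Maps model-predicted concentrations and standard-normal draws to
#' observed values: proportional \eqn{y = f (1 + \sqrt{\sigma^2_p}\,
#' \epsilon)}, additive \eqn{y = f + \sqrt{\sigma^2_a}\, \epsilon}, or both
#' (combined, with independent draws per term).
#'
#' @param conc predicted concentrations (mg/L), non-negative.
#' @param sigma a [residual_spec].
#' @param eps standard-normal draws: a vector the length of `conc`
#'   (proportional or additive models), or a list with elements `prop` and
#'   `add` for the combined model.
#' @return observed values (mg/L); may be negative under additive error.
#' @export
apply_residual <- function(conc, sigma, eps) {
  stopifnot(inherits(sigma, "residual_spec"))
  switch(sigma$model,
         proportional = conc * (1 + sqrt(sigma$proportional) * eps),
         additive = conc + sqrt(sigma$additive) * eps,
         combined = conc * (1 + sqrt(sigma$proportional) * eps$prop) +
           sqrt(sigma$additive) * eps$add)
}

#' Residual variance of an observation given its prediction
#'
#' @param conc predicted concentration(s).
#' @param sigma a [residual_spec].
#' @return per-observation residual variances.
#' @keywords internal
residual_var <- function(conc, sigma) {
  switch(sigma$model,
         proportional = sigma$proportional * conc^2,
         additive = rep(sigma$additive, length(conc)),
         combined = sigma$proportional * conc^2 + sigma$additive)
}
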