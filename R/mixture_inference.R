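#' Model specification for estimation
#'
#' Describes which model is fitted: the structural model, whether the
#' bimodal parameter is handled by a mixture, by an observed binary
#' covariate, or not at all, and which parameters carry random effects
#' (the latter is read off the `omega` entries of the parameter object).
#'
#' @param model_id `"onecmt_oral"` or `"twocmt_parallel"`.
#' @param variant `"mixture"`, `"nonmixture"` or `"covariate"`.
#' @param mixture_param name of the parameter that differs by
#'   subpopulation (default `"CL"`; `"CLlin"` for the parallel model).
#' @param covariate column name of the binary covariate used by the
#'   covariate variant (default `"COV"`); the covariate multiplies the
#'   mixture parameter by an estimated fold-change `COVFC`.
#' @param n_components number of mixture components (2 throughout; the
#'   machinery is K-ary but only K = 2 is exercised).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model_id = c("onecmt_oral", "twocmt_parallel"),
                       variant = c("mixture", "nonmixture", "covariate"),
                       mixture_param = if (match.arg(model_id) == "onecmt_oral") "CL" else "CLlin",
                       covariate = "COV",
                       n_components = 2L) {
  model_id <- match.arg(model_id)
  variant <- match.arg(variant)
  if (variant == "mixture" && n_components < 2) {
    rlang::abort("a mixture model needs at least 2 components",
                 class = "mixvpc_usage_error")
  }
  structure(list(model_id = model_id, variant = variant,
                 mixture_param = mixture_param, covariate = covariate,
                 n_components = if (variant == "mixture") as.integer(n_components) else 1L),
            class = "model_spec")
}

#' Likelihood approximation and optimizer settings
#'
#' @param method `"laplace"` (default; scales to several random effects)
#'   or `"agq"` (adaptive Gauss-Hermite, 1 random effect only, used as a
#'   verification mode).
#' @param nodes quadrature nodes for `"agq"`.
#' @param inner_reltol relative tolerance of the per-subject random-effect
#'   mode search.
#' @param outer_reltol relative objective-function tolerance of the
#'   population optimizer.
#' @param max_evals maximum objective evaluations per start.
#' @param n_starts number of optimizer starts (component typical values are
#'   staggered around the pooled one-component estimate).
#' @return object of class `lik_settings`.
#' @export
likelihood_settings <- function(method = c("laplace", "agq"), nodes = 21L,
                                inner_reltol = 1e-8, outer_reltol = 1e-7,
                                max_evals = 2000L, n_starts = 3L) {
  method <- match.arg(method)
  stopifnot(nodes >= 1, inner_reltol > 0, outer_reltol > 0)
  structure(list(method = method, nodes = as.integer(nodes),
                 inner_reltol = inner_reltol, outer_reltol = outer_reltol,
                 max_evals = as.integer(max_evals),
                 n_starts = as.integer(n_starts)),
            class = "lik_settings")
}

# central finite-difference Hessian (small p; used at the eta mode)
fd_hessian <- function(fun, x, step = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  h <- step * pmax(abs(x), 1)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    for (j in seq_len(i)) {
      ej <- numeric(p); ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (fun(x + ei) - 2 * fun(x) + fun(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fun(x + ei + ej) - fun(x + ei - ej) -
             fun(x - ei + ej) + fun(x - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

# Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix),
# for weight function exp(-x^2)
gauss_hermite <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# build the per-subject -2 log joint density h(eta) (2*pi constants
# excluded): sum_j [log var_j + (y_j - f_j)^2 / var_j] + eta' Omega^-1 eta
make_h <- function(subject, th, omega, sigma, model_id) {
  eta_names <- names(omega)
  inv_omega <- 1 / omega
  y <- subject$obs_values
  t_obs <- subject$obs_times
  dt <- subject$dose_times; da <- subject$dose_amts
  function(eta) {
    ind <- th
    for (jj in seq_along(eta_names)) {
      ind[[eta_names[jj]]] <- ind[[eta_names[jj]]] * exp(eta[jj])
    }
    f <- predict_conc(model_id, ind, dt, da, t_obs)
    v <- pmax(residual_var(f, sigma), 1e-12)
    sum(log(v) + (y - f)^2 / v) + sum(eta^2 * inv_omega)
  }
}

# Laplace (or AGQ) -2 log marginal individual likelihood for one subject
# under one component's merged typical values. Returns iofv and eta mode.
subject_iofv <- function(subject, th, omega, sigma, model_id, settings,
                         eta_start = NULL) {
  p <- length(omega)
  # compiled fast path: closed-form 1-compartment model under Laplace
  if (model_id == "onecmt_oral" && settings$method == "laplace" && p > 0 &&
      all(names(omega) %in% c("ka", "CL", "V"))) {
    out <- .Call("C_laplace_onecmt",
                 as.numeric(c(th$ka, th$CL, th$V)),
                 as.numeric(subject$obs_times),
                 as.numeric(subject$obs_values),
                 as.numeric(subject$dose_times),
                 as.numeric(subject$dose_amts),
                 as.integer(match(names(omega), c("ka", "CL", "V")) - 1L),
                 as.numeric(omega),
                 as.numeric(c(sigma$proportional, sigma$additive)),
                 as.numeric(eta_start %||% numeric(p)),
                 PACKAGE = "mixvpc")
    return(list(iofv = out[1], eta_mode = out[-1]))
  }
  # compiled fast path: two-compartment parallel-elimination model (RK45)
  if (model_id == "twocmt_parallel" && settings$method == "laplace" && p > 0 &&
      all(names(omega) %in% c("CLlin", "Vmax", "Km", "V1", "V2", "Q"))) {
    sc <- (th$WT %||% 70) / 70
    out <- .Call("C_laplace_twocmt",
                 as.numeric(c(th$CLlin * sc, th$Vmax * sc, th$Km,
                              th$V1 * sc, th$V2 * sc, th$Q)),
                 as.numeric(subject$obs_times),
                 as.numeric(subject$obs_values),
                 as.numeric(subject$dose_times),
                 as.numeric(subject$dose_amts),
                 as.integer(match(names(omega),
                                  c("CLlin", "Vmax", "Km", "V1", "V2", "Q")) - 1L),
                 as.numeric(omega),
                 as.numeric(c(sigma$proportional, sigma$additive)),
                 as.numeric(eta_start %||% numeric(p)),
                 PACKAGE = "mixvpc")
    return(list(iofv = out[1], eta_mode = out[-1]))
  }
  h <- make_h(subject, th, omega, sigma, model_id)
  if (p == 0) {
    return(list(iofv = h(numeric(0)), eta_mode = numeric(0)))
  }
  start <- eta_start %||% numeric(p)
  opt <- stats::nlminb(start, h, lower = rep(-12, p), upper = rep(12, p),
                       control = list(rel.tol = settings$inner_reltol,
                                      iter.max = 200L))
  # retry from zero if a warm start wandered off
  if (!is.finite(opt$objective) && any(start != 0)) {
    opt <- stats::nlminb(numeric(p), h, lower = rep(-12, p),
                         upper = rep(12, p),
                         control = list(rel.tol = settings$inner_reltol,
                                        iter.max = 200L))
  }
  if (!is.finite(opt$objective)) {
    rlang::abort(paste0("inner optimization failed for subject ", subject$id),
                 class = "mixvpc_numerical_error")
  }
  eta_hat <- opt$par
  if (settings$method == "agq" && p == 1) {
    H <- fd_hessian(h, eta_hat)
    sd_hat <- sqrt(2 / max(H[1, 1], 1e-10))
    gh <- gauss_hermite(settings$nodes)
    z <- eta_hat + sd_hat * sqrt(2) * gh$x
    hz <- vapply(z, h, numeric(1))
    # integral of exp(-h/2): adaptive GH with the exp(-x^2) weight removed
    lse <- log(sum(gh$w * exp(-(hz - opt$objective) / 2 + gh$x^2))) -
      opt$objective / 2 + log(sqrt(2) * sd_hat)
    iofv <- -2 * lse + log(2 * pi) + log(omega[[1]])
  } else {
    H <- fd_hessian(h, eta_hat)
    ld <- determinant(H / 2, logarithm = TRUE)
    if (ld$sign <= 0) {
      # fall back to the prior curvature if FD noise broke positivity
      ld <- determinant(diag(1 / omega, p) , logarithm = TRUE)
    }
    iofv <- opt$objective + sum(log(omega)) + as.numeric(ld$modulus)
  }
  list(iofv = unname(iofv), eta_mode = eta_hat)
}

# merged typical values for subject/component under the model variant
merged_theta <- function(model, params, k, covariates) {
  th <- component_theta(params, k)
  if (model$variant == "covariate" && "COVFC" %in% names(th)) {
    cov <- covariates[[model$covariate]]
    if (is.null(cov)) {
      rlang::abort(paste0("covariate model requires column '",
                          model$covariate, "' in the data"),
                   class = "mixvpc_usage_error")
    }
    th[[model$mixture_param]] <- th[[model$mixture_param]] * th[["COVFC"]]^cov
    th[["COVFC"]] <- NULL
  }
  if (!is.null(covariates[["WT"]])) th[["WT"]] <- covariates[["WT"]]
  th
}

#' Per-component individual objective function value
#'
#' The individual objective function value (IOFV) for one subject under
#' component `k`: \eqn{-2 \log \int p(y_i \mid \eta) p(\eta)\, d\eta},
#' approximated by the Laplace method at the conditional mode of the
#' random effects (or by adaptive Gauss-Hermite quadrature for one random
#' effect). The additive \eqn{N_{obs} \log 2\pi} constant is excluded, so
#' IOFV differences, not absolute values, are meaningful.
#'
#' @param subject one element of [split_subjects()], or a single-subject
#'   [pk_dataset].
#' @param params [mixture_parameters].
#' @param k component index.
#' @param model a [model_spec].
#' @param settings [likelihood_settings()].
#' @param eta_start optional warm start for the mode search.
#' @return list with `iofv` and `eta_mode`.
#' @export
component_iofv <- function(subject, params, k, model,
                           settings = likelihood_settings(),
                           eta_start = NULL) {
  if (is.data.frame(subject)) subject <- split_subjects(subject)[[1]]
  if (length(subject$obs_values) < 1) {
    rlang::abort("subject has no non-missing observations",
                 class = "mixvpc_usage_error")
  }
  th <- merged_theta(model, params, k, subject$covariates)
  subject_iofv(subject, th, params$omega, params$sigma, model$model_id,
               settings, eta_start)
}

#' Posterior subpopulation membership probabilities
#'
#' Combines per-component individual objective function values with the
#' population mixing proportions:
#' \deqn{IP_k = \frac{p_k\, e^{-IOFV_k/2}}{\sum_j p_j\, e^{-IOFV_j/2}},}
#' evaluated by log-sum-exp so that any additive constant shared by all
#' components cancels exactly. Smaller IOFV (better fit) gives larger
#' posterior probability.
#'
#' @param iofv numeric vector of per-component IOFV values.
#' @param pmix mixing proportions (valid simplex; exact zeros allowed).
#' @return posterior probability vector summing to 1.
#' @export
mixture_posterior <- function(iofv, pmix) {
  if (all(pmix == 0)) {
    rlang::abort("pmix must have at least one positive entry",
                 class = "mixvpc_domain_error")
  }
  if (any(!is.finite(iofv))) {
    rlang::abort("iofv must be finite", class = "mixvpc_domain_error")
  }
  lw <- log(pmix) - iofv / 2
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}

#' Mixture-marginal individual objective function value
#'
#' \eqn{-2 \log \sum_k p_k e^{-IOFV_k/2}}, computed by log-sum-exp.
#' @inheritParams mixture_posterior
#' @return scalar marginal -2 log likelihood contribution.
#' @export
individual_ofv <- function(iofv, pmix) {
  if (all(pmix == 0)) {
    rlang::abort("pmix must have at least one positive entry",
                 class = "mixvpc_domain_error")
  }
  lw <- log(pmix) - iofv / 2
  m <- max(lw)
  -2 * (m + log(sum(exp(lw - m))))
}

# ---- transformed-parameter packing --------------------------------------

pack_params <- function(params, model) {
  par <- c()
  mp <- model$mixture_param
  if (model$variant == "mixture") {
    v <- params$theta_component[[mp]]
    for (k in seq_along(v)) par[paste0("ltc.", mp, ".", k)] <- log(v[k])
    par["qpmix"] <- stats::qlogis(params$pmix[1])
  }
  for (nm in names(params$theta_shared)) {
    par[paste0("lth.", nm)] <- log(params$theta_shared[[nm]])
  }
  for (nm in names(params$omega)) {
    par[paste0("lom.", nm)] <- log(params$omega[[nm]])
  }
  if (params$sigma$model %in% c("proportional", "combined")) {
    par["lsg.prop"] <- log(params$sigma$proportional)
  }
  if (params$sigma$model %in% c("additive", "combined")) {
    par["lsg.add"] <- log(params$sigma$additive)
  }
  par
}

unpack_params <- function(par, skeleton, model) {
  mp <- model$mixture_param
  tc <- skeleton$theta_component
  th <- skeleton$theta_shared
  om <- skeleton$omega
  pm <- skeleton$pmix
  if (model$variant == "mixture") {
    K <- length(skeleton$pmix)
    for (k in seq_len(K)) {
      nmk <- paste0("ltc.", mp, ".", k)
      if (nmk %in% names(par)) tc[[mp]][k] <- exp(par[[nmk]])
    }
    if ("qpmix" %in% names(par)) {
      p1 <- stats::plogis(par[["qpmix"]])
      pm <- c(p1, (1 - p1) * skeleton$pmix[-1] / sum(skeleton$pmix[-1]))
    }
  }
  for (nm in names(th)) {
    nmp <- paste0("lth.", nm)
    if (nmp %in% names(par)) th[[nm]] <- exp(par[[nmp]])
  }
  for (nm in names(om)) {
    nmo <- paste0("lom.", nm)
    if (nmo %in% names(par)) om[[nm]] <- exp(par[[nmo]])
  }
  prop <- if ("lsg.prop" %in% names(par)) exp(par[["lsg.prop"]])
          else if (skeleton$sigma$model %in% c("proportional", "combined")) skeleton$sigma$proportional
          else NULL
  add <- if ("lsg.add" %in% names(par)) exp(par[["lsg.add"]])
         else if (skeleton$sigma$model %in% c("additive", "combined")) skeleton$sigma$additive
         else NULL
  mixture_parameters(theta_component = tc, theta_shared = th, pmix = pm,
                     omega = om, sigma = residual_spec(proportional = prop,
                                                       additive = add))
}

# total OFV for a parameter object, with per-subject/component warm starts
total_ofv <- function(subjects, params, model, settings, warm = NULL) {
  n <- length(subjects)
  K <- length(params$pmix)
  p <- length(params$omega)
  iofv <- matrix(NA_real_, n, K)
  modes <- if (p > 0) array(NA_real_, c(n, K, p)) else NULL
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    for (k in seq_len(K)) {
      th <- merged_theta(model, params, k, s$covariates)
      es <- if (!is.null(warm) && !is.null(warm$modes)) warm$modes[i, k, ] else NULL
      if (!is.null(es) && any(!is.finite(es))) es <- NULL
      r <- subject_iofv(s, th, params$omega, params$sigma, model$model_id,
                        settings, eta_start = es)
      iofv[i, k] <- r$iofv
      if (p > 0) modes[i, k, ] <- r$eta_mode
    }
  }
  ofv <- sum(vapply(seq_len(n), function(i) individual_ofv(iofv[i, ], params$pmix),
                    numeric(1)))
  list(ofv = ofv, iofv = iofv, modes = modes)
}

# crude pooled initial estimates for the 1-compartment oral model from the
# median concentration profile (CL from dose/AUC, ke from the terminal
# slope, ka fixed at 1/h)
heuristic_init_1cmt <- function(subjects, sigma) {
  tt <- subjects[[1]]$obs_times
  med <- apply(do.call(rbind, lapply(subjects, function(s) {
    if (length(s$obs_values) == length(tt)) s$obs_values else
      stats::approx(s$obs_times, s$obs_values, tt, rule = 2)$y
  })), 2, stats::median)
  med <- pmax(med, 1e-6)
  dose <- sum(subjects[[1]]$dose_amts)
  auc <- sum(diff(tt) * (med[-1] + med[-length(med)]) / 2)
  ntail <- min(3, length(tt) - 1)
  sl <- stats::coef(stats::lm(log(med) ~ tt,
                              subset = seq_along(tt) > length(tt) - ntail))[2]
  ke <- max(-as.numeric(sl), 1e-3)
  auc_inf <- auc + med[length(med)] / ke
  CL <- dose / auc_inf
  V <- CL / ke
  mixture_parameters(theta_shared = c(ka = 1, CL = unname(CL), V = unname(V)),
                     pmix = 1,
                     omega = c(ka = 0.1, CL = 0.1, V = 0.1),
                     sigma = sigma)
}

#' Fit a population model by Laplace-approximated maximum likelihood
#'
#' Maximizes the sum over subjects of the mixture-marginal individual log
#' likelihood over transformed parameters (log for typical values and
#' variances, logit for the mixing proportion) with `nlminb`, using
#' multiple staggered starts. For the `"mixture"` variant the bimodal
#' parameter has one typical value per component plus an estimated mixing
#' proportion; `"nonmixture"` collapses to a single component;
#' `"covariate"` multiplies the parameter by an estimated fold-change
#' `COVFC` raised to the subject's binary covariate.
#'
#' @param data a [pk_dataset].
#' @param model a [model_spec].
#' @param settings [likelihood_settings()].
#' @param init optional [mixture_parameters] giving starting values (and
#'   the parameter structure). When omitted, a heuristic pooled
#'   one-compartment estimate seeds the starts (available for
#'   `"onecmt_oral"` only).
#' @param fixed character vector of parameter names to hold fixed at their
#'   `init` values (e.g. `c("Km", "Q", "V2")`, `"omega.Vmax"`, or
#'   `"sigma"`).
#' @param seed integer seed (start jitter reproducibility).
#' @return object of class `mixfit`: estimated parameters, total OFV
#'   (-2 log likelihood, 2-pi constant excluded), a phm-like `records`
#'   tibble, convergence flag, evaluation count and start diagnostics.
#' @export
fit_mixture <- function(data, model, settings = likelihood_settings(),
                        init = NULL, fixed = character(), seed = 1L) {
  subjects <- split_subjects(data)
  if (length(subjects) == 0) {
    rlang::abort("dataset has no subjects", class = "mixvpc_usage_error")
  }
  if (model$variant == "covariate") {
    has_cov <- all(vapply(subjects, function(s)
      !is.null(s$covariates[[model$covariate]]), logical(1)))
    if (!has_cov) {
      rlang::abort(paste0("covariate model requires column '",
                          model$covariate, "'"),
                   class = "mixvpc_usage_error")
    }
  }

  mp <- model$mixture_param
  if (is.null(init)) {
    if (model$model_id != "onecmt_oral") {
      rlang::abort("init parameters are required for the ODE model",
                   class = "mixvpc_usage_error")
    }
    sig0 <- residual_spec(proportional = 0.05)
    init <- heuristic_init_1cmt(subjects, sig0)
  }
  base <- init
  # reshape init to match the variant
  if (model$variant == "mixture" && !(mp %in% names(base$theta_component))) {
    pooled <- base$theta_shared[[mp]] %||% base$theta_component[[mp]][1]
    th <- base$theta_shared[setdiff(names(base$theta_shared), mp)]
    base <- mixture_parameters(
      theta_component = stats::setNames(list(c(pooled, pooled)), mp),
      theta_shared = th, pmix = c(0.5, 0.5),
      omega = base$omega, sigma = base$sigma)
  }
  if (model$variant != "mixture" && mp %in% names(base$theta_component)) {
    pooled <- exp(mean(log(base$theta_component[[mp]])))
    th <- c(base$theta_shared, stats::setNames(pooled, mp))
    base <- mixture_parameters(theta_shared = th, pmix = 1,
                               omega = base$omega, sigma = base$sigma)
  }
  if (model$variant == "covariate" && !("COVFC" %in% names(base$theta_shared))) {
    base$theta_shared <- c(base$theta_shared, COVFC = 2)
  }

  # staggered multi-start multipliers for the component typical values
  mults <- list(c(0.5, 2), c(1 / 3, 3), c(2 / 3, 1.5), c(0.4, 2.5),
                c(0.8, 1.25))
  set.seed(seed)
  informative_init <- model$variant == "mixture" &&
    diff(range(base$theta_component[[mp]])) > 0
  starts <- lapply(seq_len(settings$n_starts), function(sidx) {
    b <- base
    if (model$variant == "mixture" && !(sidx == 1 && informative_init)) {
      m <- mults[[(sidx - 1) %% length(mults) + 1]]
      pooled <- exp(mean(log(b$theta_component[[mp]])))
      b$theta_component[[mp]] <- pooled * m
      b$pmix <- rep(1 / length(b$pmix), length(b$pmix))
    } else if (model$variant != "mixture" && sidx > 1) {
      jit <- c(1, 1.5, 2 / 3, 1.25, 0.8)[(sidx - 1) %% 5 + 1]
      b$theta_shared[[mp]] <- b$theta_shared[[mp]] * jit
    }
    b
  })

  fixed_keys <- function(par_names) {
    drop <- c()
    for (f in fixed) {
      targets <- if (grepl("^omega\\.", f)) {
        paste0("lom.", sub("^omega\\.", "", f))
      } else {
        c(paste0("lth.", f), paste0("ltc.", f, ".1"), paste0("ltc.", f, ".2"))
      }
      drop <- c(drop, par_names[par_names %in% targets],
                if (f == "sigma") par_names[grepl("^lsg\\.", par_names)],
                if (f == "pmix") par_names[par_names == "qpmix"])
    }
    unique(drop)
  }

  best <- NULL
  start_log <- list()
  for (sidx in seq_along(starts)) {
    b <- starts[[sidx]]
    par0_full <- pack_params(b, model)
    drop <- fixed_keys(names(par0_full))
    est_names <- setdiff(names(par0_full), drop)
    par0 <- par0_full[est_names]
    warm <- new.env(parent = emptyenv())
    warm$modes <- NULL
    n_eval <- 0L
    obj <- function(par) {
      n_eval <<- n_eval + 1L
      names(par) <- est_names
      pp <- tryCatch(unpack_params(c(par, par0_full[drop]), b, model),
                     error = function(e) NULL)
      if (is.null(pp)) return(1e10)
      r <- tryCatch(total_ofv(subjects, pp, model, settings, warm),
                    error = function(e) NULL)
      if (is.null(r) || !is.finite(r$ofv)) return(1e10)
      warm$modes <- r$modes
      r$ofv
    }
    # central-difference gradient (relative step 1e-5); the objective is
    # smooth in the transformed parameters once the inner modes are tight
    grad <- function(par) {
      g <- numeric(length(par))
      for (j in seq_along(par)) {
        hj <- 1e-5 * max(abs(par[j]), 1)
        up <- par; up[j] <- par[j] + hj
        dn <- par; dn[j] <- par[j] - hj
        g[j] <- (obj(up) - obj(dn)) / (2 * hj)
      }
      g
    }
    opt <- tryCatch(
      stats::nlminb(par0, obj, gradient = grad,
                    control = list(rel.tol = settings$outer_reltol,
                                   iter.max = 500L,
                                   eval.max = settings$max_evals)),
      error = function(e) NULL)
    start_log[[sidx]] <- if (is.null(opt)) {
      list(start = sidx, ofv = NA_real_, convergence = NA_integer_,
           n_eval = n_eval)
    } else {
      list(start = sidx, ofv = opt$objective, convergence = opt$convergence,
           n_eval = n_eval)
    }
    if (!is.null(opt) && is.finite(opt$objective) &&
        (is.null(best) || opt$objective < best$opt$objective)) {
      best <- list(opt = opt, start = sidx, base = b,
                   est_names = est_names, fixed_par = par0_full[drop],
                   n_eval = n_eval)
    }
  }
  if (is.null(best)) {
    rlang::abort(paste0("all ", length(starts), " starts failed"),
                 class = "mixvpc_estimation_error")
  }

  par_hat <- best$opt$par
  names(par_hat) <- best$est_names
  params_hat <- unpack_params(c(par_hat, best$fixed_par), best$base, model)

  # nlminb's "false convergence" is frequently spurious with
  # finite-difference gradients; accept the optimum when the gradient is
  # numerically flat
  converged <- best$opt$convergence == 0
  if (!converged) {
    warm2 <- new.env(parent = emptyenv()); warm2$modes <- NULL
    obj_at <- function(par) {
      names(par) <- best$est_names
      pp <- unpack_params(c(par, best$fixed_par), best$base, model)
      r <- total_ofv(subjects, pp, model, settings, warm2)
      warm2$modes <- r$modes
      r$ofv
    }
    obj_at(par_hat)
    gmax <- max(vapply(seq_along(par_hat), function(j) {
      hj <- 1e-5 * max(abs(par_hat[j]), 1)
      up <- par_hat; up[j] <- par_hat[j] + hj
      dn <- par_hat; dn[j] <- par_hat[j] - hj
      abs(obj_at(up) - obj_at(dn)) / (2 * hj)
    }, numeric(1)))
    converged <- gmax < 1
  }

  boundary <- FALSE
  if (model$variant == "mixture") {
    if (min(params_hat$pmix) < 1e-6) {
      boundary <- TRUE
      rlang::warn("mixture proportion hit its boundary; fit may be degenerate")
    }
    # canonical component order: component 1 carries the smaller typical value
    v <- params_hat$theta_component[[mp]]
    if (length(v) == 2 && v[1] > v[2]) {
      params_hat$theta_component[[mp]] <- rev(v)
      params_hat$pmix <- rev(params_hat$pmix)
    }
  }

  records <- evaluate_mixture(data, params_hat, model, settings)
  ofv <- sum(records |> distinct(.data$ID, .keep_all = TRUE) |> pull(.data$OFVi))

  structure(list(params = params_hat, ofv = ofv,
                 records = records, converged = converged,
                 n_function_evals = best$n_eval, best_start = best$start,
                 boundary = boundary, model = model, settings = settings,
                 start_log = bind_rows(lapply(start_log, as_tibble)),
                 n_subjects = length(subjects)),
            class = "mixfit")
}

#' Evaluate a model at fixed parameters (the MAXEVAL = 0 analog)
#'
#' Computes, without any parameter updating, every subject's per-component
#' individual objective function value, the relative individual likelihood
#' \eqn{IL_k = e^{-(IOFV_k - \min_j IOFV_j)/2}}, the posterior membership
#' probability IP_mix and the most likely subpopulation MIXEST.
#'
#' @param data a [pk_dataset].
#' @param params [mixture_parameters] at which to evaluate.
#' @param model a [model_spec].
#' @param settings [likelihood_settings()].
#' @return phm-like tibble with one row per (ID, SUBPOP): columns ID,
#'   SUBPOP, IOFV, IL, IPmix, MIXEST, plus OFVi (the subject's marginal
#'   contribution, identical across the subject's rows).
#' @export
evaluate_mixture <- function(data, params, model,
                             settings = likelihood_settings()) {
  subjects <- split_subjects(data)
  K <- length(params$pmix)
  n <- length(subjects)
  iofv <- matrix(NA_real_, n, K)
  ip <- matrix(NA_real_, n, K)
  mixest <- integer(n)
  ofvi <- numeric(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- subjects[[i]]
    ids[i] <- s$id
    for (k in seq_len(K)) {
      th <- merged_theta(model, params, k, s$covariates)
      iofv[i, k] <- subject_iofv(s, th, params$omega, params$sigma,
                                 model$model_id, settings)$iofv
    }
    ip[i, ] <- mixture_posterior(iofv[i, ], params$pmix)
    mixest[i] <- which.max(ip[i, ])
    ofvi[i] <- individual_ofv(iofv[i, ], params$pmix)
  }
  il <- exp(-(iofv - apply(iofv, 1, min)) / 2)
  tibble(ID = rep(ids, each = K),
         SUBPOP = rep(seq_len(K), n),
         IOFV = as.vector(t(iofv)),
         IL = as.vector(t(il)),
         IPmix = as.vector(t(ip)),
         MIXEST = rep(mixest, each = K),
         OFVi = rep(ofvi, each = K))
}

#' @export
print.mixfit <- function(x, ...) {
  cat("<mixfit> ", x$model$variant, " / ", x$model$model_id,
      "  (", x$n_subjects, " subjects)\n", sep = "")
  cat("  OFV:", format(x$ofv, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  if (x$model$variant == "mixture") {
    tab <- x$records |> count(.data$MIXEST)
    cat("  MIXEST counts:",
        paste(tab$MIXEST, tab$n / length(x$params$pmix), sep = ":",
              collapse = "  "), "\n")
  }
  invisible(x)
}
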