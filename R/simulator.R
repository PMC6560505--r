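#' Define a simulation scenario
#'
#' A scenario fully specifies one simulation experiment: the structural
#' model, the true mixture parameters, the number of subjects, the dosing
#' and sampling design, and covariate generators.
#'
#' @param model_id `"onecmt_oral"` or `"twocmt_parallel"`.
#' @param params true [mixture_parameters].
#' @param n_subjects number of virtual subjects (>= 1).
#' @param dose_times,dose_amts dosing design (h, mg).
#' @param sample_times strictly increasing observation times (h).
#' @param covariate_generators named list of functions `function(n)`
#'   returning n covariate values (e.g. body weight draws).
#' @param design_label free-text label.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(model_id, params, n_subjects,
                          dose_times, dose_amts, sample_times,
                          covariate_generators = list(),
                          design_label = model_id) {
  stopifnot(inherits(params, "mix_params"))
  if (n_subjects < 1) {
    rlang::abort("n_subjects must be >= 1", class = "mixvpc_usage_error")
  }
  if (any(diff(sample_times) <= 0)) {
    rlang::abort("sample_times must be strictly increasing",
                 class = "mixvpc_usage_error")
  }
  structure(list(model_id = model_id, params = params,
                 n_subjects = n_subjects,
                 dose_times = dose_times, dose_amts = dose_amts,
                 sample_times = sample_times,
                 covariate_generators = covariate_generators,
                 design_label = design_label),
            class = "scenario_spec")
}

#' Built-in simulation scenarios
#'
#' Three fully parameterized mixture-population scenarios:
#' \describe{
#'   \item{`linear-70-30`}{One-compartment oral model, 1000 subjects,
#'     100 mg dose at t = 0, samples at 0.5/1/2/4/8/12 h. Bimodal clearance
#'     20 vs 80 L/h (fourfold) with 70/30 mixture proportions; ka = 1/h,
#'     V = 100 L; lognormal interindividual variances 0.09 on ka, CL and V;
#'     proportional residual variance 0.04.}
#'   \item{`linear-85-15`}{As above but clearance 20 vs 60 L/h (threefold)
#'     and 85/15 proportions — a harder, less-separated mixture.}
#'   \item{`parallel-40-60`}{Two-compartment model with parallel linear and
#'     Michaelis-Menten elimination, 36 subjects, 50 mg IV bolus at 0, 168,
#'     336 and 504 h, 22 samples over 672 h. Linear clearance 0.03 vs
#'     0.12 L/h (fourfold) with 40/60 proportions; Vmax = 1.2 mg/h,
#'     Km = 10 mg/L, V1 = 3 L, V2 = 2 L, Q = 0.075 L/h; disposition
#'     parameters weight-scaled; lognormal variances 0.09 on CLlin, Vmax
#'     and V1; proportional residual variance 0.04; body weights lognormal
#'     with median 70 kg and 20% CV.}
#' }
#' Subjects also carry a binary covariate `COV` equal to their true
#' subpopulation minus one (the "genotype" a covariate model would use).
#'
#' @param name one of `"linear-70-30"`, `"linear-85-15"`,
#'   `"parallel-40-60"`.
#' @param n_subjects optional override of the scenario's subject count
#'   (e.g. for reduced-size estimation studies).
#' @return a [scenario_spec].
#' @export
scenario_preset <- function(name, n_subjects = NULL) {
  presets <- c("linear-70-30", "linear-85-15", "parallel-40-60")
  if (!name %in% presets) {
    rlang::abort(paste0("unknown scenario '", name, "'; valid presets: ",
                        paste(presets, collapse = ", ")),
                 class = "mixvpc_usage_error")
  }
  if (name %in% c("linear-70-30", "linear-85-15")) {
    cl <- if (name == "linear-70-30") c(20, 80) else c(20, 60)
    pm <- if (name == "linear-70-30") c(0.7, 0.3) else c(0.85, 0.15)
    params <- mixture_parameters(
      theta_component = list(CL = cl),
      theta_shared = c(ka = 1, V = 100),
      pmix = pm,
      omega = c(ka = 0.09, CL = 0.09, V = 0.09),
      sigma = residual_spec(proportional = 0.04))
    scenario_spec("onecmt_oral", params,
                  n_subjects = n_subjects %||% 1000,
                  dose_times = 0, dose_amts = 100,
                  sample_times = c(0.5, 1, 2, 4, 8, 12),
                  design_label = name)
  } else {
    params <- mixture_parameters(
      theta_component = list(CLlin = c(0.03, 0.12)),
      theta_shared = c(Vmax = 1.2, Km = 10, V1 = 3, V2 = 2, Q = 0.075),
      pmix = c(0.4, 0.6),
      omega = c(CLlin = 0.09, Vmax = 0.09, V1 = 0.09),
      sigma = residual_spec(proportional = 0.04))
    # rich sampling: early profile after the first and last dose, troughs
    # between (22 observations over 672 h; exact times are a design choice)
    st <- c(1, 2, 4, 8, 24, 48, 96, 144, 168, 240, 336, 408, 504,
            505, 506, 508, 512, 528, 552, 600, 648, 672)
    scenario_spec("twocmt_parallel", params,
                  n_subjects = n_subjects %||% 36,
                  dose_times = c(0, 168, 336, 504), dose_amts = rep(50, 4),
                  sample_times = st,
                  covariate_generators = list(
                    WT = function(n) stats::rlnorm(n, meanlog = log(70),
                                                   sdlog = sqrt(log(1 + 0.2^2)))),
                  design_label = name)
  }
}

# deterministic substream seeds below 2^31
derive_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647
}

# realize one individual's parameter set: component typicals, covariate
# effect (covariate variant), lognormal random effects, carried covariates
realize_params <- function(model, params, k, covariates, eta) {
  th <- component_theta(params, k)
  if (!is.null(model) && model$variant == "covariate" && "COVFC" %in% names(th)) {
    cov <- covariates[[model$covariate %||% "COV"]]
    th[[model$mixture_param]] <- th[[model$mixture_param]] * th[["COVFC"]]^cov
    th[["COVFC"]] <- NULL
  }
  for (nm in names(eta)) th[[nm]] <- th[[nm]] * exp(eta[[nm]])
  if (!is.null(covariates[["WT"]])) th[["WT"]] <- covariates[["WT"]]
  th
}

#' Simulate a mixture-population dataset
#'
#' For every subject: draw the true subpopulation from the mixture
#' proportions, draw independent lognormal random effects (individual value
#' = component typical value times \eqn{e^\eta}, \eqn{\eta \sim N(0,
#' \omega^2)}), predict concentrations at the sampling times through the
#' structural model, and apply residual error. Fully reproducible given the
#' seed.
#'
#' @param spec a [scenario_spec].
#' @param seed integer seed.
#' @return list with `dataset` (a [pk_dataset] including `COV`, the true
#'   subpopulation as a 0/1 covariate, plus any generated covariates) and
#'   `truth` (tibble: ID, TRUEK, realized individual parameters).
#' @export
simulate_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  params <- spec$params
  K <- length(params$pmix)
  ids <- sprintf("%d", seq_len(n))

  truek <- sample.int(K, n, replace = TRUE, prob = params$pmix)
  covs <- lapply(spec$covariate_generators, function(g) g(n))
  eta_names <- names(params$omega)
  eta <- matrix(stats::rnorm(n * length(eta_names)), nrow = n) %*%
    diag(sqrt(params$omega), length(eta_names))
  colnames(eta) <- eta_names

  nt <- length(spec$sample_times)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    subj_cov <- c(lapply(covs, `[`, i), list(COV = truek[i] - 1L))
    ind <- realize_params(NULL, params, truek[i], subj_cov,
                          as.list(eta[i, , drop = TRUE]))
    f <- predict_conc(spec$model_id, ind, spec$dose_times, spec$dose_amts,
                      spec$sample_times)
    eps <- if (params$sigma$model == "combined") {
      list(prop = stats::rnorm(nt), add = stats::rnorm(nt))
    } else stats::rnorm(nt)
    dv <- apply_residual(f, params$sigma, eps)
    nd <- length(spec$dose_times)
    tb <- tibble(ID = ids[i],
                 TIME = c(spec$dose_times, spec$sample_times),
                 AMT = c(spec$dose_amts, rep(NA_real_, nt)),
                 DV = c(rep(NA_real_, nd), dv),
                 EVID = c(rep(1L, nd), rep(0L, nt)),
                 MDV = c(rep(1L, nd), rep(0L, nt)),
                 COV = truek[i] - 1L)
    for (nm in names(covs)) tb[[nm]] <- covs[[nm]][i]
    rows[[i]] <- tb
    tr <- tibble(ID = ids[i], TRUEK = truek[i])
    for (nm in setdiff(names(ind), "WT")) tr[[nm]] <- ind[[nm]]
    if (!is.null(ind[["WT"]])) tr$WT <- ind[["WT"]]
    truth[[i]] <- tr
  }
  list(dataset = pk_dataset(bind_rows(rows), design_label = spec$design_label),
       truth = bind_rows(truth))
}

#' Simulate replicate datasets over an existing design
#'
#' Produces `R` datasets with the same subjects, dosing, sampling times and
#' covariates as the template, redrawing subpopulation membership from the
#' model's mixing proportions, random effects and residual error in each
#' replicate. Each replicate uses an independent substream derived from
#' `seed`, so adding replicates never changes earlier ones.
#'
#' @param params [mixture_parameters] to simulate from (typically a fit's
#'   estimates).
#' @param template a [pk_dataset] providing the design.
#' @param model a [model_spec] (structural model and variant).
#' @param R number of replicates (>= 1).
#' @param seed integer seed.
#' @return list of `R` [pk_dataset] tibbles; each carries a `truth`
#'   attribute with the drawn membership.
#' @export
simulate_replicates <- function(params, template, model, R, seed) {
  if (R < 1) rlang::abort("R must be >= 1", class = "mixvpc_usage_error")
  subjects <- split_subjects(template)
  K <- length(params$pmix)
  eta_names <- names(params$omega)
  n <- length(subjects)
  ids <- vapply(subjects, `[[`, "", "id")
  # the design is identical across replicates: reuse the template table and
  # overwrite only DV (observation rows) and the membership covariate
  base <- as_tibble(template)
  tmpl_id <- as.character(base$ID)
  is_obs <- base$EVID == 0L &
    (if ("MDV" %in% names(base)) base$MDV == 0L else TRUE)
  obs_rows <- split(which(is_obs), factor(tmpl_id[is_obs], levels = ids))
  all_rows <- split(seq_len(nrow(base)), factor(tmpl_id, levels = ids))
  keep_cov <- !is.null(model$variant) && model$variant == "covariate" &&
    "COV" %in% names(base)
  lapply(seq_len(R), function(r) {
    set.seed(derive_seed(seed, r))
    truek <- sample.int(K, n, replace = TRUE, prob = params$pmix)
    dv <- base$DV
    cov <- if ("COV" %in% names(base)) base$COV
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      eta <- as.list(stats::rnorm(length(eta_names), 0, sqrt(params$omega)))
      names(eta) <- eta_names
      ind <- realize_params(model, params, truek[i], s$covariates, eta)
      f <- predict_conc(model$model_id, ind, s$dose_times, s$dose_amts,
                        s$obs_times)
      nt <- length(s$obs_times)
      eps <- if (params$sigma$model == "combined") {
        list(prop = stats::rnorm(nt), add = stats::rnorm(nt))
      } else stats::rnorm(nt)
      dv[obs_rows[[i]]] <- apply_residual(f, params$sigma, eps)
      # for a covariate model the covariate is an observed quantity carried
      # over from the template; otherwise COV records the replicate's
      # redrawn membership (diagnostic only)
      if (!is.null(cov) && !keep_cov) cov[all_rows[[i]]] <- truek[i] - 1L
    }
    out <- base
    out$DV <- dv
    if (!is.null(cov)) out$COV <- cov
    attr(out, "truth") <- tibble(ID = ids, TRUEK = truek)
    out
  })
}
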