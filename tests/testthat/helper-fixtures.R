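# Shared fixtures. Expensive fits are built once per test run and reused
# across test files.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# reduced-size (n = 250) realization of the 70/30 linear scenario plus its
# two-component mixture fit
fixture_70_30 <- function() {
  get_fixture("f7030", function() {
    spec <- scenario_preset("linear-70-30", n_subjects = 250)
    sim <- simulate_dataset(spec, 1)
    fit <- fit_mixture(sim$dataset, model_spec("onecmt_oral", "mixture"),
                       likelihood_settings(n_starts = 2), seed = 1)
    list(spec = spec, sim = sim, fit = fit)
  })
}

# reduced-size (n = 250) realization of the 85/15 linear scenario + fit
fixture_85_15 <- function() {
  get_fixture("f8515", function() {
    spec <- scenario_preset("linear-85-15", n_subjects = 250)
    sim <- simulate_dataset(spec, 1)
    fit <- fit_mixture(sim$dataset, model_spec("onecmt_oral", "mixture"),
                       likelihood_settings(n_starts = 2), seed = 1)
    list(spec = spec, sim = sim, fit = fit)
  })
}

# small synthetic phm-like records table with prescribed posteriors
make_records <- function(ip1, pmix = c(0.5, 0.5)) {
  n <- length(ip1)
  tibble::tibble(
    ID = rep(sprintf("%d", seq_len(n)), each = 2),
    SUBPOP = rep(1:2, n),
    IOFV = as.vector(vapply(ip1, function(p) {
      # any iofv pair consistent with the posterior under the given prior
      d <- -2 * (log(p / (1 - p)) - log(pmix[1] / pmix[2]))
      c(0, d)
    }, numeric(2))),
    IL = 1,
    IPmix = as.vector(rbind(ip1, 1 - ip1)),
    MIXEST = rep(ifelse(ip1 >= 0.5, 1L, 2L), each = 2),
    OFVi = 0)
}

# tiny one-subject dataset helper
one_subject_data <- function(y, times, dose = 100, cov = NULL) {
  nt <- length(times)
  tb <- tibble::tibble(ID = "1",
                       TIME = c(0, times),
                       AMT = c(dose, rep(NA_real_, nt)),
                       DV = c(NA_real_, y),
                       EVID = c(1L, rep(0L, nt)),
                       MDV = c(1L, rep(0L, nt)))
  if (!is.null(cov)) tb$COV <- cov
  pk_dataset(tb)
}
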