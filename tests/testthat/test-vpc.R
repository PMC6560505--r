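test_that("nominal binning gives one bin per design time", {
  spec <- scenario_preset("linear-70-30", n_subjects = 40)
  sim <- simulate_dataset(spec, 4)
  obs <- sim$dataset |> dplyr::filter(EVID == 0)
  b <- bin_observations(obs$TIME, obs$DV, vpc_config())
  expect_equal(nrow(b$bins), 6)
  expect_true(all(b$bins$n == 40))
  expect_equal(b$bins$mid, c(0.5, 1, 2, 4, 8, 12))

  b1 <- bin_observations(3.7, 1.0, vpc_config())
  expect_equal(nrow(b1$bins), 1)
  expect_equal(b1$idx, 1)
})

test_that("quantile binning balances counts and validates the bin count", {
  cfg <- vpc_config(bin_mode = "quantile", n_bins = 4)
  times <- seq(0.1, 10, length.out = 100)
  b <- bin_observations(times, times, cfg)
  expect_equal(unname(b$bins$n), rep(25, 4))
  expect_error(bin_observations(c(1, 2, 3), 1:3,
                                vpc_config(bin_mode = "quantile", n_bins = 8)),
               class = "mixvpc_usage_error")
})

test_that("percentiles use linear interpolation", {
  expect_equal(mixvpc:::obs_percentiles(1:11, 50), 6)
  expect_equal(mixvpc:::obs_percentiles(1:11, c(5, 50, 95)),
               unname(stats::quantile(1:11, c(0.05, 0.5, 0.95), type = 7)))
})

test_that("self-comparison puts every observed percentile inside its band", {
  spec <- scenario_preset("linear-70-30", n_subjects = 30)
  sim <- simulate_dataset(spec, 8)
  obs <- sim$dataset |> dplyr::filter(EVID == 0)
  tv <- tibble::tibble(time = obs$TIME, value = obs$DV)
  bands <- percentile_bands(tv, replicate(25, tv, simplify = FALSE),
                            vpc_config(n_replicates = 25))
  expect_equal(sum(bands$outside), 0)
  expect_equal(bands$obs, bands$lo)
  expect_equal(bands$obs, bands$hi)
})

test_that("separation histogram counts posteriors and flags separation", {
  rec <- make_records(rep(1, 25))
  h <- separation_histogram(rec)
  expect_equal(h$count[20], 25)
  expect_equal(sum(h$count), 25)
  expect_equal(attr(h, "separation_index"), 1)

  # ip1 uniform on (0,1): flat histogram, index -> P(ip1 <= .2) +
  # P(ip1 >= .8) = 0.4
  ip <- (seq_len(2000) - 0.5) / 2000
  hu <- separation_histogram(make_records(ip))
  expect_true(all(hu$count == 100))
  expect_equal(attr(hu, "separation_index"), 0.4, tolerance = 0.01)

  expect_error(separation_histogram(make_records(numeric(0))),
               class = "mixvpc_usage_error")
})

test_that("the 85/15 mixture is less separated than the 70/30 mixture", {
  mod <- model_spec("onecmt_oral", "mixture")
  s1 <- scenario_preset("linear-70-30", n_subjects = 120)
  s2 <- scenario_preset("linear-85-15", n_subjects = 120)
  r1 <- evaluate_mixture(simulate_dataset(s1, 19)$dataset, s1$params, mod)
  r2 <- evaluate_mixture(simulate_dataset(s2, 19)$dataset, s2$params, mod)
  i1 <- attr(separation_histogram(r1), "separation_index")
  i2 <- attr(separation_histogram(r2), "separation_index")
  expect_gt(i1, i2)
})

test_that("traditional VPC is deterministic and accounts for every
           observation", {
  spec <- scenario_preset("linear-70-30", n_subjects = 40)
  sim <- simulate_dataset(spec, 14)
  fit <- list(params = spec$params,
              model = model_spec("onecmt_oral", "mixture"),
              settings = likelihood_settings(), records = NULL)
  cfg <- vpc_config(n_replicates = 30, seed = 5)
  v1 <- traditional_vpc(sim$dataset, fit, cfg)
  v2 <- traditional_vpc(sim$dataset, fit, cfg)
  expect_identical(v1$bands, v2$bands)
  expect_equal(unique(v1$bands$stratum), "all")
  expect_equal(sum(v1$bands$n_obs[v1$bands$percentile == 50]), 40 * 6)
})

test_that("mixture VPC strata partition the observations and match the
           standalone allocation summary", {
  spec <- scenario_preset("linear-70-30", n_subjects = 60)
  sim <- simulate_dataset(spec, 23)
  mod <- model_spec("onecmt_oral", "mixture")
  fit <- list(params = spec$params, model = mod,
              settings = likelihood_settings(), records = NULL)
  cfg <- vpc_config(n_replicates = 20, strategy = "mixest", seed = 3)
  v <- mixture_vpc(sim$dataset, fit, cfg)
  # every observation lands in exactly one stratum
  tot <- v$bands |> dplyr::filter(percentile == 50) |>
    dplyr::summarise(n = sum(n_obs))
  expect_equal(tot$n, 60 * 6)
  expect_s3_class(v$allocation, "allocation_summary")
  expect_equal(sum(v$allocation$origid_pct), 100, tolerance = 1e-9)
  expect_equal(sum(v$allocation$simid_pct), 100, tolerance = 1e-9)

  # reproducible bit for bit
  v2 <- mixture_vpc(sim$dataset, fit, cfg)
  expect_identical(v$bands, v2$bands)
})

test_that("mixest and randomized VPCs coincide under perfect separation", {
  # widen the clearance gap so posteriors are effectively 0/1
  params <- mixture_parameters(theta_component = list(CL = c(5, 500)),
                               theta_shared = c(ka = 1, V = 100),
                               pmix = c(0.6, 0.4),
                               omega = c(CL = 0.04),
                               sigma = residual_spec(proportional = 0.01))
  spec <- scenario_spec("onecmt_oral", params, n_subjects = 40,
                        dose_times = 0, dose_amts = 100,
                        sample_times = c(0.5, 1, 2, 4, 8, 12))
  sim <- simulate_dataset(spec, 6)
  mod <- model_spec("onecmt_oral", "mixture")
  fit <- list(params = params, model = mod,
              settings = likelihood_settings(), records = NULL)
  vm <- mixture_vpc(sim$dataset, fit,
                    vpc_config(n_replicates = 20, strategy = "mixest",
                               seed = 2))
  vr <- mixture_vpc(sim$dataset, fit,
                    vpc_config(n_replicates = 20, strategy = "randomized",
                               seed = 2))
  expect_equal(vm$bands, vr$bands)
})

test_that("pooled observed percentiles lie between the per-subpopulation
           ones", {
  spec <- scenario_preset("linear-70-30", n_subjects = 80)
  sim <- simulate_dataset(spec, 33)
  mod <- model_spec("onecmt_oral", "mixture")
  rec <- evaluate_mixture(sim$dataset, spec$params, mod)
  a <- mixest_assign(rec)
  obs <- sim$dataset |> dplyr::filter(EVID == 0)
  for (tt in c(0.5, 2, 12)) {
    v <- obs$DV[obs$TIME == tt]
    v1 <- obs$DV[obs$TIME == tt & obs$ID %in% a$ID[a$COMP == 1]]
    v2 <- obs$DV[obs$TIME == tt & obs$ID %in% a$ID[a$COMP == 2]]
    med <- stats::median(v)
    expect_gte(med, min(stats::median(v1), stats::median(v2)))
    expect_lte(med, max(stats::median(v1), stats::median(v2)))
  }
})

test_that("VPC results tidy, summarise and export cleanly", {
  spec <- scenario_preset("linear-70-30", n_subjects = 25)
  sim <- simulate_dataset(spec, 3)
  fit <- list(params = spec$params,
              model = model_spec("onecmt_oral", "mixture"),
              settings = likelihood_settings(), records = NULL)
  v <- traditional_vpc(sim$dataset, fit, vpc_config(n_replicates = 20))
  td <- tidy(v)
  expect_true(all(c("stratum", "bin", "percentile", "obs", "lo", "hi") %in%
                    names(td)))
  g <- glance(v)
  expect_equal(g$cells, 18)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_vpc(v, csv)
  write_vpc(v, js)
  expect_true(file.exists(csv) && file.exists(js))
  expect_s3_class(autoplot(v), "ggplot")
})
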