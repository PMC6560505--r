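# independent ODE oracle for the 1-compartment oral model (depot + central)
ode_1cmt_oracle <- function(params, dose, t) {
  rhs <- function(t, y, p) {
    list(c(-p[["ka"]] * y[1],
           p[["ka"]] * y[1] - p[["CL"]] / p[["V"]] * y[2]))
  }
  sol <- deSolve::lsoda(c(A0 = dose, A1 = 0), times = c(0, t), rhs,
                        unlist(params), rtol = 1e-10, atol = 1e-12)
  sol[-1, "A1"] / params[["V"]]
}

test_that("1-cmt oral closed form matches a stiff ODE oracle", {
  p <- list(ka = 1, CL = 20, V = 100)
  t <- c(0.5, 1, 2, 4, 8, 12)
  cf <- conc_1cmt_oral(p, 0, 100, t)
  expect_equal(cf, ode_1cmt_oracle(p, 100, t), tolerance = 1e-8)
  expect_equal(cf[3], 0.6687, tolerance = 1e-4)
})

test_that("1-cmt profile is causal, symmetric in ka/ke, and superposes", {
  p <- list(ka = 1, CL = 20, V = 100)
  expect_equal(conc_1cmt_oral(p, 0, 100, 0), 0)
  # flip-flop: the biexponential difference (exp(-ke t) - exp(-ka t)) /
  # (ka - ke) is symmetric in ka and ke, so profiles scaled by 1/ka match
  p_sw <- list(ka = 0.2, CL = 100, V = 100)   # ke = 1, ka = 0.2
  p_or <- list(ka = 1, CL = 20, V = 100)      # ke = 0.2, ka = 1
  t <- c(0.5, 2, 7, 30)
  expect_equal(conc_1cmt_oral(p_or, 0, 100, t) / p_or$ka,
               conc_1cmt_oral(p_sw, 0, 100, t) / p_sw$ka,
               tolerance = 1e-12)
  # superposition over doses
  multi <- conc_1cmt_oral(p, c(0, 12), c(100, 50), t + 12)
  single <- conc_1cmt_oral(p, 0, 100, t + 12) + conc_1cmt_oral(p, 12, 50, t + 12)
  expect_equal(multi, single, tolerance = 1e-12)
  # equal-rate degenerate case stays finite and close to nearby rates
  p_eq <- list(ka = 0.2, CL = 20, V = 100)
  p_near <- list(ka = 0.2 * (1 + 1e-5), CL = 20, V = 100)
  expect_equal(conc_1cmt_oral(p_eq, 0, 100, t), conc_1cmt_oral(p_near, 0, 100, t),
               tolerance = 1e-4)
})

test_that("2-cmt parallel model reduces to the linear analytic solution", {
  # Vmax = 0: classical two-compartment bolus; eigenvalue oracle
  p <- list(CLlin = 0.06, Vmax = 0, Km = 10, V1 = 3, V2 = 2, Q = 0.075,
            WT = 70)
  A <- matrix(c(-(p$CLlin + p$Q) / p$V1, p$Q / p$V2,
                p$Q / p$V1, -p$Q / p$V2), 2, 2, byrow = TRUE)
  t <- c(1, 4, 24, 96, 168)
  eg <- eigen(A)
  y0 <- c(50, 0)
  c_oracle <- vapply(t, function(tt) {
    y <- Re(eg$vectors %*% diag(exp(eg$values * tt)) %*%
              solve(eg$vectors, y0))
    y[1] / p$V1
  }, numeric(1))
  expect_equal(conc_2cmt_parallel(p, 0, 50, t), c_oracle, tolerance = 1e-6)
})

test_that("2-cmt parallel model is causal and has a correct linear limit", {
  p <- list(CLlin = 0.03, Vmax = 1.2, Km = 10, V1 = 3, V2 = 2, Q = 0.075,
            WT = 70)
  expect_equal(conc_2cmt_parallel(p, 168, 50, c(0, 10, 100)), c(0, 0, 0))
  # Km very large: effective linear clearance CLlin + Vmax/Km
  p_mm <- modifyList(p, list(Km = 1e9, Vmax = 1e9 * 0.03))
  p_lin <- modifyList(p, list(Vmax = 0, CLlin = 0.06))
  t <- c(1, 24, 96, 168)
  expect_equal(conc_2cmt_parallel(p_mm, 0, 50, t),
               conc_2cmt_parallel(p_lin, 0, 50, t), tolerance = 1e-4)
})

test_that("dose linearity holds iff elimination is linear", {
  t <- c(1, 8, 48, 168)
  p_lin <- list(CLlin = 0.06, Vmax = 0, Km = 10, V1 = 3, V2 = 2, Q = 0.075,
                WT = 70)
  c1 <- conc_2cmt_parallel(p_lin, 0, 50, t)
  c2 <- conc_2cmt_parallel(p_lin, 0, 100, t)
  expect_equal(c2, 2 * c1, tolerance = 1e-6)
  p_mm <- modifyList(p_lin, list(Vmax = 1.2))
  c1m <- conc_2cmt_parallel(p_mm, 0, 50, t)
  c2m <- conc_2cmt_parallel(p_mm, 0, 100, t)
  expect_gt(max(abs(c2m - 2 * c1m) / pmax(c2m, 1e-12)), 1e-3)
})

test_that("weight scaling acts linearly on the four disposition parameters", {
  p70 <- list(CLlin = 0.06, Vmax = 1.2, Km = 10, V1 = 3, V2 = 2, Q = 0.075,
              WT = 70)
  p140 <- modifyList(p70, list(WT = 140))
  pref <- modifyList(p70, list(CLlin = 0.12, Vmax = 2.4, V1 = 6, V2 = 4,
                               WT = 70))
  t <- c(1, 24, 168)
  expect_equal(conc_2cmt_parallel(p140, 0, 50, t),
               conc_2cmt_parallel(pref, 0, 50, t), tolerance = 1e-8)
})

test_that("residual error models evaluate per their definitions", {
  sp <- residual_spec(proportional = 0.04)
  expect_equal(apply_residual(2, sp, 0), 2)
  expect_equal(apply_residual(2, sp, 1), 2.4)
  sa <- residual_spec(additive = 0.25)
  expect_equal(apply_residual(0, sa, -2), -1.0)
  sc <- residual_spec(proportional = 0.04, additive = 0.25)
  expect_equal(apply_residual(2, sc, list(prop = 1, add = 1)), 2.4 + 0.5)
  expect_error(residual_spec(proportional = -0.1),
               class = "mixvpc_domain_error")
})

test_that("non-positive structural parameters are rejected", {
  expect_error(conc_1cmt_oral(list(ka = 1, CL = -20, V = 100), 0, 100, 1),
               class = "mixvpc_domain_error")
  expect_error(conc_2cmt_parallel(list(CLlin = 0.03, Vmax = 1.2, Km = 0,
                                       V1 = 3, V2 = 2, Q = 0.075), 0, 50, 1),
               class = "mixvpc_domain_error")
})
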