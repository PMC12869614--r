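test_that("parameter containers enforce bounds", {
  eps <- 2^-52
  p <- tristan_params(0.0167, 4.5e-4)
  expect_equal(unname(p[["k1"]]), 0.0167)
  expect_equal(attr(p, "vh"), 0.77)
  expect_error(tristan_params(0, 1e-3))
  expect_error(tristan_params(1.5, 1e-3))
  expect_silent(tristan_params(eps, 1))
  expect_error(berks_params(0.1, 0.01, 0.1, 0.01, 1.2))
  expect_silent(berks_params(eps, eps, eps, eps, eps))
})

test_that("near-zero influx produces a near-zero intracellular curve", {
  t <- test_grid(dt = 5, duration = 600)
  ce <- conc_series(t, gamma_input(t), "Ce")
  p <- tristan_params(2^-52, 1e-3)
  ci <- tristan_forward(p, ce)
  bound <- 2^-52 * sum(abs(ce$values)) * 5 / 0.77
  expect_lte(max(abs(ci$values)), bound)
})

test_that("step-input response converges to the analytic closed form", {
  # dt = 1 s over 3600 s; k1 = 0.0167, k2 = 4.5e-4 s^-1, vh = 0.77
  dt <- 1; t <- seq(0, 3600, by = dt)
  c0 <- 1
  ce <- conc_series(t, rep(c0, length(t)), "Ce")
  p <- tristan_params(0.0167, 4.5e-4)
  ci <- tristan_forward(p, ce, dt)
  analytic <- (0.0167 * c0 / 4.5e-4) * (1 - exp(-4.5e-4 * 3600 / 0.77))
  expect_lt(abs(ci$values[length(t)] - analytic) / analytic, 0.01)
})

test_that("discrete convolution matches 4th-order ODE integration at 100x finer step", {
  dt <- 1
  t <- seq(0, 1200, by = dt)
  k1 <- 0.0167; k2 <- 2e-3; vh <- 0.77
  ce_fun <- function(s) gamma_input(s, amp = 1, tp = 150)
  ce <- conc_series(t, ce_fun(t), "Ce")
  ci <- tristan_forward(tristan_params(k1, k2, vh), ce, dt)
  ode_fun <- function(s, y, parms) list((k1 * ce_fun(s) - k2 * y) / vh)
  sol <- deSolve::ode(c(ci = 0), seq(0, 1200, by = dt / 100), ode_fun, NULL,
                      method = "rk4")
  oracle <- sol[match(t, round(sol[, "time"], 9)), "ci"]
  expect_lt(max(abs(ci$values - oracle)) / max(oracle), 0.005)
})

test_that("plasma input mixes arterial and venous blood with hematocrit correction", {
  t <- test_grid(dt = 5, duration = 300)
  n <- length(t)
  ca <- conc_series(t, rep(1, n), "Ca")
  cv <- conc_series(t, rep(2, n), "Cv")
  # fa = 0.2, hct = 0.4: (0.2 + 1.6)/0.6 = 3
  expect_equal(plasma_input(ca, cv, 0.2, 0.4)$values, rep(3, n))
  # fa = 1, hct -> 0 limit: Cp = Ca
  expect_equal(plasma_input(ca, cv, 1, 1e-12)$values, rep(1, n),
               tolerance = 1e-9)
  # Ca = Cv: fa irrelevant, Cp = Ca/(1 - hct)
  expect_equal(plasma_input(ca, ca, 0.5, 0.4)$values, rep(1 / 0.6, n))
  expect_error(plasma_input(ca, conc_series(t + 1, rep(2, n), "Cv"), 0.5, 0.4),
               "time grid")
})

test_that("a unit impulse reads out the biexponential kernel exactly", {
  dt <- 2; t <- seq(0, 400, by = dt)
  impulse <- rep(0, length(t)); impulse[1] <- 1 / dt
  # fa = 1 and hct ~ 0 make Cp the impulse itself
  ca <- conc_series(t, impulse, "Ca")
  cv <- conc_series(t, rep(0, length(t)), "Cv")
  p <- berks_params(0.05, 0.01, 0.002, 5e-4, 1)
  ct <- berks_forward(p, ca, cv, hct = 1e-15, dt)
  kernel <- 0.05 * exp(-0.01 * t) + 0.002 * exp(-5e-4 * t)
  expect_equal(ct$values, kernel, tolerance = 1e-9)
})

test_that("single-exponential dual-input model coincides with the reference-region kernel", {
  # alpha- at eps: Berks reduces to one exponential; matching tristan with
  # k1/vh = alpha+, k2/vh = beta+ applied to Cp in place of Ce
  dt <- 5; t <- seq(0, 1200, by = dt)
  ca <- conc_series(t, gamma_input(t), "Ca")
  cv <- conc_series(t, gamma_input(t, amp = 1.5, tp = 90), "Cv")
  hct <- 0.4; fa <- 0.3
  eps <- 2^-52
  vh <- 0.77
  alpha <- 0.01; beta <- 8e-4
  bp <- berks_params(alpha, beta, eps, eps, fa)
  ct <- berks_forward(bp, ca, cv, hct, dt)
  cp <- plasma_input(ca, cv, fa, hct)
  tp <- tristan_params(alpha * vh, beta * vh, vh)
  ci <- tristan_forward(tp, cp, dt)
  expect_equal(ct$values, ci$values, tolerance = 1e-10)
})

test_that("dual-input convolution matches high-resolution quadrature", {
  dt <- 1; t <- seq(0, 1200, by = dt)
  ca <- conc_series(t, gamma_input(t, amp = 1, tp = 150), "Ca")
  cv <- conc_series(t, gamma_input(t, amp = 0.8, tp = 200), "Cv")
  hct <- 0.4
  p <- berks_params(0.02, 0.004, 0.005, 3e-4, 0.25)
  ct <- berks_forward(p, ca, cv, hct, dt)
  cp <- plasma_input(ca, cv, 0.25, hct)
  cp_fun <- stats::splinefun(t, cp$values)
  kernel <- function(s) 0.02 * exp(-0.004 * s) + 0.005 * exp(-3e-4 * s)
  probe <- seq(60, 1200, by = 60)
  oracle <- sapply(probe, function(tt) {
    s <- seq(0, tt, by = 0.02)
    f <- kernel(tt - s) * cp_fun(s)
    sum((f[-1] + f[-length(f)]) / 2) * 0.02
  })
  got <- ct$values[match(probe, t)]
  expect_lt(max(abs(got - oracle)) / max(oracle), 0.005)
})

test_that("forward models are linear and causal in their inputs", {
  set.seed(71)
  dt <- 5; t <- seq(-30, 900, by = dt)
  x <- c(rep(0, 6), runif(length(t) - 6, 0, 3))
  ce <- conc_series(t, x, "Ce")
  p <- tristan_params(0.01, 1e-3)
  base <- tristan_forward(p, ce, dt)$values
  # scaling and superposition
  expect_equal(tristan_forward(p, conc_series(t, 3 * x, "Ce"), dt)$values,
               3 * base, tolerance = 1e-12)
  y <- c(rep(0, 6), runif(length(t) - 6, 0, 2))
  expect_equal(tristan_forward(p, conc_series(t, x + y, "Ce"), dt)$values,
               base + tristan_forward(p, conc_series(t, y, "Ce"), dt)$values,
               tolerance = 1e-12)
  # causality: perturbing a late sample leaves earlier outputs bit-identical
  x2 <- x; k <- length(t) - 10; x2[k] <- x2[k] + 5
  pert <- tristan_forward(p, conc_series(t, x2, "Ce"), dt)$values
  expect_identical(pert[1:(k - 1)], base[1:(k - 1)])
  expect_false(isTRUE(all.equal(pert[k:length(t)], base[k:length(t)])))
})

test_that("step response is monotone in the uptake and efflux rates", {
  dt <- 10; t <- seq(0, 1800, by = dt)
  ce <- conc_series(t, rep(1, length(t)), "Ce")
  probe <- length(t) %/% 2
  k1s <- c(0.001, 0.005, 0.02, 0.1)
  vals_k1 <- sapply(k1s, function(k1)
    tristan_forward(tristan_params(k1, 1e-3), ce, dt)$values[probe])
  expect_true(all(diff(vals_k1) > 0))
  k2s <- c(1e-4, 1e-3, 5e-3, 2e-2)
  vals_k2 <- sapply(k2s, function(k2)
    tristan_forward(tristan_params(0.01, k2), ce, dt)$values[probe])
  expect_true(all(diff(vals_k2) < 0))
})

test_that("rate unit conversion is exact", {
  expect_equal(to_per_minute(0), 0)
  expect_equal(to_per_minute(1 / 60), 1)
  expect_equal(to_per_minute(0.0167), 1.002)
  expect_equal(to_per_second(to_per_minute(0.0167)), 0.0167)
  expect_error(to_per_minute(-1))
})
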