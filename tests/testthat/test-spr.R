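# well-conditioned study kinetics used throughout: association and
# dissociation both relax visibly inside a 300 s phase
KP <- kinetic_params(ka = 1e5, kd = 1e-2, Rmax = 100, kt = 1e8)
TIMES <- seq(0, 600, by = 5)
CONCS <- c(0.1, 0.3, 1, 3, 10) * 1e-7   # 0.1x..10x KD (KD = 100 nM)

test_that("the transport-free model equals the closed-form Langmuir solution", {
  p_inf <- kinetic_params(1e5, 1e-2, 100, kt = Inf)
  s <- simulate_sensorgram(p_inf, 1e-7, TIMES, 300)
  kobs <- 1e5 * 1e-7 + 1e-2
  req <- 1e5 * 1e-7 * 100 / kobs
  ref_assoc <- req * (1 - exp(-kobs * TIMES[TIMES <= 300]))
  expect_equal(s$response[s$time <= 300], ref_assoc, tolerance = 1e-10)
  r300 <- req * (1 - exp(-kobs * 300))
  ref_diss <- r300 * exp(-1e-2 * (TIMES[TIMES > 300] - 300))
  expect_equal(s$response[s$time > 300], ref_diss, tolerance = 1e-10)
})

test_that("the mass-transport model converges monotonically to the Langmuir limit", {
  p_inf <- kinetic_params(1e5, 1e-2, 100, kt = Inf)
  ref <- simulate_sensorgram(p_inf, 1e-7, TIMES, 300)$response
  devs <- purrr::map_dbl(c(1e6, 1e8, 1e10), function(kt) {
    p <- kinetic_params(1e5, 1e-2, 100, kt = kt)
    max(abs(simulate_sensorgram(p, 1e-7, TIMES, 300)$response - ref))
  })
  expect_true(all(diff(devs) < 0))
  # at moderate binding-site density (ka * Rmax well below kt) the transport
  # model is numerically indistinguishable from Langmuir at kt >= 1e10
  p_slow_inf <- kinetic_params(1e4, 1e-2, 50, kt = Inf)
  ref2 <- simulate_sensorgram(p_slow_inf, 1e-6, TIMES, 300)$response
  p_slow <- kinetic_params(1e4, 1e-2, 50, kt = 1e10)
  dev10 <- max(abs(simulate_sensorgram(p_slow, 1e-6, TIMES, 300)$response - ref2))
  expect_lt(dev10, 1e-3)
})

test_that("the adaptive integrator matches an independent fixed-step integrator", {
  p <- kinetic_params(1e5, 1e-2, 100, kt = 1e6)   # strong transport limitation
  mine <- simulate_sensorgram(p, 1e-7, TIMES, 300)
  rk <- deSolve::ode(
    c(R = 0), seq(0, 300, by = 0.05),
    function(t, y, parms) {
      free <- 100 - y[1]
      list((1e5 * 1e-7 * free - 1e-2 * y[1]) / (1 + 1e5 * free / 1e6))
    }, parms = NULL, method = "rk4")
  ref <- rk[match(TIMES[TIMES <= 300], rk[, "time"]), "R"]
  expect_lt(max(abs(mine$response[mine$time <= 300] - ref)), 1e-4)
})

test_that("association saturates to Rmax and phases are monotone", {
  p <- kinetic_params(1e5, 1e-9, 100, kt = Inf)
  s <- simulate_sensorgram(p, 1e-4, seq(0, 5000, by = 50), 5000)
  expect_equal(s$response[length(s$response)], 100, tolerance = 1e-3)
  s2 <- simulate_sensorgram(KP, 1e-7, TIMES, 300)
  expect_true(all(diff(s2$response[s2$time <= 300]) >= -1e-9))
  expect_true(all(diff(s2$response[s2$time > 300]) <= 1e-9))
  expect_error(simulate_sensorgram(KP, 1e-7, c(0, 1, 1, 2), 300), "increasing")
  expect_error(kinetic_params(-1, 1, 1), "positive")
})

test_that("noiseless global fitting recovers the planted rate constants", {
  sg <- make_sensorgrams(KP, CONCS, noise_sd = 0, seed = 1,
                         times = TIMES, t_assoc = 300)
  fit <- fit_sensorgrams(sg$data, t_assoc = 300, model = "mass_transport",
                         n_starts = 3, seed = 2)
  expect_lt(abs(fit$params$ka - KP$ka) / KP$ka, 1e-3)
  expect_lt(abs(fit$params$kd - KP$kd) / KP$kd, 1e-3)
  expect_lt(abs(fit$KD - sg$truth$KD) / sg$truth$KD, 1e-3)
  # the KD field is definitionally kd/ka
  expect_identical(fit$KD, fit$params$kd / fit$params$ka)
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n_curves, 5)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "KD"], fit$KD)
})

test_that("KD is recovered within 5% at 1% noise (seeded Monte Carlo)", {
  p_l <- kinetic_params(1e5, 1e-2, 100, kt = Inf)
  errs <- purrr::map_dbl(1:10, function(rep) {
    sg <- make_sensorgrams(p_l, CONCS, noise_sd = 1, seed = 100 + rep,
                           times = TIMES, t_assoc = 300)
    fit <- fit_sensorgrams(sg$data, t_assoc = 300, model = "langmuir",
                           n_starts = 3, seed = rep)
    abs(fit$KD - 1e-7) / 1e-7
  })
  expect_lt(stats::median(errs), 0.05)
})

test_that("the equilibrium constant is the ratio of rate constants", {
  expect_equal(equilibrium_kd(1e6, 4.81e-5), 48.1e-12)
  expect_equal(equilibrium_kd(1, 0), 0)
  expect_error(equilibrium_kd(0, 1), "positive")
  for (seed in 1:5) {
    pr <- withr::with_seed(seed, stats::runif(2, 1e-6, 1e6))
    expect_equal(equilibrium_kd(pr[1], pr[2]), pr[2] / pr[1])
  }
})

test_that("a single concentration fits with a warning", {
  sg <- make_sensorgrams(KP, 1e-7, noise_sd = 0, seed = 1,
                         times = TIMES, t_assoc = 300)
  expect_warning(
    fit_sensorgrams(sg$data, t_assoc = 300, model = "langmuir",
                    n_starts = 2, seed = 3),
    "single concentration")
})
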