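conc_series <- function(kd) 10^seq(log10(kd) - 1.5, log10(kd) + 1.5,
                                   length.out = 12)

test_that("noiseless hyperbola data are refit to 4 significant digits", {
  for (kd in c(1.01e-6, 1.12e-6)) {
    cv <- simulate_equilibrium_curve(kd, 1, conc_series(kd))
    fit <- fit_hyperbola(cv)
    expect_true(fit$converged)
    expect_equal(fit$kd, kd, tolerance = 1e-4)
    expect_equal(fit$bmax, 1, tolerance = 1e-4)
  }
})

test_that("hyperbola round trips recover parameters over a 3-decade grid", {
  for (kd in c(1e-7, 1e-6, 1e-5)) for (bmax in c(0.5, 50)) {
    fit <- fit_hyperbola(simulate_equilibrium_curve(kd, bmax, conc_series(kd)))
    expect_lt(abs(fit$kd - kd) / kd, 1e-3)
    expect_lt(abs(fit$bmax - bmax) / bmax, 1e-3)
  }
})

test_that("least squares agrees with a dense 2-D grid search on noisy data", {
  kd <- 2e-6
  cv <- simulate_equilibrium_curve(kd, 1, conc_series(kd),
                                   noise_sd = 0.03, seed = 8)
  fit <- fit_hyperbola(cv)
  kds <- 10^seq(-6.2, -5.2, length.out = 120)
  bms <- seq(0.8, 1.2, length.out = 120)
  rss <- outer(kds, bms, Vectorize(function(k, b)
    sum((cv$response - b * cv$concentration / (k + cv$concentration))^2)))
  best <- arrayInd(which.min(rss), dim(rss))
  expect_equal(fit$kd, kds[best[1]], tolerance = 0.02)
  expect_equal(fit$bmax, bms[best[2]], tolerance = 0.01)
  expect_lte(fit$rss, min(rss) + 1e-10)
})

test_that("degenerate hyperbola inputs are flagged, not silently fitted", {
  flat <- binding_curve(conc_series(1e-6), rep(0.7, 12))
  fit <- fit_hyperbola(flat)
  expect_false(fit$converged)
  expect_match(fit$message, "non-identifiable")
  expect_error(fit_hyperbola(binding_curve(c(1e-6, 1e-6), c(0.1, 0.2))),
               "distinct")
})

test_that("fitted K_D bias stays small under 2% response noise", {
  kd <- 1e-6
  kds <- vapply(1:60, function(s) {
    cv <- simulate_equilibrium_curve(kd, 1, 10^seq(-7, -5, length.out = 12),
                                     noise_sd = 0.02, seed = 300 + s)
    fit_hyperbola(cv)$kd
  }, numeric(1))
  expect_lt(abs(mean(kds) - kd) / kd, 0.05)
})

single_cycle_schedule <- function(concs, t_inj = 120, t_diss = 600) {
  n <- length(concs)
  injection_schedule(start = (0:n) * t_inj,
                     end = c(seq_len(n) * t_inj, n * t_inj + t_diss),
                     concentration = c(concs, 0))
}

test_that("noiseless kinetic sensorgrams are refit within 1%", {
  for (kd_true in c(572e-9, 509e-9)) {
    kon <- 1e5; koff <- kon * kd_true
    sch <- single_cycle_schedule(kd_true * c(0.3, 1, 3, 10, 30))
    sg <- simulate_sensorgram(kon, koff, 100, sch, dt = 0.2)
    fit <- fit_langmuir(sg, sch)
    expect_true(fit$converged)
    expect_lt(abs(fit$kd - kd_true) / kd_true, 0.01)
    expect_lt(abs(fit$rmax - 100) / 100, 0.01)
  }
})

test_that("slow high-affinity kinetics are recovered with long injections", {
  kd_true <- 4.5e-9; kon <- 1e5; koff <- kon * kd_true
  sch <- single_cycle_schedule(kd_true * c(1, 3, 10, 30, 100),
                               t_inj = 600, t_diss = 1800)
  sg <- simulate_sensorgram(kon, koff, 100, sch, dt = 1)
  fit <- fit_langmuir(sg, sch)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - kd_true) / kd_true, 0.01)
})

test_that("the fitted model reproduces an independent forward simulation", {
  kon <- 2e5; koff <- 0.05; rmax <- 60
  sch <- single_cycle_schedule(c(1e-7, 1e-6, 1e-5))
  sg <- simulate_sensorgram(kon, koff, rmax, sch, dt = 0.2)
  fit <- fit_langmuir(sg, sch)
  # forward RK4 simulation at the fitted parameters vs predict()
  fwd <- simulate_sensorgram(fit$kon, fit$koff, fit$rmax, sch, dt = 0.2)
  expect_lt(max(abs(predict(fit, newdata = fwd) - fwd$response)), 5e-3)
  expect_lt(max(abs(predict(fit) - sg$response)), 1e-2)
})

test_that("degenerate sensorgrams are flagged non-identifiable", {
  sch <- single_cycle_schedule(c(1e-6, 1e-5))
  flat <- data.frame(time = seq(0, 840, by = 1), response = 0)
  fit <- fit_langmuir(flat, sch)
  expect_false(fit$converged)
  expect_match(fit$message, "non-identifiable")
})

test_that("the Langmuir fit is scale-equivariant in the response", {
  kon <- 1e5; koff <- 0.02; rmax <- 50
  sch <- single_cycle_schedule(c(1e-7, 1e-6, 3e-6))
  sg <- simulate_sensorgram(kon, koff, rmax, sch, dt = 0.2)
  f1 <- fit_langmuir(sg, sch)
  sg2 <- sg; sg2$response <- 4 * sg$response
  f2 <- fit_langmuir(sg2, sch)
  expect_equal(f2$rmax / f1$rmax, 4, tolerance = 1e-3)
  expect_equal(f2$kon, f1$kon, tolerance = 1e-3)
  expect_equal(f2$koff, f1$koff, tolerance = 1e-3)
})

test_that("steady-state extraction matches the closed-form plateau", {
  # fast-exchange interaction: plateaus are reached within each segment
  kd_true <- 102e-6; kon <- 1e5; koff <- kon * kd_true
  concs <- kd_true * c(0.1, 0.3, 1, 3, 10)
  sch <- single_cycle_schedule(concs, t_inj = 60, t_diss = 120)
  sg <- simulate_sensorgram(kon, koff, 100, sch, dt = 0.005)
  ss <- steady_state_responses(sg, sch)
  expect_equal(ss$response, 100 * concs / (concs + kd_true), tolerance = 0.01)
  # plateau estimate equals the brute-force mean of the designated samples
  i <- 3
  t0 <- sch$end[i] - 0.1 * (sch$end[i] - sch$start[i])
  manual <- mean(sg$response[sg$time >= t0 & sg$time <= sch$end[i]])
  expect_equal(ss$response[i], manual)
  # hyperbola refit of the steady-state curve returns the planted K_D
  fit <- fit_hyperbola(ss)
  expect_lt(abs(fit$kd - kd_true) / kd_true, 0.01)
  expect_error(steady_state_responses(sg, sch, plateau_fraction = 1e-6),
               "plateau")
})
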