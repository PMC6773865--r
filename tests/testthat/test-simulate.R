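test_that("the ppH simulator is bit-reproducible and honours a zero rate", {
  cfg <- pph_sim_config(image_height = 32, image_width = 32, duration = 80,
                        scission_rate = 0, ccs_density = 0, seed = 3)
  s1 <- simulate_pph_movie(cfg)
  s2 <- simulate_pph_movie(cfg)
  expect_identical(s1$ph55$frames, s2$ph55$frames)
  expect_identical(s1$ph74$frames, s2$ph74$frames)
  expect_equal(nrow(s1$events), 0L)
  # pH 5.5 movie is background + noise only: no segmentable objects
  expect_equal(nrow(segment_movie(s1$ph55)), 0L)
  # different seed changes the noise
  s3 <- simulate_pph_movie(pph_sim_config(image_height = 32, image_width = 32,
                                          duration = 80, scission_rate = 0,
                                          ccs_density = 0, seed = 4))
  expect_false(identical(s1$ph55$frames, s3$ph55$frames))
})

test_that("event counts follow the Poisson law of the configured rate", {
  # mean count over 20 seeds within 3 SE of rate x area x duration
  cfg0 <- pph_sim_config(image_height = 48, image_width = 48, duration = 200,
                         scission_rate = 0.3, ccs_density = 0,
                         read_noise_sd = 0, poisson_gain = 0)
  area <- sum(simulate_pph_movie(cfg0)$mask) * 0.15^2
  lambda <- 0.3 * area * 200 / 60
  counts <- vapply(1:20, function(s) {
    cfg <- pph_sim_config(image_height = 48, image_width = 48, duration = 200,
                          scission_rate = 0.3, ccs_density = 0,
                          read_noise_sd = 0, poisson_gain = 0, seed = s)
    nrow(simulate_pph_movie(cfg)$events)
  }, numeric(1))
  se <- sqrt(lambda / 20)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("alternating acquisition gives 4 s pH 5.5 sampling and 8-12 s visibility", {
  cfg <- pph_sim_config(image_height = 32, image_width = 32, duration = 120,
                        frame_period = 2, scission_rate = 0, seed = 1)
  sim <- simulate_pph_movie(cfg)
  expect_true(all(diff(sim$ph55$frame_times) == 4))
  # an event visible for exactly 3 pH 5.5 frames spans 8-12 s of clock
  # time depending on its phase relative to the frame grid
  t55 <- sim$ph55$frame_times
  for (sc in c(10, 11.9)) {
    vis <- t55[t55 >= sc & t55 < sc + 12]
    expect_equal(length(vis), 3L)
  }
  span3 <- diff(range(t55[t55 >= 10 & t55 < 10 + 12])) + 4
  expect_true(span3 >= 8 && span3 <= 12)
})

test_that("ground-truth structure is internally consistent", {
  sim <- noiseless_sim(seed = 31, orphan_fraction = 0.2)
  ev <- sim$events
  expect_true(all(ev$birth_s <= ev$scission_s))
  xi <- round(ev$x_px); yi <- round(ev$y_px)
  expect_true(all(sim$mask[cbind(yi, xi)]))
  # vesicle fluorescence appears in pH 5.5 frames only at/after
  # scission: at spatially isolated event sites the first pH 5.5 frame
  # with above-background signal is at/after the scission time
  bg <- 100
  dmin <- vapply(seq_len(nrow(ev)), function(i)
    min(Inf, sqrt((ev$x_px[-i] - ev$x_px[i])^2 +
                    (ev$y_px[-i] - ev$y_px[i])^2)), numeric(1))
  for (i in which(dmin > 12)) {
    sig <- sim$ph55$frames[yi[i], xi[i], ] - bg
    first <- which(sig > 30)[1]
    if (!is.na(first))
      expect_gte(sim$ph55$frame_times[first], ev$scission_s[i])
  }
  expect_error(simulate_pph_movie(pph_sim_config(
    mask = matrix(FALSE, 96, 96))), "zero area")
})

test_that("equilibrium curves follow the one-site hyperbola", {
  kd <- 2e-6
  cv <- simulate_equilibrium_curve(kd, 1, c(0, kd, 1e3 * kd))
  expect_equal(cv$response[1], 0)
  expect_equal(cv$response[2], 0.5)           # half-saturation at X = KD
  expect_equal(cv$response[3], 1, tolerance = 1e-3)  # saturation limit
  expect_error(simulate_equilibrium_curve(kd, 1, c(-1e-6, kd)), ">= 0")
  # fixed seed reproduces noise
  c1 <- simulate_equilibrium_curve(kd, 1, rep(kd, 5), noise_sd = 0.1, seed = 7)
  c2 <- simulate_equilibrium_curve(kd, 1, rep(kd, 5), noise_sd = 0.1, seed = 7)
  expect_identical(c1$response, c2$response)
})

test_that("sensorgram integration matches the closed-form association curve", {
  kon <- 1e5; koff <- 0.01; rmax <- 80; C <- 2e-7
  sch <- injection_schedule(0, 300, C)
  sg <- simulate_sensorgram(kon, koff, rmax, sch, dt = 0.1)
  k <- kon * C + koff
  closed <- rmax * C / (C + koff / kon) * (1 - exp(-k * sg$time))
  expect_lt(max(abs(sg$response - closed)), 1e-6)
  # no analyte: flat zero
  sg0 <- simulate_sensorgram(kon, koff, rmax, injection_schedule(0, 100, 0))
  expect_true(all(sg0$response == 0))
  # long injection approaches the steady state rmax C / (C + KD)
  sg_inf <- simulate_sensorgram(kon, koff, rmax, injection_schedule(0, 2000, C))
  expect_equal(sg_inf$response[nrow(sg_inf)], rmax * C / (C + koff / kon),
               tolerance = 1e-6)
  # integration error shrinks with dt (at least first order)
  err <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    s <- simulate_sensorgram(kon, koff, rmax, sch, dt = dt)
    max(abs(s$response - rmax * C / (C + koff / kon) * (1 - exp(-k * s$time))))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  # malformed schedules are rejected
  expect_error(injection_schedule(c(0, 70), c(60, 130), c(1e-6, 0)),
               "contiguous")
})

test_that("event streams are reproducible piecewise-Poisson realizations", {
  s1 <- simulate_event_stream(12, 8, t_ca = 300, t_wc = 600, seed = 5)
  s2 <- simulate_event_stream(12, 8, t_ca = 300, t_wc = 600, seed = 5)
  expect_identical(s1$event_times, s2$event_times)
  expect_equal(s1$mode_boundary, 300)
  # zero CA rate: empty cell-attached window, ratio undefined downstream
  s0 <- simulate_event_stream(0, 8, t_ca = 300, t_wc = 600, seed = 5)
  expect_equal(sum(s0$event_times < 300), 0L)
  expect_error(frequency_ratio(s0), "undefined")
  # matched rates: mean f over seeds ~ 100%
  fs <- vapply(1:100, function(s)
    frequency_ratio(simulate_event_stream(40, 40, 300, 600, seed = s))$f,
    numeric(1))
  expect_lt(abs(mean(fs) - 100), 3 * sd(fs) / sqrt(length(fs)) + 2)
  # time-varying whole-cell rate via thinning
  sv <- simulate_event_stream(40, function(t) 40 * exp(-t / 120),
                              t_ca = 120, t_wc = 600, seed = 9)
  early <- sum(sv$event_times >= 120 & sv$event_times < 320)
  late <- sum(sv$event_times >= 520)
  expect_gt(early, late)
})
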