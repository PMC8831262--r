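test_that("Carreau-Yasuda viscosity hits both plateaus and the printed formula", {
  fl <- fluid_properties()
  expect_identical(carreau_yasuda_viscosity(0, fl), fl$cy_mu0)
  expect_equal(carreau_yasuda_viscosity(1e15, fl), fl$cy_muinf,
               tolerance = 1e-6)
  # independent evaluation of the closed form at gamma = 100 / s
  g <- 100
  direct <- fl$cy_muinf + (fl$cy_mu0 - fl$cy_muinf) *
    (1 + (fl$cy_lambda * g)^fl$cy_a)^((fl$cy_n - 1)/fl$cy_a)
  expect_equal(carreau_yasuda_viscosity(g, fl), direct, tolerance = 1e-12)
  # monotone non-increasing for shear-thinning parameters
  gg <- 10^seq(-2, 5, length.out = 40)
  expect_true(all(diff(carreau_yasuda_viscosity(gg, fl)) <= 0))
  expect_error(carreau_yasuda_viscosity(-1, fl), "shear_rate")
})

test_that("waveform harmonics round-trip to the samples", {
  for (seed in c(3, 11)) {
    wf <- random_waveform(seed, n_harmonics = 4, n_samples = 50)
    rec <- waveform_eval(wf, wf$times)
    expect_lt(max(abs(rec - wf$samples)), 1e-9)
  }
  # even sample count exercises the Nyquist term
  wf <- flow_waveform(c(5, 9, 4, 2, 6, 8, 1, 3), period = 0.8)
  expect_lt(max(abs(waveform_eval(wf, wf$times) - wf$samples)), 1e-9)
})

test_that("steady Womersley wall shear equals the Poiseuille closed form", {
  wf <- flow_waveform(rep(5, 16), period = 1)
  w <- womersley_wall_shear(wf, radius = 3, n_time = 16)
  expect_equal(w$wall_shear_series,
               rep(4 * 0.0035 * 5e-6/(pi * (3e-3)^3), 16),
               tolerance = 1e-12)
  expect_error(womersley_wall_shear(wf, radius = -1), "radius")
})

test_that("zero-mean sinusoid has zero cycle-average wall shear", {
  tt <- (0:63)/64
  wf <- flow_waveform(3 * sin(2 * pi * tt), period = 1)
  w <- womersley_wall_shear(wf, radius = 3)
  expect_lt(abs(mean(w$wall_shear_series)), 1e-9)
})

test_that("velocity profile conserves flow and satisfies no-slip", {
  wf <- random_waveform(7, n_harmonics = 4)
  w <- womersley_wall_shear(wf, radius = 3, n_time = 16, n_radial = 129)
  r <- w$r * 1e-3
  n <- length(r)
  h <- r[2] - r[1]
  simpson <- c(1, rep(c(4, 2), (n - 3)/2), 4, 1) * h/3
  q_num <- colSums(w$velocity_profile * (2 * pi * r * simpson))
  q_true <- waveform_eval(wf, w$times, n_harmonics = w$n_harmonics) * 1e-6
  expect_lt(max(abs(q_num - q_true))/max(abs(q_true)), 1e-6)
  expect_lt(max(abs(w$velocity_profile[n, ])), 1e-12)
})

test_that("wall shear matches the wall velocity gradient on a fine grid", {
  wf <- random_waveform(13, n_harmonics = 2)
  w <- womersley_wall_shear(wf, radius = 3, n_time = 16, n_radial = 2049)
  n <- 2049
  h <- (w$r[2] - w$r[1]) * 1e-3
  dudr <- (3 * w$velocity_profile[n, ] - 4 * w$velocity_profile[n - 1, ] +
             w$velocity_profile[n - 2, ])/(2 * h)
  tau_fd <- -0.0035 * dudr
  expect_lt(max(abs(tau_fd - w$wall_shear_series))/
              max(abs(w$wall_shear_series)), 1e-4)
})

test_that("low-frequency limit converges to quasi-steady Poiseuille", {
  # a very long period drives all Womersley numbers toward zero
  tt <- (0:63)/64
  q <- 5 + 2 * sin(2 * pi * tt)
  wf <- flow_waveform(q, period = 4e4)
  w <- womersley_wall_shear(wf, radius = 3)
  expect_lt(max(w$alpha), 0.1)
  qs <- 4 * 0.0035 * waveform_eval(wf, w$times) * 1e-6/(pi * (3e-3)^3)
  expect_lt(max(abs(w$wall_shear_series - qs))/max(abs(qs)), 1e-3)
})

test_that("Womersley number guard rejects alpha > 50", {
  tt <- (0:63)/64
  wf <- flow_waveform(5 + sin(2 * pi * tt), period = 0.0005)
  expect_error(womersley_wall_shear(wf, radius = 3), "exceeds 50")
})

test_that("waveform scaling reaches the 0.9 Pa setpoint for arbitrary shapes", {
  for (seed in 1:6) {
    wf <- random_waveform(seed, n_harmonics = 2 + seed %% 3)
    sc <- scale_waveform_to_target_wss(wf, cca_radius = 3)
    re <- womersley_tawss(womersley_wall_shear(sc$waveform, 3))
    expect_lt(abs(re - 0.9), 1e-3)
  }
})

test_that("steady waveform scaling factor has the Poiseuille closed form", {
  wf <- flow_waveform(rep(5, 16), period = 1)
  sc <- scale_waveform_to_target_wss(wf, cca_radius = 3)
  expect_equal(sc$factor, 0.9 * pi * (3e-3)^3/(4 * 0.0035 * 5e-6),
               tolerance = 1e-9)
})

test_that("rescaling an already-scaled waveform is the identity", {
  wf <- random_waveform(21)
  sc1 <- scale_waveform_to_target_wss(wf, 3)
  sc2 <- scale_waveform_to_target_wss(sc1$waveform, 3)
  expect_equal(sc2$factor, 1, tolerance = 1e-6)
  expect_error(
    scale_waveform_to_target_wss(flow_waveform(rep(0, 8), 1), 3),
    "zero")
})

test_that("outflow split conserves flow and decreases with stenosis degree", {
  s0 <- split_outflow(0)
  expect_equal(s0$ica_fraction + s0$eca_fraction, 1)
  expect_equal(s0$ica_fraction, 0.64)
  expect_equal(split_outflow(1)$ica_fraction, 0)
  dd <- seq(0, 1, by = 0.05)
  f <- split_outflow(dd)$ica_fraction
  expect_true(all(diff(f) <= 1e-12))
  expect_error(split_outflow(1.2), "\\[0, 1\\]")
  expect_error(split_outflow(-0.1), "\\[0, 1\\]")
})
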