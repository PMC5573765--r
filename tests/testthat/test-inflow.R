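test_that("fourier_fit recovers constructed waveforms and preserves the mean", {
  # pure fundamental sinusoid
  n <- 256L
  tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
  x <- 3 * cos(2 * pi * tt + 0.4)
  wf <- fourier_fit(sampled_waveform(tt, x), 1L)
  expect_equal(wf$mean_flow, 0, tolerance = 1e-12)
  expect_equal(Mod(wf$harmonics[1L]), 3, tolerance = 1e-10)
  expect_equal(Arg(wf$harmonics[1L]), 0.4, tolerance = 1e-10)

  # constant signal: mean only
  wf0 <- fourier_fit(sampled_waveform(tt, rep(2.5, n)), 5L)
  expect_equal(wf0$mean_flow, 2.5)
  expect_true(all(Mod(wf0$harmonics) < 1e-12))

  # construct-then-recover with 3 known harmonics at n_modes = 15
  h <- complex(real = c(1, -0.5, 0.2), imaginary = c(0.3, 0.1, -0.7))
  truth <- fourier_waveform(1, 4, c(h, rep(0 + 0i, 12L)))
  fit <- fourier_fit(sampled_waveform(tt, eval_waveform(truth, tt)), 15L)
  expect_equal(fit$mean_flow, 4, tolerance = 1e-12)
  expect_equal(fit$harmonics[1:3], h, tolerance = 1e-10)
  expect_true(all(Mod(fit$harmonics[4:15]) < 1e-10))
})

test_that("fourier_fit rejects bad sampling and over-asking", {
  tt <- c(0, 0.1, 0.15, 0.4, 0.7, 0.8, 0.85, 0.9, 0.95, 0.99)
  expect_error(fourier_fit(sampled_waveform(tt, sin(tt)), 2L), "non-uniform")
  # resampling rescue
  expect_s3_class(fourier_fit(sampled_waveform(tt, sin(tt)), 2L,
                              resample = TRUE), "fourier_waveform")
  tu <- seq(0, 0.9, by = 0.1)
  expect_error(fourier_fit(sampled_waveform(tu, sin(tu)), 8L), "Nyquist")
})

test_that("fourier_fit o evaluate is the identity on band-limited signals", {
  set.seed(42)
  n <- 512L
  tt <- seq(0, 2, length.out = n + 1L)[-(n + 1L)]
  for (rep in 1:5) {
    k <- sample(3:12, 1L)
    h <- complex(real = rnorm(k), imaginary = rnorm(k))
    truth <- fourier_waveform(2, rnorm(1L), h)
    fit <- fourier_fit(sampled_waveform(tt, eval_waveform(truth, tt)), k)
    expect_equal(fit$harmonics, truth$harmonics, tolerance = 1e-10)
    expect_equal(fit$mean_flow, truth$mean_flow, tolerance = 1e-10)
    # periodicity of the evaluated waveform
    t0 <- runif(4L)
    expect_equal(eval_waveform(fit, t0), eval_waveform(fit, t0 + 2),
                 tolerance = 1e-12)
  }
})

test_that("reynolds_number matches direct arithmetic and is linear", {
  fl <- fluid_properties()
  expect_equal(reynolds_number(0, 5e-3, fl), 0)
  expect_equal(reynolds_number(1e-5, 5e-3, fl),
               4 * 1060 * 1e-5 / (pi * 3.5e-3 * 5e-3), tolerance = 1e-12)
  expect_equal(reynolds_number(2e-5, 5e-3, fl),
               2 * reynolds_number(1e-5, 5e-3, fl))
  expect_error(reynolds_number(1e-5, 0, fl), "diameter")
})

test_that("scale_to_peak_reynolds hits the target exactly and is linear", {
  wf <- gen_inflow_waveform(generator_config(seed = 2L))
  s1 <- scale_to_peak_reynolds(wf, 1300, 5e-3)
  expect_equal(peak_reynolds(s1, 5e-3), 1300, tolerance = 1e-6)
  # already at target: unchanged
  s2 <- scale_to_peak_reynolds(s1, 1300, 5e-3)
  expect_equal(s2$harmonics, s1$harmonics, tolerance = 1e-12)
  # doubling the target doubles the waveform
  s3 <- scale_to_peak_reynolds(wf, 2600, 5e-3)
  expect_equal(s3$mean_flow / s1$mean_flow, 2, tolerance = 1e-12)
  expect_equal(s3$harmonics, 2 * s1$harmonics, tolerance = 1e-12)
  zero <- fourier_waveform(1, 0)
  expect_error(scale_to_peak_reynolds(zero, 1300, 5e-3), "zero")
})

test_that("womersley_number matches its definition", {
  fl <- fluid_properties()
  expect_equal(womersley_number(5e-3, 0, fl), 0)
  expect_equal(womersley_number(5e-3, 2 * pi, fl),
               2.5e-3 * sqrt(2 * pi * 1060 / 3.5e-3), tolerance = 1e-12)
  expect_equal(womersley_number(5e-3, 8 * pi, fl),
               2 * womersley_number(5e-3, 2 * pi, fl), tolerance = 1e-12)
})

test_that("steady Womersley profile is Poiseuille", {
  R <- 2.5e-3
  Q <- 1e-5
  fld <- womersley_field(R, fourier_waveform(1, Q))
  u0 <- womersley_velocity(fld, 0, 0)
  expect_equal(u0, 2 * Q / (pi * R^2), tolerance = 1e-12)
  expect_equal(womersley_velocity(fld, R / sqrt(2), 0), u0 / 2,
               tolerance = 1e-12)
  expect_equal(womersley_velocity(fld, R, 0.3), 0, tolerance = 1e-15)
  expect_error(womersley_velocity(fld, 1.1 * R, 0), "within")
})

test_that("oscillatory profile matches an independent finite-difference solve", {
  fl <- fluid_properties()
  R <- 2.5e-3
  # choose omega for alpha = 10
  alpha <- 10
  omega <- (alpha / R)^2 * fl$viscosity / fl$density
  fd <- womersley_fd_oracle(R, omega, fl)
  # drive the analytic field with the oracle's complex flow as harmonic 1
  wf <- fourier_waveform(2 * pi / omega, 0, fd$flow)
  fld <- womersley_field(R, wf, fl)
  u_impl <- womersley_velocity(fld, fd$r, 0)
  expect_lt(max(abs(u_impl - Re(fd$u))) / max(abs(fd$u)), 1e-6)
})

test_that("cross-sectional flow is recovered at random times (flow consistency)", {
  set.seed(7)
  for (s in 1:3) {
    k <- 15L
    wf <- fourier_waveform(1, 1e-5,
                           complex(real = rnorm(k, sd = 2e-6),
                                   imaginary = rnorm(k, sd = 2e-6)))
    fld <- womersley_field(2.5e-3, wf)
    tt <- runif(100L)
    q_num <- womersley_flow(fld, tt)
    q_ref <- eval_waveform(wf, tt)
    expect_lt(max(abs(q_num - q_ref)) / max(abs(q_ref)), 1e-6)
  }
})

test_that("single-harmonic profile converges to parabolic as alpha -> 0", {
  fl <- fluid_properties()
  R <- 2.5e-3
  Q <- 1e-6
  for (alpha in c(0.05, 0.15)) {  # below and above the series switchover
    omega <- (alpha / R)^2 * fl$viscosity / fl$density
    fld <- womersley_field(R, fourier_waveform(2 * pi / omega, 0, Q + 0i), fl)
    rr <- seq(0, R, length.out = 101L)
    u <- womersley_velocity(fld, rr, 0)
    u_pois <- 2 * Q / (pi * R^2) * (1 - (rr / R)^2)
    expect_lt(max(abs(u - u_pois)) / (2 * Q / (pi * R^2)), 1e-3)
  }
})
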