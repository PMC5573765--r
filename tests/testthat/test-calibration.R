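refs_fixture <- function(n = 101L) {
  tt <- seq(0, 1, length.out = n)
  qr <- 10 + 3 * sin(2 * pi * tt)
  calibration_refs(sampled_waveform(tt, qr, "ml_s"))
}

test_that("cost_phi reproduces its closed-form terms", {
  refs <- refs_fixture()
  tt <- refs$Q_R$times
  p_match <- sampled_waveform(tt, 80 + 50 * (1 + sin(2 * pi * tt)) / 2)
  expect_equal(max(p_match$values), 130)
  expect_equal(min(p_match$values), 80)
  phi0 <- cost_phi(p_match, refs$Q_R, refs)
  expect_equal(phi0$total, 0)
  # single-term systolic overshoot: 143 vs 130 gives exactly 0.01
  p_hi <- sampled_waveform(tt, 80 + 63 * (1 + sin(2 * pi * tt)) / 2)
  phi1 <- cost_phi(p_hi, refs$Q_R, refs)
  expect_equal(phi1$term_sys, ((143 - 130) / 130)^2)
  expect_equal(phi1$total, phi1$term_sys + phi1$term_dia + phi1$term_flow)
  expect_equal(phi1$term_flow, 0)
  # doubling a strictly positive flow: flow term exactly 1
  q2 <- sampled_waveform(tt, 2 * refs$Q_R$values, "ml_s")
  phi2 <- cost_phi(p_match, q2, refs)
  expect_equal(phi2$total, 1, tolerance = 1e-12)
  # degenerate reference
  expect_error(cost_phi(p_match, q2,
                        calibration_refs(sampled_waveform(tt, rep(0, length(tt))))),
               "zero")
})

test_that("cost_phi is invariant to common time shifts and resampling", {
  refs <- refs_fixture()
  tt <- refs$Q_R$times
  qv <- sampled_waveform(tt, refs$Q_R$values * 1.07, "ml_s")
  p <- sampled_waveform(tt, 80 + 45 * (1 + sin(2 * pi * tt + 1)) / 2)
  base <- cost_phi(p, qv, refs)$total
  shifted <- cost_phi(sampled_waveform(tt + 5, p$values),
                      sampled_waveform(tt + 5, qv$values, "ml_s"), refs)$total
  expect_equal(shifted, base, tolerance = 1e-12)
  # denser common resampling changes the quadrature only slightly
  t2 <- seq(0, 1, length.out = 401L)
  refs2 <- calibration_refs(sampled_waveform(t2, 10 + 3 * sin(2 * pi * t2),
                                             "ml_s"))
  qv2 <- sampled_waveform(t2, (10 + 3 * sin(2 * pi * t2)) * 1.07, "ml_s")
  p2 <- sampled_waveform(t2, 80 + 45 * (1 + sin(2 * pi * t2 + 1)) / 2)
  expect_equal(cost_phi(p2, qv2, refs2)$total, base, tolerance = 1e-4)
})

test_that("identify_internal_elements recovers constructed branch laws", {
  n <- 10001L
  tt <- seq(0, 1, length.out = n)
  two_harm <- function(a1, a2, ph) 10 + a1 * sin(2 * pi * tt + ph) +
    a2 * sin(4 * pi * tt)
  mk_branch <- function(R, L, a1, a2, ph) {
    q <- two_harm(a1, a2, ph)
    dq <- a1 * 2 * pi * cos(2 * pi * tt + ph) + a2 * 4 * pi * cos(4 * pi * tt)
    list(dP = sampled_waveform(tt, R * q * abs(q) + L * dq, "mmHg"),
         Q = sampled_waveform(tt, q, "ml_s"))
  }
  truth <- list(A1 = c(R = 5e-3, L = 4e-3), A2 = c(R = 2e-3, L = 8e-3),
                V1 = c(R = 1e-2, L = 6e-3))
  branches <- list(
    A1 = mk_branch(truth$A1["R"], truth$A1["L"], 3, 1, 0.3),
    A2 = mk_branch(truth$A2["R"], truth$A2["L"], 2, 0.7, 1.1),
    V1 = mk_branch(truth$V1["R"], truth$V1["L"], 4, 1.5, 2.0))
  est <- identify_internal_elements(branches)
  expect_equal(est$R1A, unname(truth$A1["R"]), tolerance = 1e-6)
  expect_equal(est$L1A, unname(truth$A1["L"]), tolerance = 1e-6)
  expect_equal(est$R2A, unname(truth$A2["R"]), tolerance = 1e-6)
  expect_equal(est$L2A, unname(truth$A2["L"]), tolerance = 1e-6)
  expect_equal(est$R1V, unname(truth$V1["R"]), tolerance = 1e-6)
  expect_equal(est$L1V, unname(truth$V1["L"]), tolerance = 1e-6)
  expect_true(all(attr(est, "residuals") < 1e-6))

  # L = 0 truth yields an essentially zero inductance estimate
  branches$A1 <- mk_branch(5e-3, 0, 3, 1, 0.3)
  est0 <- identify_internal_elements(branches)
  expect_lt(est0$L1A, 1e-8)

  # steady flow leaves L unidentifiable and must error, naming the branch
  branches$V1 <- list(dP = sampled_waveform(tt, rep(1, n), "mmHg"),
                      Q = sampled_waveform(tt, rep(5, n), "ml_s"))
  expect_error(identify_internal_elements(branches), "V1")
})

test_that("optimize_windkessel recovers a synthetic truth and is deterministic", {
  tr <- gen_truth_network(generator_config(seed = 7L))
  model <- zero_d_evaluator(tr$inflow, tr$internal)
  init <- perturb_windkessel(tr$windkessel, 2)
  wk <- optimize_windkessel(model, tr$refs, init, restarts = 2L,
                            maxit = 1000L, seed = 7L)
  expect_true(wk$tie_rao_uao)
  expect_true(all(wk_free_params(wk) > 0))
  expect_lt(attr(wk, "phi")$total, 1e-4)
  err <- abs(wk_free_params(wk) - wk_free_params(tr$windkessel)) /
    wk_free_params(tr$windkessel)
  expect_lt(median(err), 0.05)
  # determinism at identical seed and init (cheap settings)
  w1 <- optimize_windkessel(model, tr$refs, init, restarts = 1L,
                            maxit = 40L, seed = 3L)
  w2 <- optimize_windkessel(model, tr$refs, init, restarts = 1L,
                            maxit = 40L, seed = 3L)
  expect_identical(wk_free_params(w1), wk_free_params(w2))
})

test_that("optimize_windkessel never worsens an already optimal start", {
  tr <- gen_truth_network(generator_config(seed = 9L))
  model <- zero_d_evaluator(tr$inflow, tr$internal)
  out <- model(tr$windkessel)
  expect_equal(cost_phi(out$P_BAI, out$Q_VO, tr$refs)$total, 0,
               tolerance = 1e-12)
  wk <- optimize_windkessel(model, tr$refs, tr$windkessel, restarts = 1L,
                            maxit = 60L, seed = 1L)
  expect_lte(attr(wk, "phi")$total, 1e-12)
})

test_that("calibrate closes the outer loop on its 0D fixed point", {
  tr <- gen_truth_network(generator_config(seed = 8L))
  # surrogate = exact 0D model: after the first optimization the loop is at
  # a fixed point, so the second outer iteration must see a small change
  res <- calibrate(tr$surrogate, tr$refs, tr$inflow, tr$internal,
                   init_wk = tr$windkessel, outer_tol = 0.05,
                   max_outer = 3L, restarts = 1L, maxit = 300L, seed = 2L)
  expect_true(res$converged)
  expect_lte(nrow(res$history), 3L)
  # max_outer = 1 with a distant start: single history row, not converged
  res1 <- calibrate(tr$surrogate, tr$refs, tr$inflow, tr$internal,
                    init_wk = perturb_windkessel(tr$windkessel, 2),
                    outer_tol = 1e-3, max_outer = 1L, restarts = 1L,
                    maxit = 200L, seed = 2L)
  expect_identical(nrow(res1$history), 1L)
  expect_false(res1$converged)
})

test_that("calibrate converges from perturbed internal elements", {
  tr <- gen_truth_network(generator_config(seed = 10L), perturb_internal = 1.2)
  init_internal <- internal_elements()  # generic first estimate
  res <- calibrate(tr$surrogate, tr$refs, tr$inflow, init_internal,
                   init_wk = perturb_windkessel(tr$windkessel, 1.5),
                   outer_tol = 0.02, max_outer = 10L, restarts = 1L,
                   maxit = 600L, seed = 4L)
  expect_true(res$converged)
  expect_lt(res$history$phi[nrow(res$history)], 1e-2)
})
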