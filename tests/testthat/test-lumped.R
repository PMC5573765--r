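test_that("rcr_pressure_rate relaxes toward the resistive equilibrium", {
  term <- windkessel_terminal(1, 2, 0.5)
  steady <- rcr_pressure_rate(P = 3 * (1 + 2), Q = 3, dQdt = 0, term)
  expect_identical(steady$mode, "ode")
  expect_equal(steady$value, 0)
  below <- rcr_pressure_rate(P = 5, Q = 3, dQdt = 0, term)
  expect_gt(below$value, 0)
  alg <- rcr_pressure_rate(P = 0, Q = 3, dQdt = 0, list(R1 = 1, R2 = 2, C = 0))
  expect_identical(alg$mode, "algebraic")
  expect_equal(alg$value, 9)
})

test_that("integrated RCR pressure amplitude matches the analytic impedance", {
  term <- windkessel_terminal(1, 2, 0.5)
  omega <- 2 * pi
  qamp <- 3
  dt <- 5e-5
  # integrate dP/dt with RK4 from the analytic steady state
  Z <- term$R1 + term$R2 / (1 + 1i * omega * term$R2 * term$C)
  q <- function(t) qamp * cos(omega * t)
  dq <- function(t) -qamp * omega * sin(omega * t)
  f <- function(t, P) rcr_pressure_rate(P, q(t), dq(t), term)$value
  P <- Re(Z * qamp)  # analytic P at t = 0 (zero-mean drive)
  nn <- round(2 / dt)
  Ps <- numeric(nn + 1L); Ps[1L] <- P
  for (i in seq_len(nn)) {
    t <- (i - 1L) * dt
    k1 <- f(t, P); k2 <- f(t + dt / 2, P + dt / 2 * k1)
    k3 <- f(t + dt / 2, P + dt / 2 * k2); k4 <- f(t + dt, P + dt * k3)
    P <- P + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    Ps[i + 1L] <- P
  }
  amp <- (max(Ps) - min(Ps)) / 2
  expect_equal(amp, Mod(Z) * qamp, tolerance = 1e-4)
})

test_that("zero inflow from zero pressure stays identically zero", {
  sol <- simulate_network(fourier_waveform(1, 0, flow_units = "ml_s"),
                          table1_windkessel("P1-IN"), internal_elements(),
                          dt = 1e-3, max_cycles = 3L, P_init = 0)
  expect_true(all(abs(unlist(sol$node_pressures)) < 1e-12))
  expect_true(all(abs(unlist(sol$branch_flows)) < 1e-12))
})

test_that("constant inflow reaches the steady split of the nonlinear algebra oracle", {
  wk <- table1_windkessel("P1-IN")
  internal <- internal_elements()
  q0 <- 10  # mL/s
  sol <- simulate_network(fourier_waveform(1, q0, flow_units = "ml_s"),
                          wk, internal, dt = 1e-3, max_cycles = 100L,
                          tol = 1e-12, P_init = "dc")
  qv_sim <- mean(sol$branch_flows$Q_VO)
  # oracle: steady loop balance with quadratic resistors included
  r_art <- 1 / (1 / (wk$rao$R1 + wk$rao$R2) + 1 / (wk$uao$R1 + wk$uao$R2))
  r_ven <- wk$vo$R1 + wk$vo$R2
  bal <- function(qv) {
    qa <- q0 - qv
    internal$R2A * qa * abs(qa) + qa * r_art -
      internal$R1V * qv * abs(qv) - qv * r_ven
  }
  qv_star <- uniroot(bal, c(0, q0), tol = 1e-12)$root
  expect_equal(qv_sim, qv_star, tolerance = 1e-6)
  # and the dc resistive split is a close approximation
  expect_equal(qv_sim / q0, dc_flow_split(wk), tolerance = 1e-2)
})

test_that("junction flow balance (Kirchhoff) holds at every stored instant", {
  wf <- gen_inflow_waveform(generator_config(seed = 4L))
  sol <- simulate_network(wf, table1_windkessel("P2-IN"),
                          internal_elements(), dt = 1e-3, max_cycles = 10L,
                          P_init = "dc")
  bf <- sol$branch_flows
  expect_lt(max(abs(bf$Q_in - bf$Q_VO - bf$Q_RAO - bf$Q_UAO)),
            1e-9 * max(abs(bf$Q_in)))
})

test_that("periodic steady state: capacitor currents average to zero and the full-period split matches the DC split", {
  set.seed(11)
  for (s in 1:3) {
    wk <- windkessel_set(
      rao = windkessel_terminal(6.88 * runif(1, 0.5, 1.5),
                                59.8 * runif(1, 0.5, 1.5),
                                0.01 * runif(1, 0.5, 1.5)),
      vo = windkessel_terminal(7 * runif(1, 0.5, 1.5),
                               10.3 * runif(1, 0.5, 1.5),
                               10.5 * runif(1, 0.5, 1.5)))
    wf <- gen_inflow_waveform(generator_config(seed = s))
    sol <- simulate_network(wf, wk, internal_elements(), dt = 1e-3,
                            max_cycles = 400L, tol = 2e-6, P_init = "dc")
    # cycle-averaged capacitor current, reconstructed from the traces:
    # I_C = Q - (P - R1 Q)/R2 at each terminal
    np <- sol$node_pressures; bf <- sol$branch_flows
    for (nm in c("RAO", "UAO", "VO")) {
      term <- wk[[tolower(nm)]]
      q <- bf[[paste0("Q_", nm)]]
      p <- np[[paste0("P_", nm)]]
      ic <- mean(q - (p - term$R1 * q) / term$R2)
      expect_lt(abs(ic), 1e-3 * abs(mean(q)))
    }
    full <- analysis_window("custom", start = sol$times[1L],
                            end = sol$times[length(sol$times)])
    expect_equal(window_flow_split(sol, full)[["venous"]] / 100,
                 dc_flow_split(wk), tolerance = 1e-2)
  }
})

test_that("halving the time step changes P_BAI by less than 0.1% RMS", {
  wf <- gen_inflow_waveform(generator_config(seed = 5L))
  wk <- table1_windkessel("P1-IN")
  s1 <- simulate_network(wf, wk, internal_elements(), dt = 2e-4,
                         max_cycles = 10L, tol = 1e-6, P_init = "dc")
  s2 <- simulate_network(wf, wk, internal_elements(), dt = 1e-4,
                         max_cycles = 10L, tol = 1e-6, P_init = "dc")
  p1 <- s1$node_pressures$P_BAI
  p2 <- s2$node_pressures$P_BAI[seq(1L, length(s2$times), by = 2L)]
  expect_lt(sqrt(mean((p1 - p2)^2)) / diff(range(p2)), 1e-3)
})

test_that("dc_flow_split reproduces hand arithmetic", {
  # three identical terminals: arterial parallel pair halves the resistance
  t0 <- windkessel_terminal(1, 2, 1)
  expect_equal(dc_flow_split(windkessel_set(rao = t0, vo = t0)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(dc_flow_split(table1_windkessel("P1-IN")),
               (66.68 / 2) / (66.68 / 2 + 17.30), tolerance = 1e-12)
  expect_equal(dc_flow_split(table1_windkessel("P2-IN")),
               (56.40 / 2) / (56.40 / 2 + 14.50), tolerance = 1e-12)
})

test_that("window_flow_split integrates, splits and recombines consistently", {
  wf <- gen_inflow_waveform(generator_config(seed = 6L))
  sol <- simulate_network(wf, table1_windkessel("P1-IN"),
                          internal_elements(), dt = 1e-3, max_cycles = 10L,
                          P_init = "dc")
  ws <- window_flow_split(sol, analysis_window("WS"))
  expect_equal(sum(ws), 100)
  expect_error(window_flow_split(sol, analysis_window("custom", start = 0.2,
                                                      end = 0.5)),
               "outside")
  # additivity: recombining WS, WD and the remainder reproduces WT
  intg <- function(a, b, col) {
    sel <- sol$times >= a - 1e-12 & sol$times <= b + 1e-12
    ts <- sol$times[sel]
    v <- sol$branch_flows[[col]][sel]
    sum(diff(ts) * (v[-1L] + v[-length(v)])) / 2
  }
  for (col in c("Q_VO", "Q_RAO")) {
    expect_equal(intg(1, 2, col),
                 intg(1, 1.1, col) + intg(1.1, 1.4, col) +
                   intg(1.4, 1.7, col) + intg(1.7, 2, col),
                 tolerance = 1e-10)
  }
  # constant 2:1 flows by direct construction of the split formula
  wk_eq <- windkessel_set(rao = windkessel_terminal(2, 2, 1),
                          vo = windkessel_terminal(0.5, 0.5, 1))
  sol2 <- simulate_network(fourier_waveform(1, 9, flow_units = "ml_s"),
                           wk_eq, internal_elements(), dt = 1e-3,
                           max_cycles = 100L, tol = 1e-10, P_init = "dc")
  full <- analysis_window("custom", start = sol2$times[1L],
                          end = sol2$times[length(sol2$times)])
  expect_equal(window_flow_split(sol2, full)[["venous"]], 200 / 3,
               tolerance = 0.5)
})
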