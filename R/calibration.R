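#' Calibration reference targets
#'
#' Reference systolic/diastolic inlet pressures and a reference venous
#' outflow waveform against which the Windkessel parameters are calibrated.
#' Defaults are the physiological brachial references of 130/80 mmHg.
#'
#' @param Q_R Reference venous outflow waveform, a [sampled_waveform()]
#'   spanning one period, mL/s.
#' @param P_RS Reference systolic pressure, mmHg.
#' @param P_RD Reference diastolic pressure, mmHg; 0 < P_RD < P_RS.
#' @return An object of class `calibration_refs`.
#' @export
calibration_refs <- function(Q_R, P_RS = 130, P_RD = 80) {
  stopifnot(inherits(Q_R, "sampled_waveform"), P_RS > P_RD, P_RD > 0)
  structure(list(P_RS = P_RS, P_RD = P_RD, Q_R = Q_R),
            class = "calibration_refs")
}

#' Calibration cost
#'
#' The scalar cost driving Windkessel calibration:
#' \deqn{\Phi = \left(\frac{\max(P_{BAI}) - P_{RS}}{P_{RS}}\right)^2
#'  + \left(\frac{\min(P_{BAI}) - P_{RD}}{P_{RD}}\right)^2
#'  + \left(\frac{\int |Q_{VO} - Q_R|\,dt}{\int |Q_R|\,dt}\right)^2,}
#' with integrals over one pulse period (trapezoidal quadrature on the
#' reference grid; `Q_VO` is linearly interpolated onto it) and the pressure
#' extrema taken over the discrete samples.
#'
#' @param P_BAI Inlet pressure waveform over one period, a
#'   [sampled_waveform()] (mmHg).
#' @param Q_VO Venous outflow waveform over one period, a
#'   [sampled_waveform()] (mL/s).
#' @param refs A [calibration_refs()].
#' @return An object of class `cost_breakdown`: list with `term_sys`,
#'   `term_dia`, `term_flow`, `total`.
#' @export
cost_phi <- function(P_BAI, Q_VO, refs) {
  stopifnot(inherits(P_BAI, "sampled_waveform"),
            inherits(Q_VO, "sampled_waveform"),
            inherits(refs, "calibration_refs"))
  term_sys <- ((max(P_BAI$values) - refs$P_RS) / refs$P_RS)^2
  term_dia <- ((min(P_BAI$values) - refs$P_RD) / refs$P_RD)^2
  tr <- refs$Q_R$times
  qr <- refs$Q_R$values
  denom <- trapz(tr, abs(qr))
  if (denom == 0) stop("reference flow integral is zero")
  # align Q_VO on the reference grid (tolerating a common time offset)
  tq <- Q_VO$times - Q_VO$times[1L] + tr[1L]
  qv <- approx(tq, Q_VO$values, xout = tr, rule = 2)$y
  term_flow <- (trapz(tr, abs(qv - qr)) / denom)^2
  structure(list(term_sys = term_sys, term_dia = term_dia,
                 term_flow = term_flow,
                 total = term_sys + term_dia + term_flow),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Phi = %.6g (sys %.3g, dia %.3g, flow %.3g)\n",
              x$total, x$term_sys, x$term_dia, x$term_flow))
  invisible(x)
}

#' Build a 0D model evaluator for calibration
#'
#' Wraps [simulate_network()] into the callable contract used by
#' [optimize_windkessel()] and [calibrate()]: a deterministic function
#' mapping a [windkessel_set()] to the traces needed by the cost.
#'
#' @param inflow A [fourier_waveform()] inlet flow.
#' @param internal An [internal_elements()].
#' @param dt Integrator step, s (coarser than the reporting default is
#'   adequate inside the optimizer).
#' @param max_cycles,tol,P_init Passed to [simulate_network()]; the DC warm
#'   start is the default so each evaluation reaches periodic steady state
#'   in a few cycles.
#' @return A function `f(wk)` returning a list with `P_BAI` and `Q_VO`
#'   [sampled_waveform()]s and the full `sol`.
#' @export
zero_d_evaluator <- function(inflow, internal, dt = 1e-3, max_cycles = 30L,
                             tol = 1e-5, P_init = "dc") {
  force(inflow); force(internal); force(dt); force(max_cycles); force(tol)
  force(P_init)
  function(wk) {
    # explicit RK4 is only conditionally stable: refine the step below the
    # fastest time constants of the tested parameter set (inductor loop
    # L/R and the capacitor nodes C*(R1 || R2))
    tau_loop <- (internal$L2A + internal$L1V) /
      (wk$vo$R1 + 1 / (1 / wk$rao$R1 + 1 / wk$uao$R1))
    tau_cap <- min(vapply(list(wk$rao, wk$uao, wk$vo), function(tm)
      tm$C * tm$R1 * tm$R2 / (tm$R1 + tm$R2), numeric(1L)))
    dt_use <- min(dt, tau_loop, tau_cap)
    nsteps <- min(ceiling(inflow$period / dt_use), 100000L)
    sol <- simulate_network(inflow, wk, internal, dt = inflow$period / nsteps,
                            max_cycles = max_cycles, tol = tol,
                            P_init = P_init)
    list(P_BAI = sampled_waveform(sol$times, sol$node_pressures$P_BAI, "mmHg"),
         Q_VO = sampled_waveform(sol$times, sol$branch_flows$Q_VO, "ml_s"),
         sol = sol)
  }
}

# 6-parameter log encoding of a tied Windkessel set
wk_to_theta <- function(wk) {
  log(c(wk$uao$R1, wk$uao$R2, wk$uao$C, wk$vo$R1, wk$vo$R2, wk$vo$C))
}

theta_to_wk <- function(theta) {
  p <- exp(theta)
  art <- windkessel_terminal(p[1L], p[2L], p[3L])
  windkessel_set(rao = art, vo = windkessel_terminal(p[4L], p[5L], p[6L]),
                 tie_rao_uao = TRUE)
}

#' Optimize Windkessel parameters against reference targets
#'
#' Minimizes the calibration cost [cost_phi()] over the six free Windkessel
#' parameters (the RAO/UAO tie reduces nine to six) by Nelder-Mead simplex
#' search on log-transformed parameters, which enforces positivity without
#' explicit constraints. The search restarts from seeded multiplicative
#' jitters of the initial guess and keeps the best cost.
#'
#' @param model A deterministic callable `f(wk) -> list(P_BAI, Q_VO, ...)`,
#'   e.g. from [zero_d_evaluator()].
#' @param refs A [calibration_refs()].
#' @param init Initial [windkessel_set()].
#' @param restarts Number of simplex starts (the first is `init` itself).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param jitter_sd Log-scale s.d. of the restart jitter.
#' @param seed Integer seed for the restart jitters (deterministic output).
#' @return A [windkessel_set()] with attributes `phi` (final
#'   [cost_phi()] breakdown) and `history` (data.frame of per-start best
#'   costs).
#' @export
optimize_windkessel <- function(model, refs, init, restarts = 3L,
                                maxit = 1500L, jitter_sd = 0.15, seed = 1L) {
  stopifnot(is.function(model), inherits(refs, "calibration_refs"),
            inherits(init, "windkessel_set"))
  obj <- function(theta) {
    wk <- theta_to_wk(theta)
    out <- tryCatch(model(wk), error = function(e)
      stop("model evaluation failed at R1_UAO=", signif(exp(theta[1L]), 4),
           ", ...: ", conditionMessage(e)))
    # parameters far outside the physical range can destabilize the
    # explicit integrator; treat a non-finite trace as a very bad fit
    if (!all(is.finite(out$P_BAI$values)) || !all(is.finite(out$Q_VO$values)))
      return(1e6)
    cost_phi(out$P_BAI, out$Q_VO, refs)$total
  }
  theta0 <- wk_to_theta(init)
  rng <- local({set.seed(seed); replicate(max(restarts - 1L, 0L),
                                          rnorm(length(theta0), 0, jitter_sd))})
  starts <- cbind(theta0, if (restarts > 1L) theta0 + rng)
  best <- NULL
  hist <- data.frame(start = integer(0), phi = numeric(0))
  for (j in seq_len(ncol(starts))) {
    fit <- optim(starts[, j], obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12))
    hist <- rbind(hist, data.frame(start = j, phi = fit$value))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish from the incumbent
  fit <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  if (fit$value < best$value) best <- fit
  phi0 <- obj(theta0)
  if (best$value > phi0) best <- list(par = theta0, value = phi0)
  wk <- theta_to_wk(best$par)
  out <- model(wk)
  attr(wk, "phi") <- if (all(is.finite(out$P_BAI$values)) &&
                         all(is.finite(out$Q_VO$values)))
    cost_phi(out$P_BAI, out$Q_VO, refs)
  else
    structure(list(term_sys = Inf, term_dia = Inf, term_flow = Inf,
                   total = Inf), class = "cost_breakdown")
  attr(wk, "history") <- hist
  wk
}

#' Identify internal lumped elements from branch traces
#'
#' Per-branch least-squares fit of the constitutive law
#' `dP(t) = R.Q|Q| + L.dQ/dt` (dQ/dt by central differences on the interior
#' samples), with nonnegative clipping of the estimates. This is the
#' extraction step by which a high-fidelity run refines the internal
#' elements of the 0D network.
#'
#' @param branches Named list with entries `A1`, `A2`, `V1`, each a list of
#'   [sampled_waveform()]s `dP` (mmHg) and `Q` (mL/s) spanning at least one
#'   period with at least 100 samples; e.g. from [branch_traces()].
#' @return An [internal_elements()] with attribute `residuals`, the named
#'   per-branch RMS fit residuals (mmHg).
#' @export
identify_internal_elements <- function(branches) {
  stopifnot(all(c("A1", "A2", "V1") %in% names(branches)))
  fit_one <- function(br, name) {
    tt <- br$Q$times; q <- br$Q$values; dp <- br$dP$values
    if (length(q) < 100L) stop("branch ", name, ": need >= 100 samples")
    n <- length(q)
    idx <- 2L:(n - 1L)
    dqdt <- (q[idx + 1L] - q[idx - 1L]) / (tt[idx + 1L] - tt[idx - 1L])
    x1 <- (q * abs(q))[idx]
    y <- dp[idx]
    if (sd(dqdt) < 1e-10 * (sd(q) + 1e-300) || sd(q) < 1e-12 * (mean(abs(q)) + 1e-300))
      stop("branch ", name, ": regressor is rank-deficient (steady flow; ",
           "inductance unidentifiable)")
    X <- cbind(Rq = x1, L = dqdt)
    if (qr(X)$rank < 2L)
      stop("branch ", name, ": regressor is rank-deficient")
    cf <- qr.solve(X, y)
    res <- sqrt(mean((y - X %*% cf)^2))
    c(R = max(cf[1L], 0), L = max(cf[2L], 0), rms = res)
  }
  a1 <- fit_one(branches$A1, "A1")
  a2 <- fit_one(branches$A2, "A2")
  v1 <- fit_one(branches$V1, "V1")
  out <- internal_elements(L1A = a1["L"], L2A = a2["L"], L1V = v1["L"],
                           R1A = a1["R"], R2A = a2["R"], R1V = v1["R"])
  attr(out, "residuals") <- c(A1 = unname(a1["rms"]), A2 = unname(a2["rms"]),
                              V1 = unname(v1["rms"]))
  out
}

#' Iterative Windkessel calibration against a high-fidelity surrogate
#'
#' Alternates (i) [optimize_windkessel()] on the 0D network with the current
#' internal-element estimates, (ii) a surrogate (high-fidelity) run with the
#' optimized Windkessel parameters, and (iii)
#' [identify_internal_elements()] on the surrogate's branch traces, until
#' the maximum relative change of the nine Windkessel parameters falls below
#' `outer_tol` or `max_outer` iterations are reached.
#'
#' @param surrogate A callable `f(wk) -> network_solution` standing in for
#'   the high-fidelity model (see [gen_truth_network()] for a shipped test
#'   surrogate).
#' @param refs A [calibration_refs()].
#' @param inflow The inlet [fourier_waveform()] used by the 0D model.
#' @param init_internal Initial [internal_elements()] estimate.
#' @param init_wk Initial [windkessel_set()].
#' @param outer_tol Relative-change stopping tolerance on the Windkessel
#'   parameters. Default 0.01.
#' @param max_outer Maximum outer iterations.
#' @param dt_0d Time step of the inner 0D evaluations, s.
#' @param ... Further arguments passed to [optimize_windkessel()].
#' @return An object of class `calibration_result`: list with `windkessel`,
#'   `internal`, `history` (data.frame of per-iteration cost and parameter
#'   change), `converged`.
#' @export
calibrate <- function(surrogate, refs, inflow, init_internal, init_wk,
                      outer_tol = 0.01, max_outer = 10L, dt_0d = 1e-3, ...) {
  stopifnot(is.function(surrogate), inherits(refs, "calibration_refs"),
            inherits(init_internal, "internal_elements"),
            inherits(init_wk, "windkessel_set"))
  internal <- init_internal
  wk <- init_wk
  history <- data.frame(iter = integer(0), phi = numeric(0),
                        max_rel_change = numeric(0))
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    model <- zero_d_evaluator(inflow, internal, dt = dt_0d)
    wk_new <- optimize_windkessel(model, refs, wk, ...)
    change <- max(abs(wk_vector(wk_new) - wk_vector(wk)) /
                    pmax(abs(wk_vector(wk)), 1e-12))
    phi <- attr(wk_new, "phi")$total
    history <- rbind(history, data.frame(iter = it, phi = phi,
                                         max_rel_change = change))
    wk <- wk_new
    if (change < outer_tol) { converged <- TRUE; break }
    sol <- surrogate(wk)
    internal <- identify_internal_elements(branch_traces(sol))
  }
  structure(list(windkessel = wk, internal = internal, history = history,
                 converged = converged),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: %d outer iteration(s), %s; final Phi = %.4g\n",
              nrow(x$history),
              if (x$converged) "converged" else "not converged",
              x$history$phi[nrow(x$history)]))
  invisible(x)
}
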