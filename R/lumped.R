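#' RCR Windkessel terminal
#'
#' A three-element Windkessel outlet boundary condition: proximal resistance
#' R1 in series with the parallel combination of distal resistance R2 and
#' compliance C, referenced to zero distal pressure. Clinical units
#' throughout: mmHg.mL^-1.s for resistances, mL/mmHg for compliance.
#'
#' @param R1 Proximal resistance, mmHg.mL^-1.s (> 0).
#' @param R2 Distal resistance, mmHg.mL^-1.s (> 0).
#' @param C Compliance, mL/mmHg (> 0).
#' @return An object of class `windkessel_terminal`.
#' @export
windkessel_terminal <- function(R1, R2, C) {
  stopifnot(is.numeric(R1), R1 > 0, is.numeric(R2), R2 > 0,
            is.numeric(C), C > 0)
  structure(list(R1 = R1, R2 = R2, C = C), class = "windkessel_terminal")
}

#' @export
print.windkessel_terminal <- function(x, ...) {
  cat(sprintf("RCR terminal: R1 = %.4g, R2 = %.4g mmHg.mL^-1.s, C = %.4g mL/mmHg\n",
              x$R1, x$R2, x$C))
  invisible(x)
}

#' Windkessel set for the three AVF outlets
#'
#' Terminals for the Radial Artery Outlet (RAO), Ulnar Artery Outlet (UAO)
#' and Venous Outlet (VO). With `tie_rao_uao = TRUE` (the default, matching
#' the assumption that both distal arteries share the same peripheral
#' behaviour) the UAO terminal is forced equal to the RAO terminal and may be
#' omitted.
#'
#' @param rao,uao,vo [windkessel_terminal()] objects.
#' @param tie_rao_uao Logical; enforce RAO == UAO.
#' @return An object of class `windkessel_set`.
#' @export
windkessel_set <- function(rao, vo, uao = NULL, tie_rao_uao = TRUE) {
  stopifnot(inherits(rao, "windkessel_terminal"),
            inherits(vo, "windkessel_terminal"))
  if (is.null(uao)) {
    if (!tie_rao_uao) stop("uao must be supplied when tie_rao_uao = FALSE")
    uao <- rao
  }
  stopifnot(inherits(uao, "windkessel_terminal"))
  if (tie_rao_uao &&
      !isTRUE(all.equal(unclass(rao), unclass(uao), tolerance = 1e-12)))
    stop("tie_rao_uao = TRUE requires rao and uao to be identical")
  structure(list(rao = rao, uao = uao, vo = vo, tie_rao_uao = tie_rao_uao),
            class = "windkessel_set")
}

#' @export
print.windkessel_set <- function(x, ...) {
  cat("Windkessel set (RAO/UAO ", if (x$tie_rao_uao) "tied" else "free", "):\n",
      sep = "")
  for (nm in c("rao", "uao", "vo")) {
    cat(" ", toupper(nm), ": ")
    print(x[[nm]])
  }
  invisible(x)
}

# flatten to the 9-vector the integrator expects
wk_vector <- function(wk) {
  c(wk$rao$R1, wk$rao$R2, wk$rao$C,
    wk$uao$R1, wk$uao$R2, wk$uao$C,
    wk$vo$R1, wk$vo$R2, wk$vo$C)
}

#' Internal lumped elements of the 0D network
#'
#' Inductances and quadratic resistance coefficients of the three internal
#' branches standing in for the 3D domain: the proximal artery (inlet to
#' anastomosis; L1A, R1A), the distal artery (anastomosis to arterial
#' outlets; L2A, R2A) and the vein (anastomosis to venous outlet; L1V, R1V).
#' Quadratic resistors follow the sign-preserving law dP = R.Q.|Q|.
#'
#' @param L1A,L2A,L1V Inductances, mmHg.mL^-1.s^2 (>= 0).
#' @param R1A,R2A,R1V Quadratic resistance coefficients, mmHg.mL^-2.s^2 (>= 0).
#' @return An object of class `internal_elements`.
#' @export
internal_elements <- function(L1A = 5e-3, L2A = 5e-3, L1V = 5e-3,
                              R1A = 5e-3, R2A = 5e-3, R1V = 1e-2) {
  v <- c(L1A = L1A, L2A = L2A, L1V = L1V, R1A = R1A, R2A = R2A, R1V = R1V)
  stopifnot(is.numeric(v), all(v >= 0))
  structure(as.list(v), class = "internal_elements")
}

#' @export
print.internal_elements <- function(x, ...) {
  cat(sprintf("Internal elements: L = (%.3g, %.3g, %.3g) mmHg.mL^-1.s^2, R = (%.3g, %.3g, %.3g) mmHg.mL^-2.s^2\n",
              x$L1A, x$L2A, x$L1V, x$R1A, x$R2A, x$R1V))
  invisible(x)
}

internal_vector <- function(internal) {
  c(internal$L1A, internal$L2A, internal$L1V,
    internal$R1A, internal$R2A, internal$R1V)
}

#' Packaged Windkessel parameter fixtures
#'
#' Loads the packaged calibrated Windkessel parameter sets for the two
#' patient-derived inner-curvature AVF configurations ("P1-IN", "P2-IN"),
#' in clinical units.
#'
#' @param config `"P1-IN"` or `"P2-IN"`.
#' @return A [windkessel_set()].
#' @export
table1_windkessel <- function(config = c("P1-IN", "P2-IN")) {
  config <- match.arg(config)
  path <- system.file("extdata", "table1.json", package = "avflow",
                      mustWork = TRUE)
  tab <- jsonlite::fromJSON(path)
  p <- tab[[config]]
  windkessel_set(
    rao = windkessel_terminal(p$R1_RAO, p$R2_RAO, p$C_RAO),
    vo = windkessel_terminal(p$R1_VO, p$R2_VO, p$C_VO),
    uao = windkessel_terminal(p$R1_UAO, p$R2_UAO, p$C_UAO),
    tie_rao_uao = TRUE)
}

#' RCR terminal pressure rate
#'
#' Explicit rearrangement of the Windkessel terminal relation
#' \deqn{P = Q(R_1+R_2) - R_2 C \frac{d}{dt}(P - R_1 Q)}
#' into \deqn{dP/dt = \frac{Q(R_1+R_2) - P}{R_2 C} + R_1 \frac{dQ}{dt}.}
#' For `C = 0` the relation degenerates to the algebraic law
#' `P = Q (R1 + R2)`, signalled by mode `"algebraic"`.
#'
#' @param P Terminal pressure, mmHg.
#' @param Q Terminal flow, mL/s.
#' @param dQdt Terminal flow rate of change, mL/s^2.
#' @param term A [windkessel_terminal()] (or a list with R1, R2, C where
#'   C may be 0).
#' @return A list with `mode` (`"ode"` or `"algebraic"`) and `value`
#'   (dP/dt in mmHg/s, or the algebraic pressure in mmHg).
#' @export
rcr_pressure_rate <- function(P, Q, dQdt, term) {
  stopifnot(is.numeric(P), is.numeric(Q), is.numeric(dQdt))
  if (term$C == 0)
    return(list(mode = "algebraic", value = Q * (term$R1 + term$R2)))
  list(mode = "ode",
       value = (Q * (term$R1 + term$R2) - P) / (term$R2 * term$C) +
         term$R1 * dQdt)
}

#' Analysis window
#'
#' Time windows over the reported cycle used throughout the unsteadiness
#' analyses: WT spans the full pulse period [1.0, 2.0] s, WS systole
#' [1.1, 1.4] s and WD part of diastole [1.4, 1.7] s (the reported cycle is
#' the second simulated period, mapped to [1, 2] s for a 1 s pulse).
#'
#' @param label One of "WT", "WS", "WD", or "custom".
#' @param start,end Window bounds, s; required for `"custom"`, defaulted to
#'   the canonical values otherwise.
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(label = c("WT", "WS", "WD", "custom"),
                            start = NULL, end = NULL) {
  label <- match.arg(label)
  canon <- list(WT = c(1.0, 2.0), WS = c(1.1, 1.4), WD = c(1.4, 1.7))
  if (label == "custom") {
    if (is.null(start) || is.null(end)) stop("custom window needs start and end")
  } else {
    start <- start %||% canon[[label]][1L]
    end <- end %||% canon[[label]][2L]
  }
  stopifnot(end > start)
  structure(list(label = label, start = start, end = end),
            class = "analysis_window")
}

#' Integrate the 0D Windkessel network to periodic steady state
#'
#' Integrates the lumped network (three inductive branches with quadratic
#' resistors, three RCR terminals with the RAO/UAO pair merged at one node)
#' by fixed-step classical Runge-Kutta from a uniform initial pressure,
#' cycle by cycle, until the cycle-to-cycle RMS change of the inlet pressure
#' P_BAI falls below `tol` times its final-cycle range, or `max_cycles` is
#' reached. Returns the final-cycle traces with times mapped to
#' `[period, 2*period]` so the canonical WT/WS/WD windows apply directly.
#'
#' @param inflow A [fourier_waveform()]; converted to mL/s if tagged SI.
#' @param wk A [windkessel_set()].
#' @param internal An [internal_elements()]; `L2A + L1V` must be > 0.
#' @param dt Time step, s; must divide the period. Default 1e-4 s.
#' @param max_cycles Maximum number of cycles to integrate (>= 2).
#' @param tol Periodicity tolerance on normalized cycle-to-cycle RMS of
#'   P_BAI. Default 5e-3.
#' @param P_init Initial capacitor pressure, mmHg (uniform; default 78,
#'   the conventional initialization), or the string `"dc"` to warm-start
#'   each capacitor at its resistive-divider steady value. The venous
#'   compliance time constant can reach tens of seconds, so the uniform
#'   start may need hundreds of cycles to settle; the DC warm start removes
#'   that transient and is recommended whenever the cycle-averaged state is
#'   what matters.
#' @return An object of class `network_solution` with elements `times` (s),
#'   `node_pressures` (data.frame: P_BAI, P_AN, P_RAO, P_UAO, P_VO, mmHg),
#'   `branch_flows` (data.frame: Q_in, Q_art, Q_RAO, Q_UAO, Q_VO, mL/s),
#'   `cycles_run`, `periodicity_residual`, `converged`, `period`, `dt`.
#' @export
simulate_network <- function(inflow, wk, internal = internal_elements(),
                             dt = 1e-4, max_cycles = 20L, tol = 5e-3,
                             P_init = 78) {
  stopifnot(inherits(inflow, "fourier_waveform"),
            inherits(wk, "windkessel_set"),
            inherits(internal, "internal_elements"),
            dt > 0, max_cycles >= 2)
  if (inflow$flow_units == "m3_s") {
    inflow <- fourier_waveform(inflow$period, inflow$mean_flow * 1e6,
                               inflow$harmonics * 1e6, flow_units = "ml_s")
  }
  period <- inflow$period
  nsteps <- round(period / dt)
  if (abs(nsteps * dt - period) > 1e-9 * period)
    stop("dt must divide the waveform period")
  th <- seq(0, period, by = dt / 2)
  qin <- eval_waveform(inflow, th)
  dqin <- eval_waveform(inflow, th, derivative = TRUE)
  if (identical(P_init, "dc")) {
    qbar <- inflow$mean_flow
    r_art <- 1 / (1 / (wk$rao$R1 + wk$rao$R2) + 1 / (wk$uao$R1 + wk$uao$R2))
    r_ven <- wk$vo$R1 + wk$vo$R2
    qv0 <- dc_flow_split(wk) * qbar
    if (qbar > 0) {
      # steady loop balance including the quadratic internal resistors
      bal <- function(qv) {
        qa <- qbar - qv
        internal$R2A * qa * abs(qa) + qa * r_art -
          internal$R1V * qv * abs(qv) - qv * r_ven
      }
      qv0 <- tryCatch(stats::uniroot(bal, c(0, qbar), tol = 1e-12)$root,
                      error = function(e) qv0)
    }
    g_art <- 1 / (wk$rao$R1 + wk$rao$R2) + 1 / (wk$uao$R1 + wk$uao$R2)
    q_rao <- (qbar - qv0) * (1 / (wk$rao$R1 + wk$rao$R2)) / g_art
    q_uao <- (qbar - qv0) * (1 / (wk$uao$R1 + wk$uao$R2)) / g_art
    init_state <- c(qv0, q_rao * wk$rao$R2, q_uao * wk$uao$R2,
                    qv0 * wk$vo$R2)
  } else {
    stopifnot(is.numeric(P_init), length(P_init) == 1L)
    init_state <- c(0, P_init, P_init, P_init)
  }
  res <- network_rk4_cpp(qin, dqin, wk_vector(wk), internal_vector(internal),
                         dt, period, as.integer(max_cycles), tol, init_state)
  times <- period + seq(0, period, by = dt)
  structure(list(
    times = times,
    node_pressures = data.frame(
      P_BAI = res$pbai, P_AN = res$pan, P_RAO = res$paj, P_UAO = res$paj,
      P_VO = res$pvj),
    branch_flows = data.frame(
      Q_in = res$qin, Q_art = res$qrao + res$quao, Q_RAO = res$qrao,
      Q_UAO = res$quao, Q_VO = res$qv),
    cycles_run = res$cycles_run,
    periodicity_residual = res$periodicity_residual,
    converged = res$converged,
    period = period, dt = dt),
    class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("0D network solution: %d cycles (%s), residual %.3g\n",
              x$cycles_run, if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$periodicity_residual))
  cat(sprintf("  P_BAI range [%.2f, %.2f] mmHg; mean venous split %.1f%%\n",
              min(x$node_pressures$P_BAI), max(x$node_pressures$P_BAI),
              window_flow_split(x, analysis_window("custom",
                start = x$times[1L], end = x$times[length(x$times)]))[1L]))
  invisible(x)
}

#' Internal branch traces of a network solution
#'
#' Extracts the pressure drop and flow of the three internal branches
#' (proximal artery A1, distal artery A2, vein V1) from a
#' [simulate_network()] solution, in the form consumed by
#' [identify_internal_elements()].
#'
#' @param sol A `network_solution`.
#' @return Named list (`A1`, `A2`, `V1`) of lists with `dP` and `Q`
#'   [sampled_waveform()]s (mmHg, mL/s).
#' @export
branch_traces <- function(sol) {
  stopifnot(inherits(sol, "network_solution"))
  np <- sol$node_pressures; bf <- sol$branch_flows; tt <- sol$times
  list(
    A1 = list(dP = sampled_waveform(tt, np$P_BAI - np$P_AN, "mmHg"),
              Q = sampled_waveform(tt, bf$Q_in, "ml_s")),
    A2 = list(dP = sampled_waveform(tt, np$P_AN - np$P_RAO, "mmHg"),
              Q = sampled_waveform(tt, bf$Q_art, "ml_s")),
    V1 = list(dP = sampled_waveform(tt, np$P_AN - np$P_VO, "mmHg"),
              Q = sampled_waveform(tt, bf$Q_VO, "ml_s")))
}

#' DC (cycle-averaged) venous flow fraction of a Windkessel set
#'
#' In periodic steady state the cycle-averaged current into each compliance
#' vanishes, so the mean flow split of the terminal-dominated network is the
#' resistive divider
#' \deqn{f_{ven} = \frac{R_{art,par}}{R_{art,par} + R_{1,VO} + R_{2,VO}},}
#' where `R_art_par` is the parallel combination of the two arterial series
#' resistances `R1 + R2`.
#'
#' @param wk A [windkessel_set()].
#' @return The venous flow fraction in [0, 1].
#' @export
dc_flow_split <- function(wk) {
  stopifnot(inherits(wk, "windkessel_set"))
  r_rao <- wk$rao$R1 + wk$rao$R2
  r_uao <- wk$uao$R1 + wk$uao$R2
  r_art <- 1 / (1 / r_rao + 1 / r_uao)
  r_ven <- wk$vo$R1 + wk$vo$R2
  r_art / (r_art + r_ven)
}

#' Windowed venous:arterial flow split
#'
#' Time-integrates the venous outflow and the summed distal arterial
#' outflows over an analysis window of the final cycle and expresses them as
#' percentages summing to 100.
#'
#' @param sol A `network_solution`.
#' @param window An [analysis_window()] lying within the solution's span.
#' @return Named numeric vector `c(venous = ..., arterial = ...)`, percent.
#' @export
window_flow_split <- function(sol, window) {
  stopifnot(inherits(sol, "network_solution"),
            inherits(window, "analysis_window"))
  tt <- sol$times
  if (window$start < tt[1L] - 1e-9 || window$end > tt[length(tt)] + 1e-9)
    stop("window [", window$start, ", ", window$end,
         "] lies outside the solution span")
  sel <- tt >= window$start - 1e-12 & tt <= window$end + 1e-12
  ts <- tt[sel]
  qv <- trapz(ts, sol$branch_flows$Q_VO[sel])
  qa <- trapz(ts, sol$branch_flows$Q_RAO[sel] + sol$branch_flows$Q_UAO[sel])
  tot <- qv + qa
  if (tot == 0) stop("zero net outflow in window")
  c(venous = 100 * qv / tot, arterial = 100 * qa / tot)
}
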