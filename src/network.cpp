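#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the three-terminal Windkessel network.
//
// Topology (merged RAO/UAO arterial path):
//   BAI --[L1A, R1A]-- AN --[L2A, R2A]-- AJ --[RCR_RAO || RCR_UAO]-- ground
//                        \--[L1V, R1V]-- VJ --[RCR_VO]------------- ground
//
// The inlet flow Q_in(t) is prescribed, so the branch through (L1A, R1A)
// carries Q_in and only shifts P_BAI relative to P_AN. Kirchhoff at AN
// (Q_in = Q_art + Q_ven) removes one state: Q_art = Q_in - Q_ven.
//
// States: y = (Q_ven, Pc_RAO, Pc_UAO, Pc_VO), where Pc_* is the pressure at
// the capacitor node of each RCR terminal (P_terminal = Pc + R1*Q,
// C dPc/dt = Q - Pc/R2). Quadratic resistors use the sign-preserving law
// dP = R * Q * |Q|. Units: mmHg, mL/s.

struct Params {
  double r1rao, r2rao, crao, r1uao, r2uao, cuao, r1vo, r2vo, cvo;
  double l1a, l2a, l1v, r1a, r2a, r1v;
};

struct Deriv {
  double dqv, dprao, dpuao, dpvo;
  double paj, pvj, qrao, quao;
};

static inline Deriv deriv(const Params& p, double qin, double dqin,
                          double qv, double prao, double puao, double pvo) {
  Deriv d;
  const double qa = qin - qv;
  const double ga = 1.0 / p.r1rao + 1.0 / p.r1uao;
  d.paj = (qa + prao / p.r1rao + puao / p.r1uao) / ga;
  d.qrao = (d.paj - prao) / p.r1rao;
  d.quao = (d.paj - puao) / p.r1uao;
  d.dprao = (d.qrao - prao / p.r2rao) / p.crao;
  d.dpuao = (d.quao - puao / p.r2uao) / p.cuao;
  d.pvj = pvo + p.r1vo * qv;
  d.dpvo = (qv - pvo / p.r2vo) / p.cvo;
  // loop equation between the parallel AN->AJ and AN->VJ branches
  d.dqv = (p.l2a * dqin + p.r2a * qa * std::fabs(qa) + d.paj
           - p.r1v * qv * std::fabs(qv) - d.pvj) / (p.l1v + p.l2a);
  return d;
}

// qin_half/dqin_half: inflow and its derivative sampled on the half-step
// grid of one period, length 2*nsteps+1 (t = 0, dt/2, ..., T).
// [[Rcpp::export]]
List network_rk4_cpp(NumericVector qin_half, NumericVector dqin_half,
                     NumericVector wk, NumericVector internal,
                     double dt, double period, int max_cycles, double tol,
                     NumericVector init_state) {
  Params p;
  p.r1rao = wk[0]; p.r2rao = wk[1]; p.crao = wk[2];
  p.r1uao = wk[3]; p.r2uao = wk[4]; p.cuao = wk[5];
  p.r1vo  = wk[6]; p.r2vo  = wk[7]; p.cvo  = wk[8];
  p.l1a = internal[0]; p.l2a = internal[1]; p.l1v = internal[2];
  p.r1a = internal[3]; p.r2a = internal[4]; p.r1v = internal[5];

  const int nsteps = (int) std::lround(period / dt);
  if (qin_half.size() != 2 * nsteps + 1)
    stop("inflow grid length does not match dt and period");
  if (p.l1v + p.l2a <= 0.0)
    stop("L2A + L1V must be strictly positive (inductor-free networks are not supported)");

  // state: (Q_ven, Pc_RAO, Pc_UAO, Pc_VO)
  if (init_state.size() != 4) stop("init_state must have length 4");
  double qv = init_state[0], prao = init_state[1], puao = init_state[2],
    pvo = init_state[3];

  const int np = nsteps + 1;
  NumericVector pbai(np), pan(np), paj(np), pvj(np),
    qv_out(np), qrao_out(np), quao_out(np), qin_out(np);
  NumericVector pbai_prev(np);

  double residual = NA_REAL;
  int cycles = 0;
  bool converged = false;

  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    for (int i = 0; i <= nsteps; ++i) {
      const double qin = qin_half[2 * i];
      const double dqin = dqin_half[2 * i];
      // record state at step start (i) with algebraic outputs
      Deriv d0 = deriv(p, qin, dqin, qv, prao, puao, pvo);
      const double p_an = d0.pvj + p.r1v * qv * std::fabs(qv) + p.l1v * d0.dqv;
      pbai[i] = p_an + p.r1a * qin * std::fabs(qin) + p.l1a * dqin;
      pan[i] = p_an; paj[i] = d0.paj; pvj[i] = d0.pvj;
      qv_out[i] = qv; qrao_out[i] = d0.qrao; quao_out[i] = d0.quao;
      qin_out[i] = qin;
      if (i == nsteps) break;

      const double qin_h = qin_half[2 * i + 1], dqin_h = dqin_half[2 * i + 1];
      const double qin_1 = qin_half[2 * i + 2], dqin_1 = dqin_half[2 * i + 2];
      Deriv k1 = d0;
      Deriv k2 = deriv(p, qin_h, dqin_h,
                       qv + 0.5 * dt * k1.dqv, prao + 0.5 * dt * k1.dprao,
                       puao + 0.5 * dt * k1.dpuao, pvo + 0.5 * dt * k1.dpvo);
      Deriv k3 = deriv(p, qin_h, dqin_h,
                       qv + 0.5 * dt * k2.dqv, prao + 0.5 * dt * k2.dprao,
                       puao + 0.5 * dt * k2.dpuao, pvo + 0.5 * dt * k2.dpvo);
      Deriv k4 = deriv(p, qin_1, dqin_1,
                       qv + dt * k3.dqv, prao + dt * k3.dprao,
                       puao + dt * k3.dpuao, pvo + dt * k3.dpvo);
      qv   += dt / 6.0 * (k1.dqv + 2 * k2.dqv + 2 * k3.dqv + k4.dqv);
      prao += dt / 6.0 * (k1.dprao + 2 * k2.dprao + 2 * k3.dprao + k4.dprao);
      puao += dt / 6.0 * (k1.dpuao + 2 * k2.dpuao + 2 * k3.dpuao + k4.dpuao);
      pvo  += dt / 6.0 * (k1.dpvo + 2 * k2.dpvo + 2 * k3.dpvo + k4.dpvo);
    }
    cycles = cyc + 1;
    if (cyc > 0) {
      double ss = 0.0, mx = pbai[0], mn = pbai[0];
      for (int i = 0; i < np; ++i) {
        const double e = pbai[i] - pbai_prev[i];
        ss += e * e;
        if (pbai[i] > mx) mx = pbai[i];
        if (pbai[i] < mn) mn = pbai[i];
      }
      const double range = mx - mn;
      residual = std::sqrt(ss / np) / (range > 0 ? range : 1.0);
      if (residual < tol) { converged = true; break; }
    }
    pbai_prev = clone(pbai);
  }

  return List::create(
    _["pbai"] = pbai, _["pan"] = pan, _["paj"] = paj, _["pvj"] = pvj,
    _["qv"] = qv_out, _["qrao"] = qrao_out, _["quao"] = quao_out,
    _["qin"] = qin_out, _["cycles_run"] = cycles,
    _["periodicity_residual"] = residual, _["converged"] = converged);
}
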