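#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the bilateral rhythm-generator circuit.
//
// Continuous states: membrane voltage V and NaP slow inactivation h for every
// population. Discrete states: per-limb phase (stance/swing) and the
// stance-progress coordinate s, updated once per step after the RK4 update.
// Sensory feedback values are held constant within a step (they change on the
// slow limb time scale, so this costs O(dt) only at phase-switch events).

struct Net {
  int n;
  NumericVector C, gNaP, gL, ENa, EL, EsynE, EsynI;
  NumericVector VmHalf, km, VhHalf, kh, tau0, Vtau, ktau, VoutMin, VoutMax;
  IntegerVector burster;
  IntegerVector cSrc, cTgt;        // population-to-population connections
  NumericVector cW;
  IntegerVector cSign;             // +1 excitatory, -1 inhibitory
  NumericVector gE0, gI0;          // static (drive) conductances
};

static inline double outf(double V, double vmin, double vmax) {
  if (V <= vmin) return 0.0;
  if (V >= vmax) return 1.0;
  return (V - vmin) / (vmax - vmin);
}

static void rhs(const Net &net,
                const std::vector<double> &V, const std::vector<double> &h,
                const std::vector<double> &gEfb, const std::vector<double> &gIfb,
                std::vector<double> &out,
                std::vector<double> &dV, std::vector<double> &dh) {
  const int n = net.n;
  for (int i = 0; i < n; ++i)
    out[i] = outf(V[i], net.VoutMin[i], net.VoutMax[i]);
  std::vector<double> gE(n), gI(n);
  for (int i = 0; i < n; ++i) { gE[i] = net.gE0[i] + gEfb[i]; gI[i] = net.gI0[i] + gIfb[i]; }
  const int nc = net.cSrc.size();
  for (int c = 0; c < nc; ++c) {
    double contrib = net.cW[c] * out[net.cSrc[c]];
    if (net.cSign[c] > 0) gE[net.cTgt[c]] += contrib; else gI[net.cTgt[c]] += contrib;
  }
  for (int i = 0; i < n; ++i) {
    double Vi = V[i];
    double INaP = 0.0;
    if (net.burster[i]) {
      double minf = 1.0 / (1.0 + std::exp((Vi - net.VmHalf[i]) / net.km[i]));
      INaP = net.gNaP[i] * minf * h[i] * (Vi - net.ENa[i]);
    }
    double I = -INaP - net.gL[i] * (Vi - net.EL[i])
               - gE[i] * (Vi - net.EsynE[i]) - gI[i] * (Vi - net.EsynI[i]);
    dV[i] = I / net.C[i];
    if (net.burster[i]) {
      double hinf = 1.0 / (1.0 + std::exp((Vi - net.VhHalf[i]) / net.kh[i]));
      double tauh = net.tau0[i] / std::cosh((Vi - net.Vtau[i]) / net.ktau[i]);
      dh[i] = (hinf - h[i]) / tauh;
    } else {
      dh[i] = 0.0;
    }
  }
}

// [[Rcpp::export]]
List cpg_integrate_cpp(List pops, List conns, NumericVector gE0, NumericVector gI0,
                       List fb, List limbs, List control) {
  Net net;
  net.n      = as<int>(pops["n"]);
  net.C      = pops["C"];      net.gNaP  = pops["gNaP"];  net.gL   = pops["gL"];
  net.ENa    = pops["ENa"];    net.EL    = pops["EL"];
  net.EsynE  = pops["EsynE"];  net.EsynI = pops["EsynI"];
  net.VmHalf = pops["Vm_half"]; net.km   = pops["km"];
  net.VhHalf = pops["Vh_half"]; net.kh   = pops["kh"];
  net.tau0   = pops["tau0"];   net.Vtau  = pops["Vtau"];  net.ktau = pops["ktau"];
  net.VoutMin = pops["Vout_min"]; net.VoutMax = pops["Vout_max"];
  net.burster = pops["burster"];
  net.cSrc = conns["src"]; net.cTgt = conns["tgt"];
  net.cW   = conns["w"];   net.cSign = conns["sign"];
  net.gE0 = gE0; net.gI0 = gI0;

  // feedback connections: chan 0 = SF-E1-L, 1 = SF-E1-R, 2 = SF-E2-L, 3 = SF-E2-R
  IntegerVector fbChan = fb["chan"], fbTgt = fb["tgt"], fbSign = fb["sign"];
  NumericVector fbW = fb["w"];
  const int nfb = fbChan.size();

  const double thetaSw = as<double>(limbs["theta_sw"]);
  const double hyst    = as<double>(limbs["hysteresis"]);
  const double kE1     = as<double>(limbs["kE1"]);
  const double kE2     = as<double>(limbs["kE2"]);
  const double psiL    = as<double>(limbs["psiL"]);
  const double psiR    = as<double>(limbs["psiR"]);
  const double betaL   = as<double>(limbs["betaL"]);
  const double betaR   = as<double>(limbs["betaR"]);
  const int iRGF_L = as<int>(limbs["iRGF_L"]);  // 0-based, -1 if absent
  const int iRGF_R = as<int>(limbs["iRGF_R"]);
  const int iRGE_L = as<int>(limbs["iRGE_L"]);
  const int iRGE_R = as<int>(limbs["iRGE_R"]);
  int phase[2] = { as<int>(limbs["phaseL0"]), as<int>(limbs["phaseR0"]) }; // 0 stance, 1 swing
  double s[2]  = { as<double>(limbs["sL0"]), as<double>(limbs["sR0"]) };

  const double dt   = as<double>(control["dt"]);       // ms
  const long nsteps = as<double>(control["nsteps"]);
  const int every   = as<int>(control["record_every"]);
  const bool recV   = as<bool>(control["record_v"]);

  const int n = net.n;
  std::vector<double> V = as<std::vector<double> >(control["V0"]);
  std::vector<double> h = as<std::vector<double> >(control["h0"]);

  const long nrec = nsteps / every + 1;
  NumericVector tRec(nrec);
  NumericMatrix outRec(nrec, n);
  NumericMatrix vRec(recV ? nrec : 1, recV ? n : 1);
  NumericMatrix phRec(nrec, 2), sRec(nrec, 2), fbRec(nrec, 4);

  std::vector<double> gEfb(n, 0.0), gIfb(n, 0.0), out(n), dV(n), dh(n);
  std::vector<double> k1V(n), k1h(n), k2V(n), k2h(n), k3V(n), k3h(n), k4V(n), k4h(n);
  std::vector<double> Vt(n), ht(n);

  const int iRGF[2] = { iRGF_L, iRGF_R };
  const int iRGE[2] = { iRGE_L, iRGE_R };
  const double beta[2] = { betaL, betaR };
  const double psi[2] = { psiL, psiR };
  double sf[4]; // E1-L, E1-R, E2-L, E2-R (after presynaptic scaling)

  long irec = 0;
  for (long step = 0; step <= nsteps; ++step) {
    // feedback signals for this step (constant within the step)
    for (int ch = 0; ch < 4; ++ch) sf[ch] = 0.0;
    for (int side = 0; side < 2; ++side) {
      if (iRGF[side] < 0) continue;
      if (phase[side] == 0) { // stance: ramp + load feedback, presynaptically scaled
        sf[side]     = psi[side] * kE1 * s[side];
        double eout  = (iRGE[side] >= 0) ? outf(V[iRGE[side]], net.VoutMin[iRGE[side]], net.VoutMax[iRGE[side]]) : 0.0;
        sf[2 + side] = psi[side] * kE2 * eout;
      }
    }
    std::fill(gEfb.begin(), gEfb.end(), 0.0);
    std::fill(gIfb.begin(), gIfb.end(), 0.0);
    for (int c = 0; c < nfb; ++c) {
      double contrib = fbW[c] * sf[fbChan[c]];
      if (fbSign[c] > 0) gEfb[fbTgt[c]] += contrib; else gIfb[fbTgt[c]] += contrib;
    }

    if (step % every == 0) {
      tRec[irec] = step * dt;
      for (int i = 0; i < n; ++i) {
        double o = outf(V[i], net.VoutMin[i], net.VoutMax[i]);
        outRec(irec, i) = o;
        if (recV) vRec(irec, i) = V[i];
        if (!std::isfinite(V[i]))
          stop("non-finite state in population %d at t = %f ms", i + 1, step * dt);
      }
      phRec(irec, 0) = phase[0]; phRec(irec, 1) = phase[1];
      sRec(irec, 0) = s[0];      sRec(irec, 1) = s[1];
      for (int ch = 0; ch < 4; ++ch) fbRec(irec, ch) = sf[ch];
      ++irec;
    }
    if (step == nsteps) break;

    // RK4 step for (V, h)
    rhs(net, V, h, gEfb, gIfb, out, k1V, k1h);
    for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * k1V[i]; ht[i] = h[i] + 0.5 * dt * k1h[i]; }
    rhs(net, Vt, ht, gEfb, gIfb, out, k2V, k2h);
    for (int i = 0; i < n; ++i) { Vt[i] = V[i] + 0.5 * dt * k2V[i]; ht[i] = h[i] + 0.5 * dt * k2h[i]; }
    rhs(net, Vt, ht, gEfb, gIfb, out, k3V, k3h);
    for (int i = 0; i < n; ++i) { Vt[i] = V[i] + dt * k3V[i]; ht[i] = h[i] + dt * k3h[i]; }
    rhs(net, Vt, ht, gEfb, gIfb, out, k4V, k4h);
    for (int i = 0; i < n; ++i) {
      V[i] += dt / 6.0 * (k1V[i] + 2.0 * k2V[i] + 2.0 * k3V[i] + k4V[i]);
      h[i] += dt / 6.0 * (k1h[i] + 2.0 * k2h[i] + 2.0 * k3h[i] + k4h[i]);
      if (h[i] < 0.0) h[i] = 0.0; else if (h[i] > 1.0) h[i] = 1.0;
    }

    // limb state machine: belt advances s during stance; RG-F output switches phase
    for (int side = 0; side < 2; ++side) {
      if (iRGF[side] < 0) continue;
      if (phase[side] == 0) s[side] += beta[side] * dt / 1000.0; // s in belt units, t in s
      double fo = outf(V[iRGF[side]], net.VoutMin[iRGF[side]], net.VoutMax[iRGF[side]]);
      if (phase[side] == 0 && fo > thetaSw + hyst) {
        phase[side] = 1;                       // swing onset
      } else if (phase[side] == 1 && fo < thetaSw - hyst) {
        phase[side] = 0; s[side] = 0.0;        // stance onset: progress resets
      }
    }
  }

  return List::create(_["time"] = tRec, _["out"] = outRec,
                      _["V"] = recV ? (SEXP)vRec : R_NilValue,
                      _["phase"] = phRec, _["s"] = sRec, _["feedback"] = fbRec,
                      _["V_final"] = NumericVector(V.begin(), V.end()),
                      _["h_final"] = NumericVector(h.begin(), h.end()));
}
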