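// Compiled core: coupled PBK right-hand side (bile acid + bosentan + RO 47-8634)
// and an adaptive Dormand-Prince 5(4) integrator with hard event restarts.
//
// State layout (amounts, µmol):
//   0 AL   liver (BA)             9 DDEP  bosentan gut depot     17 MB  RO blood
//   1 AG   gall bladder          10 DB    bosentan blood         18 ML  RO liver
//   2 AI   intestinal lumen      11 DL    bosentan liver         19 MR  RO rapidly perf.
//   3 AIT  intestinal tissue     12 DR    bosentan rapidly perf. 20 MS  RO slowly perf.
//   4 AB   blood                 13 DS    bosentan slowly perf.  21 MF  RO adipose
//   5 AR   rapidly perfused      14 DF    bosentan adipose       22 MBIL RO biliary sink
//   6 AS   slowly perfused       15 DMET  other-metabolite sink
//   7 AF   adipose               16 DBIL  bosentan biliary sink
//   8 AFEC fecal sink
//
// Tissue exchange is perfusion-limited; the model runs on whole-blood
// concentrations with tissue:blood partitions K = P_tissue:plasma / BP.
// "Free" liver concentrations driving the Michaelis-Menten / inhibition terms
// are venous plasma-equivalent: CVL = A_liver / (V_L * P_liver).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#define NSTATE 23

struct Pars {
  // physiology
  double VB, VL, VIT, VR, VS, VF;
  double QLa, QIT, QR, QS, QF, QC, QLtot;
  // bile acid
  double KL, KIT, KR, KS, KF;     // tissue:blood partitions
  double PL;                      // liver tissue:plasma (free conc denominator)
  double synth, qfec, kfec_clamp, QIb, ka;
  double VmaxB, KmB;
  // bosentan
  double kad, VmaxM, KmM, CLM, frm, kbb;
  double KLb, KRb, KSb, KFb, PLb;
  // RO 47-8634
  double kbm;
  double KLm, KRm, KSm, KFm, PLm;
  // inhibition
  double Kib, Kim;
  // switches / guards
  bool ba_on, drug_on, inhib_on;
  double negtol;
};

static double getp(const NumericVector& p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing engine parameter '%s'", nm);
  return as<double>(p[nm]);
}

static Pars make_pars(const NumericVector& p) {
  Pars q;
  q.VB = getp(p, "VB"); q.VL = getp(p, "VL"); q.VIT = getp(p, "VIT");
  q.VR = getp(p, "VR"); q.VS = getp(p, "VS"); q.VF = getp(p, "VF");
  q.QLa = getp(p, "QLa"); q.QIT = getp(p, "QIT"); q.QR = getp(p, "QR");
  q.QS = getp(p, "QS"); q.QF = getp(p, "QF");
  q.QLtot = q.QLa + q.QIT;
  q.QC = q.QLtot + q.QR + q.QS + q.QF;
  q.KL = getp(p, "KL"); q.KIT = getp(p, "KIT"); q.KR = getp(p, "KR");
  q.KS = getp(p, "KS"); q.KF = getp(p, "KF"); q.PL = getp(p, "PL");
  q.synth = getp(p, "synth"); q.qfec = getp(p, "qfec");
  q.kfec_clamp = getp(p, "kfec_clamp");
  q.QIb = getp(p, "QIb"); q.ka = getp(p, "ka");
  q.VmaxB = getp(p, "VmaxB"); q.KmB = getp(p, "KmB");
  q.kad = getp(p, "kad"); q.VmaxM = getp(p, "VmaxM"); q.KmM = getp(p, "KmM");
  q.CLM = getp(p, "CLM"); q.frm = getp(p, "frm"); q.kbb = getp(p, "kbb");
  q.KLb = getp(p, "KLb"); q.KRb = getp(p, "KRb"); q.KSb = getp(p, "KSb");
  q.KFb = getp(p, "KFb"); q.PLb = getp(p, "PLb");
  q.kbm = getp(p, "kbm");
  q.KLm = getp(p, "KLm"); q.KRm = getp(p, "KRm"); q.KSm = getp(p, "KSm");
  q.KFm = getp(p, "KFm"); q.PLm = getp(p, "PLm");
  q.Kib = getp(p, "Kib"); q.Kim = getp(p, "Kim");
  q.ba_on = getp(p, "ba_on") > 0.5;
  q.drug_on = getp(p, "drug_on") > 0.5;
  q.inhib_on = getp(p, "inhib_on") > 0.5;
  q.negtol = getp(p, "negtol");
  return q;
}

static void rhs(const Pars& P, const double* y, double* dy) {
  for (int i = 0; i < NSTATE; ++i) dy[i] = 0.0;

  double CVLb_free = 0.0, CVLm_free = 0.0;

  if (P.drug_on) {
    // bosentan
    double CAb  = y[10] / P.VB;
    double CVLb = y[11] / (P.VL * P.KLb);
    double CVRb = y[12] / (P.VR * P.KRb);
    double CVSb = y[13] / (P.VS * P.KSb);
    double CVFb = y[14] / (P.VF * P.KFb);
    CVLb_free   = y[11] / (P.VL * P.PLb);
    double vmet = P.VmaxM * CVLb_free / (P.KmM + CVLb_free) + P.CLM * CVLb_free;
    double absd = P.kad * y[9];
    dy[9]  = -absd;
    dy[10] = P.QLtot * CVLb + P.QR * CVRb + P.QS * CVSb + P.QF * CVFb - P.QC * CAb;
    dy[11] = P.QLtot * (CAb - CVLb) + absd - vmet - P.kbb * y[11];
    dy[12] = P.QR * (CAb - CVRb);
    dy[13] = P.QS * (CAb - CVSb);
    dy[14] = P.QF * (CAb - CVFb);
    dy[15] = (1.0 - P.frm) * vmet;
    dy[16] = P.kbb * y[11];
    // RO 47-8634 (formed 1:1 from the routed fraction of bosentan turnover)
    double CAm  = y[17] / P.VB;
    double CVLm = y[18] / (P.VL * P.KLm);
    double CVRm = y[19] / (P.VR * P.KRm);
    double CVSm = y[20] / (P.VS * P.KSm);
    double CVFm = y[21] / (P.VF * P.KFm);
    CVLm_free   = y[18] / (P.VL * P.PLm);
    dy[17] = P.QLtot * CVLm + P.QR * CVRm + P.QS * CVSm + P.QF * CVFm - P.QC * CAm;
    dy[18] = P.QLtot * (CAm - CVLm) + P.frm * vmet - P.kbm * y[18];
    dy[19] = P.QR * (CAm - CVRm);
    dy[20] = P.QS * (CAm - CVSm);
    dy[21] = P.QF * (CAm - CVFm);
    dy[22] = P.kbm * y[18];
  }

  if (P.ba_on) {
    double CA   = y[4] / P.VB;
    double CVL  = y[0] / (P.VL * P.KL);
    double CVIT = y[3] / (P.VIT * P.KIT);
    double CVR  = y[5] / (P.VR * P.KR);
    double CVS  = y[6] / (P.VS * P.KS);
    double CVF  = y[7] / (P.VF * P.KF);
    double Cfree = y[0] / (P.VL * P.PL);
    double vmax_eff = P.VmaxB;
    if (P.inhib_on)
      vmax_eff /= (1.0 + CVLb_free / P.Kib + CVLm_free / P.Kim);
    double E    = vmax_eff * Cfree / (P.KmB + Cfree);
    double absr = P.ka * y[2];
    double fec  = P.qfec * y[2] / (y[2] + P.kfec_clamp);
    dy[0] = P.QLa * CA + P.QIT * CVIT - P.QLtot * CVL + P.synth - E;
    dy[1] = (1.0 - P.QIb) * E;
    dy[2] = P.QIb * E - absr - fec;
    dy[3] = P.QIT * (CA - CVIT) + absr;
    dy[4] = P.QLtot * CVL + P.QR * CVR + P.QS * CVS + P.QF * CVF - P.QC * CA;
    dy[5] = P.QR * (CA - CVR);
    dy[6] = P.QS * (CA - CVS);
    dy[7] = P.QF * (CA - CVF);
    dy[8] = fec;
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector y0, NumericVector pars,
                           NumericMatrix events, NumericVector tout,
                           double rtol, double atol) {
  const Pars P = make_pars(pars);
  const int nt = tout.size();
  NumericMatrix out(nt, NSTATE);

  double y[NSTATE], ynew[NSTATE], ytmp[NSTATE];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
         k6[NSTATE], k7[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  double t = tout[0];
  const double tend = tout[nt - 1];
  int ig = 0;
  // leading output points at/before t0
  while (ig < nt && tout[ig] <= t + 1e-12) {
    for (int i = 0; i < NSTATE; ++i) out(ig, i) = y[i];
    ++ig;
  }

  // segment boundaries: event times inside (t, tend], then tend
  std::vector<double> bnd;
  std::vector<int> evrow;
  for (int r = 0; r < events.nrow(); ++r) {
    double te = events(r, 0);
    if (te > t + 1e-12 && te <= tend + 1e-12) { bnd.push_back(te); evrow.push_back(r); }
  }
  bnd.push_back(tend); evrow.push_back(-1);

  rhs(P, y, k1);
  double h = 1e-3;
  const double hmin = 1e-11, tol_t = 1e-10;

  for (size_t seg = 0; seg < bnd.size(); ++seg) {
    double tseg = bnd[seg];
    while (t < tseg - tol_t) {
      if (h > tseg - t) h = tseg - t;
      if (h < hmin) stop("integration failure: step size underflow at t = %f h", t);

      for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      rhs(P, ytmp, k2);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      rhs(P, ytmp, k3);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      rhs(P, ytmp, k4);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      rhs(P, ytmp, k5);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      rhs(P, ytmp, k6);
      for (int i = 0; i < NSTATE; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      rhs(P, ynew, k7);

      double err = 0.0;
      for (int i = 0; i < NSTATE; ++i) {
        double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double r = ei / sc;
        err += r * r;
      }
      err = std::sqrt(err / NSTATE);

      if (err <= 1.0 || h <= hmin * 2) {
        // accept; cubic Hermite dense output on (t, t+h]
        double tnew = t + h;
        while (ig < nt && tout[ig] <= tnew + tol_t &&
               (tout[ig] < tseg - tol_t || std::fabs(tseg - tend) < tol_t)) {
          double th = (tout[ig] - t) / h;
          double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
          double h10 = th * (1 - th) * (1 - th);
          double h01 = th * th * (3 - 2 * th);
          double h11 = th * th * (th - 1);
          for (int i = 0; i < NSTATE; ++i)
            out(ig, i) = h00 * y[i] + h10 * h * k1[i] + h01 * ynew[i] +
                         h11 * h * k7[i];
          ++ig;
        }
        for (int i = 0; i < NSTATE; ++i) {
          y[i] = ynew[i];
          k1[i] = k7[i];  // FSAL
        }
        // negative-amount guard (stiff-solver noise is clamped, real
        // negativity raises)
        bool redo_f = false;
        for (int i = 0; i < NSTATE; ++i) {
          if (y[i] < 0) {
            if (y[i] < -P.negtol)
              stop("state-validity error: compartment %d = %g at t = %f h",
                   i + 1, y[i], tnew);
            y[i] = 0.0;
            redo_f = true;
          }
        }
        if (redo_f) rhs(P, y, k1);
        t = tnew;
      }
      double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < hmin) h = hmin;
    }
    // segment boundary reached: apply event (if any), then emit boundary
    // grid points with the post-event state
    int r = evrow[seg];
    if (r >= 0) {
      int type = (int)events(r, 1);
      double val = events(r, 2);
      if (type == 1) {            // gall-bladder emptying: pure transfer
        y[2] += y[1];
        y[1] = 0.0;
      } else if (type == 2) {     // oral bosentan dose into gut depot (µmol)
        y[9] += val;
      } else {
        stop("unknown event type %d", type);
      }
      rhs(P, y, k1);
    }
    while (ig < nt && tout[ig] <= tseg + tol_t) {
      for (int i = 0; i < NSTATE; ++i) out(ig, i) = y[i];
      ++ig;
    }
  }
  return out;
}
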