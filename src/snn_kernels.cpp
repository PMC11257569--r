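#include <Rcpp.h>
using namespace Rcpp;

// Time-recursion kernels for the spiking layers. The surrounding
// orchestration (weight matmuls, readout convolutions, Adam) stays in R;
// only the per-step state updates, which cannot be vectorized over time
// because of the spike reset, live here.

// Forward pass of one alpha (spike-response) layer.
// current: Nt x n input current. Returns pre-reset traces E, I, U and the
// binary spike matrix S (hard = true) or soft spikes (hard = false, no
// reset; used for gradient validation).
// [[Rcpp::export(name = ".layerForwardAlphaCpp")]]
List layerForwardAlphaCpp(NumericMatrix current, NumericVector alpha,
                          NumericVector beta, NumericVector uThr,
                          double slope, bool hard) {
  int nt = current.nrow(), n = current.ncol();
  NumericMatrix E(nt, n), I(nt, n), U(nt, n), S(nt, n);
  std::vector<double> ta(n), e(n, 0.0), ii(n, 0.0);
  for (int j = 0; j < n; ++j) {
    ta[j] = std::log(alpha[j]) / (std::log(beta[j]) - std::log(alpha[j])) + 1.0;
  }
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < n; ++j) {
      double e1 = alpha[j] * e[j] + current(t, j);
      double i1 = beta[j] * ii[j] - current(t, j);
      double u = ta[j] * (e1 + i1);
      double s;
      if (hard) {
        s = (u > uThr[j]) ? 1.0 : 0.0;
      } else {
        double x = u - uThr[j];
        s = 0.5 * (1.0 + x / (1.0 + slope * std::fabs(x)));
      }
      E(t, j) = e1; I(t, j) = i1; U(t, j) = u; S(t, j) = s;
      double kp = hard ? (1.0 - s) : 1.0;
      e[j] = e1 * kp; ii[j] = i1 * kp;
    }
  }
  return List::create(_["E"] = E, _["I"] = I, _["U"] = U, _["S"] = S);
}

// Forward pass of one LIF layer.
// [[Rcpp::export(name = ".layerForwardLifCpp")]]
List layerForwardLifCpp(NumericMatrix current, NumericVector beta,
                        NumericVector uThr, double slope, bool hard) {
  int nt = current.nrow(), n = current.ncol();
  NumericMatrix U(nt, n), S(nt, n);
  std::vector<double> u(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < n; ++j) {
      double u1 = beta[j] * u[j] + current(t, j);
      double s;
      if (hard) {
        s = (u1 > uThr[j]) ? 1.0 : 0.0;
      } else {
        double x = u1 - uThr[j];
        s = 0.5 * (1.0 + x / (1.0 + slope * std::fabs(x)));
      }
      U(t, j) = u1; S(t, j) = s;
      u[j] = hard ? u1 * (1.0 - s) : u1;
    }
  }
  return List::create(_["U"] = U, _["S"] = S);
}

static inline double surr(double x, double slope) {
  double d = 1.0 + slope * std::fabs(x);
  return 1.0 / (d * d);
}

// Adjoint sweep of one alpha layer. gS: dL/dS. Resets detached.
// [[Rcpp::export(name = ".layerBackwardAlphaCpp")]]
List layerBackwardAlphaCpp(NumericMatrix gS, NumericMatrix E,
                           NumericMatrix I, NumericMatrix U,
                           NumericMatrix S, NumericVector alpha,
                           NumericVector beta, NumericVector uThr,
                           double slope, bool hard) {
  int nt = gS.nrow(), n = gS.ncol();
  NumericMatrix gIin(nt, n);
  NumericVector gAlpha(n), gBeta(n);
  for (int j = 0; j < n; ++j) {
    double la = std::log(alpha[j]), lb = std::log(beta[j]);
    double den = (lb - la) * (lb - la);
    double ta = la / (lb - la) + 1.0;
    double dTadA = lb / (alpha[j] * den);
    double dTadB = -la / (beta[j] * den);
    double gE = 0.0, gI = 0.0, sumGU_U = 0.0, gA = 0.0, gB = 0.0;
    for (int t = nt - 1; t >= 0; --t) {
      double sg = surr(U(t, j) - uThr[j], slope);
      if (!hard) sg *= 0.5;
      double gU = gS(t, j) * sg;
      sumGU_U += gU * U(t, j);
      gE += ta * gU;
      gI += ta * gU;
      gIin(t, j) = gE - gI;
      if (t > 0) {
        double kp = hard ? (1.0 - S(t - 1, j)) : 1.0;
        gA += gE * E(t - 1, j) * kp;
        gB += gI * I(t - 1, j) * kp;
        gE *= alpha[j] * kp;
        gI *= beta[j] * kp;
      }
    }
    gAlpha[j] = gA + sumGU_U / ta * dTadA;
    gBeta[j] = gB + sumGU_U / ta * dTadB;
  }
  return List::create(_["gIin"] = gIin, _["gAlpha"] = gAlpha,
                      _["gBeta"] = gBeta);
}

// Adjoint sweep of one LIF layer.
// [[Rcpp::export(name = ".layerBackwardLifCpp")]]
List layerBackwardLifCpp(NumericMatrix gS, NumericMatrix U, NumericMatrix S,
                         NumericVector beta, NumericVector uThr,
                         double slope, bool hard) {
  int nt = gS.nrow(), n = gS.ncol();
  NumericMatrix gIin(nt, n);
  NumericVector gBeta(n);
  for (int j = 0; j < n; ++j) {
    double gU = 0.0, gB = 0.0;
    for (int t = nt - 1; t >= 0; --t) {
      double sg = surr(U(t, j) - uThr[j], slope);
      if (!hard) sg *= 0.5;
      gU += gS(t, j) * sg;
      gIin(t, j) = gU;
      if (t > 0) {
        double kp = hard ? (1.0 - S(t - 1, j)) : 1.0;
        gB += gU * U(t - 1, j) * kp;
        gU *= beta[j] * kp;
      }
    }
    gBeta[j] = gB;
  }
  return List::create(_["gIin"] = gIin, _["gBeta"] = gBeta);
}
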