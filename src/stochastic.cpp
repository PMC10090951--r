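#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler integration of the coupled GTPase circuit with
// Ornstein-Uhlenbeck noise channels. The OU channels are advanced with the
// printed update rule eta += -eta*dt + sigma*dW + 0.5*sigma^2*(dW^2 - dt)
// (scheme 0) or plain Euler-Maruyama (scheme 1), both scaled by 1/tauNoise
// for general relaxation times. State variables are advanced by the Euler
// scheme. Channel order per step is fixed: stimulus; then species channels
// (mGEF, mGAP, mGstar, tGEF, tGstar, S, X, tGAP) when mode >= 1; then
// connection channels (fact1..fact9, S2, X) when mode == 2. Wiener
// increments are drawn from R's RNG so set.seed() controls reproducibility.

static inline double nhill(double x, double B, double Kn, double n) {
  if (!(x > 0.0)) return 0.0;       // x <= 0 (or NaN guarded upstream)
  if (x >= 1.0) return 1.0;
  double xn = std::pow(x, n);
  return B * xn / (Kn + xn);
}

// [[Rcpp::export(name = ".stochasticEngine")]]
List stochasticEngine(NumericVector init, double stimulus,
                      List par, int variantCode, int gateCode,
                      int mode, double sigmaSti, double tauNoise,
                      NumericVector sigmaSpe, NumericVector sigmaLink,
                      double dt, int nSteps, int saveEvery, int scheme) {
  NumericVector tau = par["tau"], k = par["k"], ymax = par["ymax"];
  NumericVector sec = par["secretion"], cell = par["cell"], orG = par["orGate"];
  NumericVector B = par["B"], K = par["K"], n = par["n"];
  double tGAP = as<double>(par["tGAP"]);

  double Kn[9];
  for (int i = 0; i < 9; ++i) Kn[i] = std::pow(K[i], n[i]);

  double s[7];
  for (int i = 0; i < 7; ++i) s[i] = init[i];

  const bool speciesNoise = (mode == 1);
  const bool linkNoise = (mode == 2);

  double etaSti = 0.0;
  double etaSpe[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double etaLink[11] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0};

  int nSave = nSteps / saveEvery + 1;
  NumericMatrix out(nSave, 7);
  NumericVector tOut(nSave);
  int iSave = 0, nFloored = 0;
  for (int j = 0; j < 7; ++j) out(0, j) = s[j];
  tOut[0] = 0.0;
  iSave = 1;

  const double sqrtdt = std::sqrt(dt);
  for (int step = 0; step < nSteps; ++step) {
    // advance OU channels (fixed order; one Wiener increment per channel)
    {
      double dW = norm_rand() * sqrtdt;
      double corr = (scheme == 0) ? 0.5 * sigmaSti * sigmaSti * (dW * dW - dt)
                                  : 0.0;
      etaSti += (-etaSti * dt + sigmaSti * dW + corr) / tauNoise;
    }
    if (speciesNoise) {
      for (int c = 0; c < 8; ++c) {
        double sg = sigmaSpe[c];
        double dW = norm_rand() * sqrtdt;
        double corr = (scheme == 0) ? 0.5 * sg * sg * (dW * dW - dt) : 0.0;
        etaSpe[c] += (-etaSpe[c] * dt + sg * dW + corr) / tauNoise;
      }
    }
    if (linkNoise) {
      for (int c = 0; c < 11; ++c) {
        double sg = sigmaLink[c];
        double dW = norm_rand() * sqrtdt;
        double corr = (scheme == 0) ? 0.5 * sg * sg * (dW * dW - dt) : 0.0;
        etaLink[c] += (-etaLink[c] * dt + sg * dW + corr) / tauNoise;
      }
    }

    double mGEF = s[0], mGAP = s[1], mGstar = s[2], tGEF = s[3],
           tGstar = s[4], S = s[5], X = s[6];

    double f1 = nhill(stimulus + etaSti, B[0], Kn[0], n[0]);
    double f2 = nhill(tGEF, B[1], Kn[1], n[1]);
    double f3 = nhill(tGstar, B[2], Kn[2], n[2]);
    double f4 = nhill(mGEF, B[3], Kn[3], n[3]);
    double f5 = nhill(mGAP, B[4], Kn[4], n[4]);
    double f6 = nhill(mGstar, B[5], Kn[5], n[5]);
    double f7 = nhill(tGEF, B[6], Kn[6], n[6]);
    double tGAPeff = speciesNoise ? tGAP + etaSpe[7] : tGAP;
    double f8 = nhill(tGAPeff, B[7], Kn[7], n[7]);
    double f9 = nhill(mGAP, B[8], Kn[8], n[8]);

    if (linkNoise) {
      f1 += etaLink[0]; f2 += etaLink[1]; f3 += etaLink[2]; f4 += etaLink[3];
      f5 += etaLink[4]; f6 += etaLink[5]; f7 += etaLink[6]; f8 += etaLink[7];
      // fact9 channel (etaLink[8]) enters the secretion rate sum below
    }

    double drive;
    if (variantCode == 1) drive = 0.0;                       // single switch
    else if (gateCode == 0) drive = f2 * f3;                 // AND
    else drive = orG[0] * f2 + orG[1] * f3;                  // OR

    double dmGEF = ((f1 + k[0]) * ymax[0] - mGEF);
    double dmGAP = ((drive + k[1]) * ymax[1] - mGAP);
    double dmGstar = ((f4 + k[2]) * (1.0 - mGstar) - f5 * mGstar);
    double dtGEF = ((f6 + k[3]) * ymax[2] - tGEF);
    double dtGstar = ((f7 + k[4]) * (1.0 - tGstar) - f8 * tGstar);
    if (speciesNoise) {
      dmGEF += etaSpe[0]; dmGAP += etaSpe[1]; dmGstar += etaSpe[2];
      dtGEF += etaSpe[3]; dtGstar += etaSpe[4];
    }
    dmGEF /= tau[0]; dmGAP /= tau[1]; dmGstar /= tau[2];
    dtGEF /= tau[3]; dtGstar /= tau[4];

    double secRate = sec[0] * f9 + sec[1];                   // beta_S f9 + k_S
    double endo = sec[2] * S / (S + sec[4]);                 // alpha_S S/(S+K2)
    if (linkNoise) { secRate += etaLink[8]; endo -= etaLink[9]; }
    double dS = (secRate - endo) * X - sec[3] * S;
    double prolif = cell[0] * S / (S + cell[2]) * (1.0 - X / cell[3]);
    if (linkNoise) prolif += etaLink[10];
    double dX = prolif - cell[1] * X;
    if (speciesNoise) { dS += etaSpe[5]; dX += etaSpe[6]; }

    s[0] = mGEF + dt * dmGEF;
    s[1] = mGAP + dt * dmGAP;
    s[2] = mGstar + dt * dmGstar;
    s[3] = tGEF + dt * dtGEF;
    s[4] = tGstar + dt * dtGstar;
    s[5] = S + dt * dS;
    s[6] = X + dt * dX;
    if (s[5] < 0.0) { s[5] = 0.0; ++nFloored; }
    if (s[6] < 0.0) { s[6] = 0.0; ++nFloored; }

    for (int j = 0; j < 7; ++j) {
      if (!R_finite(s[j]))
        stop("non-finite state at step %d (variable %d)", step + 1, j + 1);
    }

    if ((step + 1) % saveEvery == 0 && iSave < nSave) {
      for (int j = 0; j < 7; ++j) out(iSave, j) = s[j];
      tOut[iSave] = (step + 1) * dt;
      ++iSave;
    }
  }

  return List::create(_["time"] = tOut, _["states"] = out,
                      _["nFloored"] = nFloored);
}
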