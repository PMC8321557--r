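#include <Rcpp.h>
using namespace Rcpp;

// Batched Euler-Maruyama integration of the five-neuron STG subcircuit.
// All randomness (initial voltages, current noise) is drawn in R and passed
// in, so results are bit-identical to the reference R implementation.
//
// zMat: B x 2 (g_el, g_synA in nS); x0: B x 5 initial voltages (mV);
// noise: B x 5 x nSteps standard normals. Returns hub trace (B x nSteps)
// and, optionally, the full voltage array.
// [[Rcpp::export(name = ".stgSimulateCpp")]]
List stgSimulateCpp(NumericMatrix zMat, int nSteps, double dt,
                    NumericMatrix x0, NumericVector noise, double noiseSd,
                    bool fullTrace) {
  const int B = zMat.nrow();
  const double Cm = 1.0, gLeak = 1e-4;
  const double gCa[5] = {1.9e-2, 1.9e-2, 1.7e-2, 8.5e-3, 8.5e-3};
  const double gK[5]  = {3.9e-2, 3.9e-2, 1.9e-2, 1.5e-2, 1.5e-2};
  const double gH[5]  = {2.5e-2, 2.5e-2, 8.0e-3, 1.0e-2, 1.0e-2};
  const double VLeak = -40.0, VCa = 100.0, VK = -80.0, VHyp = -20.0,
               VSyn = -75.0;
  const double v1 = 0.0, v2 = 20.0, v3 = 0.0, v4 = 15.0, v5 = 78.3,
               v6 = 10.5, v7 = -42.2, v8 = 87.3, v9 = 5.0, vth = -25.0;
  const double phiN = 0.002, gSynB = 5e-3;
  const double sqdt = std::sqrt(dt);

  std::vector<double> x(B * 5), N(B * 5), H(B * 5);
  for (int b = 0; b < B; ++b)
    for (int j = 0; j < 5; ++j) {
      double xv = x0(b, j);
      x[b + B * j] = xv;
      N[b + B * j] = 0.5 * (1.0 + std::tanh((xv - v3) / v4));
      H[b + B * j] = 1.0 / (1.0 + std::exp((xv + v5) / v6));
    }

  NumericMatrix hub(B, nSteps);
  NumericVector full;
  if (fullTrace) {
    full = NumericVector(Dimension(B, 5, nSteps));
  }
  std::vector<double> I(B * 5), Sinf(B * 5);
  const double *np = noise.begin();

  for (int t = 0; t < nSteps; ++t) {
    for (int j = 0; j < 5; ++j) {
      for (int b = 0; b < B; ++b) {
        const int k = b + B * j;
        const double xv = x[k];
        const double Minf = 0.5 * (1.0 + std::tanh((xv - v1) / v2));
        Sinf[k] = 1.0 / (1.0 + std::exp((vth - xv) / v9));
        I[k] = gLeak * (xv - VLeak) + gCa[j] * Minf * (xv - VCa) +
               gK[j] * N[k] * (xv - VK) + gH[j] * H[k] * (xv - VHyp);
      }
    }
    for (int b = 0; b < B; ++b) {
      const double gel = zMat(b, 0) * 1e-3, gsA = zMat(b, 1) * 1e-3;
      const double xf1 = x[b], xf2 = x[b + B], xh = x[b + 2 * B],
                   xs1 = x[b + 3 * B], xs2 = x[b + 4 * B];
      // electrical coupling: f1<->hub, s1<->hub
      I[b] += gel * (xf1 - xh);
      I[b + 3 * B] += gel * (xs1 - xh);
      I[b + 2 * B] += gel * (xh - xf1) + gel * (xh - xs1);
      // synaptic: mutual inhibition in pairs; f2, s2 inhibit the hub
      I[b] += gSynB * Sinf[b + B] * (xf1 - VSyn);
      I[b + B] += gSynB * Sinf[b] * (xf2 - VSyn);
      I[b + 3 * B] += gSynB * Sinf[b + 4 * B] * (xs1 - VSyn);
      I[b + 4 * B] += gSynB * Sinf[b + 3 * B] * (xs2 - VSyn);
      I[b + 2 * B] += gsA * Sinf[b + B] * (xh - VSyn) +
                      gsA * Sinf[b + 4 * B] * (xh - VSyn);
    }
    for (int j = 0; j < 5; ++j) {
      for (int b = 0; b < B; ++b) {
        const int k = b + B * j;
        const double xv = x[k];
        const double Ninf = 0.5 * (1.0 + std::tanh((xv - v3) / v4));
        const double lamN = phiN * std::cosh((xv - v3) / (2.0 * v4));
        const double Hinf = 1.0 / (1.0 + std::exp((xv + v5) / v6));
        const double tauH =
            272.0 + 1499.0 / (1.0 + std::exp((-xv + v7) / v8));
        const double xn = xv + dt * (-I[k] / Cm) +
                          sqdt * noiseSd / Cm *
                              np[b + (size_t)B * (j + 5 * (size_t)t)];
        if (!std::isfinite(xn))
          stop("stgSimulateBatch: non-finite state at step %d", t + 1);
        x[k] = xn;
        N[k] += dt * lamN * (Ninf - N[k]);
        H[k] += dt * (Hinf - H[k]) / tauH;
      }
    }
    for (int b = 0; b < B; ++b) hub(b, t) = x[b + 2 * B];
    if (fullTrace) {
      double *fp = full.begin();
      for (int j = 0; j < 5; ++j)
        for (int b = 0; b < B; ++b)
          fp[b + (size_t)B * (j + 5 * (size_t)t)] = x[b + B * j];
    }
  }
  if (fullTrace) return List::create(_["hub"] = hub, _["full"] = full);
  return List::create(_["hub"] = hub);
}
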