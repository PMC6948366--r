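#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis-Hastings sampler for the ball-and-stick model with up to two
// sticks per voxel:
//
//   mu_j = S0 [ (1 - f1 - f2) exp(-b_j d)
//               + f1 exp(-b_j d (g_j . v1)^2)
//               + f2 exp(-b_j d (g_j . v2)^2) ]
//
// with Gaussian measurement noise of precision tau (Gibbs-updated with a
// vague Gamma prior), a Gamma prior on the diffusivity d, a uniform-on-the-
// simplex base prior on (f1, f2) optionally sharpened by an automatic
// relevance determination (ARD) term  log p(f) += -log f  that shrinks
// unsupported sticks to zero, and a uniform-on-the-sphere prior on each
// stick orientation (polar/azimuth parameterisation, hence a sin(theta)
// density term). Proposal standard deviations adapt during burn-in toward
// a 0.44 acceptance rate.
//
// The three compartment signals (ball, stick 1, stick 2) are cached so a
// proposal only recomputes the compartment it touches.

struct VoxState {
  // parameters: 0 s0, 1 d, 2 f1, 3 f2, 4 th1, 5 ph1, 6 th2, 7 ph2
  double p[8];
  std::vector<double> eball, e1, e2; // attenuation per measurement
  double ssr;
};

static void comp_ball(const double *b, int n, double d, double *out) {
  for (int j = 0; j < n; j++) out[j] = std::exp(-b[j] * d);
}
static void comp_stick(const double *b, const double *gx, const double *gy,
                       const double *gz, int n, double d, double th, double ph,
                       double *out) {
  double vx = std::sin(th) * std::cos(ph), vy = std::sin(th) * std::sin(ph),
         vz = std::cos(th);
  for (int j = 0; j < n; j++) {
    double c = gx[j] * vx + gy[j] * vy + gz[j] * vz;
    out[j] = std::exp(-b[j] * d * c * c);
  }
}
static double ssr_of(const double *y, int n, double s0, double f1, double f2,
                     const double *eball, const double *e1, const double *e2) {
  double fiso = 1.0 - f1 - f2, s = 0.0;
  for (int j = 0; j < n; j++) {
    double r = y[j] - s0 * (fiso * eball[j] + f1 * e1[j] + f2 * e2[j]);
    s += r * r;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_bedpost(NumericMatrix Y, NumericVector bvals, NumericMatrix bvecs,
                 int njumps, int burnin, int thin,
                 double d_shape, double d_rate, bool ard_f1, bool ard_f2,
                 double sigma_floor_frac) {
  const int n = Y.nrow();      // measurements per voxel
  const int nvox = Y.ncol();
  const int K = njumps / thin; // retained samples
  const double FMIN = 1e-6;    // ARD prior is improper at f = 0

  std::vector<double> b(bvals.begin(), bvals.end());
  std::vector<double> gx(n), gy(n), gz(n);
  for (int j = 0; j < n; j++) {
    gx[j] = bvecs(0, j); gy[j] = bvecs(1, j); gz[j] = bvecs(2, j);
  }
  int nb0 = 0;
  for (int j = 0; j < n; j++) if (b[j] == 0.0) nb0++;

  NumericMatrix out_f1(K, nvox), out_f2(K, nvox), out_d(K, nvox),
      out_s0(K, nvox), out_th1(K, nvox), out_ph1(K, nvox), out_th2(K, nvox),
      out_ph2(K, nvox);
  NumericVector out_acc(nvox);
  LogicalVector out_bad(nvox);

  VoxState st;
  st.eball.resize(n); st.e1.resize(n); st.e2.resize(n);
  std::vector<double> tmp(n), y(n);
  RNGScope scope;

  for (int vox = 0; vox < nvox; vox++) {
    for (int j = 0; j < n; j++) y[j] = Y(j, vox);

    double s0init = 0.0;
    if (nb0 > 0) {
      for (int j = 0; j < n; j++) if (b[j] == 0.0) s0init += y[j];
      s0init /= nb0;
    }
    if (!(s0init > 0.0)) {  // unusable voxel: emit zeros, flag
      out_bad[vox] = true;
      continue;
    }

    // initial stick orientation: gradient of strongest attenuation
    int jmin = -1; double ymin = R_PosInf;
    for (int j = 0; j < n; j++)
      if (b[j] > 0.0 && y[j] < ymin) { ymin = y[j]; jmin = j; }
    double *p = st.p;
    p[0] = s0init; p[1] = 1e-3; p[2] = 0.3; p[3] = 0.05;
    if (jmin >= 0) {
      p[4] = std::acos(std::max(-1.0, std::min(1.0, gz[jmin])));
      p[5] = std::atan2(gy[jmin], gx[jmin]);
    } else { p[4] = M_PI / 2; p[5] = 0.0; }
    // second stick: most-attenuated direction at least 45 degrees away
    // from the first (falls back to orthogonal)
    p[6] = p[4] + M_PI / 2; p[7] = p[5];
    if (jmin >= 0) {
      double v1x = std::sin(p[4]) * std::cos(p[5]),
             v1y = std::sin(p[4]) * std::sin(p[5]), v1z = std::cos(p[4]);
      int jmin2 = -1; double ymin2 = R_PosInf;
      for (int j = 0; j < n; j++) {
        if (b[j] <= 0.0) continue;
        double c = std::fabs(gx[j] * v1x + gy[j] * v1y + gz[j] * v1z);
        if (c < 0.7071 && y[j] < ymin2) { ymin2 = y[j]; jmin2 = j; }
      }
      if (jmin2 >= 0) {
        p[6] = std::acos(std::max(-1.0, std::min(1.0, gz[jmin2])));
        p[7] = std::atan2(gy[jmin2], gx[jmin2]);
      }
    }

    comp_ball(b.data(), n, p[1], st.eball.data());
    comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, p[1], p[4], p[5],
               st.e1.data());
    comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, p[1], p[6], p[7],
               st.e2.data());
    st.ssr = ssr_of(y.data(), n, p[0], p[2], p[3], st.eball.data(),
                    st.e1.data(), st.e2.data());

    double sd[8] = {0.02 * s0init, 1e-4, 0.05, 0.05, 0.2, 0.2, 0.2, 0.2};
    int acc_blk[8] = {0}, try_blk[8] = {0};
    long acc_post = 0, try_post = 0;

    const double sigma_min = sigma_floor_frac * s0init;
    const double tau_max = 1.0 / (sigma_min * sigma_min);
    double tau = std::min(n / std::max(st.ssr, 1e-12), tau_max);

    int kept = 0;
    const int total = burnin + njumps;
    std::vector<double> eball_new(n), es_new(n);
    for (int it = 0; it < total; it++) {
      // Gibbs update of noise precision, capped at the sigma floor
      tau = R::rgamma(1e-3 + 0.5 * n, 1.0 / (1e-3 + 0.5 * st.ssr));
      if (tau > tau_max) tau = tau_max;

      for (int ip = 0; ip < 8; ip++) {
        double old = p[ip];
        double prop = old + sd[ip] * norm_rand();
        bool ok = true;
        double lpr = 0.0;  // log prior ratio
        switch (ip) {
        case 0: ok = prop > 0.0; break;
        case 1:
          ok = prop > 0.0;
          if (ok) lpr = (d_shape - 1.0) * (std::log(prop) - std::log(old)) -
                        d_rate * (prop - old);
          break;
        case 2:
          ok = prop >= FMIN && prop + p[3] <= 1.0;
          if (ok && ard_f1) lpr = -(std::log(prop) - std::log(old));
          break;
        case 3:
          ok = prop >= FMIN && p[2] + prop <= 1.0;
          if (ok && ard_f2) lpr = -(std::log(prop) - std::log(old));
          break;
        case 4: case 6: {
          double s_new = std::fabs(std::sin(prop)), s_old = std::fabs(std::sin(old));
          ok = s_new > 1e-12;
          if (ok) lpr = std::log(s_new) - std::log(s_old);
          break;
        }
        default: break;  // azimuth: flat
        }
        bool in_blk = it < burnin;
        if (in_blk) try_blk[ip]++; else try_post++;
        if (!ok) continue;

        // recompute only the compartments the proposal touches
        double new_ssr;
        const double *eb = st.eball.data(), *e1 = st.e1.data(),
                     *e2 = st.e2.data();
        switch (ip) {
        case 0:
          new_ssr = ssr_of(y.data(), n, prop, p[2], p[3], eb, e1, e2);
          break;
        case 1:
          comp_ball(b.data(), n, prop, eball_new.data());
          comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, prop,
                     p[4], p[5], es_new.data());
          comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, prop,
                     p[6], p[7], tmp.data());
          new_ssr = ssr_of(y.data(), n, p[0], p[2], p[3], eball_new.data(),
                           es_new.data(), tmp.data());
          break;
        case 2:
          new_ssr = ssr_of(y.data(), n, p[0], prop, p[3], eb, e1, e2);
          break;
        case 3:
          new_ssr = ssr_of(y.data(), n, p[0], p[2], prop, eb, e1, e2);
          break;
        case 4: case 5:
          comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, p[1],
                     ip == 4 ? prop : p[4], ip == 5 ? prop : p[5],
                     es_new.data());
          new_ssr = ssr_of(y.data(), n, p[0], p[2], p[3], eb, es_new.data(), e2);
          break;
        default:
          comp_stick(b.data(), gx.data(), gy.data(), gz.data(), n, p[1],
                     ip == 6 ? prop : p[6], ip == 7 ? prop : p[7],
                     es_new.data());
          new_ssr = ssr_of(y.data(), n, p[0], p[2], p[3], eb, e1, es_new.data());
        }

        double logalpha = -0.5 * tau * (new_ssr - st.ssr) + lpr;
        if (logalpha >= 0.0 || std::log(unif_rand()) < logalpha) {
          p[ip] = prop;
          st.ssr = new_ssr;
          if (ip == 1) {
            std::swap(st.eball, eball_new); std::swap(st.e1, es_new);
            std::swap(st.e2, tmp);
          } else if (ip == 4 || ip == 5) std::swap(st.e1, es_new);
          else if (ip == 6 || ip == 7) std::swap(st.e2, es_new);
          if (in_blk) acc_blk[ip]++; else acc_post++;
        }
      }

      // adapt proposal widths during burn-in
      if (it < burnin && (it + 1) % 50 == 0) {
        for (int ip = 0; ip < 8; ip++) {
          if (try_blk[ip] > 0) {
            double rate = (double)acc_blk[ip] / try_blk[ip];
            sd[ip] *= std::exp(rate - 0.44);
          }
          acc_blk[ip] = 0; try_blk[ip] = 0;
        }
      }

      if (it >= burnin && (it - burnin + 1) % thin == 0 && kept < K) {
        // sticks keep their chain identity (no per-sample reordering:
        // swapping by volume fraction would label-switch near f1 = f2)
        out_f1(kept, vox) = p[2];  out_f2(kept, vox) = p[3];
        out_th1(kept, vox) = p[4]; out_ph1(kept, vox) = p[5];
        out_th2(kept, vox) = p[6]; out_ph2(kept, vox) = p[7];
        out_d(kept, vox) = p[1];   out_s0(kept, vox) = p[0];
        kept++;
      }
    }
    double acc = try_post > 0 ? (double)acc_post / try_post : 0.0;
    out_acc[vox] = acc;
    if (acc < 0.05 || acc > 0.95) out_bad[vox] = true;
  }

  return List::create(
      _["f1"] = out_f1, _["f2"] = out_f2, _["d"] = out_d, _["s0"] = out_s0,
      _["th1"] = out_th1, _["ph1"] = out_ph1, _["th2"] = out_th2,
      _["ph2"] = out_ph2, _["acceptance"] = out_acc, _["flagged"] = out_bad);
  }
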