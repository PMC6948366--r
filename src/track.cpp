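#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Probabilistic streamline propagation over a voxelwise posterior sample set.
//
// Each seed voxel launches `nsamples` streamline samples. A sample draws one
// posterior realisation at every voxel it enters (nearest-voxel lookup:
// floor(position / voxel size)), picks one of the supported sticks with
// probability proportional to its volume fraction, sign-aligns it with the
// previous step direction, terminates if the cosine with the previous
// direction falls below the curvature threshold, and otherwise advances by
// the step length. Both directions from the seed are propagated (two
// half-tracts per sample). A sample succeeds when either half-tract enters
// the target mask; termination otherwise occurs on leaving the brain mask or
// grid, a curvature violation, a detected loop, or the step cap. The loop
// check records the entry direction into cells of a half-resolution grid and
// terminates when a cell is re-entered with direction reversed beyond 90
// degrees.

struct Sampler {
  const double *f1, *f2, *th1, *ph1, *th2, *ph2;
  const int *support;
  int K;
  // draw an orientation at voxel v; returns false if no stick supported
  bool draw(int v, double out[3]) const {
    int sup = support[v];
    if (sup <= 0) return false;
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    size_t o = (size_t)v * K + k;
    double a = f1[o], b2 = (sup >= 2) ? f2[o] : 0.0;
    double tot = a + b2;
    if (tot <= 0.0) return false;
    double th, ph;
    if (sup >= 2 && unif_rand() * tot > a) { th = th2[o]; ph = ph2[o]; }
    else { th = th1[o]; ph = ph1[o]; }
    out[0] = std::sin(th) * std::cos(ph);
    out[1] = std::sin(th) * std::sin(ph);
    out[2] = std::cos(th);
    return true;
  }
};

// [[Rcpp::export]]
List cpp_track(IntegerVector dims, NumericVector voxsize,
               NumericMatrix f1, NumericMatrix f2, NumericMatrix th1,
               NumericMatrix ph1, NumericMatrix th2, NumericMatrix ph2,
               IntegerVector support, IntegerVector seed_mask,
               IntegerVector target_mask, IntegerVector brain_mask,
               int nsamples, double step, double curv, bool loopcheck,
               int maxsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const int K = f1.nrow();

  Sampler smp;
  // transpose to voxel-major layout for cache-friendly lookup
  std::vector<double> tf1(nvox * K), tf2(nvox * K), tth1(nvox * K),
      tph1(nvox * K), tth2(nvox * K), tph2(nvox * K);
  for (size_t v = 0; v < nvox; v++)
    for (int k = 0; k < K; k++) {
      size_t o = v * K + k;
      tf1[o] = f1(k, v); tf2[o] = f2(k, v);
      tth1[o] = th1(k, v); tph1[o] = ph1(k, v);
      tth2[o] = th2(k, v); tph2[o] = ph2(k, v);
    }
  smp.f1 = tf1.data(); smp.f2 = tf2.data(); smp.th1 = tth1.data();
  smp.ph1 = tph1.data(); smp.th2 = tth2.data(); smp.ph2 = tph2.data();
  smp.support = support.begin(); smp.K = K;

  IntegerVector succ(nvox), visit(nvox);

  // loopcheck state on a half-resolution grid
  const int cx = (nx + 1) / 2, cy = (ny + 1) / 2, cz = (nz + 1) / 2;
  const size_t ncell = (size_t)cx * cy * cz;
  std::vector<long> cell_id(ncell, -1);
  std::vector<double> cell_dir(ncell * 3, 0.0);
  long tract_id = 0;

  std::vector<int> visited;
  visited.reserve(4 * maxsteps);

  RNGScope scope;

  for (size_t sv = 0; sv < nvox; sv++) {
    if (!seed_mask[sv]) continue;
    int si = sv % nx, sj = (sv / nx) % ny, sk = sv / ((size_t)nx * ny);
    double seedpos[3] = {(si + 0.5) * voxsize[0], (sj + 0.5) * voxsize[1],
                         (sk + 0.5) * voxsize[2]};
    for (int s = 0; s < nsamples; s++) {
      double dir0[3];
      if (!smp.draw(sv, dir0)) continue;
      bool success = false;
      visited.clear();
      visited.push_back((int)sv);
      for (int half = 0; half < 2; half++) {
        double pos[3] = {seedpos[0], seedpos[1], seedpos[2]};
        double dir[3] = {dir0[0], dir0[1], dir0[2]};
        if (half == 1) { dir[0] = -dir[0]; dir[1] = -dir[1]; dir[2] = -dir[2]; }
        tract_id++;
        for (int stp = 0; stp < maxsteps; stp++) {
          pos[0] += step * dir[0];
          pos[1] += step * dir[1];
          pos[2] += step * dir[2];
          int i = (int)std::floor(pos[0] / voxsize[0]);
          int j = (int)std::floor(pos[1] / voxsize[1]);
          int k = (int)std::floor(pos[2] / voxsize[2]);
          if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) break;
          size_t v = i + nx * (j + (size_t)ny * k);
          if (!brain_mask[v]) break;
          visited.push_back((int)v);
          if (target_mask[v]) { success = true; break; }
          if (loopcheck) {
            size_t cell = (i / 2) + cx * ((j / 2) + (size_t)cy * (k / 2));
            if (cell_id[cell] == tract_id) {
              double d = cell_dir[3 * cell] * dir[0] +
                         cell_dir[3 * cell + 1] * dir[1] +
                         cell_dir[3 * cell + 2] * dir[2];
              if (d < 0.0) break;
            } else {
              cell_id[cell] = tract_id;
              cell_dir[3 * cell] = dir[0];
              cell_dir[3 * cell + 1] = dir[1];
              cell_dir[3 * cell + 2] = dir[2];
            }
          }
          double nd[3];
          if (!smp.draw((int)v, nd)) break;
          double dot = nd[0] * dir[0] + nd[1] * dir[1] + nd[2] * dir[2];
          if (dot < 0.0) { nd[0] = -nd[0]; nd[1] = -nd[1]; nd[2] = -nd[2]; dot = -dot; }
          if (dot < curv) break;
          dir[0] = nd[0]; dir[1] = nd[1]; dir[2] = nd[2];
        }
        if (success) break;
      }
      if (success) {
        succ[sv]++;
        std::sort(visited.begin(), visited.end());
        visited.erase(std::unique(visited.begin(), visited.end()),
                      visited.end());
        for (size_t q = 0; q < visited.size(); q++) visit[visited[q]]++;
      }
    }
  }
  return List::create(_["success"] = succ, _["visitation"] = visit);
}
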