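#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact continuous-time simulation of the active-passive lattice gas.
// Site codes: 0 empty, 1 active right (+1), 2 active left (-1), 3 passive.
// Rates (nondimensional units, D_T = D_R = 1, v0 = Pe): passive jumps at
// 1/h^2 per neighbor; active jumps at 1/h^2 + sigma*Pe/(2h) horizontally
// (sign by orientation), 1/h^2 vertically; orientation flips at rate 1.
// Jumps into occupied sites are aborted (rejection-style Gillespie: the
// per-particle total rate is configuration independent, so event selection
// is O(1) and the chain remains statistically exact).
// [[Rcpp::export]]
List aplg_gillespie_cpp(IntegerMatrix occ0, double h, double Pe,
                        double t0, NumericVector save_times,
                        bool track = false) {
  int nx = occ0.nrow(), ny = occ0.ncol();
  int ns = save_times.size();
  if (Pe > 0 && h > 2.0 / Pe)
    stop("h > 2/Pe: negative backward jump rate");

  std::vector<int> grid((size_t)nx * ny, -1); // particle id or -1
  std::vector<int> px, py, ptype;             // ptype: 1,2,3
  std::vector<int> actives, passives;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = occ0(i, j);
      if (c != 0) {
        int id = (int)px.size();
        px.push_back(i); py.push_back(j); ptype.push_back(c);
        grid[(size_t)i + (size_t)nx * j] = id;
        if (c == 3) passives.push_back(id); else actives.push_back(id);
      }
    }
  int na = (int)actives.size(), np = (int)passives.size();
  double rj = 1.0 / (h * h);          // per-neighbor base jump rate
  double drift = Pe / (2.0 * h);      // horizontal bias
  double ra_tot = 4.0 * rj + 1.0;     // per active particle (jumps + flip)
  double rp_tot = 4.0 * rj;           // per passive particle
  double Rtot = na * ra_tot + np * rp_tot;

  std::vector<double> dxnet, dynet;
  std::vector<int> nflips;
  if (track) { dxnet.assign(px.size(), 0.0); dynet.assign(px.size(), 0.0);
               nflips.assign(px.size(), 0); }

  // kymograph storage: per-species column counts at each save time
  IntegerMatrix kp(ns, nx), km(ns, nx), k0(ns, nx);
  RNGScope scope;
  double t = t0;
  long long nevents = 0;
  int k = 0;
  auto record = [&](int row) {
    for (int id = 0; id < (int)px.size(); ++id) {
      int c = ptype[id], i = px[id];
      if (c == 1) kp(row, i)++; else if (c == 2) km(row, i)++; else k0(row, i)++;
    }
  };
  while (k < ns && (Rtot <= 0 || save_times[k] <= t + 1e-14)) { record(k); ++k; }
  if (Rtot > 0) {
    while (k < ns) {
      t += -std::log(unif_rand()) / Rtot;
      while (k < ns && t >= save_times[k]) { record(k); ++k; }
      if (k >= ns) break;
      ++nevents;
      if (nevents % 2000000 == 0) Rcpp::checkUserInterrupt();
      double u = unif_rand() * Rtot;
      int id, di = 0, dj = 0;
      if (u < na * ra_tot) {
        id = actives[(int)(unif_rand() * na)];
        double w = unif_rand() * ra_tot;
        if (w < 1.0) { // orientation flip
          ptype[id] = (ptype[id] == 1) ? 2 : 1;
          if (track) nflips[id]++;
          continue;
        }
        w -= 1.0;
        double sg = (ptype[id] == 1) ? 1.0 : -1.0;
        double rright = rj + sg * drift, rleft = rj - sg * drift;
        if (w < rright) di = 1;
        else if (w < rright + rleft) di = -1;
        else if (w < rright + rleft + rj) dj = 1;
        else dj = -1;
      } else {
        id = passives[(int)(unif_rand() * np)];
        double w = unif_rand() * 4.0;
        if (w < 1.0) di = 1; else if (w < 2.0) di = -1;
        else if (w < 3.0) dj = 1; else dj = -1;
      }
      int xi = px[id] + di, yj = py[id] + dj;
      if (xi < 0) xi += nx; else if (xi >= nx) xi -= nx;
      if (yj < 0) yj += ny; else if (yj >= ny) yj -= ny;
      size_t tgt = (size_t)xi + (size_t)nx * yj;
      if (grid[tgt] >= 0) continue; // exclusion: aborted jump
      grid[(size_t)px[id] + (size_t)nx * py[id]] = -1;
      grid[tgt] = id;
      px[id] = xi; py[id] = yj;
      if (track) { dxnet[id] += di * h; dynet[id] += dj * h; }
    }
  }
  IntegerMatrix occ(nx, ny);
  for (int id = 0; id < (int)px.size(); ++id) occ(px[id], py[id]) = ptype[id];
  List out = List::create(_["times"] = save_times,
                          _["kymo_p"] = kp, _["kymo_m"] = km, _["kymo_0"] = k0,
                          _["occupancy"] = occ, _["nevents"] = (double)nevents);
  if (track) {
    out["dx"] = NumericVector(dxnet.begin(), dxnet.end());
    out["dy"] = NumericVector(dynet.begin(), dynet.end());
    out["nflips"] = IntegerVector(nflips.begin(), nflips.end());
  }
  return out;
}
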