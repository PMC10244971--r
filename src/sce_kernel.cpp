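// Inner loops of the subcellular-element mechanics: pairwise soft-core
// Morse forces, linear springs, ring bending triplets, and the overdamped
// forward-Euler update. Pair index lists are built in R (they change only
// at topology events / neighbour refreshes) and passed down as 0-based
// integer vectors; this file only evaluates forces and advances positions.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct MorseP { double U, V, xi, ga; };

static inline MorseP as_morse(const NumericVector& p) {
  MorseP m; m.U = p[0]; m.V = p[1]; m.xi = p[2]; m.ga = p[3]; return m;
}

// accumulate Morse pair forces into F (and energy); action-reaction exact
static void morse_pairs(const NumericMatrix& pos, const IntegerVector& I,
                        const IntegerVector& J, const MorseP& mp,
                        NumericMatrix& F, double* energy) {
  const int n = I.size();
  for (int k = 0; k < n; ++k) {
    const int i = I[k], j = J[k];
    const double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1);
    const double r = std::sqrt(dx*dx + dy*dy);
    if (energy) *energy += mp.U*std::exp(-r/mp.xi) - mp.V*std::exp(-r/mp.ga);
    if (r < 1e-12) continue;            // soft core: zero force at coincidence
    const double dEdr = -(mp.U/mp.xi)*std::exp(-r/mp.xi)
                        + (mp.V/mp.ga)*std::exp(-r/mp.ga);
    const double fx = -dEdr * dx / r, fy = -dEdr * dy / r;
    F(i,0) += fx; F(i,1) += fy;
    F(j,0) -= fx; F(j,1) -= fy;
  }
}

static void spring_pairs(const NumericMatrix& pos, const IntegerVector& I,
                         const IntegerVector& J, const NumericVector& kk,
                         double l0, NumericMatrix& F, double* energy) {
  const int n = I.size();
  for (int k = 0; k < n; ++k) {
    const int i = I[k], j = J[k];
    const double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1);
    const double r = std::sqrt(dx*dx + dy*dy);
    const double ks = kk[k];
    if (energy) *energy += 0.5 * ks * (r - l0) * (r - l0);
    if (r < 1e-12) continue;            // degenerate: direction undefined
    const double fmag = -ks * (r - l0) / r;
    const double fx = fmag * dx, fy = fmag * dy;
    F(i,0) += fx; F(i,1) += fy;
    F(j,0) -= fx; F(j,1) -= fy;
  }
}

// angle penalty at the centre node c between legs to p and q
static void bend_triplets(const NumericMatrix& pos, const IntegerVector& P,
                          const IntegerVector& C, const IntegerVector& Q,
                          double kb, double th0, NumericMatrix& F,
                          double* energy) {
  const int n = C.size();
  for (int k = 0; k < n; ++k) {
    const int p = P[k], c = C[k], q = Q[k];
    const double ux = pos(p,0)-pos(c,0), uy = pos(p,1)-pos(c,1);
    const double vx = pos(q,0)-pos(c,0), vy = pos(q,1)-pos(c,1);
    const double lu = std::sqrt(ux*ux + uy*uy), lv = std::sqrt(vx*vx + vy*vy);
    if (lu < 1e-12 || lv < 1e-12) continue;
    double ct = (ux*vx + uy*vy) / (lu*lv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    const double th = std::acos(ct);
    if (energy) *energy += 0.5 * kb * (th - th0) * (th - th0);
    const double st = std::sqrt(std::max(0.0, 1.0 - ct*ct));
    if (st < 1e-9) continue;            // straight wall at rest: zero force
    const double uhx = ux/lu, uhy = uy/lu, vhx = vx/lv, vhy = vy/lv;
    const double coef = -kb * (th - th0);
    const double fpx = coef * (ct*uhx - vhx) / (lu*st);
    const double fpy = coef * (ct*uhy - vhy) / (lu*st);
    const double fqx = coef * (ct*vhx - uhx) / (lv*st);
    const double fqy = coef * (ct*vhy - uhy) / (lv*st);
    F(p,0) += fpx; F(p,1) += fpy;
    F(q,0) += fqx; F(q,1) += fqy;
    F(c,0) -= fpx + fqx; F(c,1) -= fpy + fqy;
  }
}

static double assemble(const NumericMatrix& pos, const List& pairs,
                       const NumericVector& m_turg, const NumericVector& m_pres,
                       const NumericVector& m_ved, double ext_l0,
                       double adh_l0, double k_bend, double theta0,
                       NumericMatrix& F, bool want_energy) {
  double energy = 0.0;
  double* ep = want_energy ? &energy : (double*)0;
  morse_pairs(pos, pairs["turg_i"], pairs["turg_j"], as_morse(m_turg), F, ep);
  morse_pairs(pos, pairs["pres_i"], pairs["pres_j"], as_morse(m_pres), F, ep);
  morse_pairs(pos, pairs["ved_i"],  pairs["ved_j"],  as_morse(m_ved),  F, ep);
  spring_pairs(pos, pairs["ext_i"], pairs["ext_j"], pairs["ext_k"], ext_l0, F, ep);
  spring_pairs(pos, pairs["adh_i"], pairs["adh_j"], pairs["adh_k"], adh_l0, F, ep);
  bend_triplets(pos, pairs["bend_p"], pairs["bend_c"], pairs["bend_q"],
                k_bend, theta0, F, ep);
  return energy;
}

// [[Rcpp::export]]
List sce_forces_cpp(NumericMatrix pos, List pairs,
                    NumericVector m_turg, NumericVector m_pres,
                    NumericVector m_ved, double ext_l0, double adh_l0,
                    double k_bend, double theta0, bool breakdown) {
  const int n = pos.nrow();
  if (!breakdown) {
    NumericMatrix F(n, 2);
    double e = assemble(pos, pairs, m_turg, m_pres, m_ved, ext_l0, adh_l0,
                        k_bend, theta0, F, true);
    return List::create(_["force"] = F, _["energy"] = e);
  }
  List terms;
  NumericMatrix Ft(n,2), Fp(n,2), Fv(n,2), Fe(n,2), Fa(n,2), Fb(n,2);
  double e = 0.0;
  morse_pairs(pos, pairs["turg_i"], pairs["turg_j"], as_morse(m_turg), Ft, &e);
  morse_pairs(pos, pairs["pres_i"], pairs["pres_j"], as_morse(m_pres), Fp, &e);
  morse_pairs(pos, pairs["ved_i"],  pairs["ved_j"],  as_morse(m_ved),  Fv, &e);
  spring_pairs(pos, pairs["ext_i"], pairs["ext_j"], pairs["ext_k"], ext_l0, Fe, &e);
  spring_pairs(pos, pairs["adh_i"], pairs["adh_j"], pairs["adh_k"], adh_l0, Fa, &e);
  bend_triplets(pos, pairs["bend_p"], pairs["bend_c"], pairs["bend_q"],
                k_bend, theta0, Fb, &e);
  NumericMatrix F(n, 2);
  for (int i = 0; i < n; ++i) {
    F(i,0) = Ft(i,0)+Fp(i,0)+Fv(i,0)+Fe(i,0)+Fa(i,0)+Fb(i,0);
    F(i,1) = Ft(i,1)+Fp(i,1)+Fv(i,1)+Fe(i,1)+Fa(i,1)+Fb(i,1);
  }
  return List::create(_["force"] = F, _["energy"] = e,
                      _["turgor"] = Ft, _["pressure"] = Fp,
                      _["volume_exclusion"] = Fv, _["extensibility"] = Fe,
                      _["adhesion"] = Fa, _["bending"] = Fb);
}

// nsteps of overdamped forward Euler; fext is held constant over the block
// [[Rcpp::export]]
List sce_integrate_cpp(NumericMatrix pos_in, NumericVector eta, List pairs,
                       NumericVector m_turg, NumericVector m_pres,
                       NumericVector m_ved, double ext_l0, double adh_l0,
                       double k_bend, double theta0, NumericMatrix fext,
                       int nsteps, double dt, bool track_energy) {
  const int n = pos_in.nrow();
  NumericMatrix pos = clone(pos_in);
  NumericVector etrace(track_energy ? nsteps : 0);
  NumericMatrix F(n, 2);
  for (int s = 0; s < nsteps; ++s) {
    std::fill(F.begin(), F.end(), 0.0);
    double e = assemble(pos, pairs, m_turg, m_pres, m_ved, ext_l0, adh_l0,
                        k_bend, theta0, F, track_energy);
    if (track_energy) etrace[s] = e;
    for (int i = 0; i < n; ++i) {
      pos(i,0) += (F(i,0) + fext(i,0)) * dt / eta[i];
      pos(i,1) += (F(i,1) + fext(i,1)) * dt / eta[i];
      if (!std::isfinite(pos(i,0)) || !std::isfinite(pos(i,1)))
        stop("numerical instability: non-finite position at node row %d (step %d)",
             i + 1, s + 1);
    }
  }
  return List::create(_["pos"] = pos, _["energy"] = etrace);
}

// Greedy adhesion pairing: accept candidate pairs in ascending distance
// order while each node has fewer than max_partners partners in the other
// node's cell. ids are stable node ids (for deterministic tie-breaks),
// ci/cj the owning cells. Returns a keep mask over the candidates.
// [[Rcpp::export]]
LogicalVector greedy_pairs_cpp(IntegerVector idi, IntegerVector idj,
                               IntegerVector ci, IntegerVector cj,
                               NumericVector dist, int max_partners) {
  const int n = idi.size();
  std::vector<int> ord(n);
  for (int k = 0; k < n; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (dist[a] != dist[b]) return dist[a] < dist[b];
    if (idi[a] != idi[b]) return idi[a] < idi[b];
    return idj[a] < idj[b];
  });
  std::map<std::pair<int,int>, int> count;   // (node id, other cell) -> n
  LogicalVector keep(n, false);
  for (int q = 0; q < n; ++q) {
    const int k = ord[q];
    auto ka = std::make_pair(idi[k], cj[k]);
    auto kb = std::make_pair(idj[k], ci[k]);
    int na = count.count(ka) ? count[ka] : 0;
    int nb = count.count(kb) ? count[kb] : 0;
    if (na < max_partners && nb < max_partners) {
      keep[k] = true;
      count[ka] = na + 1;
      count[kb] = nb + 1;
    }
  }
  return keep;
}

// Uniform-grid candidate pair search: all pairs of points from *different*
// cells within `cutoff`. Returns 1-based row index pairs and distances.
// [[Rcpp::export]]
List grid_pairs_cpp(NumericMatrix pos, IntegerVector cell, double cutoff) {
  const int n = pos.nrow();
  std::vector<int> pi, pj;
  std::vector<double> pd;
  if (n >= 2 && cutoff > 0) {
    double xmin = pos(0,0), ymin = pos(0,1);
    for (int i = 1; i < n; ++i) {
      if (pos(i,0) < xmin) xmin = pos(i,0);
      if (pos(i,1) < ymin) ymin = pos(i,1);
    }
    const double h = cutoff;
    std::vector<long> key(n);
    long nx = 0;
    std::vector<int> gx(n), gy(n);
    for (int i = 0; i < n; ++i) {
      gx[i] = (int)std::floor((pos(i,0) - xmin) / h);
      gy[i] = (int)std::floor((pos(i,1) - ymin) / h);
      if (gx[i] + 1 > nx) nx = gx[i] + 1;
    }
    std::multimap<long,int> grid;
    for (int i = 0; i < n; ++i) {
      key[i] = (long)gy[i] * (nx + 2) + gx[i];
      grid.insert(std::make_pair(key[i], i));
    }
    const double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i) {
      for (int dyc = -1; dyc <= 1; ++dyc) {
        for (int dxc = -1; dxc <= 1; ++dxc) {
          const long k = (long)(gy[i] + dyc) * (nx + 2) + (gx[i] + dxc);
          auto range = grid.equal_range(k);
          for (auto it = range.first; it != range.second; ++it) {
            const int j = it->second;
            if (j <= i || cell[i] == cell[j]) continue;
            const double dx = pos(i,0) - pos(j,0), dy = pos(i,1) - pos(j,1);
            const double d2 = dx*dx + dy*dy;
            if (d2 <= c2) {
              pi.push_back(i + 1); pj.push_back(j + 1);
              pd.push_back(std::sqrt(d2));
            }
          }
        }
      }
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  NumericVector dist(pd.size());
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k,0) = pi[k]; pairs(k,1) = pj[k]; dist[k] = pd[k];
  }
  return List::create(_["pairs"] = pairs, _["dist"] = dist);
}
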