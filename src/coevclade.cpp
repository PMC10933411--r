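#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Single-site heat-bath (Gibbs) sampler for a pairwise Potts model
// P(s) ~ exp(sum_i h_i(s_i) + sum_(i,j) J_ij(s_i, s_j)).
// h: L x q fields; edges: m x 2 one-based site pairs; J: list of q x q
// matrices, one per edge, J[e](a,b) for (s_i = a, s_j = b).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix potts_gibbs_cpp(NumericMatrix h, IntegerMatrix edges, List J,
                              int n_samples, int burn_in, int thin) {
  const int L = h.nrow(), q = h.ncol(), m = edges.nrow();
  std::vector<std::vector<std::array<int, 3>>> adj(L);
  std::vector<NumericMatrix> Jm(m);
  for (int e = 0; e < m; e++) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    adj[i].push_back({e, j, 0});
    adj[j].push_back({e, i, 1});
    Jm[e] = as<NumericMatrix>(J[e]);
  }
  // Detect the common diagonal-coupling case (J = s * I): there the
  // conditional can be evaluated multiplicatively from precomputed exp()
  // tables, avoiding exp calls inside the sweeps entirely.
  bool all_diag = true;
  std::vector<double> diag_factor(m, 1.0);
  for (int e = 0; e < m && all_diag; e++) {
    for (int a = 0; a < q && all_diag; a++)
      for (int b = 0; b < q; b++)
        if (a != b && Jm[e](a, b) != 0.0) { all_diag = false; break; }
    if (all_diag) {
      double d0 = Jm[e](0, 0);
      for (int a = 1; a < q; a++)
        if (Jm[e](a, a) != d0) { all_diag = false; break; }
      diag_factor[e] = std::exp(d0);
    }
  }
  std::vector<double> eh(L * q);  // exp(h), row-contiguous per site
  for (int i = 0; i < L; i++)
    for (int a = 0; a < q; a++) eh[i * q + a] = std::exp(h(i, a));
  IntegerMatrix out(n_samples, L);
  std::vector<int> s(L);
  for (int i = 0; i < L; i++) s[i] = (int)std::floor(unif_rand() * q);
  std::vector<double> logp(q), p(q);
  const int total = burn_in + n_samples * thin;
  int taken = 0;
  for (int sweep = 0; sweep < total && taken < n_samples; sweep++) {
    for (int i = 0; i < L; i++) {
      double Z = 0.0;
      if (all_diag) {
        const double *ehi = &eh[i * q];
        for (int a = 0; a < q; a++) p[a] = ehi[a];
        for (const auto &ed : adj[i]) p[s[ed[1]]] *= diag_factor[ed[0]];
        for (int a = 0; a < q; a++) Z += p[a];
      } else {
        double mx = R_NegInf;
        for (int a = 0; a < q; a++) {
          double lp = h(i, a);
          for (const auto &ed : adj[i]) {
            const NumericMatrix &je = Jm[ed[0]];
            lp += (ed[2] == 0) ? je(a, s[ed[1]]) : je(s[ed[1]], a);
          }
          logp[a] = lp;
          if (lp > mx) mx = lp;
        }
        for (int a = 0; a < q; a++) { p[a] = std::exp(logp[a] - mx); Z += p[a]; }
      }
      double u = unif_rand() * Z, c = 0.0;
      int pick = q - 1;
      for (int a = 0; a < q; a++) { c += p[a]; if (u <= c) { pick = a; break; } }
      s[i] = pick;
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % thin == 0)) {
      for (int i = 0; i < L; i++) out(taken, i) = s[i] + 1;
      taken++;
    }
  }
  return out;
}

// Direct information by iterative proportional fitting, all column pairs.
// E: (L*q) x (L*q) coupling matrix (gauge state q zero), f1: L x q.
// For each pair (i, j): W(a,b) = exp(E_ij(a,b)); scale mu1, mu2 until the
// two-site model P(a,b) ~ W(a,b) mu1(a) mu2(b) has marginals f1(i,.) and
// f1(j,.) within tol; DI = KL(P || f1_i x f1_j), natural log.
// [[Rcpp::export]]
List di_ipf_cpp(NumericMatrix E, NumericMatrix f1, int q, double tol,
                int max_iter) {
  const int L = f1.nrow();
  NumericMatrix di(L, L);
  LogicalMatrix conv(L, L);
  std::fill(conv.begin(), conv.end(), true);
  std::vector<double> W(q * q), mu1(q), mu2(q), n1(q), n2(q);
  for (int i = 0; i < L; i++) {
    for (int j = i + 1; j < L; j++) {
      for (int a = 0; a < q; a++)
        for (int b = 0; b < q; b++)
          W[a * q + b] = std::exp(E(i * q + a, j * q + b));
      for (int a = 0; a < q; a++) { mu1[a] = 1.0 / q; mu2[a] = 1.0 / q; }
      bool ok = false;
      for (int it = 0; it < max_iter; it++) {
        double diff = 0.0, z1 = 0.0, z2 = 0.0;
        for (int a = 0; a < q; a++) {
          double sv = 0.0;
          for (int b = 0; b < q; b++) sv += W[a * q + b] * mu2[b];
          n1[a] = f1(i, a) / sv;
          z1 += n1[a];
        }
        for (int a = 0; a < q; a++) n1[a] /= z1;
        for (int b = 0; b < q; b++) {
          double sv = 0.0;
          for (int a = 0; a < q; a++) sv += W[a * q + b] * n1[a];
          n2[b] = f1(j, b) / sv;
          z2 += n2[b];
        }
        for (int b = 0; b < q; b++) n2[b] /= z2;
        for (int a = 0; a < q; a++) {
          diff = std::max(diff, std::fabs(n1[a] - mu1[a]));
          diff = std::max(diff, std::fabs(n2[a] - mu2[a]));
          mu1[a] = n1[a];
          mu2[a] = n2[a];
        }
        if (diff < tol) { ok = true; break; }
      }
      if (!ok) { conv(i, j) = false; conv(j, i) = false; }
      double Z = 0.0;
      for (int a = 0; a < q; a++)
        for (int b = 0; b < q; b++)
          Z += W[a * q + b] * mu1[a] * mu2[b];
      double d = 0.0;
      for (int a = 0; a < q; a++) {
        for (int b = 0; b < q; b++) {
          double pab = W[a * q + b] * mu1[a] * mu2[b] / Z;
          if (pab > 0.0)
            d += pab * std::log(pab / (f1(i, a) * f1(j, b)));
        }
      }
      di(i, j) = d;
      di(j, i) = d;
    }
  }
  return List::create(Named("di") = di, Named("converged") = conv);
}
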