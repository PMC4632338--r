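#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// On-lattice kinetic Monte Carlo ensemble with excluded volume: one molecule
// per site, hops to free von Neumann neighbours at per-direction rate
// D/a^2, periodic boundaries, fixed initial placement shared by all
// repetitions.
//
// The chain is simulated by uniformization: hop attempts into occupied sites
// are retained as null events, so the total event rate
//   R = sum_sp N_sp * 4 * rate_sp
// is constant and the number of events in a recording interval is
// Poisson(R * dt). This is distributionally identical to the
// enumerate/select/advance procedure with exponential waiting times (null
// self-loops do not change the law of a continuous-time Markov chain) and
// makes each event O(1).
//
// Direction displacements match the D2Q5 stencil (row, column) convention.
static const int DI[4] = {0, -1, 0, 1};
static const int DJ[4] = {1, 0, -1, 0};

// [[Rcpp::export]]
List kmc_ensemble_cpp(int nSites, IntegerVector spOfMol,
                      IntegerVector si0, IntegerVector sj0,
                      NumericVector hopRate, LogicalVector mobile,
                      NumericVector recordTimes, int coarseFactor, int reps) {
  const int nMol = spOfMol.size();
  const int nSp = hopRate.size();
  const int nT = recordTimes.size();
  const int nVox = nSites / coarseFactor;

  // group molecule indices by species (classes of the event catalogue)
  std::vector<int> cnt(nSp, 0);
  for (int m = 0; m < nMol; ++m) cnt[spOfMol[m]]++;
  std::vector<int> offset(nSp + 1, 0);
  for (int s = 0; s < nSp; ++s) offset[s + 1] = offset[s] + cnt[s];
  std::vector<int> byClass(nMol);
  {
    std::vector<int> pos(offset.begin(), offset.end() - 1);
    for (int m = 0; m < nMol; ++m) byClass[pos[spOfMol[m]]++] = m;
  }
  std::vector<double> clsRate(nSp), cumRate(nSp);
  double Rtot = 0.0;
  for (int s = 0; s < nSp; ++s) {
    clsRate[s] = mobile[s] ? cnt[s] * 4.0 * hopRate[s] : 0.0;
    Rtot += clsRate[s];
    cumRate[s] = Rtot;
  }
  if (Rtot <= 0.0) stop("no mobile molecules: total event rate is zero");

  std::vector<double> occSum((size_t)nVox * nVox * nSp * nT, 0.0);
  std::vector<double> msdSum((size_t)nSp * nT, 0.0);
  std::vector<double> hopSum((size_t)nSp * nT, 0.0);

  std::vector<int> grid((size_t)nSites * nSites);
  std::vector<int> si(nMol), sj(nMol), dx(nMol), dy(nMol), hops(nMol);

  for (int rep = 0; rep < reps; ++rep) {
    std::fill(grid.begin(), grid.end(), -1);
    for (int m = 0; m < nMol; ++m) {
      si[m] = si0[m]; sj[m] = sj0[m]; dx[m] = 0; dy[m] = 0; hops[m] = 0;
      grid[(size_t)si[m] * nSites + sj[m]] = m;
    }
    double tPrev = 0.0;
    for (int k = 0; k < nT; ++k) {
      double lambda = Rtot * (recordTimes[k] - tPrev);
      tPrev = recordTimes[k];
      double nevD = R::rpois(lambda);
      long long nev = (long long)nevD;
      for (long long e = 0; e < nev; ++e) {
        double u = unif_rand() * Rtot;
        int s = 0;
        while (u > cumRate[s]) ++s;
        if (s >= nSp) s = nSp - 1;
        // remaining uniform picks (molecule, direction) within the class
        double uRem = (u - (s > 0 ? cumRate[s - 1] : 0.0)) / clsRate[s];
        long long idx = (long long)(uRem * (cnt[s] * 4.0));
        if (idx >= (long long)cnt[s] * 4) idx = (long long)cnt[s] * 4 - 1;
        int m = byClass[offset[s] + (int)(idx >> 2)];
        int d = (int)(idx & 3);
        int ti = si[m] + DI[d];
        if (ti < 0) ti += nSites; else if (ti >= nSites) ti -= nSites;
        int tj = sj[m] + DJ[d];
        if (tj < 0) tj += nSites; else if (tj >= nSites) tj -= nSites;
        size_t tcell = (size_t)ti * nSites + tj;
        if (grid[tcell] >= 0) continue; // blocked: null event
        grid[(size_t)si[m] * nSites + sj[m]] = -1;
        grid[tcell] = m;
        si[m] = ti; sj[m] = tj;
        dx[m] += DI[d]; dy[m] += DJ[d]; hops[m]++;
      }
      for (int m = 0; m < nMol; ++m) {
        int s = spOfMol[m];
        int vi = si[m] / coarseFactor, vj = sj[m] / coarseFactor;
        occSum[(size_t)vi + (size_t)nVox * (vj + (size_t)nVox * (s + (size_t)nSp * k))] += 1.0;
        msdSum[(size_t)s + (size_t)nSp * k] +=
            (double)dx[m] * dx[m] + (double)dy[m] * dy[m];
        hopSum[(size_t)s + (size_t)nSp * k] += (double)hops[m];
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector occ(occSum.begin(), occSum.end());
  occ = occ / (double)reps;
  occ.attr("dim") = IntegerVector::create(nVox, nVox, nSp, nT);
  NumericMatrix msd(nSp, nT), hop(nSp, nT);
  for (int k = 0; k < nT; ++k)
    for (int s = 0; s < nSp; ++s) {
      double denom = (double)cnt[s] * reps;
      msd(s, k) = cnt[s] > 0 ? msdSum[(size_t)s + (size_t)nSp * k] / denom : 0.0;
      hop(s, k) = cnt[s] > 0 ? hopSum[(size_t)s + (size_t)nSp * k] / denom : 0.0;
    }
  return List::create(_["occ"] = occ, _["msd"] = msd, _["hops"] = hop,
                      _["counts"] = IntegerVector(cnt.begin(), cnt.end()));
}
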