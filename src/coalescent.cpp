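// Hudson-style backward coalescent with crossover recombination, gene
// conversion (Wiuf/Hein two-breakpoint tracts, geometric lengths) and
// piecewise-constant demography, optionally with a symmetric n-island
// structure. Time is measured in units of 4*N0 generations, N0 the
// reference (present/ancestral, as encoded by the caller) effective size.
//
// Sample carrier sets are 64-bit masks, so n <= 64 chromosomes.
// Mutations are laid down after the genealogy, from recorded
// (duration x ancestral-material) pieces: either Poisson(theta) or an
// exact fixed number (conditioning on the observed S).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Seg {
  double a, b;        // half-open [a, b), positions as fraction of the locus
  uint64_t set;       // descendant samples carrying this material
};

struct Lin {
  std::vector<Seg> segs;
  int deme;
};

struct Piece {        // one lineage's material over one time slice
  double w;           // dt * total segment length
  double len;         // total segment length
  std::vector<Seg> segs;
};

inline double seg_len(const std::vector<Seg>& s) {
  double t = 0.0;
  for (const auto& x : s) t += x.b - x.a;
  return t;
}

inline double span_left(const std::vector<Seg>& s)  { return s.front().a; }
inline double span_right(const std::vector<Seg>& s) { return s.back().b; }

// merge two lineages; material ancestral to the full sample is dropped
std::vector<Seg> merge_segs(const std::vector<Seg>& x, const std::vector<Seg>& y,
                            uint64_t full) {
  std::vector<double> bp;
  bp.reserve(2 * (x.size() + y.size()));
  for (const auto& s : x) { bp.push_back(s.a); bp.push_back(s.b); }
  for (const auto& s : y) { bp.push_back(s.a); bp.push_back(s.b); }
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  std::vector<Seg> out;
  size_t ix = 0, iy = 0;
  for (size_t k = 0; k + 1 < bp.size(); ++k) {
    double a = bp[k], b = bp[k + 1];
    while (ix < x.size() && x[ix].b <= a) ++ix;
    while (iy < y.size() && y[iy].b <= a) ++iy;
    uint64_t u = 0;
    if (ix < x.size() && x[ix].a <= a && x[ix].b >= b) u |= x[ix].set;
    if (iy < y.size() && y[iy].a <= a && y[iy].b >= b) u |= y[iy].set;
    if (u == 0 || u == full) continue;
    if (!out.empty() && out.back().b == a && out.back().set == u) {
      out.back().b = b;
    } else {
      out.push_back({a, b, u});
    }
  }
  return out;
}

// split segments at point x: left gets [0,x), right gets [x,1)
void split_at(const std::vector<Seg>& s, double x,
              std::vector<Seg>& left, std::vector<Seg>& right) {
  for (const auto& sg : s) {
    if (sg.b <= x) left.push_back(sg);
    else if (sg.a >= x) right.push_back(sg);
    else {
      left.push_back({sg.a, x, sg.set});
      right.push_back({x, sg.b, sg.set});
    }
  }
}

// split into material inside [x0,x1) (tract) and outside
void split_tract(const std::vector<Seg>& s, double x0, double x1,
                 std::vector<Seg>& inside, std::vector<Seg>& outside) {
  for (const auto& sg : s) {
    double a = sg.a, b = sg.b;
    if (b <= x0 || a >= x1) { outside.push_back(sg); continue; }
    if (a < x0) outside.push_back({a, x0, sg.set});
    inside.push_back({std::max(a, x0), std::min(b, x1), sg.set});
    if (b > x1) outside.push_back({x1, b, sg.set});
  }
}

inline double runif01() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

} // namespace

// [[Rcpp::export]]
List simulate_coalescent_cpp(int n, int reps, double theta, double rho,
                             double conv_ratio, double tract_mean_bp,
                             double L_bp, int fixed_s,
                             NumericVector epoch_start, NumericVector epoch_size,
                             int npop, double mig, bool return_sets) {
  if (n < 2 || n > 64) stop("sample size must be between 2 and 64");
  if (!R_FINITE(theta) || !R_FINITE(rho) || theta < 0 || rho < 0)
    stop("non-finite or negative rate");
  const uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  const int nepoch = epoch_start.size();
  List out(reps);

  for (int rep = 0; rep < reps; ++rep) {
    // initial lineages: one segment covering the locus, samples split
    // as evenly as possible across demes
    std::vector<Lin> lin(n);
    for (int i = 0; i < n; ++i) {
      lin[i].segs = { Seg{0.0, 1.0, 1ULL << i} };
      lin[i].deme = (npop > 1) ? (i * npop) / n : 0;
    }

    std::vector<Piece> pieces;
    pieces.reserve(4 * n);
    double t = 0.0;
    int ep = 0;

    while (!lin.empty()) {
      while (ep + 1 < nepoch && t >= epoch_start[ep + 1]) ++ep;
      double relN = epoch_size[ep];
      double next_change = (ep + 1 < nepoch) ? epoch_start[ep + 1] : R_PosInf;

      // event rates
      std::vector<int> kd(npop, 0);
      for (const auto& l : lin) kd[l.deme]++;
      double coal = 0.0;
      for (int d = 0; d < npop; ++d)
        coal += (double)kd[d] * (kd[d] - 1) / relN;
      double rec = 0.0, conv = 0.0;
      std::vector<double> spans(lin.size());
      for (size_t i = 0; i < lin.size(); ++i) {
        spans[i] = span_right(lin[i].segs) - span_left(lin[i].segs);
        rec  += rho * spans[i];
        conv += conv_ratio * rho * spans[i];
      }
      double migr = (npop > 1) ? mig * (double)lin.size() : 0.0;
      double tot = coal + rec + conv + migr;
      if (tot <= 0.0) stop("zero total event rate with active lineages");

      double dt = exp_rand() / tot;
      if (t + dt > next_change) {           // rates change; redraw (memoryless)
        double slice = next_change - t;
        for (const auto& l : lin) {
          double ln = seg_len(l.segs);
          pieces.push_back({slice * ln, ln, l.segs});
        }
        t = next_change;
        continue;
      }

      for (const auto& l : lin) {
        double ln = seg_len(l.segs);
        pieces.push_back({dt * ln, ln, l.segs});
      }
      t += dt;

      double u = unif_rand() * tot;
      if (u < coal) {
        // coalescence: pick deme, then a random pair within it
        double acc = 0.0;
        int d = 0;
        for (; d < npop; ++d) {
          acc += (double)kd[d] * (kd[d] - 1) / relN;
          if (u < acc) break;
        }
        if (d >= npop) d = npop - 1;
        int i = -1, j = -1;
        int pick1 = (int)std::floor(runif01() * kd[d]);
        int pick2 = (int)std::floor(runif01() * (kd[d] - 1));
        int c = 0;
        for (size_t q = 0; q < lin.size(); ++q) {
          if (lin[q].deme != d) continue;
          if (c == pick1) i = (int)q;
          ++c;
        }
        c = 0;
        for (size_t q = 0; q < lin.size(); ++q) {
          if (lin[q].deme != d || (int)q == i) continue;
          if (c == pick2) j = (int)q;
          ++c;
        }
        std::vector<Seg> m = merge_segs(lin[i].segs, lin[j].segs, full);
        int lo = std::min(i, j), hi = std::max(i, j);
        lin.erase(lin.begin() + hi);
        if (m.empty()) lin.erase(lin.begin() + lo);
        else lin[lo].segs = std::move(m);
      } else if (u < coal + rec) {
        // crossover at a uniform point within the breakable span
        double v = (u - coal) / rho;
        size_t i = 0;
        for (; i < lin.size(); ++i) { if (v < spans[i]) break; v -= spans[i]; }
        if (i == lin.size()) i = lin.size() - 1;
        double x = span_left(lin[i].segs) + runif01() * spans[i];
        std::vector<Seg> le, ri;
        split_at(lin[i].segs, x, le, ri);
        if (!le.empty() && !ri.empty()) {
          lin[i].segs = std::move(le);
          Lin nl; nl.segs = std::move(ri); nl.deme = lin[i].deme;
          lin.push_back(std::move(nl));
        }
      } else if (u < coal + rec + conv) {
        // gene conversion: geometric tract (mean tract_mean_bp)
        double v = (u - coal - rec) / (conv_ratio * rho);
        size_t i = 0;
        for (; i < lin.size(); ++i) { if (v < spans[i]) break; v -= spans[i]; }
        if (i == lin.size()) i = lin.size() - 1;
        double x0 = span_left(lin[i].segs) + runif01() * spans[i];
        double p = 1.0 / tract_mean_bp;
        double g = 1.0 + std::floor(std::log(runif01()) / std::log1p(-p));
        double x1 = x0 + g / L_bp;
        std::vector<Seg> ins, outs;
        split_tract(lin[i].segs, x0, x1, ins, outs);
        if (!ins.empty() && !outs.empty()) {
          lin[i].segs = std::move(ins);
          Lin nl; nl.segs = std::move(outs); nl.deme = lin[i].deme;
          lin.push_back(std::move(nl));
        }
      } else {
        // migration to a uniformly chosen other deme
        size_t i = (size_t)std::floor(runif01() * lin.size());
        if (i >= lin.size()) i = lin.size() - 1;
        int d = (int)std::floor(runif01() * (npop - 1));
        if (d >= lin[i].deme) ++d;
        lin[i].deme = d;
      }
    }

    // mutation stage
    double W = 0.0;
    for (const auto& p : pieces) W += p.w;
    int S;
    if (fixed_s >= 0) S = fixed_s;
    else S = (int)R::rpois(theta * W);

    NumericVector pos(S);
    std::vector<uint64_t> sets(S);
    std::vector<double> cum(pieces.size());
    double acc = 0.0;
    for (size_t i = 0; i < pieces.size(); ++i) { acc += pieces[i].w; cum[i] = acc; }
    for (int s = 0; s < S; ++s) {
      double u = runif01() * W;
      size_t lo = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
      if (lo >= pieces.size()) lo = pieces.size() - 1;
      const Piece& pc = pieces[lo];
      double v = runif01() * pc.len;
      double x = pc.segs.back().a;
      uint64_t st = pc.segs.back().set;
      for (const auto& sg : pc.segs) {
        double ln = sg.b - sg.a;
        if (v < ln) { x = sg.a + v; st = sg.set; break; }
        v -= ln;
      }
      pos[s] = x;
      sets[s] = st;
    }

    // sort by position
    IntegerVector ord(S);
    for (int s = 0; s < S; ++s) ord[s] = s;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return pos[a] < pos[b]; });

    NumericVector spos(S);
    IntegerVector cnt(S);
    for (int s = 0; s < S; ++s) {
      spos[s] = pos[ord[s]];
#ifdef _MSC_VER
      int c = 0; uint64_t m = sets[ord[s]];
      while (m) { c += (int)(m & 1); m >>= 1; }
      cnt[s] = c;
#else
      cnt[s] = __builtin_popcountll(sets[ord[s]]);
#endif
    }

    if (return_sets) {
      IntegerMatrix geno(n, S);
      for (int s = 0; s < S; ++s) {
        uint64_t m = sets[ord[s]];
        for (int i = 0; i < n; ++i) geno(i, s) = (int)((m >> i) & 1ULL);
      }
      out[rep] = List::create(_["positions"] = spos,
                              _["counts"] = cnt,
                              _["genotypes"] = geno);
    } else {
      out[rep] = List::create(_["positions"] = spos, _["counts"] = cnt);
    }
  }
  return out;
}
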