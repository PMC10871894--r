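// Forward-in-time Wright-Fisher engine for Fisher's geometric model.
//
// State crosses the R/C++ boundary each generation: genomes are integer
// vectors of mutation ids (1-based indices into the R-side mutation
// registry), sorted by genomic position.  All randomness goes through R's
// RNG (unif_rand/norm_rand/exp_rand/R::rpois) so set.seed() governs the
// whole simulation and runs are bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// Position lookup: ids <= m0 live in the registry snapshot; larger ids are
// mutations created earlier in the current generation.
struct PosLookup {
  const double* reg;
  int m0;
  const std::vector<double>* fresh;
  double at(int id) const {
    return id <= m0 ? reg[id - 1] : (*fresh)[id - m0 - 1];
  }
};

struct NewMuts {
  std::vector<double> pos;   // integer-valued bp positions
  std::vector<double> eff;   // column-major n_traits x k
  int n_traits;
  int m0;                    // registry count at entry
};

// One recombinant product of two sorted haploid genomes.
// exp_co = r_bp * L is the expected crossover count.
std::vector<int> meiosis(const int* a, int na, const int* b, int nb,
                         const PosLookup& pos, double exp_co, double L) {
  int k = exp_co > 0 ? (int) R::rpois(exp_co) : 0;
  bool on_a = unif_rand() < 0.5;
  if (k == 0) {
    const int* src = on_a ? a : b;
    int ns = on_a ? na : nb;
    return std::vector<int>(src, src + ns);
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  bp.push_back(L + 1.0);  // sentinel closing the last segment
  std::vector<int> out;
  out.reserve((size_t) std::max(na, nb));
  int ia = 0, ib = 0;
  for (size_t s = 0; s < bp.size(); ++s) {
    double end = bp[s];
    if (on_a) {
      while (ia < na && pos.at(a[ia]) < end) out.push_back(a[ia++]);
      while (ib < nb && pos.at(b[ib]) < end) ++ib;
    } else {
      while (ib < nb && pos.at(b[ib]) < end) out.push_back(b[ib++]);
      while (ia < na && pos.at(a[ia]) < end) ++ia;
    }
    on_a = !on_a;
  }
  return out;
}

// Poisson(mu*L) new mutations on a gamete; exponential magnitude (mean
// lambda), uniform direction on the (n-1)-sphere; inserted position-sorted.
void add_mutations(std::vector<int>& g, double exp_mut, double L,
                   double lambda, int n_traits, NewMuts& nm,
                   const PosLookup& pos) {
  if (exp_mut <= 0) return;
  int k = (int) R::rpois(exp_mut);
  for (int i = 0; i < k; ++i) {
    double p = std::floor(unif_rand() * L);
    if (p >= L) p = L - 1;  // guard against unif_rand() == 1
    double norm2 = 0.0;
    std::vector<double> d(n_traits);
    do {
      norm2 = 0.0;
      for (int t = 0; t < n_traits; ++t) {
        d[t] = norm_rand();
        norm2 += d[t] * d[t];
      }
    } while (norm2 == 0.0);
    double mag = exp_rand() * lambda;
    double scale = mag / std::sqrt(norm2);
    for (int t = 0; t < n_traits; ++t) nm.eff.push_back(d[t] * scale);
    nm.pos.push_back(p);
    int id = nm.m0 + (int) nm.pos.size();
    // insert after any existing mutation at the same position
    int lo = 0, hi = (int) g.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (pos.at(g[mid]) <= p) lo = mid + 1; else hi = mid;
    }
    g.insert(g.begin() + lo, id);
  }
}

// Dosage weight of a mutation given copy count and carried ploidy.
inline double dosage_weight(int count, int ploidy, double h) {
  if (ploidy == 1) return 1.0;
  if (ploidy == 2) return count == 2 ? 1.0 : h;
  return count / 4.0;  // tetraploid: additive dosage
}

void phenotype_of(const std::vector<int>* const* gs, int ploidy,
                  const double* eff, const double* hvec, int n_traits,
                  const double* background, double* out,
                  std::vector<int>& all) {
  for (int t = 0; t < n_traits; ++t) out[t] = background[t];
  all.clear();
  for (int c = 0; c < ploidy; ++c)
    all.insert(all.end(), gs[c]->begin(), gs[c]->end());
  if (all.empty()) return;
  std::sort(all.begin(), all.end());
  size_t i = 0;
  while (i < all.size()) {
    int id = all[i];
    size_t j = i;
    while (j < all.size() && all[j] == id) ++j;
    double w = dosage_weight((int)(j - i), ploidy, hvec[id - 1]);
    const double* col = eff + (size_t)(id - 1) * n_traits;
    for (int t = 0; t < n_traits; ++t) out[t] += w * col[t];
    i = j;
  }
}

int pick_parent(const std::vector<double>& cumfit) {
  double total = cumfit.back();
  double u = unif_rand() * total;
  int lo = 0, hi = (int) cumfit.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumfit[mid] <= u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

struct PopState {
  std::vector<std::vector<int>> genomes;  // flat, per-copy
  std::vector<int> copies;                // per individual
  std::vector<int> first;                 // index of first genome per ind
  std::vector<bool> female;
};

PopState state_from_r(List genomes, IntegerVector copies,
                      LogicalVector female) {
  PopState s;
  int ng = genomes.size();
  s.genomes.resize(ng);
  for (int i = 0; i < ng; ++i) {
    IntegerVector g = genomes[i];
    s.genomes[i].assign(g.begin(), g.end());
  }
  int n = copies.size();
  s.copies.assign(copies.begin(), copies.end());
  s.female.resize(n);
  s.first.resize(n);
  int off = 0;
  for (int i = 0; i < n; ++i) {
    s.first[i] = off;
    off += copies[i];
    s.female[i] = female[i];
  }
  if (off != ng) stop("genome list length does not match copy counts");
  return s;
}

// One generation of Wright-Fisher reproduction with fitness-proportional
// parentage.  system: 0 diploid, 1 haplodiploid, 2 tetraploid.
// Writes offspring into `next` and appends new mutations to `nm`.
void wf_generation(const PopState& cur, const std::vector<double>& fitness,
                   int system, int n_off_f, int n_off_m,
                   const PosLookup& pos, NewMuts& nm,
                   double r_bp, double L, double mu, double lambda,
                   int n_traits, PopState& next) {
  int n = (int) cur.copies.size();
  std::vector<int> fem_idx, mal_idx;
  std::vector<double> fem_cum, mal_cum;
  double fsum = 0, msum = 0;
  for (int i = 0; i < n; ++i) {
    if (cur.female[i]) {
      fsum += fitness[i];
      fem_idx.push_back(i);
      fem_cum.push_back(fsum);
    } else {
      msum += fitness[i];
      mal_idx.push_back(i);
      mal_cum.push_back(msum);
    }
  }
  bool need_fathers = !(system == 1 && n_off_f == 0);
  if (fem_idx.empty() || fsum <= 0.0)
    stop("selection collapse: no female with positive fitness");
  if (need_fathers && (mal_idx.empty() || msum <= 0.0))
    stop("selection collapse: no male with positive fitness");

  double exp_co = r_bp * L;
  double exp_mut = mu * L;
  int n_off = n_off_f + n_off_m;
  next.genomes.clear();
  next.copies.assign(n_off, 0);
  next.first.assign(n_off, 0);
  next.female.assign(n_off, false);

  for (int j = 0; j < n_off; ++j) {
    bool is_f = j < n_off_f;
    next.female[j] = is_f;
    next.first[j] = (int) next.genomes.size();
    int mom = fem_idx[pick_parent(fem_cum)];
    if (system == 0) {  // diploid
      int dad = mal_idx[pick_parent(mal_cum)];
      const std::vector<int>& m1 = cur.genomes[cur.first[mom]];
      const std::vector<int>& m2 = cur.genomes[cur.first[mom] + 1];
      std::vector<int> gm = meiosis(m1.data(), (int) m1.size(), m2.data(),
                                    (int) m2.size(), pos, exp_co, L);
      add_mutations(gm, exp_mut, L, lambda, n_traits, nm, pos);
      const std::vector<int>& p1 = cur.genomes[cur.first[dad]];
      const std::vector<int>& p2 = cur.genomes[cur.first[dad] + 1];
      std::vector<int> gp = meiosis(p1.data(), (int) p1.size(), p2.data(),
                                    (int) p2.size(), pos, exp_co, L);
      add_mutations(gp, exp_mut, L, lambda, n_traits, nm, pos);
      next.genomes.push_back(std::move(gm));
      next.genomes.push_back(std::move(gp));
      next.copies[j] = 2;
    } else if (system == 1) {  // haplodiploid, arrhenotokous
      const std::vector<int>& m1 = cur.genomes[cur.first[mom]];
      const std::vector<int>& m2 = cur.genomes[cur.first[mom] + 1];
      std::vector<int> gm = meiosis(m1.data(), (int) m1.size(), m2.data(),
                                    (int) m2.size(), pos, exp_co, L);
      add_mutations(gm, exp_mut, L, lambda, n_traits, nm, pos);
      if (is_f) {
        int dad = mal_idx[pick_parent(mal_cum)];
        // haploid father transmits his single copy without recombination
        std::vector<int> gp = cur.genomes[cur.first[dad]];
        add_mutations(gp, exp_mut, L, lambda, n_traits, nm, pos);
        next.genomes.push_back(std::move(gm));
        next.genomes.push_back(std::move(gp));
        next.copies[j] = 2;
      } else {  // sons from an unfertilized egg
        next.genomes.push_back(std::move(gm));
        next.copies[j] = 1;
      }
    } else {  // tetraploid: random bivalents, one product per bivalent
      int dad = mal_idx[pick_parent(mal_cum)];
      int parents[2] = {mom, dad};
      for (int pi = 0; pi < 2; ++pi) {
        int par = parents[pi];
        int idx[4] = {0, 1, 2, 3};
        for (int i2 = 3; i2 > 0; --i2) {
          int jj = (int) std::floor(unif_rand() * (i2 + 1));
          if (jj > i2) jj = i2;
          std::swap(idx[i2], idx[jj]);
        }
        for (int b = 0; b < 2; ++b) {
          const std::vector<int>& c1 = cur.genomes[cur.first[par] + idx[2 * b]];
          const std::vector<int>& c2 =
              cur.genomes[cur.first[par] + idx[2 * b + 1]];
          std::vector<int> g = meiosis(c1.data(), (int) c1.size(), c2.data(),
                                       (int) c2.size(), pos, exp_co, L);
          add_mutations(g, exp_mut, L, lambda, n_traits, nm, pos);
          next.genomes.push_back(std::move(g));
        }
      }
      next.copies[j] = 4;
    }
  }
}

List state_to_r(const PopState& s) {
  List g((int) s.genomes.size());
  for (size_t i = 0; i < s.genomes.size(); ++i)
    g[(int) i] = IntegerVector(s.genomes[i].begin(), s.genomes[i].end());
  return List::create(
      _["genomes"] = g,
      _["copies"] = IntegerVector(s.copies.begin(), s.copies.end()),
      _["female"] = LogicalVector(s.female.begin(), s.female.end()));
}

}  // namespace

// In-place append of new mutation rows into the registry's preallocated
// column vectors.  Only slots beyond the current logical count are ever
// written, so snapshots of the meaningful prefix taken earlier by R code
// are unaffected.
// [[Rcpp::export]]
void cpp_reg_write(NumericVector position, NumericMatrix effect,
                   NumericVector h, IntegerVector origin_gen,
                   IntegerVector origin_code, IntegerVector ids,
                   NumericVector new_pos, NumericMatrix new_eff,
                   NumericVector new_h, IntegerVector new_gen,
                   IntegerVector new_code) {
  int k = ids.size();
  int n_traits = effect.nrow();
  for (int i = 0; i < k; ++i) {
    int id = ids[i] - 1;
    if (id < 0 || id >= position.size()) stop("registry write out of range");
    REAL(position)[id] = new_pos[i];
    REAL(h)[id] = new_h[i];
    INTEGER(origin_gen)[id] = new_gen[i];
    INTEGER(origin_code)[id] = new_code[i];
    double* col = REAL(effect) + (size_t) id * n_traits;
    for (int t = 0; t < n_traits; ++t) col[t] = new_eff(t, i);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_phenotypes(List genomes, IntegerVector copies,
                             NumericMatrix eff, NumericVector hvec,
                             NumericVector background) {
  int n = copies.size();
  int n_traits = (int) background.size();
  if (eff.nrow() != n_traits) stop("effect matrix row count != trait count");
  PopState s = state_from_r(genomes, copies,
                            LogicalVector(n, true));  // sex irrelevant here
  NumericMatrix out(n, n_traits);
  std::vector<double> ph(n_traits);
  std::vector<int> scratch;
  const std::vector<int>* gs[4];
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < s.copies[i]; ++c)
      gs[c] = &s.genomes[s.first[i] + c];
    phenotype_of(gs, s.copies[i], REAL(eff), REAL(hvec), n_traits,
                 REAL(background), ph.data(), scratch);
    for (int t = 0; t < n_traits; ++t) out(i, t) = ph[t];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_meiosis_one(IntegerVector a, IntegerVector b,
                              NumericVector reg_pos, double r_bp, double L) {
  std::vector<double> none;
  PosLookup pos{REAL(reg_pos), (int) reg_pos.size(), &none};
  std::vector<int> g = meiosis(a.begin(), a.size(), b.begin(), b.size(), pos,
                               r_bp * L, L);
  return IntegerVector(g.begin(), g.end());
}

// [[Rcpp::export]]
List cpp_wf_generation(List genomes, IntegerVector copies,
                       LogicalVector female, NumericVector fitness,
                       int system, int n_off_f, int n_off_m,
                       NumericVector reg_pos, int reg_count, double r_bp,
                       double L, double mu, double lambda, int n_traits) {
  PopState cur = state_from_r(genomes, copies, female);
  std::vector<double> fit(fitness.begin(), fitness.end());
  NewMuts nm;
  nm.n_traits = n_traits;
  nm.m0 = reg_count;
  PosLookup pos{REAL(reg_pos), reg_count, &nm.pos};
  PopState next;
  wf_generation(cur, fit, system, n_off_f, n_off_m, pos, nm, r_bp, L, mu,
                lambda, n_traits, next);
  List out = state_to_r(next);
  int k = (int) nm.pos.size();
  NumericMatrix effm(n_traits, k);
  std::copy(nm.eff.begin(), nm.eff.end(), effm.begin());
  out["new_positions"] = NumericVector(nm.pos.begin(), nm.pos.end());
  out["new_effects"] = effm;
  return out;
}

// Run a single-mutant trial until the target allele fixes or is lost.
// Mutation is off (the trial concerns one segregating variant); fitness is
// recomputed each generation from the registry effects and the surface
// exp(-(x^2)^q).  Returns outcome 1 (fixed), 0 (lost), NA (max_gen hit).
// [[Rcpp::export]]
List cpp_fixation_trial(List genomes, IntegerVector copies,
                        LogicalVector female, int system,
                        NumericVector reg_pos, NumericMatrix eff,
                        NumericVector hvec, NumericVector background,
                        NumericVector optimum, double q, double r_bp,
                        double L, int n_off_f, int n_off_m, int target_id,
                        int max_gen) {
  PopState cur = state_from_r(genomes, copies, female);
  int n_traits = (int) optimum.size();
  NewMuts nm;
  nm.n_traits = n_traits;
  nm.m0 = (int) reg_pos.size();
  PosLookup pos{REAL(reg_pos), nm.m0, &nm.pos};
  std::vector<double> ph(n_traits);
  std::vector<int> scratch;
  const std::vector<int>* gs[4];
  // wild-type (empty-genome) fitness, reused for the unmutated majority
  double d2_wt = 0;
  for (int t = 0; t < n_traits; ++t) {
    double d = background[t] - optimum[t];
    d2_wt += d * d;
  }
  double w_wt = std::exp(q == 1.0 ? -d2_wt : -std::pow(d2_wt, q));
  PopState next;
  int gen = 0;
  while (gen < max_gen) {
    int n = (int) cur.copies.size();
    std::vector<double> fit(n);
    for (int i = 0; i < n; ++i) {
      bool empty = true;
      for (int c = 0; c < cur.copies[i]; ++c) {
        gs[c] = &cur.genomes[cur.first[i] + c];
        if (!gs[c]->empty()) empty = false;
      }
      if (empty) {
        fit[i] = w_wt;
        continue;
      }
      phenotype_of(gs, cur.copies[i], REAL(eff), REAL(hvec), n_traits,
                   REAL(background), ph.data(), scratch);
      double d2 = 0;
      for (int t = 0; t < n_traits; ++t) {
        double d = ph[t] - optimum[t];
        d2 += d * d;
      }
      fit[i] = std::exp(q == 1.0 ? -d2 : -std::pow(d2, q));
    }
    wf_generation(cur, fit, system, n_off_f, n_off_m, pos, nm, r_bp, L,
                  0.0, 0.0, n_traits, next);
    std::swap(cur, next);
    ++gen;
    int count = 0, total = (int) cur.genomes.size();
    for (int g = 0; g < total; ++g)
      count += (int) std::count(cur.genomes[g].begin(), cur.genomes[g].end(),
                                target_id);
    if (count == 0)
      return List::create(_["outcome"] = 0, _["generations"] = gen);
    if (count == total)
      return List::create(_["outcome"] = 1, _["generations"] = gen);
  }
  return List::create(_["outcome"] = NA_INTEGER, _["generations"] = gen);
}
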