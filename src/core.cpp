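// Grammatical-evolution core: codon -> tree mapping under the GEDT grammar,
// balanced-accuracy fitness, sensible initialization, genetic operators and
// the island-model GA / random-search loops.
//
// All randomness is drawn from R's RNG so that set.seed() in R makes every
// routine reproducible. Codons are stored as integers in [0, 2^codon_bits).
#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <climits>
using namespace Rcpp;

namespace {

// Flat ternary decision tree. var[i] >= 0: internal node splitting on that
// 0-based SNP, children kid[3i..3i+2]. var[i] == -1: leaf with class cls[i]
// (1 = '+', 0 = '-'). Node 0 is the root.
struct FlatTree {
  std::vector<int> var;
  std::vector<int> cls;
  std::vector<int> kid;
  bool valid;
  FlatTree() : valid(false) {}
  int size() const { return (int)var.size(); }
};

const int NODE_CAP = 250000;  // hard safety cap on mapped tree size

// uniform integer in [0, n)
inline int rand_int(int n) {
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

// Reads codons left to right, wrapping around at most max_wraps times.
struct CodonReader {
  const std::vector<int>& codons;
  int pos, wraps, max_wraps;
  CodonReader(const std::vector<int>& c, int mw)
      : codons(c), pos(0), wraps(0), max_wraps(mw) {}
  bool next(int& out) {
    if (pos == (int)codons.size()) {
      if (wraps >= max_wraps) return false;
      ++wraps;
      pos = 0;
    }
    out = codons[pos++];
    return true;
  }
};

// Expand one <pseudoV>. Alternative 0 (codon even) is the recursive
// <v><val_0><pseudoV><val_1><pseudoV><val_2><pseudoV> rule, alternative 1 is
// <class>. <v> has n_snps alternatives; <class> has two ('+' then '-').
// Single-alternative non-terminals (S, val_0, val_1, val_2) consume no codon.
// Returns the node index, or -1 when the wrap budget is exhausted.
int expand_pseudoV(FlatTree& t, CodonReader& r, int n_snps) {
  int c;
  if (!r.next(c)) return -1;
  if (t.size() >= NODE_CAP) return -1;
  if (c % 2 == 1) {  // <class>
    if (!r.next(c)) return -1;
    int idx = t.size();
    t.var.push_back(-1);
    t.cls.push_back(c % 2 == 0 ? 1 : 0);
    t.kid.push_back(-1); t.kid.push_back(-1); t.kid.push_back(-1);
    return idx;
  }
  if (!r.next(c)) return -1;  // <v>
  int idx = t.size();
  t.var.push_back(c % n_snps);
  t.cls.push_back(-1);
  t.kid.push_back(-1); t.kid.push_back(-1); t.kid.push_back(-1);
  for (int g = 0; g < 3; ++g) {
    int k = expand_pseudoV(t, r, n_snps);
    if (k < 0) return -1;
    t.kid[3 * idx + g] = k;
  }
  return idx;
}

FlatTree map_codons(const std::vector<int>& codons, int n_snps, int max_wraps) {
  FlatTree t;
  if (codons.empty()) return t;
  CodonReader r(codons, max_wraps);
  int root = expand_pseudoV(t, r, n_snps);
  t.valid = (root == 0);
  return t;
}

// Balanced accuracy of a mapped tree on a genotype matrix (individuals x
// SNPs, values 0/1/2) with labels y (1 = case). Invalid trees score 0.
double tree_balanced_accuracy(const FlatTree& t, const IntegerMatrix& geno,
                              const IntegerVector& y, int n_case, int n_ctrl) {
  if (!t.valid) return 0.0;
  int n = geno.nrow(), tp = 0, tn = 0;
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (t.var[node] >= 0)
      node = t.kid[3 * node + geno(i, t.var[node])];
    if (y[i] == 1) { if (t.cls[node] == 1) ++tp; }
    else           { if (t.cls[node] == 0) ++tn; }
  }
  return 0.5 * ((double)tp / n_case + (double)tn / n_ctrl);
}

// Sensible initialization: build a tree directly from the grammar, then
// encode it as codons (bare alternative indices).
int build_random_tree(FlatTree& t, int depth, bool full, int n_snps) {
  bool leaf;
  if (depth <= 0) leaf = true;
  else if (full) leaf = false;
  else leaf = (unif_rand() < 0.5);
  int idx = t.size();
  if (leaf) {
    t.var.push_back(-1);
    t.cls.push_back(rand_int(2));
    t.kid.push_back(-1); t.kid.push_back(-1); t.kid.push_back(-1);
    return idx;
  }
  t.var.push_back(rand_int(n_snps));
  t.cls.push_back(-1);
  t.kid.push_back(-1); t.kid.push_back(-1); t.kid.push_back(-1);
  for (int g = 0; g < 3; ++g) {
    int k = build_random_tree(t, depth - 1, full, n_snps);
    t.kid[3 * idx + g] = k;
  }
  return idx;
}

void encode_node(const FlatTree& t, int node, std::vector<int>& out) {
  if (t.var[node] < 0) {
    out.push_back(1);                          // pseudoV -> class
    out.push_back(t.cls[node] == 1 ? 0 : 1);   // '+' is alternative 0
  } else {
    out.push_back(0);                          // pseudoV -> recursive rule
    out.push_back(t.var[node]);                // v -> V_(k+1)
    for (int g = 0; g < 3; ++g) encode_node(t, t.kid[3 * node + g], out);
  }
}

std::vector<int> sensible_genome(int n_snps, int max_depth, bool full,
                                 int min_c, int max_c, int codon_range) {
  FlatTree t;
  int d = full ? max_depth : 1 + rand_int(max_depth);
  build_random_tree(t, d, full, n_snps);
  std::vector<int> codons;
  encode_node(t, 0, codons);
  if ((int)codons.size() > max_c)
    stop("sensible initialization produced a genome of %d codons, above max_chromosome = %d; lower sensible_init_max_depth",
         (int)codons.size(), max_c);
  while ((int)codons.size() < min_c) codons.push_back(rand_int(codon_range));
  return codons;
}

// Per-bit mutation realised as a Binomial(n_bits, rate) flip count with
// distinct uniform positions — identical in distribution to independent
// Bernoulli flips per bit.
std::vector<int> mutate_codons(const std::vector<int>& g, double rate, int bits) {
  std::vector<int> out = g;
  if (rate <= 0.0 || g.empty()) return out;
  long nbits = (long)g.size() * bits;
  int full_mask = (1 << bits) - 1;
  if (rate >= 1.0) {
    for (size_t i = 0; i < out.size(); ++i) out[i] ^= full_mask;
    return out;
  }
  int nflip = (int)R::rbinom((double)nbits, rate);
  if (nflip <= 0) return out;
  std::set<long> pos;
  while ((int)pos.size() < nflip) {
    long p = (long)(unif_rand() * nbits);
    if (p >= nbits) continue;
    pos.insert(p);
  }
  for (std::set<long>::const_iterator it = pos.begin(); it != pos.end(); ++it) {
    int ci = (int)(*it / bits), bi = (int)(*it % bits);
    out[ci] ^= (1 << (bits - 1 - bi));  // bit 0 is the most significant
  }
  return out;
}

// One-point crossover at codon boundaries; cut points drawn independently in
// each parent. Offspring outside the chromosome-size limits trigger a
// resample of the cut points; after `retries` failures the parents are
// returned unchanged.
bool crossover_codons(const std::vector<int>& a, const std::vector<int>& b,
                      int min_c, int max_c, int retries,
                      std::vector<int>& c1, std::vector<int>& c2) {
  for (int r = 0; r < retries; ++r) {
    int ca = rand_int((int)a.size() + 1);
    int cb = rand_int((int)b.size() + 1);
    int l1 = ca + ((int)b.size() - cb);
    int l2 = cb + ((int)a.size() - ca);
    if (l1 < min_c || l1 > max_c || l2 < min_c || l2 > max_c) continue;
    c1.assign(a.begin(), a.begin() + ca);
    c1.insert(c1.end(), b.begin() + cb, b.end());
    c2.assign(b.begin(), b.begin() + cb);
    c2.insert(c2.end(), a.begin() + ca, a.end());
    return true;
  }
  c1 = a;
  c2 = b;
  return false;
}

struct Ind {
  std::vector<int> codons;
  double fit;
  int nodes;  // mapped tree size; INT_MAX for invalid (parsimony tie-break)
  Ind() : fit(0.0), nodes(INT_MAX) {}
};

void evaluate_ind(Ind& ind, const IntegerMatrix& geno, const IntegerVector& y,
                  int n_snps, int max_wraps, int n_case, int n_ctrl) {
  FlatTree t = map_codons(ind.codons, n_snps, max_wraps);
  if (t.valid) {
    ind.fit = tree_balanced_accuracy(t, geno, y, n_case, n_ctrl);
    ind.nodes = t.size();
  } else {
    ind.fit = 0.0;
    ind.nodes = INT_MAX;
  }
}

// index of tournament winner within an island (ties uniform at random)
int tournament(const std::vector<Ind>& isl, int k) {
  int best = rand_int((int)isl.size());
  int n_tie = 1;
  for (int j = 1; j < k; ++j) {
    int c = rand_int((int)isl.size());
    if (isl[c].fit > isl[best].fit) { best = c; n_tie = 1; }
    else if (isl[c].fit == isl[best].fit && c != best) {
      ++n_tie;
      if (unif_rand() < 1.0 / n_tie) best = c;
    }
  }
  return best;
}

List flat_to_list(const FlatTree& t) {
  return List::create(_["valid"] = t.valid,
                      _["var"] = IntegerVector(t.var.begin(), t.var.end()),
                      _["cls"] = IntegerVector(t.cls.begin(), t.cls.end()),
                      _["kid"] = IntegerVector(t.kid.begin(), t.kid.end()));
}

std::vector<int> as_codon_vec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

struct GaParams {
  int generations, pop_size, n_islands, migration_interval, tournament_size;
  int min_c, max_c, max_wraps, max_depth, codon_bits, codon_range;
  double crossover_rate, mutation_rate, duplication_rate;
  explicit GaParams(const List& par) {
    generations        = as<int>(par["generations"]);
    pop_size           = as<int>(par["population_size"]);
    n_islands          = as<int>(par["n_islands"]);
    migration_interval = as<int>(par["migration_interval"]);
    tournament_size    = as<int>(par["tournament_size"]);
    min_c              = as<int>(par["min_chromosome"]);
    max_c              = as<int>(par["max_chromosome"]);
    max_wraps          = as<int>(par["max_wraps"]);
    max_depth          = as<int>(par["sensible_init_max_depth"]);
    codon_bits         = as<int>(par["codon_size_bits"]);
    codon_range        = 1 << codon_bits;
    crossover_rate     = as<double>(par["crossover_rate"]);
    mutation_rate      = as<double>(par["mutation_rate"]);
    duplication_rate   = as<double>(par["duplication_rate"]);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_map(IntegerVector codons, int n_snps, int max_wraps) {
  std::vector<int> c = as_codon_vec(codons);
  return flat_to_list(map_codons(c, n_snps, max_wraps));
}

// [[Rcpp::export]]
double cpp_fitness(IntegerVector codons, IntegerMatrix geno, IntegerVector y,
                   int n_snps, int max_wraps) {
  int n_case = 0, n_ctrl = 0;
  for (int i = 0; i < y.size(); ++i) (y[i] == 1 ? n_case : n_ctrl)++;
  std::vector<int> c = as_codon_vec(codons);
  FlatTree t = map_codons(c, n_snps, max_wraps);
  return tree_balanced_accuracy(t, geno, y, n_case, n_ctrl);
}

// [[Rcpp::export]]
List cpp_sensible_init(int n, int n_snps, int max_depth, int min_c, int max_c,
                       int codon_bits) {
  int range = 1 << codon_bits;
  List out(n);
  int n_full = (n + 1) / 2;
  for (int i = 0; i < n; ++i) {
    std::vector<int> g =
        sensible_genome(n_snps, max_depth, i < n_full, min_c, max_c, range);
    out[i] = IntegerVector(g.begin(), g.end());
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mutate(IntegerVector codons, double rate, int codon_bits) {
  std::vector<int> g = mutate_codons(as_codon_vec(codons), rate, codon_bits);
  return IntegerVector(g.begin(), g.end());
}

// [[Rcpp::export]]
List cpp_crossover(IntegerVector a, IntegerVector b, int min_c, int max_c,
                   int retries) {
  std::vector<int> c1, c2;
  bool ok = crossover_codons(as_codon_vec(a), as_codon_vec(b), min_c, max_c,
                             retries, c1, c2);
  return List::create(_["child1"] = IntegerVector(c1.begin(), c1.end()),
                      _["child2"] = IntegerVector(c2.begin(), c2.end()),
                      _["crossed"] = ok);
}

// [[Rcpp::export]]
List cpp_evolve(IntegerMatrix geno, IntegerVector y, int n_snps, List par) {
  GaParams p(par);
  int n_case = 0, n_ctrl = 0;
  for (int i = 0; i < y.size(); ++i) (y[i] == 1 ? n_case : n_ctrl)++;

  // split the population across islands as evenly as possible
  std::vector<std::vector<Ind> > isl(p.n_islands);
  {
    int base = p.pop_size / p.n_islands, extra = p.pop_size % p.n_islands;
    for (int s = 0; s < p.n_islands; ++s) {
      int sz = base + (s < extra ? 1 : 0);
      isl[s].resize(sz);
      int n_full = (sz + 1) / 2;
      for (int i = 0; i < sz; ++i)
        isl[s][i].codons = sensible_genome(n_snps, p.max_depth, i < n_full,
                                           p.min_c, p.max_c, p.codon_range);
    }
  }

  Ind best;
  best.fit = -1.0;
  int best_gen = 0;
  long n_eval = 0;
  std::vector<double> trace_best, trace_mean;

  for (int gen = 1; gen <= p.generations; ++gen) {
    // evaluate every individual in every island
    double sum = 0.0;
    Ind* gen_best = 0;
    for (int s = 0; s < p.n_islands; ++s)
      for (size_t i = 0; i < isl[s].size(); ++i) {
        Ind& ind = isl[s][i];
        evaluate_ind(ind, geno, y, n_snps, p.max_wraps, n_case, n_ctrl);
        ++n_eval;
        sum += ind.fit;
        if (!gen_best || ind.fit > gen_best->fit ||
            (ind.fit == gen_best->fit && ind.nodes < gen_best->nodes))
          gen_best = &ind;
      }
    // best-ever: strict improvement only, so earlier generations win ties
    if (gen_best->fit > best.fit) {
      best = *gen_best;
      best_gen = gen;
    }
    trace_best.push_back(best.fit);
    trace_mean.push_back(sum / p.pop_size);
    if (best.fit >= 1.0 || gen == p.generations) break;

    // periodic broadcast migration: each island's best replaces the worst
    // individuals of every other island
    if (p.n_islands > 1 && p.migration_interval > 0 &&
        gen % p.migration_interval == 0) {
      std::vector<Ind> migrants;
      for (int s = 0; s < p.n_islands; ++s) {
        size_t bi = 0;
        for (size_t i = 1; i < isl[s].size(); ++i)
          if (isl[s][i].fit > isl[s][bi].fit) bi = i;
        migrants.push_back(isl[s][bi]);
      }
      for (int s = 0; s < p.n_islands; ++s) {
        // indices of the (n_islands - 1) worst residents
        std::vector<size_t> idx(isl[s].size());
        for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
        std::stable_sort(idx.begin(), idx.end(),
                         [&](size_t a, size_t b) {
                           return isl[s][a].fit < isl[s][b].fit;
                         });
        size_t w = 0;
        for (int m = 0; m < p.n_islands; ++m) {
          if (m == s) continue;
          isl[s][idx[w++]] = migrants[m];
        }
      }
    }

    // breed the next generation island by island
    for (int s = 0; s < p.n_islands; ++s) {
      int N = (int)isl[s].size();
      std::vector<size_t> idx(N);
      for (int i = 0; i < N; ++i) idx[i] = i;
      std::stable_sort(idx.begin(), idx.end(),
                       [&](size_t a, size_t b) {
                         return isl[s][a].fit > isl[s][b].fit;
                       });
      // disjoint operator fractions: the top duplication_rate of the island
      // is reproduced unchanged, crossover_rate of the new generation comes
      // from one-point crossover of tournament-selected parents (no
      // mutation), and the remainder are tournament-selected copies that
      // undergo per-bit mutation
      int n_dup = (int)(p.duplication_rate * N + 0.5);
      if (n_dup < 1) n_dup = 1;
      if (n_dup > N) n_dup = N;
      int n_cross = (int)(p.crossover_rate * N + 0.5);
      if (n_cross > N - n_dup) n_cross = N - n_dup;
      std::vector<Ind> next;
      next.reserve(N);
      for (int i = 0; i < n_dup; ++i) next.push_back(isl[s][idx[i]]);
      while ((int)next.size() < n_dup + n_cross) {
        int p1 = tournament(isl[s], p.tournament_size);
        int p2 = tournament(isl[s], p.tournament_size);
        std::vector<int> c1, c2;
        crossover_codons(isl[s][p1].codons, isl[s][p2].codons, p.min_c,
                         p.max_c, 10, c1, c2);
        Ind o1; o1.codons = c1;
        next.push_back(o1);
        if ((int)next.size() < n_dup + n_cross) {
          Ind o2; o2.codons = c2;
          next.push_back(o2);
        }
      }
      while ((int)next.size() < N) {
        int p1 = tournament(isl[s], p.tournament_size);
        Ind o;
        o.codons =
            mutate_codons(isl[s][p1].codons, p.mutation_rate, p.codon_bits);
        next.push_back(o);
      }
      isl[s].swap(next);
    }
  }

  return List::create(
      _["best_codons"] = IntegerVector(best.codons.begin(), best.codons.end()),
      _["best_fitness"] = best.fit, _["best_generation"] = best_gen,
      _["generations_run"] = (int)trace_best.size(),
      _["n_evaluations"] = (double)n_eval,
      _["trace_best"] = NumericVector(trace_best.begin(), trace_best.end()),
      _["trace_mean"] = NumericVector(trace_mean.begin(), trace_mean.end()));
}

// [[Rcpp::export]]
List cpp_random_search(IntegerMatrix geno, IntegerVector y, int n_snps,
                       List par) {
  GaParams p(par);
  int n_case = 0, n_ctrl = 0;
  for (int i = 0; i < y.size(); ++i) (y[i] == 1 ? n_case : n_ctrl)++;

  Ind best;
  best.fit = -1.0;
  int best_gen = 0;
  long n_eval = 0;
  std::vector<double> trace_best, trace_mean;

  for (int gen = 1; gen <= p.generations; ++gen) {
    double sum = 0.0;
    Ind gen_best;
    gen_best.fit = -1.0;
    int n_full = (p.pop_size + 1) / 2;
    for (int i = 0; i < p.pop_size; ++i) {
      Ind ind;
      ind.codons = sensible_genome(n_snps, p.max_depth, i < n_full, p.min_c,
                                   p.max_c, p.codon_range);
      evaluate_ind(ind, geno, y, n_snps, p.max_wraps, n_case, n_ctrl);
      ++n_eval;
      sum += ind.fit;
      if (ind.fit > gen_best.fit ||
          (ind.fit == gen_best.fit && ind.nodes < gen_best.nodes))
        gen_best = ind;
    }
    if (gen_best.fit > best.fit) {
      best = gen_best;
      best_gen = gen;
    }
    trace_best.push_back(best.fit);
    trace_mean.push_back(sum / p.pop_size);
    if (best.fit >= 1.0) break;
  }

  return List::create(
      _["best_codons"] = IntegerVector(best.codons.begin(), best.codons.end()),
      _["best_fitness"] = best.fit, _["best_generation"] = best_gen,
      _["generations_run"] = (int)trace_best.size(),
      _["n_evaluations"] = (double)n_eval,
      _["trace_best"] = NumericVector(trace_best.begin(), trace_best.end()),
      _["trace_mean"] = NumericVector(trace_mean.begin(), trace_mean.end()));
}
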