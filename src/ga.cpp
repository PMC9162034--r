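#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <cmath>

using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand / norm_rand) so that a
// single set.seed() in R fixes the whole draw stream, in the documented
// order. Exported wrappers get an RNGScope automatically via Rcpp attributes.
//
// Chromosomes are stored ROW-MAJOR internally (entry (i,j) at W[i*N + j]):
// every operator works on rows, so rows must be contiguous. Conversion to
// and from R's column-major matrices happens only at the interface.

// ---------------------------------------------------------------------------
// ordinal binning: ceiling(n * x) with the x <= 0 edge case mapping to bin 1
// and clamping to n for values a rounding error above 1.
static inline int to_bin(double x, int n) {
  if (x <= 0.0) return 1;
  int b = (int)std::ceil(x * (double)n);
  if (b < 1) b = 1;
  if (b > n) b = n;
  return b;
}

// Fitness of one chromosome against the (forward-transformed) observed panel.
// W: N x N row-major; X: T x N column-major (entry (t,i) at X[t + i*T], bin
// centres). The predicted trajectory is seeded at the observed time 0 and
// free-runs, so the t = 0 terms vanish and the loop starts at t = 1.
static void eval_fitness(const double* W, int N, const double* X, int T,
                         int nbins, double* per_gene, double* work) {
  double* cur = work;
  double* nxt = work + N;
  for (int i = 0; i < N; ++i) {
    per_gene[i] = 0.0;
    cur[i] = X[0 + i * T];
  }
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      const double* row = W + (size_t)i * N;
      double s = 0.0;
      for (int j = 0; j < N; ++j) s += row[j] * cur[j];
      nxt[i] = s;
    }
    for (int i = 0; i < N; ++i) {
      double xo = X[t + i * T];
      int bo = to_bin(xo, nbins);
      int bp = to_bin(nxt[i], nbins);
      int B = bo > bp ? bo - bp : bp - bo;
      if (B != 0) per_gene[i] += (double)B * std::fabs(nxt[i] - xo);
      cur[i] = nxt[i];
    }
  }
}

static inline double sum_n(const double* v, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += v[i];
  return s;
}

// ---------------------------------------------------------------------------
// Operators on row-major chromosomes. `free_pos[i]` lists the evolvable
// (non-fixed) column indices of row i; `wfix[i]` is the row's total fixed
// weight, so the evolvable weights of row i must sum to 1 - wfix[i].

// Blending: per row one Unif(0,1) coin; if it fires, one Unif(0,1) beta and
// both rows are replaced by their convex combinations. Fixed entries are
// identical in both parents and are preserved automatically.
static void op_blend(double* A, double* B, int N, double pb) {
  for (int i = 0; i < N; ++i) {
    if (unif_rand() < pb) {
      double beta = unif_rand();
      double* ra = A + (size_t)i * N;
      double* rb = B + (size_t)i * N;
      for (int j = 0; j < N; ++j) {
        double a = ra[j], b = rb[j];
        ra[j] = beta * a + (1.0 - beta) * b;
        rb[j] = (1.0 - beta) * a + beta * b;
      }
    }
  }
}

// Crossover: per row one coin; if it fires and the row has >= 2 evolvable
// positions, Fisher-Yates shuffle of the evolvable values (m - 1 index draws).
static void op_crossover(double* W, int N, double pc,
                         const std::vector<std::vector<int>>& free_pos,
                         std::vector<double>& buf) {
  for (int i = 0; i < N; ++i) {
    if (unif_rand() < pc) {
      const std::vector<int>& fp = free_pos[i];
      int m = (int)fp.size();
      if (m < 2) continue;
      double* row = W + (size_t)i * N;
      buf.resize(m);
      for (int q = 0; q < m; ++q) buf[q] = row[fp[q]];
      for (int idx = m - 1; idx > 0; --idx) {
        int j = (int)(unif_rand() * (idx + 1));
        if (j > idx) j = idx;
        double tmp = buf[idx]; buf[idx] = buf[j]; buf[j] = tmp;
      }
      for (int q = 0; q < m; ++q) row[fp[q]] = buf[q];
    }
  }
}

// Mutation: per row one coin; if it fires and the row has >= 2 evolvable
// positions, one uniform position draw and one Normal(0, sigma^2) epsilon,
// then the boundary rules: clamp below at 0; clamp above at 1 - wfix with
// all other evolvable weights zeroed; even redistribution when the selected
// weight held the entire evolvable mass; multiplicative rescaling otherwise.
static void op_mutate(double* W, int N, double pm, double sigma,
                      const std::vector<std::vector<int>>& free_pos,
                      const std::vector<double>& wfix) {
  for (int i = 0; i < N; ++i) {
    if (unif_rand() < pm) {
      const std::vector<int>& fp = free_pos[i];
      int m = (int)fp.size();
      if (m < 2) continue;
      double* row = W + (size_t)i * N;
      int pos = (int)(unif_rand() * m);
      if (pos >= m) pos = m - 1;
      double eps = norm_rand() * sigma;
      double avail = 1.0 - wfix[i];
      double wold = row[fp[pos]];
      double wstar = wold + eps;
      if (wstar > avail) {
        for (int q = 0; q < m; ++q) row[fp[q]] = 0.0;
        row[fp[pos]] = avail;
      } else {
        if (wstar < 0.0) wstar = 0.0;
        double others = avail - wold;
        if (others <= 0.0) {
          double share = (avail - wstar) / (double)(m - 1);
          for (int q = 0; q < m; ++q) row[fp[q]] = share;
          row[fp[pos]] = wstar;
        } else {
          double scale = (avail - wstar) / others;
          for (int q = 0; q < m; ++q) row[fp[q]] *= scale;
          row[fp[pos]] = wstar;
        }
      }
    }
  }
}

// Gene swap: for each row, find the donor whose gene (evaluated inside its
// own chromosome) is strictly fitter than best's; apply all such swaps at
// once, re-evaluate, keep everything iff the total strictly improves (donors
// then receive best's old rows). Ties among donors go to the earliest donor.
// Returns true iff accepted; on accept, best/per_gene/total are updated in
// place and dirty[] flags donors whose rows changed.
static bool do_gene_swap(double* best, double* best_pg, double& best_tot,
                         double* const* donors, double* const* donor_pg,
                         int ndon, char* dirty,
                         const double* X, int T, int nbins, int N,
                         std::vector<double>& trial,
                         std::vector<double>& trial_pg,
                         std::vector<double>& work,
                         std::vector<int>& src) {
  src.assign(N, -1);
  bool any = false;
  for (int i = 0; i < N; ++i) {
    double v = best_pg[i];
    for (int d = 0; d < ndon; ++d) {
      if (donor_pg[d][i] < v) { v = donor_pg[d][i]; src[i] = d; }
    }
    if (src[i] >= 0) any = true;
  }
  if (!any) return false;
  for (int i = 0; i < N; ++i) {
    const double* from = src[i] >= 0 ? donors[src[i]] : best;
    std::copy(from + (size_t)i * N, from + (size_t)(i + 1) * N,
              trial.data() + (size_t)i * N);
  }
  eval_fitness(trial.data(), N, X, T, nbins, trial_pg.data(), work.data());
  double trial_tot = sum_n(trial_pg.data(), N);
  if (trial_tot < best_tot) {
    for (int i = 0; i < N; ++i) {
      if (src[i] >= 0) {
        std::copy(best + (size_t)i * N, best + (size_t)(i + 1) * N,
                  donors[src[i]] + (size_t)i * N);
        dirty[src[i]] = 1;
      }
    }
    std::copy(trial.begin(), trial.end(), best);
    std::copy(trial_pg.begin(), trial_pg.end(), best_pg);
    best_tot = trial_tot;
    return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// interface helpers

static std::vector<std::vector<int>> free_list(const NumericMatrix& free_mask) {
  int N = free_mask.nrow();
  std::vector<std::vector<int>> fp(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (free_mask(i, j) != 0.0) fp[i].push_back(j);
  return fp;
}

static std::vector<double> fixed_row_sums(const NumericMatrix& fixed_values,
                                          const NumericMatrix& free_mask) {
  int N = free_mask.nrow();
  std::vector<double> wfix(N, 0.0);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      if (free_mask(i, j) == 0.0) wfix[i] += fixed_values(i, j);
  return wfix;
}

static std::vector<double> to_rowmajor(const NumericMatrix& W) {
  int N = W.nrow();
  std::vector<double> out((size_t)N * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) out[(size_t)i * N + j] = W(i, j);
  return out;
}

static NumericMatrix from_rowmajor(const std::vector<double>& W, int N) {
  NumericMatrix out(N, N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) out(i, j) = W[(size_t)i * N + j];
  return out;
}

// [[Rcpp::export]]
List cpp_fitness(NumericMatrix W, NumericMatrix x_obs, int nbins) {
  int N = W.nrow();
  int T = x_obs.nrow();
  std::vector<double> w = to_rowmajor(W);
  std::vector<double> pg(N), work(2 * N);
  eval_fitness(w.data(), N, REAL(x_obs), T, nbins, pg.data(), work.data());
  return List::create(_["total"] = sum_n(pg.data(), N),
                      _["per_gene"] = NumericVector(pg.begin(), pg.end()));
}

// [[Rcpp::export]]
List cpp_blend_pair(NumericMatrix B, NumericMatrix C, double pb) {
  int N = B.nrow();
  std::vector<double> b = to_rowmajor(B), c = to_rowmajor(C);
  op_blend(b.data(), c.data(), N, pb);
  return List::create(_["B"] = from_rowmajor(b, N),
                      _["C"] = from_rowmajor(c, N));
}

// [[Rcpp::export]]
NumericMatrix cpp_crossover(NumericMatrix W, double pc, NumericMatrix free_mask) {
  int N = W.nrow();
  std::vector<double> w = to_rowmajor(W);
  std::vector<double> buf;
  op_crossover(w.data(), N, pc, free_list(free_mask), buf);
  return from_rowmajor(w, N);
}

// [[Rcpp::export]]
NumericMatrix cpp_mutate(NumericMatrix W, double pm, double sigma,
                         NumericMatrix free_mask, NumericMatrix fixed_values) {
  int N = W.nrow();
  std::vector<double> w = to_rowmajor(W);
  op_mutate(w.data(), N, pm, sigma, free_list(free_mask),
            fixed_row_sums(fixed_values, free_mask));
  return from_rowmajor(w, N);
}

// [[Rcpp::export]]
List cpp_gene_swap(NumericMatrix best, List donors, NumericMatrix x_obs,
                   int nbins) {
  int N = best.nrow(), T = x_obs.nrow();
  int nd = donors.size();
  std::vector<double> b = to_rowmajor(best);
  std::vector<std::vector<double>> dw(nd);
  std::vector<std::vector<double>> dpg(nd, std::vector<double>(N));
  std::vector<double*> dptr(nd), dpgp(nd);
  std::vector<char> dirty(nd, 0);
  std::vector<double> best_pg(N), work(2 * N), trial((size_t)N * N),
      trial_pg(N);
  std::vector<int> src;
  eval_fitness(b.data(), N, REAL(x_obs), T, nbins, best_pg.data(),
               work.data());
  double best_tot = sum_n(best_pg.data(), N);
  for (int d = 0; d < nd; ++d) {
    dw[d] = to_rowmajor(as<NumericMatrix>(donors[d]));
    dptr[d] = dw[d].data();
    eval_fitness(dptr[d], N, REAL(x_obs), T, nbins, dpg[d].data(),
                 work.data());
    dpgp[d] = dpg[d].data();
  }
  bool acc = do_gene_swap(b.data(), best_pg.data(), best_tot, dptr.data(),
                          dpgp.data(), nd, dirty.data(), REAL(x_obs), T,
                          nbins, N, trial, trial_pg, work, src);
  List out_donors(nd);
  for (int d = 0; d < nd; ++d) out_donors[d] = from_rowmajor(dw[d], N);
  return List::create(_["best"] = from_rowmajor(b, N),
                      _["donors"] = out_donors,
                      _["accepted"] = acc, _["total"] = best_tot,
                      _["per_gene"] = NumericVector(best_pg.begin(),
                                                    best_pg.end()));
}

// ---------------------------------------------------------------------------
// Full adaptive GA run. The initial population is supplied from R (so the
// initialization draws are shared with initialize_population()); all
// in-loop draws happen here on the same RNG stream. Draw order per
// generation: pairing permutation; per pair (in pairing order) blending row
// coins/betas; per offspring (original index order) crossover row
// coins/shuffles; per offspring mutation row coins/positions/epsilons.
// [[Rcpp::export]]
List cpp_run_ga(List init_pop, NumericMatrix free_mask, NumericMatrix fixed_values,
                NumericMatrix x_obs, int nbins, List hp, bool record_history) {
  const int N = free_mask.nrow();
  const int T = x_obs.nrow();
  const int k = init_pop.size();
  const double* X = REAL(x_obs);

  const double probb = hp["probb"], factorb = hp["factorb"], maxb = hp["maxb"];
  const double probc = hp["probc"], factorc = hp["factorc"], minc = hp["minc"];
  const double probm = hp["probm"], factorm = hp["factorm"], minm = hp["minm"];
  const double sigma0 = hp["sigma"], factors = hp["factors"], mins = hp["mins"];
  const int iterb = hp["iterb"], iterc = hp["iterc"], iterm = hp["iterm"];
  const int iters = hp["iters"], iterr = hp["iterr"];
  const int max_iter = hp["max_iter"];
  const double min_improve = hp["min_improve"], min_dev = hp["min_dev"];
  const bool reintroduce_identity =
      as<std::string>(hp["reintroduce"]) == "identity";

  std::vector<std::vector<int>> fp = free_list(free_mask);
  std::vector<double> wfix = fixed_row_sums(fixed_values, free_mask);
  const size_t NN = (size_t)N * N;

  // identity chromosome respecting fixed values (evolvable diagonal assumed)
  std::vector<double> identity(NN);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j)
      identity[(size_t)i * N + j] =
          free_mask(i, j) != 0.0 ? 0.0 : fixed_values(i, j);
  for (int i = 0; i < N; ++i) identity[(size_t)i * N + i] += 1.0 - wfix[i];

  // population state with cached fitness
  std::vector<std::vector<double>> pop(k, std::vector<double>(NN));
  std::vector<std::vector<double>> pg(k, std::vector<double>(N));
  std::vector<double> tot(k);
  std::vector<double> work(2 * N), trial(NN), trial_pg(N), buf;
  std::vector<int> src;
  for (int c = 0; c < k; ++c) {
    pop[c] = to_rowmajor(as<NumericMatrix>(init_pop[c]));
    eval_fitness(pop[c].data(), N, X, T, nbins, pg[c].data(), work.data());
    tot[c] = sum_n(pg[c].data(), N);
  }

  const int m = k - 1;  // even number of non-elite chromosomes
  std::vector<std::vector<double>> off(m, std::vector<double>(NN));
  std::vector<std::vector<double>> off_pg(m, std::vector<double>(N));
  std::vector<double> off_tot(m);
  std::vector<int> perm(m);
  std::vector<double*> dptr(m), dpgp(m);
  std::vector<char> dirty(m, 0);

  double pb = probb, pc = probc, pm = probm, sigma = sigma0;
  int stagnation = 0;
  int gen = 0;

  NumericMatrix history;
  if (record_history) history = NumericMatrix(max_iter, 5);
  std::vector<double> block_times;
  auto block_start = std::chrono::steady_clock::now();

  double prev_elite;
  {
    int e0 = 0;
    for (int c = 1; c < k; ++c) if (tot[c] < tot[e0]) e0 = c;
    prev_elite = tot[e0];
  }

  while (gen < max_iter) {
    ++gen;

    // --- selection with elitism + multi-donor gene swap
    int ei = 0;
    for (int c = 1; c < k; ++c) if (tot[c] < tot[ei]) ei = c;
    // move elite to slot 0, preserving the relative order of the rest
    if (ei != 0) {
      std::vector<double> ew = std::move(pop[ei]);
      std::vector<double> eg = std::move(pg[ei]);
      double et = tot[ei];
      for (int c = ei; c > 0; --c) {
        pop[c] = std::move(pop[c - 1]);
        pg[c] = std::move(pg[c - 1]);
        tot[c] = tot[c - 1];
      }
      pop[0] = std::move(ew); pg[0] = std::move(eg); tot[0] = et;
    }
    for (int d = 0; d < m; ++d) {
      dptr[d] = pop[d + 1].data();
      dpgp[d] = pg[d + 1].data();
      dirty[d] = 0;
    }
    bool acc = do_gene_swap(pop[0].data(), pg[0].data(), tot[0], dptr.data(),
                            dpgp.data(), m, dirty.data(), X, T, nbins, N,
                            trial, trial_pg, work, src);
    if (acc) {
      for (int d = 0; d < m; ++d) {
        if (dirty[d]) {
          eval_fitness(pop[d + 1].data(), N, X, T, nbins, pg[d + 1].data(),
                       work.data());
          tot[d + 1] = sum_n(pg[d + 1].data(), N);
        }
      }
    }

    // --- offspring = copies of the non-elite parents
    for (int d = 0; d < m; ++d) off[d] = pop[d + 1];

    // --- blending on random pairs
    for (int d = 0; d < m; ++d) perm[d] = d;
    for (int idx = m - 1; idx > 0; --idx) {
      int j = (int)(unif_rand() * (idx + 1));
      if (j > idx) j = idx;
      int tmp = perm[idx]; perm[idx] = perm[j]; perm[j] = tmp;
    }
    for (int p = 0; p + 1 < m; p += 2)
      op_blend(off[perm[p]].data(), off[perm[p + 1]].data(), N, pb);

    // --- crossover, mutation
    for (int d = 0; d < m; ++d)
      op_crossover(off[d].data(), N, pc, fp, buf);
    for (int d = 0; d < m; ++d)
      op_mutate(off[d].data(), N, pm, sigma, fp, wfix);

    // --- survival: pairwise (parent d vs offspring d) with gene swap;
    //     the fitter of the pair (tie to the parent) keeps slot d+1
    for (int d = 0; d < m; ++d) {
      eval_fitness(off[d].data(), N, X, T, nbins, off_pg[d].data(),
                   work.data());
      off_tot[d] = sum_n(off_pg[d].data(), N);
      char dd = 0;
      if (tot[d + 1] <= off_tot[d]) {
        double* donw = off[d].data();
        double* dong = off_pg[d].data();
        do_gene_swap(pop[d + 1].data(), pg[d + 1].data(), tot[d + 1],
                     &donw, &dong, 1, &dd, X, T, nbins, N,
                     trial, trial_pg, work, src);
      } else {
        double* donw = pop[d + 1].data();
        double* dong = pg[d + 1].data();
        do_gene_swap(off[d].data(), off_pg[d].data(), off_tot[d],
                     &donw, &dong, 1, &dd, X, T, nbins, N,
                     trial, trial_pg, work, src);
        std::swap(pop[d + 1], off[d]);
        std::swap(pg[d + 1], off_pg[d]);
        tot[d + 1] = off_tot[d];
      }
    }

    // --- stagnation bookkeeping on the elite objective
    int ei2 = 0;
    for (int c = 1; c < k; ++c) if (tot[c] < tot[ei2]) ei2 = c;
    double elite_tot = tot[ei2];
    if (prev_elite - elite_tot > min_improve) stagnation = 0;
    else ++stagnation;
    prev_elite = elite_tot;

    // --- reintroduction into the non-elite population
    if (stagnation > 0 && stagnation % iterr == 0) {
      int worst = 1;
      for (int c = 2; c < k; ++c) if (tot[c] >= tot[worst]) worst = c;
      if (reintroduce_identity) {
        pop[worst] = identity;
        eval_fitness(pop[worst].data(), N, X, T, nbins, pg[worst].data(),
                     work.data());
        tot[worst] = sum_n(pg[worst].data(), N);
      } else {
        int esrc = (ei2 == worst) ? 0 : ei2;
        pop[worst] = pop[esrc];
        pg[worst] = pg[esrc];
        tot[worst] = tot[esrc];
      }
    }

    // --- multiplicative control-parameter adaptation with clamping
    if (stagnation > 0) {
      if (stagnation % iterb == 0) pb = std::min(factorb * pb, maxb);
      if (stagnation % iterc == 0) pc = std::max(factorc * pc, minc);
      if (stagnation % iterm == 0) pm = std::max(factorm * pm, minm);
      if (stagnation % iters == 0) sigma = std::max(factors * sigma, mins);
    }

    if (record_history) {
      history(gen - 1, 0) = elite_tot;
      history(gen - 1, 1) = pb;
      history(gen - 1, 2) = pc;
      history(gen - 1, 3) = pm;
      history(gen - 1, 4) = sigma;
    }

    // --- stopping: solution check only every thousand generations
    if (gen % 1000 == 0) {
      auto now = std::chrono::steady_clock::now();
      block_times.push_back(
          std::chrono::duration<double>(now - block_start).count());
      block_start = now;
      if (elite_tot <= min_dev) break;
    }
  }

  if (gen % 1000 != 0) {
    auto now = std::chrono::steady_clock::now();
    block_times.push_back(
        std::chrono::duration<double>(now - block_start).count());
  }
  int ef = 0;
  for (int c = 1; c < k; ++c) if (tot[c] < tot[ef]) ef = c;
  bool solved = tot[ef] <= min_dev;

  List out = List::create(
      _["best"] = from_rowmajor(pop[ef], N),
      _["total"] = tot[ef],
      _["per_gene"] = NumericVector(pg[ef].begin(), pg[ef].end()),
      _["generations"] = gen,
      _["solved"] = solved,
      _["block_times"] = NumericVector(block_times.begin(), block_times.end()),
      _["controls"] = NumericVector::create(_["p_b"] = pb, _["p_c"] = pc,
                                            _["p_m"] = pm, _["sigma"] = sigma),
      _["stagnation"] = stagnation);
  if (record_history) {
    out["history"] = history(Range(0, gen - 1), Range(0, 4));
  }
  return out;
}
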