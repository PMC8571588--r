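#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Backward-time coalescent for one locus under a piecewise-constant,
// event-driven demography.  Time is measured in generations, backwards from
// the present.  Events (rows of `events`, sorted by ascending time):
//   type 1: merge   -- all lineages in pop a move to pop b
//   type 2: admix   -- each lineage in pop a moves to pop b with prob x,
//                      else to pop c
//   type 3: resize  -- pop a's effective size N becomes x
// Coalescence within a pop of (diploid) size N occurs at rate C(k,2)/(2N)
// per generation among its k lineages.  Uses R's RNG throughout so set.seed()
// governs reproducibility.

struct Tree {
  std::vector<double> time;
  std::vector<int> parent;
  int root;
};

static Tree sim_tree(const IntegerVector& sample_sizes,
                     const NumericVector& pop_sizes,
                     const NumericMatrix& events) {
  const int npop = sample_sizes.size();
  int n_tips = 0;
  for (int p = 0; p < npop; ++p) n_tips += sample_sizes[p];
  if (n_tips < 2) stop("need at least two sampled gene copies");

  Tree tr;
  tr.time.assign(2 * n_tips - 1, 0.0);
  tr.parent.assign(2 * n_tips - 1, -1);
  int next_node = n_tips;

  std::vector<int> lin_node(n_tips), lin_pop(n_tips);
  {
    int k = 0;
    for (int p = 0; p < npop; ++p)
      for (int i = 0; i < sample_sizes[p]; ++i) { lin_node[k] = k; lin_pop[k] = p; ++k; }
  }
  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  for (int p = 0; p < npop; ++p)
    if (!(N[p] > 0)) stop("population sizes must be positive");

  double t = 0.0;
  int ei = 0;
  const int n_ev = events.nrow();
  std::vector<double> rate(npop);

  while (lin_node.size() > 1) {
    double total = 0.0;
    std::vector<int> k_in(npop, 0);
    for (size_t i = 0; i < lin_pop.size(); ++i) k_in[lin_pop[i]]++;
    for (int p = 0; p < npop; ++p) {
      double k = k_in[p];
      rate[p] = (k >= 2) ? k * (k - 1.0) / 2.0 / (2.0 * N[p]) : 0.0;
      total += rate[p];
    }
    double t_next = (total > 0) ? t + R::exp_rand() / total : R_PosInf;

    if (ei < n_ev && events(ei, 0) <= t_next) {
      t = events(ei, 0);
      int type = (int)events(ei, 1);
      int a = (int)events(ei, 2);
      if (type == 1) {
        int b = (int)events(ei, 3);
        for (size_t i = 0; i < lin_pop.size(); ++i)
          if (lin_pop[i] == a) lin_pop[i] = b;
      } else if (type == 2) {
        int b = (int)events(ei, 3), c = (int)events(ei, 4);
        double r = events(ei, 5);
        for (size_t i = 0; i < lin_pop.size(); ++i)
          if (lin_pop[i] == a) lin_pop[i] = (unif_rand() < r) ? b : c;
      } else if (type == 3) {
        double newN = events(ei, 5);
        if (!(newN > 0)) stop("resize event with non-positive N");
        N[a] = newN;
      } else stop("unknown event type");
      ++ei;
      continue;
    }

    if (!R_FINITE(t_next))
      stop("lineages stranded: no coalescence possible and no events remain");
    t = t_next;
    // pick population proportional to rate
    double u = unif_rand() * total, acc = 0.0;
    int pp = npop - 1;
    for (int p = 0; p < npop; ++p) { acc += rate[p]; if (u <= acc) { pp = p; break; } }
    // pick an unordered pair uniformly within pop pp
    std::vector<int> idx;
    for (size_t i = 0; i < lin_pop.size(); ++i)
      if (lin_pop[i] == pp) idx.push_back((int)i);
    int k = idx.size();
    int i1 = (int)(unif_rand() * k); if (i1 == k) i1 = k - 1;
    int i2 = (int)(unif_rand() * (k - 1)); if (i2 == k - 1) i2 = k - 2;
    if (i2 >= i1) ++i2;
    int a = idx[i1], b = idx[i2];
    tr.time[next_node] = t;
    tr.parent[lin_node[a]] = next_node;
    tr.parent[lin_node[b]] = next_node;
    lin_node[a] = next_node;
    lin_pop[a] = pp;
    // remove lineage b
    lin_node[b] = lin_node.back(); lin_node.pop_back();
    lin_pop[b] = lin_pop.back(); lin_pop.pop_back();
    ++next_node;
  }
  tr.root = lin_node[0];
  return tr;
}

static int smm_net(double mu_len) {
  int m = (int)R::rpois(mu_len);
  int net = 0;
  for (int j = 0; j < m; ++j) net += (unif_rand() < 0.5) ? -1 : 1;
  return net;
}

// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector sample_sizes, NumericVector pop_sizes,
                   NumericMatrix events, double mu, int ancestral_size) {
  Tree tr = sim_tree(sample_sizes, pop_sizes, events);
  int nnode = tr.time.size();
  int n_tips = (nnode + 1) / 2;
  std::vector<int> size(nnode);
  size[tr.root] = ancestral_size;
  // parents are always created after children, so a reverse index sweep
  // visits every parent before its children
  for (int v = nnode - 1; v >= 0; --v) {
    if (v == tr.root) continue;
    double len = tr.time[tr.parent[v]] - tr.time[v];
    size[v] = size[tr.parent[v]] + ((mu > 0) ? smm_net(mu * len) : 0);
  }
  IntegerVector alleles(n_tips);
  for (int i = 0; i < n_tips; ++i) alleles[i] = size[i];
  return List::create(_["alleles"] = alleles,
                      _["tmrca"] = tr.time[tr.root],
                      _["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["node_time"] = NumericVector(tr.time.begin(), tr.time.end()));
}

// [[Rcpp::export]]
IntegerMatrix sim_dataset_cpp(IntegerVector sample_sizes, NumericVector pop_sizes,
                              NumericMatrix events, double mu, int n_loci,
                              int ancestral_size) {
  int n_tips = 0;
  for (int p = 0; p < sample_sizes.size(); ++p) n_tips += sample_sizes[p];
  IntegerMatrix out(n_tips, n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Tree tr = sim_tree(sample_sizes, pop_sizes, events);
    int nnode = tr.time.size();
    std::vector<int> size(nnode);
    size[tr.root] = ancestral_size;
    for (int v = nnode - 1; v >= 0; --v) {
      if (v == tr.root) continue;
      double len = tr.time[tr.parent[v]] - tr.time[v];
      size[v] = size[tr.parent[v]] + ((mu > 0) ? smm_net(mu * len) : 0);
    }
    for (int i = 0; i < n_tips; ++i) out(i, l) = size[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Summary statistics on a gene-copy matrix (n_copies x L), NA allowed.
// Copies 2i, 2i+1 belong to diploid individual i (used for allele sharing).
// Output layout: for each pop {NAL, HET, VAR}; for each pair
// {NAL, HET, VAR (pooled), FST, DAS, DMU2}; for each trio {alpha}.

typedef std::map<int, int> AlleleCount;

static void locus_counts(const IntegerMatrix& g, int l,
                         const std::vector<int>& rows, AlleleCount& cnt, int& n) {
  cnt.clear(); n = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    int a = g(rows[i], l);
    if (a == NA_INTEGER) continue;
    cnt[a]++; ++n;
  }
}

static double gene_div(const AlleleCount& cnt, int n, bool unbiased) {
  if (n < 2) return NA_REAL;
  double s2 = 0.0;
  for (AlleleCount::const_iterator it = cnt.begin(); it != cnt.end(); ++it) {
    double p = (double)it->second / n;
    s2 += p * p;
  }
  double h = 1.0 - s2;
  return unbiased ? h * n / (n - 1.0) : h;
}

static double size_var(const IntegerMatrix& g, int l, const std::vector<int>& rows) {
  double s = 0, s2 = 0; int n = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    int a = g(rows[i], l);
    if (a == NA_INTEGER) continue;
    s += a; s2 += (double)a * a; ++n;
  }
  if (n < 2) return NA_REAL;
  double m = s / n;
  return (s2 - n * m * m) / (n - 1.0);
}

// [[Rcpp::export]]
NumericVector summary_stats_cpp(IntegerMatrix geno, IntegerVector pop, int npop,
                                IntegerMatrix pairs, IntegerMatrix trios,
                                bool do_das = true) {
  const int L = geno.ncol();
  const int npair = pairs.nrow(), ntrio = trios.nrow();
  std::vector< std::vector<int> > rows(npop);
  for (int i = 0; i < pop.size(); ++i) rows[pop[i]].push_back(i);

  NumericVector out(3 * npop + 6 * npair + ntrio);
  int oi = 0;
  AlleleCount cnt, cnt2;

  for (int p = 0; p < npop; ++p) {
    double nal = 0, het = 0, var = 0; int n_nal = 0, n_het = 0, n_var = 0;
    for (int l = 0; l < L; ++l) {
      int n; locus_counts(geno, l, rows[p], cnt, n);
      if (n > 0) { nal += cnt.size(); ++n_nal; }
      double h = gene_div(cnt, n, true);
      if (!ISNA(h)) { het += h; ++n_het; }
      double v = size_var(geno, l, rows[p]);
      if (!ISNA(v)) { var += v; ++n_var; }
    }
    out[oi++] = n_nal ? nal / n_nal : NA_REAL;
    out[oi++] = n_het ? het / n_het : NA_REAL;
    out[oi++] = n_var ? var / n_var : NA_REAL;
  }

  for (int q = 0; q < npair; ++q) {
    int p1 = pairs(q, 0), p2 = pairs(q, 1);
    std::vector<int> pooled(rows[p1]);
    pooled.insert(pooled.end(), rows[p2].begin(), rows[p2].end());
    double nal = 0, het = 0, var = 0;
    int n_nal = 0, n_het = 0, n_var = 0;
    double hb_sum = 0, hw_sum = 0; // for ratio-of-sums FST
    double dmu2 = 0; int n_dmu = 0;
    double das_sum = 0; long das_n = 0;
    for (int l = 0; l < L; ++l) {
      int n; locus_counts(geno, l, pooled, cnt, n);
      if (n > 0) { nal += cnt.size(); ++n_nal; }
      double h = gene_div(cnt, n, true);
      if (!ISNA(h)) { het += h; ++n_het; }
      double v = size_var(geno, l, pooled);
      if (!ISNA(v)) { var += v; ++n_var; }

      int n1, n2;
      locus_counts(geno, l, rows[p1], cnt, n1);
      locus_counts(geno, l, rows[p2], cnt2, n2);
      if (n1 >= 2 && n2 >= 2) {
        double h1 = gene_div(cnt, n1, true), h2 = gene_div(cnt2, n2, true);
        double cross = 0.0;
        for (AlleleCount::iterator it = cnt.begin(); it != cnt.end(); ++it) {
          AlleleCount::iterator jt = cnt2.find(it->first);
          if (jt != cnt2.end())
            cross += ((double)it->second / n1) * ((double)jt->second / n2);
        }
        double hb = 1.0 - cross;
        hb_sum += hb; hw_sum += 0.5 * (h1 + h2);
        double m1 = 0, m2 = 0;
        for (AlleleCount::iterator it = cnt.begin(); it != cnt.end(); ++it)
          m1 += (double)it->first * it->second / n1;
        for (AlleleCount::iterator it = cnt2.begin(); it != cnt2.end(); ++it)
          m2 += (double)it->first * it->second / n2;
        dmu2 += (m1 - m2) * (m1 - m2); ++n_dmu;
      }
      // allele sharing between cross-population diploid individuals
      if (do_das)
      for (size_t i = 0; i + 1 < rows[p1].size(); i += 2) {
        int a1 = geno(rows[p1][i], l), a2 = geno(rows[p1][i + 1], l);
        if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
        for (size_t j = 0; j + 1 < rows[p2].size(); j += 2) {
          int b1 = geno(rows[p2][j], l), b2 = geno(rows[p2][j + 1], l);
          if (b1 == NA_INTEGER || b2 == NA_INTEGER) continue;
          // shared alleles with multiplicity (min-count matching)
          int sh = 0;
          {
            std::map<int,int> ca, cb;
            ca[a1]++; ca[a2]++; cb[b1]++; cb[b2]++;
            for (std::map<int,int>::iterator it = ca.begin(); it != ca.end(); ++it) {
              std::map<int,int>::iterator jt = cb.find(it->first);
              if (jt != cb.end()) sh += std::min(it->second, jt->second);
            }
          }
          das_sum += sh / 2.0; ++das_n;
        }
      }
    }
    out[oi++] = n_nal ? nal / n_nal : NA_REAL;
    out[oi++] = n_het ? het / n_het : NA_REAL;
    out[oi++] = n_var ? var / n_var : NA_REAL;
    out[oi++] = (hb_sum > 0) ? (hb_sum - hw_sum) / hb_sum : NA_REAL;
    out[oi++] = das_n ? 1.0 - das_sum / das_n : NA_REAL;
    out[oi++] = n_dmu ? dmu2 / n_dmu : NA_REAL;
  }

  for (int s = 0; s < ntrio; ++s) {
    int pa = trios(s, 0), p1 = trios(s, 1), p2 = trios(s, 2);
    double num = 0, den = 0;
    AlleleCount ca, c1, c2;
    for (int l = 0; l < L; ++l) {
      int na, n1, n2;
      locus_counts(geno, l, rows[pa], ca, na);
      locus_counts(geno, l, rows[p1], c1, n1);
      locus_counts(geno, l, rows[p2], c2, n2);
      if (na < 1 || n1 < 1 || n2 < 1) continue;
      std::map<int, bool> alleles;
      for (AlleleCount::iterator it = ca.begin(); it != ca.end(); ++it) alleles[it->first] = true;
      for (AlleleCount::iterator it = c1.begin(); it != c1.end(); ++it) alleles[it->first] = true;
      for (AlleleCount::iterator it = c2.begin(); it != c2.end(); ++it) alleles[it->first] = true;
      for (std::map<int, bool>::iterator it = alleles.begin(); it != alleles.end(); ++it) {
        int a = it->first;
        double fa = ca.count(a) ? (double)ca[a] / na : 0.0;
        double f1 = c1.count(a) ? (double)c1[a] / n1 : 0.0;
        double f2 = c2.count(a) ? (double)c2[a] / n2 : 0.0;
        num += (fa - f2) * (f1 - f2);
        den += (f1 - f2) * (f1 - f2);
      }
    }
    double alpha = (den > 0) ? num / den : NA_REAL;
    if (!ISNA(alpha)) alpha = std::max(0.0, std::min(1.0, alpha));
    out[oi++] = alpha;
  }
  return out;
}
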