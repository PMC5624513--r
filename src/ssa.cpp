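#include <Rcpp.h>
using namespace Rcpp;

// Thermodynamic mean-activation transcription rate for one gene.
// reg_levels: current levels of the regulating species (proteins and/or the
// stimulating ligand), reg_act: TRUE for activators, reg_k: dissociation
// constants. States enumerate every subset of regulators with at most two
// bound; a state's weight is the product of occupancies chi = level / k.
// Relative rates: a0 unbound, a_inh if any bound inhibitor (inhibition
// dominates), a_act if only activators bound.
// [[Rcpp::export]]
double thermo_rate_cpp(NumericVector reg_levels, LogicalVector reg_act,
                       NumericVector reg_k, double alpha_txn, double a0,
                       double a_act, double a_inh) {
  int m = reg_levels.size();
  double num = a0, den = 1.0; // empty state: weight 1, rate a0
  for (int mask = 1; mask < (1 << m); ++mask) {
    int nb = 0;
    for (int i = 0; i < m; ++i) if (mask & (1 << i)) ++nb;
    if (nb > 2) continue; // at most two regulators bound simultaneously
    double w = 1.0;
    bool inh = false;
    for (int i = 0; i < m; ++i) {
      if (mask & (1 << i)) {
        w *= reg_levels[i] / reg_k[i];
        if (!reg_act[i]) inh = true;
      }
    }
    num += w * (inh ? a_inh : a_act);
    den += w;
  }
  return alpha_txn * num / den;
}

static inline void record_state(IntegerMatrix &rec, int row,
                                const std::vector<double> &x,
                                const std::vector<double> &y, double s) {
  int n = x.size();
  for (int i = 0; i < n; ++i) rec(row, i) = (int)x[i];
  for (int i = 0; i < (int)y.size(); ++i) rec(row, n + i) = (int)y[i];
  rec(row, n + y.size()) = (int)s;
}

// One exact SSA trajectory of the three-gene (or general) thermodynamic
// model: species mRNA x_i, protein y_i, clamped stimulus s. Reactions per
// gene: mRNA decay, protein decay, saturating translation, thermodynamic
// transcription. Uses R's RNG (seed with set.seed before calling).
// edges: rows (regulator, target, activating) with 0-based gene indices.
// [[Rcpp::export]]
IntegerMatrix ssa_thermo_cpp(int n_genes, IntegerMatrix edges,
                             IntegerVector init_x, IntegerVector init_y,
                             double lambda, double alpha_txn,
                             double alpha_transl, NumericVector k_half,
                             double a0, double a_act, double a_inh,
                             int stim_target, double stim_time,
                             double stim_level, double stim_k,
                             NumericVector record_times, double t_end) {
  std::vector<double> x(n_genes), y(n_genes);
  for (int i = 0; i < n_genes; ++i) { x[i] = init_x[i]; y[i] = init_y[i]; }
  double s = 0.0;

  // per-gene regulator lists (protein regulators plus optional stimulus)
  std::vector<std::vector<int>> reg_src(n_genes);   // -1 for stimulus
  std::vector<std::vector<int>> reg_act(n_genes);
  for (int e = 0; e < edges.nrow(); ++e) {
    reg_src[edges(e, 1)].push_back(edges(e, 0));
    reg_act[edges(e, 1)].push_back(edges(e, 2));
  }
  if (stim_target >= 0) {
    reg_src[stim_target].push_back(-1);
    reg_act[stim_target].push_back(1);
  }

  int n_rec = record_times.size();
  IntegerMatrix rec(n_rec, 2 * n_genes + 1);
  int rec_i = 0;
  double t = 0.0;
  bool stim_on = false;

  std::vector<double> a(4 * n_genes);
  RNGScope scope;
  while (true) {
    double total = 0.0;
    for (int i = 0; i < n_genes; ++i) {
      a[4 * i] = lambda * x[i];                               // mRNA decay
      a[4 * i + 1] = lambda * y[i];                           // protein decay
      a[4 * i + 2] = x[i] > 0 ? alpha_transl / (1.0 + k_half[i] / x[i]) : 0.0;
      // transcription: thermodynamic mean activation over bound states
      int m = reg_src[i].size();
      double num = a0, den = 1.0;
      for (int mask = 1; mask < (1 << m); ++mask) {
        int nb = 0;
        for (int r = 0; r < m; ++r) if (mask & (1 << r)) ++nb;
        if (nb > 2) continue;
        double w = 1.0;
        bool inh = false;
        for (int r = 0; r < m; ++r) {
          if (mask & (1 << r)) {
            int src = reg_src[i][r];
            double lev = src < 0 ? s : y[src];
            double kk = src < 0 ? stim_k : k_half[src];
            w *= lev / kk;
            if (!reg_act[i][r]) inh = true;
          }
        }
        num += w * (inh ? a_inh : a_act);
        den += w;
      }
      a[4 * i + 3] = alpha_txn * num / den;
      total += a[4 * i] + a[4 * i + 1] + a[4 * i + 2] + a[4 * i + 3];
    }

    double t_next = (total > 0) ? t + R::exp_rand() / total
                                : std::numeric_limits<double>::infinity();
    if (!stim_on && t_next >= stim_time && stim_time <= t_end) {
      while (rec_i < n_rec && record_times[rec_i] < stim_time)
        record_state(rec, rec_i++, x, y, s);
      t = stim_time;
      s = stim_level;
      stim_on = true;
      continue;
    }
    if (t_next > t_end) {
      while (rec_i < n_rec) record_state(rec, rec_i++, x, y, s);
      break;
    }
    while (rec_i < n_rec && record_times[rec_i] < t_next)
      record_state(rec, rec_i++, x, y, s);
    // pick reaction
    double u = unif_rand() * total, acc = 0.0;
    int j = 0;
    for (; j < 4 * n_genes - 1; ++j) { acc += a[j]; if (u <= acc) break; }
    int g = j / 4, kind = j % 4;
    if (kind == 0) x[g] -= 1;
    else if (kind == 1) y[g] -= 1;
    else if (kind == 2) y[g] += 1;
    else x[g] += 1;
    t = t_next;
  }
  return rec;
}

// One exact SSA trajectory of the mass-action model: species combined
// mRNA/protein x_i, free gene copies g_i, bound complexes per regulatory
// edge, clamped stimulus. Reactions: basal transcription, decay, regulator
// binding/unbinding, regulated transcription.
// edges rows: (regulator, target, activating), regulator -1 = stimulus.
// Basal transcription propensity is k_txn * g_free by default (gene
// templated); literal_basal = true uses k_txn * x_i instead.
// [[Rcpp::export]]
IntegerMatrix ssa_mass_action_cpp(int n_genes, IntegerMatrix edges,
                                  IntegerVector init_x, int gene_copies,
                                  double k_txn, double k_decay, double k_on,
                                  double k_off, double k_reg_act,
                                  double k_reg_inh, int stim_target,
                                  double stim_time, double stim_level,
                                  NumericVector record_times, double t_end,
                                  bool literal_basal) {
  int n_edges = edges.nrow();
  std::vector<double> x(n_genes), b(n_edges, 0.0), gfree(n_genes,
                                                         (double)gene_copies);
  for (int i = 0; i < n_genes; ++i) x[i] = init_x[i];
  double s = 0.0;

  int n_rec = record_times.size();
  IntegerMatrix rec(n_rec, n_genes + n_edges + 1);
  int rec_i = 0;
  double t = 0.0;
  bool stim_on = false;

  int n_rxn = 2 * n_genes + 3 * n_edges;
  std::vector<double> a(n_rxn);
  RNGScope scope;
  while (true) {
    double total = 0.0;
    for (int i = 0; i < n_genes; ++i) {
      a[2 * i] = k_txn * (literal_basal ? x[i] : gfree[i]);
      a[2 * i + 1] = k_decay * x[i];
      total += a[2 * i] + a[2 * i + 1];
    }
    for (int e = 0; e < n_edges; ++e) {
      int r = edges(e, 0), tg = edges(e, 1);
      double lev = r < 0 ? s : x[r];
      int base = 2 * n_genes + 3 * e;
      a[base] = k_on * gfree[tg] * lev;                 // binding
      a[base + 1] = k_off * b[e];                       // unbinding
      a[base + 2] = (edges(e, 2) ? k_reg_act : k_reg_inh) * b[e];
      total += a[base] + a[base + 1] + a[base + 2];
    }

    double t_next = (total > 0) ? t + R::exp_rand() / total
                                : std::numeric_limits<double>::infinity();
    if (!stim_on && t_next >= stim_time && stim_time <= t_end) {
      while (rec_i < n_rec && record_times[rec_i] < stim_time) {
        for (int i = 0; i < n_genes; ++i) rec(rec_i, i) = (int)x[i];
        for (int e = 0; e < n_edges; ++e) rec(rec_i, n_genes + e) = (int)b[e];
        rec(rec_i, n_genes + n_edges) = (int)s;
        ++rec_i;
      }
      t = stim_time;
      s = stim_level;
      stim_on = true;
      continue;
    }
    bool done = t_next > t_end;
    double t_stop = done ? t_end + 1.0 : t_next;
    while (rec_i < n_rec && record_times[rec_i] < t_stop) {
      for (int i = 0; i < n_genes; ++i) rec(rec_i, i) = (int)x[i];
      for (int e = 0; e < n_edges; ++e) rec(rec_i, n_genes + e) = (int)b[e];
      rec(rec_i, n_genes + n_edges) = (int)s;
      ++rec_i;
    }
    if (done) break;

    double u = unif_rand() * total, acc = 0.0;
    int j = 0;
    for (; j < n_rxn - 1; ++j) { acc += a[j]; if (u <= acc) break; }
    if (j < 2 * n_genes) {
      int g = j / 2;
      if (j % 2 == 0) x[g] += 1; else x[g] -= 1;
    } else {
      int e = (j - 2 * n_genes) / 3, kind = (j - 2 * n_genes) % 3;
      int r = edges(e, 0), tg = edges(e, 1);
      if (kind == 0) {            // binding: consume a free protein (not s)
        b[e] += 1; gfree[tg] -= 1;
        if (r >= 0) x[r] -= 1;
      } else if (kind == 1) {     // unbinding
        b[e] -= 1; gfree[tg] += 1;
        if (r >= 0) x[r] += 1;
      } else {                    // regulated transcription
        x[tg] += 1;
      }
    }
    t = t_next;
  }
  return rec;
}
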