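// Forward Wright-Fisher simulator for a two-split, two-bottleneck
// domestication demography with uniform recombination, finite-sites biallelic
// mutation (recurrent hits rejected) and optional planted sweeps under
// additive viability selection (fitness 1, 1+s, 1+2s) in one breed.
//
// Populations are indexed 0 = breed1, 1 = breed2, 2 = wild, 3 = domestic
// (the domestic ancestor exists only between the two splits). All randomness
// comes from R's RNG (RNGScope), so set.seed() on the R side governs runs.
//
// Haplotypes are stored row-major with a fixed column capacity W; bytes at
// column indices >= S (the active site count) are kept at zero so whole-row
// copies never leak stale alleles. Columns are unsorted during the run (each
// carries its base position); the sampled output is sorted by position.

#include <Rcpp.h>
#include <unordered_set>
#include <cstring>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<uint8_t> buf;  // n * W bytes
  int n = 0;                 // gametes (2 x diploids)
  bool exists = false;
};

struct Sweep {
  int target;        // pop index (0 or 1)
  double s;
  int onset;         // generations before present
  int mode;          // 0 complete, 1 partial, 2 track (no conditioning)
  double target_freq, freq_tol;
  double init_freq;  // <= 0 means single copy
  int want_pos;
  int col = -1;      // active column index, -1 before introduction
  int pos = -1;      // realized base position
};

struct Model {
  double N_anc, T_dom, T_split, N_b1, D_b1, N_b2, D_b2, N_breed, m, mu, r;
};

class WF {
public:
  Model md;
  double L, muL, rL;
  int W = 2048, S = 0;
  std::vector<int> pos;            // base position per active column
  std::unordered_set<int> occupied;
  std::vector<Pop> pops{4};
  std::vector<uint8_t> xmask;  // crossover parity scratch
  std::vector<int> order;      // column indices sorted by position
  std::vector<Sweep> sweeps;

  void refresh_order() {
    order.resize(S);
    for (int j = 0; j < S; ++j) order[j] = j;
    const int *pp = pos.data();
    std::sort(order.begin(), order.end(),
              [pp](int a, int b) { return pp[a] < pp[b]; });
  }
  std::vector<std::vector<double>> traj;  // per sweep, target-pop frequency

  bool pop_exists(int p, int t) const {
    if (p == 2) return true;
    if (p == 3) return md.T_dom > 0 && t >= md.T_split && t < md.T_dom;
    return md.T_split > 0 && t < md.T_split;
  }
  int pop_size(int p, int t) const {  // diploids
    if (p == 2) return (int) md.N_anc;
    if (p == 3) return t >= md.T_dom - md.D_b1 ? (int) md.N_b1
                                               : (int) md.N_breed;
    return t >= md.T_split - md.D_b2 ? (int) md.N_b2 : (int) md.N_breed;
  }
  int ancestor(int p, int t_parent) const {
    if (p == 3) return 2;
    if (p <= 1) return pop_exists(3, t_parent) ? 3 : 2;
    return 2;
  }

  uint8_t *row(Pop &P, int i) { return P.buf.data() + (size_t) i * W; }

  void init(int t_start) {
    Pop &wild = pops[2];
    wild.n = 2 * pop_size(2, t_start);
    wild.buf.assign((size_t) wild.n * W, 0);
    wild.exists = true;
  }

  // ---- reproduction -------------------------------------------------------
  // Fitness CDF over the diploids of pop q at generation t (parents).
  void fitness_cdf(int q, int t, std::vector<double> &cdf) {
    Pop &P = pops[q];
    int N = P.n / 2;
    cdf.resize(N);
    bool any_sel = false;
    for (const Sweep &sw : sweeps) {
      if (sw.col >= 0 && sw.target == q && sw.s != 0.0) any_sel = true;
    }
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 1.0;
      if (any_sel) {
        for (const Sweep &sw : sweeps) {
          if (sw.col >= 0 && sw.target == q && sw.s != 0.0) {
            int g = row(P, 2 * i)[sw.col] + row(P, 2 * i + 1)[sw.col];
            w *= 1.0 + sw.s * g;
          }
        }
      }
      acc += w;
      cdf[i] = acc;
    }
  }

  int draw_parent(const std::vector<double> &cdf) {
    double u = unif_rand() * cdf.back();
    return (int) (std::lower_bound(cdf.begin(), cdf.end(), u) - cdf.begin());
  }

  // Build one gamete from parent individual `pi` of pop q into `child`.
  void make_gamete(Pop &Q, int pi, uint8_t *child) {
    uint8_t *a = row(Q, 2 * pi), *b = row(Q, 2 * pi + 1);
    if (unif_rand() < 0.5) std::swap(a, b);
    int nx = (int) R::rpois(rL);
    if (nx == 0) {
      std::memcpy(child, a, S);
      return;
    }
    if (nx > 64) nx = 64;
    double xp[64];
    for (int k = 0; k < nx; ++k) xp[k] = unif_rand() * L;
    std::sort(xp, xp + nx);
    const int *pp = pos.data();
    if (nx == 1) {  // the common case, branchless so the compiler vectorizes
      const int x = (int) xp[0];
      for (int j = 0; j < S; ++j) {
        const uint8_t take_b = (uint8_t) - (pp[j] >= x);
        child[j] = (uint8_t) ((a[j] & ~take_b) | (b[j] & take_b));
      }
      return;
    }
    // general case: one walk over the columns in position order flips the
    // take-from-b parity at each crossover point — O(S) whatever nx is
    if ((int) xmask.size() < S) xmask.resize(S);
    uint8_t *m = xmask.data();
    int k = 0;
    uint8_t par = 0;
    for (int jj = 0; jj < S; ++jj) {
      const int j = order[jj];
      while (k < nx && xp[k] <= pp[j]) { par ^= 1; ++k; }
      m[j] = (uint8_t) - par;
    }
    for (int j = 0; j < S; ++j) {
      child[j] = (uint8_t) ((a[j] & ~m[j]) | (b[j] & m[j]));
    }
  }

  // Produce generation t_child from generation t_child + 1.
  void advance(int t_child) {
    int t_parent = t_child + 1;
    std::vector<Pop> next(4);
    std::vector<double> cdf[4];
    bool have_cdf[4] = {false, false, false, false};
    bool breeds_parent = pop_exists(0, t_parent) && pop_exists(1, t_parent);
    for (int p = 0; p < 4; ++p) {
      if (!pop_exists(p, t_child)) continue;
      int q0 = pops[p].exists ? p : ancestor(p, t_parent);
      int n_child = 2 * pop_size(p, t_child);
      next[p].n = n_child;
      next[p].exists = true;
      next[p].buf.assign((size_t) n_child * W, 0);
      for (int g = 0; g < n_child; ++g) {
        int q = q0;
        if (breeds_parent && p <= 1 && md.m > 0 && unif_rand() < md.m) {
          q = 1 - p;
        }
        if (!have_cdf[q]) { fitness_cdf(q, t_parent, cdf[q]); have_cdf[q] = true; }
        int pi = draw_parent(cdf[q]);
        make_gamete(pops[q], pi, row(next[p], g));
      }
    }
    for (int p = 0; p < 4; ++p) pops[p] = std::move(next[p]);
    mutate();
    if (S > W - 64 || (t_child & 7) == 0) compact(true);  // keep S lean
    refresh_order();
  }

  void mutate() {
    int tot = 0;
    for (const Pop &P : pops) if (P.exists) tot += P.n;
    int n_mut = (int) R::rpois(muL * tot);
    for (int k = 0; k < n_mut; ++k) {
      if (S >= W) compact(true);
      int p_at = -1;
      for (int tries = 0; tries < 64 && p_at < 0; ++tries) {
        int cand = (int) (unif_rand() * L);
        if (cand >= (int) L) cand = (int) L - 1;
        if (!occupied.count(cand)) p_at = cand;  // recurrent hit rejected
      }
      if (p_at < 0) continue;  // region saturated; drop the mutation
      int g = (int) (unif_rand() * tot);
      for (Pop &P : pops) {
        if (!P.exists) continue;
        if (g < P.n) { row(P, g)[S] = 1; break; }
        g -= P.n;
      }
      occupied.insert(p_at);
      pos.push_back(p_at);
      ++S;
    }
  }

  bool is_tracked(int col) const {
    for (const Sweep &sw : sweeps) if (sw.col == col) return true;
    return false;
  }

  // Drop globally fixed/lost columns (tracked sweep columns are kept).
  void compact(bool grow_if_full) {
    std::vector<long> cnt(S, 0);
    long tot = 0;
    for (Pop &P : pops) {
      if (!P.exists) continue;
      tot += P.n;
      for (int i = 0; i < P.n; ++i) {
        const uint8_t *r = row(P, i);
        for (int j = 0; j < S; ++j) cnt[j] += r[j];
      }
    }
    std::vector<int> keep;
    keep.reserve(S);
    for (int j = 0; j < S; ++j) {
      if ((cnt[j] > 0 && cnt[j] < tot) || is_tracked(j)) keep.push_back(j);
    }
    int S2 = (int) keep.size();
    int W2 = W;
    if (grow_if_full && S2 > W - 64) W2 = 2 * W;
    std::vector<int> pos2(S2);
    occupied.clear();
    for (int jj = 0; jj < S2; ++jj) {
      pos2[jj] = pos[keep[jj]];
      occupied.insert(pos2[jj]);
    }
    for (Pop &P : pops) {
      if (!P.exists) continue;
      std::vector<uint8_t> nb((size_t) P.n * W2, 0);
      for (int i = 0; i < P.n; ++i) {
        const uint8_t *src = row(P, i);
        uint8_t *dst = nb.data() + (size_t) i * W2;
        for (int jj = 0; jj < S2; ++jj) dst[jj] = src[keep[jj]];
      }
      P.buf = std::move(nb);
    }
    for (Sweep &sw : sweeps) {
      if (sw.col < 0) continue;
      auto it = std::find(keep.begin(), keep.end(), sw.col);
      sw.col = (int) (it - keep.begin());  // tracked columns always kept
    }
    pos = std::move(pos2);
    S = S2;
    W = W2;
  }

  void introduce(Sweep &sw) {
    if (S >= W) compact(true);
    Pop &P = pops[sw.target];
    int at = sw.want_pos;
    while (occupied.count(at)) ++at;  // recurrent-hit rejection
    int ncopy = sw.init_freq > 0 ? std::max(1, (int) std::lround(sw.init_freq * P.n))
                                 : 1;
    // choose `ncopy` distinct gametes (partial Fisher-Yates)
    std::vector<int> idx(P.n);
    for (int i = 0; i < P.n; ++i) idx[i] = i;
    for (int k = 0; k < ncopy; ++k) {
      int j = k + (int) (unif_rand() * (P.n - k));
      std::swap(idx[k], idx[j]);
      row(P, idx[k])[S] = 1;
    }
    occupied.insert(at);
    pos.push_back(at);
    sw.col = S;
    sw.pos = at;
    ++S;
    refresh_order();
  }

  double freq(int p, int col) const {
    const Pop &P = pops[p];
    if (!P.exists || col < 0) return NA_REAL;
    long c = 0;
    for (int i = 0; i < P.n; ++i) c += P.buf[(size_t) i * W + col];
    return (double) c / P.n;
  }

  void record_traj() {
    for (size_t k = 0; k < sweeps.size(); ++k) {
      if (sweeps[k].col >= 0) {
        traj[k].push_back(freq(sweeps[k].target, sweeps[k].col));
      }
    }
  }

  // diploid sample: gamete row indices per population (2 per individual)
  std::vector<std::vector<int>> draw_sample(const IntegerVector &n_hap) {
    std::vector<std::vector<int>> samp(3);
    for (int p = 0; p < 3; ++p) {
      Pop &P = pops[p];
      if (!P.exists) stop("population %d does not exist at sampling time",
                          p + 1);
      int need = n_hap[p] / 2, N = P.n / 2;
      if (need > N) stop("sample exceeds population size");
      std::vector<int> idx(N);
      for (int i = 0; i < N; ++i) idx[i] = i;
      for (int k = 0; k < need; ++k) {
        int j = k + (int) (unif_rand() * (N - k));
        std::swap(idx[k], idx[j]);
        samp[p].push_back(2 * idx[k]);
        samp[p].push_back(2 * idx[k] + 1);
      }
    }
    return samp;
  }

  // Complete sweeps condition on population fixation; partial sweeps on the
  // frequency among the *sampled* haplotypes (the frequency at which
  // sampling occurs).
  bool conditions_met(const std::vector<std::vector<int>> &samp) {
    for (const Sweep &sw : sweeps) {
      if (sw.mode == 2) continue;
      if (sw.mode == 0) {
        if (freq(sw.target, sw.col) < 1.0) return false;
        continue;
      }
      Pop &P = pops[sw.target];
      const std::vector<int> &rows = samp[sw.target];
      long c = 0;
      for (int r : rows) c += P.buf[(size_t) r * W + sw.col];
      double f = (double) c / rows.size();
      if (f <= 0.0 || f >= 1.0 ||
          std::fabs(f - sw.target_freq) > sw.freq_tol) return false;
    }
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".forward_wf_cpp")]]
List forward_wf_cpp(List model, List sweep_list, double region_length,
                    IntegerVector n_hap, int burn_in, int max_attempts) {
  WF wf;
  wf.md = Model{
    as<double>(model["N_anc"]), as<double>(model["T_dom"]),
    as<double>(model["T_split"]), as<double>(model["N_bottleneck1"]),
    as<double>(model["D_bottleneck1"]), as<double>(model["N_bottleneck2"]),
    as<double>(model["D_bottleneck2"]), as<double>(model["N_breed"]),
    as<double>(model["m"]), as<double>(model["mu"]), as<double>(model["r"])};
  wf.L = region_length;
  wf.muL = wf.md.mu * region_length;
  wf.rL = wf.md.r * (region_length - 1);
  for (int k = 0; k < sweep_list.size(); ++k) {
    List s = sweep_list[k];
    Sweep sw;
    sw.target = as<int>(s["target"]);
    sw.s = as<double>(s["s"]);
    sw.onset = as<int>(s["onset"]);
    sw.mode = as<int>(s["mode"]);
    sw.target_freq = as<double>(s["target_frequency"]);
    sw.freq_tol = as<double>(s["frequency_tol"]);
    sw.init_freq = as<double>(s["initial_frequency"]);
    sw.want_pos = as<int>(s["position"]);
    wf.sweeps.push_back(sw);
  }
  wf.traj.assign(wf.sweeps.size(), {});

  int t_start = (int) wf.md.T_dom + burn_in;
  int t_snap = -1;
  bool conditioned = false;
  for (const Sweep &sw : wf.sweeps) {
    t_snap = std::max(t_snap, sw.onset);
    if (sw.mode != 2) conditioned = true;
  }

  if (!wf.sweeps.empty() && t_snap > t_start - 1) {
    stop("sweep onset predates the start of the simulation");
  }
  wf.init(t_start);
  for (int t = t_start - 1; t > t_snap && t >= 0; --t) wf.advance(t);

  int rejections = 0;
  std::vector<std::vector<int>> samp;
  if (!wf.sweeps.empty()) {
    wf.advance(t_snap);  // pre-loop stopped at generation t_snap + 1
    // snapshot right before the first introduction; retry the tail only
    WF snap = wf;
    int attempt = 0;
    for (;;) {
      for (size_t k = 0; k < wf.sweeps.size(); ++k) {
        if (wf.sweeps[k].onset == t_snap) wf.introduce(wf.sweeps[k]);
      }
      wf.record_traj();
      for (int tt = t_snap - 1; tt >= 0; --tt) {
        wf.advance(tt);
        for (size_t k = 0; k < wf.sweeps.size(); ++k) {
          if (wf.sweeps[k].onset == tt) wf.introduce(wf.sweeps[k]);
        }
        wf.record_traj();
      }
      samp = wf.draw_sample(n_hap);
      if (!conditioned || wf.conditions_met(samp)) break;
      ++attempt;
      ++rejections;
      if (attempt >= max_attempts) {
        stop("rejection limit exceeded while conditioning on sweep outcome");
      }
      wf = snap;
      wf.traj.assign(wf.sweeps.size(), {});
    }
  } else {
    samp = wf.draw_sample(n_hap);
  }

  // ---- emit the sampled present generation ---------------------------------
  int n_pops = 3;
  int n_tot = 0;
  for (int p = 0; p < n_pops; ++p) n_tot += n_hap[p];
  IntegerMatrix out(n_tot, wf.S);
  int r0 = 0;
  for (int p = 0; p < n_pops; ++p) {
    Pop &P = wf.pops[p];
    for (size_t k = 0; k < samp[p].size(); ++k) {
      const uint8_t *a = wf.row(P, samp[p][k]);
      for (int jj = 0; jj < wf.S; ++jj) out(r0 + (int) k, jj) = a[jj];
    }
    r0 += n_hap[p];
  }

  // final population frequencies of sweep alleles
  NumericMatrix sweep_freq(wf.sweeps.size(), 3);
  IntegerVector sweep_pos_out(wf.sweeps.size());
  for (size_t k = 0; k < wf.sweeps.size(); ++k) {
    for (int p = 0; p < 3; ++p) sweep_freq(k, p) = wf.freq(p, wf.sweeps[k].col);
    sweep_pos_out[k] = wf.sweeps[k].pos;
  }
  List traj_out(wf.sweeps.size());
  for (size_t k = 0; k < wf.sweeps.size(); ++k) traj_out[k] = wrap(wf.traj[k]);

  return List::create(
      _["alleles"] = out, _["pos"] = wrap(wf.pos),
      _["sweep_pos"] = sweep_pos_out, _["sweep_freq"] = sweep_freq,
      _["rejections"] = rejections, _["trajectories"] = traj_out);
}
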