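// Exact Gillespie simulation of tumour growth on a 2-D deme lattice.
//
// Events are drawn from (deme, genotype) classes whose rates are
// count x per-cell rate; this is statistically identical to tracking
// individual cells.  Only "active" demes (ever touched by tumour cells)
// are simulated stochastically; untouched demes sit at exactly K normal
// cells and contribute no events, which cannot affect the tumour because
// normal cells never disperse.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double K;
  double mu;            // driver mutation rate per division
  double s;             // mean driver fitness effect
  double res_rate;      // resistance mutation rate per division
  double m;             // upper bound on division rate
  double r_init;
  double normal_rate;   // normal-cell division rate
  double death_rate;    // per-cell death rate when deme pop > K
  double d;             // dispersal probability per tumour division
  int L;                // lattice side
  bool boundary_error;  // error if a tumour cell occupies a boundary deme
  bool seed_normals;    // demes initially filled with K normal cells
  double p0_mu;         // exp(-mu), cached for the Poisson draws
  double p0_res;        // exp(-res_rate)
};

struct Deme {
  std::vector<std::pair<int, double>> tum;  // genotype index (0-based) -> count
  double normal = 0.0;
  double tumcnt = 0.0;
  double tumdiv = 0.0;  // sum count * r
  int key = -1;         // row * L + col; -1 when the slot is free
};

// Fenwick tree over per-deme event rates (slot == deme pool index).
struct Fenwick {
  int cap = 0;
  std::vector<double> tree;  // 1-based
  std::vector<double> leaf;

  void add_raw(int i, double delta) {
    for (int j = i + 1; j <= cap; j += j & (-j)) tree[j] += delta;
  }
  void rebuild() {
    std::fill(tree.begin(), tree.end(), 0.0);
    for (int i = 0; i < (int)leaf.size(); ++i)
      if (leaf[i] != 0.0) add_raw(i, leaf[i]);
  }
  void resize_cap(int n) {
    int c = 1;
    while (c < n) c <<= 1;
    if (c == cap) return;
    cap = c;
    tree.assign(cap + 1, 0.0);
    rebuild();
  }
  void set(int i, double value) {
    if (i >= (int)leaf.size()) leaf.resize(i + 1, 0.0);
    if (i >= cap) resize_cap((int)leaf.size());
    double delta = value - leaf[i];
    if (delta != 0.0) { leaf[i] = value; add_raw(i, delta); }
  }
  double total() const { return cap ? tree[cap] : 0.0; }
  // slot whose cumulative rate interval contains u; residual within it
  int select(double u, double* residual) const {
    int pos = 0;
    for (int step = cap; step > 0; step >>= 1) {
      int nxt = pos + step;
      if (nxt <= cap && tree[nxt] < u) { pos = nxt; u -= tree[nxt]; }
    }
    *residual = u;
    return pos;
  }
};

// Exact Poisson draw by inversion; one uniform, fast for small lambda.
static inline int rpois_inv(double lambda, double p0) {
  double u = unif_rand();
  if (u < p0) return 0;
  int k = 0;
  double p = p0, c = p0;
  while (u >= c && k < 1000) {
    ++k;
    p *= lambda / k;
    c += p;
  }
  return k;
}

struct Engine {
  Params P;
  std::vector<Deme> pool;               // slot-indexed deme store
  std::vector<int> free_slots;
  std::unordered_map<int, int> key2slot;  // active demes only
  Fenwick fen;

  // genotype registry (0-based internally; exported 1-based)
  std::vector<int> parent, clone_id, n_drivers, resistant;
  std::vector<double> r, origin_time;
  std::vector<double> gcount;
  int next_clone = 0;

  double time = 0.0;
  double tumour_size = 0.0;
  double event_count = 0.0;
  bool extinct = false;

  int new_genotype(int par, int cl, int ndrv, double rate_, int res,
                   double t0) {
    parent.push_back(par);
    clone_id.push_back(cl);
    n_drivers.push_back(ndrv);
    resistant.push_back(res);
    r.push_back(rate_);
    origin_time.push_back(t0);
    gcount.push_back(0.0);
    return (int)parent.size() - 1;
  }

  int activate(int key) {
    auto it = key2slot.find(key);
    if (it != key2slot.end()) return it->second;
    int slot;
    if (!free_slots.empty()) {
      slot = free_slots.back();
      free_slots.pop_back();
    } else {
      slot = (int)pool.size();
      pool.push_back(Deme());
    }
    Deme& d = pool[slot];
    d.tum.clear();
    d.normal = P.seed_normals ? P.K : 0.0;
    d.tumcnt = d.tumdiv = 0.0;
    d.key = key;
    key2slot[key] = slot;
    return slot;
  }

  void refresh(int slot) {
    Deme& d = pool[slot];
    double pop = d.normal + d.tumcnt;
    double rate = d.tumdiv + d.normal * P.normal_rate;
    if (pop > P.K) rate += pop * P.death_rate;
    if (d.tumcnt == 0.0 && d.normal == (P.seed_normals ? P.K : 0.0)) {
      // deme back at its resting state: freeze it
      fen.set(slot, 0.0);
      key2slot.erase(d.key);
      d.key = -1;
      free_slots.push_back(slot);
      return;
    }
    fen.set(slot, rate);
  }

  void add_tumour(Deme& d, int g, double delta) {
    bool found = false;
    for (auto& pr : d.tum) {
      if (pr.first == g) {
        pr.second += delta;
        if (pr.second <= 0.0) {
          pr = d.tum.back();
          d.tum.pop_back();
        }
        found = true;
        break;
      }
    }
    if (!found) {
      if (delta < 0) stop("internal error: removing absent genotype");
      d.tum.push_back(std::make_pair(g, delta));
    }
    d.tumcnt += delta;
    d.tumdiv += delta * r[g];
    gcount[g] += delta;
    tumour_size += delta;
  }

  bool is_boundary(int key) const {
    int row = key / P.L, col = key % P.L;
    return row == 0 || col == 0 || row == P.L - 1 || col == P.L - 1;
  }

  // daughter genotype after mutation draws (may create registry entries)
  int mutate_daughter(int g) {
    int nmut = (P.mu > 0.0) ? rpois_inv(P.mu, P.p0_mu) : 0;
    int nres = (P.res_rate > 0.0) ? rpois_inv(P.res_rate, P.p0_res) : 0;
    if (nmut == 0 && nres == 0) return g;
    int child = g;
    int res = resistant[child] || nres > 0;
    for (int k = 0; k < nmut; ++k) {
      double X = exp_rand() * P.s;
      double rn = r[child] * (1.0 + X * (1.0 - r[child] / P.m));
      // X is unbounded, so cap infinitesimally below m to keep r < m
      if (rn >= P.m) rn = P.m * (1.0 - 1e-12);
      child = new_genotype(child, next_clone++, n_drivers[child] + 1, rn,
                           res, time);
    }
    if (nmut == 0 && res && !resistant[g]) {
      // resistance-only mutation: new lineage entry, same driver clone
      child = new_genotype(g, clone_id[g], n_drivers[g], r[g], 1, time);
    }
    return child;
  }

  // Executes one event in the deme at `slot`; u is the residual rate.
  void execute(int slot, double u) {
    Deme& d = pool[slot];
    // tumour divisions, one class per genotype present
    for (size_t i = 0; i < d.tum.size(); ++i) {
      double cls = d.tum[i].second * r[d.tum[i].first];
      if (u < cls) {
        int g = d.tum[i].first;
        int child = mutate_daughter(g);
        int key = d.key;
        int target_key = key;
        if (P.d > 0.0 && unif_rand() < P.d) {
          int dir = (int)(unif_rand() * 4.0);
          if (dir > 3) dir = 3;
          int row = key / P.L, col = key % P.L;
          static const int dr[4] = {-1, 1, 0, 0};
          static const int dc[4] = {0, 0, -1, 1};
          int r2 = row + dr[dir], c2 = col + dc[dir];
          // off-lattice moves stay put (reachable only with boundary
          // occupancy allowed)
          if (r2 >= 0 && c2 >= 0 && r2 < P.L && c2 < P.L)
            target_key = r2 * P.L + c2;
        }
        if (P.boundary_error && is_boundary(target_key))
          stop("lattice exhausted: tumour cell reached a boundary deme");
        if (target_key == key) {
          add_tumour(d, child, 1.0);
          refresh(slot);
        } else {
          int tslot = activate(target_key);  // may reallocate the pool
          add_tumour(pool[tslot], child, 1.0);
          refresh(tslot);
          refresh(slot);
        }
        return;
      }
      u -= cls;
    }
    // normal division
    double ndiv = d.normal * P.normal_rate;
    if (u < ndiv) {
      d.normal += 1.0;
      refresh(slot);
      return;
    }
    u -= ndiv;
    // crowding death: victim uniform over all cells in the deme
    double pop = d.normal + d.tumcnt;
    if (pop <= P.K) return;  // FP residual overflow: null event
    double v = unif_rand() * pop;
    if (v < d.normal) {
      d.normal -= 1.0;
    } else {
      v -= d.normal;
      for (size_t i = 0; i < d.tum.size(); ++i) {
        if (v < d.tum[i].second) {
          add_tumour(d, d.tum[i].first, -1.0);
          break;
        }
        v -= d.tum[i].second;
      }
    }
    refresh(slot);
    if (tumour_size <= 0.0) extinct = true;
  }
};

List export_counts(const std::vector<double>& gcount) {
  std::vector<int> id;
  std::vector<double> cnt;
  for (size_t i = 0; i < gcount.size(); ++i)
    if (gcount[i] > 0) { id.push_back((int)i + 1); cnt.push_back(gcount[i]); }
  return List::create(_["genotype_id"] = wrap(id), _["count"] = wrap(cnt));
}

DataFrame export_grid(const Engine& E) {
  std::vector<int> row, col, gid;
  std::vector<double> cnt;
  for (const auto& kv : E.key2slot) {
    const Deme& d = E.pool[kv.second];
    int rr = kv.first / E.P.L + 1, cc = kv.first % E.P.L + 1;
    for (const auto& pr : d.tum) {
      if (pr.second <= 0) continue;
      row.push_back(rr); col.push_back(cc);
      gid.push_back(pr.first + 1); cnt.push_back(pr.second);
    }
  }
  return DataFrame::create(_["row"] = wrap(row), _["col"] = wrap(col),
                           _["genotype_id"] = wrap(gid),
                           _["count"] = wrap(cnt));
}

void load_state(Engine& E, List state) {
  List gen = state["genotypes"];
  IntegerVector gp = gen["parent_id"], gc = gen["clone_id"],
                gn = gen["n_drivers"];
  LogicalVector gr = gen["resistant"];
  NumericVector gv = gen["division_rate"], gt = gen["origin_time"];
  int G = gp.size();
  for (int i = 0; i < G; ++i) {
    E.parent.push_back(gp[i] == NA_INTEGER ? -1 : gp[i] - 1);
    E.clone_id.push_back(gc[i] - 1);
    E.n_drivers.push_back(gn[i]);
    E.resistant.push_back(gr[i] ? 1 : 0);
    E.r.push_back(gv[i]);
    E.origin_time.push_back(gt[i]);
    E.gcount.push_back(0.0);
    if (gc[i] > E.next_clone) E.next_clone = gc[i];
  }
  DataFrame nm = as<DataFrame>(state["normals"]);
  IntegerVector nrow_ = nm["row"], ncol_ = nm["col"];
  NumericVector ncnt = nm["normal"];
  for (int i = 0; i < nrow_.size(); ++i) {
    int key = (nrow_[i] - 1) * E.P.L + (ncol_[i] - 1);
    E.pool[E.activate(key)].normal = ncnt[i];
  }
  DataFrame dm = as<DataFrame>(state["demes"]);
  IntegerVector drow = dm["row"], dcol = dm["col"], dgen = dm["genotype_id"];
  NumericVector dcnt = dm["count"];
  for (int i = 0; i < drow.size(); ++i) {
    if (dcnt[i] <= 0) continue;
    int key = (drow[i] - 1) * E.P.L + (dcol[i] - 1);
    int slot = E.activate(key);
    E.add_tumour(E.pool[slot], dgen[i] - 1, dcnt[i]);
  }
  std::vector<int> slots;
  for (const auto& kv : E.key2slot) slots.push_back(kv.second);
  for (int slot : slots) E.refresh(slot);  // refresh may freeze demes
  E.time = as<double>(state["time"]);
  E.event_count = as<double>(state["event_count"]);
}

}  // namespace

// [[Rcpp::export(rng = true)]]
List cpp_run(Nullable<List> state_, List par, double target_size,
             double max_time, NumericVector record_sizes, double record_dt,
             double max_events, bool record_grids) {
  Engine E;
  E.P.K = as<double>(par["K"]);
  E.P.mu = as<double>(par["mu"]);
  E.P.s = as<double>(par["s"]);
  E.P.res_rate = as<double>(par["resistance_rate"]);
  E.P.m = as<double>(par["m"]);
  E.P.r_init = as<double>(par["r_init"]);
  E.P.normal_rate = as<double>(par["normal_rate"]);
  E.P.death_rate = as<double>(par["death_multiplier"]);
  E.P.d = as<double>(par["d"]);
  E.P.L = as<int>(par["lattice_side"]);
  E.P.boundary_error = as<bool>(par["boundary_error"]);
  E.P.seed_normals = as<bool>(par["seed_normal_cells"]);
  E.P.p0_mu = std::exp(-E.P.mu);
  E.P.p0_res = std::exp(-E.P.res_rate);

  if (state_.isNotNull()) {
    load_state(E, List(state_));
  } else {
    // founder: centre deme, K normal cells + 1 tumour cell
    int c = E.P.L / 2;
    int key = c * E.P.L + c;
    if (E.P.boundary_error && E.is_boundary(key))
      stop("lattice side too small: centre deme lies on the boundary");
    int g = E.new_genotype(-1, E.next_clone++, 0, E.P.r_init, 0, 0.0);
    int slot = E.activate(key);
    E.add_tumour(E.pool[slot], g, 1.0);
    E.refresh(slot);
  }
  E.tumour_size = 0.0;
  for (double g : E.gcount) E.tumour_size += g;

  // size snapshots at first crossing of each record size (sorted)
  std::vector<double> rs(record_sizes.begin(), record_sizes.end());
  std::sort(rs.begin(), rs.end());
  size_t rs_idx = 0;
  while (rs_idx < rs.size() && E.tumour_size >= rs[rs_idx]) ++rs_idx;
  List snap_counts, snap_grids;
  std::vector<double> snap_time, snap_size, snap_target;

  // fixed-interval time snapshots (thinned if they accumulate)
  std::vector<double> trec_time;
  List trec_counts;
  double next_rec = E.time;
  bool do_trec = record_dt > 0;

  bool reached = E.tumour_size >= target_size;
  bool timed_out = false, event_capped = false;

  while (!reached && !E.extinct) {
    double total = E.fen.total();
    if (total <= 0.0) break;  // no events possible (degenerate configs)
    double dt = exp_rand() / total;
    double tnew = E.time + dt;
    if (do_trec) {
      while (next_rec <= tnew && next_rec <= max_time) {
        trec_time.push_back(next_rec);
        trec_counts.push_back(export_counts(E.gcount));
        next_rec += record_dt;
        if (trec_time.size() > 4000) {  // thin to bound memory
          std::vector<double> t2;
          List c2;
          for (size_t i = 0; i < trec_time.size(); i += 2) {
            t2.push_back(trec_time[i]);
            c2.push_back(trec_counts[i]);
          }
          trec_time.swap(t2);
          trec_counts = c2;
          record_dt *= 2.0;
          next_rec = trec_time.back() + record_dt;
        }
      }
    }
    if (tnew > max_time) { E.time = max_time; timed_out = true; break; }
    E.time = tnew;
    double u = unif_rand() * total;
    double resid;
    int slot = E.fen.select(u, &resid);
    if (slot < (int)E.pool.size() && E.pool[slot].key >= 0) {
      E.execute(slot, resid);
    }  // else: FP overshoot past the last occupied slot, null event
    E.event_count += 1.0;
    if (((long long)E.event_count & 0xFFFFFF) == 0) {
      E.fen.rebuild();  // cancel accumulated floating-point drift
      checkUserInterrupt();
    }
    while (rs_idx < rs.size() && E.tumour_size >= rs[rs_idx]) {
      snap_target.push_back(rs[rs_idx]);
      snap_time.push_back(E.time);
      snap_size.push_back(E.tumour_size);
      snap_counts.push_back(export_counts(E.gcount));
      if (record_grids) snap_grids.push_back(export_grid(E));
      ++rs_idx;
    }
    if (E.tumour_size >= target_size) reached = true;
    if (max_events > 0 && E.event_count >= max_events) {
      event_capped = true;
      break;
    }
  }

  // registry export (1-based ids)
  int G = (int)E.parent.size();
  IntegerVector gid(G), gpar(G), gcl(G), gnd(G);
  LogicalVector gres(G);
  NumericVector gr_(G), gorig(G), gcnt(G);
  for (int i = 0; i < G; ++i) {
    gid[i] = i + 1;
    gpar[i] = E.parent[i] < 0 ? NA_INTEGER : E.parent[i] + 1;
    gcl[i] = E.clone_id[i] + 1;
    gnd[i] = E.n_drivers[i];
    gres[i] = E.resistant[i] != 0;
    gr_[i] = E.r[i];
    gorig[i] = E.origin_time[i];
    gcnt[i] = E.gcount[i];
  }
  DataFrame genotypes = DataFrame::create(
      _["id"] = gid, _["parent_id"] = gpar, _["clone_id"] = gcl,
      _["n_drivers"] = gnd, _["division_rate"] = gr_, _["resistant"] = gres,
      _["origin_time"] = gorig, _["count"] = gcnt);

  std::vector<int> nrow_, ncol_;
  std::vector<double> ncnt;
  for (const auto& kv : E.key2slot) {
    nrow_.push_back(kv.first / E.P.L + 1);
    ncol_.push_back(kv.first % E.P.L + 1);
    ncnt.push_back(E.pool[kv.second].normal);
  }
  DataFrame normals = DataFrame::create(
      _["row"] = wrap(nrow_), _["col"] = wrap(ncol_),
      _["normal"] = wrap(ncnt));

  return List::create(
      _["time"] = E.time, _["tumour_size"] = E.tumour_size,
      _["event_count"] = E.event_count, _["extinct"] = E.extinct,
      _["reached_target"] = reached, _["timed_out"] = timed_out,
      _["event_capped"] = event_capped, _["genotypes"] = genotypes,
      _["demes"] = export_grid(E), _["normals"] = normals,
      _["snap_target"] = wrap(snap_target), _["snap_time"] = wrap(snap_time),
      _["snap_size"] = wrap(snap_size), _["snap_counts"] = snap_counts,
      _["snap_grids"] = snap_grids, _["trec_time"] = wrap(trec_time),
      _["trec_counts"] = trec_counts);
}
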