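// Discrete-time kinetic Monte Carlo core for hop diffusion with reversible
// dimerization on a periodically compartmentalized square lattice.
//
// All randomness flows through R's RNG (unif_rand / exp_rand) so that runs
// are reproducible with set.seed().  Draw order per step is fixed: walker
// moves in ascending id order (dimer followers are skipped), then site
// shuffles and reaction trials in ascending site-key order, then dimer
// lifetimes at formation.

#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// directions: 0 = +x, 1 = -x, 2 = +y, 3 = -y
static inline int draw_direction(int x, int y, int n, double p) {
  const bool bar[4] = { (x + 1) % n == 0, x % n == 0,
                        (y + 1) % n == 0, y % n == 0 };
  const int b = bar[0] + bar[1] + bar[2] + bar[3];
  const double pn = (1.0 - b * p) / (4 - b);
  double u = unif_rand(), c = 0.0;
  for (int k = 0; k < 4; ++k) {
    c += bar[k] ? p : pn;
    if (u < c) return k;
  }
  return 3;
}

static inline void apply_dir(int dir, int L, int &x, int &y, int &ux, int &uy) {
  switch (dir) {
    case 0: x = (x + 1) % L; ++ux; break;
    case 1: x = (x + L - 1) % L; --ux; break;
    case 2: y = (y + 1) % L; ++uy; break;
    default: y = (y + L - 1) % L; --uy; break;
  }
}

static inline int sample_lifetime_steps(double tau_d) {
  int s = (int)std::ceil(exp_rand() * tau_d);
  return s < 1 ? 1 : s;
}

// [[Rcpp::export]]
List engine_run_kmc(int L, int n, double p, double p_r, double tau_d,
                    int N, double n_steps_d, int tracer,
                    bool record_all, int thin_traj) {
  const long long n_steps = (long long)n_steps_d;
  std::vector<int> x(N), y(N), partner(N, -1);
  std::vector<long long> dissoc(N, -1), just_diss(N, -1);

  // initial placement: every second site along rows, starting at the center
  {
    const int per_row = L / 2;
    if ((long long)N > (long long)per_row * L)
      stop("cannot place %d particles at two-site spacing on a %d x %d lattice", N, L, L);
    int x0 = L / 2, y0 = L / 2;
    for (int i = 0; i < N; ++i) {
      int row = i / per_row, k = i % per_row;
      x[i] = (x0 + 2 * k) % L;
      y[i] = (y0 + row) % L;
    }
  }

  std::vector<double> ev;           // tracer events: step, type, partner, x, y
  std::vector<double> aev;          // all reactions: step, id1, id2, x, y
  std::vector<double> traj;         // step, ux, uy (tracer, unwrapped)
  long long tracer_monomer_steps = 0;
  int t_ux = 0, t_uy = 0;
  bool conservation_ok = true;

  if (thin_traj > 0) { traj.push_back(0); traj.push_back(0); traj.push_back(0); }

  std::map<long long, std::vector<int>> occ;

  for (long long step = 1; step <= n_steps; ++step) {
    // phase 1: synchronous moves (one draw per monomer or dimer)
    for (int i = 0; i < N; ++i) {
      if (partner[i] >= 0 && partner[i] < i) continue;  // dimer follower
      int dir = draw_direction(x[i], y[i], n, p);
      int ux = 0, uy = 0;
      apply_dir(dir, L, x[i], y[i], ux, uy);
      if (partner[i] >= 0) { x[partner[i]] = x[i]; y[partner[i]] = y[i]; }
      if (i == tracer || partner[i] == tracer) { t_ux += ux; t_uy += uy; }
    }

    // phase 2: scheduled dissociations
    for (int i = 0; i < N; ++i) {
      int j = partner[i];
      if (j > i && dissoc[i] == step) {
        partner[i] = -1; partner[j] = -1;
        just_diss[i] = step; just_diss[j] = step;
        dissoc[i] = -1;
        if (i == tracer || j == tracer) {
          int other = (i == tracer) ? j : i;
          ev.push_back((double)step); ev.push_back(2);
          ev.push_back(other); ev.push_back(x[i]); ev.push_back(y[i]);
        }
      }
    }

    // phase 3: dimerization on co-occupancy
    occ.clear();
    for (int i = 0; i < N; ++i)
      if (partner[i] < 0 && just_diss[i] != step)
        occ[(long long)y[i] * L + x[i]].push_back(i);
    for (auto &kv : occ) {
      std::vector<int> &v = kv.second;
      const int sz = (int)v.size();
      if (sz < 2) continue;
      for (int i = sz - 1; i > 0; --i) {        // Fisher-Yates
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(v[i], v[j]);
      }
      for (int q = 0; q + 1 < sz; q += 2) {
        if (p_r < 1.0 && unif_rand() >= p_r) continue;
        int i = v[q] < v[q + 1] ? v[q] : v[q + 1];
        int j = v[q] < v[q + 1] ? v[q + 1] : v[q];
        partner[i] = j; partner[j] = i;
        dissoc[i] = step + sample_lifetime_steps(tau_d);
        if (i == tracer || j == tracer) {
          int other = (i == tracer) ? j : i;
          ev.push_back((double)step); ev.push_back(1);
          ev.push_back(other); ev.push_back(x[i]); ev.push_back(y[i]);
        }
        if (record_all) {
          aev.push_back((double)step); aev.push_back(i); aev.push_back(j);
          aev.push_back(x[i]); aev.push_back(y[i]);
        }
      }
    }

    if (partner[tracer] < 0) ++tracer_monomer_steps;
    if (thin_traj > 0 && step % thin_traj == 0) {
      traj.push_back((double)step); traj.push_back(t_ux); traj.push_back(t_uy);
    }
    if ((step & 0xFFFF) == 0) {
      int free_m = 0, dim = 0;
      for (int i = 0; i < N; ++i) {
        if (partner[i] < 0) ++free_m; else if (partner[i] > i) ++dim;
      }
      if (free_m + 2 * dim != N) conservation_ok = false;
      checkUserInterrupt();
    }
  }

  auto to_mat = [](std::vector<double> &v, int ncol) {
    int nr = (int)(v.size() / ncol);
    NumericMatrix m(nr, ncol);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < ncol; ++c) m(r, c) = v[(size_t)r * ncol + c];
    return m;
  };

  return List::create(
    _["events"] = to_mat(ev, 5),
    _["all_events"] = record_all ? to_mat(aev, 5) : NumericMatrix(0, 5),
    _["trajectory"] = thin_traj > 0 ? to_mat(traj, 3) : NumericMatrix(0, 3),
    _["tracer_monomer_steps"] = (double)tracer_monomer_steps,
    _["conservation_ok"] = conservation_ok);
}

// Independent non-reacting walkers; unwrapped displacements sampled every
// `thin` steps.  Rows of X/Y are samples (first row = 0), columns walkers.
// [[Rcpp::export]]
List engine_walker_paths(int L, int n, double p, int W, double n_steps_d, int thin) {
  const long long n_steps = (long long)n_steps_d;
  const long long n_samp = n_steps / thin;
  NumericMatrix X(n_samp + 1, W), Y(n_samp + 1, W);
  std::vector<int> x(W), y(W), ux(W, 0), uy(W, 0);
  for (int w = 0; w < W; ++w) {
    x[w] = (int)(unif_rand() * L); if (x[w] >= L) x[w] = L - 1;
    y[w] = (int)(unif_rand() * L); if (y[w] >= L) y[w] = L - 1;
  }
  long long row = 1;
  for (long long step = 1; step <= n_steps; ++step) {
    for (int w = 0; w < W; ++w) {
      int dir = draw_direction(x[w], y[w], n, p);
      apply_dir(dir, L, x[w], y[w], ux[w], uy[w]);
    }
    if (step % thin == 0) {
      for (int w = 0; w < W; ++w) { X(row, w) = ux[w]; Y(row, w) = uy[w]; }
      ++row;
    }
    if ((step & 0x3FF) == 0) checkUserInterrupt();
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// Escape times of single walkers released uniformly inside one compartment
// of a 3x3-compartment torus (first time the compartment index changes).
// [[Rcpp::export]]
IntegerVector engine_escape_samples(int n, double p, int reps) {
  const int L = 3 * n;
  IntegerVector out(reps);
  for (int r = 0; r < reps; ++r) {
    int x = n + (int)(unif_rand() * n), y = n + (int)(unif_rand() * n);
    if (x >= 2 * n) x = 2 * n - 1;
    if (y >= 2 * n) y = 2 * n - 1;
    int ux = 0, uy = 0, t = 0;
    while (x / n == 1 && y / n == 1) {
      int dir = draw_direction(x, y, n, p);
      apply_dir(dir, L, x, y, ux, uy);
      ++t;
    }
    out[r] = t;
    if ((r & 0xFF) == 0) checkUserInterrupt();
  }
  return out;
}

// Two-particle burst statistics: a freshly dissociated pair in the center
// compartment of a 3x3 torus is followed until the two walkers sit in
// different compartments (burst over).  Counts encounters (co-occupancies),
// reactions (each encounter reacts with prob p_r; the dimer then moves for
// an exponential lifetime and dissociates in place), and legs (dissociation-
// to-outcome segments).  Amplitude counts the initiating reaction.
// [[Rcpp::export]]
List engine_pair_burst(int n, double p, double p_r, double tau_d, int reps) {
  const int L = 3 * n;
  IntegerVector amplitude(reps);
  long long legs = 0, encounters = 0, reactions = 0;
  for (int r = 0; r < reps; ++r) {
    int s = (int)(unif_rand() * (n * n)); if (s >= n * n) s = n * n - 1;
    int x1 = n + s % n, y1 = n + s / n, x2 = x1, y2 = y1;
    int d1 = 0, d2 = 0;
    int A = 1;  // the initiating reaction
    for (;;) {
      // one leg: until co-occupancy or compartment separation
      bool escaped = false;
      for (;;) {
        int dir = draw_direction(x1, y1, n, p);
        apply_dir(dir, L, x1, y1, d1, d2);
        dir = draw_direction(x2, y2, n, p);
        apply_dir(dir, L, x2, y2, d1, d2);
        if (x1 == x2 && y1 == y2) break;
        if (x1 / n != x2 / n || y1 / n != y2 / n) { escaped = true; break; }
      }
      ++legs;
      if (escaped) break;
      ++encounters;
      if (unif_rand() < p_r) {
        ++A; ++reactions;
        int life = sample_lifetime_steps(tau_d);
        for (int t = 0; t < life; ++t) {       // dimer drifts, then splits
          int dir = draw_direction(x1, y1, n, p);
          apply_dir(dir, L, x1, y1, d1, d2);
        }
        x2 = x1; y2 = y1;
      }
    }
    amplitude[r] = A;
    if ((r & 0xFF) == 0) checkUserInterrupt();
  }
  double amp_mean = 0;
  for (int r = 0; r < reps; ++r) amp_mean += amplitude[r];
  amp_mean /= reps;
  return List::create(
    _["amplitude"] = amplitude,
    _["n_bursts"] = reps,
    _["n_legs"] = (double)legs,
    _["n_encounters"] = (double)encounters,
    _["p_fug"] = (double)reps / (double)legs,
    _["mean_encounters"] = (double)encounters / (double)reps,
    _["mean_amplitude"] = amp_mean);
}

// Mean re-encounter time of a freshly dissociated pair in a single
// compartment with reflecting walls (barrier probability mass redistributed
// over the allowed directions), averaged over a uniform release site.
// [[Rcpp::export]]
List engine_pair_reencounter(int n, int reps) {
  double total = 0, total2 = 0;
  for (int r = 0; r < reps; ++r) {
    int s = (int)(unif_rand() * (n * n)); if (s >= n * n) s = n * n - 1;
    int x1 = s % n, y1 = s / n, x2 = x1, y2 = y1, dummy = 0;
    long long t = 0;
    do {
      int dir = draw_direction(x1, y1, n, 0.0);
      apply_dir(dir, n, x1, y1, dummy, dummy);  // L = n, but p = 0: no wrap crossing
      dir = draw_direction(x2, y2, n, 0.0);
      apply_dir(dir, n, x2, y2, dummy, dummy);
      ++t;
    } while (x1 != x2 || y1 != y2);
    total += (double)t; total2 += (double)t * (double)t;
    if ((r & 0xFF) == 0) checkUserInterrupt();
  }
  double m = total / reps;
  return List::create(_["mean"] = m,
                      _["se"] = std::sqrt((total2 / reps - m * m) / reps));
}
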