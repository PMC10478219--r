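#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Site codes: 0 = vacant, 2 = undifferentiated, +1 / -1 = differentiated.
// The lattice is stored column-major (R matrix); site (i, j) = grid(i, j).

namespace {

struct Neigh {
  int di[8];
  int dj[8];
  int n;
};

Neigh make_neigh(bool moore) {
  Neigh nb;
  int di4[4] = {-1, 1, 0, 0};
  int dj4[4] = {0, 0, -1, 1};
  int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  nb.n = moore ? 8 : 4;
  for (int k = 0; k < nb.n; ++k) {
    nb.di[k] = moore ? di8[k] : di4[k];
    nb.dj[k] = moore ? dj8[k] : dj4[k];
  }
  return nb;
}

// Sum of spins over differentiated neighbours; vacant/undifferentiated
// contribute zero (spin-0 dilution).  Also counts occupied neighbours.
inline void neighbour_sums(const IntegerMatrix &g, int i, int j,
                           const Neigh &nb, bool periodic, int L,
                           int &spin_sum, int &occ) {
  spin_sum = 0;
  occ = 0;
  for (int k = 0; k < nb.n; ++k) {
    int ii = i + nb.di[k];
    int jj = j + nb.dj[k];
    if (periodic) {
      ii = (ii + L) % L;
      jj = (jj + L) % L;
    } else if (ii < 0 || ii >= L || jj < 0 || jj >= L) {
      continue;
    }
    int s = g(ii, jj);
    if (s != 0) ++occ;
    if (s == 1 || s == -1) spin_sum += s;
  }
}

// Total interaction energy H = -J * sum over bonds of sigma_i sigma_j,
// bonds enumerated once (right/down, plus diagonals for Moore); only
// differentiated pairs contribute.
double total_energy(const IntegerMatrix &g, int J, bool moore,
                    bool periodic, int L) {
  long acc = 0;
  int ndir = moore ? 4 : 2;
  // bond directions: right, down, down-right, down-left
  int di[4] = {0, 1, 1, 1};
  int dj[4] = {1, 0, 1, -1};
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < L; ++j) {
      int s = g(i, j);
      if (s != 1 && s != -1) continue;
      for (int k = 0; k < ndir; ++k) {
        int ii = i + di[k];
        int jj = j + dj[k];
        if (periodic) {
          ii = (ii + L) % L;
          jj = (jj + L) % L;
        } else if (ii < 0 || ii >= L || jj < 0 || jj >= L) {
          continue;
        }
        int t = g(ii, jj);
        if (t == 1 || t == -1) acc += s * t;
      }
    }
  }
  return -static_cast<double>(J) * static_cast<double>(acc);
}

}  // namespace

// Run a CPIM or pure-Ising simulation for `sweeps` sweeps of L^2
// asynchronous single-site attempts each.  Uses R's RNG stream so runs
// are a pure function of set.seed().  The grid is modified in place.
// [[Rcpp::export]]
List run_lattice_cpp(IntegerMatrix grid, double T, int J, double b,
                     double d, double g, bool moore, bool periodic,
                     int sweeps, bool pure_ising, bool stop_at_edge,
                     int record_every, int snapshot_every,
                     bool record_config) {
  const int L = grid.nrow();
  const Neigh nb = make_neigh(moore);
  const double log_keep = std::log1p(-b);  // log(1 - b)

  // incremental tallies
  int n_occ = 0, n_plus = 0, n_minus = 0;
  bool edge_occupied = false;
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) {
      int s = grid(i, j);
      if (s != 0) {
        ++n_occ;
        if (i == 0 || j == 0 || i == L - 1 || j == L - 1)
          edge_occupied = true;
      }
      if (s == 1) ++n_plus;
      if (s == -1) ++n_minus;
    }

  int n_rec = (record_every > 0) ? sweeps / record_every + 1 : 0;
  NumericMatrix obs(n_rec > 0 ? n_rec : 1, 12);
  int rec = 0;
  List snapshots;
  IntegerVector snapshot_sweeps;
  std::vector<int> config_codes;
  if (record_config) config_codes.reserve(sweeps);

  auto record = [&](int sweep_idx, int col_, int dif_, int dea_,
                    int att_, int acc_) {
    if (record_every <= 0 || rec >= obs.nrow()) return;
    double energy = total_energy(grid, J, moore, periodic, L);
    int M = n_plus - n_minus;
    obs(rec, 0) = sweep_idx;
    obs(rec, 1) = n_occ;
    obs(rec, 2) = n_plus;
    obs(rec, 3) = n_minus;
    obs(rec, 4) = M;
    obs(rec, 5) = n_occ > 0 ? static_cast<double>(M) / n_occ : NA_REAL;
    obs(rec, 6) = energy;
    obs(rec, 7) = col_;
    obs(rec, 8) = dea_;
    obs(rec, 9) = dif_;
    obs(rec, 10) = att_;
    obs(rec, 11) = acc_;
    ++rec;
  };

  int sweep_done = 0;
  bool stopped_early = false;
  for (int sw = 1; sw <= sweeps; ++sw) {
    int col = 0, dif = 0, dea = 0, att = 0, acc = 0;
    const int attempts = L * L;
    for (int a = 0; a < attempts; ++a) {
      int i = static_cast<int>(R::unif_rand() * L);
      int j = static_cast<int>(R::unif_rand() * L);
      if (i >= L) i = L - 1;
      if (j >= L) j = L - 1;
      int s = grid(i, j);

      if (pure_ising || s == 1 || s == -1) {
        if (!pure_ising && d > 0 && R::unif_rand() < d) {
          // death of a differentiated cell
          grid(i, j) = 0;
          --n_occ;
          if (s == 1) --n_plus; else --n_minus;
          ++dea;
          continue;
        }
        // Metropolis spin-flip attempt
        int spin_sum, occk;
        neighbour_sums(grid, i, j, nb, periodic, L, spin_sum, occk);
        double dH = 2.0 * J * s * spin_sum;
        ++att;
        if (dH <= 0.0 || R::unif_rand() < std::exp(-dH / T)) {
          grid(i, j) = -s;
          n_plus += (s == 1) ? -1 : 1;
          n_minus += (s == -1) ? -1 : 1;
          ++acc;
        }
      } else if (s == 0) {
        int spin_sum, occk;
        neighbour_sums(grid, i, j, nb, periodic, L, spin_sum, occk);
        if (occk > 0) {
          // colonization prob 1 - (1-b)^k, independent per-neighbour law
          double p = 1.0 - std::exp(occk * log_keep);
          if (R::unif_rand() < p) {
            grid(i, j) = 2;
            ++n_occ;
            ++col;
            if (i == 0 || j == 0 || i == L - 1 || j == L - 1)
              edge_occupied = true;
          }
        }
      } else {  // undifferentiated (*)
        if (d > 0 && R::unif_rand() < d) {
          grid(i, j) = 0;
          --n_occ;
          ++dea;
        } else if (R::unif_rand() < g) {
          int spin = (R::unif_rand() < 0.5) ? 1 : -1;
          grid(i, j) = spin;
          if (spin == 1) ++n_plus; else ++n_minus;
          ++dif;
        }
      }
    }
    sweep_done = sw;
    if (record_every > 0 && sw % record_every == 0)
      record(sw, col, dif, dea, att, acc);
    if (snapshot_every > 0 && sw % snapshot_every == 0) {
      snapshots.push_back(clone(grid));
      snapshot_sweeps.push_back(sw);
    }
    if (record_config) {
      // pack the grid (tiny lattices only) into one integer
      int code = 0, bit = 0;
      for (int j = 0; j < L; ++j)
        for (int i = 0; i < L; ++i, ++bit)
          if (grid(i, j) == 1) code |= (1 << bit);
      config_codes.push_back(code);
    }
    if (stop_at_edge && edge_occupied) {
      stopped_early = true;
      break;
    }
  }

  NumericMatrix obs_out(rec, 12);
  for (int r = 0; r < rec; ++r)
    for (int c = 0; c < 12; ++c) obs_out(r, c) = obs(r, c);

  return List::create(
      _["grid"] = grid, _["observables"] = obs_out,
      _["snapshots"] = snapshots, _["snapshot_sweeps"] = snapshot_sweeps,
      _["sweeps_done"] = sweep_done, _["stopped_at_edge"] = stopped_early,
      _["configs"] = record_config ? wrap(config_codes) : R_NilValue);
}

// Connected-component labelling of same-valued sites, one state at a
// time, 4- or 8-connectivity.  States not in `states` get label 0.
// [[Rcpp::export]]
List label_clusters_cpp(IntegerMatrix grid, int connectivity,
                        IntegerVector states) {
  const int L1 = grid.nrow(), L2 = grid.ncol();
  const bool moore = (connectivity == 8);
  const Neigh nb = make_neigh(moore);
  IntegerMatrix labels(L1, L2);
  std::vector<int> sizes, cl_state;
  int next = 0;
  std::vector<bool> wanted(512, false);
  for (int k = 0; k < states.size(); ++k) wanted[states[k] + 256] = true;

  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < L2; ++j0) {
    for (int i0 = 0; i0 < L1; ++i0) {
      int s = grid(i0, j0);
      if (!wanted[s + 256] || labels(i0, j0) != 0) continue;
      ++next;
      int size = 0;
      labels(i0, j0) = next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        ++size;
        for (int k = 0; k < nb.n; ++k) {
          int ii = p.first + nb.di[k];
          int jj = p.second + nb.dj[k];
          if (ii < 0 || ii >= L1 || jj < 0 || jj >= L2) continue;
          if (grid(ii, jj) == s && labels(ii, jj) == 0) {
            labels(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
      sizes.push_back(size);
      cl_state.push_back(s);
    }
  }
  return List::create(_["labels"] = labels, _["size"] = wrap(sizes),
                      _["state"] = wrap(cl_state));
}

// [[Rcpp::export]]
double total_energy_cpp(IntegerMatrix grid, int J, bool moore,
                        bool periodic) {
  return total_energy(grid, J, moore, periodic, grid.nrow());
}
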