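// Underdamped Langevin dynamics for bead-spring ring networks.
//
// Model (reduced Lennard-Jones units, kB = 1, bead mass m = 1):
//   - Kremer-Grest bonds between consecutive beads of each closed ring:
//     FENE  U = -0.5 K R0^2 ln(1 - (r/R0)^2)  plus the full-diameter WCA
//     core on the bonded pair (bond length ~0.97 sigma)
//   - WCA (purely repulsive, truncated-shifted LJ) between all
//     non-bonded bead pairs within 2^(1/6) sigma
//   - bending: U = kb (1 + cos theta) at each bond angle (zero when
//     straight), giving persistence length ~ kb sigma at T = 1
//   - optional slit: harmonic walls at z = +/- gap/2, with an optional
//     linear ramp of the gap (used for disk compression)
//   - optional cap on the pair-force magnitude ("soft push", used to
//     resolve build-time overlaps without strand crossing)
//
// Integrator: BAOAB splitting of Langevin dynamics (velocity-Verlet drift/
// kick with an exact Ornstein-Uhlenbeck velocity update). All randomness
// comes from an internal xoshiro256++ generator seeded from a user seed,
// so trajectories are bit-reproducible on one thread.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 seeding
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_spare = false;
  double spare = 0.0;
  double gauss() {  // Marsaglia polar method: deterministic, no trig
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m;
    has_spare = true;
    return u * m;
  }
};

struct Params {
  double K, R0, eps, sigma, kb, gamma, dt, T;
  double rc2;          // WCA cutoff^2
  bool wall;
  double gap_start, gap_end, wall_k;
  long ramp_steps;
  double fmax, fmax_end;  // pair-force cap ramp; fmax <= 0 disables
  double sigma_start;     // WCA diameter ramp start; <= 0 disables
};

struct System {
  int N;
  std::vector<double> x, v, f;         // 3N each
  std::vector<int> ring_of;            // ring index per bead
  std::vector<int> offset, len;        // per ring
  std::vector<int> off_of, len_of;     // per-ring lookups used in build_list
  // Verlet list
  std::vector<int> nbr_start, nbr;
  std::vector<double> x_at_build;
  double skin = 0.4, list_cut2 = 0.0;

  void build_list() {
    const double rc = std::pow(2.0, 1.0 / 6.0);
    const double cut = rc + skin;
    list_cut2 = cut * cut;
    // cell grid
    double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], x[3 * i + k]);
        hi[k] = std::max(hi[k], x[3 * i + k]);
      }
    int nc[3]; double cell[3];
    for (int k = 0; k < 3; ++k) {
      nc[k] = std::max(1, (int)((hi[k] - lo[k]) / cut));
      cell[k] = (hi[k] - lo[k]) / nc[k] + 1e-12;
      if (cell[k] <= 0) cell[k] = 1.0;
    }
    const long ncell = (long)nc[0] * nc[1] * nc[2];
    if (ncell > 100000000L || !std::isfinite(hi[0]) || !std::isfinite(lo[0]))
      stop("simulation exploded: coordinates span %.3g sigma", hi[0] - lo[0]);
    std::vector<int> head(ncell, -1), nxt(N, -1);
    auto cidx = [&](int i) {
      int c[3];
      for (int k = 0; k < 3; ++k) {
        c[k] = (int)((x[3 * i + k] - lo[k]) / cell[k]);
        if (c[k] >= nc[k]) c[k] = nc[k] - 1;
        if (c[k] < 0) c[k] = 0;
      }
      return ((long)c[2] * nc[1] + c[1]) * nc[0] + c[0];
    };
    for (int i = 0; i < N; ++i) {
      long c = cidx(i);
      nxt[i] = head[c]; head[c] = i;
    }
    nbr_start.assign(N + 1, 0);
    nbr.clear();
    for (int i = 0; i < N; ++i) {
      nbr_start[i] = (int)nbr.size();
      int ci[3];
      for (int k = 0; k < 3; ++k) {
        ci[k] = (int)((x[3 * i + k] - lo[k]) / cell[k]);
        if (ci[k] >= nc[k]) ci[k] = nc[k] - 1;
        if (ci[k] < 0) ci[k] = 0;
      }
      // full 27-cell scan but pairs deduplicated by j > i; cell lists
      // are short, so the dominant cost is the distance check below
      const double xi0 = x[3 * i], xi1 = x[3 * i + 1], xi2 = x[3 * i + 2];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int cc[3] = {ci[0] + dx, ci[1] + dy, ci[2] + dz};
            if (cc[0] < 0 || cc[0] >= nc[0] || cc[1] < 0 || cc[1] >= nc[1] ||
                cc[2] < 0 || cc[2] >= nc[2]) continue;
            long c = ((long)cc[2] * nc[1] + cc[1]) * nc[0] + cc[0];
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double d0 = xi0 - x[3 * j], d1 = xi1 - x[3 * j + 1],
                     d2v = xi2 - x[3 * j + 2];
              double d2 = d0 * d0 + d1 * d1 + d2v * d2v;
              if (d2 >= list_cut2) continue;
              if (ring_of[i] == ring_of[j]) {
                const int r = ring_of[i], m = len_of[r];
                const int ai = i - off_of[r], aj = j - off_of[r];
                const int dd = std::abs(ai - aj);
                if (dd == 1 || dd == m - 1) continue;  // bonded pair
              }
              nbr.push_back(j);
            }
          }
    }
    nbr_start[N] = (int)nbr.size();
    x_at_build = x;
  }

  bool need_rebuild() const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < 3 * N; i += 3) {
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = x[i + k] - x_at_build[i + k];
        d2 += d * d;
      }
      if (d2 > lim2) return true;
    }
    return false;
  }
};

// returns false on FENE overstretch / non-finite coordinates
bool compute_forces(System& S, const Params& P, double gap, double cap,
                    double sig_cur, double* epot, double* e_terms,
                    std::string* err) {
  const int N = S.N;
  std::fill(S.f.begin(), S.f.end(), 0.0);
  double e_fene = 0, e_wca = 0, e_bend = 0, e_wall = 0;
  const double sig2 = sig_cur * sig_cur;
  const double rc2_cur = sig2 * std::pow(2.0, 1.0 / 3.0);
  // pair WCA
  for (int i = 0; i < N; ++i) {
    for (int t = S.nbr_start[i]; t < S.nbr_start[i + 1]; ++t) {
      int j = S.nbr[t];
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = S.x[3 * i + k] - S.x[3 * j + k];
        r2 += d[k] * d[k];
      }
      if (r2 >= rc2_cur) continue;
      double s2 = sig2 / r2, s6 = s2 * s2 * s2;
      double fr = 24.0 * P.eps * (2.0 * s6 * s6 - s6) / r2; // F/r
      e_wca += 4.0 * P.eps * (s6 * s6 - s6) + P.eps;
      if (cap > 0) {
        double fmag = fr * std::sqrt(r2);
        if (fmag > cap) fr = cap / std::sqrt(r2);
      }
      for (int k = 0; k < 3; ++k) {
        S.f[3 * i + k] += fr * d[k];
        S.f[3 * j + k] -= fr * d[k];
      }
    }
  }
  // FENE bonds (ring-closed)
  const double R02 = P.R0 * P.R0;
  for (size_t r = 0; r < S.len.size(); ++r) {
    const int o = S.offset[r], m = S.len[r];
    for (int a = 0; a < m; ++a) {
      int i = o + a, j = o + (a + 1) % m;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = S.x[3 * i + k] - S.x[3 * j + k];
        r2 += d[k] * d[k];
      }
      if (r2 >= R02 || !std::isfinite(r2)) {
        if (err) {
          char buf[160];
          snprintf(buf, sizeof(buf),
                   "FENE bond %d-%d of ring %d overstretched (r = %.4f >= "
                   "R0 = %.3f)", i + 1, j + 1, (int)r + 1, std::sqrt(r2), P.R0);
          *err = buf;
        }
        return false;
      }
      double fr = -P.K / (1.0 - r2 / R02);  // F/r (attractive)
      e_fene += -0.5 * P.K * R02 * std::log(1.0 - r2 / R02);
      // full-diameter WCA core of the Kremer-Grest bond (not ramped);
      // its energy is booked under the pair (WCA) term so the FENE term
      // stays the pure closed-form -0.5 K R0^2 ln(1 - (r/R0)^2)
      const double sigb2 = P.sigma * P.sigma;
      if (r2 < sigb2 * std::pow(2.0, 1.0 / 3.0)) {
        double s2 = sigb2 / r2, s6 = s2 * s2 * s2;
        fr += 24.0 * P.eps * (2.0 * s6 * s6 - s6) / r2;
        e_wca += 4.0 * P.eps * (s6 * s6 - s6) + P.eps;
      }
      for (int k = 0; k < 3; ++k) {
        S.f[3 * i + k] += fr * d[k];
        S.f[3 * j + k] -= fr * d[k];
      }
    }
  }
  // bending: U = kb (1 + cos theta), theta the angle at bead b between
  // bonds (a-b) and (b-c); straight chain theta = pi -> U = 0
  if (P.kb > 0) {
    for (size_t r = 0; r < S.len.size(); ++r) {
      const int o = S.offset[r], m = S.len[r];
      for (int t = 0; t < m; ++t) {
        int a = o + t, b = o + (t + 1) % m, c = o + (t + 2) % m;
        double e1[3], e2[3], l1 = 0, l2 = 0;
        for (int k = 0; k < 3; ++k) {
          e1[k] = S.x[3 * a + k] - S.x[3 * b + k];
          e2[k] = S.x[3 * c + k] - S.x[3 * b + k];
          l1 += e1[k] * e1[k];
          l2 += e2[k] * e2[k];
        }
        l1 = std::sqrt(l1); l2 = std::sqrt(l2);
        double ct = 0;
        for (int k = 0; k < 3; ++k) ct += e1[k] * e2[k];
        ct /= (l1 * l2);
        if (ct > 1) ct = 1; if (ct < -1) ct = -1;
        e_bend += P.kb * (1.0 + ct);
        // dU/d(cos theta) = kb; force = -kb * d(cos)/dx
        for (int k = 0; k < 3; ++k) {
          double da = (e2[k] / (l1 * l2)) - ct * e1[k] / (l1 * l1);
          double dc = (e1[k] / (l1 * l2)) - ct * e2[k] / (l2 * l2);
          S.f[3 * a + k] += -P.kb * da;
          S.f[3 * c + k] += -P.kb * dc;
          S.f[3 * b + k] += P.kb * (da + dc);
        }
      }
    }
  }
  // slit walls
  if (P.wall && gap > 0) {
    const double z0 = 0.5 * gap;
    for (int i = 0; i < N; ++i) {
      double z = S.x[3 * i + 2];
      if (z > z0) {
        double d = z - z0;
        e_wall += 0.5 * P.wall_k * d * d;
        S.f[3 * i + 2] -= P.wall_k * d;
      } else if (z < -z0) {
        double d = z + z0;
        e_wall += 0.5 * P.wall_k * d * d;
        S.f[3 * i + 2] -= P.wall_k * d;
      }
    }
  }
  if (epot) *epot = e_fene + e_wca + e_bend + e_wall;
  if (e_terms) {
    e_terms[0] = e_fene; e_terms[1] = e_wca;
    e_terms[2] = e_bend; e_terms[3] = e_wall;
  }
  return true;
}

Params read_params(List par) {
  Params P;
  P.K = as<double>(par["K"]);
  P.R0 = as<double>(par["R0"]);
  P.eps = as<double>(par["eps"]);
  P.sigma = as<double>(par["sigma"]);
  P.kb = as<double>(par["kappa_bend"]);
  P.gamma = as<double>(par["gamma"]);
  P.dt = as<double>(par["dt"]);
  P.T = as<double>(par["temperature"]);
  double rc = std::pow(2.0, 1.0 / 6.0) * P.sigma;
  P.rc2 = rc * rc;
  P.wall = as<bool>(par["wall"]);
  P.gap_start = as<double>(par["gap_start"]);
  P.gap_end = as<double>(par["gap_end"]);
  P.ramp_steps = (long)as<double>(par["ramp_steps"]);
  P.wall_k = as<double>(par["wall_k"]);
  P.fmax = as<double>(par["fmax"]);
  P.fmax_end = as<double>(par["fmax_end"]);
  P.sigma_start = as<double>(par["sigma_start"]);
  if (P.dt <= 0 || P.gamma <= 0 || P.R0 <= P.sigma)
    stop("invalid parameters: need dt > 0, gamma > 0, R0 > sigma");
  return P;
}

System make_system(NumericMatrix pos, NumericMatrix vel,
                   IntegerVector ring_len) {
  System S;
  S.N = pos.nrow();
  S.x.resize(3 * S.N); S.v.resize(3 * S.N); S.f.resize(3 * S.N);
  for (int i = 0; i < S.N; ++i)
    for (int k = 0; k < 3; ++k) {
      S.x[3 * i + k] = pos(i, k);
      S.v[3 * i + k] = vel(i, k);
    }
  int tot = 0;
  for (int r = 0; r < ring_len.size(); ++r) {
    S.offset.push_back(tot);
    S.len.push_back(ring_len[r]);
    tot += ring_len[r];
  }
  if (tot != S.N) stop("ring lengths do not match number of beads");
  S.ring_of.resize(S.N);
  for (size_t r = 0; r < S.len.size(); ++r)
    for (int a = 0; a < S.len[r]; ++a) S.ring_of[S.offset[r] + a] = (int)r;
  S.off_of = S.offset;
  S.len_of = S.len;
  return S;
}

} // namespace

// [[Rcpp::export]]
List cpp_langevin_run(NumericMatrix pos, NumericMatrix vel,
                      IntegerVector ring_len, List par,
                      double n_steps_d, double dump_every_d,
                      double seed_d) {
  Params P = read_params(par);
  System S = make_system(pos, vel, ring_len);
  const long n_steps = (long)n_steps_d;
  const long dump_every = (long)dump_every_d;
  Xoshiro rng((uint64_t)seed_d);

  const double c1 = std::exp(-P.gamma * P.dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * P.T);
  const double hdt = 0.5 * P.dt;

  S.build_list();
  std::string err;
  double epot = 0;
  auto gap_at = [&](long step) {
    if (!P.wall) return -1.0;
    if (P.ramp_steps <= 0 || step >= P.ramp_steps) return P.gap_end;
    double fr = (double)step / (double)P.ramp_steps;
    return P.gap_start + fr * (P.gap_end - P.gap_start);
  };
  auto cap_at = [&](long step) {
    if (P.fmax <= 0) return -1.0;
    if (P.fmax_end <= P.fmax || n_steps <= 1) return P.fmax;
    return P.fmax + (P.fmax_end - P.fmax) * (double)step / (double)n_steps;
  };
  auto sig_at = [&](long step) {
    if (P.sigma_start <= 0 || n_steps <= 0) return P.sigma;
    double fr = (double)step / (double)n_steps;
    return P.sigma_start + fr * (P.sigma - P.sigma_start);
  };
  if (!compute_forces(S, P, gap_at(0), cap_at(0), sig_at(0), &epot, nullptr,
                      &err))
    stop(err);

  const long n_dumps = dump_every > 0 ? n_steps / dump_every : 0;
  NumericVector frames(n_dumps * (long)S.N * 3L);
  NumericVector dump_time(n_dumps), dump_temp(n_dumps), dump_epot(n_dumps);
  long idump = 0;
  double temp_acc = 0; long temp_n = 0;

  for (long step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < 3 * S.N; ++i) S.v[i] += hdt * S.f[i];
    // A: half drift
    for (int i = 0; i < 3 * S.N; ++i) S.x[i] += hdt * S.v[i];
    // O: exact OU on velocities
    for (int i = 0; i < 3 * S.N; ++i)
      S.v[i] = c1 * S.v[i] + c2 * rng.gauss();
    // kinetic temperature measured here, on the post-thermostat
    // (half-step) velocities: full-step velocities of the splitting
    // carry an O((w dt)^2) bias on stiff bonded modes
    double ke = 0;
    for (int i = 0; i < 3 * S.N; ++i) ke += S.v[i] * S.v[i];
    // A: half drift
    for (int i = 0; i < 3 * S.N; ++i) S.x[i] += hdt * S.v[i];
    if (S.need_rebuild()) S.build_list();
    if (!compute_forces(S, P, gap_at(step), cap_at(step), sig_at(step),
                        &epot, nullptr, &err))
      stop("step %ld: %s", step, err.c_str());
    // B: half kick
    for (int i = 0; i < 3 * S.N; ++i) S.v[i] += hdt * S.f[i];

    temp_acc += ke / (3.0 * S.N);
    ++temp_n;

    if (dump_every > 0 && step % dump_every == 0) {
      for (int i = 0; i < S.N; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(idump * S.N + i) * 3 + k] = S.x[3 * i + k];
      dump_time[idump] = step * P.dt;
      dump_temp[idump] = ke / (3.0 * S.N);
      dump_epot[idump] = epot;
      ++idump;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix outp(S.N, 3), outv(S.N, 3);
  for (int i = 0; i < S.N; ++i)
    for (int k = 0; k < 3; ++k) {
      outp(i, k) = S.x[3 * i + k];
      outv(i, k) = S.v[3 * i + k];
    }
  return List::create(
      _["pos"] = outp, _["vel"] = outv, _["frames"] = frames,
      _["n_dumps"] = (double)idump, _["dump_time"] = dump_time,
      _["dump_temp"] = dump_temp, _["dump_epot"] = dump_epot,
      _["mean_temp"] = temp_n > 0 ? temp_acc / temp_n : NA_REAL);
}

// [[Rcpp::export]]
List cpp_energy(NumericMatrix pos, IntegerVector ring_len, List par) {
  Params P = read_params(par);
  NumericMatrix vel(pos.nrow(), 3);
  System S = make_system(pos, vel, ring_len);
  S.build_list();
  double epot = 0, terms[4];
  std::string err;
  if (!compute_forces(S, P, P.wall ? P.gap_end : -1.0, -1.0, P.sigma, &epot,
                      terms, &err))
    stop(err);
  return List::create(_["fene"] = terms[0], _["wca"] = terms[1],
                      _["bend"] = terms[2], _["wall"] = terms[3],
                      _["total"] = epot);
}
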