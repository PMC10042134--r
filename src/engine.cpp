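// Agent-based germinal center engine.
//
// B cells and Tfh cells move on a 3D spherical lattice split into dark-zone
// (DZ, z < 0) and light-zone (LZ, z >= 0) hemispheres. Founder B cells enter
// the DZ during the influx window, expand with somatic hypermutation, then
// compete in the LZ for FDC-held antigen and Tfh help. Positively selected
// cells recycle to the DZ with a pMHC-dependent number of divisions; a
// fraction of post-division cells exit as output and (after a secretion
// delay) feed soluble antibody back onto FDC antigen as epitope masking.
//
// All randomness comes from R's RNG (unif_rand) so runs are exactly
// reproducible under set.seed(). The antigen ledger (free + masked + pMHC in
// live cells + consumed == initial) and the lattice occupancy map are audited
// at every recording time; violations abort with a diagnostic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

using namespace Rcpp;

namespace {

// Fast counter-based PRNG (splitmix64) for the engine's inner loop; its
// 64-bit state is seeded from R's RNG at run start, so results remain a
// deterministic function of set.seed().
struct SplitMix {
  uint64_t s;
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

static SplitMix g_rng;

inline double runif01() { return g_rng.unif(); }
inline int rint_below(int n) { return g_rng.below(n); }

struct Params {
  int shape_dim, shape_side;
  double gamma, eta;
  double founder_stop_h;
  int founder_initial_div;
  double radius_um, spacing_um;
  int fdc_count, fdc_arm_sites;
  double antigen_per_fdc;
  int tfh_count;
  double tfh_rate, tfh_threshold, tfh_multiplier;
  double b_speed, tfh_speed; // um/min
  double zone_bias;
  int moore; // 1 = 26-neighborhood, 0 = 6
  double cycle_h, cycle_jitter, p_mut, silent_h;
  double cc_lifetime_h, capture_rate_h, fdc_site_sat;
  int pmhc_cap, div_min, div_max;
  double div_slope, p_output;
  int endogenous;
  int ab_bins;
  double ab_kd_min, ab_kd_max, ab_kd_scale, ab_prod_rate, ab_delay_h;
  double inject_h, inject_kd, inject_dose; // inject_h < 0 => none
  double mask_update_h;
  double dt, horizon_h, record_h;
  int extinction, collapse_arm_h;
};

enum CellState : uint8_t { CB = 0, CC = 1 };

struct Cell {
  int32_t site;
  int16_t cx, cy, cz;
  uint8_t czone;
  int32_t clone;
  int8_t bcr[8];
  uint8_t state;
  uint8_t recycled;
  uint8_t held;
  uint8_t alive;
  int16_t div_left;
  int16_t pmhc;
  int16_t mutations;
  float signal;
  float next_div_h;
  float cc_entry_h;
  float aff;
};

struct Engine {
  Params P;
  // lattice
  int K, W;
  std::vector<int32_t> grid;     // dense (W^3) -> site id or -1
  std::vector<int16_t> sx, sy, sz;
  std::vector<uint8_t> zone;     // 0 DZ, 1 LZ
  std::vector<int32_t> occ;      // site -> occupant (-1 empty, >=0 cell,
                                 // <= -2 Tfh index -(i+2))
  std::vector<int32_t> lz_sites, dz_sites;
  int ndirs, n_up, n_mid;
  int dirs[26][3];
  std::vector<int32_t> nbr; // nsites x ndirs neighbor table (-1 = off-lattice)
  // antigen
  std::vector<int32_t> ag_of_site; // site -> antigen-site index or -1
  std::vector<int32_t> ag_site;    // antigen-site index -> site
  std::vector<int32_t> ag_free, ag_masked;
  double initial_antigen;
  double consumed;
  // antibody pool
  std::vector<double> bin_kd, bin_conc;
  std::vector<std::vector<int32_t>> bin_out_hourly; // outputs per hour bucket
  std::vector<int> bin_ptr;                          // delayed prefix pointer
  std::vector<double> bin_producers;
  double exo_conc, exo_kd;
  bool injected;
  double theta;
  // agents
  std::vector<Cell> cells;
  std::vector<int32_t> free_slots;
  std::vector<int32_t> live_list;
  std::vector<int32_t> tfh_site;
  std::vector<int16_t> tfh_x, tfh_y, tfh_z;
  std::vector<uint8_t> tfh_zone;
  std::vector<uint8_t> tfh_held;
  int live;
  // optimal epitope
  int opt[8];
  // bookkeeping
  long founders_admitted;
  long output_count;
  std::vector<int> div_grants;
  long cc_sel, cc_apop_pmhc, cc_apop_nopmhc;
  long sel_pmhc_sum;
  bool collapsed;
  double collapse_h;
  // records
  std::vector<double> rec_time, rec_meanaff, rec_theta;
  std::vector<int> rec_size, rec_ncb, rec_ncc, rec_nclones;
  std::vector<double> rec_free, rec_masked, rec_consumed;
  std::vector<long> rec_output;
  std::vector<double> cen_time;
  std::vector<int> cen_clone, cen_count;

  double aff_of(const int8_t* bcr) const {
    int d = 0;
    for (int k = 0; k < P.shape_dim; k++) d += std::abs((int)bcr[k] - opt[k]);
    return std::exp(-std::pow(d / P.gamma, P.eta));
  }

  int site_at(int x, int y, int z) const {
    if (x < -K || x > K || y < -K || y > K || z < -K || z > K) return -1;
    return grid[(size_t)(x + K) + (size_t)W * ((y + K) + (size_t)W * (z + K))];
  }

  void build_lattice() {
    K = (int)std::floor(P.radius_um / P.spacing_um);
    W = 2 * K + 1;
    grid.assign((size_t)W * W * W, -1);
    double r2 = (P.radius_um / P.spacing_um) * (P.radius_um / P.spacing_um);
    for (int z = -K; z <= K; z++)
      for (int y = -K; y <= K; y++)
        for (int x = -K; x <= K; x++) {
          if ((double)x * x + (double)y * y + (double)z * z <= r2) {
            int id = (int)sx.size();
            grid[(size_t)(x + K) + (size_t)W * ((y + K) + (size_t)W * (z + K))] = id;
            sx.push_back(x); sy.push_back(y); sz.push_back(z);
            uint8_t zn = z >= 0 ? 1 : 0;
            zone.push_back(zn);
            if (zn) lz_sites.push_back(id); else dz_sites.push_back(id);
          }
        }
    occ.assign(sx.size(), -1);
    // directions ordered by dz (+1 block first, then 0, then -1) so a
    // zone-biased move can draw from a contiguous index range
    ndirs = 0; n_up = 0; n_mid = 0;
    for (int dz = 1; dz >= -1; dz--)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          if (!P.moore && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
          dirs[ndirs][0] = dx; dirs[ndirs][1] = dy; dirs[ndirs][2] = dz;
          if (dz == 1) n_up++;
          if (dz == 0) n_mid++;
          ndirs++;
        }
    nbr.assign((size_t)sx.size() * ndirs, -1);
    for (size_t i = 0; i < sx.size(); i++)
      for (int d = 0; d < ndirs; d++)
        nbr[i * ndirs + d] =
          site_at(sx[i] + dirs[d][0], sy[i] + dirs[d][1], sz[i] + dirs[d][2]);
  }

  void place_fdcs() {
    ag_of_site.assign(sx.size(), -1);
    // antigen is integer-valued per site; distribute per-FDC amount equally
    for (int f = 0; f < P.fdc_count; f++) {
      int center = lz_sites[rint_below((int)lz_sites.size())];
      std::vector<int> sites_f;
      sites_f.push_back(center);
      const int arms[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int a = 0; a < 6; a++)
        for (int l = 1; l <= P.fdc_arm_sites; l++) {
          int s = site_at(sx[center] + arms[a][0] * l,
                          sy[center] + arms[a][1] * l,
                          sz[center] + arms[a][2] * l);
          if (s < 0 || !zone[s]) break; // dendrites stay in the LZ
          sites_f.push_back(s);
        }
      long total = (long)std::llround(P.antigen_per_fdc);
      int n = (int)sites_f.size();
      long base = total / n, rem = total % n;
      for (int i = 0; i < n; i++) {
        long amt = base + (i < rem ? 1 : 0);
        int s = sites_f[i];
        int ai = ag_of_site[s];
        if (ai < 0) {
          ai = (int)ag_site.size();
          ag_of_site[s] = ai;
          ag_site.push_back(s);
          ag_free.push_back(0);
          ag_masked.push_back(0);
        }
        ag_free[ai] += (int)amt;
      }
    }
    initial_antigen = 0;
    for (size_t i = 0; i < ag_free.size(); i++) initial_antigen += ag_free[i];
    consumed = 0;
  }

  void place_tfh() {
    tfh_site.assign(P.tfh_count, -1);
    tfh_x.assign(P.tfh_count, 0); tfh_y.assign(P.tfh_count, 0);
    tfh_z.assign(P.tfh_count, 0);
    tfh_zone.assign(P.tfh_count, 1);
    tfh_held.assign(P.tfh_count, 0);
    for (int i = 0; i < P.tfh_count; i++) {
      for (int tries = 0; tries < 1000; tries++) {
        int s = lz_sites[rint_below((int)lz_sites.size())];
        if (occ[s] == -1) { occ[s] = -(i + 2); tfh_site[i] = s; break; }
      }
      if (tfh_site[i] < 0) stop("could not place Tfh cell (lattice full)");
      tfh_x[i] = sx[tfh_site[i]]; tfh_y[i] = sy[tfh_site[i]];
      tfh_z[i] = sz[tfh_site[i]];
    }
  }

  void init_antibody() {
    bin_kd.resize(P.ab_bins);
    bin_conc.assign(P.ab_bins, 0.0);
    int nh = (int)std::ceil(P.horizon_h) + 2;
    bin_out_hourly.assign(P.ab_bins, std::vector<int32_t>(nh, 0));
    bin_ptr.assign(P.ab_bins, 0);
    bin_producers.assign(P.ab_bins, 0.0);
    double lmin = std::log(P.ab_kd_min), lmax = std::log(P.ab_kd_max);
    for (int b = 0; b < P.ab_bins; b++)
      bin_kd[b] = std::exp(lmin + (lmax - lmin) * (b + 0.5) / P.ab_bins);
    exo_conc = 0; exo_kd = 1; injected = false; theta = 0;
  }

  int kd_bin(double kd) const {
    double lmin = std::log(P.ab_kd_min), lmax = std::log(P.ab_kd_max);
    double u = (std::log(kd) - lmin) / (lmax - lmin) * P.ab_bins;
    int b = (int)std::floor(u);
    if (b < 0) b = 0;
    if (b >= P.ab_bins) b = P.ab_bins - 1;
    return b;
  }

  // competitive Langmuir occupancy of the antigen epitope by all antibody
  // species: theta = S / (1 + S), S = sum C_i / KD_i
  double pool_theta() const {
    double S = 0;
    for (int b = 0; b < P.ab_bins; b++) S += bin_conc[b] / bin_kd[b];
    if (injected) S += exo_conc / exo_kd;
    return S / (1.0 + S);
  }

  void update_masking(double t) {
    if (P.endogenous) {
      for (int b = 0; b < P.ab_bins; b++) {
        int hmax = (int)std::floor(t - P.ab_delay_h);
        while (bin_ptr[b] <= hmax && bin_ptr[b] < (int)bin_out_hourly[b].size()) {
          bin_producers[b] += bin_out_hourly[b][bin_ptr[b]];
          bin_ptr[b]++;
        }
        bin_conc[b] += P.ab_prod_rate * bin_producers[b] * P.mask_update_h;
      }
    }
    if (!injected && P.inject_h >= 0 && t >= P.inject_h - 1e-9) {
      injected = true;
      exo_conc = P.inject_dose;
      exo_kd = P.inject_kd;
    }
    theta = pool_theta();
    for (size_t i = 0; i < ag_site.size(); i++) {
      int tot = ag_free[i] + ag_masked[i];
      int m = (int)std::lround(theta * tot);
      ag_masked[i] = m;
      ag_free[i] = tot - m;
    }
  }

  int new_slot() {
    if (!free_slots.empty()) {
      int s = free_slots.back();
      free_slots.pop_back();
      return s;
    }
    cells.push_back(Cell());
    return (int)cells.size() - 1;
  }

  void kill(int i) {
    consumed += cells[i].pmhc;
    occ[cells[i].site] = -1;
    cells[i].alive = 0;
    free_slots.push_back(i);
    live--;
  }

  void admit_founder(double t, const int* bcr) {
    int s = -1;
    for (int tries = 0; tries < 2000; tries++) {
      int c = dz_sites[rint_below((int)dz_sites.size())];
      if (occ[c] == -1) { s = c; break; }
    }
    if (s < 0) return; // DZ saturated; entry lost (never observed in practice)
    int i = new_slot();
    Cell& c = cells[i];
    c.site = s; occ[s] = i;
    c.cx = sx[s]; c.cy = sy[s]; c.cz = sz[s];
    c.czone = zone[s];
    c.clone = (int)founders_admitted;
    for (int k = 0; k < P.shape_dim; k++) c.bcr[k] = (int8_t)bcr[k];
    c.state = CB; c.recycled = 0; c.held = 0; c.alive = 1;
    c.div_left = (int16_t)P.founder_initial_div;
    c.pmhc = 0; c.mutations = 0; c.signal = 0;
    c.next_div_h = (float)(t + cycle_len());
    c.cc_entry_h = 0;
    c.aff = (float)aff_of(c.bcr);
    live_list.push_back(i);
    founders_admitted++;
    live++;
  }

  double cycle_len() const {
    return P.cycle_h * (1.0 + P.cycle_jitter * (2.0 * runif01() - 1.0));
  }

  void mutate(Cell& c) {
    for (;;) {
      int k = rint_below(P.shape_dim);
      int d = runif01() < 0.5 ? -1 : 1;
      int v = c.bcr[k] + d;
      if (v >= 0 && v < P.shape_side) {
        c.bcr[k] = (int8_t)v;
        c.mutations++;
        c.aff = (float)aff_of(c.bcr);
        return;
      }
    }
  }

  int dyn_div(int pmhc) const {
    int d = P.div_min + (int)std::lround(P.div_slope * std::log((double)pmhc));
    if (d < P.div_min) d = P.div_min;
    if (d > P.div_max) d = P.div_max;
    return d;
  }

  void divide_cell(int i, double t) {
    Cell& c = cells[i];
    if (!c.alive || c.state != CB || t < c.next_div_h) return;
    if (c.div_left <= 0) { finish_program(i, t); return; }
    // free neighbor site for the second daughter
    const int32_t* nb = &nbr[(size_t)c.site * ndirs];
    int cand[26], nc2 = 0;
    for (int j = 0; j < ndirs; j++) {
      int s = nb[j];
      if (s >= 0 && occ[s] == -1) cand[nc2++] = s;
    }
    if (nc2 == 0) { c.next_div_h = (float)(t + 0.1); return; }
    int s2 = cand[rint_below(nc2)];
    int i2 = new_slot();
    Cell& c1 = cells[i]; // re-reference: new_slot may reallocate
    Cell& c2 = cells[i2];
    c2 = c1;
    c2.site = s2; occ[s2] = i2;
    c2.cx = sx[s2]; c2.cy = sy[s2]; c2.cz = sz[s2];
    c2.czone = zone[s2];
    live_list.push_back(i2);
    live++;
    c1.div_left--; c2.div_left = c1.div_left;
    c1.next_div_h = (float)(t + cycle_len());
    c2.next_div_h = (float)(t + cycle_len());
    bool can_mut = t >= P.silent_h;
    if (can_mut && runif01() < P.p_mut) mutate(c1);
    if (can_mut && runif01() < P.p_mut) mutate(c2);
    if (c1.div_left <= 0) {
      finish_program(i, t);
      finish_program(i2, t);
    }
  }

  // capture probability = attempt rate x affinity x accessible antigen
  // density: masked antigen blocks binding and sparse dendrites (below the
  // saturation density) are proportionally harder to engage
  inline void capture_cell(int i, double p_capture) {
    Cell& c = cells[i];
    if (!c.alive || c.state != CC || c.pmhc >= P.pmhc_cap) return;
    int ai = ag_of_site[c.site];
    if (ai < 0) return;
    if (ag_free[ai] < 1) return;
    int tot = ag_free[ai] + ag_masked[ai];
    double dens = (double)ag_free[ai] /
      (tot > P.fdc_site_sat ? tot : P.fdc_site_sat);
    if (runif01() < p_capture * c.aff * dens) {
      ag_free[ai]--;
      c.pmhc++;
    }
  }

  // move one mobile agent; bias toward its target zone when outside it,
  // confinement (rejected crossing) when inside it; the agent carries its
  // own coordinates so the move only touches the (cache-resident) grid
  inline void move_agent(int32_t& site, int16_t& x, int16_t& y, int16_t& z,
                         uint8_t& zn, int target_zone, double p_move,
                         int occ_code) {
    // one PRNG draw provides both the move gate (high bits) and the
    // direction (low bits)
    uint64_t u = g_rng.next();
    if (p_move < 1.0 && (u >> 11) * 0x1.0p-53 >= p_move) return;
    int d;
    bool in_target = zn == (uint8_t)target_zone;
    if (!in_target && runif01() < P.zone_bias) {
      // restrict to directions with the correct z sign (contiguous block)
      d = target_zone == 1 ? rint_below(n_up)
                           : n_up + n_mid + rint_below(ndirs - n_up - n_mid);
    } else {
      d = (int)(u % (uint64_t)ndirs);
    }
    int nx = x + dirs[d][0], ny = y + dirs[d][1], nz = z + dirs[d][2];
    int s = site_at(nx, ny, nz);
    if (s < 0 || occ[s] != -1) return;
    if (in_target && zone[s] != (uint8_t)target_zone) return;
    occ[site] = -1;
    occ[s] = occ_code;
    site = s;
    x = (int16_t)nx; y = (int16_t)ny; z = (int16_t)nz;
    zn = zone[s];
  }

  void run(const NumericVector& f_time, const IntegerMatrix& f_bcr) {
    // seed the fast engine PRNG from R's RNG stream
    uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
    uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
    g_rng.s = (hi << 32) ^ lo ^ 0xDEADBEEFCAFEBABEULL;
    build_lattice();
    place_fdcs();
    place_tfh();
    init_antibody();
    cells.reserve(20000);
    live = 0;
    founders_admitted = 0;
    output_count = 0;
    cc_sel = cc_apop_pmhc = cc_apop_nopmhc = 0;
    sel_pmhc_sum = 0;
    collapsed = false;
    collapse_h = -1;

    for (int k = 0; k < P.shape_dim; k++) opt[k] = P.shape_side / 2;

    const double dt = P.dt;
    const long nsteps = (long)std::llround(P.horizon_h / dt);
    const double p_move_b = std::min(1.0, P.b_speed * 60.0 * dt / P.spacing_um);
    const double p_move_t = std::min(1.0, P.tfh_speed * 60.0 * dt / P.spacing_um);
    const double p_capture = std::min(1.0, P.capture_rate_h * dt);
    const double sig_gain = P.tfh_rate * P.tfh_multiplier * dt;
    long next_mask = 0, mask_every = std::max(1L, (long)std::llround(P.mask_update_h / dt));
    long rec_every = std::max(1L, (long)std::llround(P.record_h / dt));
    int next_founder = 0;
    const int nf = f_time.size();

    record(0.0); // initial (empty) state

    for (long step = 1; step <= nsteps; step++) {
      double t = step * dt;

      // compact the live-cell index list (lazy removal of last step's
      // deaths; order preserved for determinism)
      {
        size_t w = 0;
        for (size_t r = 0; r < live_list.size(); r++)
          if (cells[live_list[r]].alive) live_list[w++] = live_list[r];
        live_list.resize(w);
      }

      // 1. founder influx
      while (next_founder < nf && f_time[next_founder] <= t) {
        if (f_time[next_founder] <= P.founder_stop_h + 1e-9) {
          int bcr[8];
          for (int k = 0; k < P.shape_dim; k++) bcr[k] = f_bcr(next_founder, k);
          admit_founder(t, bcr);
        }
        next_founder++;
      }

      // antibody production, injection and masking re-equilibration runs
      // between division and capture (see fused pass below)
      bool ab_step = step >= next_mask;
      if (ab_step) next_mask += mask_every;

      // 3. motility (held = engaged in a Tfh contact this step: no movement)
      for (int li = 0; li < (int)live_list.size(); li++) {
        Cell& c = cells[live_list[li]];
        if (c.held) { c.held = 0; continue; }
        int tz = (c.state == CB) ? 0 : 1;
        move_agent(c.site, c.cx, c.cy, c.cz, c.czone, tz, p_move_b,
                   live_list[li]);
      }
      for (int j = 0; j < (int)tfh_site.size(); j++) {
        if (tfh_held[j]) { tfh_held[j] = 0; continue; }
        move_agent(tfh_site[j], tfh_x[j], tfh_y[j], tfh_z[j], tfh_zone[j], 1,
                   p_move_t, -(j + 2));
      }

      // 4. division with SHM, then 5. antigen capture. On steps where the
      // antibody pool re-equilibrates, the two phases run separately with
      // the masking update between them (division -> antibody -> capture);
      // on all other steps the phases are independent of one another (a
      // division changes neither antigen nor any other cell's capture, and
      // a capture changes no division), so they run as one fused pass over
      // the live list.
      const int n_before_div = (int)live_list.size();
      if (ab_step) {
        for (int li = 0; li < n_before_div; li++) divide_cell(live_list[li], t);
        update_masking(t);
        for (int li = 0; li < n_before_div; li++) capture_cell(live_list[li], p_capture);
      } else {
        for (int li = 0; li < n_before_div; li++) {
          divide_cell(live_list[li], t);
          capture_cell(live_list[li], p_capture);
        }
      }

      // 6. Tfh interactions: each Tfh polarizes to the adjacent unengaged
      //    centrocyte with the highest pMHC (ties uniform at random)
      for (int j = 0; j < (int)tfh_site.size(); j++) {
        const int32_t* nb = &nbr[(size_t)tfh_site[j] * ndirs];
        int best = -1, best_pmhc = 0, nties = 0;
        for (int d = 0; d < ndirs; d++) {
          int s = nb[d];
          if (s < 0) continue;
          int o = occ[s];
          if (o < 0) continue;
          Cell& c = cells[o];
          if (c.state != CC || c.pmhc < 1 || c.held) continue;
          if (c.pmhc > best_pmhc) { best = o; best_pmhc = c.pmhc; nties = 1; }
          else if (c.pmhc == best_pmhc) {
            nties++;
            if (runif01() < 1.0 / nties) best = o;
          }
        }
        if (best >= 0) {
          cells[best].held = 1;
          cells[best].signal += (float)sig_gain;
          tfh_held[j] = 1;
        }
      }

      // 7. selection decisions
      for (int li = 0; li < (int)live_list.size(); li++) {
        int i = live_list[li];
        Cell& c = cells[i];
        if (!c.alive || c.state != CC) continue;
        if (c.signal >= P.tfh_threshold) {
          int nd = dyn_div(c.pmhc);
          div_grants.push_back(nd);
          cc_sel++;
          sel_pmhc_sum += c.pmhc;
          consumed += c.pmhc;
          c.pmhc = 0; c.signal = 0; c.held = 0;
          c.state = CB; c.recycled = 1;
          c.div_left = (int16_t)nd;
          c.next_div_h = (float)(t + cycle_len());
        } else if (t - c.cc_entry_h > P.cc_lifetime_h) {
          if (c.pmhc >= 1) cc_apop_pmhc++; else cc_apop_nopmhc++;
          kill(i);
        }
      }

      // 8. collapse check (armed after the influx window; GC starts empty)
      if (!collapsed && t > P.collapse_arm_h && live < P.extinction) {
        collapsed = true;
        collapse_h = t;
      }

      // 9. recording + audits
      if (step % rec_every == 0) record(t);
    }
  }

  void finish_program(int i, double t) {
    Cell& c = cells[i];
    if (c.div_left > 0) return;
    if (c.recycled && runif01() < P.p_output) {
      // differentiate to output (exits via the DZ); antibody production
      // starts after the secretion delay
      output_count++;
      double kd = P.ab_kd_scale / c.aff;
      int hb = (int)std::floor(t);
      int b = kd_bin(kd);
      if (hb >= 0 && hb < (int)bin_out_hourly[b].size())
        bin_out_hourly[b][hb]++;
      kill(i);
    } else {
      c.state = CC;
      c.recycled = 0;
      c.cc_entry_h = (float)t;
      c.pmhc = 0;
      c.signal = 0;
    }
  }

  void record(double t) {
    // audits first
    double free_tot = 0, masked_tot = 0;
    for (size_t i = 0; i < ag_free.size(); i++) {
      if (ag_free[i] < 0 || ag_masked[i] < 0)
        stop("antigen ledger negative at t=%f", t);
      free_tot += ag_free[i];
      masked_tot += ag_masked[i];
    }
    double held_pmhc = 0;
    long nlive = 0, ncb = 0, ncc = 0;
    double aff_sum = 0;
    std::vector<int> clone_count((size_t)std::max<long>(1, founders_admitted), 0);
    for (size_t i = 0; i < cells.size(); i++) {
      const Cell& c = cells[i];
      if (!c.alive) continue;
      nlive++;
      held_pmhc += c.pmhc;
      aff_sum += c.aff;
      if (c.state == CB) ncb++; else ncc++;
      clone_count[c.clone]++;
      if (occ[c.site] != (int)i)
        stop("occupancy map mismatch for cell %d at t=%f", (int)i, t);
    }
    if (nlive != live) stop("live-count bookkeeping mismatch at t=%f", t);
    double ledger = free_tot + masked_tot + held_pmhc + consumed;
    if (std::fabs(ledger - initial_antigen) > 0.5)
      stop("antigen ledger violation at t=%f: %f vs %f", t, ledger,
           initial_antigen);
    long occ_n = 0;
    for (size_t s = 0; s < occ.size(); s++) if (occ[s] != -1) occ_n++;
    if (occ_n != nlive + (long)tfh_site.size())
      stop("occupancy audit failed at t=%f", t);

    int nclones = 0;
    for (size_t k = 0; k < clone_count.size(); k++) {
      if (clone_count[k] > 0) {
        nclones++;
        cen_time.push_back(t);
        cen_clone.push_back((int)k);
        cen_count.push_back(clone_count[k]);
      }
    }
    rec_time.push_back(t);
    rec_size.push_back((int)nlive);
    rec_ncb.push_back((int)ncb);
    rec_ncc.push_back((int)ncc);
    rec_nclones.push_back(nclones);
    rec_meanaff.push_back(nlive ? aff_sum / nlive : 0.0);
    rec_theta.push_back(theta);
    rec_free.push_back(free_tot);
    rec_masked.push_back(masked_tot);
    rec_consumed.push_back(consumed);
    rec_output.push_back(output_count);
  }
};

Params parse_params(const List& cfg) {
  Params P;
  P.shape_dim = as<int>(cfg["shape_dim"]);
  P.shape_side = as<int>(cfg["shape_side"]);
  P.gamma = as<double>(cfg["affinity_gamma"]);
  P.eta = as<double>(cfg["affinity_eta"]);
  P.founder_stop_h = as<double>(cfg["founder_stop_h"]);
  P.founder_initial_div = as<int>(cfg["founder_initial_divisions"]);
  P.radius_um = as<double>(cfg["lattice_radius_um"]);
  P.spacing_um = as<double>(cfg["lattice_spacing_um"]);
  P.fdc_count = as<int>(cfg["fdc_count"]);
  P.fdc_arm_sites = as<int>(cfg["fdc_arm_sites"]);
  P.antigen_per_fdc = as<double>(cfg["antigen_per_fdc"]);
  P.tfh_count = as<int>(cfg["tfh_count"]);
  P.tfh_rate = as<double>(cfg["tfh_signal_rate_per_h"]);
  P.tfh_threshold = as<double>(cfg["tfh_signal_threshold"]);
  P.tfh_multiplier = as<double>(cfg["tfh_signal_multiplier"]);
  P.b_speed = as<double>(cfg["b_speed_um_min"]);
  P.tfh_speed = as<double>(cfg["tfh_speed_um_min"]);
  P.zone_bias = as<double>(cfg["zone_bias"]);
  P.moore = as<std::string>(cfg["neighborhood"]) == "moore" ? 1 : 0;
  P.cycle_h = as<double>(cfg["cycle_h"]);
  P.cycle_jitter = as<double>(cfg["cycle_jitter"]);
  P.p_mut = as<double>(cfg["p_mutation"]);
  P.silent_h = as<double>(cfg["mutation_silent_h"]);
  P.cc_lifetime_h = as<double>(cfg["cc_lifetime_h"]);
  P.capture_rate_h = as<double>(cfg["capture_rate_per_h"]);
  P.fdc_site_sat = as<double>(cfg["fdc_site_saturation"]);
  P.pmhc_cap = as<int>(cfg["pmhc_cap"]);
  P.div_min = as<int>(cfg["div_min"]);
  P.div_max = as<int>(cfg["div_max"]);
  P.div_slope = as<double>(cfg["div_slope"]);
  P.p_output = as<double>(cfg["p_output"]);
  P.endogenous = as<bool>(cfg["endogenous_feedback"]) ? 1 : 0;
  P.ab_bins = as<int>(cfg["ab_kd_bins"]);
  P.ab_kd_min = as<double>(cfg["ab_kd_min_nm"]);
  P.ab_kd_max = as<double>(cfg["ab_kd_max_nm"]);
  P.ab_kd_scale = as<double>(cfg["ab_kd_scale_nm"]);
  P.ab_prod_rate = as<double>(cfg["ab_production_rate_nm_per_cell_h"]);
  P.ab_delay_h = as<double>(cfg["ab_secretion_delay_h"]);
  double inj_day = as<double>(cfg["inject_day"]);
  if (NumericVector::is_na(inj_day)) {
    P.inject_h = -1; P.inject_kd = 1;
  } else {
    P.inject_h = inj_day * 24.0;
    P.inject_kd = as<double>(cfg["inject_kd_nm"]);
  }
  P.inject_dose = as<double>(cfg["inject_dose_nm"]);
  P.mask_update_h = as<double>(cfg["mask_update_h"]);
  P.dt = as<double>(cfg["dt_h"]);
  P.horizon_h = as<double>(cfg["horizon_days"]) * 24.0;
  P.record_h = as<double>(cfg["record_every_h"]);
  P.extinction = as<int>(cfg["extinction_threshold"]);
  P.collapse_arm_h = as<int>(cfg["collapse_check_after_h"]);
  return P;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_run_gc(List cfg, NumericVector founder_time, IntegerMatrix founder_bcr) {
  Engine E;
  E.P = parse_params(cfg);
  if (E.P.shape_dim < 1 || E.P.shape_dim > 8)
    stop("engine supports shape-space dimension 1..8");
  if (E.P.shape_side > 127) stop("shape_side too large for engine storage");
  if (founder_bcr.ncol() != E.P.shape_dim)
    stop("founder BCR matrix has wrong dimension");
  if (founder_bcr.nrow() < founder_time.size())
    stop("fewer founder BCRs than entry times");
  E.run(founder_time, founder_bcr);

  List census = List::create(
    _["time_h"] = wrap(E.cen_time),
    _["clone_id"] = wrap(E.cen_clone),
    _["count"] = wrap(E.cen_count));
  List summary = List::create(
    _["time_h"] = wrap(E.rec_time),
    _["size"] = wrap(E.rec_size),
    _["n_centroblast"] = wrap(E.rec_ncb),
    _["n_centrocyte"] = wrap(E.rec_ncc),
    _["n_clones"] = wrap(E.rec_nclones),
    _["mean_affinity"] = wrap(E.rec_meanaff),
    _["free_antigen"] = wrap(E.rec_free),
    _["masked_antigen"] = wrap(E.rec_masked),
    _["consumed_antigen"] = wrap(E.rec_consumed),
    _["masked_fraction"] = wrap(E.rec_theta),
    _["output_cum"] = wrap(E.rec_output));
  return List::create(
    _["census"] = census,
    _["summary"] = summary,
    _["founders_admitted"] = (double)E.founders_admitted,
    _["output_count"] = (double)E.output_count,
    _["collapse_h"] = E.collapsed ? E.collapse_h : NA_REAL,
    _["division_grants"] = wrap(E.div_grants),
    _["cc_selected"] = (double)E.cc_sel,
    _["sel_pmhc_mean"] = E.cc_sel ? (double)E.sel_pmhc_sum / E.cc_sel : NA_REAL,
    _["cc_apoptosis_with_pmhc"] = (double)E.cc_apop_pmhc,
    _["cc_apoptosis_no_pmhc"] = (double)E.cc_apop_nopmhc,
    _["n_sites"] = (int)E.sx.size(),
    _["n_antigen_sites"] = (int)E.ag_site.size(),
    _["initial_antigen"] = E.initial_antigen,
    _["ledger_ok"] = true);
}

//' @noRd
// [[Rcpp::export]]
double cpp_masked_theta(NumericVector conc, NumericVector kd) {
  if (conc.size() != kd.size()) stop("concentration/KD length mismatch");
  double S = 0;
  for (int i = 0; i < conc.size(); i++) {
    if (conc[i] < 0) stop("negative antibody concentration");
    if (kd[i] <= 0) stop("non-positive KD");
    S += conc[i] / kd[i];
  }
  return S / (1.0 + S);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_dynamic_divisions(IntegerVector pmhc, int div_min,
                                    int div_max, double slope) {
  IntegerVector out(pmhc.size());
  for (int i = 0; i < pmhc.size(); i++) {
    if (pmhc[i] < 1) stop("dynamic division number requires pMHC >= 1");
    int d = div_min + (int)std::lround(slope * std::log((double)pmhc[i]));
    if (d < div_min) d = div_min;
    if (d > div_max) d = div_max;
    out[i] = d;
  }
  return out;
}
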