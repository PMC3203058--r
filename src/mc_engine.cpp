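// Metropolis Monte Carlo engine for two self-avoiding lattice polymers with
// typed binding regions and two species of diffusing bridging molecules.
//
// State lives on a periodic cubic lattice of side L.  Occupancy encoding:
//   occ[site] == 0            empty
//   occ[site] in 1..NB        bead (id = occ - 1)
//   occ[site] >  NB           molecule (id = occ - NB - 1)
//
// Energy model: for each molecule, its 6 nearest-neighbour sites are scanned
// in fixed lexicographic offset order; cognate beads contribute a heterotypic
// bond (-affinity), same-species molecules a homotypic bond candidate.  A
// molecule counts at most `valency` bonds (cap over hetero+homo by default,
// or homo only when cap_scope = homo).  A homotypic pair contributes its
// energy once, and only when the pair lies within the counted candidates of
// BOTH partners (mutual-counting rule) -- this keeps the energy a pure,
// deterministic function of the microstate, as Metropolis requires.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// lexicographic order of the 6 unit offsets
static const int OFF[6][3] = {
  {-1, 0, 0}, {0, -1, 0}, {0, 0, -1}, {0, 0, 1}, {0, 1, 0}, {1, 0, 0}
};

// region type codes (match R side - 1): ALPHA=0, BETA=1, GAMMA=2, INERT=3
// species codes: A=0, B=1

struct Engine {
  int L, L2, L3;
  int NB, NM, NP, Nent;
  int v;                 // valency cap
  bool cap_total;        // cap applies to hetero+homo (true) or homo only
  double aff[2][4];
  double eh[2];

  std::vector<int> occ;
  std::vector<int> nbt;          // neighbour table, 6 per site
  std::vector<int> bpos, btype, bpoly, bblock;
  std::vector<int> pstart, plen; // per polymer
  std::vector<int> mpos, msp;
  std::vector<double> ub, um;    // unwrapped coords (3*NB, 3*NM)
  std::vector<double> ub0, um0;  // initial unwrapped coords

  double E;                      // running energy
  double E0;

  // move bookkeeping: 0=molecule step, 1=corner flip, 2=end rotation, 3=crankshaft
  long long att[4], acc[4], nul[4];

  std::vector<char> inA;         // affected-molecule flags
  std::vector<int> shell_stamp;  // for local density
  int stampgen;

  inline int wrap(int a) const { int r = a % L; return r < 0 ? r + L : r; }
  inline int sidx(int x, int y, int z) const { return wrap(x) + L * wrap(y) + L2 * wrap(z); }
  inline void coords(int s, int &x, int &y, int &z) const {
    x = s % L; y = (s / L) % L; z = s / L2;
  }
  // minimal-image component difference (valid for |true diff| < L/2)
  inline int mi(int d) const {
    if (d > L / 2) d -= L;
    if (d < -(L / 2)) d += L;
    return d;
  }
  inline void mivec(int s_from, int s_to, int d[3]) const {
    int x1, y1, z1, x2, y2, z2;
    coords(s_from, x1, y1, z1); coords(s_to, x2, y2, z2);
    d[0] = mi(x2 - x1); d[1] = mi(y2 - y1); d[2] = mi(z2 - z1);
  }

  void build_tables() {
    L2 = L * L; L3 = L2 * L;
    nbt.assign(6 * (size_t)L3, 0);
    for (int s = 0; s < L3; ++s) {
      int x, y, z; coords(s, x, y, z);
      for (int k = 0; k < 6; ++k)
        nbt[6 * (size_t)s + k] = sidx(x + OFF[k][0], y + OFF[k][1], z + OFF[k][2]);
    }
    occ.assign(L3, 0);
    for (int i = 0; i < NB; ++i) occ[bpos[i]] = i + 1;
    for (int j = 0; j < NM; ++j) occ[mpos[j]] = NB + 1 + j;
    inA.assign(NM, 0);
    shell_stamp.assign(L3, 0);
    stampgen = 0;
    att[0] = att[1] = att[2] = att[3] = 0;
    acc[0] = acc[1] = acc[2] = acc[3] = 0;
    nul[0] = nul[1] = nul[2] = nul[3] = 0;
  }

  // --- energy ----------------------------------------------------------

  // scan molecule j sitting at site s; returns hetero energy, fills counted
  // homotypic partner ids into partners[] (size >= 6)
  inline double scan_mol(int j, int s, int *partners, int &npart) const {
    const int sp = msp[j];
    double ehet = 0.0;
    int nb_ = 0, nhomo = 0;
    npart = 0;
    const int *nn = &nbt[6 * (size_t)s];
    for (int k = 0; k < 6; ++k) {
      const int o = occ[nn[k]];
      if (o == 0) continue;
      if (o <= NB) {
        const double a = aff[sp][btype[o - 1]];
        if (a > 0.0) {
          if (cap_total) { if (nb_ < v) { ehet -= a; ++nb_; } }
          else { ehet -= a; }
        }
      } else {
        const int j2 = o - NB - 1;
        if (msp[j2] == sp) {
          const int cnt = cap_total ? nb_ : nhomo;
          if (cnt < v) { partners[npart++] = j2; ++nb_; ++nhomo; }
        }
      }
    }
    return ehet;
  }

  // does molecule q's counted set include molecule `target`?
  inline bool counts_partner(int q, int target) const {
    const int sp = msp[q];
    int nb_ = 0, nhomo = 0;
    const int *nn = &nbt[6 * (size_t)mpos[q]];
    for (int k = 0; k < 6; ++k) {
      const int o = occ[nn[k]];
      if (o == 0) continue;
      if (o <= NB) {
        if (aff[sp][btype[o - 1]] > 0.0 && cap_total) {
          if (nb_ < v) ++nb_;
        }
      } else {
        const int j2 = o - NB - 1;
        if (msp[j2] == sp) {
          const int cnt = cap_total ? nb_ : nhomo;
          if (cnt >= v) return false;
          if (j2 == target) return true;
          ++nb_; ++nhomo;
        }
      }
    }
    return false;
  }

  double total_energy(double *hetero_out, double *homo_out,
                      int *hb_counts, int *mb_counts) const {
    double ehet = 0.0, ehomo = 0.0;
    int partners[6], npart;
    for (int j = 0; j < NM; ++j) {
      const double e = scan_mol(j, mpos[j], partners, npart);
      ehet += e;
      if (hb_counts) {
        // counted hetero bonds = round(-e / mean affinity) is ill-defined for
        // mixed affinities; recount explicitly
        int sp = msp[j], nb_ = 0, cnt = 0;
        const int *nn = &nbt[6 * (size_t)mpos[j]];
        for (int k = 0; k < 6; ++k) {
          const int o = occ[nn[k]];
          if (o == 0) continue;
          if (o <= NB) {
            if (aff[sp][btype[o - 1]] > 0.0) {
              if (!cap_total || nb_ < v) { ++cnt; ++nb_; }
            }
          } else if (msp[o - NB - 1] == sp) {
            if (cap_total && nb_ < v) ++nb_;
          }
        }
        hb_counts[j] = cnt;
      }
      for (int t = 0; t < npart; ++t) {
        const int j2 = partners[t];
        const bool active = counts_partner(j2, j);
        if (active && mb_counts) { ++mb_counts[j]; }
        if (j2 > j && active) ehomo -= eh[msp[j]];
      }
    }
    if (hetero_out) *hetero_out = ehet;
    if (homo_out) *homo_out = ehomo;
    return ehet + ehomo;
  }

  // energy restricted to pairs/molecules touching the affected set A
  double local_energy(const int *A, int nA) {
    double e = 0.0;
    int partners[6], npart;
    for (int t = 0; t < nA; ++t) {
      const int j = A[t];
      e += scan_mol(j, mpos[j], partners, npart);
      for (int q = 0; q < npart; ++q) {
        const int j2 = partners[q];
        if (inA[j2] && j2 < j) continue;       // pair handled from j2's side
        if (counts_partner(j2, j)) e -= eh[msp[j]];
      }
    }
    return e;
  }

  // affected molecules: any molecule adjacent to one of `sites`, plus moved_mol
  int build_affected(const int *sites, int ns, int moved_mol, int *A) {
    int nA = 0;
    if (moved_mol >= 0) { A[nA++] = moved_mol; inA[moved_mol] = 1; }
    for (int t = 0; t < ns; ++t) {
      const int *nn = &nbt[6 * (size_t)sites[t]];
      for (int k = 0; k < 6; ++k) {
        const int o = occ[nn[k]];
        if (o > NB) {
          const int j = o - NB - 1;
          if (!inA[j]) { A[nA++] = j; inA[j] = 1; }
        }
      }
    }
    return nA;
  }
  inline void clear_affected(const int *A, int nA) {
    for (int t = 0; t < nA; ++t) inA[A[t]] = 0;
  }

  inline bool metropolis(double dE) {
    if (dE <= 0.0) return true;
    return unif_rand() < std::exp(-dE);
  }

  // --- moves -----------------------------------------------------------

  void move_molecule(int j) {
    ++att[0];
    const int s = mpos[j];
    const int k = (int)(unif_rand() * 6.0);
    const int t = nbt[6 * (size_t)s + (k >= 6 ? 5 : k)];
    if (occ[t] != 0) return;  // rejected outright
    int sites[2] = { s, t };
    int A[32];
    const int nA = build_affected(sites, 2, j, A);
    const double eb = local_energy(A, nA);
    occ[s] = 0; occ[t] = NB + 1 + j; mpos[j] = t;
    const double ea = local_energy(A, nA);
    clear_affected(A, nA);
    const double dE = ea - eb;
    if (metropolis(dE)) {
      E += dE; ++acc[0];
      int d[3]; mivec(s, t, d);
      um[3 * j] += d[0]; um[3 * j + 1] += d[1]; um[3 * j + 2] += d[2];
    } else {
      occ[t] = 0; occ[s] = NB + 1 + j; mpos[j] = s;
    }
  }

  // shared tail for single-bead displacement i: s_old -> s_new (s_new empty)
  void do_bead_step(int i, int s_new, int kind) {
    const int s_old = bpos[i];
    int sites[2] = { s_old, s_new };
    int A[32];
    const int nA = build_affected(sites, 2, -1, A);
    const double eb = local_energy(A, nA);
    occ[s_old] = 0; occ[s_new] = i + 1; bpos[i] = s_new;
    const double ea = local_energy(A, nA);
    clear_affected(A, nA);
    const double dE = ea - eb;
    if (metropolis(dE)) {
      E += dE; ++acc[kind];
      int d[3]; mivec(s_old, s_new, d);
      ub[3 * i] += d[0]; ub[3 * i + 1] += d[1]; ub[3 * i + 2] += d[2];
    } else {
      occ[s_new] = 0; occ[s_old] = i + 1; bpos[i] = s_old;
    }
  }

  void move_bead_local(int i) {
    const int p = bpoly_of(i);
    const int lo = pstart[p], hi = pstart[p] + plen[p] - 1;
    if (i == lo || i == hi) {
      // end rotation: propose a uniform neighbour of the single chain neighbour
      ++att[2];
      const int nb_bead = (i == lo) ? i + 1 : i - 1;
      const int k = (int)(unif_rand() * 6.0);
      const int t = nbt[6 * (size_t)bpos[nb_bead] + (k >= 6 ? 5 : k)];
      if (t == bpos[i]) { ++nul[2]; return; }   // proposes current position
      if (occ[t] != 0) return;
      do_bead_step(i, t, 2);
    } else {
      // corner flip
      ++att[1];
      const int sp_ = bpos[i - 1], sc = bpos[i], sn = bpos[i + 1];
      int d1[3], d2[3];
      mivec(sp_, sc, d1); mivec(sc, sn, d2);
      if (d1[0] == d2[0] && d1[1] == d2[1] && d1[2] == d2[2]) { ++nul[1]; return; } // straight
      int xp, yp, zp; coords(sp_, xp, yp, zp);
      const int t = sidx(xp + d2[0], yp + d2[1], zp + d2[2]);
      if (occ[t] != 0) return;
      do_bead_step(i, t, 1);
    }
  }

  void move_crankshaft(int i) {
    ++att[3];
    const int p = bpoly_of(i);
    const int hi = pstart[p] + plen[p] - 1;
    if (i + 3 > hi) { ++nul[3]; return; }
    const int s1 = bpos[i], s2 = bpos[i + 1], s3 = bpos[i + 2], s4 = bpos[i + 3];
    int a[3]; mivec(s1, s4, a);
    if (std::abs(a[0]) + std::abs(a[1]) + std::abs(a[2]) != 1) { ++nul[3]; return; }
    int p1[3], p2[3];
    mivec(s1, s2, p1); mivec(s4, s3, p2);
    const int th = 1 + (int)(unif_rand() * 3.0); // 1=90, 2=180, 3=270 degrees
    int r1[3], r2[3];
    rot_about(a, p1, th, r1);
    rot_about(a, p2, th, r2);
    if (r1[0] == p1[0] && r1[1] == p1[1] && r1[2] == p1[2] &&
        r2[0] == p2[0] && r2[1] == p2[1] && r2[2] == p2[2]) { ++nul[3]; return; }
    int x1, y1, z1, x4, y4, z4;
    coords(s1, x1, y1, z1); coords(s4, x4, y4, z4);
    const int t2 = sidx(x1 + r1[0], y1 + r1[1], z1 + r1[2]);
    const int t3 = sidx(x4 + r2[0], y4 + r2[1], z4 + r2[2]);
    // vacate, then test targets
    occ[s2] = 0; occ[s3] = 0;
    if (occ[t2] != 0 || occ[t3] != 0) {
      occ[s2] = i + 2; occ[s3] = i + 3;
      return;
    }
    int sites[4] = { s2, s3, t2, t3 };
    // restore occupancy for the "before" energy
    occ[s2] = i + 2; occ[s3] = i + 3;
    int A[64];
    const int nA = build_affected(sites, 4, -1, A);
    const double eb = local_energy(A, nA);
    occ[s2] = 0; occ[s3] = 0;
    occ[t2] = i + 2; occ[t3] = i + 3;
    bpos[i + 1] = t2; bpos[i + 2] = t3;
    const double ea = local_energy(A, nA);
    clear_affected(A, nA);
    const double dE = ea - eb;
    if (metropolis(dE)) {
      E += dE; ++acc[3];
      int d[3];
      mivec(s2, t2, d);
      ub[3 * (i + 1)] += d[0]; ub[3 * (i + 1) + 1] += d[1]; ub[3 * (i + 1) + 2] += d[2];
      mivec(s3, t3, d);
      ub[3 * (i + 2)] += d[0]; ub[3 * (i + 2) + 1] += d[1]; ub[3 * (i + 2) + 2] += d[2];
    } else {
      occ[t2] = 0; occ[t3] = 0;
      occ[s2] = i + 2; occ[s3] = i + 3;
      bpos[i + 1] = s2; bpos[i + 2] = s3;
    }
  }

  // rotate p about unit axis a by th*90 degrees (Rodrigues, integer form)
  static void rot_about(const int a[3], const int p[3], int th, int out[3]) {
    const int ap = a[0] * p[0] + a[1] * p[1] + a[2] * p[2];
    int cx[3] = { a[1] * p[2] - a[2] * p[1],
                  a[2] * p[0] - a[0] * p[2],
                  a[0] * p[1] - a[1] * p[0] };
    for (int k = 0; k < 3; ++k) {
      if (th == 1)      out[k] = ap * a[k] + cx[k];
      else if (th == 2) out[k] = 2 * ap * a[k] - p[k];
      else              out[k] = ap * a[k] - cx[k];
    }
  }

  inline int bpoly_of(int i) const { return bpoly[i]; }

  void attempt() {
    int e = (int)(unif_rand() * Nent);
    if (e >= Nent) e = Nent - 1;
    if (e < NB) {
      if (unif_rand() < 0.5) move_bead_local(e);
      else move_crankshaft(e);
    } else {
      move_molecule(e - NB);
    }
  }

  void sweep() { for (int t = 0; t < Nent; ++t) attempt(); }

  // --- observables -----------------------------------------------------

  // contact booleans per functional block (ALPHA/BETA blocks), against the
  // GAMMA block of the same polymer; returns via out arrays sized n_blocks
  void contacts(std::vector<int> &block_contact, std::vector<int> &block_bridges,
                const std::vector<int> &block_type, const std::vector<int> &block_poly,
                const std::vector<int> &gamma_block_of_poly) const {
    const int nblk = (int)block_type.size();
    std::fill(block_contact.begin(), block_contact.end(), 0);
    std::fill(block_bridges.begin(), block_bridges.end(), 0);
    // molecule-mediated bridges; a molecule can only bridge regions it has
    // affinity for (cognate bridging, the model's interaction mechanism)
    for (int j = 0; j < NM; ++j) {
      unsigned int mask = 0;
      const int sp = msp[j];
      const int *nn = &nbt[6 * (size_t)mpos[j]];
      for (int k = 0; k < 6; ++k) {
        const int o = occ[nn[k]];
        if (o > 0 && o <= NB && aff[sp][btype[o - 1]] > 0.0)
          mask |= (1u << bblock[o - 1]);
      }
      if (!mask) continue;
      for (int b = 0; b < nblk; ++b) {
        if (block_type[b] != 0 && block_type[b] != 1) continue;
        const int g = gamma_block_of_poly[block_poly[b]];
        if (g < 0) continue;
        if ((mask & (1u << b)) && (mask & (1u << g))) {
          block_contact[b] = 1;
          ++block_bridges[b];
        }
      }
    }
    // direct bead adjacency
    for (int i = 0; i < NB; ++i) {
      const int b = bblock[i];
      if (block_type[b] != 0 && block_type[b] != 1) continue;
      if (block_contact[b]) continue;
      const int *nn = &nbt[6 * (size_t)bpos[i]];
      for (int k = 0; k < 6; ++k) {
        const int o = occ[nn[k]];
        if (o > 0 && o <= NB) {
          const int i2 = o - 1;
          if (bpoly[i2] == bpoly[i] && btype[i2] == 2) { block_contact[b] = 1; break; }
        }
      }
    }
  }

  // density of species `sp` within Chebyshev radius R of any GAMMA bead of
  // polymer p, normalised by the union-shell site count
  double local_density(int p, int sp, int R) {
    ++stampgen;
    long nsites = 0, nmol = 0;
    for (int i = 0; i < NB; ++i) {
      if (bpoly[i] != p || btype[i] != 2) continue;
      int x, y, z; coords(bpos[i], x, y, z);
      for (int dx = -R; dx <= R; ++dx)
        for (int dy = -R; dy <= R; ++dy)
          for (int dz = -R; dz <= R; ++dz) {
            const int s = sidx(x + dx, y + dy, z + dz);
            if (shell_stamp[s] == stampgen) continue;
            shell_stamp[s] = stampgen;
            ++nsites;
            const int o = occ[s];
            if (o > NB && msp[o - NB - 1] == sp) ++nmol;
          }
    }
    return nsites ? (double)nmol / (double)nsites : 0.0;
  }

  // largest nearest-neighbour-connected cluster fraction for species sp
  double largest_cluster_fraction(int sp) const {
    int nsp = 0;
    for (int j = 0; j < NM; ++j) if (msp[j] == sp) ++nsp;
    if (nsp == 0) return NA_REAL;
    std::vector<char> seen(NM, 0);
    std::vector<int> stack;
    int best = 0;
    for (int j = 0; j < NM; ++j) {
      if (msp[j] != sp || seen[j]) continue;
      int size = 0;
      stack.clear(); stack.push_back(j); seen[j] = 1;
      while (!stack.empty()) {
        const int q = stack.back(); stack.pop_back();
        ++size;
        const int *nn = &nbt[6 * (size_t)mpos[q]];
        for (int k = 0; k < 6; ++k) {
          const int o = occ[nn[k]];
          if (o > NB) {
            const int j2 = o - NB - 1;
            if (!seen[j2] && msp[j2] == sp) { seen[j2] = 1; stack.push_back(j2); }
          }
        }
      }
      if (size > best) best = size;
    }
    return (double)best / (double)nsp;
  }

  void validate() const {
    std::vector<int> chk(L3, 0);
    for (int i = 0; i < NB; ++i) {
      if (chk[bpos[i]]) stop("state invariant violated: site shared (bead %d)", i + 1);
      chk[bpos[i]] = 1;
      if (occ[bpos[i]] != i + 1) stop("occupancy map inconsistent at bead %d", i + 1);
    }
    for (int j = 0; j < NM; ++j) {
      if (chk[mpos[j]]) stop("state invariant violated: site shared (molecule %d)", j + 1);
      chk[mpos[j]] = 1;
      if (occ[mpos[j]] != NB + 1 + j) stop("occupancy map inconsistent at molecule %d", j + 1);
    }
    for (int p = 0; p < NP; ++p) {
      for (int i = pstart[p]; i < pstart[p] + plen[p] - 1; ++i) {
        int d[3]; mivec(bpos[i], bpos[i + 1], d);
        if (std::abs(d[0]) + std::abs(d[1]) + std::abs(d[2]) != 1)
          stop("chain connectivity broken between beads %d and %d", i + 1, i + 2);
      }
    }
  }
};

static Engine make_engine(const IntegerMatrix &beads, const IntegerVector &btype,
                          const IntegerVector &bpoly, const IntegerVector &bblock,
                          const IntegerMatrix &mols, const IntegerVector &mspecies,
                          int L, const NumericMatrix &affinity,
                          const NumericVector &ehomo, int valency, bool cap_total) {
  Engine en;
  en.L = L; en.L2 = L * L; en.L3 = L * L * L;
  en.NB = beads.nrow(); en.NM = mols.nrow();
  en.v = valency; en.cap_total = cap_total;
  en.Nent = en.NB + en.NM;
  for (int s = 0; s < 2; ++s)
    for (int t = 0; t < 4; ++t) en.aff[s][t] = affinity(s, t);
  en.eh[0] = ehomo[0]; en.eh[1] = ehomo[1];

  en.btype.resize(en.NB); en.bpoly.resize(en.NB); en.bblock.resize(en.NB);
  en.bpos.resize(en.NB);
  int np = 0;
  for (int i = 0; i < en.NB; ++i) {
    en.btype[i] = btype[i]; en.bpoly[i] = bpoly[i]; en.bblock[i] = bblock[i];
    if (bpoly[i] + 1 > np) np = bpoly[i] + 1;
  }
  en.NP = np;
  en.pstart.assign(np, -1); en.plen.assign(np, 0);
  for (int i = 0; i < en.NB; ++i) {
    const int p = bpoly[i];
    if (en.pstart[p] < 0) en.pstart[p] = i;
    ++en.plen[p];
  }
  en.mpos.resize(en.NM); en.msp.resize(en.NM);
  for (int i = 0; i < en.NB; ++i)
    en.bpos[i] = ((beads(i, 0) % L + L) % L) + L * ((beads(i, 1) % L + L) % L)
               + L * L * ((beads(i, 2) % L + L) % L);
  for (int j = 0; j < en.NM; ++j) {
    en.mpos[j] = ((mols(j, 0) % L + L) % L) + L * ((mols(j, 1) % L + L) % L)
               + L * L * ((mols(j, 2) % L + L) % L);
    en.msp[j] = mspecies[j];
  }
  en.build_tables();
  en.ub.resize(3 * en.NB); en.um.resize(3 * en.NM);
  for (int i = 0; i < en.NB; ++i) {
    en.ub[3 * i] = beads(i, 0); en.ub[3 * i + 1] = beads(i, 1); en.ub[3 * i + 2] = beads(i, 2);
  }
  for (int j = 0; j < en.NM; ++j) {
    en.um[3 * j] = mols(j, 0); en.um[3 * j + 1] = mols(j, 1); en.um[3 * j + 2] = mols(j, 2);
  }
  en.ub0 = en.ub; en.um0 = en.um;
  en.E0 = en.E = en.total_energy(nullptr, nullptr, nullptr, nullptr);
  en.validate();
  return en;
}

// [[Rcpp::export]]
List cpp_total_energy(IntegerMatrix beads, IntegerVector btype, IntegerVector bpoly,
                      IntegerVector bblock, IntegerMatrix mols, IntegerVector mspecies,
                      int L, NumericMatrix affinity, NumericVector ehomo,
                      int valency, bool cap_total) {
  Engine en = make_engine(beads, btype, bpoly, bblock, mols, mspecies, L,
                          affinity, ehomo, valency, cap_total);
  double ehet = 0.0, ehm = 0.0;
  std::vector<int> hb(en.NM, 0), mb(en.NM, 0);
  const double tot = en.total_energy(&ehet, &ehm, hb.data(), mb.data());
  return List::create(_["hetero_total"] = ehet, _["homo_total"] = ehm,
                      _["total"] = tot,
                      _["hetero_bonds"] = IntegerVector(hb.begin(), hb.end()),
                      _["homo_bonds"] = IntegerVector(mb.begin(), mb.end()));
}

// run `sweeps` MC sweeps; record observables every `record_every` sweeps.
// frame_every > 0 additionally stores coordinate frames.
// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix beads, IntegerVector btype, IntegerVector bpoly,
                IntegerVector bblock, IntegerMatrix mols, IntegerVector mspecies,
                int L, NumericMatrix affinity, NumericVector ehomo,
                int valency, bool cap_total,
                int sweeps, int record_every, int shell_radius,
                int frame_every, int validate_every) {
  Engine en = make_engine(beads, btype, bpoly, bblock, mols, mspecies, L,
                          affinity, ehomo, valency, cap_total);

  // block structure (global block ids are assumed consecutive, < 32)
  int nblk = 0;
  for (int i = 0; i < en.NB; ++i) if (en.bblock[i] + 1 > nblk) nblk = en.bblock[i] + 1;
  if (nblk > 31) stop("more than 31 polymer blocks are not supported");
  std::vector<int> block_type(nblk, -1), block_poly(nblk, -1);
  for (int i = 0; i < en.NB; ++i) {
    block_type[en.bblock[i]] = en.btype[i];
    block_poly[en.bblock[i]] = en.bpoly[i];
  }
  std::vector<int> gamma_of(en.NP, -1);
  for (int b = 0; b < nblk; ++b)
    if (block_type[b] == 2) gamma_of[block_poly[b]] = b;
  std::vector<int> alpha_blocks, beta_blocks;
  for (int b = 0; b < nblk; ++b) {
    if (block_type[b] == 0) alpha_blocks.push_back(b);
    if (block_type[b] == 1) beta_blocks.push_back(b);
  }

  const int nrec = (record_every > 0) ? sweeps / record_every : 0;
  const int ncol = 13;
  NumericMatrix series(nrec, ncol);
  std::vector<int> bc(nblk), bb(nblk);
  List frames;

  int irec = 0;
  for (int sw = 1; sw <= sweeps; ++sw) {
    en.sweep();
    if (validate_every > 0 && sw % validate_every == 0) en.validate();
    if (record_every > 0 && sw % record_every == 0) {
      en.contacts(bc, bb, block_type, block_poly, gamma_of);
      double pa = 0.0, pb = 0.0;
      for (size_t t = 0; t < alpha_blocks.size(); ++t) pa += bc[alpha_blocks[t]];
      for (size_t t = 0; t < beta_blocks.size(); ++t) pb += bc[beta_blocks[t]];
      pa = alpha_blocks.empty() ? NA_REAL : pa / alpha_blocks.size();
      pb = beta_blocks.empty() ? NA_REAL : pb / beta_blocks.size();
      const double rho1 = en.local_density(0, 0, shell_radius);
      const double rho2 = (en.NP > 1) ? en.local_density(1, 0, shell_radius) : NA_REAL;
      double S = NA_REAL;
      if (en.NP > 1)
        S = (rho1 + rho2 > 0.0) ? (rho1 - rho2) / (rho1 + rho2) : 0.0;
      const double clA = en.largest_cluster_fraction(0);
      const double clB = en.largest_cluster_fraction(1);
      // mean-squared displacements (lattice units^2)
      double msd_mol = NA_REAL;
      if (en.NM > 0) {
        double acc_ = 0.0;
        for (int j = 0; j < en.NM; ++j) {
          const double dx = en.um[3 * j] - en.um0[3 * j];
          const double dy = en.um[3 * j + 1] - en.um0[3 * j + 1];
          const double dz = en.um[3 * j + 2] - en.um0[3 * j + 2];
          acc_ += dx * dx + dy * dy + dz * dz;
        }
        msd_mol = acc_ / en.NM;
      }
      double msd_com1 = NA_REAL, msd_com2 = NA_REAL;
      for (int p = 0; p < std::min(en.NP, 2); ++p) {
        double cx = 0, cy = 0, cz = 0;
        for (int i = en.pstart[p]; i < en.pstart[p] + en.plen[p]; ++i) {
          cx += en.ub[3 * i] - en.ub0[3 * i];
          cy += en.ub[3 * i + 1] - en.ub0[3 * i + 1];
          cz += en.ub[3 * i + 2] - en.ub0[3 * i + 2];
        }
        cx /= en.plen[p]; cy /= en.plen[p]; cz /= en.plen[p];
        const double m = cx * cx + cy * cy + cz * cz;
        if (p == 0) msd_com1 = m; else msd_com2 = m;
      }
      series(irec, 0) = sw;
      series(irec, 1) = pa;
      series(irec, 2) = pb;
      series(irec, 3) = (ISNA(pa) || ISNA(pb)) ? NA_REAL : 0.5 * (pa + pb);
      series(irec, 4) = S;
      series(irec, 5) = clA;
      series(irec, 6) = clB;
      series(irec, 7) = rho1;
      series(irec, 8) = rho2;
      series(irec, 9) = en.E;
      series(irec, 10) = msd_mol;
      series(irec, 11) = msd_com1;
      series(irec, 12) = msd_com2;
      ++irec;
      if (frame_every > 0 && sw % frame_every == 0) {
        IntegerMatrix fb(en.NB, 3), fm(en.NM, 3);
        for (int i = 0; i < en.NB; ++i) {
          int x, y, z; en.coords(en.bpos[i], x, y, z);
          fb(i, 0) = x; fb(i, 1) = y; fb(i, 2) = z;
        }
        for (int j = 0; j < en.NM; ++j) {
          int x, y, z; en.coords(en.mpos[j], x, y, z);
          fm(j, 0) = x; fm(j, 1) = y; fm(j, 2) = z;
        }
        frames.push_back(List::create(_["sweep"] = sw, _["beads"] = fb, _["mols"] = fm));
      }
    }
  }
  en.validate();
  double ehet = 0.0, ehm = 0.0;
  const double efinal = en.total_energy(&ehet, &ehm, nullptr, nullptr);

  IntegerMatrix fb(en.NB, 3), fm(en.NM, 3);
  for (int i = 0; i < en.NB; ++i) {
    int x, y, z; en.coords(en.bpos[i], x, y, z);
    fb(i, 0) = x; fb(i, 1) = y; fb(i, 2) = z;
  }
  for (int j = 0; j < en.NM; ++j) {
    int x, y, z; en.coords(en.mpos[j], x, y, z);
    fm(j, 0) = x; fm(j, 1) = y; fm(j, 2) = z;
  }
  CharacterVector kinds = CharacterVector::create("molecule_step", "corner_flip",
                                                  "end_rotation", "crankshaft");
  NumericVector attempts(4), accepts(4), nulls(4);
  for (int k = 0; k < 4; ++k) {
    // reorder: molecule=0, corner=1, end=2, crank=3 -> report in kinds order
    int src = (k == 0) ? 0 : (k == 1) ? 1 : (k == 2) ? 2 : 3;
    attempts[k] = (double)en.att[src];
    accepts[k] = (double)en.acc[src];
    nulls[k] = (double)en.nul[src];
  }
  return List::create(
    _["series"] = series,
    _["beads"] = fb, _["mols"] = fm,
    _["energy_initial"] = en.E0,
    _["energy_running"] = en.E,
    _["energy_final"] = efinal,
    _["hetero_final"] = ehet, _["homo_final"] = ehm,
    _["move_kinds"] = kinds,
    _["attempts"] = attempts, _["accepts"] = accepts, _["nulls"] = nulls,
    _["frames"] = frames);
}

// Micro-system sampler for the exact-enumeration Boltzmann check: tallies
// canonical (translation-quotiented) microstate codes.  Requires a single
// short polymer and a single molecule on a small lattice.
// code = ((rel(bead2) * L^3) + rel(bead3)) * L^3 + rel(molecule),
// rel(.) computed with bead 1 at the origin.
// [[Rcpp::export]]
IntegerVector cpp_run_histogram(IntegerMatrix beads, IntegerVector btype,
                                IntegerVector bpoly, IntegerVector bblock,
                                IntegerMatrix mols, IntegerVector mspecies,
                                int L, NumericMatrix affinity, NumericVector ehomo,
                                int valency, bool cap_total,
                                double sweeps, int sample_every_moves) {
  Engine en = make_engine(beads, btype, bpoly, bblock, mols, mspecies, L,
                          affinity, ehomo, valency, cap_total);
  if (en.NB != 3 || en.NM != 1 || en.NP != 1)
    stop("histogram sampler supports exactly one 3-bead polymer and one molecule");
  const double ncodes_d = (double)en.L3 * en.L3 * en.L3;
  if (ncodes_d > 2e7) stop("lattice too large for microstate tally");
  const int L3 = en.L3;
  IntegerVector counts((int)ncodes_d);
  const long long nmoves = (long long)(sweeps * en.Nent);
  int since = 0;
  for (long long t = 0; t < nmoves; ++t) {
    en.attempt();
    if (++since == sample_every_moves) {
      since = 0;
      int x0, y0, z0, x, y, z;
      en.coords(en.bpos[0], x0, y0, z0);
      en.coords(en.bpos[1], x, y, z);
      const int r2 = en.sidx(x - x0, y - y0, z - z0);
      en.coords(en.bpos[2], x, y, z);
      const int r3 = en.sidx(x - x0, y - y0, z - z0);
      en.coords(en.mpos[0], x, y, z);
      const int rm = en.sidx(x - x0, y - y0, z - z0);
      ++counts[(r2 * L3 + r3) * L3 + rm];
    }
  }
  en.validate();
  return counts;
}

// [[Rcpp::export]]
List cpp_validate_state(IntegerMatrix beads, IntegerVector btype, IntegerVector bpoly,
                        IntegerVector bblock, IntegerMatrix mols, IntegerVector mspecies,
                        int L, NumericMatrix affinity, NumericVector ehomo,
                        int valency, bool cap_total) {
  Engine en = make_engine(beads, btype, bpoly, bblock, mols, mspecies, L,
                          affinity, ehomo, valency, cap_total);
  en.validate();
  return List::create(_["ok"] = true);
}

// single-state observables, shared with the R-level observables module
// [[Rcpp::export]]
List cpp_state_observables(IntegerMatrix beads, IntegerVector btype, IntegerVector bpoly,
                           IntegerVector bblock, IntegerMatrix mols, IntegerVector mspecies,
                           int L, NumericMatrix affinity, NumericVector ehomo,
                           int valency, bool cap_total, int shell_radius) {
  Engine en = make_engine(beads, btype, bpoly, bblock, mols, mspecies, L,
                          affinity, ehomo, valency, cap_total);
  int nblk = 0;
  for (int i = 0; i < en.NB; ++i) if (en.bblock[i] + 1 > nblk) nblk = en.bblock[i] + 1;
  std::vector<int> block_type(nblk, -1), block_poly(nblk, -1);
  for (int i = 0; i < en.NB; ++i) {
    block_type[en.bblock[i]] = en.btype[i];
    block_poly[en.bblock[i]] = en.bpoly[i];
  }
  std::vector<int> gamma_of(en.NP, -1);
  for (int b = 0; b < nblk; ++b)
    if (block_type[b] == 2) gamma_of[block_poly[b]] = b;
  std::vector<int> bc(nblk), bb(nblk);
  en.contacts(bc, bb, block_type, block_poly, gamma_of);
  NumericVector rho(en.NP);
  for (int p = 0; p < en.NP; ++p) rho[p] = en.local_density(p, 0, shell_radius);
  return List::create(
    _["block_contact"] = IntegerVector(bc.begin(), bc.end()),
    _["block_bridges"] = IntegerVector(bb.begin(), bb.end()),
    _["block_type"] = IntegerVector(block_type.begin(), block_type.end()),
    _["block_poly"] = IntegerVector(block_poly.begin(), block_poly.end()),
    _["rho_A"] = rho,
    _["cluster_A"] = en.largest_cluster_fraction(0),
    _["cluster_B"] = en.largest_cluster_fraction(1));
}
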