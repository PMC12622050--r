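#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// FNV-1a hash over the sequence plus one integer; drives deterministic
// tie-breaking in the lattice chain-growth surrogate.
static uint64_t fnv1a(const std::string& s, int extra) {
  uint64_t h = 1469598103934665603ULL;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  for (int b = 0; b < 4; ++b) {
    h ^= (uint64_t)((extra >> (8 * b)) & 0xff);
    h *= 1099511628211ULL;
  }
  return h;
}

static inline int64_t pack_key(int x, int y, int z) {
  return (((int64_t)(x + 1024)) << 22) | (((int64_t)(y + 1024)) << 11) |
         ((int64_t)(z + 1024));
}

struct Cand { int x, y, z, score, dir; };

// Deterministic greedy self-avoiding chain growth on a cubic lattice.
// Each step places the next residue on the free neighbour that creates the
// most new hydrophobic-hydrophobic contacts; ties are rotated by a hash of
// (sequence, position). Depth-first backtracking guarantees termination.
// Returns integer lattice coordinates (unit spacing), one row per residue.
// [[Rcpp::export]]
IntegerMatrix cpp_lattice_fold(std::string seq, LogicalVector hydrophobic,
                               int max_expansions) {
  const int L = (int)seq.size();
  if ((int)hydrophobic.size() != L) stop("hydrophobic flags must match sequence length");
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  std::vector<int> X(L), Y(L), Z(L);
  std::unordered_map<int64_t, int> occ;  // position -> residue index
  std::vector<std::vector<Cand> > cands(L);
  std::vector<size_t> next_idx(L, 0);

  X[0] = 0; Y[0] = 0; Z[0] = 0;
  occ[pack_key(0, 0, 0)] = 0;
  int i = 1;
  long expansions = 0;

  while (i < L) {
    if (next_idx[i] == 0) {
      // build candidate list for position i
      std::vector<Cand> cs;
      for (int d = 0; d < 6; ++d) {
        const int nx = X[i - 1] + dx[d];
        const int ny = Y[i - 1] + dy[d];
        const int nz = Z[i - 1] + dz[d];
        if (occ.count(pack_key(nx, ny, nz))) continue;
        int score = 0;
        if (hydrophobic[i]) {
          for (int e = 0; e < 6; ++e) {
            auto it = occ.find(pack_key(nx + dx[e], ny + dy[e], nz + dz[e]));
            if (it != occ.end() && hydrophobic[it->second]) ++score;
          }
        }
        Cand c; c.x = nx; c.y = ny; c.z = nz; c.score = score; c.dir = d;
        cs.push_back(c);
      }
      std::stable_sort(cs.begin(), cs.end(), [](const Cand& a, const Cand& b) {
        return a.score > b.score;
      });
      // rotate each equal-score block by a hash of the prefix placed so
      // far plus the position, so a mutation only perturbs growth from
      // its own position onward
      const uint64_t h = fnv1a(seq.substr(0, i + 1), i);
      size_t s0 = 0;
      while (s0 < cs.size()) {
        size_t s1 = s0;
        while (s1 < cs.size() && cs[s1].score == cs[s0].score) ++s1;
        const size_t blk = s1 - s0;
        if (blk > 1) std::rotate(cs.begin() + s0, cs.begin() + s0 + (h % blk), cs.begin() + s1);
        s0 = s1;
      }
      cands[i] = cs;
    }
    if (next_idx[i] >= cands[i].size()) {
      // dead end: backtrack
      cands[i].clear();
      next_idx[i] = 0;
      --i;
      if (i < 1) stop("lattice chain growth failed from the origin");
      occ.erase(pack_key(X[i], Y[i], Z[i]));
      continue;
    }
    const Cand& c = cands[i][next_idx[i]++];
    if (++expansions > max_expansions) stop("lattice chain growth exceeded expansion budget");
    X[i] = c.x; Y[i] = c.y; Z[i] = c.z;
    occ[pack_key(c.x, c.y, c.z)] = i;
    ++i;
  }

  IntegerMatrix out(L, 3);
  for (int r = 0; r < L; ++r) { out(r, 0) = X[r]; out(r, 1) = Y[r]; out(r, 2) = Z[r]; }
  return out;
}

// Count residue-residue contacts: pairwise distance < cutoff with sequence
// separation >= minsep.
// [[Rcpp::export]]
int cpp_contact_count(NumericMatrix coords, double cutoff, int minsep) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minsep; j < n; ++j) {
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return count;
}

// Count hydrophobic-hydrophobic contacts under the same definition.
// [[Rcpp::export]]
int cpp_hh_contact_count(NumericMatrix coords, LogicalVector hydrophobic,
                         double cutoff, int minsep) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    if (!hydrophobic[i]) continue;
    for (int j = i + minsep; j < n; ++j) {
      if (!hydrophobic[j]) continue;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return count;
}

// Fold a sequence and return its contact density directly (contacts per
// residue at the given cutoff/separation), avoiding intermediate
// containers on the hot sampling path.
// [[Rcpp::export]]
double cpp_lattice_contact_density(std::string seq, LogicalVector hydrophobic,
                                   double cutoff, int minsep,
                                   int max_expansions) {
  IntegerMatrix lat = cpp_lattice_fold(seq, hydrophobic, max_expansions);
  const int n = lat.nrow();
  const double c2 = (cutoff / 3.8) * (cutoff / 3.8);
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + minsep; j < n; ++j) {
      const double dx = lat(i, 0) - lat(j, 0);
      const double dy = lat(i, 1) - lat(j, 1);
      const double dz = lat(i, 2) - lat(j, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return (double)count / (double)n;
}
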