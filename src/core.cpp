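// Compiled core for the bond-matrix enumeration machinery.
//
// A molecular system over n heavy atoms is a symmetric n x n integer matrix B
// with zero diagonal, entry caps B[i][j] <= min(b_i, b_j) and row sums bounded
// by the per-atom total bond order t_i (implicit hydrogens fill the slack).
// Everything here works on the row-major upper triangle of B.
//
// The depth-first generator assigns one upper-triangle entry at a time while
// tracking the remaining total-bond-order capacity of every atom, so each
// emitted matrix is valid by construction and each valid matrix is emitted
// exactly once, in lexicographically ascending order of its upper triangle.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <functional>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct PairList {
  int n;
  std::vector<std::pair<int, int> > pairs; // (i, j), i < j, row-major
  explicit PairList(int n_) : n(n_) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) pairs.push_back(std::make_pair(i, j));
  }
};

// all permutations of 0..n-1 preserving classid; identity excluded
std::vector<std::vector<int> > class_perms(const std::vector<int>& classid, int n) {
  std::vector<std::vector<int> > perms;
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  do {
    bool ok = true, ident = true;
    for (int i = 0; i < n; ++i) {
      if (classid[p[i]] != classid[i]) { ok = false; break; }
      if (p[i] != i) ident = false;
    }
    if (ok && !ident) perms.push_back(p);
  } while (std::next_permutation(p.begin(), p.end()));
  return perms;
}

} // namespace

// ---------------------------------------------------------------------------
// counting
// ---------------------------------------------------------------------------

// Count all valid matrices. With tally_rows = TRUE also returns, per value of
// the first upper-triangle entry, the number of completions (a resume log: the
// run can be partitioned by fixing that entry via `fix_first`).
// fix_first >= 0 pins the value of the first upper-triangle entry.
// [[Rcpp::export]]
List count_matrices_cpp(IntegerVector t, IntegerVector b, int fix_first = -1) {
  const int n = t.size();
  if (n <= 1) {
    return List::create(_["count"] = 1.0,
                        _["first_entry_tally"] = NumericVector(0));
  }
  PairList pl(n);
  std::vector<int> rem(t.begin(), t.end());
  std::vector<int> bb(b.begin(), b.end());
  long long count = 0;
  std::vector<long long> tally(bb[0] > bb[1] ? bb[1] + 1 : bb[0] + 1, 0);
  int first_val = 0;

  std::function<void(size_t)> dfs = [&](size_t k) {
    if (k == pl.pairs.size()) {
      ++count;
      ++tally[first_val];
      return;
    }
    const int i = pl.pairs[k].first, j = pl.pairs[k].second;
    int mx = std::min(std::min(bb[i], bb[j]), std::min(rem[i], rem[j]));
    int lo = 0;
    if (k == 0 && fix_first >= 0) {
      if (fix_first > mx) return;
      lo = mx = fix_first;
    }
    for (int v = lo; v <= mx; ++v) {
      if (k == 0) first_val = v;
      rem[i] -= v; rem[j] -= v;
      dfs(k + 1);
      rem[i] += v; rem[j] += v;
    }
  };
  dfs(0);

  NumericVector tl(tally.size());
  for (size_t i = 0; i < tally.size(); ++i) tl[i] = static_cast<double>(tally[i]);
  return List::create(_["count"] = static_cast<double>(count),
                      _["first_entry_tally"] = tl);
}

// Count matrices fixed by the permutation g (0-based). Upper-triangle entries
// are tied along the orbits that g induces on atom pairs; a matrix fixed by g
// assigns one value per orbit. Used for Burnside orbit counting.
// [[Rcpp::export]]
double count_fixed_cpp(IntegerVector t, IntegerVector b, IntegerVector g) {
  const int n = t.size();
  if (n <= 1) return 1.0;
  std::vector<std::vector<std::pair<int, int> > > orbits;
  std::vector<std::vector<int> > seen(n, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (seen[i][j]) continue;
      std::vector<std::pair<int, int> > orb;
      int a = i, c = j;
      while (!seen[std::min(a, c)][std::max(a, c)]) {
        seen[std::min(a, c)][std::max(a, c)] = 1;
        orb.push_back(std::make_pair(std::min(a, c), std::max(a, c)));
        int a2 = g[a], c2 = g[c];
        a = a2; c = c2;
      }
      orbits.push_back(orb);
    }
  std::vector<int> rem(t.begin(), t.end());
  long long count = 0;
  std::function<void(size_t)> dfs = [&](size_t k) {
    if (k == orbits.size()) { ++count; return; }
    const std::vector<std::pair<int, int> >& orb = orbits[k];
    std::vector<int> inc(n, 0);
    int mx = 1 << 29;
    for (size_t e = 0; e < orb.size(); ++e) {
      ++inc[orb[e].first];
      ++inc[orb[e].second];
      mx = std::min(mx, std::min(b[orb[e].first], b[orb[e].second]));
    }
    for (int i = 0; i < n; ++i)
      if (inc[i]) mx = std::min(mx, rem[i] / inc[i]);
    for (int v = 0; v <= mx; ++v) {
      for (int i = 0; i < n; ++i) rem[i] -= v * inc[i];
      dfs(k + 1);
      for (int i = 0; i < n; ++i) rem[i] += v * inc[i];
    }
  };
  dfs(0);
  return static_cast<double>(count);
}

// Count matrices that are lexicographically minimal within their orbit under
// the class-permutation group, i.e. the number of orbits, by direct
// enumeration. Cross-checks the Burnside count on the same group.
// [[Rcpp::export]]
double count_orbits_direct_cpp(IntegerVector t, IntegerVector b, IntegerVector classid) {
  const int n = t.size();
  if (n <= 1) return 1.0;
  PairList pl(n);
  std::vector<int> cid(classid.begin(), classid.end());
  std::vector<std::vector<int> > perms = class_perms(cid, n);
  std::vector<int> rem(t.begin(), t.end());
  std::vector<std::vector<int> > B(n, std::vector<int>(n, 0));
  long long count = 0;

  std::function<bool()> canonical = [&]() {
    for (size_t p = 0; p < perms.size(); ++p) {
      const std::vector<int>& g = perms[p];
      for (size_t k = 0; k < pl.pairs.size(); ++k) {
        const int a = B[pl.pairs[k].first][pl.pairs[k].second];
        const int c = B[g[pl.pairs[k].first]][g[pl.pairs[k].second]];
        if (c < a) return false;
        if (c > a) break;
      }
    }
    return true;
  };
  std::function<void(size_t)> dfs = [&](size_t k) {
    if (k == pl.pairs.size()) {
      if (canonical()) ++count;
      return;
    }
    const int i = pl.pairs[k].first, j = pl.pairs[k].second;
    const int mx = std::min(std::min(b[i], b[j]), std::min(rem[i], rem[j]));
    for (int v = 0; v <= mx; ++v) {
      B[i][j] = B[j][i] = v; rem[i] -= v; rem[j] -= v;
      dfs(k + 1);
      rem[i] += v; rem[j] += v;
    }
    B[i][j] = B[j][i] = 0;
  };
  dfs(0);
  return static_cast<double>(count);
}

// ---------------------------------------------------------------------------
// materialized enumeration (small systems)
// ---------------------------------------------------------------------------

// Emit every valid matrix as a row of upper-triangle entries, lexicographically
// ascending. Guarded by max_n: exceeding it aborts with an error so callers
// cannot accidentally materialize a combinatorial explosion.
// [[Rcpp::export]]
IntegerMatrix enumerate_matrices_cpp(IntegerVector t, IntegerVector b, double max_n) {
  const int n = t.size();
  const int np = n >= 2 ? n * (n - 1) / 2 : 0;
  PairList pl(n);
  std::vector<int> rem(t.begin(), t.end());
  std::vector<int> cur(np, 0);
  std::vector<std::vector<int> > rows;

  std::function<void(size_t)> dfs = [&](size_t k) {
    if (k == pl.pairs.size()) {
      if (static_cast<double>(rows.size()) >= max_n)
        stop("enumeration exceeds max_n = %g matrices; use count mode", max_n);
      rows.push_back(cur);
      return;
    }
    const int i = pl.pairs[k].first, j = pl.pairs[k].second;
    const int mx = std::min(std::min(b[i], b[j]), std::min(rem[i], rem[j]));
    for (int v = 0; v <= mx; ++v) {
      cur[k] = v; rem[i] -= v; rem[j] -= v;
      dfs(k + 1);
      rem[i] += v; rem[j] += v;
    }
    cur[k] = 0;
  };
  if (n >= 2) dfs(0); else rows.push_back(cur);

  IntegerMatrix out(static_cast<int>(rows.size()), np);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int c = 0; c < np; ++c) out(static_cast<int>(r), c) = rows[r][c];
  return out;
}

// ---------------------------------------------------------------------------
// unique-product census
// ---------------------------------------------------------------------------

// Enumerate the connected, valence-legal graphs over one atom multiset,
// keeping one representative per isomorphism class: the representative is the
// lexicographically minimal matrix under the class-permutation group.
// Atoms of the same class must be contiguous. A cheap necessary condition
// (non-decreasing first-row entries within a class) prunes the search; the
// exact minimality test runs at the leaves.
// [[Rcpp::export]]
IntegerMatrix unique_connected_cpp(IntegerVector t, IntegerVector b, IntegerVector classid) {
  const int n = t.size();
  PairList pl(n);
  std::vector<int> cid(classid.begin(), classid.end());
  std::vector<std::vector<int> > perms = class_perms(cid, n);
  std::vector<int> rem(t.begin(), t.end());
  std::vector<std::vector<int> > B(n, std::vector<int>(n, 0));
  std::vector<std::array<int8_t, 28> > out;

  std::function<bool()> connected = [&]() {
    int seen = 1;
    unsigned mask = 1;
    int stack[8];
    int sp = 0;
    stack[sp++] = 0;
    while (sp) {
      const int u = stack[--sp];
      for (int v = 0; v < n; ++v)
        if (B[u][v] && !((mask >> v) & 1)) {
          mask |= 1u << v;
          ++seen;
          stack[sp++] = v;
        }
    }
    return seen == n;
  };
  std::function<bool()> canonical = [&]() {
    for (size_t p = 0; p < perms.size(); ++p) {
      const std::vector<int>& g = perms[p];
      for (size_t k = 0; k < pl.pairs.size(); ++k) {
        const int a = B[pl.pairs[k].first][pl.pairs[k].second];
        const int c = B[g[pl.pairs[k].first]][g[pl.pairs[k].second]];
        if (c < a) return false;
        if (c > a) break;
      }
    }
    return true;
  };
  std::function<void(size_t)> dfs = [&](size_t k) {
    if (k == pl.pairs.size()) {
      if (!connected() || !canonical()) return;
      std::array<int8_t, 28> key;
      key.fill(0);
      for (size_t e = 0; e < pl.pairs.size(); ++e)
        key[e] = static_cast<int8_t>(B[pl.pairs[e].first][pl.pairs[e].second]);
      out.push_back(key);
      return;
    }
    const int i = pl.pairs[k].first, j = pl.pairs[k].second;
    const int mx = std::min(std::min(b[i], b[j]), std::min(rem[i], rem[j]));
    int lo = 0;
    if (i == 0 && j > 1 && cid[j] == cid[j - 1]) lo = B[0][j - 1];
    for (int v = lo; v <= mx; ++v) {
      B[i][j] = B[j][i] = v; rem[i] -= v; rem[j] -= v;
      dfs(k + 1);
      rem[i] += v; rem[j] += v;
    }
    B[i][j] = B[j][i] = 0;
  };
  if (n > 8) stop("census enumeration supports at most 8 atoms");
  if (n >= 2) dfs(0);

  const int np = n >= 2 ? n * (n - 1) / 2 : 0;
  IntegerMatrix M(static_cast<int>(out.size()), np);
  for (size_t r = 0; r < out.size(); ++r)
    for (int c = 0; c < np; ++c) M(static_cast<int>(r), c) = out[r][c];
  if (n == 1) return IntegerMatrix(1, 0);
  return M;
}

// ---------------------------------------------------------------------------
// minimal bond edit distance of a product against the template set
// ---------------------------------------------------------------------------

// A product is a connected component with nc carbons, nn nitrogens and no
// oxygens (product atoms ordered C..C N O..O). It is placed injectively onto
// the matching element slots of each 8-atom template (slots 0-4 carbon, 5
// nitrogen, 6-7 oxygen) and the bond edits are counted:
//   * placed-placed pairs contribute |P - SM|,
//   * bonds between a placed and an unplaced template atom are broken,
//   * with residual = "template" the unplaced atoms keep their mutual template
//     bonds (the true minimum over all systems containing the product);
//     with residual = "fragmented" those bonds are also counted as broken
//     (the product is referenced to the product-plus-bare-atoms system).
// The reported distance is the minimum over templates and placements.
// [[Rcpp::export]]
IntegerVector min_edit_cpp(IntegerMatrix tri, IntegerVector elemcounts, List templates,
                           bool fragmented_residual) {
  const int nc = elemcounts[0], nn = elemcounts[1], no = elemcounts[2];
  const int k = nc + nn + no;
  const int m = tri.nrow();
  if (k > 8) stop("products larger than the 8-atom template are not supported");

  std::vector<std::array<std::array<int, 8>, 8> > sms;
  std::vector<int> smtot;
  for (int s = 0; s < templates.size(); ++s) {
    IntegerMatrix S = templates[s];
    if (S.nrow() != 8 || S.ncol() != 8) stop("templates must be 8x8");
    std::array<std::array<int, 8>, 8> sm;
    int tot = 0;
    for (int i = 0; i < 8; ++i)
      for (int j = 0; j < 8; ++j) {
        sm[i][j] = S(i, j);
        if (j > i) tot += S(i, j);
      }
    sms.push_back(sm);
    smtot.push_back(tot);
  }

  // element-preserving injective placements, deduplicated
  std::vector<std::array<int, 8> > placements;
  {
    std::vector<int> cperm;
    for (int i = 0; i < 5; ++i) cperm.push_back(i);
    do {
      std::vector<int> operm;
      operm.push_back(6); operm.push_back(7);
      do {
        std::array<int, 8> ph;
        ph.fill(-1);
        int idx = 0;
        for (int a = 0; a < nc; ++a) ph[idx++] = cperm[a];
        if (nn) ph[idx++] = 5;
        for (int a = 0; a < no; ++a) ph[idx++] = operm[a];
        placements.push_back(ph);
        if (no < 2) break;
      } while (std::next_permutation(operm.begin(), operm.end()));
    } while (std::next_permutation(cperm.begin(), cperm.end()));
    std::sort(placements.begin(), placements.end());
    placements.erase(std::unique(placements.begin(), placements.end()),
                     placements.end());
  }

  IntegerVector res(m);
  int P[8][8];
  for (int r = 0; r < m; ++r) {
    int c2 = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j) { P[i][j] = P[j][i] = tri(r, c2++); }
    int best = 1 << 29;
    for (size_t s = 0; s < sms.size(); ++s) {
      const std::array<std::array<int, 8>, 8>& sm = sms[s];
      for (size_t pi = 0; pi < placements.size(); ++pi) {
        const std::array<int, 8>& ph = placements[pi];
        unsigned placedmask = 0;
        for (int i = 0; i < k; ++i) placedmask |= 1u << ph[i];
        int cost = 0;
        int smplaced = 0;
        for (int i = 0; i < k && cost < best; ++i) {
          for (int j = i + 1; j < k; ++j) {
            cost += std::abs(P[i][j] - sm[ph[i]][ph[j]]);
            smplaced += sm[ph[i]][ph[j]];
          }
          for (int sl = 0; sl < 8; ++sl)
            if (!((placedmask >> sl) & 1)) cost += sm[ph[i]][sl];
        }
        if (fragmented_residual) {
          // smtot - smplaced - (placed,unplaced bonds already charged above)
          int cross = 0;
          for (int i = 0; i < k; ++i)
            for (int sl = 0; sl < 8; ++sl)
              if (!((placedmask >> sl) & 1)) cross += sm[ph[i]][sl];
          cost += smtot[s] - smplaced - cross;
        }
        if (cost < best) best = cost;
      }
    }
    res[r] = best;
  }
  return res;
}

// ---------------------------------------------------------------------------
// SMILES writer
// ---------------------------------------------------------------------------

// Kekulized SMILES for a bond matrix: spanning-tree traversal with numbered
// ring closures, '=' and '#' bond symbols, '.'-separated fragments. Implicit
// hydrogens are left to the reader's default valence model, which matches the
// t caps used here for C, N and O.
std::string write_smiles_graph(const std::vector<std::vector<int> >& B,
                               const std::vector<std::string>& sym) {
  const int n = static_cast<int>(sym.size());
  std::vector<bool> vis(n, false);
  std::vector<std::vector<int> > ring(n), ringbond(n);
  {
    // classify edges: BFS tree edges vs ring-closure edges
    std::vector<bool> seen(n, false);
    std::vector<std::vector<bool> > treeedge(n, std::vector<bool>(n, false));
    int digit = 1;
    for (int s0 = 0; s0 < n; ++s0) {
      if (seen[s0]) continue;
      std::vector<int> st(1, s0);
      seen[s0] = true;
      while (!st.empty()) {
        const int u = st.back();
        st.pop_back();
        for (int v = 0; v < n; ++v)
          if (B[u][v] && !seen[v]) {
            seen[v] = true;
            treeedge[u][v] = treeedge[v][u] = true;
            st.push_back(v);
          }
      }
    }
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v)
        if (B[u][v] && !treeedge[u][v]) {
          ring[u].push_back(digit);  ringbond[u].push_back(B[u][v]);
          ring[v].push_back(digit);  ringbond[v].push_back(B[u][v]);
          ++digit;
        }
  }
  std::string s;
  std::function<void(int, int)> wr = [&](int u, int parent) {
    vis[u] = true;
    const std::string& el = sym[u];
    const bool organic = (el == "B" || el == "C" || el == "N" || el == "O" ||
                          el == "P" || el == "S" || el == "F" || el == "Cl" ||
                          el == "Br" || el == "I");
    if (organic) s += el; else { s += "["; s += el; s += "]"; }
    for (size_t r = 0; r < ring[u].size(); ++r) {
      if (ringbond[u][r] == 2) s += "=";
      else if (ringbond[u][r] == 3) s += "#";
      const int d = ring[u][r];
      if (d >= 10) { s += "%"; s += std::to_string(d); }
      else s += std::to_string(d);
    }
    std::vector<int> kids;
    for (int v = 0; v < n; ++v) {
      if (!B[u][v] || v == parent || vis[v]) continue;
      bool isclosure = false;
      for (size_t a = 0; a < ring[u].size() && !isclosure; ++a)
        for (size_t b2 = 0; b2 < ring[v].size(); ++b2)
          if (ring[u][a] == ring[v][b2]) { isclosure = true; break; }
      if (!isclosure) kids.push_back(v);
    }
    for (size_t c = 0; c < kids.size(); ++c) {
      const int v = kids[c];
      if (vis[v]) continue;
      bool more = false;
      for (size_t c3 = c + 1; c3 < kids.size(); ++c3)
        if (!vis[kids[c3]]) more = true;
      if (more) s += "(";
      if (B[u][v] == 2) s += "=";
      else if (B[u][v] == 3) s += "#";
      wr(v, u);
      if (more) s += ")";
    }
  };
  for (int s0 = 0; s0 < n; ++s0) {
    if (vis[s0]) continue;
    if (!s.empty()) s += ".";
    wr(s0, -1);
  }
  return s;
}

// [[Rcpp::export]]
CharacterVector tri_to_smiles_cpp(IntegerMatrix tri, CharacterVector sym) {
  const int k = sym.size();
  const int m = tri.nrow();
  std::vector<std::string> symbols(k);
  for (int i = 0; i < k; ++i) symbols[i] = as<std::string>(sym[i]);
  CharacterVector out(m);
  for (int r = 0; r < m; ++r) {
    std::vector<std::vector<int> > B(k, std::vector<int>(k, 0));
    int c2 = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j) { B[i][j] = B[j][i] = tri(r, c2++); }
    out[r] = write_smiles_graph(B, symbols);
  }
  return out;
}

// Fragment products out of full systems: keep connected components with at
// least min_atoms heavy atoms, return their dot-joined SMILES, kept-atom count
// and the cyclomatic ring count of the kept part.
// [[Rcpp::export]]
List system_products_cpp(IntegerMatrix tri, CharacterVector sym, int min_atoms) {
  const int nAll = sym.size();
  const int m = tri.nrow();
  std::vector<std::string> symbols(nAll);
  for (int i = 0; i < nAll; ++i) symbols[i] = as<std::string>(sym[i]);
  CharacterVector smi(m);
  IntegerVector natoms(m), rings(m);
  for (int r = 0; r < m; ++r) {
    std::vector<std::vector<int> > B(nAll, std::vector<int>(nAll, 0));
    int c2 = 0;
    for (int i = 0; i < nAll; ++i)
      for (int j = i + 1; j < nAll; ++j) { B[i][j] = B[j][i] = tri(r, c2++); }
    std::vector<int> comp(nAll, -1);
    int nc = 0;
    for (int s0 = 0; s0 < nAll; ++s0) {
      if (comp[s0] >= 0) continue;
      std::vector<int> st(1, s0);
      comp[s0] = nc;
      while (!st.empty()) {
        const int u = st.back();
        st.pop_back();
        for (int v = 0; v < nAll; ++v)
          if (B[u][v] && comp[v] < 0) { comp[v] = nc; st.push_back(v); }
      }
      ++nc;
    }
    std::vector<int> csize(nc, 0);
    for (int i = 0; i < nAll; ++i) ++csize[comp[i]];
    std::vector<int> keep;
    for (int i = 0; i < nAll; ++i)
      if (csize[comp[i]] >= min_atoms) keep.push_back(i);
    if (keep.empty()) {
      smi[r] = NA_STRING;
      natoms[r] = 0;
      rings[r] = 0;
      continue;
    }
    int E = 0, C = 0;
    std::vector<bool> compseen(nc, false);
    for (size_t a = 0; a < keep.size(); ++a) {
      if (!compseen[comp[keep[a]]]) { compseen[comp[keep[a]]] = true; ++C; }
      for (size_t b2 = a + 1; b2 < keep.size(); ++b2)
        if (B[keep[a]][keep[b2]]) ++E;
    }
    rings[r] = E - static_cast<int>(keep.size()) + C;
    natoms[r] = static_cast<int>(keep.size());
    std::vector<std::vector<int> > A(keep.size(), std::vector<int>(keep.size(), 0));
    std::vector<std::string> s2(keep.size());
    for (size_t a = 0; a < keep.size(); ++a) {
      s2[a] = symbols[keep[a]];
      for (size_t b2 = 0; b2 < keep.size(); ++b2) A[a][b2] = B[keep[a]][keep[b2]];
    }
    smi[r] = write_smiles_graph(A, s2);
  }
  return List::create(_["smiles"] = smi, _["natoms"] = natoms, _["rings"] = rings);
}
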