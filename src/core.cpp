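// Alignment and depth kernels: k-mer seed index, banded local extension
// (soft-clipping semantics), CIGAR depth accumulation, banded Smith-Waterman
// for pairwise gap-sequence similarity, and banded affine profile-profile
// progressive MSA with majority-rule consensus.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <array>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp_base(c);
  return r;
}

// FNV-1a; used only for deterministic multi-mapper tie spreading
static uint64_t fnv1a(const std::string& s) {
  uint64_t h = 1469598103934665603ULL;
  for (unsigned char c : s) { h ^= c; h *= 1099511628211ULL; }
  return h;
}

// ---------------------------------------------------------------------------
// Seed index: sorted (kmer-hash, contig<<40 | pos) pairs, binary search lookup
// ---------------------------------------------------------------------------

struct SeedIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<std::pair<uint64_t, uint64_t>> entries; // (hash, loc)
  size_t n_skipped; // k-mers containing N
};

// 2-bit rolling encoding; returns false if any base is N
static bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t h = 0;
  for (int i = 0; i < k; i++) {
    int c = base_code(s[i]);
    if (c > 3) return false;
    h = (h << 2) | (uint64_t)c;
  }
  out = h;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->n_skipped = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int ci = 0; ci < seqs.size(); ci++) {
    std::string s = as<std::string>(seqs[ci]);
    idx->names.push_back(as<std::string>(names[ci]));
    idx->seqs.push_back(s);
    int n = (int)s.size();
    if (n < k) continue;
    uint64_t h = 0;
    int valid = 0; // length of current N-free run ending here
    for (int i = 0; i < n; i++) {
      int c = base_code(s[i]);
      if (c > 3) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      valid++;
      if (valid >= k) {
        int pos = i - k + 1;
        idx->entries.emplace_back(h, ((uint64_t)ci << 40) | (uint64_t)pos);
      }
    }
    // count skipped N-containing k-mers for diagnostics
    for (int i = 0; i + k <= n; i++) {
      bool ok = true;
      for (int j = i; j < i + k; j++) if (base_code(s[j]) > 3) { ok = false; break; }
      if (!ok) idx->n_skipped++;
    }
  }
  std::sort(idx->entries.begin(), idx->entries.end());
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xp) {
  XPtr<SeedIndex> idx(xp);
  size_t distinct = 0;
  for (size_t i = 0; i < idx->entries.size(); i++)
    if (i == 0 || idx->entries[i].first != idx->entries[i - 1].first) distinct++;
  return List::create(_["k"] = idx->k,
                      _["n_positions"] = (double)idx->entries.size(),
                      _["n_distinct"] = (double)distinct,
                      _["n_skipped"] = (double)idx->n_skipped);
}

// [[Rcpp::export]]
IntegerMatrix cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<SeedIndex> idx(xp);
  uint64_t h;
  if ((int)kmer.size() != idx->k || !encode_kmer(kmer.c_str(), idx->k, h))
    return IntegerMatrix(0, 2);
  auto lo = std::lower_bound(idx->entries.begin(), idx->entries.end(),
                             std::make_pair(h, (uint64_t)0));
  auto hi = std::upper_bound(idx->entries.begin(), idx->entries.end(),
                             std::make_pair(h, ~(uint64_t)0));
  int n = (int)(hi - lo);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    uint64_t loc = (lo + i)->second;
    out(i, 0) = (int)(loc >> 40) + 1;            // 1-based contig index
    out(i, 1) = (int)(loc & 0xFFFFFFFFFFULL);    // 0-based position
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded local alignment (Smith-Waterman, linear gap penalty).
// N scores 0 against anything. Scores are caller-supplied: the read mapper
// uses stringent bwa-like costs (1/-4/-5) so alignments stop at insertion
// junctions; the gap-sequence similarity search uses permissive costs
// (1/-1/-2) so ~80%-identity pairs still chain. Traceback yields spans,
// match/edit counts and a CIGAR over the aligned portion.
// ---------------------------------------------------------------------------

struct AlnResult {
  int score = 0;
  int a_start = 0, a_end = 0; // query, 0-based half-open
  int b_start = 0, b_end = 0; // subject
  int matches = 0, edits = 0, cols = 0;
  std::string cigar; // aligned portion only (M/I/D); I = insertion in query
};

// band: j - i in [lo, hi] where i indexes A (query), j indexes B (subject)
static AlnResult banded_local(const std::string& A, const std::string& B,
                              int lo, int hi, int MATCH = 1, int MISM = -1,
                              int GAP = -2) {
  const int m = (int)A.size(), n = (int)B.size();
  const int W = hi - lo + 1;
  // dir: 0 stop, 1 diag, 2 up (gap in B, consume A), 3 left (gap in A)
  std::vector<uint8_t> dir((size_t)(m + 1) * W, 0);
  std::vector<int> prev(W, 0), cur(W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    std::fill(cur.begin(), cur.end(), 0);
    int jlo = std::max(1, i + lo), jhi = std::min(n, i + hi);
    for (int j = jlo; j <= jhi; j++) {
      int b = j - i - lo; // in [0, W)
      int ca = base_code(A[i - 1]), cb = base_code(B[j - 1]);
      int sub = (ca > 3 || cb > 3) ? 0 : (ca == cb ? MATCH : MISM);
      int bd = (j - 1) - (i - 1) - lo;
      int d = (bd >= 0 && bd < W) ? prev[bd] + sub : sub; // (0,0) edge ok: prev=0
      int bu = j - (i - 1) - lo;
      int u = (bu >= 0 && bu < W) ? prev[bu] + GAP : INT32_MIN / 2;
      int bl = (j - 1) - i - lo;
      int l = (bl >= 0 && bl < W) ? cur[bl] + GAP : INT32_MIN / 2;
      int v = d; uint8_t dd = 1;
      if (u > v) { v = u; dd = 2; }
      if (l > v) { v = l; dd = 3; }
      if (v <= 0) { v = 0; dd = 0; }
      cur[b] = v;
      dir[(size_t)i * W + b] = dd;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  AlnResult res;
  if (best <= 0) return res;
  res.score = best;
  // traceback
  int i = bi, j = bj;
  std::string ops;
  while (i > 0 && j > 0) {
    int b = j - i - lo;
    if (b < 0 || b >= W) break;
    uint8_t d = dir[(size_t)i * W + b];
    if (d == 0) break;
    if (d == 1) {
      int ca = base_code(A[i - 1]), cb = base_code(B[j - 1]);
      bool match = (ca == cb && ca <= 3);
      ops.push_back('M');
      if (match) res.matches++; else res.edits++;
      i--; j--;
    } else if (d == 2) { ops.push_back('I'); res.edits++; i--; }
    else { ops.push_back('D'); res.edits++; j--; }
  }
  res.a_start = i; res.a_end = bi;
  res.b_start = j; res.b_end = bj;
  res.cols = (int)ops.size();
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) q++;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  res.cigar = cig;
  return res;
}

// ---------------------------------------------------------------------------
// Read mapping: seed, cluster candidate diagonals, banded local extension
// ---------------------------------------------------------------------------

struct Candidate { int contig; int diag; int votes; };

// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, CharacterVector ids,
                   double max_edit_frac, double min_aligned_frac,
                   int max_seed_hits, int max_candidates) {
  XPtr<SeedIndex> idx(xp);
  const int k = idx->k;
  const int nr = reads.size();
  IntegerVector o_contig(nr, NA_INTEGER), o_rstart(nr, NA_INTEGER),
      o_rend(nr, NA_INTEGER), o_qstart(nr, NA_INTEGER), o_qend(nr, NA_INTEGER),
      o_edits(nr, NA_INTEGER), o_ties(nr, 0);
  CharacterVector o_cigar(nr, NA_STRING);
  LogicalVector o_mapped(nr, false);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  for (int r = 0; r < nr; r++) {
    std::string q = as<std::string>(reads[r]);
    int m = (int)q.size();
    if (m < k) continue;
    // collect seed diagonals
    std::vector<std::pair<int64_t, int>> diags; // (contig<<32 | diag+off, offset unused)
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < m; i++) {
      int c = base_code(q[i]);
      if (c > 3) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      valid++;
      if (valid < k) continue;
      int off = i - k + 1;
      auto lo = std::lower_bound(idx->entries.begin(), idx->entries.end(),
                                 std::make_pair(h, (uint64_t)0));
      auto hi = std::upper_bound(idx->entries.begin(), idx->entries.end(),
                                 std::make_pair(h, ~(uint64_t)0));
      if (hi - lo > max_seed_hits) continue; // over-repetitive seed
      for (auto it = lo; it != hi; ++it) {
        int ctg = (int)(it->second >> 40);
        int pos = (int)(it->second & 0xFFFFFFFFFFULL);
        int diag = pos - off;
        diags.emplace_back(((int64_t)ctg << 33) | (int64_t)(diag + (1 << 30)), 1);
      }
    }
    if (diags.empty()) continue;
    std::sort(diags.begin(), diags.end());
    // cluster nearby diagonals (within 8) into candidates with vote counts
    std::vector<Candidate> cands;
    for (size_t i = 0; i < diags.size();) {
      int ctg = (int)(diags[i].first >> 33);
      int diag = (int)(diags[i].first & ((1LL << 33) - 1)) - (1 << 30);
      size_t j = i + 1;
      int last = diag;
      int votes = 1;
      while (j < diags.size()) {
        int c2 = (int)(diags[j].first >> 33);
        int d2 = (int)(diags[j].first & ((1LL << 33) - 1)) - (1 << 30);
        if (c2 != ctg || d2 - last > 8) break;
        last = d2; votes++; j++;
      }
      cands.push_back({ctg, diag, votes});
      i = j;
    }
    // keep the most-voted candidates (stable: ties by contig, diag)
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Candidate& a, const Candidate& b) {
                       if (a.votes != b.votes) return a.votes > b.votes;
                       if (a.contig != b.contig) return a.contig < b.contig;
                       return a.diag < b.diag;
                     });
    if ((int)cands.size() > max_candidates) cands.resize(max_candidates);

    struct Placed {
      int score, edits, contig, rstart, rend, qstart, qend, clip5, clip3;
      std::string cigar;
    };
    std::vector<Placed> placed;
    int W = std::max(8, (int)std::ceil(0.1 * m)) + 4;
    for (const Candidate& cd : cands) {
      const std::string& ref = idx->seqs[cd.contig];
      int wstart = std::max(0, cd.diag - W);
      int wend = std::min((int)ref.size(), cd.diag + m + W);
      if (wend - wstart < k) continue;
      std::string win = ref.substr(wstart, wend - wstart);
      int off = cd.diag - wstart; // expected j - i
      AlnResult a = banded_local(q, win, off - W, off + W, 1, -4, -5);
      if (a.score <= 0) continue;
      int alen_q = a.a_end - a.a_start;
      if (alen_q < min_aligned_frac * m) continue;
      if (a.edits > max_edit_frac * alen_q) continue;
      Placed p;
      p.score = a.score; p.edits = a.edits; p.contig = cd.contig;
      p.rstart = wstart + a.b_start; p.rend = wstart + a.b_end;
      p.qstart = a.a_start; p.qend = a.a_end;
      p.clip5 = a.a_start; p.clip3 = m - a.a_end;
      p.cigar = a.cigar;
      placed.push_back(p);
    }
    if (placed.empty()) continue;
    // rank: max score, then min edits, then (contig, start) for stability
    std::stable_sort(placed.begin(), placed.end(),
                     [](const Placed& a, const Placed& b) {
                       if (a.score != b.score) return a.score > b.score;
                       if (a.edits != b.edits) return a.edits < b.edits;
                       if (a.contig != b.contig) return a.contig < b.contig;
                       return a.rstart < b.rstart;
                     });
    // ties on (score, edits): deterministic hash-of-id spreading
    int nt = 1;
    while (nt < (int)placed.size() && placed[nt].score == placed[0].score &&
           placed[nt].edits == placed[0].edits)
      nt++;
    int pick = 0;
    if (nt > 1) pick = (int)(fnv1a(as<std::string>(ids[r])) % (uint64_t)nt);
    const Placed& p = placed[pick];
    std::string cig;
    if (p.clip5 > 0) cig += std::to_string(p.clip5) + "S";
    cig += p.cigar;
    if (p.clip3 > 0) cig += std::to_string(p.clip3) + "S";
    o_contig[r] = p.contig + 1;
    o_rstart[r] = p.rstart; o_rend[r] = p.rend;
    o_qstart[r] = p.qstart; o_qend[r] = p.qend;
    o_edits[r] = p.edits;
    o_cigar[r] = cig;
    o_ties[r] = nt;
    o_mapped[r] = true;
  }
  return List::create(_["mapped"] = o_mapped, _["contig"] = o_contig,
                      _["ref_start"] = o_rstart, _["ref_end"] = o_rend,
                      _["query_start"] = o_qstart, _["query_end"] = o_qend,
                      _["edits"] = o_edits, _["cigar"] = o_cigar,
                      _["n_ties"] = o_ties);
}

// ---------------------------------------------------------------------------
// Depth accumulation from CIGAR strings (M/=/X increment; D/N consume only)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_depth_from_cigar(IntegerVector contig, IntegerVector pos0,
                          CharacterVector cigar, CharacterVector ids,
                          IntegerVector contig_lens) {
  int nc = contig_lens.size();
  List out(nc);
  std::vector<IntegerVector> depth;
  for (int c = 0; c < nc; c++) depth.push_back(IntegerVector(contig_lens[c], 0));
  int n = contig.size();
  for (int r = 0; r < n; r++) {
    if (contig[r] == NA_INTEGER) continue;
    int ci = contig[r] - 1;
    if (ci < 0 || ci >= nc) stop("record '%s': contig index out of range", as<std::string>(ids[r]).c_str());
    int p = pos0[r];
    std::string cg = as<std::string>(cigar[r]);
    int len = contig_lens[ci];
    size_t i = 0;
    while (i < cg.size()) {
      long num = 0;
      while (i < cg.size() && isdigit((unsigned char)cg[i])) { num = num * 10 + (cg[i] - '0'); i++; }
      if (i >= cg.size()) stop("record '%s': malformed CIGAR", as<std::string>(ids[r]).c_str());
      char op = cg[i++];
      switch (op) {
        case 'M': case '=': case 'X':
          if (p + num > len)
            stop("record '%s': CIGAR extends beyond contig end", as<std::string>(ids[r]).c_str());
          for (long j = 0; j < num; j++) depth[ci][p + j]++;
          p += num;
          break;
        case 'D': case 'N':
          if (p + num > len)
            stop("record '%s': CIGAR extends beyond contig end", as<std::string>(ids[r]).c_str());
          p += num;
          break;
        case 'I': case 'S': case 'H': case 'P':
          break;
        default:
          stop("record '%s': unknown CIGAR op '%c'", as<std::string>(ids[r]).c_str(), op);
      }
    }
  }
  for (int c = 0; c < nc; c++) out[c] = depth[c];
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise local alignment of gap sequences (seeded, banded, both strands)
// ---------------------------------------------------------------------------

// best shared-kmer diagonal between a and b; returns false if no shared kmer
static bool best_diagonal(const std::string& a, const std::string& b, int k,
                          int& best_diag, int& votes) {
  if ((int)a.size() < k || (int)b.size() < k) return false;
  std::vector<std::pair<uint64_t, int>> ak;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t h = 0; int valid = 0;
  for (int i = 0; i < (int)a.size(); i++) {
    int c = base_code(a[i]);
    if (c > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid >= k) ak.emplace_back(h, i - k + 1);
  }
  if (ak.empty()) return false;
  std::sort(ak.begin(), ak.end());
  std::vector<int> diags;
  h = 0; valid = 0;
  for (int j = 0; j < (int)b.size(); j++) {
    int c = base_code(b[j]);
    if (c > 3) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    int bo = j - k + 1;
    auto lo = std::lower_bound(ak.begin(), ak.end(), std::make_pair(h, INT32_MIN));
    for (auto it = lo; it != ak.end() && it->first == h; ++it) {
      diags.push_back(bo - it->second); // j - i
      if (diags.size() > 200000) break;
    }
  }
  if (diags.empty()) return false;
  std::sort(diags.begin(), diags.end());
  // densest window of width 16
  int bestv = 0, bestd = 0;
  for (size_t i = 0; i < diags.size(); i++) {
    size_t j = i;
    while (j < diags.size() && diags[j] - diags[i] <= 16) j++;
    if ((int)(j - i) > bestv) { bestv = (int)(j - i); bestd = diags[(i + j - 1) / 2]; }
  }
  best_diag = bestd; votes = bestv;
  return true;
}

static AlnResult seeded_local(const std::string& a, const std::string& b,
                              int seed_k, int band_cap) {
  AlnResult res;
  if (a == b) { // identity shortcut
    res.score = (int)a.size();
    res.a_start = 0; res.a_end = (int)a.size();
    res.b_start = 0; res.b_end = (int)b.size();
    res.matches = (int)a.size(); res.cols = (int)a.size();
    res.cigar = std::to_string(a.size()) + "M";
    return res;
  }
  int diag, votes;
  if (!best_diagonal(a, b, seed_k, diag, votes)) return res; // score 0 = no hit
  int mn = (int)std::min(a.size(), b.size());
  int W = std::min(band_cap, std::max(32, mn / 10 + 16));
  return banded_local(a, b, diag - W, diag + W);
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, int seed_k,
                     bool both_strands, int band_cap) {
  AlnResult f = seeded_local(a, b, seed_k, band_cap);
  int strand = 1;
  AlnResult best = f;
  if (both_strands) {
    AlnResult r = seeded_local(a, revcomp(b), seed_k, band_cap);
    if (r.score > f.score) { best = r; strand = -1; }
  }
  double identity = best.cols > 0 ? 100.0 * best.matches / best.cols : 0.0;
  return List::create(_["found"] = best.score > 0, _["score"] = best.score,
                      _["identity"] = identity, _["aln_len"] = best.cols,
                      _["matches"] = best.matches, _["edits"] = best.edits,
                      _["a_start"] = best.a_start, _["a_end"] = best.a_end,
                      _["b_start"] = best.b_start, _["b_end"] = best.b_end,
                      _["strand"] = strand);
}

// fraction of query k-mers found in subject (prefilter + guide distances)
// [[Rcpp::export]]
NumericMatrix cpp_kmer_share(CharacterVector seqs, int k) {
  int n = seqs.size();
  std::vector<std::vector<uint64_t>> km(n);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    uint64_t h = 0; int valid = 0;
    for (size_t j = 0; j < s.size(); j++) {
      int c = base_code(s[j]);
      if (c > 3) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid >= k) km[i].push_back(h);
    }
    std::sort(km[i].begin(), km[i].end());
    km[i].erase(std::unique(km[i].begin(), km[i].end()), km[i].end());
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; i++) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; j++) {
      size_t shared = 0, ai = 0, bi = 0;
      while (ai < km[i].size() && bi < km[j].size()) {
        if (km[i][ai] == km[j][bi]) { shared++; ai++; bi++; }
        else if (km[i][ai] < km[j][bi]) ai++;
        else bi++;
      }
      size_t mn = std::min(km[i].size(), km[j].size());
      double frac = mn > 0 ? (double)shared / (double)mn : 0.0;
      out(i, j) = frac; out(j, i) = frac;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Progressive MSA: banded affine profile-profile alignment along an
// hclust-style merge order. Scores: match +1, mismatch -1 (N neutral),
// gap open -2 (covers first gap column), gap extend -0.5; existing profile
// gaps score -0.5 against bases, 0 against gaps.
// ---------------------------------------------------------------------------

static inline int sym_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'N': return 4; default: return 5; // '-'
  }
}

static const double SYM_SCORE[6][6] = {
  //  A     C     G     T     N     -
  { 1.0, -1.0, -1.0, -1.0,  0.0, -0.5},
  {-1.0,  1.0, -1.0, -1.0,  0.0, -0.5},
  {-1.0, -1.0,  1.0, -1.0,  0.0, -0.5},
  {-1.0, -1.0, -1.0,  1.0,  0.0, -0.5},
  { 0.0,  0.0,  0.0,  0.0,  0.0, -0.5},
  {-0.5, -0.5, -0.5, -0.5, -0.5,  0.0},
};

typedef std::vector<std::array<double, 6>> Profile; // per-column frequencies

static Profile profile_of(const std::vector<std::string>& rows) {
  size_t L = rows[0].size();
  Profile p(L);
  for (size_t j = 0; j < L; j++) p[j].fill(0.0);
  for (const std::string& r : rows)
    for (size_t j = 0; j < L; j++) p[j][sym_code(r[j])] += 1.0;
  double nr = (double)rows.size();
  for (size_t j = 0; j < L; j++)
    for (int s = 0; s < 6; s++) p[j][s] /= nr;
  return p;
}

static inline double col_score(const std::array<double, 6>& x,
                               const std::array<double, 6>& y) {
  double s = 0.0;
  for (int a = 0; a < 6; a++) {
    if (x[a] == 0.0) continue;
    for (int b = 0; b < 6; b++) {
      if (y[b] == 0.0) continue;
      s += x[a] * y[b] * SYM_SCORE[a][b];
    }
  }
  return s;
}

// merge two alignments (vectors of equal-length rows) by banded global affine
static void profile_merge(std::vector<std::string>& A, std::vector<std::string>& B,
                          std::vector<std::string>& out_rows) {
  const double OPEN = -2.0, EXT = -0.5, NEG = -1e18;
  int LA = (int)A[0].size(), LB = (int)B[0].size();
  Profile pa = profile_of(A), pb = profile_of(B);
  int dl = LB - LA;
  int lo = std::min(0, dl) - 64, hi = std::max(0, dl) + 64;
  int W = hi - lo + 1;
  // states: 0 = M (col/col), 1 = X (col of A vs gap), 2 = Y (gap vs col of B)
  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // trace: per (i, band, state) the predecessor state, 2 bits each
  std::vector<uint8_t> tr((size_t)(LA + 1) * W * 3, 0);
  auto TR = [&](int i, int b, int s) -> uint8_t& {
    return tr[((size_t)i * W + b) * 3 + s];
  };
  // row i = 0
  {
    int b0 = 0 - 0 - lo;
    if (b0 >= 0 && b0 < W) Mp[b0] = 0.0;
    for (int j = 1; j <= LB; j++) {
      int b = j - 0 - lo;
      if (b < 0 || b >= W) continue;
      Yp[b] = OPEN + EXT * (j - 1);
      TR(0, b, 2) = 2;
    }
  }
  for (int i = 1; i <= LA; i++) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int jlo = std::max(0, i + lo), jhi = std::min(LB, i + hi);
    for (int j = jlo; j <= jhi; j++) {
      int b = j - i - lo;
      // X: consume A column i, gap in B (move i-1 -> i, same j): prev-row band b+1
      {
        int bu = j - (i - 1) - lo;
        if (bu >= 0 && bu < W) {
          double fromM = Mp[bu] + OPEN, fromX = Xp[bu] + EXT;
          if (fromM >= fromX) { Xc[b] = fromM; TR(i, b, 1) = 0; }
          else { Xc[b] = fromX; TR(i, b, 1) = 1; }
        }
      }
      // Y: gap in A, consume B column j (same i, j-1 -> j): same-row band b-1
      if (b - 1 >= 0) {
        double fromM = Mc[b - 1] + OPEN, fromY = Yc[b - 1] + OPEN; // placeholder
        fromY = Yc[b - 1] + EXT;
        if (fromM >= fromY) { Yc[b] = fromM; TR(i, b, 2) = 0; }
        else { Yc[b] = fromY; TR(i, b, 2) = 2; }
      }
      // M: consume both (i-1, j-1): prev-row band b
      if (j >= 1) {
        double sc = col_score(pa[i - 1], pb[j - 1]);
        int bd = (j - 1) - (i - 1) - lo;
        if (bd >= 0 && bd < W) {
          double m0 = Mp[bd], x0 = Xp[bd], y0 = Yp[bd];
          double v = m0; uint8_t st = 0;
          if (x0 > v) { v = x0; st = 1; }
          if (y0 > v) { v = y0; st = 2; }
          if (v > NEG / 2) { Mc[b] = v + sc; TR(i, b, 0) = st; }
        }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  int bend = LB - LA - lo;
  if (bend < 0 || bend >= W) stop("profile alignment band too narrow");
  double vM = Mp[bend], vX = Xp[bend], vY = Yp[bend];
  int state = 0; double v = vM;
  if (vX > v) { v = vX; state = 1; }
  if (vY > v) { v = vY; state = 2; }
  // traceback -> ops: 0 both, 1 A-col + gap, 2 gap + B-col
  std::vector<uint8_t> ops;
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    int b = j - i - lo;
    uint8_t prev = TR(i, b, state);
    if (state == 0) { ops.push_back(0); i--; j--; }
    else if (state == 1) { ops.push_back(1); i--; }
    else { ops.push_back(2); j--; }
    state = prev;
    if ((int)ops.size() > LA + LB + 4) stop("profile alignment traceback failed");
  }
  std::reverse(ops.begin(), ops.end());
  size_t L = ops.size();
  out_rows.clear();
  for (const std::string& r : A) {
    std::string s; s.reserve(L);
    size_t p = 0;
    for (uint8_t op : ops) s.push_back(op == 2 ? '-' : r[p++]);
    out_rows.push_back(s);
  }
  for (const std::string& r : B) {
    std::string s; s.reserve(L);
    size_t p = 0;
    for (uint8_t op : ops) s.push_back(op == 1 ? '-' : r[p++]);
    out_rows.push_back(s);
  }
}

// merge: (n-1) x 2 hclust-style matrix; negative = leaf index, positive = node
// [[Rcpp::export]]
CharacterVector cpp_progressive_msa(CharacterVector seqs, IntegerMatrix merge) {
  int n = seqs.size();
  if (n == 1) return CharacterVector::create(seqs[0]);
  std::vector<std::vector<std::string>> node_rows(n - 1);
  std::vector<std::vector<int>> node_idx(n - 1);
  for (int s = 0; s < n - 1; s++) {
    std::vector<std::string> left, right;
    std::vector<int> li, ri;
    for (int side = 0; side < 2; side++) {
      int v = merge(s, side);
      std::vector<std::string>& tgt = side == 0 ? left : right;
      std::vector<int>& ti = side == 0 ? li : ri;
      if (v < 0) { tgt.push_back(as<std::string>(seqs[-v - 1])); ti.push_back(-v - 1); }
      else { tgt = node_rows[v - 1]; ti = node_idx[v - 1]; }
    }
    std::vector<std::string> merged;
    profile_merge(left, right, merged);
    node_rows[s] = merged;
    node_idx[s] = li;
    node_idx[s].insert(node_idx[s].end(), ri.begin(), ri.end());
  }
  const std::vector<std::string>& rows = node_rows[n - 2];
  const std::vector<int>& ord = node_idx[n - 2];
  CharacterVector out(n);
  for (int i = 0; i < n; i++) out[ord[i]] = rows[i];
  return out;
}

// [[Rcpp::export]]
std::string cpp_majority_consensus(CharacterVector rows) {
  int n = rows.size();
  if (n == 0) return "";
  std::vector<std::string> rs(n);
  for (int i = 0; i < n; i++) rs[i] = as<std::string>(rows[i]);
  size_t L = rs[0].size();
  std::string out;
  out.reserve(L);
  for (size_t j = 0; j < L; j++) {
    int cnt[6] = {0, 0, 0, 0, 0, 0};
    for (int i = 0; i < n; i++) cnt[sym_code(rs[i][j])]++;
    if (2 * cnt[5] > n) continue; // strict gap majority: column omitted
    int best = -1, bc = 0;
    for (int b = 0; b < 4; b++) // ties resolved in A<C<G<T order
      if (cnt[b] > bc) { bc = cnt[b]; best = b; }
    if (best < 0) { out.push_back('N'); continue; } // only N (and minority gaps)
    out.push_back("ACGT"[best]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read mutation helpers (use R's RNG: reproducible under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_substitute(CharacterVector reads, double rate) {
  if (rate <= 0) return reads;
  RNGScope scope;
  int n = reads.size();
  CharacterVector out(n);
  const char* bases = "ACGT";
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(reads[i]);
    for (size_t j = 0; j < s.size(); j++) {
      if (unif_rand() < rate) {
        int c = base_code(s[j]);
        if (c > 3) continue;
        int nb = (int)(unif_rand() * 3.0);
        if (nb > 2) nb = 2;
        // pick uniformly among the three other bases
        int b = 0, seen = 0;
        for (b = 0; b < 4; b++) { if (b == c) continue; if (seen == nb) break; seen++; }
        s[j] = bases[b];
      }
    }
    out[i] = s;
  }
  return out;
}

// terminal deamination: C->T at 5' offsets, G->A at 3' offsets,
// probability p0 * decay^offset
// [[Rcpp::export]]
CharacterVector cpp_deaminate(CharacterVector reads, double p0, double decay) {
  if (p0 <= 0) return reads;
  RNGScope scope;
  int n = reads.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(reads[i]);
    int L = (int)s.size();
    double p = p0;
    for (int j = 0; j < L && p > 1e-9; j++, p *= decay)
      if (s[j] == 'C' && unif_rand() < p) s[j] = 'T';
    p = p0;
    for (int j = L - 1; j >= 0 && p > 1e-9; j--, p *= decay)
      if (s[j] == 'G' && unif_rand() < p) s[j] = 'A';
    out[i] = s;
  }
  return out;
}
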