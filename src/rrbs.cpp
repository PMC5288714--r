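// Core loops for the RRBS pipeline: bisulfite read simulation, trimming,
// bisulfite-aware ungapped alignment, and per-cytosine tallying.
// All randomness goes through R's RNG so set.seed() governs results.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static std::string conv_ct(std::string s) {
  for (auto& c : s) if (c == 'C') c = 'T';
  return s;
}

static std::string conv_ga(std::string s) {
  for (auto& c : s) if (c == 'G') c = 'A';
  return s;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(std::string(x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Read simulation
//
// For each fragment and each strand mode (OT = original top, OB = original
// bottom) draw Poisson(coverage) reads. OT reads copy the fragment 5' prefix;
// OB reads copy the reverse complement prefix (i.e. start from the fragment's
// 3' end). Each cytosine in the template is drawn methylated with its true
// level; unmethylated cytosines convert to T with probability `conversion`.
// Uniform substitution errors are applied afterwards.
// [[Rcpp::export(name = ".cpp_simulate_reads")]]
List cpp_simulate_reads(CharacterVector frag_seq,
                        List c_pos, List c_lev,
                        List g_pos, List g_lev,
                        double coverage, int read_length,
                        double conversion, double error_rate,
                        double lowq_frac, int lowq_len,
                        int base_q,
                        std::string adapter, bool adapter_readthrough) {
  int nf = frag_seq.size();
  std::vector<std::string> seqs, quals;
  std::vector<int> frag_out, mode_out, nmeth_out, nun_out, trunc_out;
  const char qchar = (char)(33 + base_q);
  const char qlow  = (char)(33 + 2);
  const char bases[4] = {'A', 'C', 'G', 'T'};

  for (int f = 0; f < nf; ++f) {
    std::string frag = std::string(frag_seq[f]);
    std::string bot  = revcomp(frag);
    int flen = (int)frag.size();
    IntegerVector cp = c_pos[f];
    NumericVector cl = c_lev[f];
    IntegerVector gp = g_pos[f];
    NumericVector gl = g_lev[f];
    for (int mode = 0; mode < 2; ++mode) {
      int n = (int)R::rpois(coverage);
      for (int r = 0; r < n; ++r) {
        int rl = std::min(read_length, flen);
        std::string tmpl = (mode == 0) ? frag.substr(0, rl) : bot.substr(0, rl);
        int nmeth = 0, nun = 0;
        if (mode == 0) {
          for (int j = 0; j < cp.size(); ++j) {
            int p = cp[j];
            if (p >= rl) continue;
            if (unif_rand() < cl[j]) { ++nmeth; }
            else { ++nun; if (unif_rand() < conversion) tmpl[p] = 'T'; }
          }
        } else {
          // cytosines of the bottom strand sit opposite genome G's;
          // in bottom-strand coordinates position = flen - 1 - g
          for (int j = 0; j < gp.size(); ++j) {
            int p = flen - 1 - gp[j];
            if (p < 0 || p >= rl) continue;
            if (unif_rand() < gl[j]) { ++nmeth; }
            else { ++nun; if (unif_rand() < conversion) tmpl[p] = 'T'; }
          }
        }
        bool truncated = rl < read_length;
        // read-through is planted only when >= 3 adapter bases fit: shorter
        // pieces sit below the resolution of the overlap-3 trimming rule
        int room = read_length - rl;
        if (truncated && adapter_readthrough && adapter.size() > 0 &&
            room >= 3) {
          tmpl += adapter.substr(0, std::min((int)adapter.size(), room));
        }
        for (size_t b = 0; b < tmpl.size(); ++b) {
          if (error_rate > 0 && unif_rand() < error_rate) {
            char cur = tmpl[b], nb;
            do { nb = bases[(int)(unif_rand() * 4) & 3]; } while (nb == cur);
            tmpl[b] = nb;
          }
        }
        std::string q(tmpl.size(), qchar);
        if (lowq_frac > 0 && unif_rand() < lowq_frac) {
          int tl = std::min(lowq_len, (int)q.size());
          for (int b = (int)q.size() - tl; b < (int)q.size(); ++b) q[b] = qlow;
        }
        seqs.push_back(tmpl);
        quals.push_back(q);
        frag_out.push_back(f + 1);
        mode_out.push_back(mode);
        nmeth_out.push_back(nmeth);
        nun_out.push_back(nun);
        trunc_out.push_back(truncated ? 1 : 0);
      }
    }
  }
  return List::create(_["sequence"] = wrap(seqs),
                      _["quality"] = wrap(quals),
                      _["fragment"] = wrap(frag_out),
                      _["strand_mode"] = wrap(mode_out),
                      _["n_meth_draws"] = wrap(nmeth_out),
                      _["n_unmeth_draws"] = wrap(nun_out),
                      _["truncated"] = wrap(trunc_out));
}

// ---------------------------------------------------------------------------
// Trimming: (1) adapter at the 3' end (full occurrence, else longest suffix
// overlap with the adapter prefix, min 3), (2) 3' bases below the quality
// floor, (3) leading/trailing N runs.
// [[Rcpp::export(name = ".cpp_trim_reads")]]
List cpp_trim_reads(CharacterVector seq, CharacterVector qual,
                    std::string adapter, int quality_floor, int phred_offset,
                    int min_len) {
  R_xlen_t n = seq.size();
  CharacterVector oseq(n), oqual(n);
  LogicalVector keep(n);
  int alen = (int)adapter.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = std::string(seq[i]);
    std::string q = std::string(qual[i]);
    if (s.size() != q.size())
      stop("sequence and quality lengths differ for read %d", (int)i + 1);
    int len = (int)s.size();
    if (alen >= 3) {
      size_t hit = s.find(adapter);
      if (hit != std::string::npos) {
        len = (int)hit;
      } else {
        int maxov = std::min(alen - 1, len);
        for (int ov = maxov; ov >= 3; --ov) {
          if (s.compare(len - ov, ov, adapter, 0, ov) == 0) { len -= ov; break; }
        }
      }
    }
    while (len > 0 && (int)q[len - 1] - phred_offset < quality_floor) --len;
    while (len > 0 && s[len - 1] == 'N') --len;
    int start = 0;
    while (start < len && s[start] == 'N') ++start;
    std::string ts = s.substr(start, len - start);
    std::string tq = q.substr(start, len - start);
    oseq[i] = ts;
    oqual[i] = tq;
    keep[i] = (int)ts.size() >= min_len;
  }
  return List::create(_["sequence"] = oseq, _["quality"] = oqual,
                      _["keep"] = keep);
}

// ---------------------------------------------------------------------------
// Alignment. Candidate placements are every ungapped offset of the read in
// every fragment, in both strand interpretations:
//   OT: read C->T vs fragment C->T
//   OB: revcomp(read) G->A vs fragment G->A
// Candidates are generated with a k-mer seed index (k = 10) using the
// pigeonhole principle over max_mm + 2 disjoint read parts: every placement
// with <= max_mm + 1 converted-space mismatches shares an exact seed, and
// counted (bisulfite-aware) mismatches are never below converted-space
// mismatches, so best and second-best counted mismatches -- and hence the
// uniqueness gap -- are decided exactly. Short reads fall back to a
// brute-force scan.

struct SeedIndex {
  // CSR layout over all 4^k kmer keys
  std::vector<uint32_t> offsets;   // size nkeys + 1
  std::vector<uint64_t> hits;      // (frag << 16) | pos
};

static const int KSEED = 10;
static const uint32_t NKEYS = 1u << (2 * KSEED);

static inline int base_code(char b) {
  switch (b) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

static bool encode_kmer(const std::string& s, int pos, uint32_t& key) {
  uint32_t k = 0;
  for (int i = 0; i < KSEED; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    k = (k << 2) | (uint32_t)c;
  }
  key = k;
  return true;
}

static void build_index(const std::vector<std::string>& seqs, SeedIndex& idx) {
  std::vector<uint32_t> counts(NKEYS + 1, 0);
  uint32_t key;
  for (size_t f = 0; f < seqs.size(); ++f) {
    const std::string& s = seqs[f];
    int lim = (int)s.size() - KSEED;
    for (int p = 0; p <= lim; ++p)
      if (encode_kmer(s, p, key)) ++counts[key + 1];
  }
  for (uint32_t i = 0; i < NKEYS; ++i) counts[i + 1] += counts[i];
  idx.offsets = counts;
  idx.hits.resize(counts[NKEYS]);
  std::vector<uint32_t> cur(counts.begin(), counts.end() - 1);
  for (size_t f = 0; f < seqs.size(); ++f) {
    const std::string& s = seqs[f];
    int lim = (int)s.size() - KSEED;
    for (int p = 0; p <= lim; ++p)
      if (encode_kmer(s, p, key))
        idx.hits[cur[key]++] = ((uint64_t)f << 16) | (uint64_t)p;
  }
}

// converted-space mismatches with early exit
static int conv_mismatches(const std::string& q, const std::string& ref,
                           int off, int cap) {
  int mm = 0, L = (int)q.size();
  for (int i = 0; i < L; ++i) {
    if (q[i] != ref[off + i] && ++mm > cap) return mm;
  }
  return mm;
}

// bisulfite-aware counted mismatches between original read (or its revcomp
// for OB) and the original fragment: ignore read T vs fragment C (OT) and
// read A vs fragment G (OB)
static int counted_mismatches(const std::string& r, const std::string& frag,
                              int off, int mode) {
  int mm = 0, L = (int)r.size();
  for (int i = 0; i < L; ++i) {
    char a = r[i], b = frag[off + i];
    if (a == b) continue;
    if (mode == 0 && a == 'T' && b == 'C') continue;
    if (mode == 1 && a == 'A' && b == 'G') continue;
    ++mm;
  }
  return mm;
}

struct Cand { int frag, off, mode; };

// [[Rcpp::export(name = ".cpp_align_reads")]]
List cpp_align_reads(CharacterVector reads, CharacterVector frag_seq,
                     int max_mm) {
  int nf = frag_seq.size();
  std::vector<std::string> orig(nf), fct(nf), fga(nf);
  for (int f = 0; f < nf; ++f) {
    orig[f] = std::string(frag_seq[f]);
    fct[f] = conv_ct(orig[f]);
    fga[f] = conv_ga(orig[f]);
  }
  SeedIndex ict, iga;
  build_index(fct, ict);
  build_index(fga, iga);

  int nparts = max_mm + 2;
  int cap = max_mm + 1;  // placements beyond this cannot affect the decision

  R_xlen_t nr = reads.size();
  IntegerVector status(nr), out_frag(nr), out_off(nr), out_mode(nr),
      out_mm(nr), out_mm2(nr);

  std::vector<Cand> cands;
  std::unordered_set<uint64_t> seen;

  for (R_xlen_t i = 0; i < nr; ++i) {
    std::string rd = std::string(reads[i]);
    int L = (int)rd.size();
    std::string qct = conv_ct(rd);
    std::string rr = revcomp(rd);
    std::string qga = conv_ga(rr);
    cands.clear();
    seen.clear();

    int part = L / nparts;
    bool seeded = part >= KSEED;
    if (seeded) {
      for (int mode = 0; mode < 2; ++mode) {
        const std::string& q = (mode == 0) ? qct : qga;
        const SeedIndex& idx = (mode == 0) ? ict : iga;
        for (int s = 0; s < nparts; ++s) {
          int sp = s * part;
          uint32_t key;
          if (!encode_kmer(q, sp, key)) continue;
          uint32_t lo = idx.offsets[key], hi = idx.offsets[key + 1];
          for (uint32_t h = lo; h < hi; ++h) {
            int f = (int)(idx.hits[h] >> 16);
            int p = (int)(idx.hits[h] & 0xFFFF);
            int off = p - sp;
            if (off < 0 || off + L > (int)orig[f].size()) continue;
            uint64_t kk = ((uint64_t)mode << 62) | ((uint64_t)f << 16) |
                          (uint64_t)off;
            if (!seen.insert(kk).second) continue;
            cands.push_back({f, off, mode});
          }
        }
      }
    } else {
      for (int mode = 0; mode < 2; ++mode)
        for (int f = 0; f < nf; ++f) {
          int lim = (int)orig[f].size() - L;
          for (int off = 0; off <= lim; ++off)
            cands.push_back({f, off, mode});
        }
    }

    int best = INT_MAX, second = INT_MAX;
    int bf = NA_INTEGER, boff = NA_INTEGER, bmode = NA_INTEGER;
    for (const Cand& c : cands) {
      const std::string& q = (c.mode == 0) ? qct : qga;
      const std::string& ref = (c.mode == 0) ? fct[c.frag] : fga[c.frag];
      if (conv_mismatches(q, ref, c.off, cap) > cap) continue;
      const std::string& r = (c.mode == 0) ? rd : rr;
      int mm = counted_mismatches(r, orig[c.frag], c.off, c.mode);
      if (mm < best) {
        second = best; best = mm;
        bf = c.frag + 1; boff = c.off; bmode = c.mode;
      } else if (mm < second) {
        second = mm;
      }
    }

    if (best > max_mm) {
      status[i] = 2;  // unmapped
      out_frag[i] = NA_INTEGER; out_off[i] = NA_INTEGER;
      out_mode[i] = NA_INTEGER; out_mm[i] = NA_INTEGER; out_mm2[i] = NA_INTEGER;
    } else {
      bool unique = (second == INT_MAX) || (second - best >= 2);
      status[i] = unique ? 0 : 1;
      out_frag[i] = bf; out_off[i] = boff; out_mode[i] = bmode;
      out_mm[i] = best;
      out_mm2[i] = (second == INT_MAX) ? NA_INTEGER : second;
    }
  }
  return List::create(_["status"] = status, _["fragment"] = out_frag,
                      _["offset"] = out_off, _["strand_mode"] = out_mode,
                      _["counted_mismatches"] = out_mm,
                      _["second_best_mismatches"] = out_mm2);
}

// ---------------------------------------------------------------------------
// Per-cytosine tallies from unique alignments. OT reads inform + strand C's
// (read base C = methylated, T = unmethylated); OB reads inform - strand C's
// at genome G positions (revcomp(read) base G = methylated, A = unmethylated).
// [[Rcpp::export(name = ".cpp_call_sites")]]
DataFrame cpp_call_sites(IntegerVector aln_frag, IntegerVector aln_off,
                         IntegerVector aln_mode, CharacterVector aln_seq,
                         List c_pos, List g_pos) {
  std::unordered_map<uint64_t, std::pair<int,int>> tally;
  R_xlen_t n = aln_frag.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int f = aln_frag[i] - 1;
    int off = aln_off[i];
    int mode = aln_mode[i];
    std::string s = std::string(aln_seq[i]);
    int L = (int)s.size();
    if (mode == 0) {
      IntegerVector cp = c_pos[f];
      for (int j = 0; j < cp.size(); ++j) {
        int p = cp[j];
        if (p < off || p >= off + L) continue;
        char b = s[p - off];
        if (b != 'C' && b != 'T') continue;
        uint64_t key = ((uint64_t)f << 21) | ((uint64_t)p << 1);
        auto& t = tally[key];
        if (b == 'C') ++t.first; else ++t.second;
      }
    } else {
      std::string rr = revcomp(s);
      IntegerVector gp = g_pos[f];
      for (int j = 0; j < gp.size(); ++j) {
        int p = gp[j];
        if (p < off || p >= off + L) continue;
        char b = rr[p - off];
        if (b != 'G' && b != 'A') continue;
        uint64_t key = ((uint64_t)f << 21) | ((uint64_t)p << 1) | 1ull;
        auto& t = tally[key];
        if (b == 'G') ++t.first; else ++t.second;
      }
    }
  }
  R_xlen_t m = (R_xlen_t)tally.size();
  IntegerVector frag(m), pos(m), strand(m), meth(m), unmeth(m);
  R_xlen_t k = 0;
  for (const auto& kv : tally) {
    frag[k] = (int)(kv.first >> 21) + 1;
    pos[k] = (int)((kv.first >> 1) & 0xFFFFF);
    strand[k] = (int)(kv.first & 1ull);
    meth[k] = kv.second.first;
    unmeth[k] = kv.second.second;
    ++k;
  }
  return DataFrame::create(_["fragment"] = frag, _["pos"] = pos,
                           _["strand"] = strand, _["meth"] = meth,
                           _["unmeth"] = unmeth);
}
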