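// Compiled inner loops: k-mer seed index, ungapped X-drop extension,
// six-frame translated search, word-set extraction and the bootstrap
// naive-Bayes classifier, per-base read mutation, PWM scanning.
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <cctype>

using namespace Rcpp;

static const std::string AA_LETTERS = "ARNDCQEGHILKMFPSTWYV";

static inline int nt_code(char c) {
  switch (std::toupper(static_cast<unsigned char>(c))) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default:  return -1;
  }
}

static int aa_table[256];
static bool aa_table_ready = false;
static void init_aa_table() {
  if (aa_table_ready) return;
  for (int i = 0; i < 256; ++i) aa_table[i] = -1;
  for (size_t i = 0; i < AA_LETTERS.size(); ++i) {
    aa_table[static_cast<unsigned char>(AA_LETTERS[i])] = static_cast<int>(i);
    aa_table[static_cast<unsigned char>(std::tolower(AA_LETTERS[i]))] = static_cast<int>(i);
  }
  aa_table_ready = true;
}

static std::vector<int8_t> encode_seq(const std::string& s, bool protein) {
  std::vector<int8_t> out(s.size());
  if (protein) {
    init_aa_table();
    for (size_t i = 0; i < s.size(); ++i) out[i] = static_cast<int8_t>(aa_table[(unsigned char) s[i]]);
  } else {
    for (size_t i = 0; i < s.size(); ++i) out[i] = static_cast<int8_t>(nt_code(s[i]));
  }
  return out;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t>& q) {
  std::vector<int8_t> r(q.size());
  for (size_t i = 0; i < q.size(); ++i) {
    int8_t b = q[q.size() - 1 - i];
    r[i] = (b < 0) ? b : static_cast<int8_t>(3 - b);
  }
  return r;
}

struct SeedIndex {
  int k;
  bool protein;
  int alpha;                       // alphabet size (4 or 20)
  std::vector<std::string> names;
  std::vector<std::vector<int8_t>> seqs;
  double total_letters;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> pos;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k, bool protein) {
  SeedIndex* idx = new SeedIndex();
  idx->k = k;
  idx->protein = protein;
  idx->alpha = protein ? 20 : 4;
  idx->total_letters = 0.0;
  int n = seqs.size();
  idx->names.reserve(n);
  idx->seqs.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(encode_seq(s, protein));
    idx->total_letters += s.size();
  }
  const uint64_t A = idx->alpha;
  for (int r = 0; r < n; ++r) {
    const std::vector<int8_t>& s = idx->seqs[r];
    if ((int) s.size() < k) continue;
    uint64_t key = 0, pw = 1;
    for (int j = 0; j < k - 1; ++j) pw *= A;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (s[i] < 0) { valid = 0; key = 0; continue; }
      key = (valid < k) ? key * A + s[i] : (key % pw) * A + s[i];
      if (valid < k) ++valid;
      if (valid == k) idx->pos[key].push_back(std::make_pair((int32_t) r, (int32_t)(i - k + 1)));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP p) {
  XPtr<SeedIndex> idx(p);
  double npos = 0;
  for (auto& kv : idx->pos) npos += kv.second.size();
  return List::create(_["k"] = idx->k, _["protein"] = idx->protein,
                      _["n_refs"] = (int) idx->seqs.size(),
                      _["n_kmers"] = (double) idx->pos.size(),
                      _["n_positions"] = npos,
                      _["total_letters"] = idx->total_letters);
}

// [[Rcpp::export]]
DataFrame cpp_index_positions(SEXP p, std::string kmer) {
  XPtr<SeedIndex> idx(p);
  std::vector<int8_t> w = encode_seq(kmer, idx->protein);
  uint64_t key = 0;
  for (size_t i = 0; i < w.size(); ++i) {
    if (w[i] < 0) stop("invalid letter in k-mer");
    key = key * idx->alpha + w[i];
  }
  std::vector<std::string> rn;
  std::vector<int> off;
  auto it = idx->pos.find(key);
  if ((int) w.size() == idx->k && it != idx->pos.end()) {
    for (auto& pr : it->second) {
      rn.push_back(idx->names[pr.first]);
      off.push_back(pr.second);
    }
  }
  return DataFrame::create(_["subject"] = rn, _["offset"] = off,
                           _["stringsAsFactors"] = false);
}

struct RawHit {
  int ref;
  int strand;    // +1 / -1 (nucleotide); always +1 for protein queries
  int frame;     // 0 for plain search; +-1..3 for translated
  double score;
  int qs, qe, ss, se;  // 0-based half-open, query coords on the searched strand
  int matches, len;
  int pep_len;   // peptide length for translated E-values (0 otherwise)
};

// Ungapped X-drop extension of an exact seed; returns score and fills bounds.
static void extend_seed(const std::vector<int8_t>& q, const std::vector<int8_t>& s,
                        int qi, int si, int k, const int* sm, int alpha, int xdrop,
                        RawHit& h) {
  double seed = 0;
  for (int j = 0; j < k; ++j) seed += sm[q[qi + j] * alpha + s[si + j]];
  // right
  double run = 0, best = 0; int bq = qi + k;
  {
    int a = qi + k, b = si + k;
    while (a < (int) q.size() && b < (int) s.size() && q[a] >= 0 && s[b] >= 0) {
      run += sm[q[a] * alpha + s[b]];
      if (run > best) { best = run; bq = a + 1; }
      if (best - run > xdrop) break;
      ++a; ++b;
    }
  }
  double right = best; int qe = bq;
  // left
  run = 0; best = 0; int lq = qi;
  {
    int a = qi - 1, b = si - 1;
    while (a >= 0 && b >= 0 && q[a] >= 0 && s[b] >= 0) {
      run += sm[q[a] * alpha + s[b]];
      if (run > best) { best = run; lq = a; }
      if (best - run > xdrop) break;
      --a; --b;
    }
  }
  double left = best;
  h.score = seed + left + right;
  h.qs = lq; h.qe = qe;
  h.ss = si - (qi - lq); h.se = si + (qe - qi);
  h.len = h.qe - h.qs;
  int m = 0;
  for (int j = 0; j < h.len; ++j) if (q[h.qs + j] == s[h.ss + j]) ++m;
  h.matches = m;
}

// Search one encoded query strand against the index, collecting the best
// extension per (ref, diagonal); seeds falling inside an already-extended
// region on the same diagonal are skipped.
static void search_strand(const std::vector<int8_t>& q, SeedIndex& idx,
                          const int* sm, int xdrop, int strand, int frame,
                          int pep_len, std::vector<RawHit>& out) {
  int k = idx.k;
  if ((int) q.size() < k) return;
  const uint64_t A = idx.alpha;
  uint64_t key = 0, pw = 1;
  for (int j = 0; j < k - 1; ++j) pw *= A;
  std::unordered_map<int64_t, std::pair<size_t, std::pair<int,int>>> diag; // -> (hit idx in out, covered q-interval)
  size_t base = out.size();
  int valid = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i] < 0) { valid = 0; key = 0; continue; }
    key = (valid < k) ? key * A + q[i] : (key % pw) * A + q[i];
    if (valid < k) ++valid;
    if (valid < k) continue;
    int qi = (int) i - k + 1;
    auto it = idx.pos.find(key);
    if (it == idx.pos.end()) continue;
    for (auto& pr : it->second) {
      int r = pr.first, si = pr.second;
      int64_t dkey = (int64_t) r * 4000000000LL + (si - qi);
      auto dit = diag.find(dkey);
      if (dit != diag.end()) {
        std::pair<int,int>& cov = dit->second.second;
        if (qi >= cov.first && qi + k <= cov.second) continue;
      }
      RawHit h; h.ref = r; h.strand = strand; h.frame = frame; h.pep_len = pep_len;
      extend_seed(q, idx.seqs[r], qi, si, k, sm, idx.alpha, xdrop, h);
      if (dit != diag.end()) {
        RawHit& prev = out[dit->second.first];
        if (h.score > prev.score) { prev = h; }
        dit->second.second = std::make_pair(std::min(dit->second.second.first, h.qs),
                                            std::max(dit->second.second.second, h.qe));
      } else {
        out.push_back(h);
        diag[dkey] = std::make_pair(out.size() - 1, std::make_pair(h.qs, h.qe));
      }
    }
  }
  (void) base;
}

// Greedy overlap merge within (ref, strand, frame): keep the strongest
// extension, drop weaker ones whose query interval overlaps an accepted one
// by >= half of the shorter interval.
static std::vector<RawHit> merge_hits(std::vector<RawHit>& hits,
                                      const std::vector<std::string>& names) {
  std::sort(hits.begin(), hits.end(), [&](const RawHit& a, const RawHit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (names[a.ref] != names[b.ref]) return names[a.ref] < names[b.ref];
    if (a.qs != b.qs) return a.qs < b.qs;
    return a.ss < b.ss;
  });
  std::vector<RawHit> acc;
  for (auto& h : hits) {
    bool keep = true;
    for (auto& a : acc) {
      if (a.ref != h.ref || a.strand != h.strand || a.frame != h.frame) continue;
      int ov = std::min(a.qe, h.qe) - std::max(a.qs, h.qs);
      int shorter = std::min(a.qe - a.qs, h.qe - h.qs);
      if (ov > 0 && shorter > 0 && 2 * ov >= shorter) { keep = false; break; }
    }
    if (keep) acc.push_back(h);
  }
  return acc;
}

static DataFrame hits_to_df(const std::vector<std::string>& qid_per_hit,
                            const std::vector<RawHit>& hits,
                            const std::vector<int>& qlen_per_hit,
                            SeedIndex& idx, double lambda, double K) {
  int n = hits.size();
  CharacterVector qid(n), sid(n), strand(n);
  NumericVector score(n), ev(n), pident(n);
  IntegerVector len(n), mism(n), qs(n), qe(n), ss(n), se(n), frame(n);
  for (int i = 0; i < n; ++i) {
    const RawHit& h = hits[i];
    qid[i] = qid_per_hit[i];
    sid[i] = idx.names[h.ref];
    score[i] = h.score;
    int qlen = qlen_per_hit[i];
    double m = (h.pep_len > 0) ? (double) h.pep_len : (double) qlen;
    ev[i] = K * m * idx.total_letters * std::exp(-lambda * h.score);
    pident[i] = h.len > 0 ? 100.0 * h.matches / h.len : 0.0;
    len[i] = h.len;
    mism[i] = h.len - h.matches;
    if (h.frame == 0 && h.strand < 0) {
      // plain nucleotide search on the reverse strand: map back to forward coords
      qs[i] = qlen - h.qe; qe[i] = qlen - h.qs;
    } else {
      qs[i] = h.qs; qe[i] = h.qe;
    }
    ss[i] = h.ss; se[i] = h.se;
    strand[i] = (h.strand < 0) ? "-" : "+";
    frame[i] = (h.frame == 0) ? NA_INTEGER : h.frame;
  }
  return DataFrame::create(_["query"] = qid, _["subject"] = sid,
                           _["score"] = score, _["evalue"] = ev,
                           _["pident"] = pident, _["length"] = len,
                           _["mismatch"] = mism,
                           _["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["strand"] = strand, _["frame"] = frame,
                           _["stringsAsFactors"] = false);
}

static void finalize_query(std::vector<RawHit>& raw, SeedIndex& idx,
                           double lambda, double K, double max_e, bool best_only,
                           const std::string& qid, int qlen,
                           std::vector<std::string>& all_qid,
                           std::vector<RawHit>& all_hits,
                           std::vector<int>& all_qlen) {
  std::vector<RawHit> merged = merge_hits(raw, idx.names);
  // E-value filter, then sort by descending score / subject id
  std::vector<RawHit> kept;
  for (auto& h : merged) {
    double m = (h.pep_len > 0) ? (double) h.pep_len : (double) qlen;
    double e = K * m * idx.total_letters * std::exp(-lambda * h.score);
    if (e <= max_e) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [&](const RawHit& a, const RawHit& b) {
    if (a.score != b.score) return a.score > b.score;
    return idx.names[a.ref] < idx.names[b.ref];
  });
  if (best_only && kept.size() > 1) kept.resize(1);
  for (auto& h : kept) {
    all_qid.push_back(qid);
    all_hits.push_back(h);
    all_qlen.push_back(qlen);
  }
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector qseqs, CharacterVector qids, SEXP p,
                     IntegerMatrix sm, double lambda, double K, double max_e,
                     int xdrop, bool best_only, bool both_strands) {
  XPtr<SeedIndex> idx(p);
  int alpha = idx->alpha;
  if (sm.nrow() != alpha || sm.ncol() != alpha) stop("score matrix does not match alphabet");
  std::vector<int> smv(alpha * alpha);
  for (int i = 0; i < alpha; ++i)
    for (int j = 0; j < alpha; ++j) smv[i * alpha + j] = sm(i, j);
  std::vector<std::string> all_qid; std::vector<RawHit> all_hits; std::vector<int> all_qlen;
  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string qs = as<std::string>(qseqs[qi]);
    std::vector<int8_t> q = encode_seq(qs, idx->protein);
    std::vector<RawHit> raw;
    search_strand(q, *idx, smv.data(), xdrop, +1, 0, 0, raw);
    if (both_strands && !idx->protein) {
      std::vector<int8_t> qr = revcomp(q);
      search_strand(qr, *idx, smv.data(), xdrop, -1, 0, 0, raw);
    }
    finalize_query(raw, *idx, lambda, K, max_e, best_only,
                   as<std::string>(qids[qi]), (int) q.size(),
                   all_qid, all_hits, all_qlen);
  }
  return hits_to_df(all_qid, all_hits, all_qlen, *idx, lambda, K);
}

// Standard genetic code, indexed by codon with T=0,C=1,A=2,G=3.
static const char GENCODE[] =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
static inline int tcag(int acgt) {
  // convert A0 C1 G2 T3 -> T0 C1 A2 G3
  switch (acgt) { case 0: return 2; case 1: return 1; case 2: return 3; case 3: return 0; }
  return -1;
}

// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector seqs, int frame) {
  // frame in +-1..3; '*' marks stops, 'X' ambiguous codons
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> q = encode_seq(s, false);
    if (frame < 0) q = revcomp(q);
    int off = std::abs(frame) - 1;
    std::string pep;
    for (int j = off; j + 2 < (int) q.size(); j += 3) {
      if (q[j] < 0 || q[j+1] < 0 || q[j+2] < 0) { pep.push_back('X'); continue; }
      int ci = tcag(q[j]) * 16 + tcag(q[j+1]) * 4 + tcag(q[j+2]);
      pep.push_back(GENCODE[ci]);
    }
    out[i] = pep;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_translated_search(CharacterVector qseqs, CharacterVector qids, SEXP p,
                                IntegerMatrix sm, double lambda, double K,
                                double max_e, int xdrop, bool best_only) {
  XPtr<SeedIndex> idx(p);
  if (!idx->protein) stop("translated search needs a protein index");
  int alpha = idx->alpha;
  std::vector<int> smv(alpha * alpha);
  for (int i = 0; i < alpha; ++i)
    for (int j = 0; j < alpha; ++j) smv[i * alpha + j] = sm(i, j);
  init_aa_table();
  std::vector<std::string> all_qid; std::vector<RawHit> all_hits; std::vector<int> all_qlen;
  for (int qi = 0; qi < qseqs.size(); ++qi) {
    std::string s = as<std::string>(qseqs[qi]);
    std::vector<int8_t> nt = encode_seq(s, false);
    int L = (int) nt.size();
    std::vector<RawHit> raw;
    for (int dir = 0; dir < 2; ++dir) {
      std::vector<int8_t> q = (dir == 0) ? nt : revcomp(nt);
      for (int off = 0; off < 3; ++off) {
        int frame = (dir == 0) ? (off + 1) : -(off + 1);
        // translate, keeping stop positions to split peptides
        int npep = (int)((int) q.size() - off) / 3;
        if (npep <= 0) continue;
        std::vector<int8_t> pep(npep);
        for (int j = 0; j < npep; ++j) {
          int b = off + 3 * j;
          if (q[b] < 0 || q[b+1] < 0 || q[b+2] < 0) { pep[j] = -2; continue; }
          char a = GENCODE[tcag(q[b]) * 16 + tcag(q[b+1]) * 4 + tcag(q[b+2])];
          pep[j] = (a == '*') ? -2 : (int8_t) aa_table[(unsigned char) a];
        }
        // split at stops (-2)
        int start = 0;
        for (int j = 0; j <= npep; ++j) {
          if (j == npep || pep[j] == -2) {
            int plen = j - start;
            if (plen >= idx->k) {
              std::vector<int8_t> sub(pep.begin() + start, pep.begin() + j);
              std::vector<RawHit> praw;
              search_strand(sub, *idx, smv.data(), xdrop, frame > 0 ? +1 : -1,
                            frame, plen, praw);
              // map peptide-local aa coords to forward-read nt coords
              for (auto& h : praw) {
                int aa_s = start + h.qs, aa_e = start + h.qe;
                int nt_s, nt_e;
                if (frame > 0) {
                  nt_s = off + 3 * aa_s;
                  nt_e = off + 3 * aa_e;
                } else {
                  nt_s = L - (off + 3 * aa_e);
                  nt_e = L - (off + 3 * aa_s);
                }
                h.qs = nt_s; h.qe = nt_e;
                raw.push_back(h);
              }
            }
            start = j + 1;
          }
        }
      }
    }
    // raw hits already have final query coords; merge/filter/sort
    finalize_query(raw, *idx, lambda, K, max_e, best_only,
                   as<std::string>(qids[qi]), L, all_qid, all_hits, all_qlen);
  }
  return hits_to_df(all_qid, all_hits, all_qlen, *idx, lambda, K);
}

// ---- naive-Bayes words and classification -------------------------------

// [[Rcpp::export]]
List cpp_word_sets(CharacterVector seqs, int w) {
  // sorted unique w-mer ids (0-based) over both strands of each sequence
  int n = seqs.size();
  List out(n);
  uint64_t pw = 1;
  for (int j = 0; j < w - 1; ++j) pw *= 4;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> q = encode_seq(s, false);
    std::vector<int> words;
    for (int dir = 0; dir < 2; ++dir) {
      std::vector<int8_t> x = (dir == 0) ? q : revcomp(q);
      uint64_t key = 0; int valid = 0;
      for (size_t j = 0; j < x.size(); ++j) {
        if (x[j] < 0) { valid = 0; key = 0; continue; }
        key = (valid < w) ? key * 4 + x[j] : (key % pw) * 4 + x[j];
        if (valid < w) ++valid;
        if (valid == w) words.push_back((int) key);
      }
    }
    std::sort(words.begin(), words.end());
    words.erase(std::unique(words.begin(), words.end()), words.end());
    out[i] = IntegerVector(words.begin(), words.end());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_classify_nb(List word_sets, NumericMatrix logp, IntegerMatrix lineage,
                     int n_boot, double subsample) {
  // logp: n_words x n_genera log P(w|g); lineage: n_genera x n_ranks node ids
  // Uses R's RNG: caller is responsible for set.seed().
  int n_reads = word_sets.size();
  int G = logp.ncol();
  int R = lineage.ncol();
  IntegerVector best(n_reads);
  NumericMatrix conf(n_reads, R);
  std::vector<double> sc(G);
  RNGScope rng;
  for (int i = 0; i < n_reads; ++i) {
    IntegerVector wv = word_sets[i];
    int nw = wv.size();
    if (nw == 0) { best[i] = NA_INTEGER; for (int r = 0; r < R; ++r) conf(i, r) = 0.0; continue; }
    std::fill(sc.begin(), sc.end(), 0.0);
    for (int j = 0; j < nw; ++j) {
      int w = wv[j];
      for (int g = 0; g < G; ++g) sc[g] += logp(w, g);
    }
    int b = 0;
    for (int g = 1; g < G; ++g) if (sc[g] > sc[b]) b = g;
    best[i] = b + 1;
    int m = (int) std::ceil(subsample * nw);
    if (m < 1) m = 1;
    std::vector<int> agree(R, 0);
    for (int t = 0; t < n_boot; ++t) {
      std::fill(sc.begin(), sc.end(), 0.0);
      for (int d = 0; d < m; ++d) {
        int j = (int)(unif_rand() * nw);
        if (j >= nw) j = nw - 1;
        int w = wv[j];
        for (int g = 0; g < G; ++g) sc[g] += logp(w, g);
      }
      int tb = 0;
      for (int g = 1; g < G; ++g) if (sc[g] > sc[tb]) tb = g;
      for (int r = 0; r < R; ++r)
        if (lineage(tb, r) == lineage(b, r)) ++agree[r];
    }
    for (int r = 0; r < R; ++r) conf(i, r) = (double) agree[r] / n_boot;
  }
  return List::create(_["best"] = best, _["confidence"] = conf);
}

// ---- read mutation and PWM scan -----------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_point_mutate(CharacterVector seqs, double rate) {
  // i.i.d. per-base substitutions excluding the current base; uses R's RNG
  static const char NT[] = "ACGT";
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope rng;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int) s.size();
    int ne = (int) R::rbinom((double) L, rate);
    for (int e = 0; e < ne; ++e) {
      int pos = (int)(unif_rand() * L);
      if (pos >= L) pos = L - 1;
      int cur = nt_code(s[pos]);
      if (cur < 0) continue;
      int nb = (cur + 1 + (int)(unif_rand() * 3)) % 4;
      s[pos] = NT[nb];
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_pwm_scan(CharacterVector seqs, NumericMatrix pwm) {
  // best-scoring window per sequence over both strands; pwm is 4 x L (ACGT rows)
  int L = pwm.ncol();
  int n = seqs.size();
  NumericVector best(n);
  IntegerVector start(n);
  CharacterVector strand(n);
  LogicalVector valid(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::vector<int8_t> f = encode_seq(s, false);
    int sl = (int) f.size();
    if (sl < L) { valid[i] = false; best[i] = R_NegInf; start[i] = NA_INTEGER; strand[i] = NA_STRING; continue; }
    valid[i] = true;
    double b = R_NegInf; int bs = 0; int bstr = 0;
    for (int dir = 0; dir < 2; ++dir) {
      std::vector<int8_t> q = (dir == 0) ? f : revcomp(f);
      for (int p = 0; p + L <= sl; ++p) {
        double sc = 0;
        bool ok = true;
        for (int j = 0; j < L; ++j) {
          if (q[p + j] < 0) { ok = false; break; }
          sc += pwm(q[p + j], j);
        }
        if (!ok) continue;
        if (sc > b) {
          b = sc;
          bstr = dir;
          bs = (dir == 0) ? p : sl - p - L;  // forward-strand coords
        }
      }
    }
    best[i] = b; start[i] = bs; strand[i] = bstr == 0 ? "+" : "-";
  }
  return DataFrame::create(_["score"] = best, _["start"] = start,
                           _["strand"] = strand, _["valid"] = valid,
                           _["stringsAsFactors"] = false);
}
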