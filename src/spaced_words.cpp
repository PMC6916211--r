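// Spaced-word extraction and matching core.
//
// Sequences are encoded A=0, C=1, G=2, T=3, anything else = 4 (N).  A
// window of pattern length ell is usable only if it contains no N; the
// spaced word is the 2-bit packing of the nucleotides at the pattern's
// match positions (weight <= 32 enforced on the R side).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static inline uint8_t code_of(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (std::size_t i = 0; i < s.size(); ++i) v[i] = code_of(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (std::size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? static_cast<uint8_t>(3 - c) : static_cast<uint8_t>(4);
  }
  return r;
}

// Append (key, record, pos) for every N-free window of one sequence.
static void collect_windows(const std::vector<uint8_t>& seq,
                            const std::vector<int>& moff, int ell,
                            int rec,
                            std::vector<uint64_t>& keys,
                            std::vector<int>& recs,
                            std::vector<int>& poss) {
  const int n = static_cast<int>(seq.size());
  if (n < ell) return;
  int ncount = 0;
  for (int i = 0; i < ell; ++i) ncount += (seq[i] == 4);
  for (int p = 0; p + ell <= n; ++p) {
    if (p > 0) ncount += (seq[p + ell - 1] == 4) - (seq[p - 1] == 4);
    if (ncount == 0) {
      uint64_t k = 0;
      for (int o : moff) k = (k << 2) | seq[p + o];
      keys.push_back(k);
      recs.push_back(rec);
      poss.push_back(p);
    }
  }
}

// [[Rcpp::export]]
List cpp_extract_spaced_words(std::string seq, IntegerVector matchOffsets,
                              int ell) {
  std::vector<int> moff(matchOffsets.begin(), matchOffsets.end());
  std::vector<uint8_t> enc = encode_seq(seq);
  std::vector<uint64_t> keys;
  std::vector<int> recs, poss;
  collect_windows(enc, moff, ell, 0, keys, recs, poss);
  const int w = static_cast<int>(moff.size());
  CharacterVector kmers(keys.size());
  IntegerVector pos(keys.size());
  std::string buf(w, 'N');
  static const char* ALPH = "ACGT";
  for (std::size_t i = 0; i < keys.size(); ++i) {
    uint64_t k = keys[i];
    for (int j = w - 1; j >= 0; --j) {
      buf[j] = ALPH[k & 3u];
      k >>= 2;
    }
    kmers[i] = buf;
    pos[i] = poss[i];
  }
  return List::create(_["key"] = kmers, _["pos"] = pos);
}

struct WindowIndex {
  std::vector<uint64_t> keys;  // sorted
  std::vector<int> recs, poss; // permuted alongside keys
};

static WindowIndex build_index(const std::vector<std::vector<uint8_t> >& seqs,
                               const std::vector<int>& moff, int ell) {
  std::vector<uint64_t> keys;
  std::vector<int> recs, poss;
  for (std::size_t r = 0; r < seqs.size(); ++r)
    collect_windows(seqs[r], moff, ell, static_cast<int>(r), keys, recs, poss);
  std::vector<std::size_t> ord(keys.size());
  for (std::size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
    return keys[a] < keys[b];
  });
  WindowIndex idx;
  idx.keys.reserve(keys.size());
  idx.recs.reserve(keys.size());
  idx.poss.reserve(keys.size());
  for (std::size_t i : ord) {
    idx.keys.push_back(keys[i]);
    idx.recs.push_back(recs[i]);
    idx.poss.push_back(poss[i]);
  }
  return idx;
}

// All spaced-word matches between setA (forward) and setB (forward and
// reverse-complement).  qryPos on the reverse strand is the window start
// within the reverse-complemented record.  No score threshold is applied
// here; filtering happens downstream.
// [[Rcpp::export]]
DataFrame cpp_enumerate_matches(CharacterVector seqsA, CharacterVector seqsB,
                                IntegerVector matchOffsets,
                                IntegerVector dontCareOffsets, int ell,
                                IntegerMatrix scoreMatrix, bool excludeSelf,
                                int maxBucket) {
  std::vector<int> moff(matchOffsets.begin(), matchOffsets.end());
  std::vector<int> doff(dontCareOffsets.begin(), dontCareOffsets.end());

  std::vector<std::vector<uint8_t> > encA(seqsA.size()), encB(seqsB.size());
  for (int i = 0; i < seqsA.size(); ++i)
    encA[i] = encode_seq(as<std::string>(seqsA[i]));
  for (int i = 0; i < seqsB.size(); ++i)
    encB[i] = encode_seq(as<std::string>(seqsB[i]));

  WindowIndex idx = build_index(encA, moff, ell);

  int sm[4][4];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) sm[a][b] = scoreMatrix(a, b);

  std::vector<int> refRec, refPos, qryRec, qryPos, score, mism;
  std::vector<int> strand;  // 0 forward, 1 reverse

  for (int br = 0; br < static_cast<int>(encB.size()); ++br) {
    for (int orient = 0; orient < 2; ++orient) {
      const std::vector<uint8_t> bseq =
          (orient == 0) ? encB[br] : revcomp_codes(encB[br]);
      std::vector<uint64_t> keys;
      std::vector<int> recs, poss;
      collect_windows(bseq, moff, ell, br, keys, recs, poss);
      for (std::size_t i = 0; i < keys.size(); ++i) {
        const uint64_t k = keys[i];
        const int bp = poss[i];
        auto lo = std::lower_bound(idx.keys.begin(), idx.keys.end(), k);
        auto hi = std::upper_bound(lo, idx.keys.end(), k);
        if (maxBucket > 0 && (hi - lo) > maxBucket) continue;
        for (auto it = lo; it != hi; ++it) {
          const std::size_t j = it - idx.keys.begin();
          const int ar = idx.recs[j];
          const int ap = idx.poss[j];
          if (excludeSelf && orient == 0 && ar == br && ap == bp) continue;
          int s = 0, m = 0;
          const std::vector<uint8_t>& aseq = encA[ar];
          for (int o : doff) {
            const uint8_t ca = aseq[ap + o];
            const uint8_t cb = bseq[bp + o];
            s += sm[ca][cb];
            m += (ca != cb);
          }
          refRec.push_back(ar + 1);
          refPos.push_back(ap);
          qryRec.push_back(br + 1);
          qryPos.push_back(bp);
          strand.push_back(orient);
          score.push_back(s);
          mism.push_back(m);
        }
      }
    }
  }

  const std::size_t n = refRec.size();
  CharacterVector strandChr(n);
  for (std::size_t i = 0; i < n; ++i)
    strandChr[i] = (strand[i] == 0) ? "forward" : "reverse";
  return DataFrame::create(
      _["refRecord"] = IntegerVector(refRec.begin(), refRec.end()),
      _["refPos"] = IntegerVector(refPos.begin(), refPos.end()),
      _["qryRecord"] = IntegerVector(qryRec.begin(), qryRec.end()),
      _["qryPos"] = IntegerVector(qryPos.begin(), qryPos.end()),
      _["strand"] = strandChr,
      _["score"] = IntegerVector(score.begin(), score.end()),
      _["mismatches"] = IntegerVector(mism.begin(), mism.end()),
      _["stringsAsFactors"] = false);
}
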