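#include <Rcpp.h>
using namespace Rcpp;

// SOLiD di-base code: XOR of the 2-bit base encodings (A=0, C=1, G=2, T=3).
// This realises the standard table 0:{AA,CC,GG,TT} 1:{AC,CA,GT,TG}
// 2:{AG,GA,CT,TC} 3:{AT,TA,CG,GC} and is invariant under complementing
// both bases of a pair.
static inline int bit2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline int dibase(char a, char b) {
  int x = bit2(a), y = bit2(b);
  if (x < 0 || y < 0) return -1;
  return x ^ y;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
CharacterVector cpp_encode_color(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = LENGTH(STRING_ELT(seqs, i));
    if (n < 2) stop("cannot color-encode a sequence shorter than 2");
    std::string col(n - 1, '0');
    for (int j = 0; j + 1 < n; ++j) {
      int c = dibase(s[j], s[j + 1]);
      col[j] = (c < 0) ? '0' : (char)('0' + c);
    }
    out[i] = col;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// Most-likely base translation of a color read against a reference window,
// by dynamic programming over the four candidate bases per position.
// colors[i] (0-based) is the transition into base i+1; the primer base
// anchors the chain. Transition cost 1 when the observed color disagrees
// with code(prev, cur); emission cost 1 unless cur equals the reference
// base or (ref C, cur T) -- the zero-cost bisulfite mismatch.
// [[Rcpp::export]]
List cpp_decode_color(std::string primer, std::string colors,
                      std::string ref_window) {
  int n = (int)colors.size();
  if ((int)ref_window.size() < n)
    stop("reference window shorter than color read");
  const int INF = 1 << 28;
  // primary cost = color disagreements + non-BS emission disagreements;
  // secondary cost = color disagreements alone, so that among equal-cost
  // translations the one trusting the observed colors wins (a final-color
  // mismatch then decodes as a base change, not as a color error)
  std::vector<int> prev(4), cur(4), prev2(4), cur2(4);
  std::vector<std::vector<int> > bt(n, std::vector<int>(4, 0));
  int p0 = bit2(primer[0]);
  if (p0 < 0) stop("invalid primer base");
  for (int i = 0; i < n; ++i) {
    int obs = colors[i] - '0';
    for (int b = 0; b < 4; ++b) {
      int emis;
      char rb = ref_window[i];
      if (BASES[b] == rb) emis = 0;
      else if (rb == 'C' && BASES[b] == 'T') emis = 0;
      else emis = 1;
      int best = INF, best2 = INF, barg = 0;
      if (i == 0) {
        int trans = ((p0 ^ b) == obs && obs >= 0 && obs <= 3) ? 0 : 1;
        best = trans + emis;
        best2 = trans;
      } else {
        for (int pb = 0; pb < 4; ++pb) {
          int trans = ((pb ^ b) == obs && obs >= 0 && obs <= 3) ? 0 : 1;
          int v = prev[pb] + trans + emis;
          int v2 = prev2[pb] + trans;
          if (v < best || (v == best && v2 < best2)) {
            best = v; best2 = v2; barg = pb;
          }
        }
      }
      cur[b] = best;
      cur2[b] = best2;
      bt[i][b] = barg;
    }
    prev = cur;
    prev2 = cur2;
  }
  int best = INF, best2 = INF, barg = 0;
  for (int b = 0; b < 4; ++b) {
    if (prev[b] < best || (prev[b] == best && prev2[b] < best2)) {
      best = prev[b]; best2 = prev2[b]; barg = b;
    }
  }
  std::string bases(n, 'A');
  int b = barg;
  for (int i = n - 1; i >= 0; --i) {
    bases[i] = BASES[b];
    b = bt[i][b];
  }
  return List::create(_["bases"] = bases, _["cost"] = best);
}

// Adjacent-color mismatch count: position i contributes 1 iff both colors
// flanking base i disagree with the reference colors AND the decoded base
// is a non-bisulfite mismatch. The final base, which has no second flanking
// color, is charged on its single color. Also returns the number of
// bisulfite (ref C / decoded T) mismatches for reporting.
// [[Rcpp::export]]
IntegerVector cpp_color_mm(std::string primer, std::string colors,
                           std::string decoded, std::string ref_window) {
  int n = (int)colors.size();
  if ((int)decoded.size() != n || (int)ref_window.size() < n)
    stop("decoded read / reference window length mismatch");
  std::vector<int> cmis(n + 1, 0);  // 1-based; cmis[i] = color i mismatches
  for (int i = 1; i <= n; ++i) {
    char a = (i == 1) ? primer[0] : ref_window[i - 2];
    int rc = dibase(a, ref_window[i - 1]);
    int obs = colors[i - 1] - '0';
    cmis[i] = (obs != rc) ? 1 : 0;
  }
  int non_bs = 0, bs = 0;
  for (int i = 1; i <= n; ++i) {
    char d = decoded[i - 1], r = ref_window[i - 1];
    bool base_mis = (d != r);
    bool is_bs = (r == 'C' && d == 'T');
    if (base_mis && is_bs) ++bs;
    bool nb = base_mis && !is_bs;
    if (i < n) {
      if (cmis[i] && cmis[i + 1] && nb) ++non_bs;
    } else {
      if (cmis[i] && nb) ++non_bs;
    }
  }
  return IntegerVector::create(non_bs, bs);
}
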