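#include <Rcpp.h>
#include <map>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// Strand-oriented window of the (plus-stored) chromosome: rc = FALSE reads
// chrom[pos, pos+len); rc = TRUE reads the reverse-complement text, i.e. the
// minus strand 5'->3', at offset pos of that text. chrom is a 1-based index
// into the genome vector (passed whole to avoid copying chromosome strings).
// [[Rcpp::export]]
std::string cpp_window(CharacterVector chroms, int chrom, int pos, int len,
                       bool rc) {
  const char* s = CHAR(STRING_ELT(chroms, chrom - 1));
  int n = LENGTH(STRING_ELT(chroms, chrom - 1));
  if (pos < 0 || pos + len > n) stop("window out of range");
  std::string w(len, 'N');
  if (!rc) {
    for (int j = 0; j < len; ++j) w[j] = s[pos + j];
  } else {
    for (int j = 0; j < len; ++j) w[j] = comp(s[n - 1 - (pos + j)]);
  }
  return w;
}

// Bisulfite-aware mismatch tally of an (orientation-aligned) read against a
// strand-oriented reference window: ref C / read T is a bisulfite mismatch,
// every other difference is a non-bisulfite mismatch.
// [[Rcpp::export]]
IntegerVector cpp_verify_bs(std::string read, CharacterVector chroms,
                            int chrom, int pos, bool rc) {
  const char* chromseq = CHAR(STRING_ELT(chroms, chrom - 1));
  int len = (int)read.size();
  int n = LENGTH(STRING_ELT(chroms, chrom - 1));
  if (pos < 0 || pos + len > n) stop("alignment window out of range");
  int non_bs = 0, bs = 0;
  for (int j = 0; j < len; ++j) {
    char r = rc ? comp(chromseq[n - 1 - (pos + j)]) : chromseq[pos + j];
    char q = read[j];
    if (q == r) continue;
    if (r == 'C' && q == 'T') ++bs; else ++non_bs;
  }
  return IntegerVector::create(non_bs, bs);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int n = LENGTH(STRING_ELT(seqs, i));
    std::string r(n, 'N');
    for (int j = 0; j < n; ++j) r[j] = comp(s[n - 1 - j]);
    out[i] = r;
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// Normalized Shannon entropy of the A/C/G/T histogram (N etc. excluded),
// divided by log2(4) so values lie in [0, 1].
// [[Rcpp::export]]
NumericVector cpp_entropy(CharacterVector reads) {
  NumericVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = LENGTH(STRING_ELT(reads, i));
    double cnt[4] = {0, 0, 0, 0};
    double tot = 0;
    for (int j = 0; j < n; ++j) {
      switch (s[j]) {
      case 'A': ++cnt[0]; ++tot; break;
      case 'C': ++cnt[1]; ++tot; break;
      case 'G': ++cnt[2]; ++tot; break;
      case 'T': ++cnt[3]; ++tot; break;
      default: break;
      }
    }
    double h = 0;
    if (tot > 0) {
      for (int b = 0; b < 4; ++b) {
        if (cnt[b] > 0) {
          double p = cnt[b] / tot;
          h -= p * std::log2(p);
        }
      }
    }
    out[i] = h / 2.0;
  }
  return out;
}

// Accumulate per-cytosine methylation evidence from orientation-aligned
// reads. Sites live on the strand of the alignment text: rc = FALSE tallies
// plus-strand Cs, rc = TRUE minus-strand Cs (reported in plus coordinates).
// Read C over ref C = methylated; read T over ref C = unmethylated.
// [[Rcpp::export]]
List cpp_tally_meth(CharacterVector chrom_seqs, IntegerVector chrom_idx,
                    IntegerVector pos_text, LogicalVector rc,
                    CharacterVector reads) {
  int nc = chrom_seqs.size();
  std::vector<const char*> seqs(nc);
  std::vector<int> lens(nc);
  for (int c = 0; c < nc; ++c) {
    seqs[c] = CHAR(STRING_ELT(chrom_seqs, c));
    lens[c] = LENGTH(STRING_ELT(chrom_seqs, c));
  }
  // (chrom, strand, pos) -> (n_meth, n_unmeth); strand 0 = plus, 1 = minus
  std::map<std::pair<int, std::pair<int, int> >, std::pair<int, int> > tab;
  for (int i = 0; i < reads.size(); ++i) {
    int c = chrom_idx[i] - 1;
    if (c < 0 || c >= nc) stop("bad chromosome index");
    const char* g = seqs[c];
    int L = lens[c];
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    int p = pos_text[i];
    bool minus = rc[i];
    if (p < 0 || p + len > L) stop("alignment out of range");
    for (int j = 0; j < len; ++j) {
      char refc, q = s[j];
      int plus_pos, strand;
      if (!minus) {
        plus_pos = p + j;
        refc = g[plus_pos];
        strand = 0;
      } else {
        plus_pos = L - 1 - (p + j);
        refc = comp(g[plus_pos]);
        strand = 1;
      }
      if (refc != 'C') continue;
      if (q != 'C' && q != 'T') continue;  // error/SNP bases are ignored
      std::pair<int, std::pair<int, int> > key(c,
          std::pair<int, int>(strand, plus_pos));
      std::pair<int, int>& v = tab[key];
      if (q == 'C') ++v.first; else ++v.second;
    }
  }
  int n = (int)tab.size();
  IntegerVector ochrom(n), opos(n), ostrand(n), ometh(n), ounmeth(n);
  CharacterVector octx(n);
  int i = 0;
  for (std::map<std::pair<int, std::pair<int, int> >,
       std::pair<int, int> >::iterator it = tab.begin(); it != tab.end();
       ++it, ++i) {
    int c = it->first.first;
    int strand = it->first.second.first;
    int p = it->first.second.second;
    const char* g = seqs[c];
    int L = lens[c];
    // strandwise next two bases; truncated trinucleotides fall back to the
    // bases available (next G -> CG, otherwise CHH)
    char b1 = 0, b2 = 0;
    if (strand == 0) {
      if (p + 1 < L) b1 = g[p + 1];
      if (p + 2 < L) b2 = g[p + 2];
    } else {
      if (p - 1 >= 0) b1 = comp(g[p - 1]);
      if (p - 2 >= 0) b2 = comp(g[p - 2]);
    }
    const char* ctx;
    if (b1 == 'G') ctx = "CG";
    else if (b1 != 0 && b2 == 'G') ctx = "CHG";
    else ctx = "CHH";
    ochrom[i] = c + 1;
    opos[i] = p;
    ostrand[i] = strand;
    octx[i] = ctx;
    ometh[i] = it->second.first;
    ounmeth[i] = it->second.second;
  }
  return List::create(_["chrom"] = ochrom, _["pos"] = opos,
                      _["strand"] = ostrand, _["context"] = octx,
                      _["n_meth"] = ometh, _["n_unmeth"] = ounmeth);
}
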