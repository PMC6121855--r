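#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// BLOSUM62 substitution scores (Henikoff & Henikoff 1992), residues in the
// standard order A R N D C Q E G H I L K M F P S T W Y V.
static const int AA_N = 20;
static const char AA_ORDER[AA_N + 1] = "ARNDCQEGHILKMFPSTWYV";
static const int BLOSUM62[AA_N][AA_N] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4}
};

static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'R': return 1;  case 'N': return 2;
    case 'D': return 3;  case 'C': return 4;  case 'Q': return 5;
    case 'E': return 6;  case 'G': return 7;  case 'H': return 8;
    case 'I': return 9;  case 'L': return 10; case 'K': return 11;
    case 'M': return 12; case 'F': return 13; case 'P': return 14;
    case 'S': return 15; case 'T': return 16; case 'W': return 17;
    case 'Y': return 18; case 'V': return 19;
    default: return -1;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int k = aa_index(s[i]);
    if (k < 0) stop("non-amino-acid character '%s' in sequence", std::string(1, s[i]));
    v[i] = k;
  }
  return v;
}

// Smith-Waterman local alignment with affine gaps.  Traceback over three
// state matrices (M = aligned pair, X = gap in b, Y = gap in a) yields the
// alignment length and the count of aligned columns with positive
// substitution score, from which the similarity fraction is computed.
struct SWResult { double score; double similarity; int aln_len; };

static SWResult sw_one(const std::vector<int>& a, const std::vector<int>& b,
                       double gap_open, double gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  // scores for the three states, row-rolled; traceback kept as full byte grids
  std::vector<double> M((m + 1) * (n + 1), 0.0), X((m + 1) * (n + 1), NEG),
                      Y((m + 1) * (n + 1), NEG);
  // traceback codes: 0 stop, 1 from M, 2 from X, 3 from Y
  std::vector<unsigned char> tbM((m + 1) * (n + 1), 0),
                             tbX((m + 1) * (n + 1), 0),
                             tbY((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // X: gap in b (consume a[i])
      double xo = M[at(i - 1, j)] - gap_open, xe = X[at(i - 1, j)] - gap_extend;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 1; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 2; }
      // Y: gap in a (consume b[j])
      double yo = M[at(i, j - 1)] - gap_open, ye = Y[at(i, j - 1)] - gap_extend;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 3; }
      // M: align a[i] with b[j]; code 0 marks a fresh local start
      double s = (double)BLOSUM62[a[i - 1]][b[j - 1]];
      double pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
             py = Y[at(i - 1, j - 1)];
      double prev = pm; unsigned char code = 1;
      if (px > prev) { prev = px; code = 2; }
      if (py > prev) { prev = py; code = 3; }
      if (prev <= 0.0) { prev = 0.0; code = 0; }
      double val = prev + s;
      if (val < 0.0) val = 0.0;
      M[at(i, j)] = val; tbM[at(i, j)] = code;
      if (val > best) { best = val; bi = i; bj = j; }
    }
  }
  // traceback from the best-scoring aligned pair
  int aln_len = 0, pos_cols = 0;
  if (best > 0.0) {
    int i = bi, j = bj, state = 1;
    for (;;) {
      if (state == 1) {
        ++aln_len;
        if (BLOSUM62[a[i - 1]][b[j - 1]] > 0) ++pos_cols;
        unsigned char code = tbM[at(i, j)];
        --i; --j;
        if (code == 0) break;
        state = code;
      } else if (state == 2) {
        ++aln_len;
        unsigned char code = tbX[at(i, j)];
        --i; state = code;
      } else {
        ++aln_len;
        unsigned char code = tbY[at(i, j)];
        --j; state = code;
      }
    }
  }
  SWResult r;
  r.score = best;
  r.aln_len = aln_len;
  r.similarity = aln_len > 0 ? (double)pos_cols / (double)aln_len : 0.0;
  return r;
}

// Score-only Smith-Waterman with rolling rows (no traceback storage);
// used as a fast first pass before e-value filtering.
static double sw_score_one(const std::vector<int>& a, const std::vector<int>& b,
                           double gap_open, double gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> Mprev(n + 1, 0.0), Mcur(n + 1, 0.0);
  std::vector<double> Xprev(n + 1, NEG), Xcur(n + 1, NEG);
  std::vector<double> Yprev(n + 1, NEG), Ycur(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    const int* row = BLOSUM62[a[i - 1]];
    for (int j = 1; j <= n; ++j) {
      double x = std::max(Mprev[j] - gap_open, Xprev[j] - gap_extend);
      double y = std::max(Mcur[j - 1] - gap_open, Ycur[j - 1] - gap_extend);
      double prev = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      if (prev < 0.0) prev = 0.0;
      double v = prev + (double)row[b[j - 1]];
      if (v < 0.0) v = 0.0;
      Xcur[j] = x; Ycur[j] = y; Mcur[j] = v;
      if (v > best) best = v;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return best;
}

//' @name sw_score_batch
//' @title Batch Smith-Waterman scores without traceback (internal)
//' @noRd
// [[Rcpp::export(rng = false)]]
NumericVector sw_score_batch(CharacterVector a, CharacterVector b,
                             double gap_open, double gap_extend) {
  if (a.size() != b.size()) stop("sequence vectors must have equal length");
  int np = a.size();
  NumericVector score(np);
  for (int p = 0; p < np; ++p) {
    std::vector<int> ea = encode(as<std::string>(a[p]));
    std::vector<int> eb = encode(as<std::string>(b[p]));
    if (ea.empty() || eb.empty()) stop("empty protein sequence in pair %d", p + 1);
    score[p] = sw_score_one(ea, eb, gap_open, gap_extend);
  }
  return score;
}

//' @name sw_align_batch
//' @title Batch Smith-Waterman alignment (internal)
//' @param a,b character vectors of equal length: protein sequence pairs
//' @param gap_open,gap_extend affine gap penalties (positive numbers)
//' @return data.frame with score, similarity, aln_len per pair
//' @noRd
// [[Rcpp::export(rng = false)]]
DataFrame sw_align_batch(CharacterVector a, CharacterVector b,
                         double gap_open, double gap_extend) {
  if (a.size() != b.size()) stop("sequence vectors must have equal length");
  int np = a.size();
  NumericVector score(np), sim(np);
  IntegerVector alen(np);
  for (int p = 0; p < np; ++p) {
    std::vector<int> ea = encode(as<std::string>(a[p]));
    std::vector<int> eb = encode(as<std::string>(b[p]));
    if (ea.empty() || eb.empty()) stop("empty protein sequence in pair %d", p + 1);
    SWResult r = sw_one(ea, eb, gap_open, gap_extend);
    score[p] = r.score; sim[p] = r.similarity; alen[p] = r.aln_len;
  }
  return DataFrame::create(_["raw_score"] = score, _["similarity"] = sim,
                           _["aln_len"] = alen);
}

//' @name count_shared_kmer_pairs
//' @title Candidate pairs sharing at least min_shared distinct k-mers
//' @param gene integer gene index per (gene, k-mer) record
//' @param kmer integer k-mer code per record (records unique per gene)
//' @param min_shared minimum number of shared k-mers
//' @return data.frame with columns i, j (1-based gene indices, i < j)
//' @noRd
// [[Rcpp::export(rng = false)]]
DataFrame count_shared_kmer_pairs(IntegerVector gene, IntegerVector kmer,
                                  int min_shared) {
  int nrec = gene.size();
  if (kmer.size() != nrec) stop("gene/kmer length mismatch");
  // bucket record indices by k-mer code
  std::unordered_map< int, std::vector<int> > buckets;
  buckets.reserve(nrec);
  for (int r = 0; r < nrec; ++r) buckets[kmer[r]].push_back(gene[r]);
  std::unordered_map<long long, int> paircount;
  for (auto& kv : buckets) {
    std::vector<int>& g = kv.second;
    size_t sz = g.size();
    if (sz < 2) continue;
    std::sort(g.begin(), g.end());
    for (size_t a = 0; a + 1 < sz; ++a) {
      for (size_t b = a + 1; b < sz; ++b) {
        if (g[a] == g[b]) continue;
        long long code = (long long)g[a] * 2000000000LL + g[b];
        ++paircount[code];
      }
    }
  }
  std::vector<int> vi, vj;
  for (auto& kv : paircount) {
    if (kv.second >= min_shared) {
      vi.push_back((int)(kv.first / 2000000000LL));
      vj.push_back((int)(kv.first % 2000000000LL));
    }
  }
  return DataFrame::create(_["i"] = wrap(vi), _["j"] = wrap(vj));
}

//' @name blosum62_matrix
//' @title BLOSUM62 scores as a 20x20 integer matrix (internal)
//' @noRd
// [[Rcpp::export(rng = false)]]
IntegerMatrix blosum62_matrix() {
  IntegerMatrix out(AA_N, AA_N);
  CharacterVector nm(AA_N);
  for (int i = 0; i < AA_N; ++i) {
    nm[i] = std::string(1, AA_ORDER[i]);
    for (int j = 0; j < AA_N; ++j) out(i, j) = BLOSUM62[i][j];
  }
  out.attr("dimnames") = List::create(nm, nm);
  return out;
}
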