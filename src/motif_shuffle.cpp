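// Dinucleotide-preserving sequence shuffling (Altschul-Erickson: a random
// Eulerian walk over the dinucleotide multigraph) and RRACH pentamer
// counting. Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <string>
#include <vector>
#include <array>
using namespace Rcpp;

static inline bool is_R(char c) { return c == 'A' || c == 'G'; }
static inline bool is_H(char c) { return c == 'A' || c == 'C' || c == 'T'; }

// number of RRACH matches in one sequence
static int rrach_count(const std::string& s) {
  int n = 0;
  if (s.size() < 5) return 0;
  for (size_t i = 0; i + 4 < s.size(); ++i) {
    if (is_R(s[i]) && is_R(s[i + 1]) && s[i + 2] == 'A' && s[i + 3] == 'C' &&
        is_H(s[i + 4]))
      ++n;
  }
  return n;
}

static inline int rint_below(int n) {
  // uniform integer in [0, n)
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// one dinucleotide-preserving shuffle of s
static std::string dinuc_shuffle_one(const std::string& s) {
  const size_t L = s.size();
  if (L < 3) return s;
  // map characters to vertex ids
  std::array<int, 256> vid;
  vid.fill(-1);
  std::vector<char> letter;
  std::vector<std::vector<int> > edges;  // successor vertex ids
  for (size_t i = 0; i < L; ++i) {
    unsigned char c = s[i];
    if (vid[c] < 0) {
      vid[c] = (int)letter.size();
      letter.push_back(s[i]);
      edges.push_back(std::vector<int>());
    }
  }
  const int nv = (int)letter.size();
  if (nv == 1) return s;
  for (size_t i = 0; i + 1 < L; ++i)
    edges[vid[(unsigned char)s[i]]].push_back(vid[(unsigned char)s[i + 1]]);
  const int root = vid[(unsigned char)s[L - 1]];
  // choose a random last edge per non-root vertex until they form an
  // in-tree rooted at the final character (Altschul-Erickson condition)
  std::vector<int> last(nv, -1);
  for (int attempt = 0; attempt < 10000; ++attempt) {
    for (int v = 0; v < nv; ++v) {
      last[v] = -1;
      if (v != root && !edges[v].empty())
        last[v] = edges[v][rint_below((int)edges[v].size())];
    }
    bool ok = true;
    for (int v = 0; v < nv && ok; ++v) {
      if (v == root || edges[v].empty()) continue;
      int cur = v;
      int steps = 0;
      while (cur != root && steps++ <= nv) {
        if (cur < 0 || last[cur] < 0) { ok = false; break; }
        cur = last[cur];
      }
      if (cur != root) ok = false;
    }
    if (ok) break;
    if (attempt == 9999) return s;  // degenerate; keep original
  }
  // permute the remaining edges of each vertex, append the last edge
  std::vector<std::vector<int> > out(nv);
  for (int v = 0; v < nv; ++v) {
    std::vector<int> rest;
    rest.reserve(edges[v].size());
    bool removed = false;
    for (size_t j = 0; j < edges[v].size(); ++j) {
      if (!removed && last[v] >= 0 && edges[v][j] == last[v]) {
        removed = true;
        continue;
      }
      rest.push_back(edges[v][j]);
    }
    for (int j = (int)rest.size() - 1; j > 0; --j)
      std::swap(rest[j], rest[rint_below(j + 1)]);
    if (last[v] >= 0) rest.push_back(last[v]);
    out[v] = rest;
  }
  // walk the Eulerian path from the first character
  std::string res;
  res.reserve(L);
  std::vector<size_t> ptr(nv, 0);
  int cur = vid[(unsigned char)s[0]];
  res.push_back(letter[cur]);
  for (size_t i = 1; i < L; ++i) {
    int nxt = out[cur][ptr[cur]++];
    res.push_back(letter[nxt]);
    cur = nxt;
  }
  return res;
}

//' RRACH pentamer matches per sequence
//'
//' Counts occurrences of the m6A consensus RRACH (R = A/G, H = A/C/T) on
//' the given DNA strings.
//'
//' @param seqs character vector of DNA sequences.
//' @return Integer vector of match counts.
//' @export
// [[Rcpp::export]]
IntegerVector count_rrach(CharacterVector seqs) {
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = rrach_count(as<std::string>(seqs[i]));
  return out;
}

//' Dinucleotide-preserving shuffle
//'
//' Returns one random shuffle of each sequence preserving its exact
//' dinucleotide (and hence mononucleotide) composition, via a random
//' Eulerian walk over the dinucleotide multigraph. Draws from R's RNG.
//'
//' @param seqs character vector of DNA sequences.
//' @return Character vector of shuffled sequences.
//' @export
// [[Rcpp::export]]
CharacterVector dinuc_shuffle(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = dinuc_shuffle_one(as<std::string>(seqs[i]));
  return out;
}

//' Null distribution of RRACH window hits under dinucleotide shuffling
//'
//' For each of \code{n_shuffles} rounds, shuffles every window
//' (dinucleotide-preserving) and counts how many windows contain at least
//' one RRACH match.
//'
//' @param seqs character vector of window sequences.
//' @param n_shuffles number of shuffle rounds.
//' @return Integer vector (length \code{n_shuffles}) of window-hit counts.
//' @export
// [[Rcpp::export]]
IntegerVector rrach_null_hits(CharacterVector seqs, int n_shuffles) {
  IntegerVector out(n_shuffles);
  std::vector<std::string> ss(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    ss[i] = as<std::string>(seqs[i]);
  for (int b = 0; b < n_shuffles; ++b) {
    int hits = 0;
    for (size_t i = 0; i < ss.size(); ++i)
      if (rrach_count(dinuc_shuffle_one(ss[i])) > 0) ++hits;
    out[b] = hits;
  }
  return out;
}
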