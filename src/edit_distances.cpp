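#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Classic Wagner-Fischer Levenshtein distance, two-row rolling buffer.
static int lev_one(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, sub});
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Optimal string alignment distance: Levenshtein plus transposition of
// adjacent characters (each substring edited at most once).
static int osa_one(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<std::vector<int>> d(la + 1, std::vector<int>(lb + 1));
  for (int i = 0; i <= la; ++i) d[i][0] = i;
  for (int j = 0; j <= lb; ++j) d[0][j] = j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int cost = a[i - 1] != b[j - 1];
      d[i][j] = std::min({d[i - 1][j] + 1, d[i][j - 1] + 1,
                          d[i - 1][j - 1] + cost});
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d[i][j] = std::min(d[i][j], d[i - 2][j - 2] + 1);
    }
  }
  return d[la][lb];
}

// Length of the longest common subsequence.
static int lcs_one(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 || lb == 0) return 0;
  std::vector<int> prev(lb + 1, 0), cur(lb + 1, 0);
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Jaro similarity; matching window floor(max(la,lb)/2) - 1.
static double jaro_one(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  const int window = std::max(0, std::max(la, lb) / 2 - 1);
  std::vector<bool> am(la, false), bm(lb, false);
  int matches = 0;
  for (int i = 0; i < la; ++i) {
    int lo = std::max(0, i - window), hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] = bm[j] = true;
        ++matches;
        break;
      }
    }
  }
  if (matches == 0) return 0.0;
  int t = 0, k = 0;
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[k]) ++k;
    if (a[i] != b[k]) ++t;
    ++k;
  }
  double m = matches;
  return (m / la + m / lb + (m - t / 2.0) / m) / 3.0;
}

// [[Rcpp::export(name = ".lev_distance_cpp")]]
IntegerVector lev_distance_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lev_one(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// [[Rcpp::export(name = ".osa_distance_cpp")]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = osa_one(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// [[Rcpp::export(name = ".lcs_length_cpp")]]
IntegerVector lcs_length_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lcs_one(as<std::string>(a[i]), as<std::string>(b[i]));
  return out;
}

// [[Rcpp::export(name = ".jaro_winkler_cpp")]]
NumericVector jaro_winkler_cpp(CharacterVector a, CharacterVector b,
                               double prefix_scale, int max_prefix) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    double j = jaro_one(sa, sb);
    int l = 0;
    int lim = std::min({(int)sa.size(), (int)sb.size(), max_prefix});
    while (l < lim && sa[l] == sb[l]) ++l;
    out[i] = j + l * prefix_scale * (1.0 - j);
  }
  return out;
}
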