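#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Decode UTF-8 bytes to code points so edits are counted per character,
// not per byte. Invalid bytes are kept as-is (one unit each).
static std::vector<uint32_t> utf8_codepoints(const char *s) {
  std::vector<uint32_t> out;
  const unsigned char *p = reinterpret_cast<const unsigned char *>(s);
  while (*p) {
    uint32_t cp;
    int extra;
    if (*p < 0x80) { cp = *p; extra = 0; }
    else if ((*p >> 5) == 0x6) { cp = *p & 0x1F; extra = 1; }
    else if ((*p >> 4) == 0xE) { cp = *p & 0x0F; extra = 2; }
    else if ((*p >> 3) == 0x1E) { cp = *p & 0x07; extra = 3; }
    else { out.push_back(*p++); continue; }
    ++p;
    for (int k = 0; k < extra; ++k) {
      if ((*p & 0xC0) != 0x80) break;
      cp = (cp << 6) | (*p & 0x3F);
      ++p;
    }
    out.push_back(cp);
  }
  return out;
}

// Classic two-row dynamic programme over the edit recursion with base case
// max(i, j) when min(i, j) = 0 and unit substitution cost when characters
// differ.
static int lev_one(const std::vector<uint32_t> &a,
                   const std::vector<uint32_t> &b) {
  const size_t la = a.size(), lb = b.size();
  if (la == 0) return static_cast<int>(lb);
  if (lb == 0) return static_cast<int>(la);
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (size_t j = 0; j <= lb; ++j) prev[j] = static_cast<int>(j);
  for (size_t i = 1; i <= la; ++i) {
    cur[0] = static_cast<int>(i);
    for (size_t j = 1; j <= lb; ++j) {
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int m = del < ins ? del : ins;
      cur[j] = m < sub ? m : sub;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".lev_distance_cpp")]]
IntegerVector lev_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = na > nb ? na : nb;
  if (na == 0 || nb == 0) return IntegerVector(0);
  IntegerVector out(n);
  // cache decoding of the shorter (typically recycled) side
  if (nb == 1) {
    std::vector<uint32_t> bv = utf8_codepoints(Rf_translateCharUTF8(b[0]));
    for (R_xlen_t i = 0; i < n; ++i) {
      if (a[i % na] == NA_STRING || b[0] == NA_STRING) { out[i] = NA_INTEGER; continue; }
      out[i] = lev_one(utf8_codepoints(Rf_translateCharUTF8(a[i % na])), bv);
    }
    return out;
  }
  if (na == 1) {
    std::vector<uint32_t> av = utf8_codepoints(Rf_translateCharUTF8(a[0]));
    for (R_xlen_t i = 0; i < n; ++i) {
      if (a[0] == NA_STRING || b[i % nb] == NA_STRING) { out[i] = NA_INTEGER; continue; }
      out[i] = lev_one(av, utf8_codepoints(Rf_translateCharUTF8(b[i % nb])));
    }
    return out;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i % na] == NA_STRING || b[i % nb] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = lev_one(utf8_codepoints(Rf_translateCharUTF8(a[i % na])),
                     utf8_codepoints(Rf_translateCharUTF8(b[i % nb])));
  }
  return out;
}
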