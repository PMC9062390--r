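#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// FNV-1a, 64-bit: offset basis 14695981039346656037, prime 1099511628211.
// Fixed here so fingerprints are bit-exact across platforms and sessions.
static inline uint64_t fnv1a64(const char *s) {
  uint64_t h = 14695981039346656037ULL;
  for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
    h ^= (uint64_t)(*p);
    h *= 1099511628211ULL;
  }
  return h;
}

// [[Rcpp::export(name = ".fnv1a64_hex")]]
CharacterVector fnv1a64_hex(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::snprintf(buf, sizeof(buf), "%016llx",
                  (unsigned long long)fnv1a64(CHAR(x[i])));
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export(name = ".fnv1a64_mod")]]
IntegerVector fnv1a64_mod(CharacterVector x, int mod) {
  if (mod <= 0) stop("mod must be positive");
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    out[i] = (int)(fnv1a64(CHAR(x[i])) % (uint64_t)mod);
  }
  return out;
}
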