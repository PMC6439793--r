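#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finalizer: strong avalanche, cheap, and stable across platforms.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// FNV-1a over the canonical token bytes:
//   accession bytes | 0x00 separator | chunk as 8-byte big-endian.
// The separator plus fixed-width chunk makes the encoding injective, so
// ("AB", 1) and ("A", <anything>) can never collide at the byte level.
// The seed perturbs the offset basis through splitmix64 so that distinct
// seeds give effectively independent hash functions.
//
// Output: the top 53 bits of the 64-bit mixed state, returned as a double.
// 53-bit integers are exactly representable in IEEE doubles, so sorting,
// set membership and decimal serialization in R are all bit-exact.
// [[Rcpp::export(name = ".hash_tokens_cpp")]]
NumericVector hash_tokens_cpp(CharacterVector protein_id, NumericVector chunk,
                              double seed) {
  const uint64_t FNV_OFFSET = 14695981039346656037ULL;
  const uint64_t FNV_PRIME  = 1099511628211ULL;
  R_xlen_t m = protein_id.size();
  if (chunk.size() != m) stop("protein_id and chunk must have equal length");
  uint64_t seeded_offset = FNV_OFFSET ^ splitmix64((uint64_t)seed);
  NumericVector out(m);
  for (R_xlen_t k = 0; k < m; ++k) {
    uint64_t h = seeded_offset;
    const char *p = CHAR(STRING_ELT(protein_id, k));
    for (; *p; ++p) {
      h ^= (uint8_t)(*p);
      h *= FNV_PRIME;
    }
    h *= FNV_PRIME; // separator byte 0x00 (XOR with 0 is a no-op)
    uint64_t c = (uint64_t)chunk[k];
    for (int b = 7; b >= 0; --b) {
      h ^= (uint8_t)((c >> (8 * b)) & 0xFFULL);
      h *= FNV_PRIME;
    }
    out[k] = (double)(splitmix64(h) >> 11);
  }
  return out;
}
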