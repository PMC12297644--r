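#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Exact modular arithmetic for moduli up to 52 bits, so that every value
// round-trips through an R double without loss. Intermediates use
// unsigned __int128.

static const double MAX_SAFE = 4503599627370496.0; // 2^52

static uint64_t as_u64(double x, const char* what) {
  if (!R_finite(x) || x < 0 || x > MAX_SAFE || x != std::floor(x))
    stop("%s must be a non-negative integer-valued double below 2^52", what);
  return (uint64_t)x;
}

static uint64_t mulmod_u64(uint64_t a, uint64_t b, uint64_t n) {
  return (uint64_t)(((unsigned __int128)a * b) % n);
}

static uint64_t powmod_u64(uint64_t b, uint64_t e, uint64_t n) {
  if (n == 1) return 0;
  uint64_t r = 1;
  b %= n;
  while (e > 0) {
    if (e & 1) r = mulmod_u64(r, b, n);
    b = mulmod_u64(b, b, n);
    e >>= 1;
  }
  return r;
}

// [[Rcpp::export(name = ".mod_mul")]]
NumericVector mod_mul_cpp(NumericVector a, NumericVector b, double n) {
  uint64_t nn = as_u64(n, "modulus");
  if (nn == 0) stop("modulus must be positive");
  R_xlen_t len = std::max(a.size(), b.size());
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    uint64_t ai = as_u64(a[i % a.size()], "a") % nn;
    uint64_t bi = as_u64(b[i % b.size()], "b") % nn;
    out[i] = (double)mulmod_u64(ai, bi, nn);
  }
  return out;
}

// [[Rcpp::export(name = ".mod_pow")]]
NumericVector mod_pow_cpp(NumericVector b, double e, double n) {
  uint64_t nn = as_u64(n, "modulus");
  uint64_t ee = as_u64(e, "exponent");
  if (nn == 0) stop("modulus must be positive");
  NumericVector out(b.size());
  for (R_xlen_t i = 0; i < b.size(); ++i)
    out[i] = (double)powmod_u64(as_u64(b[i], "base") % nn, ee, nn);
  return out;
}

// extended gcd on signed 128-bit; returns gcd and x with a*x = g (mod n)
// [[Rcpp::export(name = ".mod_inv")]]
double mod_inv_cpp(double a, double n) {
  uint64_t nn = as_u64(n, "modulus");
  uint64_t aa = as_u64(a, "a") % nn;
  __int128 old_r = (__int128)aa, r = (__int128)nn;
  __int128 old_s = 1, s = 0;
  while (r != 0) {
    __int128 q = old_r / r;
    __int128 tmp = old_r - q * r; old_r = r; r = tmp;
    tmp = old_s - q * s; old_s = s; s = tmp;
  }
  if (old_r != 1) return -1.0; // not invertible
  __int128 inv = old_s % (__int128)nn;
  if (inv < 0) inv += (__int128)nn;
  return (double)(uint64_t)inv;
}

// [[Rcpp::export(name = ".gcd_u64")]]
double gcd_cpp(double a, double b) {
  uint64_t x = as_u64(a, "a"), y = as_u64(b, "b");
  while (y) { uint64_t t = x % y; x = y; y = t; }
  return (double)x;
}

// deterministic Miller-Rabin, valid for all n < 3.3e24 with these bases
// [[Rcpp::export(name = ".is_prime")]]
bool is_prime_cpp(double n) {
  uint64_t nn = as_u64(n, "n");
  if (nn < 2) return false;
  for (uint64_t p : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL,
                     19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    if (nn == p) return true;
    if (nn % p == 0) return false;
  }
  uint64_t d = nn - 1;
  int s = 0;
  while ((d & 1) == 0) { d >>= 1; ++s; }
  for (uint64_t a : {2ULL, 3ULL, 5ULL, 7ULL, 11ULL, 13ULL, 17ULL,
                     19ULL, 23ULL, 29ULL, 31ULL, 37ULL}) {
    uint64_t x = powmod_u64(a % nn, d, nn);
    if (x == 1 || x == nn - 1) continue;
    bool composite = true;
    for (int i = 1; i < s; ++i) {
      x = mulmod_u64(x, x, nn);
      if (x == nn - 1) { composite = false; break; }
    }
    if (composite) return false;
  }
  return true;
}
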