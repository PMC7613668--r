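#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Saturating add into a 32-bit accumulator. The running sum is clamped to
// the int32 range after every addition, mirroring an embedded MAC unit that
// saturates instead of wrapping.
static inline int64_t sat_add32(int64_t acc, int64_t term, int *nsat) {
  acc += term;
  if (acc > INT32_MAX) { acc = INT32_MAX; (*nsat)++; }
  else if (acc < INT32_MIN) { acc = INT32_MIN; (*nsat)++; }
  return acc;
}

// Arithmetic right shift with round-half-away-from-zero.
static inline int64_t rshift_round(int64_t v, int shift) {
  if (shift <= 0) return v;
  int64_t half = (int64_t)1 << (shift - 1);
  if (v >= 0) return (v + half) >> shift;
  return -((-v + half) >> shift);
}

// Direct Form I biquad cascade in 16-bit/32-bit fixed point.
// coef: 5 x S integer matrix, rows b0,b1,b2,a1,a2 in Q(shift) format.
// x: int16-range input samples. Each section's shifted output is clamped to
// int16 before feeding the next section. Returns the final section output
// and the saturation-event count.
// [[Rcpp::export]]
List df1_cascade_fixed_cpp(IntegerVector x, IntegerMatrix coef, int shift) {
  const int n = x.size(), S = coef.ncol();
  IntegerVector y(n);
  int nsat = 0;
  std::vector<int64_t> in(n);
  for (int i = 0; i < n; ++i) in[i] = x[i];
  for (int s = 0; s < S; ++s) {
    const int64_t b0 = coef(0, s), b1 = coef(1, s), b2 = coef(2, s);
    const int64_t a1 = coef(3, s), a2 = coef(4, s);
    int64_t x1 = 0, x2 = 0, y1 = 0, y2 = 0;
    for (int i = 0; i < n; ++i) {
      int64_t acc = 0;
      acc = sat_add32(acc, b0 * in[i], &nsat);
      acc = sat_add32(acc, b1 * x1, &nsat);
      acc = sat_add32(acc, b2 * x2, &nsat);
      acc = sat_add32(acc, -a1 * y1, &nsat);
      acc = sat_add32(acc, -a2 * y2, &nsat);
      int64_t out = rshift_round(acc, shift);
      if (out > 32767) { out = 32767; nsat++; }
      else if (out < -32768) { out = -32768; nsat++; }
      x2 = x1; x1 = in[i];
      y2 = y1; y1 = out;
      in[i] = out;
    }
  }
  for (int i = 0; i < n; ++i) y[i] = (int)in[i];
  return List::create(_["y"] = y, _["saturations"] = nsat);
}

// Fixed-point rectify + exponential moving average envelope.
// State is held in a 32-bit register with `frac` fractional bits so the
// envelope does not dead-band at small amplitudes. Per sample:
//   s += round((|x| << frac) - s) / decay
// with the division implemented as a rounded right shift when decay is a
// power of two. Returns the envelope in input LSB units (double).
// [[Rcpp::export]]
NumericVector ema_envelope_fixed_cpp(IntegerVector x, int decay, int frac) {
  const int n = x.size();
  NumericVector env(n);
  int64_t s = 0;
  int shift = -1;
  if (decay > 0 && (decay & (decay - 1)) == 0) {
    shift = 0;
    while ((1 << shift) < decay) shift++;
  }
  for (int i = 0; i < n; ++i) {
    int64_t ax = x[i] < 0 ? -(int64_t)x[i] : (int64_t)x[i];
    int64_t delta = (ax << frac) - s;
    int64_t step;
    if (shift >= 0) step = rshift_round(delta, shift);
    else step = delta >= 0 ? (2 * delta + decay) / (2 * decay)
                           : -((-2 * delta + decay) / (2 * decay));
    s += step;
    if (s > INT32_MAX) s = INT32_MAX;
    if (s < INT32_MIN) s = INT32_MIN;
    env[i] = (double)s / (double)((int64_t)1 << frac);
  }
  return env;
}
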