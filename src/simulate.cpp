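#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Forward simulation of the multi-source SPAD noise model, one frame at a
// time. Per frame, per pixel, in fixed order:
//   primary  = Bernoulli(1 - exp(-pde*chi)) OR Bernoulli(1 - exp(-dcr))
//   afterpulse (n >= 1) = Bernoulli(p_ap) conditioned on the previous frame
//                          firing at the same pixel (one-frame memory)
//   crosstalk = OR over firing 4- (or 8-) connected neighbours' primary or
//               afterpulse events, each triggering independently with the
//               receiving pixel's p_ct; single pass, so crosstalk events do
//               not seed further crosstalk
//   frame value = OR of all events.
//
// Uses R's RNG stream (seeded by the caller with set.seed) and draws a fixed
// number of uniforms per frame -- h*w each for shot, dark and afterpulse plus
// n_neigh*h*w for crosstalk, pixels in column-major order -- so the stream is
// identical for identical seeds regardless of parameter values.
// [[Rcpp::export(name = ".simulate_frames_cpp")]]
IntegerVector simulate_frames_cpp(NumericMatrix chi, NumericMatrix pde,
                                  NumericMatrix dcr, NumericMatrix p_ap,
                                  NumericMatrix p_ct, int n_frames,
                                  int neighborhood) {
  const int h = chi.nrow(), w = chi.ncol();
  const R_xlen_t hw = (R_xlen_t)h * w;
  IntegerVector out((R_xlen_t)n_frames * hw);

  std::vector<double> p_shot(hw), p_dark(hw);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      R_xlen_t i = y + (R_xlen_t)h * x;
      p_shot[i] = 1.0 - std::exp(-pde(y, x) * chi(y, x));
      p_dark[i] = 1.0 - std::exp(-dcr(y, x));
    }

  // neighbour offsets (dy, dx): 4-connected, then diagonals for 8-connected
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int n_neigh = (neighborhood == 8) ? 8 : 4;

  std::vector<double> u_shot(hw), u_dark(hw), u_ap(hw), u_ct(hw * n_neigh);
  std::vector<int> seed_ev(hw), prev(hw, 0), cur(hw);

  RNGScope scope;
  for (int f = 0; f < n_frames; ++f) {
    for (R_xlen_t i = 0; i < hw; ++i) u_shot[i] = unif_rand();
    for (R_xlen_t i = 0; i < hw; ++i) u_dark[i] = unif_rand();
    for (R_xlen_t i = 0; i < hw; ++i) u_ap[i] = unif_rand();
    for (int k = 0; k < n_neigh; ++k)
      for (R_xlen_t i = 0; i < hw; ++i) u_ct[k * hw + i] = unif_rand();

    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        R_xlen_t i = y + (R_xlen_t)h * x;
        int primary = (u_shot[i] < p_shot[i]) || (u_dark[i] < p_dark[i]);
        int ap = (f > 0) && prev[i] && (u_ap[i] < p_ap(y, x));
        seed_ev[i] = primary || ap;
      }

    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        R_xlen_t i = y + (R_xlen_t)h * x;
        int v = seed_ev[i];
        if (!v) {
          double pct = p_ct(y, x);
          if (pct > 0.0) {
            for (int k = 0; k < n_neigh && !v; ++k) {
              int ny = y + dy8[k], nx = x + dx8[k];
              if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
              R_xlen_t j = ny + (R_xlen_t)h * nx;
              if (seed_ev[j] && u_ct[k * hw + i] < pct) v = 1;
            }
          }
        } else {
          // a firing pixel can also receive crosstalk; the OR absorbs it
        }
        cur[i] = v;
      }

    R_xlen_t off = (R_xlen_t)f * hw;
    for (R_xlen_t i = 0; i < hw; ++i) out[off + i] = cur[i];
    prev.swap(cur);
  }

  out.attr("dim") = IntegerVector::create(h, w, n_frames);
  return out;
}

// Event classification of a dark stack: a fire is labelled afterpulse when the
// same pixel also fired in the previous frame; otherwise it is labelled
// crosstalk when any connected neighbour fires in the same frame. Afterpulse
// takes priority, so the two classes are disjoint by construction.
// [[Rcpp::export(name = ".classify_events_cpp")]]
List classify_events_cpp(IntegerVector frames, int neighborhood) {
  IntegerVector dims = frames.attr("dim");
  const int h = dims[0], w = dims[1], n = dims[2];
  const R_xlen_t hw = (R_xlen_t)h * w;
  IntegerVector i_ap((R_xlen_t)n * hw), i_ct((R_xlen_t)n * hw);

  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int n_neigh = (neighborhood == 8) ? 8 : 4;

  for (int f = 0; f < n; ++f) {
    R_xlen_t off = (R_xlen_t)f * hw;
    R_xlen_t poff = (R_xlen_t)(f - 1) * hw;
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        R_xlen_t i = y + (R_xlen_t)h * x;
        if (!frames[off + i]) continue;
        if (f > 0 && frames[poff + i]) {
          i_ap[off + i] = 1;
          continue;
        }
        for (int k = 0; k < n_neigh; ++k) {
          int ny = y + dy8[k], nx = x + dx8[k];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (frames[off + ny + (R_xlen_t)h * nx]) {
            i_ct[off + i] = 1;
            break;
          }
        }
      }
  }
  i_ap.attr("dim") = dims;
  i_ct.attr("dim") = dims;
  return List::create(_["i_ap"] = i_ap, _["i_ct"] = i_ct);
}
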