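#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation between the reference patch (precomputed,
// zero-mean) and the frame patch at integer offset (dr, dc).
static inline double ncc_at(const NumericMatrix &frame,
                            const double *refz, double refsd,
                            int r0, int c0, int box, int dr, int dc,
                            double min_sd) {
  double sum = 0.0, sum2 = 0.0;
  const int n = box * box;
  double vals[121]; // box <= 11
  int k = 0;
  for (int c = 0; c < box; ++c) {
    for (int r = 0; r < box; ++r) {
      double v = frame(r0 + dr + r, c0 + dc + c);
      vals[k++] = v;
      sum += v;
      sum2 += v * v;
    }
  }
  double mean = sum / n;
  double var = sum2 / n - mean * mean;
  if (var <= min_sd * min_sd) return NA_REAL;
  double sd = std::sqrt(var);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += refz[i] * (vals[i] - mean);
  return acc / (n * refsd * sd);
}

// Quadratic (log-parabola when possible) sub-pixel refinement along one axis
// from correlation values at -1, 0, +1 around the peak.
static inline double subpixel(double cm, double c0, double cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    double lm = std::log(cm), l0 = std::log(c0), lp = std::log(cp);
    double den = lm - 2.0 * l0 + lp;
    if (den < 0) return 0.5 * (lm - lp) / den;
  }
  double den = cm - 2.0 * c0 + cp;
  if (den < 0) return 0.5 * (cm - cp) / den;
  return 0.0;
}

// Clamped bilinear sample of a matrix at fractional (row, col).
static inline double bilin(const NumericMatrix &img, double r, double c) {
  const int H = img.nrow(), W = img.ncol();
  if (r < 0) r = 0; if (r > H - 1) r = H - 1;
  if (c < 0) c = 0; if (c > W - 1) c = W - 1;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > H - 2) r0 = H - 2;
  if (c0 > W - 2) c0 = W - 2;
  double fr = r - r0, fc = c - c0;
  return img(r0, c0) * (1 - fr) * (1 - fc) + img(r0 + 1, c0) * fr * (1 - fc) +
         img(r0, c0 + 1) * (1 - fr) * fc + img(r0 + 1, c0 + 1) * fr * fc;
}

// Iterative Gauss-Newton (Lucas-Kanade) refinement of the displacement of a
// zero-mean reference patch within the frame, starting from (dr, dc).
// Returns false if the iteration leaves the trust region.
static bool lk_refine(const NumericMatrix &ref, const NumericMatrix &frame,
                      int r0, int c0, int box, double &dr, double &dc) {
  const int n = box * box;
  std::vector<double> gx(n), gy(n), refz(n);
  double mean = 0.0;
  int k = 0;
  for (int c = 0; c < box; ++c)
    for (int r = 0; r < box; ++r) {
      refz[k] = ref(r0 + r, c0 + c);
      mean += refz[k];
      gy[k] = (bilin(ref, r0 + r + 1, c0 + c) -
               bilin(ref, r0 + r - 1, c0 + c)) / 2.0;
      gx[k] = (bilin(ref, r0 + r, c0 + c + 1) -
               bilin(ref, r0 + r, c0 + c - 1)) / 2.0;
      ++k;
    }
  mean /= n;
  for (int i = 0; i < n; ++i) refz[i] -= mean;
  double gxx = 0, gxy = 0, gyy = 0;
  for (int i = 0; i < n; ++i) {
    gxx += gx[i] * gx[i]; gxy += gx[i] * gy[i]; gyy += gy[i] * gy[i];
  }
  double det = gxx * gyy - gxy * gxy;
  if (det <= 1e-12) return false;
  const double dr0 = dr, dc0 = dc;
  for (int it = 0; it < 10; ++it) {
    double bx = 0, by = 0, fmean = 0;
    std::vector<double> fs(n);
    k = 0;
    for (int c = 0; c < box; ++c)
      for (int r = 0; r < box; ++r) {
        fs[k] = bilin(frame, r0 + r + dr, c0 + c + dc);
        fmean += fs[k];
        ++k;
      }
    fmean /= n;
    for (int i = 0; i < n; ++i) {
      double e = (fs[i] - fmean) - refz[i];
      bx += gx[i] * e; by += gy[i] * e;
    }
    double sc = -(gyy * bx - gxy * by) / det;
    double sr = -(-gxy * bx + gxx * by) / det;
    dc += sc; dr += sr;
    if (std::fabs(dr - dr0) > 1.5 || std::fabs(dc - dc0) > 1.5) {
      dr = dr0; dc = dc0;
      return false;
    }
    if (std::fabs(sc) < 1e-4 && std::fabs(sr) < 1e-4) break;
  }
  return true;
}

// Block-matching DIC of one frame against a reference image.
// centers_r / centers_c are 0-based pixel row/col indices of box centres.
// Returns per-box displacement (dx along columns, dy along rows, in px,
// frame relative to reference) and a validity flag.
// [[Rcpp::export(name = ".dic_block_match")]]
List dic_block_match(NumericMatrix ref, NumericMatrix frame,
                     IntegerVector centers_r, IntegerVector centers_c,
                     int box, int search, double min_sd) {
  const int nb = centers_r.size();
  const int half = box / 2;
  const int H = ref.nrow(), W = ref.ncol();
  NumericVector dx(nb, NA_REAL), dy(nb, NA_REAL);
  LogicalVector valid(nb, false);
  std::vector<double> refz(box * box);
  std::vector<double> cc((2 * search + 1) * (2 * search + 1));

  for (int b = 0; b < nb; ++b) {
    const int r0 = centers_r[b] - half;
    const int c0 = centers_c[b] - half;
    if (r0 - search < 0 || c0 - search < 0 ||
        r0 + box + search > H || c0 + box + search > W)
      continue; // box too close to the border for the search window
    // zero-mean reference patch and its sd
    double sum = 0.0, sum2 = 0.0;
    int k = 0;
    for (int c = 0; c < box; ++c)
      for (int r = 0; r < box; ++r) {
        double v = ref(r0 + r, c0 + c);
        refz[k++] = v;
        sum += v; sum2 += v * v;
      }
    const int n = box * box;
    double mean = sum / n;
    double var = sum2 / n - mean * mean;
    if (var <= min_sd * min_sd) continue; // textureless box
    double refsd = std::sqrt(var);
    for (int i = 0; i < n; ++i) refz[i] -= mean;

    // integer search
    int best_i = -1;
    double best = -2.0;
    const int side = 2 * search + 1;
    for (int dr = -search; dr <= search; ++dr)
      for (int dc = -search; dc <= search; ++dc) {
        double v = ncc_at(frame, refz.data(), refsd, r0, c0, box,
                          dr, dc, min_sd);
        cc[(dr + search) * side + (dc + search)] = v;
        if (!ISNAN(v) && v > best) { best = v; best_i = (dr + search) * side + (dc + search); }
      }
    if (best_i < 0 || best < 0.1) continue; // no credible correlation peak
    int pr = best_i / side, pc = best_i % side;
    if (pr == 0 || pr == side - 1 || pc == 0 || pc == side - 1)
      continue; // peak on the search border: displacement out of range
    double c0v = cc[pr * side + pc];
    double cmr = cc[(pr - 1) * side + pc], cpr = cc[(pr + 1) * side + pc];
    double cmc = cc[pr * side + pc - 1], cpc = cc[pr * side + pc + 1];
    if (ISNAN(cmr) || ISNAN(cpr) || ISNAN(cmc) || ISNAN(cpc)) continue;
    // Gauss-Newton refinement on the intensity model from the integer
    // peak; the quadratic (log-parabola) peak fit is the fallback.
    double rr = pr - search, rc = pc - search;
    if (!lk_refine(ref, frame, r0, c0, box, rr, rc)) {
      double sr = subpixel(cmr, c0v, cpr);
      double sc = subpixel(cmc, c0v, cpc);
      if (std::fabs(sr) > 1 || std::fabs(sc) > 1) { sr = 0; sc = 0; }
      rr = (pr - search) + sr;
      rc = (pc - search) + sc;
    }
    dy[b] = rr;
    dx[b] = rc;
    valid[b] = true;
  }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["valid"] = valid);
}
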