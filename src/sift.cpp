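#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Matrices are R column-major: element (r, c) is row r (y), column c (x),
// both 0-based here.  Image x = column, y = row, pixel centers at integers.

static inline int reflect(int i, int n) {
  // symmetric border: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian convolution with symmetric border handling.
// Kernel radius 4*sigma keeps truncation error below single-precision noise.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-(double)(i * i) / s2);
    sum += k[i + radius];
  }
  for (double& v : k) v /= sum;

  NumericMatrix tmp(h, w), out(h, w);
  // vertical pass (along rows within a column)
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * img(reflect(r + i, h), c);
      tmp(r, c) = acc;
    }
  // horizontal pass
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += k[i + radius] * tmp(r, reflect(c + i, w));
      out(r, c) = acc;
    }
  return out;
}

// Keep every second pixel (rows/cols 0, 2, 4, ...).
// [[Rcpp::export]]
NumericMatrix cpp_downsample(const NumericMatrix& img) {
  int h = (img.nrow() + 1) / 2, w = (img.ncol() + 1) / 2;
  NumericMatrix out(h, w);
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r)
      out(r, c) = img(2 * r, 2 * c);
  return out;
}

// Bilinear 2x upsampling (used when the first octave is pre-doubled).
// [[Rcpp::export]]
NumericMatrix cpp_upsample2(const NumericMatrix& img) {
  int h = img.nrow(), w = img.ncol();
  int H = 2 * h, W = 2 * w;
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    double x = c / 2.0;
    int x0 = std::min((int)std::floor(x), w - 1), x1 = std::min(x0 + 1, w - 1);
    double fx = x - x0;
    for (int r = 0; r < H; ++r) {
      double y = r / 2.0;
      int y0 = std::min((int)std::floor(y), h - 1), y1 = std::min(y0 + 1, h - 1);
      double fy = y - y0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Strict extrema of a DoG octave over the 26-neighbor cube: 8 neighbors in
// the same difference image, 9 below, 9 above.  Only interior intervals and
// a 1-pixel interior spatial frame are scanned.  Returns rows of
// (row, col, interval), 0-based.
// [[Rcpp::export]]
IntegerMatrix cpp_detect_extrema(const List& dogs) {
  int nlev = dogs.size();
  std::vector<NumericMatrix> D(nlev);
  for (int i = 0; i < nlev; ++i) D[i] = as<NumericMatrix>(dogs[i]);
  int h = D[0].nrow(), w = D[0].ncol();
  std::vector<int> rows, cols, levs;
  for (int s = 1; s + 1 < nlev; ++s) {
    const NumericMatrix &lo = D[s - 1], &mi = D[s], &hi = D[s + 1];
    for (int c = 1; c + 1 < w; ++c) {
      for (int r = 1; r + 1 < h; ++r) {
        double v = mi(r, c);
        bool isMax = true, isMin = true;
        for (int dc = -1; dc <= 1 && (isMax || isMin); ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            double a = lo(r + dr, c + dc), b = hi(r + dr, c + dc);
            if (v <= a || v <= b) isMax = false;
            if (v >= a || v >= b) isMin = false;
            if (dr != 0 || dc != 0) {
              double m = mi(r + dr, c + dc);
              if (v <= m) isMax = false;
              if (v >= m) isMin = false;
            }
            if (!isMax && !isMin) break;
          }
        }
        if (isMax || isMin) {
          rows.push_back(r); cols.push_back(c); levs.push_back(s);
        }
      }
    }
  }
  IntegerMatrix out(rows.size(), 3);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i]; out(i, 1) = cols[i]; out(i, 2) = levs[i];
  }
  colnames(out) = CharacterVector::create("row", "col", "interval");
  return out;
}

// Sub-pixel localization: iteratively fit a 3D quadratic to the DoG around
// the candidate and solve H * offset = -g (central differences, unit pixel
// spacing), re-centering while any offset component exceeds 0.5 up to
// maxIter times.  Output columns: refined row, col, interval (doubles),
// interpolated response, status (0 kept; 1 low contrast; 2 singular Hessian;
// 3 left the valid domain / did not converge).
// [[Rcpp::export]]
NumericMatrix cpp_localize(const List& dogs, const IntegerMatrix& cand,
                           double contrastThreshold, int maxIter) {
  int nlev = dogs.size();
  std::vector<NumericMatrix> D(nlev);
  for (int i = 0; i < nlev; ++i) D[i] = as<NumericMatrix>(dogs[i]);
  int h = D[0].nrow(), w = D[0].ncol();
  int n = cand.nrow();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("row", "col", "interval",
                                          "response", "status");
  for (int i = 0; i < n; ++i) {
    int r = cand(i, 0), c = cand(i, 1), s = cand(i, 2);
    double or_ = 0, oc = 0, os = 0;
    int status = 3;  // assume non-convergence until proven otherwise
    double dval = 0, gr = 0, gc = 0, gs = 0;
    for (int iter = 0; iter < maxIter; ++iter) {
      const NumericMatrix &lo = D[s - 1], &mi = D[s], &hi = D[s + 1];
      dval = mi(r, c);
      gc = 0.5 * (mi(r, c + 1) - mi(r, c - 1));
      gr = 0.5 * (mi(r + 1, c) - mi(r - 1, c));
      gs = 0.5 * (hi(r, c) - lo(r, c));
      double dcc = mi(r, c + 1) + mi(r, c - 1) - 2 * dval;
      double drr = mi(r + 1, c) + mi(r - 1, c) - 2 * dval;
      double dss = hi(r, c) + lo(r, c) - 2 * dval;
      double drc = 0.25 * (mi(r + 1, c + 1) - mi(r + 1, c - 1) -
                           mi(r - 1, c + 1) + mi(r - 1, c - 1));
      double dcs = 0.25 * (hi(r, c + 1) - hi(r, c - 1) -
                           lo(r, c + 1) + lo(r, c - 1));
      double drs = 0.25 * (hi(r + 1, c) - hi(r - 1, c) -
                           lo(r + 1, c) + lo(r - 1, c));
      // solve [dcc drc dcs; drc drr drs; dcs drs dss] * o = -(gc, gr, gs)
      double det = dcc * (drr * dss - drs * drs) -
                   drc * (drc * dss - drs * dcs) +
                   dcs * (drc * drs - drr * dcs);
      if (std::fabs(det) < 1e-12) { status = 2; break; }
      double b0 = -gc, b1 = -gr, b2 = -gs;
      oc = (b0 * (drr * dss - drs * drs) - drc * (b1 * dss - drs * b2) +
            dcs * (b1 * drs - drr * b2)) / det;
      or_ = (dcc * (b1 * dss - drs * b2) - b0 * (drc * dss - drs * dcs) +
             dcs * (drc * b2 - b1 * dcs)) / det;
      os = (dcc * (drr * b2 - b1 * drs) - drc * (drc * b2 - b1 * dcs) +
            b0 * (drc * drs - drr * dcs)) / det;
      if (std::fabs(oc) < 0.5 && std::fabs(or_) < 0.5 && std::fabs(os) < 0.5) {
        status = 0;
        break;
      }
      // re-center toward the fitted vertex and retry
      c += (int)std::lround(oc);
      r += (int)std::lround(or_);
      s += (int)std::lround(os);
      if (s < 1 || s + 1 >= nlev || c < 1 || c + 1 >= w || r < 1 ||
          r + 1 >= h) {
        status = 3;
        break;
      }
    }
    if (status == 0) {
      double contrast = dval + 0.5 * (gc * oc + gr * or_ + gs * os);
      if (std::fabs(contrast) < contrastThreshold) status = 1;
      out(i, 0) = r + or_;
      out(i, 1) = c + oc;
      out(i, 2) = s + os;
      out(i, 3) = contrast;
    } else {
      out(i, 0) = r; out(i, 1) = c; out(i, 2) = s; out(i, 3) = dval;
    }
    out(i, 4) = status;
  }
  return out;
}

// Principal-curvature (edge response) test on the 2x2 spatial Hessian of the
// DoG: keep iff Det > 0 and Tr^2/Det < (CE+1)^2/CE (discard at equality).
// [[Rcpp::export]]
LogicalVector cpp_edge_keep(const List& dogs, const IntegerMatrix& pts,
                            double edgeThreshold) {
  int nlev = dogs.size();
  std::vector<NumericMatrix> D(nlev);
  for (int i = 0; i < nlev; ++i) D[i] = as<NumericMatrix>(dogs[i]);
  double bound = (edgeThreshold + 1.0) * (edgeThreshold + 1.0) / edgeThreshold;
  int n = pts.nrow();
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    int r = pts(i, 0), c = pts(i, 1), s = pts(i, 2);
    const NumericMatrix& mi = D[s];
    double v = mi(r, c);
    double dxx = mi(r, c + 1) + mi(r, c - 1) - 2 * v;
    double dyy = mi(r + 1, c) + mi(r - 1, c) - 2 * v;
    double dxy = 0.25 * (mi(r + 1, c + 1) - mi(r + 1, c - 1) -
                         mi(r - 1, c + 1) + mi(r - 1, c - 1));
    double tr = dxx + dyy, det = dxx * dyy - dxy * dxy;
    keep[i] = (det > 0) && (tr * tr / det < bound);
  }
  return keep;
}

// 36-bin gradient-orientation histogram around (x, y) in octave coordinates.
// Samples are weighted by gradient magnitude and a circular Gaussian of
// width 1.5 * sigma; window radius 3 * (1.5 * sigma).
// [[Rcpp::export]]
NumericVector cpp_orientation_hist(const NumericMatrix& L, double x, double y,
                                   double sigma) {
  int h = L.nrow(), w = L.ncol();
  double sw = 1.5 * sigma;
  int radius = std::max(1, (int)std::lround(3.0 * sw));
  int cx = (int)std::lround(x), cy = (int)std::lround(y);
  double fx = x - cx, fy = y - cy;  // weight about the sub-pixel location
  NumericVector hist(36);
  double denom = 2.0 * sw * sw;
  for (int i = -radius; i <= radius; ++i) {
    int r = cy + i;
    if (r < 1 || r + 1 >= h) continue;
    for (int j = -radius; j <= radius; ++j) {
      int c = cx + j;
      if (c < 1 || c + 1 >= w) continue;
      double dx = L(r, c + 1) - L(r, c - 1);
      double dy = L(r + 1, c) - L(r - 1, c);
      double m = std::sqrt(dx * dx + dy * dy);
      if (m == 0) continue;
      double theta = std::atan2(dy, dx) * 180.0 / M_PI;
      if (theta < 0) theta += 360.0;
      double ox = j - fx, oy = i - fy;
      double wgt = m * std::exp(-(ox * ox + oy * oy) / denom);
      int bin = (int)std::floor(theta / 10.0);
      if (bin >= 36) bin = 0;
      hist[bin] += wgt;
    }
  }
  return hist;
}

// 4x4x8 = 128-element descriptor with trilinear interpolation and Gaussian
// spatial weighting; window of 4 sub-regions each 3*sigma wide, rotated by
// -orientation.  Raw histogram; normalization/clamping is done by the caller.
// [[Rcpp::export]]
NumericVector cpp_descriptor_raw(const NumericMatrix& L, double x, double y,
                                 double sigma, double oriDeg) {
  const int d = 4, nbins = 8;
  int h = L.nrow(), w = L.ncol();
  double histWidth = 3.0 * sigma;
  int radius = (int)std::lround(histWidth * std::sqrt(2.0) * (d + 1) * 0.5);
  radius = std::min(radius, (int)std::sqrt((double)h * h + (double)w * w));
  double ori = oriDeg * M_PI / 180.0;
  double cosT = std::cos(ori), sinT = std::sin(ori);
  double binsPerDeg = nbins / 360.0;
  // padded accumulator: (d+2) x (d+2) x (nbins+2), folded at the end
  std::vector<double> raw((d + 2) * (d + 2) * (nbins + 2), 0.0);
  int cx = (int)std::lround(x), cy = (int)std::lround(y);
  double fx = x - cx, fy = y - cy;  // anchor bins at the sub-pixel location
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      // rotate offsets by -orientation (x right, y down frame)
      double ox = j - fx, oy = i - fy;
      double cRot = (ox * cosT + oy * sinT) / histWidth;
      double rRot = (-ox * sinT + oy * cosT) / histWidth;
      double rbin = rRot + d / 2.0 - 0.5;
      double cbin = cRot + d / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      int r = cy + i, c = cx + j;
      if (r < 1 || r + 1 >= h || c < 1 || c + 1 >= w) continue;  // zero outside
      double dx = L(r, c + 1) - L(r, c - 1);
      double dy = L(r + 1, c) - L(r - 1, c);
      double mag = std::sqrt(dx * dx + dy * dy);
      if (mag == 0) continue;
      double theta = std::atan2(dy, dx) * 180.0 / M_PI;
      double obin = (theta - oriDeg) * binsPerDeg;
      while (obin < 0) obin += nbins;
      while (obin >= nbins) obin -= nbins;
      double wgt =
          mag * std::exp(-(cRot * cRot + rRot * rRot) / (0.5 * d * d));
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
          o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int dr = 0; dr <= 1; ++dr) {
        double wr = wgt * (dr ? fr : 1 - fr);
        int ri = r0 + dr + 1;
        for (int dc = 0; dc <= 1; ++dc) {
          double wc = wr * (dc ? fc : 1 - fc);
          int ci = c0 + dc + 1;
          for (int dob = 0; dob <= 1; ++dob) {
            double wo = wc * (dob ? fo : 1 - fo);
            raw[(ri * (d + 2) + ci) * (nbins + 2) + o0 + dob] += wo;
          }
        }
      }
    }
  }
  NumericVector out(d * d * nbins);
  for (int ri = 1; ri <= d; ++ri)
    for (int ci = 1; ci <= d; ++ci) {
      double* cell = &raw[(ri * (d + 2) + ci) * (nbins + 2)];
      cell[0] += cell[nbins];      // wrap circular orientation bins
      cell[1] += cell[nbins + 1];
      for (int o = 0; o < nbins; ++o)
        out[((ri - 1) * d + (ci - 1)) * nbins + o] = cell[o];
    }
  return out;
}
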