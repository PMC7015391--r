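#include <Rcpp.h>
using namespace Rcpp;

// Non-local means denoising on a grayscale matrix in [0,1].
//
// Fast formulation: for each displacement d in the search window the
// per-pixel squared difference image is box-filtered (summed-area
// table) to obtain all patch distances for that displacement at once,
// so the cost is O(search^2 * npixels) instead of
// O(search^2 * patch^2 * npixels). h controls the weight decay;
// patch/search are full widths (odd). Borders use replicate padding
// semantics via index clamping.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double h,
                              int patch = 5, int search = 11) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch / 2, sr = search / 2;
  const double h2 = h * h;
  const int npatch = patch * patch;

  NumericMatrix acc(nr, nc), wsum(nr, nc);
  std::vector<double> diff2((nr + 1) * (nc + 1), 0.0);

  auto clampi = [](int v, int lo, int hi) {
    return v < lo ? lo : (v > hi ? hi : v);
  };

  for (int dj = -sr; dj <= sr; ++dj) {
    for (int di = -sr; di <= sr; ++di) {
      // summed-area table of squared differences for displacement (di, dj)
      for (int j = 0; j < nc; ++j) {
        const int j2 = clampi(j + dj, 0, nc - 1);
        double* S = &diff2[(j + 1) * (nr + 1)];
        const double* Sprev = &diff2[j * (nr + 1)];
        S[0] = 0.0;
        for (int i = 0; i < nr; ++i) {
          const int i2 = clampi(i + di, 0, nr - 1);
          const double d = img(i, j) - img(i2, j2);
          S[i + 1] = S[i] + Sprev[i + 1] - Sprev[i] + d * d;
        }
      }
      // patch distance = box sum of diff2 over the patch around each pixel
      for (int j = 0; j < nc; ++j) {
        const int ja = clampi(j - pr, 0, nc - 1);
        const int jb = clampi(j + pr, 0, nc - 1);
        const double* Sa = &diff2[ja * (nr + 1)];
        const double* Sb = &diff2[(jb + 1) * (nr + 1)];
        for (int i = 0; i < nr; ++i) {
          const int ia = clampi(i - pr, 0, nr - 1);
          const int ib = clampi(i + pr, 0, nr - 1);
          const double d2 = Sb[ib + 1] - Sb[ia] - Sa[ib + 1] + Sa[ia];
          const double w = std::exp(-d2 / (h2 * npatch));
          const int i2 = clampi(i + di, 0, nr - 1);
          const int j2 = clampi(j + dj, 0, nc - 1);
          acc(i, j) += w * img(i2, j2);
          wsum(i, j) += w;
        }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = acc(i, j) / wsum(i, j);
  return out;
}
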