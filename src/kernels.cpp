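#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Dense 3-D feature-map kernels for the seed classifier. Arrays are R
// column-major with dim (C, D, H, W); kernels have dim (Cp, C, Dp, Hp, Wp).
// Valid (no-padding) convolution:
//   O[cp,i,j,k] = sum_{c,d,h,w} I[c,i+d,j+h,k+w] * K[cp,c,d,h,w] + bias[cp]

static inline int idx4(int a, int b, int c, int d, int A, int B, int C) {
  return a + A * (b + B * (c + C * d));
}

// [[Rcpp::export(name = ".conv3dFwd")]]
NumericVector conv3dFwd(NumericVector input, NumericVector kernel,
                        NumericVector bias) {
  IntegerVector di = input.attr("dim");
  IntegerVector dk = kernel.attr("dim");
  int C = di[0], D = di[1], H = di[2], W = di[3];
  int Cp = dk[0], Ck = dk[1], Dp = dk[2], Hp = dk[3], Wp = dk[4];
  if (Ck != C) stop("kernel input channels (%d) != input channels (%d)", Ck, C);
  if (Dp > D || Hp > H || Wp > W) stop("kernel larger than input");
  int Do = D - Dp + 1, Ho = H - Hp + 1, Wo = W - Wp + 1;
  NumericVector out(Cp * Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(Cp, Do, Ho, Wo);
  const double *I = input.begin(), *K = kernel.begin();
  double *O = out.begin();
  std::vector<double> acc(Cp);
  // innermost loop runs over output channels: kernel access is contiguous
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i) {
        for (int cp = 0; cp < Cp; ++cp) acc[cp] = bias[cp];
        for (int w = 0; w < Wp; ++w) {
          int offW = C * D * H * (k + w);
          for (int h = 0; h < Hp; ++h) {
            int offH = offW + C * D * (j + h);
            for (int d = 0; d < Dp; ++d) {
              int offD = offH + C * (i + d);
              int kbase = Cp * C * (d + Dp * (h + Hp * w));
              for (int c = 0; c < C; ++c) {
                double iv = I[offD + c];
                const double *kp = K + kbase + Cp * c;
                for (int cp = 0; cp < Cp; ++cp) acc[cp] += iv * kp[cp];
              }
            }
          }
        }
        double *op = O + Cp * (i + Do * (j + Ho * k));
        for (int cp = 0; cp < Cp; ++cp) op[cp] = acc[cp];
      }
  return out;
}

// Backward pass: gradients w.r.t. input, kernel and bias given gradOut.
// [[Rcpp::export(name = ".conv3dBwd")]]
List conv3dBwd(NumericVector input, NumericVector kernel, NumericVector gradOut) {
  IntegerVector di = input.attr("dim");
  IntegerVector dk = kernel.attr("dim");
  int C = di[0], D = di[1], H = di[2], W = di[3];
  int Cp = dk[0], Dp = dk[2], Hp = dk[3], Wp = dk[4];
  int Do = D - Dp + 1, Ho = H - Hp + 1, Wo = W - Wp + 1;
  NumericVector gI(C * D * H * W), gK(kernel.size()), gB(Cp);
  gI.attr("dim") = di;
  gK.attr("dim") = dk;
  const double *I = input.begin(), *K = kernel.begin(), *G = gradOut.begin();
  double *pI = gI.begin(), *pK = gK.begin();
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i) {
        const double *g = G + Cp * (i + Do * (j + Ho * k));
        for (int cp = 0; cp < Cp; ++cp) gB[cp] += g[cp];
        for (int w = 0; w < Wp; ++w) {
          int offW = C * D * H * (k + w);
          for (int h = 0; h < Hp; ++h) {
            int offH = offW + C * D * (j + h);
            for (int d = 0; d < Dp; ++d) {
              int offD = offH + C * (i + d);
              int kbase = Cp * C * (d + Dp * (h + Hp * w));
              for (int c = 0; c < C; ++c) {
                int ii = offD + c;
                double iv = I[ii];
                const double *kp = K + kbase + Cp * c;
                double *gkp = pK + kbase + Cp * c;
                double accI = 0.0;
                for (int cp = 0; cp < Cp; ++cp) {
                  accI += g[cp] * kp[cp];
                  gkp[cp] += g[cp] * iv;
                }
                pI[ii] += accI;
              }
            }
          }
        }
      }
  return List::create(_["gradInput"] = gI, _["gradKernel"] = gK,
                      _["gradBias"] = gB);
}

// Max pooling with stride = window. Windows at the far border are clipped
// (equivalent to replication padding, since replicated edge values cannot
// change a window maximum). Returns the pooled map and the flat (1-based)
// argmax index into the input for each output element.
// [[Rcpp::export(name = ".maxpool3dFwd")]]
List maxpool3dFwd(NumericVector input, IntegerVector pool) {
  IntegerVector di = input.attr("dim");
  int C = di[0], D = di[1], H = di[2], W = di[3];
  int pd = pool[0], ph = pool[1], pw = pool[2];
  int Do = (D + pd - 1) / pd, Ho = (H + ph - 1) / ph, Wo = (W + pw - 1) / pw;
  NumericVector out(C * Do * Ho * Wo);
  IntegerVector arg(out.size());
  out.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  for (int k = 0; k < Wo; ++k)
    for (int j = 0; j < Ho; ++j)
      for (int i = 0; i < Do; ++i)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; int besti = -1;
          for (int w = k * pw; w < std::min((k + 1) * pw, W); ++w)
            for (int h = j * ph; h < std::min((j + 1) * ph, H); ++h)
              for (int d = i * pd; d < std::min((i + 1) * pd, D); ++d) {
                int ii = idx4(c, d, h, w, C, D, H);
                if (input[ii] > best) { best = input[ii]; besti = ii; }
              }
          int oi = idx4(c, i, j, k, C, Do, Ho);
          out[oi] = best;
          arg[oi] = besti + 1;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3dBwd")]]
NumericVector maxpool3dBwd(NumericVector gradOut, IntegerVector argmax,
                           IntegerVector inputDim) {
  int n = inputDim[0] * inputDim[1] * inputDim[2] * inputDim[3];
  NumericVector gI(n);
  gI.attr("dim") = inputDim;
  for (int i = 0; i < gradOut.size(); ++i) gI[argmax[i] - 1] += gradOut[i];
  return gI;
}

// 8-connected component labeling of a logical matrix (iterative flood fill).
// Labels are assigned in column-major scan order of first encounter.
// [[Rcpp::export(name = ".labelComponents8")]]
IntegerMatrix labelComponents8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
      }
    }
  return lab;
}
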