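#include <Rcpp.h>
using namespace Rcpp;

// Cumulative leaf-area fraction below relative height h for the logistic
// leaf-profile model with median RLH and shape b.
static inline double profile_cdf(double h, double rlh, double b) {
  if (h <= 0.0) return 0.0;
  if (h >= 1.0) return 1.0;
  double t = std::pow((rlh * (1.0 - h)) / ((1.0 - rlh) * h), b);
  return 1.0 / (1.0 + t);
}

// Daily Beer-Lambert light partition over a horizontal torus grid and
// vertical layers. Each plant's leaf area is spread uniformly over the
// grid cells covered by its crown disc and vertically by its cumulative
// leaf profile; within each (cell, layer) element light attenuates with
// extinction coefficient k and the absorbed fraction is shared among
// plants proportionally to their leaf area in the element.
//
// Returns absorbed PAR (MJ/day) per plant and the shading intensity
// experienced at each plant's median leaf height, self-shading excluded.
// [[Rcpp::export(name = ".light_partition_cpp")]]
List light_partition_cpp(NumericVector x, NumericVector y,
                         NumericVector height, NumericVector width,
                         NumericVector leafArea, NumericVector rlh,
                         NumericVector brlh, double fieldLx, double fieldLy,
                         double cellSize, double layerSize, double k,
                         double par, int maxLayers = 0) {
  const int n = x.size();
  const int ncx = std::max(1, (int)std::lround(fieldLx / cellSize));
  const int ncy = std::max(1, (int)std::lround(fieldLy / cellSize));
  const double cw = fieldLx / ncx, ch = fieldLy / ncy;
  const double cellArea = cw * ch; // m2
  double maxH = 0.0;
  for (int i = 0; i < n; ++i) maxH = std::max(maxH, height[i]);
  // coarsen layers for tall canopies when a layer-count cap is set
  if (maxLayers > 0 && maxH / layerSize > maxLayers)
    layerSize = maxH / maxLayers;
  const int nl = std::max(1, (int)std::ceil(maxH / layerSize));
  const int ncell = ncx * ncy;

  std::vector<std::vector<int>> plant_cells(n);
  std::vector<std::vector<double>> plant_frac(n); // per-layer LAI fraction
  std::vector<int> plant_topl(n, 0);
  std::vector<double> lad((size_t)nl * ncell, 0.0);

  for (int i = 0; i < n; ++i) {
    if (height[i] <= 0.0) continue;
    double r = width[i] / 200.0; // cm diameter -> m radius
    int c0x = (int)std::floor((x[i] - r) / cw), c1x = (int)std::floor((x[i] + r) / cw);
    int c0y = (int)std::floor((y[i] - r) / ch), c1y = (int)std::floor((y[i] + r) / ch);
    std::vector<int> cells;
    for (int cx = c0x; cx <= c1x; ++cx) {
      for (int cy = c0y; cy <= c1y; ++cy) {
        double cxm = (cx + 0.5) * cw, cym = (cy + 0.5) * ch;
        double dx = cxm - x[i], dy = cym - y[i];
        if (dx * dx + dy * dy <= r * r + 1e-12) {
          int wx = ((cx % ncx) + ncx) % ncx;
          int wy = ((cy % ncy) + ncy) % ncy;
          cells.push_back(wy * ncx + wx);
        }
      }
    }
    if (cells.empty()) {
      int wx = ((int)std::floor(x[i] / cw) % ncx + ncx) % ncx;
      int wy = ((int)std::floor(y[i] / ch) % ncy + ncy) % ncy;
      cells.push_back(wy * ncx + wx);
    }
    std::sort(cells.begin(), cells.end());
    cells.erase(std::unique(cells.begin(), cells.end()), cells.end());
    plant_cells[i].swap(cells);
    if (leafArea[i] <= 0.0) continue;
    const double laiPerCell = (leafArea[i] / plant_cells[i].size()) * 1e-4 /
      cellArea;
    const int topl = std::min(nl, (int)std::ceil(height[i] / layerSize));
    plant_topl[i] = topl;
    plant_frac[i].resize(topl);
    double Fprev = 0.0;
    for (int l = 0; l < topl; ++l) {
      double ztop = std::min((double)(l + 1) * layerSize, height[i]);
      double F = profile_cdf(ztop / height[i], rlh[i], brlh[i]);
      double lai = laiPerCell * (F - Fprev);
      plant_frac[i][l] = lai;
      Fprev = F;
      if (lai <= 0.0) continue;
      for (size_t c = 0; c < plant_cells[i].size(); ++c)
        lad[(size_t)l * ncell + plant_cells[i][c]] += lai;
    }
  }

  // light at the top of each layer, from the canopy top downward, and the
  // absorbed fraction factor per (layer, cell): I_in * (1-exp(-kL)) / L
  std::vector<double> Itop((size_t)(nl + 1) * ncell);
  std::vector<double> absFac((size_t)nl * ncell, 0.0);
  for (int c = 0; c < ncell; ++c) Itop[(size_t)nl * ncell + c] = par;
  for (int l = nl - 1; l >= 0; --l) {
    for (int c = 0; c < ncell; ++c) {
      const size_t idx = (size_t)l * ncell + c;
      const double L = lad[idx];
      const double Iin = Itop[(size_t)(l + 1) * ncell + c];
      if (L > 0.0) {
        const double tr = std::exp(-k * L);
        Itop[idx] = Iin * tr;
        absFac[idx] = Iin * (1.0 - tr) / L;
      } else {
        Itop[idx] = Iin;
      }
    }
  }
  // cumulative LAI above the top of layer l (cumAbove[l] includes layer l)
  std::vector<double> cumAbove((size_t)(nl + 1) * ncell, 0.0);
  for (int l = nl - 1; l >= 0; --l)
    for (int c = 0; c < ncell; ++c)
      cumAbove[(size_t)l * ncell + c] =
        cumAbove[(size_t)(l + 1) * ncell + c] + lad[(size_t)l * ncell + c];

  NumericVector absorbed(n, 0.0), shading(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int l = 0; l < plant_topl[i]; ++l) {
      const double lai = plant_frac[i][l];
      if (lai <= 0.0) continue;
      const size_t base = (size_t)l * ncell;
      for (size_t c = 0; c < plant_cells[i].size(); ++c)
        acc += absFac[base + plant_cells[i][c]] * lai;
    }
    absorbed[i] = acc * cellArea;
  }

  // shading intensity at the plant's median leaf height, own leaves
  // excluded: s = 1 - mean over covered cells of exp(-k * otherLAIabove)
  for (int i = 0; i < n; ++i) {
    if (height[i] <= 0.0 || plant_cells[i].empty()) { shading[i] = 0.0; continue; }
    double zm = height[i] * rlh[i];
    int lz = std::min(nl - 1, std::max(0, (int)std::floor(zm / layerSize)));
    double ownAboveTot = 0.0;
    if (leafArea[i] > 0.0) {
      double Fz = profile_cdf(((double)lz + 1.0) * layerSize /
                              std::max(height[i], 1e-9), rlh[i], brlh[i]);
      ownAboveTot = (1.0 - Fz) * (leafArea[i] / plant_cells[i].size()) *
        1e-4 / cellArea;
    }
    double acc = 0.0;
    for (size_t c = 0; c < plant_cells[i].size(); ++c) {
      double other = cumAbove[(size_t)(lz + 1) * ncell + plant_cells[i][c]] -
        ownAboveTot;
      if (other < 0.0) other = 0.0;
      acc += std::exp(-k * other);
    }
    double s = 1.0 - acc / plant_cells[i].size();
    if (s < 0.0) s = 0.0;
    if (s > 1.0 - 1e-9) s = 1.0 - 1e-9;
    shading[i] = s;
  }
  return List::create(_["absorbedMJ"] = absorbed, _["shading"] = shading);
}

// Daily morphology update: interpolates the 13 stage parameters at each
// plant's continuous BBCH stage, applies the exponential shade-response
// factors and the allometric power laws, and caps dimensions at the
// species maxima. Mirrors the R-level generating laws exactly.
// [[Rcpp::export(name = ".update_morphology_cpp")]]
List update_morphology_cpp(IntegerVector sp, NumericVector stage,
                           NumericVector s, NumericVector B,
                           NumericVector tt, List stageMats,
                           NumericVector maxH, NumericVector maxW,
                           NumericVector LA0, NumericVector RGR,
                           double shadeSign) {
  NumericMatrix SLA = stageMats["SLA"], LBR = stageMats["LBR"],
    HM = stageMats["HM"], bHM = stageMats["b_HM"], WM = stageMats["WM"],
    bWM = stageMats["b_WM"], RLH = stageMats["RLH"],
    bRLH = stageMats["b_RLH"], muSLA = stageMats["mu_SLA"],
    muLBR = stageMats["mu_LBR"], muHM = stageMats["mu_HM"],
    muWM = stageMats["mu_WM"], muRLH = stageMats["mu_RLH"];
  const int n = sp.size();
  NumericVector height(n), width(n), leafArea(n), rlh(n), brlh(n);
  for (int i = 0; i < n; ++i) {
    const int r = sp[i] - 1;
    int lo = (int)std::floor(stage[i]);
    if (lo > 9) lo = 9;
    const double fr = stage[i] - lo;
    const double w1 = 1.0 - fr;
#define IP(M) (M(r, lo) * w1 + M(r, lo + 1) * fr)
    const double sf_hm = std::exp(shadeSign * IP(muHM) * s[i]);
    const double sf_wm = std::exp(shadeSign * IP(muWM) * s[i]);
    const double sf_sla = std::exp(shadeSign * IP(muSLA) * s[i]);
    const double sf_lbr = std::exp(shadeSign * IP(muLBR) * s[i]);
    const double sf_rlh = std::exp(shadeSign * IP(muRLH) * s[i]);
    double h = IP(HM) * sf_hm * std::pow(B[i], IP(bHM));
    if (h > maxH[r]) h = maxH[r];
    if (h < 1.0) h = 1.0;
    double w = IP(WM) * sf_wm * std::pow(B[i], IP(bWM));
    if (w > maxW[r]) w = maxW[r];
    if (w < 1.0) w = 1.0;
    double lbr = IP(LBR) * sf_lbr;
    if (lbr > 1.0) lbr = 1.0;
    double la = IP(SLA) * sf_sla * lbr * B[i];
    double est = LA0[r] * std::exp(std::min(RGR[r] * tt[i], std::log(4.0)));
    if (est > 4.0 * LA0[r]) est = 4.0 * LA0[r];
    if (la < est) la = est;
    double rl = IP(RLH) * sf_rlh;
    if (rl < 0.02) rl = 0.02;
    if (rl > 0.98) rl = 0.98;
    double br = IP(bRLH);
    if (br < 1.0) br = 1.0;
#undef IP
    height[i] = h; width[i] = w; leafArea[i] = la; rlh[i] = rl;
    brlh[i] = br;
  }
  return List::create(_["height"] = height, _["width"] = width,
                      _["leafArea"] = leafArea, _["rlh"] = rlh,
                      _["brlh"] = brlh);
}

// Whole daily plant update: biomass growth from absorbed PAR through the
// temperature ramp, thermal-time accumulation, BBCH stage mapping, and
// the morphology update, in one pass.
// [[Rcpp::export(name = ".daily_update_cpp")]]
List daily_update_cpp(IntegerVector sp, NumericVector s, NumericVector B0,
                      NumericVector tt0, NumericVector absorbed,
                      double temp, double RUE, List stageMats,
                      NumericVector maxH, NumericVector maxW,
                      NumericVector LA0, NumericVector RGR,
                      NumericVector baseTempDev, NumericVector tPhoto1,
                      NumericVector tPhoto2, NumericVector floweringTT,
                      NumericVector TTflo, NumericVector TTmat,
                      double shadeSign) {
  NumericMatrix SLA = stageMats["SLA"], LBR = stageMats["LBR"],
    HM = stageMats["HM"], bHM = stageMats["b_HM"], WM = stageMats["WM"],
    bWM = stageMats["b_WM"], RLH = stageMats["RLH"],
    bRLH = stageMats["b_RLH"], muSLA = stageMats["mu_SLA"],
    muLBR = stageMats["mu_LBR"], muHM = stageMats["mu_HM"],
    muWM = stageMats["mu_WM"], muRLH = stageMats["mu_RLH"];
  const int n = sp.size();
  NumericVector B(n), tt(n), stage(n), height(n), width(n), leafArea(n),
    rlh(n), brlh(n);
  bool bad = false; int badAt = -1;
  for (int i = 0; i < n; ++i) {
    const int r = sp[i] - 1;
    double fT = (temp - tPhoto1[r]) / (tPhoto2[r] - tPhoto1[r]);
    if (fT < 0.0) fT = 0.0;
    if (fT > 1.0) fT = 1.0;
    const double dB = RUE * absorbed[i] * fT;
    if (!std::isfinite(dB) && !bad) { bad = true; badAt = i + 1; }
    B[i] = B0[i] + dB;
    double inc = temp - baseTempDev[r];
    if (inc < 0.0) inc = 0.0;
    tt[i] = tt0[i] + inc;
    double st = 4.0 * std::min(tt[i] / floweringTT[r], 1.0);
    double u = (tt[i] - floweringTT[r]) / TTflo[r];
    if (u > 0.0) st += 4.0 * std::min(u, 1.0);
    double v = (tt[i] - floweringTT[r] - TTflo[r]) / TTmat[r];
    if (v > 0.0) st += 2.0 * std::min(v, 1.0);
    stage[i] = st;
    int lo = (int)std::floor(st);
    if (lo > 9) lo = 9;
    const double fr = st - lo;
    const double w1 = 1.0 - fr;
#define IP(M) (M(r, lo) * w1 + M(r, lo + 1) * fr)
    const double sf_hm = std::exp(shadeSign * IP(muHM) * s[i]);
    const double sf_wm = std::exp(shadeSign * IP(muWM) * s[i]);
    const double sf_sla = std::exp(shadeSign * IP(muSLA) * s[i]);
    const double sf_lbr = std::exp(shadeSign * IP(muLBR) * s[i]);
    const double sf_rlh = std::exp(shadeSign * IP(muRLH) * s[i]);
    double h = IP(HM) * sf_hm * std::pow(B[i], IP(bHM));
    if (h > maxH[r]) h = maxH[r];
    if (h < 1.0) h = 1.0;
    double w = IP(WM) * sf_wm * std::pow(B[i], IP(bWM));
    if (w > maxW[r]) w = maxW[r];
    if (w < 1.0) w = 1.0;
    double lbr = IP(LBR) * sf_lbr;
    if (lbr > 1.0) lbr = 1.0;
    double la = IP(SLA) * sf_sla * lbr * B[i];
    double est = LA0[r] * std::exp(std::min(RGR[r] * tt[i], std::log(4.0)));
    if (est > 4.0 * LA0[r]) est = 4.0 * LA0[r];
    if (la < est) la = est;
    double rl = IP(RLH) * sf_rlh;
    if (rl < 0.02) rl = 0.02;
    if (rl > 0.98) rl = 0.98;
    double br = IP(bRLH);
    if (br < 1.0) br = 1.0;
#undef IP
    height[i] = h; width[i] = w; leafArea[i] = la; rlh[i] = rl;
    brlh[i] = br;
  }
  return List::create(_["B"] = B, _["tt"] = tt, _["stage"] = stage,
                      _["height"] = height, _["width"] = width,
                      _["leafArea"] = leafArea, _["rlh"] = rlh,
                      _["brlh"] = brlh, _["badPlant"] = badAt);
}
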