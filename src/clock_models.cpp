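#include <Rcpp.h>
using namespace Rcpp;

// Species layout per giant cell (21 states):
//  0 wc1_gene   [wc-1^0]     1 wc1_mrna  [wc-1^r0]   2 wc1_mrna_stab [wc-1^r1]
//  3 WC1        [WC-1]       4 wc2_gene  [wc-2^0]    5 wc2_mrna      [wc-2^r]
//  6 WC2        [WC-2]       7 frq_gene_off [frq^0]  8 frq_gene_on   [frq^1]
//  9 frq_mrna   [frq^r]     10 FRQ                  11 WCC
// 12 ccg_gene_off [ccg^0]   13 ccg_gene_on [ccg^1]  14 ccg_mrna [ccg^r]
// 15 CCG                    16 ccg2_gene_off        17 ccg2_gene_on
// 18 ccg2_mrna              19 CCG2 [CCG-2]         20 S_j (intracellular signal)
// Quorum model appends one shared state S_e at the end of the vector.
//
// Rate vector layout (40 entries, see rate_names() on the R side):
enum RateIdx {
  R_A = 0, R_ABAR, R_S1, R_S3, R_S4, R_D1, R_D3, R_C1, R_L1, R_L3,
  R_D4, R_D6, R_D7, R_D8, R_C2, R_P, R_AC, R_BC, R_SC, R_LC,
  R_DCR, R_DCP, R_KS1, R_C4, R_ETA, R_ETAEXT, R_D9, R_D10,
  R_S2, R_D2, R_L2, R_D5, R_AC2, R_BC2, R_SC2, R_LC2,
  R_DCR2, R_DCP2, R_NHILL, R_MHILL, N_RATES
};

static const int NSPEC = 21;

// model: 0 = quorum (mean-field external signal S_e), 1 = contact (chain Laplacian)
static void clock_rhs(int model, const double* y, double* dy,
                      const double* r, int ncells,
                      bool printed_bracketing, bool floor_c2) {
  const double n_h = r[R_NHILL], m_h = r[R_MHILL];
  const double Se = (model == 0) ? y[NSPEC * ncells] : 0.0;

  for (int c = 0; c < ncells; ++c) {
    const double* x = y + NSPEC * c;
    double* d = dy + NSPEC * c;

    const double WCCn = std::pow(x[11], n_h);
    const double FRQm = std::pow(x[10], m_h);
    double cbind = r[R_C2] - r[R_C4] * x[20];   // signal-modulated WCC binding
    if (floor_c2 && cbind < 0.0) cbind = 0.0;
    const double assoc = cbind * x[6] * x[3];   // (C2 - C4 S_j) [WC-2][WC-1]
    const double onoff_frq = r[R_A] * x[7] * WCCn - r[R_ABAR] * x[8];
    const double onoff_ccg = r[R_AC] * x[12] * WCCn - r[R_BC] * x[13];
    const double onoff_ccg2 = r[R_AC2] * x[16] * WCCn - r[R_BC2] * x[17];

    d[0] = 0.0;                                                        // wc-1^0
    d[1] = r[R_S1] * x[0] - r[R_D1] * x[1] - r[R_C1] * x[1] * x[10];   // wc-1^r0
    d[2] = r[R_C1] * x[1] * x[10] - r[R_D7] * x[2];                    // wc-1^r1
    d[3] = r[R_L1] * x[2] - r[R_D4] * x[3] - assoc;                    // WC-1
    d[4] = 0.0;                                                        // wc-2^0
    d[5] = r[R_S2] * x[4] - r[R_D2] * x[5];                            // wc-2^r
    d[6] = r[R_L2] * x[5] - r[R_D5] * x[6] - assoc
           + r[R_P] * x[11] * FRQm;                                    // WC-2
    d[7] = -onoff_frq;                                                 // frq^0
    d[8] = onoff_frq;                                                  // frq^1
    d[9] = r[R_S3] * x[7] + r[R_S4] * x[8] - r[R_D3] * x[9];           // frq^r
    d[10] = r[R_L3] * x[9] - r[R_D6] * x[10];                          // FRQ
    d[11] = -n_h * onoff_frq - r[R_D8] * x[11] + assoc
            - r[R_P] * x[11] * FRQm;                                   // WCC
    d[12] = -onoff_ccg;                                                // ccg^0
    d[13] = onoff_ccg;                                                 // ccg^1
    d[14] = r[R_SC] * x[13] - r[R_DCR] * x[14];                        // ccg^r
    d[15] = r[R_LC] * x[14] - r[R_DCP] * x[15];                        // CCG
    d[16] = -onoff_ccg2;                                               // ccg-2^0
    d[17] = onoff_ccg2;                                                // ccg-2^1
    d[18] = r[R_SC2] * x[17] - r[R_DCR2] * x[18];                      // ccg-2^r
    d[19] = r[R_LC2] * x[18] - r[R_DCP2] * x[19];                      // CCG-2

    if (model == 0) {
      // quorum: dS_j/dt = -D9 S_j + K_S1 [CCG] + eta (S_e - S_j)
      d[20] = -r[R_D9] * x[20] + r[R_KS1] * x[15]
              + r[R_ETA] * (Se - x[20]);
    } else {
      // contact: nearest-neighbour diffusion along the chain, single-neighbour
      // coupling at the ends (conserves the diffusive exchange).
      double lap;
      if (ncells == 1) {
        lap = 0.0;
      } else if (c == 0) {
        lap = -x[20] + y[NSPEC * (c + 1) + 20];
      } else if (c == ncells - 1) {
        lap = -x[20] + y[NSPEC * (c - 1) + 20];
      } else {
        lap = -2.0 * x[20] + y[NSPEC * (c + 1) + 20] + y[NSPEC * (c - 1) + 20];
      }
      if (printed_bracketing) {
        // literal printed form: K_S1 * ([CCG] + eta * Laplacian)
        d[20] = -r[R_D9] * x[20] + r[R_KS1] * (x[15] + r[R_ETA] * lap);
      } else {
        d[20] = -r[R_D9] * x[20] + r[R_KS1] * x[15] + r[R_ETA] * lap;
      }
    }
  }

  if (model == 0) {
    // dS_e/dt = -D10 S_e + eta_ext * sum_j (S_j - S_e)
    double acc = 0.0;
    for (int c = 0; c < ncells; ++c) acc += y[NSPEC * c + 20] - Se;
    dy[NSPEC * ncells] = -r[R_D10] * Se + r[R_ETAEXT] * acc;
  }
}

// [[Rcpp::export]]
NumericVector clock_rhs_cpp(int model, NumericVector y, NumericVector rates,
                            int ncells, bool printed_bracketing,
                            bool floor_c2) {
  if (rates.size() != N_RATES) stop("rate vector must have %d entries", N_RATES);
  int nstate = NSPEC * ncells + (model == 0 ? 1 : 0);
  if (y.size() != nstate) stop("state vector must have %d entries", nstate);
  NumericVector dy(nstate);
  clock_rhs(model, y.begin(), dy.begin(), rates.begin(), ncells,
            printed_bracketing, floor_c2);
  return dy;
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients.
static const double CK_A[6] = {0.0, 0.2, 0.3, 0.6, 1.0, 0.875};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {0.2, 0, 0, 0, 0},
  {3.0 / 40.0, 9.0 / 40.0, 0, 0, 0},
  {0.3, -0.9, 1.2, 0, 0},
  {-11.0 / 54.0, 2.5, -70.0 / 27.0, 35.0 / 27.0, 0},
  {1631.0 / 55296.0, 175.0 / 512.0, 575.0 / 13824.0,
   44275.0 / 110592.0, 253.0 / 4096.0}};
static const double CK_C[6] = {37.0 / 378.0, 0.0, 250.0 / 621.0,
                               125.0 / 594.0, 0.0, 512.0 / 1771.0};
static const double CK_DC[6] = {
  37.0 / 378.0 - 2825.0 / 27648.0, 0.0,
  250.0 / 621.0 - 18575.0 / 48384.0,
  125.0 / 594.0 - 13525.0 / 55296.0,
  -277.0 / 14336.0, 512.0 / 1771.0 - 0.25};

// Adaptive RK45 integration of the clock network, sampled on t_grid.
// Returns list(y = ntime x nstate matrix, success, n_steps, message).
// [[Rcpp::export]]
List integrate_clock_cpp(int model, NumericVector rates, NumericVector y0,
                         NumericVector t_grid, double rtol, double atol,
                         bool printed_bracketing, bool floor_c2,
                         int max_steps) {
  if (rates.size() != N_RATES) stop("rate vector must have %d entries", N_RATES);
  const int nspec_total = y0.size();
  int ncells = (model == 0) ? (nspec_total - 1) / NSPEC : nspec_total / NSPEC;
  const int nt = t_grid.size();
  NumericMatrix out(nt, nspec_total);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ytmp(nspec_total), yerr(nspec_total), ynew(nspec_total);
  std::vector<std::vector<double> > k(6, std::vector<double>(nspec_total));

  for (int s = 0; s < nspec_total; ++s) out(0, s) = y[s];
  double t = t_grid[0];
  double h = (t_grid[nt - 1] - t_grid[0]) / 100.0;
  if (h <= 0) stop("t_grid must be strictly increasing");
  long nsteps = 0;
  bool ok = true;
  std::string msg = "ok";

  for (int it = 1; it < nt && ok; ++it) {
    const double t_target = t_grid[it];
    while (t < t_target) {
      if (++nsteps > max_steps) {
        ok = false;
        msg = "max step count exceeded";
        break;
      }
      if (t + h > t_target) h = t_target - t;
      // Cash-Karp stages
      clock_rhs(model, y.data(), k[0].data(), rates.begin(), ncells,
                printed_bracketing, floor_c2);
      for (int st = 1; st < 6; ++st) {
        for (int s = 0; s < nspec_total; ++s) {
          double acc = 0.0;
          for (int j = 0; j < st; ++j) acc += CK_B[st][j] * k[j][s];
          ytmp[s] = y[s] + h * acc;
        }
        clock_rhs(model, ytmp.data(), k[st].data(), rates.begin(), ncells,
                  printed_bracketing, floor_c2);
      }
      double errmax = 0.0;
      for (int s = 0; s < nspec_total; ++s) {
        double dy5 = 0.0, err = 0.0;
        for (int st = 0; st < 6; ++st) {
          dy5 += CK_C[st] * k[st][s];
          err += CK_DC[st] * k[st][s];
        }
        ynew[s] = y[s] + h * dy5;
        double sc = atol + rtol * std::max(std::fabs(y[s]), std::fabs(ynew[s]));
        errmax = std::max(errmax, std::fabs(h * err) / sc);
      }
      if (!R_finite(errmax) || !R_finite(ynew[0])) {
        // blow-up: shrink hard, give up if the step underflows
        h *= 0.1;
        if (h < 1e-12) {
          ok = false;
          msg = "integration diverged (step underflow)";
          break;
        }
        continue;
      }
      if (errmax <= 1.0) {
        t += h;
        y = ynew;
        double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
        h *= std::min(5.0, fac);
      } else {
        h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
        if (h < 1e-12) {
          ok = false;
          msg = "integration diverged (step underflow)";
          break;
        }
      }
    }
    if (ok)
      for (int s = 0; s < nspec_total; ++s) out(it, s) = y[s];
  }

  return List::create(_["y"] = out, _["success"] = ok,
                      _["n_steps"] = (double)nsteps, _["message"] = msg);
}
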