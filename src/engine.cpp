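// Fast adaptive tau-leap core for the phage/CRISPR outbreak network.
//
// The network is assembled in R (see build_reaction_network); this file
// re-evaluates the same per-channel rate laws from the channel metadata and
// advances the state with the adaptive tau-leap scheme: species-relative
// error control (Cao, Gillespie & Petzold 2006), a critical-reaction
// partition firing near-exhausted channels one event at a time, an exact-SSA
// fallback when leaping would gain little, and step-halving on any leap that
// would drive a count negative.  Uses R's RNG so set.seed() governs
// reproducibility.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum ChannelClass {
  GROW_S = 1, GROW_R, DEATH_S, DEATH_R, BURST_WT, MUT_BURST, ACQUISITION,
  ADSORB_WT, ESC_BURST_S, ESC_BURST_R, CROSS_ADSORB, AUTO_S, AUTO_R
};

struct Net {
  int n_strains, n_s, n_sp, n_ch;
  // per-strain parameters
  std::vector<double> alpha, mu, g, K, beta, b_wt, b_m, prop;
  std::vector<int> type3;
  // species indices (0-based)
  std::vector<int> iS;              // per strain
  std::vector<int> iR;              // strain-major, n_strains * n_s
  int iP;
  std::vector<int> iE;              // n_s
  // channel metadata (0-based indices; strain/spacer 0-based, -1 if absent)
  std::vector<int> cls, strain, spacer, cons1, cons2;
  // stoichiometry as per-channel update lists
  std::vector<int> up_start;        // n_ch + 1
  std::vector<int> up_idx;
  std::vector<double> up_val;
};

static Net unpack_net(const List& nc) {
  Net n;
  n.n_strains = as<int>(nc["n_strains"]);
  n.n_s = as<int>(nc["n_s"]);
  n.n_sp = as<int>(nc["n_species"]);
  n.n_ch = as<int>(nc["n_channels"]);
  NumericMatrix pm = nc["param_matrix"];  // strains x 9
  for (int s = 0; s < n.n_strains; s++) {
    n.alpha.push_back(pm(s, 0)); n.mu.push_back(pm(s, 1));
    n.g.push_back(pm(s, 2));     n.K.push_back(pm(s, 3));
    n.beta.push_back(pm(s, 4));  n.b_wt.push_back(pm(s, 5));
    n.b_m.push_back(pm(s, 6));   n.prop.push_back(pm(s, 7));
    n.type3.push_back((int)pm(s, 8));
  }
  IntegerVector iS = nc["iS"], iRv = nc["iR"], iE = nc["iE"];
  for (int s = 0; s < n.n_strains; s++) n.iS.push_back(iS[s] - 1);
  // iR arrives column-major from the R matrix (strain rows, spacer cols)
  n.iR.assign(n.n_strains * n.n_s, 0);
  for (int i = 0; i < n.n_s; i++)
    for (int s = 0; s < n.n_strains; s++)
      n.iR[s * n.n_s + i] = iRv[i * n.n_strains + s] - 1;
  n.iP = as<int>(nc["iP"]) - 1;
  for (int i = 0; i < n.n_s; i++) n.iE.push_back(iE[i] - 1);

  IntegerVector cls = nc["cls"], strain = nc["strain"], spacer = nc["spacer"],
    cons1 = nc["cons1"], cons2 = nc["cons2"],
    up_start = nc["up_start"], up_idx = nc["up_idx"];
  NumericVector up_val = nc["up_val"];
  n.cls.assign(cls.begin(), cls.end());
  for (int j = 0; j < n.n_ch; j++) {
    n.strain.push_back(strain[j] - 1);
    n.spacer.push_back(spacer[j] == NA_INTEGER ? -1 : spacer[j] - 1);
    n.cons1.push_back(cons1[j] == NA_INTEGER ? -1 : cons1[j] - 1);
    n.cons2.push_back(cons2[j] == NA_INTEGER ? -1 : cons2[j] - 1);
  }
  n.up_start.assign(up_start.begin(), up_start.end());
  n.up_idx.assign(up_idx.begin(), up_idx.end());
  n.up_val.assign(up_val.begin(), up_val.end());
  return n;
}

static void compute_rates(const Net& n, const std::vector<double>& x,
                          std::vector<double>& a) {
  double T = 0.0;
  for (int s = 0; s < n.n_strains; s++) {
    T += x[n.iS[s]];
    for (int i = 0; i < n.n_s; i++) T += x[n.iR[s * n.n_s + i]];
  }
  double P = x[n.iP];
  std::vector<double> Rtot(n.n_strains, 0.0);
  for (int s = 0; s < n.n_strains; s++)
    for (int i = 0; i < n.n_s; i++) Rtot[s] += x[n.iR[s * n.n_s + i]];

  for (int j = 0; j < n.n_ch; j++) {
    int s = n.strain[j], i = n.spacer[j];
    double S = x[n.iS[s]];
    double Ri = (i >= 0) ? x[n.iR[s * n.n_s + i]] : 0.0;
    double Ei = (i >= 0) ? x[n.iE[i]] : 0.0;
    double inf = n.beta[s] * S * P;
    double r;
    switch (n.cls[j]) {
    case GROW_S:      r = n.g[s] * S; break;
    case GROW_R:      r = n.g[s] * Ri; break;
    case DEATH_S:     r = n.g[s] * S * T / n.K[s]; break;
    case DEATH_R:     r = n.g[s] * Ri * T / n.K[s]; break;
    case BURST_WT:    r = (1.0 - n.alpha[s]) * (1.0 - n.n_s * n.mu[s]) * inf;
                      break;
    case MUT_BURST:   r = (1.0 - n.alpha[s]) * n.mu[s] * inf; break;
    case ACQUISITION: r = (n.alpha[s] / n.n_s) * inf; break;
    case ADSORB_WT:   r = n.beta[s] * P * Rtot[s]; break;
    case ESC_BURST_S: r = n.beta[s] * S * Ei; break;
    case ESC_BURST_R: r = n.beta[s] * Ei * Ri; break;
    case CROSS_ADSORB:
      r = n.beta[s] * Ei * (n.type3[s] ? Rtot[s] : Rtot[s] - Ri); break;
    case AUTO_S:      r = n.alpha[s] * n.prop[s] * S; break;
    case AUTO_R:      r = n.alpha[s] * n.prop[s] * Ri; break;
    default:          r = 0.0;
    }
    a[j] = r;
  }
}

// [[Rcpp::export(name = ".cpp_rates")]]
NumericVector cpp_rates(List net_c, NumericVector x0) {
  Net n = unpack_net(net_c);
  std::vector<double> x(x0.begin(), x0.end()), a(n.n_ch);
  compute_rates(n, x, a);
  return NumericVector(a.begin(), a.end());
}

static void apply_channel(const Net& n, std::vector<double>& x, int j,
                          double k) {
  for (int u = n.up_start[j]; u < n.up_start[j + 1]; u++)
    x[n.up_idx[u]] += n.up_val[u] * k;
}

// categorical draw proportional to w (restricted to mask if given)
static int draw_channel(const std::vector<double>& w,
                        const std::vector<char>* mask, double wsum) {
  double u = unif_rand() * wsum, c = 0.0;
  int last = -1;
  for (size_t j = 0; j < w.size(); j++) {
    if (mask && !(*mask)[j]) continue;
    if (w[j] <= 0) continue;
    c += w[j];
    last = (int)j;
    if (u <= c) return (int)j;
  }
  return last;  // numerical slack: return the last positive channel
}

static double draw_count(double lam) {
  if (lam <= 0) return 0.0;
  if (lam > 1e9) {  // normal approximation far beyond exact-Poisson range
    double k = std::floor(R::rnorm(lam, std::sqrt(lam)) + 0.5);
    return k < 0 ? 0.0 : k;
  }
  return R::rpois(lam);
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List net_c, NumericVector x0, double t0, double t_max,
                  double record_dt, double eps, double n_critical,
                  bool stop_on_phage_extinction) {
  Net n = unpack_net(net_c);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(n.n_ch), a_nc(n.n_ch), k(n.n_ch);
  std::vector<double> mu(n.n_sp), s2(n.n_sp);
  std::vector<char> crit(n.n_ch);
  std::vector<int> small_idx; small_idx.reserve(n.n_ch);
  std::vector<double> small_lam; small_lam.reserve(n.n_ch);
  double t = t0;

  std::vector<double> rec_t;
  std::vector<double> rec_x;  // column-major n_sp x n_rec
  std::vector<double> sext_t(n.n_strains, -1.0);
  std::vector< std::vector<double> > sext_x(n.n_strains);
  double peak_phage = 0.0;

  RNGScope rng;

  // helpers ---------------------------------------------------------------
  double phage_total; double bact_total;
  std::vector<char> s_alive(n.n_strains);
  for (int s = 0; s < n.n_strains; s++) s_alive[s] = x[n.iS[s]] > 0;

  // push the current state held at time tt
  // (records use a zero-order hold: a grid time between two events carries
  //  the state before the step that crossed it)
  #define PUSH(tt, xv) do { rec_t.push_back(tt); \
    for (int ii = 0; ii < n.n_sp; ii++) rec_x.push_back((xv)[ii]); } while (0)

  #define TOTALS(xv) do { phage_total = (xv)[n.iP]; bact_total = 0.0; \
    for (int ii = 0; ii < n.n_s; ii++) phage_total += (xv)[n.iE[ii]]; \
    for (int ss = 0; ss < n.n_strains; ss++) { \
      bact_total += (xv)[n.iS[ss]]; \
      for (int ii = 0; ii < n.n_s; ii++) \
        bact_total += (xv)[n.iR[ss * n.n_s + ii]]; } } while (0)

  TOTALS(x);
  peak_phage = phage_total;
  PUSH(t, x);
  double next_rec = t + record_dt;

  bool stopped = false;
  std::string abort_msg;
  double n_leaps = 0, n_exact = 0, n_rollbacks = 0, n_crit_fired = 0;

  while (t < t_max && !stopped) {
    compute_rates(n, x, a);
    double a0 = 0.0;
    bool bad = false;
    for (int j = 0; j < n.n_ch; j++) {
      if (!std::isfinite(a[j]) || a[j] < 0) { bad = true; break; }
      a0 += a[j];
    }
    if (bad) { abort_msg = "non-finite channel rate"; break; }
    if (a0 <= 0) { t = t_max; break; }

    // critical partition: channels within n_critical firings of exhausting
    // a reactant (all consuming stoichiometries are -1 in this network,
    // but the general form is used)
    double ac0 = 0.0;
    for (int j = 0; j < n.n_ch; j++) {
      double L = R_PosInf;
      if (n.cons1[j] >= 0) L = x[n.cons1[j]];
      if (n.cons2[j] >= 0 && x[n.cons2[j]] < L) L = x[n.cons2[j]];
      crit[j] = (a[j] > 0) && std::isfinite(L) && (L < n_critical);
      a_nc[j] = crit[j] ? 0.0 : a[j];
      if (crit[j]) ac0 += a[j];
    }

    // species-relative step from the non-critical channels
    std::fill(mu.begin(), mu.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int j = 0; j < n.n_ch; j++) {
      if (a_nc[j] <= 0) continue;
      for (int u = n.up_start[j]; u < n.up_start[j + 1]; u++) {
        mu[n.up_idx[u]] += n.up_val[u] * a_nc[j];
        s2[n.up_idx[u]] += n.up_val[u] * n.up_val[u] * a_nc[j];
      }
    }
    double tau1 = R_PosInf;
    for (int i = 0; i < n.n_sp; i++) {
      if (s2[i] <= 0) continue;
      double bound = eps * x[i] / 2.0;
      if (bound < 1.0) bound = 1.0;
      double c1 = bound / std::fabs(mu[i]);
      double c2 = bound * bound / s2[i];
      if (c1 < tau1) tau1 = c1;
      if (c2 < tau1) tau1 = c2;
    }

    if (tau1 < 10.0 / a0) {
      // exact steps while leaping gains little
      n_exact += 1;
      for (int it = 0; it < 50; it++) {
        double dt = R::exp_rand() / a0;
        if (t + dt > t_max) { t = t_max; break; }
        t += dt;
        int j = draw_channel(a, NULL, a0);
        // zero-order hold: grid times crossed by this event get the
        // pre-event state
        while (next_rec <= t && next_rec <= t_max) {
          PUSH(next_rec, x); next_rec += record_dt;
        }
        apply_channel(n, x, j, 1.0);
        compute_rates(n, x, a);
        a0 = 0.0;
        for (int jj = 0; jj < n.n_ch; jj++) a0 += a[jj];
        if (a0 <= 0) { t = t_max; break; }
      }
    } else {
      double tau2 = (ac0 > 0) ? R::exp_rand() / ac0 : R_PosInf;
      n_leaps += 1;
      for (;;) {
        double tau = tau1;
        bool fire_crit = false;
        if (tau2 <= tau) { tau = tau2; fire_crit = (ac0 > 0); }
        if (t_max - t <= tau) { tau = t_max - t; fire_crit = false; }

        // per-channel Poisson counts; channels with tiny expected counts are
        // drawn as one aggregated Poisson split multinomially (exact
        // superposition/thinning, and far fewer RNG calls)
        double lam_small = 0.0;
        small_idx.clear(); small_lam.clear();
        for (int j = 0; j < n.n_ch; j++) {
          double lam = a_nc[j] * tau;
          k[j] = 0.0;
          if (lam <= 0) continue;
          if (lam < 0.1) {
            small_idx.push_back(j); small_lam.push_back(lam);
            lam_small += lam;
          } else k[j] = draw_count(lam);
        }
        if (lam_small > 0) {
          int nev = (int)R::rpois(lam_small);
          if (nev > 0) {
            // prefix sums once, then binary-search each event's channel
            for (size_t q = 1; q < small_lam.size(); q++)
              small_lam[q] += small_lam[q - 1];
            for (int e = 0; e < nev; e++) {
              double u = unif_rand() * lam_small;
              size_t lo = 0, hi = small_lam.size() - 1;
              while (lo < hi) {
                size_t mid = (lo + hi) / 2;
                if (small_lam[mid] < u) lo = mid + 1; else hi = mid;
              }
              k[small_idx[lo]] += 1.0;
            }
          }
        }
        int jc = -1;
        if (fire_crit) { jc = draw_channel(a, &crit, ac0); n_crit_fired += 1; }

        bool neg = false;
        for (int j = 0; j < n.n_ch && !neg; j++) {
          if (k[j] <= 0) continue;
          apply_channel(n, x, j, k[j]);
        }
        if (jc >= 0) apply_channel(n, x, jc, 1.0);
        for (int i = 0; i < n.n_sp; i++) if (x[i] < 0) { neg = true; break; }

        if (!neg) {
          double t_new = t + tau;
          // the pre-leap state is gone; hold the post-leap state on the grid
          // (leap widths are eps-controlled, so the hold error is O(eps))
          while (next_rec <= t_new && next_rec <= t_max) {
            PUSH(next_rec, x); next_rec += record_dt;
          }
          t = t_new;
          break;
        }
        // roll back and retry with a halved leap
        for (int j = 0; j < n.n_ch; j++)
          if (k[j] > 0) apply_channel(n, x, j, -k[j]);
        if (jc >= 0) apply_channel(n, x, jc, -1.0);
        tau1 /= 2.0;
        n_rollbacks += 1;
        tau2 = R_PosInf;  // refuse the critical firing inside a half-leap
        if (tau1 < 1e-14 / a0) {
          abort_msg = "tau-leap step collapsed";
          break;
        }
      }
      if (!abort_msg.empty()) break;
    }

    TOTALS(x);
    if (phage_total > peak_phage) peak_phage = phage_total;
    for (int s = 0; s < n.n_strains; s++) {
      if (s_alive[s] && x[n.iS[s]] <= 0) {
        s_alive[s] = 0;
        sext_t[s] = t;
        sext_x[s].assign(x.begin(), x.end());
      }
    }
    // a phage population without hosts is frozen, so bacterial extinction
    // always stops the run; phage extinction stops it unless the caller
    // needs the post-clearance bacterial dynamics (competitions)
    if ((phage_total == 0 && stop_on_phage_extinction) || bact_total == 0)
      stopped = true;
  }

  if (!abort_msg.empty()) stop("%s at t = %f", abort_msg.c_str(), t);

  while (next_rec <= t && next_rec <= t_max) {
    PUSH(next_rec, x); next_rec += record_dt;
  }
  if (rec_t.empty() || t > rec_t.back()) PUSH(t, x);

  int n_rec = (int)rec_t.size();
  NumericMatrix states(n.n_sp, n_rec);
  std::copy(rec_x.begin(), rec_x.end(), states.begin());

  List sext(n.n_strains);
  for (int s = 0; s < n.n_strains; s++) {
    if (sext_t[s] >= 0)
      sext[s] = List::create(_["t"] = sext_t[s],
                             _["x"] = NumericVector(sext_x[s].begin(),
                                                    sext_x[s].end()));
    else
      sext[s] = R_NilValue;
  }

  return List::create(
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["states"] = states,
    _["t"] = t,
    _["x"] = NumericVector(x.begin(), x.end()),
    _["peak_phage"] = peak_phage,
    _["s_extinction"] = sext,
    _["counters"] = NumericVector::create(
      _["leaps"] = n_leaps, _["exact_blocks"] = n_exact,
      _["rollbacks"] = n_rollbacks, _["critical_firings"] = n_crit_fired));
}
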