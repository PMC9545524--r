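#include <Rcpp.h>
using namespace Rcpp;

// Exact SSA for one kinesin-DDB pair on a 1-D lattice.
//
// Parameter vectors (one per motor), in order:
//   0 direction, 1 step_size, 2 k_forward0, 3 k_backstep, 4 k_detach0,
//   5 f_detach (R_PosInf = ideal bond), 6 k_reattach, 7 f_stall,
//   8 stiffness, 9 superstall clamp flag (1 = clamp forward rate at
//   k_backstep beyond stall, 0 = linear continuation floored at 0)
//
// Draw order per event matches the R reference engine (draw_event):
// one uniform for the waiting time, one for the event choice, events
// enumerated forward_k, back_k, detach_k, reattach_k, forward_d,
// back_d, detach_d, reattach_d. Uses R's global RNG so that a given
// set.seed() reproduces the same trajectory in both engines.

static inline double cargo_pos(double xk, double xd, bool ak, bool ad,
                               double kapk, double kapd) {
  if (ak && ad) return (kapk * xk + kapd * xd) / (kapk + kapd);
  return ak ? xk : xd;
}

// [[Rcpp::export]]
List pair_ssa_cpp(NumericVector pk, NumericVector pd, double t_max,
                  bool attached_k0, bool attached_d0, int max_events) {
  const double dir_k = pk[0], step_k = pk[1], kf0_k = pk[2], kb_k = pk[3],
               kd0_k = pk[4], fd_k = pk[5], kr_k = pk[6], fs_k = pk[7],
               kap_k = pk[8];
  const bool clamp_k = pk[9] != 0.0;
  const double dir_d = pd[0], step_d = pd[1], kf0_d = pd[2], kb_d = pd[3],
               kd0_d = pd[4], fd_d = pd[5], kr_d = pd[6], fs_d = pd[7],
               kap_d = pd[8];
  const bool clamp_d = pd[9] != 0.0;

  if (!attached_k0 && !attached_d0)
    stop("at least one motor must start attached");

  std::vector<double> t_v, xk_v, xd_v, cg_v;
  std::vector<int> ak_v, ad_v, ev_v;
  t_v.reserve(1024); xk_v.reserve(1024); xd_v.reserve(1024);
  cg_v.reserve(1024); ak_v.reserve(1024); ad_v.reserve(1024);
  ev_v.reserve(1024);

  double t = 0.0, xk = 0.0, xd = 0.0;
  bool ak = attached_k0, ad = attached_d0;
  double cargo = cargo_pos(xk, xd, ak, ad, kap_k, kap_d);

  t_v.push_back(t); xk_v.push_back(xk); xd_v.push_back(xd);
  cg_v.push_back(cargo); ak_v.push_back(ak); ad_v.push_back(ad);
  ev_v.push_back(NA_INTEGER);

  bool terminated_early = false, truncated = false;
  double rates[8];

  while (t < t_max && (ak || ad)) {
    if ((int)t_v.size() >= max_events) { truncated = true; break; }
    cargo = cargo_pos(xk, xd, ak, ad, kap_k, kap_d);

    for (int i = 0; i < 8; ++i) rates[i] = 0.0;
    if (ak) {
      double f_lab = kap_k * (cargo - xk);
      double load = dir_k * f_lab;
      double hind = std::max(-load, 0.0);
      if (clamp_k) hind = std::min(hind, fs_k);
      rates[0] = std::max(kf0_k + (kb_k - kf0_k) * hind / fs_k, 0.0);
      rates[1] = kb_k;
      rates[2] = R_FINITE(fd_k) ? kd0_k * std::exp(std::fabs(f_lab) / fd_k)
                                : kd0_k;
    } else {
      rates[3] = kr_k;
    }
    if (ad) {
      double f_lab = kap_d * (cargo - xd);
      double load = dir_d * f_lab;
      double hind = std::max(-load, 0.0);
      if (clamp_d) hind = std::min(hind, fs_d);
      rates[4] = std::max(kf0_d + (kb_d - kf0_d) * hind / fs_d, 0.0);
      rates[5] = kb_d;
      rates[6] = R_FINITE(fd_d) ? kd0_d * std::exp(std::fabs(f_lab) / fd_d)
                                : kd0_d;
    } else {
      rates[7] = kr_d;
    }

    double total = 0.0;
    for (int i = 0; i < 8; ++i) total += rates[i];
    if (total <= 0.0) stop("total rate is zero");

    double dt = -std::log(unif_rand()) / total;
    if (t + dt > t_max) {
      // truncate the run at t_max in the unchanged state
      t = t_max;
      t_v.push_back(t); xk_v.push_back(xk); xd_v.push_back(xd);
      cg_v.push_back(cargo); ak_v.push_back(ak); ad_v.push_back(ad);
      ev_v.push_back(NA_INTEGER);
      break;
    }
    t += dt;

    double u = unif_rand() * total, acc = 0.0;
    int ev = 7;
    for (int i = 0; i < 8; ++i) {
      acc += rates[i];
      if (u <= acc) { ev = i; break; }
    }

    switch (ev) {
      case 0: xk += dir_k * step_k; break;
      case 1: xk -= dir_k * step_k; break;
      case 2: ak = false; break;
      case 3: ak = true; xk = cargo; break;
      case 4: xd += dir_d * step_d; break;
      case 5: xd -= dir_d * step_d; break;
      case 6: ad = false; break;
      case 7: ad = true; xd = cargo; break;
    }

    if (!ak && !ad) {
      terminated_early = true;
      cargo = NA_REAL;
    } else {
      cargo = cargo_pos(xk, xd, ak, ad, kap_k, kap_d);
    }
    t_v.push_back(t); xk_v.push_back(xk); xd_v.push_back(xd);
    cg_v.push_back(cargo); ak_v.push_back(ak); ad_v.push_back(ad);
    ev_v.push_back(ev + 1);
  }

  return List::create(
    _["times"] = wrap(t_v), _["pos_k"] = wrap(xk_v),
    _["pos_d"] = wrap(xd_v), _["cargo"] = wrap(cg_v),
    _["attached_k"] = wrap(ak_v), _["attached_d"] = wrap(ad_v),
    _["event"] = wrap(ev_v),
    _["terminated_early"] = terminated_early,
    _["truncated"] = truncated);
}
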