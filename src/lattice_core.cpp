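#include <Rcpp.h>
using namespace Rcpp;

// Fixed deterministic Moore-neighbourhood order: offsets scanned row-major.
static const int OFF[8][2] = {
  {-1, -1}, {-1, 0}, {-1, 1}, {0, -1}, {0, 1}, {1, -1}, {1, 0}, {1, 1}
};

static inline bool in_bounds(int x, int y, int M, int N) {
  return x >= 1 && x <= M && y >= 1 && y <= N;
}

// [[Rcpp::export]]
IntegerMatrix cpp_moore_neighbors(int x, int y, int M, int N) {
  int nx[8], ny[8], cnt = 0;
  for (int o = 0; o < 8; ++o) {
    int ax = x + OFF[o][0], ay = y + OFF[o][1];
    if (in_bounds(ax, ay, M, N)) { nx[cnt] = ax; ny[cnt] = ay; ++cnt; }
  }
  IntegerMatrix out(cnt, 2);
  for (int i = 0; i < cnt; ++i) { out(i, 0) = nx[i]; out(i, 1) = ny[i]; }
  return out;
}

// Move weights for a forager at (x, y): epsilon down-gradient, 1 flat,
// 1 + dc up-gradient; probabilities are weights normalized over the
// in-bounds neighbourhood.
// [[Rcpp::export]]
NumericVector cpp_move_weights(int x, int y, const NumericMatrix& c,
                               double eps) {
  int M = c.nrow(), N = c.ncol();
  std::vector<double> w;
  w.reserve(8);
  double c0 = c(x - 1, y - 1);
  for (int o = 0; o < 8; ++o) {
    int ax = x + OFF[o][0], ay = y + OFF[o][1];
    if (!in_bounds(ax, ay, M, N)) continue;
    double dc = c(ax - 1, ay - 1) - c0;
    double wi;
    if (dc < 0.0) wi = eps;
    else if (dc > 0.0) wi = 1.0 + dc;
    else wi = 1.0;
    w.push_back(wi);
  }
  return NumericVector(w.begin(), w.end());
}

// One beeline step: the neighbour first entered by the ray from the centre
// of (x, y) in direction (dx, dy).  Exact 45-degree exits (|dx| == |dy|)
// take the diagonal neighbour.
static inline void beeline_step(int x, int y, double dx, double dy,
                                int& ox, int& oy) {
  int sx = (dx > 0) - (dx < 0);
  int sy = (dy > 0) - (dy < 0);
  double ax = std::fabs(dx), ay = std::fabs(dy);
  if (ax > ay) { ox = x + sx; oy = y; }
  else if (ay > ax) { ox = x; oy = y + sy; }
  else { ox = x + sx; oy = y + sy; }
}

// [[Rcpp::export]]
IntegerVector cpp_carrier_step(int x, int y, int tx, int ty) {
  if (x == tx && y == ty) stop("carrier already at target; convert instead");
  int ox, oy;
  beeline_step(x, y, (double)(tx - x), (double)(ty - y), ox, oy);
  return IntegerVector::create(ox, oy);
}

// Deposition rate of a carrier at (x, y): sum over food sources of
// A * exp(-(d_k / sigma)^2) with Euclidean distance d_k.
// [[Rcpp::export]]
double cpp_deposition_rate(int x, int y, const IntegerMatrix& food,
                           double A, double sigma) {
  double s = 0.0;
  for (int k = 0; k < food.nrow(); ++k) {
    double dx = x - food(k, 0), dy = y - food(k, 1);
    double d = std::sqrt(dx * dx + dy * dy) / sigma;
    s += A * std::exp(-d * d);
  }
  return s;
}

// Forward-Euler step of the pheromone reaction-diffusion field.
// Boundary faces close the 5-point Laplacian with a ghost cell satisfying
// the Robin relation D * dc/dn_out = -c, i.e. ghost = c - dx * c / D.
// src_mode: 0 = each carrier deposits w.r.t. all sources (as printed),
//           1 = only w.r.t. the source it visited (carrier_src gives its
//               1-based source index).
// [[Rcpp::export]]
NumericMatrix cpp_field_step(const NumericMatrix& c,
                             const IntegerMatrix& carriers,
                             const IntegerMatrix& food,
                             double D, double gamma, double A, double sigma,
                             double dt, double dx, int src_mode,
                             const IntegerVector& carrier_src) {
  int M = c.nrow(), N = c.ncol();
  NumericMatrix out(M, N);
  double inv2 = 1.0 / (dx * dx);
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      double cc = c(i, j);
      double lap = 0.0;
      // left/right (x direction)
      lap += (i > 0     ? c(i - 1, j) - cc : (D > 0 ? -dx * cc / D : 0.0));
      lap += (i < M - 1 ? c(i + 1, j) - cc : (D > 0 ? -dx * cc / D : 0.0));
      // down/up (y direction)
      lap += (j > 0     ? c(i, j - 1) - cc : (D > 0 ? -dx * cc / D : 0.0));
      lap += (j < N - 1 ? c(i, j + 1) - cc : (D > 0 ? -dx * cc / D : 0.0));
      out(i, j) = cc + dt * (D * lap * inv2 - gamma * cc);
    }
  }
  for (int a = 0; a < carriers.nrow(); ++a) {
    int x = carriers(a, 0), y = carriers(a, 1);
    double rate;
    if (src_mode == 1) {
      int k = carrier_src[a] - 1;
      double ddx = x - food(k, 0), ddy = y - food(k, 1);
      double d = std::sqrt(ddx * ddx + ddy * ddy) / sigma;
      rate = A * std::exp(-d * d);
    } else {
      rate = cpp_deposition_rate(x, y, food, A, sigma);
    }
    out(x - 1, y - 1) += dt * rate * inv2;
  }
  return out;
}

// Full event loop.  One unit of time = n ant-move events (uniform random
// selection with replacement); once food has been discovered, round(1/dt)
// field steps per unit are distributed evenly across the events, each
// executed before the ant event it precedes.
// [[Rcpp::export]]
List cpp_simulate(int M, int N, int n, IntegerVector x0, IntegerMatrix food,
                  double D, double gamma, double A, double sigma, double eps,
                  double dt, double dx, int T_max,
                  IntegerVector snapshot_times,
                  bool beeline_adaptive, int src_mode,
                  bool record_beeline) {
  int K = food.nrow();
  std::vector<int> px(n, x0[0]), py(n, x0[1]);
  std::vector<int> mode(n, 0);           // 0 forager, 1 carrier
  std::vector<int> src(n, 0);            // source of last conversion (1-based)
  std::vector<int> steps(n, 0);          // moves since conversion
  std::vector<int> conv_cheb(n, 0);      // Chebyshev distance at conversion
  NumericMatrix c(M, N);
  bool discovered = false;
  double discovery_time = NA_REAL;
  int nf = (int)std::lround(1.0 / dt);   // field steps per unit of time

  std::vector<double> bee_cheb, bee_steps;
  List snaps;
  int next_snap = 0;
  int n_snap = snapshot_times.size();

  auto take_snapshot = [&](int t_now) {
    IntegerMatrix ants(n, 3);
    for (int i = 0; i < n; ++i) {
      ants(i, 0) = px[i]; ants(i, 1) = py[i]; ants(i, 2) = mode[i];
    }
    snaps.push_back(List::create(_["time"] = t_now,
                                 _["ants"] = ants,
                                 _["field"] = clone(c)));
  };

  while (next_snap < n_snap && snapshot_times[next_snap] == 0) {
    take_snapshot(0); ++next_snap;
  }

  // scratch for the inlined field step: carrier cells with precomputed
  // deposition rates, rebuilt only after an ant event changes positions
  std::vector<int> dep_idx; std::vector<double> dep_rate;
  dep_idx.reserve(n); dep_rate.reserve(n);
  bool dep_dirty = true;
  std::vector<double> work(M * N);
  double inv2 = 1.0 / (dx * dx);

  auto rebuild_deposits = [&]() {
    dep_idx.clear(); dep_rate.clear();
    for (int i = 0; i < n; ++i) if (mode[i] == 1) {
      double rate;
      if (src_mode == 1) {
        int k = src[i] - 1;
        double ddx = px[i] - food(k, 0), ddy = py[i] - food(k, 1);
        double d = std::sqrt(ddx * ddx + ddy * ddy) / sigma;
        rate = A * std::exp(-d * d);
      } else {
        rate = cpp_deposition_rate(px[i], py[i], food, A, sigma);
      }
      dep_idx.push_back((px[i] - 1) + (py[i] - 1) * M);
      dep_rate.push_back(rate);
    }
    dep_dirty = false;
  };

  auto field_step_inplace = [&]() {
    if (dep_dirty) rebuild_deposits();
    double* cur = REAL(c);
    double* nxt = work.data();
    double robin = (D > 0) ? dx / D : 0.0;
    for (int j = 0; j < N; ++j) {
      const double* col = cur + (size_t)j * M;
      double* out = nxt + (size_t)j * M;
      for (int i = 0; i < M; ++i) {
        double cc = col[i];
        double lap =
          (i > 0     ? col[i - 1] - cc : -robin * cc) +
          (i < M - 1 ? col[i + 1] - cc : -robin * cc) +
          (j > 0     ? cur[i + (size_t)(j - 1) * M] - cc : -robin * cc) +
          (j < N - 1 ? cur[i + (size_t)(j + 1) * M] - cc : -robin * cc);
        out[i] = cc + dt * (D * lap * inv2 - gamma * cc);
      }
    }
    for (size_t a = 0; a < dep_idx.size(); ++a)
      nxt[dep_idx[a]] += dt * dep_rate[a] * inv2;
    std::copy(nxt, nxt + (size_t)M * N, cur);
  };

  for (int t = 1; t <= T_max; ++t) {
    for (int e = 1; e <= n; ++e) {
      if (discovered) {
        long long due = ((long long)e * nf) / n - ((long long)(e - 1) * nf) / n;
        for (long long f = 0; f < due; ++f) field_step_inplace();
      }
      // ant-move event
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      if (mode[i] == 1) {
        int ox, oy;
        if (beeline_adaptive) {
          beeline_step(px[i], py[i], (double)(x0[0] - px[i]),
                       (double)(x0[1] - py[i]), ox, oy);
        } else {
          int k = src[i] - 1;
          beeline_step(px[i], py[i], (double)(x0[0] - food(k, 0)),
                       (double)(x0[1] - food(k, 1)), ox, oy);
          if (!in_bounds(ox, oy, M, N)) { ox = px[i]; oy = py[i]; }
        }
        px[i] = ox; py[i] = oy;
        dep_dirty = true;
        ++steps[i];
        if (px[i] == x0[0] && py[i] == x0[1]) {
          if (record_beeline) {
            bee_cheb.push_back((double)conv_cheb[i]);
            bee_steps.push_back((double)steps[i]);
          }
          mode[i] = 0; steps[i] = 0;
        }
      } else {
        // forager: sample the Moore neighbourhood by pheromone weight
        double w[8]; int nx[8], ny[8]; int cnt = 0; double tot = 0.0;
        double c0 = c(px[i] - 1, py[i] - 1);
        for (int o = 0; o < 8; ++o) {
          int ax = px[i] + OFF[o][0], ay = py[i] + OFF[o][1];
          if (!in_bounds(ax, ay, M, N)) continue;
          double wi;
          if (!discovered) {
            wi = 1.0;
          } else {
            double dc = c(ax - 1, ay - 1) - c0;
            if (dc < 0.0) wi = eps;
            else if (dc > 0.0) wi = 1.0 + dc;
            else wi = 1.0;
          }
          nx[cnt] = ax; ny[cnt] = ay; w[cnt] = wi; tot += wi; ++cnt;
        }
        double u = unif_rand() * tot, acc = 0.0;
        int pick = cnt - 1;
        for (int o = 0; o < cnt; ++o) {
          acc += w[o];
          if (u <= acc) { pick = o; break; }
        }
        px[i] = nx[pick]; py[i] = ny[pick];
        for (int k = 0; k < K; ++k) {
          if (px[i] == food(k, 0) && py[i] == food(k, 1)) {
            mode[i] = 1; src[i] = k + 1; steps[i] = 0;
            dep_dirty = true;
            int cdx = std::abs(px[i] - x0[0]), cdy = std::abs(py[i] - x0[1]);
            conv_cheb[i] = cdx > cdy ? cdx : cdy;
            if (!discovered) {
              discovered = true;
              discovery_time = (double)(t - 1) + (double)e / n;
            }
            break;
          }
        }
      }
    }
    while (next_snap < n_snap && snapshot_times[next_snap] == t) {
      take_snapshot(t); ++next_snap;
    }
  }

  return List::create(
    _["snapshots"] = snaps,
    _["discovery_time"] = discovery_time,
    _["beeline_cheb"] = NumericVector(bee_cheb.begin(), bee_cheb.end()),
    _["beeline_steps"] = NumericVector(bee_steps.begin(), bee_steps.end()));
}

// Thomas algorithm for a constant tridiagonal system, solved independently
// for every column of B.  lower/upper have length n - 1.
// [[Rcpp::export]]
NumericMatrix cpp_tridiag_solve(const NumericVector& lower,
                                const NumericVector& diag,
                                const NumericVector& upper,
                                const NumericMatrix& B) {
  int n = diag.size(), m = B.ncol();
  if (B.nrow() != n) stop("dimension mismatch in tridiagonal solve");
  std::vector<double> cp(n), dp(n);
  NumericMatrix X(n, m);
  // factor once (coefficients identical across columns)
  cp[0] = upper.size() ? upper[0] / diag[0] : 0.0;
  for (int i = 1; i < n - 1; ++i)
    cp[i] = upper[i] / (diag[i] - lower[i - 1] * cp[i - 1]);
  for (int j = 0; j < m; ++j) {
    dp[0] = B(0, j) / diag[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (B(i, j) - lower[i - 1] * dp[i - 1]) /
              (diag[i] - lower[i - 1] * cp[i - 1]);
    X(n - 1, j) = dp[n - 1];
    for (int i = n - 2; i >= 0; --i)
      X(i, j) = dp[i] - cp[i] * X(i + 1, j);
  }
  return X;
}
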