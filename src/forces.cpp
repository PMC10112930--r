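// Force evaluation and over-damped explicit-Euler integration for the
// 2D vertex model.  Node ids arriving from R are 0-based (they index the
// serialized mesh tables directly).
//
// Forces on a node are the sum of
//   * linear springs on incident edges,  f = mod * (l - l0) along the edge,
//   * constant active tension on flagged edges,
//   * the exact gradient of the discrete bending energy (k/2)(theta - pi)^2
//     at each interior node of a cable triplet (prev, node, next).
#include <Rcpp.h>
using namespace Rcpp;

static const double LEN_EPS = 1e-12;

// Accumulate spring + tension + bending forces into (fx, fy).
// Returns max squared force magnitude over nodes.
static double accumulate_forces(int n,
                                const double* px, const double* py,
                                int ne, const int* ef, const int* et,
                                const double* rest, const double* mod,
                                const double* tension,
                                int nt, const int* tp, const int* tn,
                                const int* tq, double kbend,
                                double* fx, double* fy) {
  for (int i = 0; i < n; ++i) { fx[i] = 0.0; fy[i] = 0.0; }

  for (int e = 0; e < ne; ++e) {
    const int a = ef[e], b = et[e];
    const double dx = px[b] - px[a];
    const double dy = py[b] - py[a];
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L < LEN_EPS)
      stop("degenerate geometry: edge %d has (near-)zero length", e);
    // restoring spring force plus constant active tension, both pull the
    // endpoints together when positive
    const double c = (mod[e] * (L - rest[e]) + tension[e]) / L;
    fx[a] += c * dx; fy[a] += c * dy;
    fx[b] -= c * dx; fy[b] -= c * dy;
  }

  if (kbend > 0.0) {
    for (int t = 0; t < nt; ++t) {
      const int p = tp[t], m = tn[t], q = tq[t];
      const double ax = px[p] - px[m], ay = py[p] - py[m];
      const double bx = px[q] - px[m], by = py[q] - py[m];
      const double a2 = ax * ax + ay * ay;
      const double b2 = bx * bx + by * by;
      if (a2 < LEN_EPS * LEN_EPS || b2 < LEN_EPS * LEN_EPS)
        stop("degenerate geometry: zero-length edge in bending triplet %d", t);
      const double cross = ax * by - ay * bx;
      const double dot = ax * bx + ay * by;
      const double theta = std::atan2(std::fabs(cross), dot);  // [0, pi]
      const double sgn = (cross >= 0.0) ? 1.0 : -1.0;
      // F = -k (theta - pi) * grad(theta); grad of the signed angle is
      // (ay,-ax)/|a|^2 at prev and (-by,bx)/|b|^2 at next
      const double coef = -kbend * (theta - M_PI) * sgn;
      const double gpx = ay / a2, gpy = -ax / a2;
      const double gqx = -by / b2, gqy = bx / b2;
      fx[p] += coef * gpx; fy[p] += coef * gpy;
      fx[q] += coef * gqx; fy[q] += coef * gqy;
      fx[m] -= coef * (gpx + gqx); fy[m] -= coef * (gpy + gqy);
    }
  }

  double maxsq = 0.0;
  for (int i = 0; i < n; ++i) {
    const double s = fx[i] * fx[i] + fy[i] * fy[i];
    if (s > maxsq) maxsq = s;
  }
  return maxsq;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos,
                         IntegerVector efrom, IntegerVector eto,
                         NumericVector rest, NumericVector mod,
                         NumericVector tension,
                         IntegerMatrix triplets, double kbend) {
  const int n = pos.nrow(), ne = efrom.size(), nt = triplets.nrow();
  NumericMatrix F(n, 2);
  accumulate_forces(n, &pos(0, 0), &pos(0, 1),
                    ne, efrom.begin(), eto.begin(),
                    rest.begin(), mod.begin(), tension.begin(),
                    nt, nt ? &triplets(0, 0) : NULL,
                    nt ? &triplets(0, 1) : NULL,
                    nt ? &triplets(0, 2) : NULL, kbend,
                    &F(0, 0), &F(0, 1));
  return F;
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos,
                  IntegerVector efrom, IntegerVector eto,
                  NumericVector rest, NumericVector mod,
                  NumericVector tension,
                  IntegerMatrix triplets, double kbend) {
  const int ne = efrom.size(), nt = triplets.nrow();
  const double* px = &pos(0, 0);
  const double* py = &pos(0, 1);
  double E = 0.0;
  for (int e = 0; e < ne; ++e) {
    const int a = efrom[e], b = eto[e];
    const double dx = px[b] - px[a], dy = py[b] - py[a];
    const double L = std::sqrt(dx * dx + dy * dy);
    const double d = L - rest[e];
    E += 0.5 * mod[e] * d * d + tension[e] * L;
  }
  if (kbend > 0.0) {
    for (int t = 0; t < nt; ++t) {
      const int p = triplets(t, 0), m = triplets(t, 1), q = triplets(t, 2);
      const double ax = px[p] - px[m], ay = py[p] - py[m];
      const double bx = px[q] - px[m], by = py[q] - py[m];
      const double cross = ax * by - ay * bx;
      const double dot = ax * bx + ay * by;
      const double theta = std::atan2(std::fabs(cross), dot);
      const double dev = theta - M_PI;
      E += 0.5 * kbend * dev * dev;
    }
  }
  return E;
}

// Explicit Euler integration of eta * dx/dt = F until max|F| <= ftol or
// max_steps update steps have been taken.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos0,
               IntegerVector efrom, IntegerVector eto,
               NumericVector rest, NumericVector mod,
               NumericVector tension,
               IntegerMatrix triplets, double kbend,
               double eta, double dt, int max_steps, double ftol,
               int snapshot_every) {
  const int n = pos0.nrow(), ne = efrom.size(), nt = triplets.nrow();
  NumericMatrix pos = clone(pos0);
  double* px = &pos(0, 0);
  double* py = &pos(0, 1);
  std::vector<double> fx(n), fy(n);
  const int* tp = nt ? &triplets(0, 0) : NULL;
  const int* tn = nt ? &triplets(0, 1) : NULL;
  const int* tq = nt ? &triplets(0, 2) : NULL;

  const double mv = dt / eta;
  const double ftol2 = ftol * ftol;
  bool converged = false;
  int steps = 0;
  double maxsq = 0.0;
  List snaps;
  std::vector<double> snap_times;

  for (int step = 0; step <= max_steps; ++step) {
    maxsq = accumulate_forces(n, px, py, ne, efrom.begin(), eto.begin(),
                              rest.begin(), mod.begin(), tension.begin(),
                              nt, tp, tn, tq, kbend, fx.data(), fy.data());
    if (!R_finite(maxsq))
      stop("divergence: non-finite forces at step %d (reduce dt)", step);
    if (maxsq <= ftol2) { converged = true; break; }
    if (step == max_steps) break;  // budget exhausted before convergence
    for (int i = 0; i < n; ++i) {
      px[i] += mv * fx[i];
      py[i] += mv * fy[i];
    }
    steps = step + 1;
    if (snapshot_every > 0 && steps % snapshot_every == 0) {
      snaps.push_back(clone(pos));
      snap_times.push_back(steps * dt);
    }
    if (steps % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["positions"] = pos,
                      _["converged"] = converged,
                      _["final_max_force"] = std::sqrt(maxsq),
                      _["steps_taken"] = steps,
                      _["snapshots"] = snaps,
                      _["snapshot_times"] = wrap(snap_times));
}
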