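#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;

// Forward-Euler update of the replicase/parasite/affinity/resource lattice.
//
// Per cell and step, in this order:
//   new_r = aR * dt * r^2 * (1-m) * n
//   new_p = dt * r * (aR*r*m + a*p) * n
//   if new_r + new_p > n: rescale both by n / (new_r + new_p)   (resource cap)
//   r <- r + new_r - dR*dt*r + D*dt*(avg(r) - r)
//   p <- p + new_p - dP*dt*p + D*dt*(avg(p) - p)
//   ap <- a*p + D*dt*(avg(a*p) - a*p);  a <- ap / p_old  (unchanged if p_old == 0)
//   n <- n + n0*dt - new_r - new_p + Dn*dt*(avg(n) - n)
//   a <- a + sigma_a*sqrt(dt)/sqrt(max(p_old, eps)) * N(0,1)
//   clamp r,p,n at 0; clamp a to [a_min, a_max]
//
// avg is the mean of the adjacent neighbors with periodic wrap: the 8-cell
// Moore ring by default, or the 4-cell von-Neumann cross.  The Moore
// average is the default because the update n <- n + Dn*dt*(avg(n) - n)
// at the default parameters (Dn*dt = 1) degenerates to n <- avg(n),
// whose checkerboard mode has eigenvalue -1 under the 4-neighbor average:
// the resource field then splits into two parities that swap every step
// and the >=0 clamp rectifies the oscillation into unbounded growth.  The
// 8-neighbor average has no -1 eigenmode and is stable there.
// The division of the diffused affinity mass by the OLD parasite density is
// deliberate (the update reads pre-step quantities); see package docs.

static inline double clamp0(double x) { return x < 0.0 ? 0.0 : x; }

// [[Rcpp::export(name = ".pde_run_cpp")]]
List pde_run_cpp(NumericMatrix r0, NumericMatrix p0, NumericMatrix a0,
                 NumericMatrix n0field, double t0, int step0,
                 List par, int nsteps, double seed,
                 int trace_i, int trace_j, int snapshot_every,
                 bool moore) {
    const int nx = r0.nrow(), ny = r0.ncol();
    const int ncell = nx * ny;

    const double aR      = as<double>(par["aR"]);
    const double dR      = as<double>(par["dR"]);
    const double dP      = as<double>(par["dP"]);
    const double m       = as<double>(par["m"]);
    const double n0      = as<double>(par["n0"]);
    const double D       = as<double>(par["D"]);
    const double Dn      = as<double>(par["Dn"]);
    const double sigma_a = as<double>(par["sigma_a"]);
    const double dt      = as<double>(par["dt"]);
    const double a_min   = as<double>(par["a_min"]);
    const double a_max   = as<double>(par["a_max"]);
    const double mut_eps = as<double>(par["mut_eps"]);

    std::vector<double> r(r0.begin(), r0.end());
    std::vector<double> p(p0.begin(), p0.end());
    std::vector<double> a(a0.begin(), a0.end());
    std::vector<double> n(n0field.begin(), n0field.end());
    std::vector<double> r2(ncell), p2(ncell), a2(ncell), n2(ncell), ap(ncell);

    // periodic neighbor index tables (column-major: cell = i + nx*j)
    std::vector<int> up(nx), dn(nx), lf(ny), rt(ny);
    for (int i = 0; i < nx; ++i) {
        up[i] = (i + 1) % nx;
        dn[i] = (i + nx - 1) % nx;
    }
    for (int j = 0; j < ny; ++j) {
        lf[j] = (j + ny - 1) % ny;
        rt[j] = (j + 1) % ny;
    }

    Pcg32 rng(static_cast<std::uint64_t>(seed));

    const int nrec = nsteps + 1;
    NumericVector rec_t(nrec), rec_r(nrec), rec_p(nrec), rec_n(nrec),
                  rec_a(nrec), rec_trace(nrec);
    List snapshots;
    IntegerVector snap_steps;
    if (snapshot_every > 0) {
        int nsnap = nsteps / snapshot_every + 1;
        snapshots = List(nsnap);
        snap_steps = IntegerVector(nsnap);
    }
    int snap_k = 0;

    const double mut_base = sigma_a * std::sqrt(dt);
    const bool mutate = sigma_a > 0.0;
    const int trace_cell = trace_i + nx * trace_j;

    for (int s = 0; s <= nsteps; ++s) {
        // record current state
        double sr = 0.0, sp = 0.0, sn = 0.0, sap = 0.0;
        for (int c = 0; c < ncell; ++c) {
            sr += r[c]; sp += p[c]; sn += n[c]; sap += a[c] * p[c];
        }
        rec_t[s] = t0 + s * dt;
        rec_r[s] = sr; rec_p[s] = sp; rec_n[s] = sn;
        rec_a[s] = sp > 0.0 ? sap / sp : NA_REAL;
        rec_trace[s] = a[trace_cell];
        if (snapshot_every > 0 && s % snapshot_every == 0) {
            NumericMatrix sr_(nx, ny), sp_(nx, ny), sa_(nx, ny), sn_(nx, ny);
            std::copy(r.begin(), r.end(), sr_.begin());
            std::copy(p.begin(), p.end(), sp_.begin());
            std::copy(a.begin(), a.end(), sa_.begin());
            std::copy(n.begin(), n.end(), sn_.begin());
            snapshots[snap_k] = List::create(_["r"] = sr_, _["p"] = sp_,
                                             _["a"] = sa_, _["n"] = sn_);
            snap_steps[snap_k] = step0 + s;
            ++snap_k;
        }
        if (s == nsteps) break;

        for (int c = 0; c < ncell; ++c) ap[c] = a[c] * p[c];

        const double wavg = moore ? 0.125 : 0.25;
        for (int j = 0; j < ny; ++j) {
            const int jl = lf[j] * nx, jr = rt[j] * nx, jc = j * nx;
            for (int i = 0; i < nx; ++i) {
                const int c = i + jc;
                const int iu = up[i], id = dn[i];
                const int cu = iu + jc, cd = id + jc;
                const int cl = i + jl, cr = i + jr;
                const double rc = r[c], pc = p[c], ac = a[c], nc = n[c];

                double new_r = aR * dt * rc * rc * (1.0 - m) * nc;
                double new_p = dt * rc * (aR * rc * m + ac * pc) * nc;
                double used = new_r + new_p;
                if (used > 0.0 && used > nc) {
                    const double f = nc / used;
                    new_r *= f; new_p *= f;
                    used = nc;
                }

                double avg_r = r[cu] + r[cd] + r[cl] + r[cr];
                double avg_p = p[cu] + p[cd] + p[cl] + p[cr];
                double avg_n = n[cu] + n[cd] + n[cl] + n[cr];
                double avg_ap = ap[cu] + ap[cd] + ap[cl] + ap[cr];
                if (moore) {
                    const int c1 = iu + jl, c2 = iu + jr;
                    const int c3 = id + jl, c4 = id + jr;
                    avg_r += r[c1] + r[c2] + r[c3] + r[c4];
                    avg_p += p[c1] + p[c2] + p[c3] + p[c4];
                    avg_n += n[c1] + n[c2] + n[c3] + n[c4];
                    avg_ap += ap[c1] + ap[c2] + ap[c3] + ap[c4];
                }
                avg_r *= wavg; avg_p *= wavg; avg_n *= wavg; avg_ap *= wavg;

                r2[c] = rc + new_r - dR * dt * rc + D * dt * (avg_r - rc);
                p2[c] = pc + new_p - dP * dt * pc + D * dt * (avg_p - pc);
                const double new_ap = ap[c] + D * dt * (avg_ap - ap[c]);
                double anew = pc > 0.0 ? new_ap / pc : ac;
                n2[c] = nc + n0 * dt - used + Dn * dt * (avg_n - nc);

                if (mutate) {
                    const double pm = pc > mut_eps ? pc : mut_eps;
                    anew += mut_base / std::sqrt(pm) * rng.rnorm();
                }
                r2[c] = clamp0(r2[c]);
                p2[c] = clamp0(p2[c]);
                n2[c] = clamp0(n2[c]);
                if (anew < a_min) anew = a_min;
                if (anew > a_max) anew = a_max;
                a2[c] = anew;
            }
        }
        r.swap(r2); p.swap(p2); a.swap(a2); n.swap(n2);

        if ((s & 1023) == 0) {
            bool ok = true;
            for (int c = 0; c < ncell && ok; ++c)
                ok = R_finite(r[c]) && R_finite(p[c]) && R_finite(n[c]) &&
                     R_finite(a[c]);
            if (!ok)
                stop("non-finite field values at step %d: the forward-Euler "
                     "scheme is unstable for these parameters; reduce dt",
                     step0 + s + 1);
        }
    }

    // final full finiteness check (cheap relative to the run)
    for (int c = 0; c < ncell; ++c)
        if (!(R_finite(r[c]) && R_finite(p[c]) && R_finite(n[c]) &&
              R_finite(a[c])))
            stop("non-finite field values after run: reduce dt");

    NumericMatrix rf(nx, ny), pf(nx, ny), af(nx, ny), nf(nx, ny);
    std::copy(r.begin(), r.end(), rf.begin());
    std::copy(p.begin(), p.end(), pf.begin());
    std::copy(a.begin(), a.end(), af.begin());
    std::copy(n.begin(), n.end(), nf.begin());

    List out = List::create(
        _["r"] = rf, _["p"] = pf, _["a"] = af, _["n"] = nf,
        _["t"] = t0 + nsteps * dt, _["step"] = step0 + nsteps,
        _["rec_t"] = rec_t, _["rec_r"] = rec_r, _["rec_p"] = rec_p,
        _["rec_n"] = rec_n, _["rec_a"] = rec_a, _["rec_trace"] = rec_trace,
        _["snapshots"] = snapshots, _["snap_steps"] = snap_steps);
    return out;
}
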