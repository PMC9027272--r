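#include <Rcpp.h>
#include <vector>
#include <climits>
#include "rng.h"

using namespace Rcpp;

// Brownian-dynamics multi-agent engine for the replicase-parasite system.
// Agents are circles of radius agent_size on a periodic arena; two agents
// interact when their circles intersect (center distance < 2*agent_size).
// Per step: decrement remaining-life-times and remove expired agents, then
// visit agents in random order; an agent with more than Nmax overlapping
// neighbors dies of crowding, otherwise it takes a Brownian step and
// attempts one replication per (shuffled) neighbor.  Offspring are placed
// at the template's position with a freshly sampled lifetime and join the
// population immediately, but are not in the current step's visit order.

struct Pop {
    std::vector<double> x, y, kp;
    std::vector<int> rlt;
    std::vector<char> type;   // 0 = replicase, 1 = parasite
    std::vector<char> alive;
    std::vector<int> bin, slot;   // spatial-hash bookkeeping
    int n_alive_repl = 0, n_alive_par = 0;

    int size() const { return static_cast<int>(x.size()); }
};

struct Grid {
    double sizeX, sizeY, binw_x, binw_y;
    int nbx, nby;
    bool use_bins;
    std::vector<std::vector<int> > bins;

    Grid(double sX, double sY, double radius) : sizeX(sX), sizeY(sY) {
        nbx = static_cast<int>(sX / radius);
        nby = static_cast<int>(sY / radius);
        use_bins = (nbx >= 4 && nby >= 4);
        if (!use_bins) { nbx = nby = 1; }
        binw_x = sX / nbx;
        binw_y = sY / nby;
        bins.resize(static_cast<size_t>(nbx) * nby);
    }

    int bin_of(double px, double py) const {
        int bi = static_cast<int>(px / binw_x);
        int bj = static_cast<int>(py / binw_y);
        if (bi >= nbx) bi = nbx - 1;
        if (bj >= nby) bj = nby - 1;
        if (bi < 0) bi = 0;
        if (bj < 0) bj = 0;
        return bi + nbx * bj;
    }

    void insert(Pop& P, int id) {
        int b = bin_of(P.x[id], P.y[id]);
        P.bin[id] = b;
        P.slot[id] = static_cast<int>(bins[b].size());
        bins[b].push_back(id);
    }

    void remove(Pop& P, int id) {
        int b = P.bin[id], s = P.slot[id];
        int last = bins[b].back();
        bins[b][s] = last;
        P.slot[last] = s;
        bins[b].pop_back();
        P.bin[id] = -1;
    }

    void move(Pop& P, int id) {
        int b = bin_of(P.x[id], P.y[id]);
        if (b != P.bin[id]) { remove(P, id); insert(P, id); }
    }
};

static inline double wrap_pos(double v, double size) {
    v -= size * std::floor(v / size);
    if (v >= size) v = 0.0;   // guard against round-up at the boundary
    return v;
}

static inline double per_dist2(double x1, double y1, double x2, double y2,
                               double sX, double sY) {
    double dx = std::fabs(x1 - x2);
    if (dx > 0.5 * sX) dx = sX - dx;
    double dy = std::fabs(y1 - y2);
    if (dy > 0.5 * sY) dy = sY - dy;
    return dx * dx + dy * dy;
}

// neighbors of `id`: alive agents (other than id) within distance < radius
static void collect_neighbors(const Pop& P, const Grid& G, int id,
                              double radius, std::vector<int>& out) {
    out.clear();
    const double r2 = radius * radius;
    const double px = P.x[id], py = P.y[id];
    if (!G.use_bins) {
        for (int k = 0; k < P.size(); ++k) {
            if (k == id || !P.alive[k]) continue;
            if (per_dist2(px, py, P.x[k], P.y[k], G.sizeX, G.sizeY) < r2)
                out.push_back(k);
        }
        return;
    }
    int bi = P.bin[id] % G.nbx, bj = P.bin[id] / G.nbx;
    for (int dj = -1; dj <= 1; ++dj) {
        int jj = (bj + dj + G.nby) % G.nby;
        for (int di = -1; di <= 1; ++di) {
            int ii = (bi + di + G.nbx) % G.nbx;
            const std::vector<int>& cell = G.bins[ii + G.nbx * jj];
            for (size_t q = 0; q < cell.size(); ++q) {
                int k = cell[q];
                if (k == id || !P.alive[k]) continue;
                if (per_dist2(px, py, P.x[k], P.y[k], G.sizeX, G.sizeY) < r2)
                    out.push_back(k);
            }
        }
    }
}

static inline int sample_rlt_int(double d, double dt, Pcg32& rng) {
    if (d <= 0.0 || dt <= 0.0) return INT_MAX;
    double v = std::floor(-std::log(rng.runif_pos()) / (d * dt)) + 1.0;
    if (v > 2147483000.0) return INT_MAX;
    return static_cast<int>(v);
}

static void kill(Pop& P, Grid& G, int id) {
    P.alive[id] = 0;
    if (P.type[id] == 0) --P.n_alive_repl; else --P.n_alive_par;
    G.remove(P, id);
}

static void compact(Pop& P, Grid& G) {
    Pop Q;
    int n = 0;
    for (int k = 0; k < P.size(); ++k) if (P.alive[k]) ++n;
    Q.x.reserve(n); Q.y.reserve(n); Q.kp.reserve(n);
    Q.rlt.reserve(n); Q.type.reserve(n); Q.alive.reserve(n);
    Q.bin.reserve(n); Q.slot.reserve(n);
    for (int k = 0; k < P.size(); ++k) {
        if (!P.alive[k]) continue;
        Q.x.push_back(P.x[k]); Q.y.push_back(P.y[k]);
        Q.kp.push_back(P.kp[k]); Q.rlt.push_back(P.rlt[k]);
        Q.type.push_back(P.type[k]); Q.alive.push_back(1);
        Q.bin.push_back(-1); Q.slot.push_back(-1);
    }
    Q.n_alive_repl = P.n_alive_repl;
    Q.n_alive_par = P.n_alive_par;
    for (size_t b = 0; b < G.bins.size(); ++b) G.bins[b].clear();
    P = Q;
    for (int k = 0; k < P.size(); ++k) G.insert(P, k);
}

// [[Rcpp::export(name = ".mas_run_cpp")]]
List mas_run_cpp(List par, int snapshot_every) {
    const double sizeX      = as<double>(par["sizeX"]);
    const double sizeY      = as<double>(par["sizeY"]);
    const double agent_size = as<double>(par["agent_size"]);
    const int    Nmax       = as<int>(par["Nmax"]);
    const double d          = as<double>(par["d"]);
    const double kR         = as<double>(par["kR"]);
    const double dt         = as<double>(par["dt"]);
    const double D          = as<double>(par["D"]);
    const double delta      = as<double>(par["delta"]);
    const double mP         = as<double>(par["mP"]);
    const int    n_repl0    = as<int>(par["n_replicases0"]);
    const int    n_par0     = as<int>(par["n_parasites0"]);
    const double kP0        = as<double>(par["kP0"]);
    const double seed       = as<double>(par["seed"]);
    const int    time_limit = as<int>(par["time_limit"]);

    const double radius = 2.0 * agent_size;
    const double step_sd = std::sqrt(2.0 * D * dt);

    Pcg32 rng(static_cast<std::uint64_t>(seed), 77u);
    Pop P;
    Grid G(sizeX, sizeY, radius);

    const int n0 = n_repl0 + n_par0;
    P.x.reserve(2 * n0); P.y.reserve(2 * n0); P.kp.reserve(2 * n0);
    P.rlt.reserve(2 * n0); P.type.reserve(2 * n0); P.alive.reserve(2 * n0);
    P.bin.reserve(2 * n0); P.slot.reserve(2 * n0);
    for (int k = 0; k < n0; ++k) {
        P.x.push_back(rng.runif() * sizeX);
        P.y.push_back(rng.runif() * sizeY);
        char tp = k < n_repl0 ? 0 : 1;
        P.type.push_back(tp);
        P.kp.push_back(tp == 1 ? kP0 : NA_REAL);
        P.rlt.push_back(sample_rlt_int(d, dt, rng));
        P.alive.push_back(1);
        P.bin.push_back(-1); P.slot.push_back(-1);
        G.insert(P, k);
    }
    P.n_alive_repl = n_repl0;
    P.n_alive_par = n_par0;

    std::vector<int> rec_step, rec_nr, rec_np;
    std::vector<double> rec_mean, rec_min, rec_max;
    List snapshots;
    IntegerVector snap_steps;
    std::vector<List> snap_list;
    std::vector<int> snap_at;

    std::vector<int> order, nbrs;

    auto record = [&](int s) {
        rec_step.push_back(s);
        rec_nr.push_back(P.n_alive_repl);
        rec_np.push_back(P.n_alive_par);
        double sum = 0.0, mn = R_PosInf, mx = R_NegInf;
        int c = 0;
        for (int k = 0; k < P.size(); ++k) {
            if (!P.alive[k] || P.type[k] != 1) continue;
            double v = P.kp[k];
            sum += v; ++c;
            if (v < mn) mn = v;
            if (v > mx) mx = v;
        }
        rec_mean.push_back(c ? sum / c : NA_REAL);
        rec_min.push_back(c ? mn : NA_REAL);
        rec_max.push_back(c ? mx : NA_REAL);
    };
    auto snapshot = [&](int s) {
        int n = 0;
        for (int k = 0; k < P.size(); ++k) if (P.alive[k]) ++n;
        NumericVector sx(n), sy(n), skp(n);
        IntegerVector st(n), srlt(n);
        int q = 0;
        for (int k = 0; k < P.size(); ++k) {
            if (!P.alive[k]) continue;
            sx[q] = P.x[k]; sy[q] = P.y[k]; skp[q] = P.kp[k];
            st[q] = P.type[k]; srlt[q] = P.rlt[k];
            ++q;
        }
        snap_list.push_back(List::create(_["x"] = sx, _["y"] = sy,
                                         _["type"] = st, _["kP"] = skp,
                                         _["rlt"] = srlt));
        snap_at.push_back(s);
    };

    record(0);
    if (snapshot_every > 0) snapshot(0);

    int step = 0;
    while (step < time_limit && P.n_alive_repl > 0 && P.n_alive_par > 0) {
        // 1. age and expire
        for (int k = 0; k < P.size(); ++k) {
            if (!P.alive[k]) continue;
            if (P.rlt[k] != INT_MAX) --P.rlt[k];
            if (P.rlt[k] <= 0) kill(P, G, k);
        }

        // 2. randomized visit order over agents alive at step start
        order.clear();
        for (int k = 0; k < P.size(); ++k)
            if (P.alive[k]) order.push_back(k);
        if (!order.empty())
            rng.shuffle(order.data(), static_cast<int>(order.size()));

        // 3. per-agent crowding, Brownian move, reactions
        for (size_t oi = 0; oi < order.size(); ++oi) {
            int xi = order[oi];
            if (!P.alive[xi]) continue;

            collect_neighbors(P, G, xi, radius, nbrs);
            if (static_cast<int>(nbrs.size()) > Nmax) {
                kill(P, G, xi);
                continue;
            }
            if (!nbrs.empty())
                rng.shuffle(nbrs.data(), static_cast<int>(nbrs.size()));

            P.x[xi] = wrap_pos(P.x[xi] + step_sd * rng.rnorm(), sizeX);
            P.y[xi] = wrap_pos(P.y[xi] + step_sd * rng.rnorm(), sizeY);
            G.move(P, xi);

            for (size_t q = 0; q < nbrs.size(); ++q) {
                int nj = nbrs[q];
                if (!P.alive[nj]) continue;
                int tmpl;
                double prob;
                if (P.type[xi] == 1 && P.type[nj] == 1) {
                    continue;                    // two parasites: no reaction
                } else if (P.type[xi] == 1) {    // xi parasite, nj replicase
                    tmpl = xi; prob = P.kp[xi];
                } else if (P.type[nj] == 1) {    // xi replicase, nj parasite
                    tmpl = nj; prob = P.kp[nj];
                } else {                         // two replicases
                    tmpl = nj; prob = kR;
                }
                if (rng.runif() >= prob) continue;

                double ckp = P.kp[tmpl];
                if (P.type[tmpl] == 1 && rng.runif() < mP) {
                    ckp += (rng.runif() - 0.5) * delta;
                    if (ckp < 0.0) ckp = 0.0;
                    if (ckp > 1.0) ckp = 1.0;
                }
                P.x.push_back(P.x[tmpl]); P.y.push_back(P.y[tmpl]);
                P.type.push_back(P.type[tmpl]);
                P.kp.push_back(ckp);
                P.rlt.push_back(sample_rlt_int(d, dt, rng));
                P.alive.push_back(1);
                P.bin.push_back(-1); P.slot.push_back(-1);
                int nid = P.size() - 1;
                G.insert(P, nid);
                if (P.type[nid] == 0) ++P.n_alive_repl;
                else ++P.n_alive_par;
            }
        }

        ++step;
        record(step);
        if (snapshot_every > 0 && step % snapshot_every == 0) snapshot(step);

        int na = P.n_alive_repl + P.n_alive_par;
        if (P.size() > 20000 && na * 2 < P.size()) compact(P, G);
        if (step % 256 == 0) Rcpp::checkUserInterrupt();
    }

    // final population table
    compact(P, G);
    int n = P.size();
    NumericVector fx(n), fy(n), fkp(n);
    IntegerVector ft(n), frlt(n);
    for (int k = 0; k < n; ++k) {
        fx[k] = P.x[k]; fy[k] = P.y[k]; fkp[k] = P.kp[k];
        ft[k] = P.type[k]; frlt[k] = P.rlt[k];
    }

    List snaps(snap_list.size());
    IntegerVector snapsteps(snap_list.size());
    for (size_t q = 0; q < snap_list.size(); ++q) {
        snaps[q] = snap_list[q];
        snapsteps[q] = snap_at[q];
    }

    return List::create(
        _["step"] = wrap(rec_step), _["n_replicases"] = wrap(rec_nr),
        _["n_parasites"] = wrap(rec_np), _["mean_kP"] = wrap(rec_mean),
        _["min_kP"] = wrap(rec_min), _["max_kP"] = wrap(rec_max),
        _["steps_run"] = step,
        _["final"] = List::create(_["x"] = fx, _["y"] = fy, _["type"] = ft,
                                  _["kP"] = fkp, _["rlt"] = frlt),
        _["snapshots"] = snaps, _["snapshot_steps"] = snapsteps);
}

// Binned neighbor lists for a static point set: for each point, the indices
// (1-based) of other points with periodic center distance < radius.
// [[Rcpp::export(name = ".neighbors_binned_cpp")]]
List neighbors_binned_cpp(NumericVector x, NumericVector y,
                          double sizeX, double sizeY, double radius) {
    const int n = x.size();
    Pop P;
    Grid G(sizeX, sizeY, radius);
    P.x.assign(x.begin(), x.end());
    P.y.assign(y.begin(), y.end());
    P.kp.assign(n, 0.0); P.rlt.assign(n, 1);
    P.type.assign(n, 0); P.alive.assign(n, 1);
    P.bin.assign(n, -1); P.slot.assign(n, -1);
    for (int k = 0; k < n; ++k) G.insert(P, k);
    std::vector<int> nbrs;
    List out(n);
    for (int k = 0; k < n; ++k) {
        collect_neighbors(P, G, k, radius, nbrs);
        IntegerVector v(nbrs.size());
        for (size_t q = 0; q < nbrs.size(); ++q) v[q] = nbrs[q] + 1;
        out[k] = v;
    }
    return out;
}
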