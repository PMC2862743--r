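#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: expands one integer seed into well-separated 64-bit stream seeds
static inline uint64_t splitmix64_next(uint64_t &state) {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static inline uint64_t rotl64(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
}

// xoshiro256++ with a Marsaglia-Tsang ziggurat for normal deviates: the
// Brownian stepper draws ~10^9 gaussians per production run, which makes
// the normal sampler the hot spot of the whole package.
struct Rng {
    uint64_t s[4];

    void seed(uint64_t seed, uint64_t stream) {
        uint64_t st = seed * 0x9E3779B97F4A7C15ULL + stream;
        splitmix64_next(st);
        for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(st);
    }
    inline uint64_t next() {
        const uint64_t result = rotl64(s[0] + s[3], 23) + s[0];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl64(s[3], 45);
        return result;
    }
    inline double unif() {            // (0, 1)
        return (((double) (next() >> 11)) + 0.5) * 0x1.0p-53;
    }
    inline double expo() { return -std::log(unif()); }

    // ziggurat tables (shared, built once)
    static uint32_t kn[128];
    static double wn[128], fn[128];
    static bool zig_ready;
    static void zig_init() {
        const double m1 = 2147483648.0;
        double dn = 3.442619855899, tn = dn;
        const double vn = 9.91256303526217e-3;
        double q = vn / std::exp(-0.5 * dn * dn);
        kn[0] = (uint32_t) ((dn / q) * m1);
        kn[1] = 0;
        wn[0] = q / m1;
        wn[127] = dn / m1;
        fn[0] = 1.0;
        fn[127] = std::exp(-0.5 * dn * dn);
        for (int i = 126; i >= 1; --i) {
            dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
            kn[i + 1] = (uint32_t) ((dn / tn) * m1);
            tn = dn;
            fn[i] = std::exp(-0.5 * dn * dn);
            wn[i] = dn / m1;
        }
        zig_ready = true;
    }
    inline double normal() {
        for (;;) {
            const uint64_t u = next();
            const int32_t hz = (int32_t) (u >> 32);
            const uint32_t iz = (uint32_t) (u & 127u);
            if ((uint32_t) std::abs(hz) < kn[iz])
                return hz * wn[iz];
            // slow path: layer rejection / tail
            const double r = 3.442619855899;
            double x = hz * wn[iz];
            if (iz == 0) {
                double y;
                do {
                    x = -std::log(unif()) / r;
                    y = -std::log(unif());
                } while (y + y < x * x);
                return (hz > 0) ? r + x : -(r + x);
            }
            if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
                std::exp(-0.5 * x * x))
                return x;
        }
    }
    inline int poisson(double lambda) {
        if (lambda <= 0.0) return 0;
        if (lambda < 30.0) {           // Knuth product method
            const double L = std::exp(-lambda);
            int k = 0;
            double p = 1.0;
            do { ++k; p *= unif(); } while (p > L);
            return k - 1;
        }
        // normal approximation with continuity correction (counts this
        // large are far outside the photon regime this simulator targets)
        const double v = lambda + std::sqrt(lambda) * normal();
        return (v < 0.0) ? 0 : (int) (v + 0.5);
    }
};
uint32_t Rng::kn[128];
double Rng::wn[128], Rng::fn[128];
bool Rng::zig_ready = false;

static Rng make_engine(uint64_t seed, uint64_t stream) {
    if (!Rng::zig_ready) Rng::zig_init();
    Rng r;
    r.seed(seed, stream);
    return r;
}

// fold a coordinate back into [0, L] (reflecting walls)
static inline double reflect_coord(double v, double L) {
    while (v < 0.0 || v > L) {
        if (v < 0.0) v = -v;
        if (v > L)   v = 2.0 * L - v;
    }
    return v;
}

struct SimState {
    std::vector<double> x, y, z;
    std::vector<int>   transloc;       // 0 = free, 1 = inside the barrier channel
    std::vector<double> release_t;     // absolute release time for translocating
    std::vector<double> release_x;     // exit-side x position
};

// Per-attempt transmission probability for a step of duration dt taken from
// the side with diffusion coefficient d_from. The reference probability
// p_cross is defined for a pixel-dwell step from the left compartment;
// scaling by sqrt(dt) and 1/sqrt(D) keeps the underlying membrane
// permeability step-size independent and preserves detailed balance
// (equal-concentration equilibrium) when D differs across the barrier.
static inline double p_transmit(double p_cross, double dt, double dt_ref,
                                double d_from, double d_ref) {
    double p = p_cross * std::sqrt(dt / dt_ref) * std::sqrt(d_ref / d_from);
    return (p > 1.0) ? 1.0 : p;
}

// One Brownian update of duration dt for every particle, with barrier rules.
// Returns crossing events into the supplied vectors when record_time >= 0.
// When beam_w0 > 0, the summed PSF weight at (beam_x, beam_y, beam_z) over
// the updated particle positions is accumulated into *lambda_acc (single
// fused pass: each particle is stepped, then sensed).
static void advance_particles(SimState &st, double dt, double dt_ref,
                              double t_now,
                              double lx, double ly, double lz,
                              bool has_barrier, double bx, double half_gap,
                              double d_left, double d_right,
                              double sig_left, double sig_right,
                              double p_cross,
                              bool active, int active_src_left, double p_active,
                              double transloc_mean,
                              Rng &eng_traj, Rng &eng_dwell,
                              double record_from,
                              std::vector<double> &ev_t,
                              std::vector<int> &ev_dir,
                              std::vector<int> &ev_type,
                              double beam_x, double beam_y, double beam_z,
                              double beam_w0, double beam_wz,
                              double *lambda_acc)
{
    const double eps = 1e-3; // um, re-entry offset from the barrier plane
    const size_t n = st.x.size();
    const double t_end = t_now + dt;
    const double r2max = 9.0 * beam_w0 * beam_w0, zmax = 3.0 * beam_wz;
    const double inv_w02 = beam_w0 > 0 ? 2.0 / (beam_w0 * beam_w0) : 0.0;
    const double inv_wz2 = beam_w0 > 0 ? 2.0 / (beam_wz * beam_wz) : 0.0;
    double acc = 0.0;
    auto sense = [&](double px, double py, double pz) {
        if (beam_w0 <= 0.0) return;
        const double dz = pz - beam_z;
        if (dz > zmax || dz < -zmax) return;
        const double ddx = px - beam_x, ddy = py - beam_y;
        const double r2 = ddx * ddx + ddy * ddy;
        if (r2 < r2max)
            acc += std::exp(-r2 * inv_w02 - dz * dz * inv_wz2);
    };
    for (size_t i = 0; i < n; ++i) {
        if (st.transloc[i]) {
            if (t_end >= st.release_t[i]) {
                // release on the far side; diffusion resumes next update
                double rx = st.release_x[i];
                st.x[i] = reflect_coord(rx, lx);
                st.transloc[i] = 0;
                if (st.release_t[i] >= record_from) {
                    ev_t.push_back(st.release_t[i] - record_from);
                    ev_dir.push_back(rx > bx ? 1 : -1);
                    ev_type.push_back(1); // active
                }
            }
            sense(st.x[i], st.y[i], st.z[i]);
            continue;
        }
        const double x0 = st.x[i];
        const bool right = has_barrier && x0 > bx;
        const double D = right ? d_right : d_left;
        const double sig = right ? sig_right : sig_left;
        double nx = x0 + sig * eng_traj.normal();
        double ny = st.y[i] + sig * eng_traj.normal();
        double nz = st.z[i] + sig * eng_traj.normal();
        ny = reflect_coord(ny, ly);
        nz = reflect_coord(nz, lz);
        nx = reflect_coord(nx, lx);
        if (has_barrier && half_gap > 0.0) {
            // impenetrable slab of excluded volume (cell-gap control):
            // reflect off the near face, no transmission
            if (x0 <= bx - half_gap && nx > bx - half_gap) {
                nx = 2.0 * (bx - half_gap) - nx;
                nx = reflect_coord(nx, lx);
            } else if (x0 >= bx + half_gap && nx < bx + half_gap) {
                nx = 2.0 * (bx + half_gap) - nx;
                nx = reflect_coord(nx, lx);
            }
            st.x[i] = nx; st.y[i] = ny; st.z[i] = nz;
            sense(nx, ny, nz);
            continue;
        }
        if (has_barrier && ((x0 - bx) * (nx - bx) < 0.0)) {
            // the x-path crosses the barrier plane: attempt transmission
            if (eng_traj.unif() <
                p_transmit(p_cross, dt, dt_ref, D, d_left)) {
                if (t_end >= record_from) {
                    ev_t.push_back(t_end - record_from);
                    ev_dir.push_back(nx > bx ? 1 : -1);
                    ev_type.push_back(0); // passive
                }
            } else {
                const bool on_source = active &&
                    ((active_src_left && x0 < bx) || (!active_src_left && x0 > bx));
                if (on_source && eng_traj.unif() < p_active) {
                    // captured by the carrier channel
                    st.transloc[i] = 1;
                    st.release_t[i] = t_end + eng_dwell.expo() * transloc_mean;
                    st.release_x[i] = (x0 < bx) ? bx + eps : bx - eps;
                    // held at the pore mouth while translocating
                    st.x[i] = (x0 < bx) ? bx - eps : bx + eps;
                    st.y[i] = ny;
                    st.z[i] = nz;
                    sense(st.x[i], ny, nz);
                    continue;
                }
                // rejected: reflect about the barrier plane
                nx = 2.0 * bx - nx;
                nx = reflect_coord(nx, lx);
            }
        }
        st.x[i] = nx;
        st.y[i] = ny;
        st.z[i] = nz;
        sense(nx, ny, nz);
    }
    if (lambda_acc) *lambda_acc = acc;
}

// [[Rcpp::export]]
List cpp_simulate_carpet(List cfg)
{
    const double lx = as<double>(cfg["lx"]);
    const double ly = as<double>(cfg["ly"]);
    const double lz = as<double>(cfg["lz"]);
    const bool has_barrier = as<bool>(cfg["has_barrier"]);
    const double bx = has_barrier ? as<double>(cfg["barrier_x"]) : -1.0;
    const double half_gap = as<double>(cfg["barrier_thickness"]) / 2.0;
    const double d_left = as<double>(cfg["d_left"]);
    const double d_right = as<double>(cfg["d_right"]);
    const int n_particles = as<int>(cfg["n_particles"]);
    const double brightness = as<double>(cfg["brightness"]);
    const double background = as<double>(cfg["background"]);
    const double p_cross = as<double>(cfg["p_cross"]);
    const bool active = as<bool>(cfg["active_enabled"]);
    const int active_src_left = as<int>(cfg["active_src_left"]);
    const double p_active = as<double>(cfg["p_active"]);
    const double transloc_mean = as<double>(cfg["translocation_mean_s"]);
    const double w0 = as<double>(cfg["w0"]);
    const double wz = as<double>(cfg["wz"]);
    const int n_pixels = as<int>(cfg["n_pixels"]);
    const double pixel_size = as<double>(cfg["pixel_size"]);
    const double pixel_dwell = as<double>(cfg["pixel_dwell"]);
    const double line_period = as<double>(cfg["line_period"]);
    const bool scan_l2r = as<bool>(cfg["scan_left_to_right"]);
    const double scan_x0 = as<double>(cfg["scan_x0"]);
    const int n_lines = as<int>(cfg["n_lines"]);
    const double burn_in = as<double>(cfg["burn_in_s"]);
    const uint64_t seed = (uint64_t) as<double>(cfg["seed"]);
    const int pos_stride = as<int>(cfg["position_stride"]); // 0 = off
    const bool photons = as<bool>(cfg["photons"]);

    const double dt_retrace = line_period - n_pixels * pixel_dwell;
    const double scan_y = ly / 2.0, scan_z = lz / 2.0;
    const double sl_dwell = std::sqrt(2.0 * d_left * pixel_dwell);
    const double sr_dwell = std::sqrt(2.0 * d_right * pixel_dwell);
    const double sl_ret = std::sqrt(2.0 * d_left * dt_retrace);
    const double sr_ret = std::sqrt(2.0 * d_right * dt_retrace);

    Rng eng_traj  = make_engine(seed, 1);
    Rng eng_dwell = make_engine(seed, 2);
    Rng eng_phot  = make_engine(seed, 3);

    SimState st;
    st.x.resize(n_particles); st.y.resize(n_particles); st.z.resize(n_particles);
    st.transloc.assign(n_particles, 0);
    st.release_t.assign(n_particles, 0.0);
    st.release_x.assign(n_particles, 0.0);
    for (int i = 0; i < n_particles; ++i) {
        do {
            st.x[i] = eng_traj.unif() * lx;
        } while (has_barrier && half_gap > 0.0 &&
                 std::abs(st.x[i] - bx) < half_gap);
        st.y[i] = eng_traj.unif() * ly;
        st.z[i] = eng_traj.unif() * lz;
    }

    const int n_burn_lines = (int) std::ceil(burn_in / line_period);
    const double record_from = (double) n_burn_lines * line_period;

    std::vector<double> ev_t;
    std::vector<int> ev_dir, ev_type;

    IntegerMatrix counts(photons ? n_lines : 0, photons ? n_pixels : 0);
    IntegerMatrix occupancy(n_lines, 3); // left, right, translocating
    const int n_pos = (pos_stride > 0) ? (n_lines + pos_stride - 1) / pos_stride : 0;
    NumericMatrix pos_x(n_pos, n_pos ? n_particles : 0),
                  pos_y(n_pos, n_pos ? n_particles : 0),
                  pos_z(n_pos, n_pos ? n_particles : 0);
    std::vector<double> lambda(n_pixels);

    double t_now = 0.0;
    int pos_row = 0;
    const int total_lines = n_burn_lines + n_lines;
    for (int l = 0; l < total_lines; ++l) {
        const bool rec = (l >= n_burn_lines);
        const int lr = l - n_burn_lines;
        for (int k = 0; k < n_pixels; ++k) {
            const bool meas = rec && photons;
            const int p = scan_l2r ? k : (n_pixels - 1 - k);
            const double beam_x = scan_x0 + p * pixel_size;
            double s = 0.0;
            advance_particles(st, pixel_dwell, pixel_dwell, t_now, lx, ly, lz,
                              has_barrier, bx, half_gap, d_left, d_right,
                              sl_dwell, sr_dwell, p_cross,
                              active, active_src_left, p_active, transloc_mean,
                              eng_traj, eng_dwell,
                              record_from, ev_t, ev_dir, ev_type,
                              beam_x, scan_y, scan_z,
                              meas ? w0 : 0.0, wz, &s);
            t_now += pixel_dwell;
            if (meas) lambda[p] = background + brightness * s;
        }
        if (dt_retrace > 0.0) {
            advance_particles(st, dt_retrace, pixel_dwell, t_now, lx, ly, lz,
                              has_barrier, bx, half_gap, d_left, d_right,
                              sl_ret, sr_ret, p_cross,
                              active, active_src_left, p_active, transloc_mean,
                              eng_traj, eng_dwell,
                              record_from, ev_t, ev_dir, ev_type,
                              0.0, scan_y, scan_z, 0.0, wz, nullptr);
            t_now += dt_retrace;
        }
        if (rec) {
            if (photons) {
                for (int p = 0; p < n_pixels; ++p)
                    counts(lr, p) = eng_phot.poisson(lambda[p]);
            }
            int nl = 0, nr = 0, nt = 0;
            for (int i = 0; i < n_particles; ++i) {
                if (st.transloc[i]) { ++nt; }
                else if (has_barrier && st.x[i] > bx) { ++nr; }
                else { ++nl; }
            }
            occupancy(lr, 0) = nl; occupancy(lr, 1) = nr; occupancy(lr, 2) = nt;
            if (pos_stride > 0 && lr % pos_stride == 0) {
                for (int i = 0; i < n_particles; ++i) {
                    pos_x(pos_row, i) = st.x[i];
                    pos_y(pos_row, i) = st.y[i];
                    pos_z(pos_row, i) = st.z[i];
                }
                ++pos_row;
            }
        }
    }

    List out = List::create(
        _["counts"] = counts,
        _["occupancy"] = occupancy,
        _["event_time"] = wrap(ev_t),
        _["event_dir"] = wrap(ev_dir),
        _["event_type"] = wrap(ev_type));
    if (pos_stride > 0) {
        out["pos_x"] = pos_x; out["pos_y"] = pos_y; out["pos_z"] = pos_z;
    }
    return out;
}

// First-passage oracle: x-coordinate dynamics only, same step-size sequence as
// the full scanner (n_pixels dwell steps then one lumped retrace step), same
// barrier transmission rule, no carrier channel and no photon model.
// [[Rcpp::export]]
List cpp_crossing_times(double lx, double barrier_x, double d_left,
                        double d_right, double p_cross, double start_offset,
                        int n_pixels, double pixel_dwell, double line_period,
                        int n_rep, double horizon, double seed)
{
    const double dt_retrace = line_period - n_pixels * pixel_dwell;
    Rng eng = make_engine((uint64_t) seed, 11);
    NumericVector times(n_rep);
    const double x_start = barrier_x - start_offset;

    for (int r = 0; r < n_rep; ++r) {
        double x = x_start, t = 0.0;
        bool crossed = false;
        int k = 0;
        while (t < horizon) {
            const double dt = (k < n_pixels) ? pixel_dwell
                              : (dt_retrace > 0.0 ? dt_retrace : pixel_dwell);
            k = (k + 1) % (dt_retrace > 0.0 ? (n_pixels + 1) : n_pixels);
            const double D = (x > barrier_x) ? d_right : d_left;
            double nx = x + std::sqrt(2.0 * D * dt) * eng.normal();
            nx = reflect_coord(nx, lx);
            if ((x - barrier_x) * (nx - barrier_x) < 0.0) {
                if (eng.unif() <
                    p_transmit(p_cross, dt, pixel_dwell, D, d_left)) {
                    t += dt;
                    crossed = true;
                    x = nx;
                    break;
                }
                nx = 2.0 * barrier_x - nx;
                nx = reflect_coord(nx, lx);
            }
            x = nx;
            t += dt;
        }
        times[r] = crossed ? t : NA_REAL;
    }
    return List::create(_["times"] = times);
}
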