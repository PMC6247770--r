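#include <Rcpp.h>
#include <cmath>

// Gyromagnetic ratio of 1H: gamma/2pi = 42.577 MHz/T
static const double GAMMA = 2.0 * M_PI * 42.577e6; // rad s^-1 T^-1

// Exact rotation of magnetisation m about field vector (bx,by,bz) [T] for dt [s],
// followed by exponential relaxation toward (0,0,1). Rodrigues formula; the
// rotation angle is -gamma*|B|*dt (Larmor precession).
static inline void rotate_relax(double m[3], double bx, double by, double bz,
                                double dt, double e1, double e2) {
    double bn = std::sqrt(bx * bx + by * by + bz * bz);
    if (bn > 0.0) {
        double ux = bx / bn, uy = by / bn, uz = bz / bn;
        double ang = -GAMMA * bn * dt;
        double c = std::cos(ang), s = std::sin(ang), oc = 1.0 - c;
        double dot = ux * m[0] + uy * m[1] + uz * m[2];
        double rx = m[0] * c + (uy * m[2] - uz * m[1]) * s + ux * dot * oc;
        double ry = m[1] * c + (uz * m[0] - ux * m[2]) * s + uy * dot * oc;
        double rz = m[2] * c + (ux * m[1] - uy * m[0]) * s + uz * dot * oc;
        m[0] = rx; m[1] = ry; m[2] = rz;
    }
    m[0] *= e2;
    m[1] *= e2;
    m[2] = 1.0 + (m[2] - 1.0) * e1;
}

// Free precession about z by angle `ang` plus relaxation over an interval with
// longitudinal/transverse factors e1,e2 (exact: Bz-only evolution commutes).
static inline void precess_z_relax(double m[3], double ang, double e1, double e2) {
    double c = std::cos(ang), s = std::sin(ang);
    double mx = m[0] * c + m[1] * s;   // rotation by -ang about +z
    double my = -m[0] * s + m[1] * c;
    m[0] = mx * e2;
    m[1] = my * e2;
    m[2] = 1.0 + (m[2] - 1.0) * e1;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_simulate_passage")]]
Rcpp::List cpp_simulate_passage(double pulse_dur, double interval,
                                double peak_b1, double phase_inc,
                                int n_pulses, double g_max,
                                double refocus_amp, double refocus_dur,
                                double velocity, double z_start, double z_end,
                                double t1, double t2, double dt_pulse) {
    // units: seconds, tesla, T/m, m, m/s, radians
    double m[3] = {0.0, 0.0, 1.0};
    int nsub = (int)std::lround(pulse_dur / dt_pulse);
    if (nsub < 1) nsub = 1;
    double dt = pulse_dur / nsub;
    bool relax = R_finite(t1) && R_finite(t2);
    double e1 = relax ? std::exp(-dt / t1) : 1.0;
    double e2 = relax ? std::exp(-dt / t2) : 1.0;
    double gap = interval - pulse_dur - refocus_dur;
    if (gap < 0) gap = 0;
    double e1_ref = relax ? std::exp(-refocus_dur / t1) : 1.0;
    double e2_ref = relax ? std::exp(-refocus_dur / t2) : 1.0;
    double e1_gap = relax ? std::exp(-gap / t1) : 1.0;
    double e2_gap = relax ? std::exp(-gap / t2) : 1.0;

    double t = 0.0;      // time since start of train
    double t_exit = NA_REAL;
    int pulses_played = 0;
    bool exited = false;

    for (int n = 0; n < n_pulses; ++n) {
        double z_now = z_start + velocity * t;
        if (z_now >= z_end) { exited = true; t_exit = t; break; }
        double phi = phase_inc * n;
        double cphi = std::cos(phi), sphi = std::sin(phi);
        // RF pulse with slice-select gradient g_max
        for (int i = 0; i < nsub; ++i) {
            double tin = (i + 0.5) * dt;
            double b1 = peak_b1 * 0.5 * (1.0 - std::cos(2.0 * M_PI * tin / pulse_dur));
            double z = z_start + velocity * (t + tin);
            rotate_relax(m, b1 * cphi, b1 * sphi, g_max * z, dt, e1, e2);
        }
        t += pulse_dur;
        // rectangular refocusing lobe: analytic z-precession + relaxation
        double z0 = z_start + velocity * t;
        double ang = GAMMA * refocus_amp *
            (z0 * refocus_dur + 0.5 * velocity * refocus_dur * refocus_dur);
        precess_z_relax(m, ang, e1_ref, e2_ref);
        t += refocus_dur;
        if (gap > 0) precess_z_relax(m, 0.0, e1_gap, e2_gap);
        t += gap;
        ++pulses_played;
    }
    if (!exited) {
        double z_now = z_start + velocity * t;
        if (z_now >= z_end) { exited = true; t_exit = t; }
    }
    return Rcpp::List::create(
        Rcpp::Named("mx") = m[0], Rcpp::Named("my") = m[1],
        Rcpp::Named("mz") = m[2], Rcpp::Named("t_end") = t,
        Rcpp::Named("t_exit") = t_exit,
        Rcpp::Named("pulses_played") = pulses_played,
        Rcpp::Named("exited") = exited);
}
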