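#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// B-spline interpolation with IIR prefiltering (Unser-style), mirror
// (whole-sample symmetric) boundary for the coefficient lattice.
// Sample points strictly outside the input voxel lattice map to 0.

static int n_poles(int order) {
    switch (order) {
    case 0: case 1: return 0;
    case 2: case 3: return 1;
    case 4: case 5: return 2;
    case 6: case 7: return 3;
    default: Rcpp::stop("spline order must be in 0..7");
    }
    return 0;
}

static void get_poles(int order, double *z) {
    switch (order) {
    case 2:
        z[0] = std::sqrt(8.0) - 3.0;
        break;
    case 3:
        z[0] = std::sqrt(3.0) - 2.0;
        break;
    case 4:
        z[0] = std::sqrt(664.0 - std::sqrt(438976.0)) + std::sqrt(304.0) - 19.0;
        z[1] = std::sqrt(664.0 + std::sqrt(438976.0)) - std::sqrt(304.0) - 19.0;
        break;
    case 5:
        z[0] = std::sqrt(135.0 / 2.0 - std::sqrt(17745.0 / 4.0)) +
               std::sqrt(105.0 / 4.0) - 13.0 / 2.0;
        z[1] = std::sqrt(135.0 / 2.0 + std::sqrt(17745.0 / 4.0)) -
               std::sqrt(105.0 / 4.0) - 13.0 / 2.0;
        break;
    case 6:
        z[0] = -0.488294589303044755130118038883789062112279161239377608394;
        z[1] = -0.081679271076237512597937765737059080653379610398148178525;
        z[2] = -0.001414151808325817510872439765585925278641690553467;
        break;
    case 7:
        z[0] = -0.535280430796438165542403781681646071833923152342692414812;
        z[1] = -0.122554615192326690515272264359357343605486549427295558490;
        z[2] = -0.009148694809608276928593021651647853415692563954599448264;
        break;
    }
}

static double initial_causal(const double *c, int n, double z, double tol) {
    int horizon = n;
    if (tol > 0.0) {
        horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(z)));
    }
    if (horizon < n) {
        double zn = z, sum = c[0];
        for (int i = 1; i < horizon; i++) {
            sum += zn * c[i];
            zn *= z;
        }
        return sum;
    }
    // exact: full mirror period 2n-2
    double zn = z, iz = 1.0 / z;
    double z2n = std::pow(z, (double)(n - 1));
    double sum = c[0] + z2n * c[n - 1];
    z2n *= z2n * iz;
    for (int i = 1; i <= n - 2; i++) {
        sum += (zn + z2n) * c[i];
        zn *= z;
        z2n *= iz;
    }
    return sum / (1.0 - std::pow(z, (double)(2 * n - 2)));
}

static double initial_anticausal(const double *c, int n, double z) {
    return (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
}

static void filter_line(double *c, int n, const double *z, int nz) {
    if (n == 1) return;
    double lambda = 1.0;
    for (int k = 0; k < nz; k++) {
        lambda *= (1.0 - z[k]) * (1.0 - 1.0 / z[k]);
    }
    for (int i = 0; i < n; i++) c[i] *= lambda;
    const double tol = 1e-15;
    for (int k = 0; k < nz; k++) {
        double zk = z[k];
        c[0] = initial_causal(c, n, zk, tol);
        for (int i = 1; i < n; i++) c[i] += zk * c[i - 1];
        c[n - 1] = initial_anticausal(c, n, zk);
        for (int i = n - 2; i >= 0; i--) c[i] = zk * (c[i + 1] - c[i]);
    }
}

// In-place prefilter of a 3-D array (column-major, dims d0,d1,d2)
static void prefilter3(std::vector<double> &a, int d0, int d1, int d2,
                       int order) {
    int nz = n_poles(order);
    if (nz == 0) return;
    double z[3];
    get_poles(order, z);
    std::vector<double> line;
    // axis 0
    line.resize(d0);
    for (int k = 0; k < d2; k++)
        for (int j = 0; j < d1; j++) {
            double *base = &a[(size_t)k * d0 * d1 + (size_t)j * d0];
            filter_line(base, d0, z, nz); // contiguous
        }
    // axis 1
    line.resize(d1);
    for (int k = 0; k < d2; k++)
        for (int i = 0; i < d0; i++) {
            for (int j = 0; j < d1; j++)
                line[j] = a[(size_t)k * d0 * d1 + (size_t)j * d0 + i];
            filter_line(&line[0], d1, z, nz);
            for (int j = 0; j < d1; j++)
                a[(size_t)k * d0 * d1 + (size_t)j * d0 + i] = line[j];
        }
    // axis 2
    line.resize(d2);
    for (int j = 0; j < d1; j++)
        for (int i = 0; i < d0; i++) {
            for (int k = 0; k < d2; k++)
                line[k] = a[(size_t)k * d0 * d1 + (size_t)j * d0 + i];
            filter_line(&line[0], d2, z, nz);
            for (int k = 0; k < d2; k++)
                a[(size_t)k * d0 * d1 + (size_t)j * d0 + i] = line[k];
        }
}

// de Boor weights for the n+1 cardinal B-splines covering x;
// on return k0 is the first support index, w[j] = beta_order(x - (k0+j)).
static inline void bspline_weights(double x, int order, int &k0, double *w) {
    if (order == 0) {
        k0 = (int)std::floor(x + 0.5);
        w[0] = 1.0;
        return;
    }
    double u = x + (order + 1) * 0.5;
    int i = (int)std::floor(u);
    k0 = i - order;
    double left[9], right[9], N[9];
    N[0] = 1.0;
    for (int j = 1; j <= order; j++) {
        left[j] = u - (double)(i + 1 - j);
        right[j] = (double)(i + j) - u;
        double saved = 0.0;
        for (int r = 0; r < j; r++) {
            double temp = N[r] / (right[r + 1] + left[j - r]);
            N[r] = saved + right[r + 1] * temp;
            saved = left[j - r] * temp;
        }
        N[j] = saved;
    }
    for (int j = 0; j <= order; j++) w[j] = N[j];
}

static inline int mirror_index(int i, int n) {
    if (n == 1) return 0;
    int period = 2 * n - 2;
    i %= period;
    if (i < 0) i += period;
    if (i >= n) i = period - i;
    return i;
}

static double sample3(const std::vector<double> &c, int d0, int d1, int d2,
                      double x, double y, double z, int order) {
    const double eps = 1e-9;
    if (x < -eps || x > d0 - 1 + eps || y < -eps || y > d1 - 1 + eps ||
        z < -eps || z > d2 - 1 + eps)
        return 0.0;
    int kx, ky, kz;
    double wx[9], wy[9], wz[9];
    bspline_weights(x, order, kx, wx);
    bspline_weights(y, order, ky, wy);
    bspline_weights(z, order, kz, wz);
    int ix[9], iy[9], iz[9];
    for (int j = 0; j <= order; j++) {
        ix[j] = mirror_index(kx + j, d0);
        iy[j] = mirror_index(ky + j, d1);
        iz[j] = mirror_index(kz + j, d2);
    }
    double acc = 0.0;
    for (int c2 = 0; c2 <= order; c2++) {
        double acc2 = 0.0;
        size_t off2 = (size_t)iz[c2] * d0 * d1;
        for (int c1 = 0; c1 <= order; c1++) {
            double acc1 = 0.0;
            size_t off1 = off2 + (size_t)iy[c1] * d0;
            for (int c0 = 0; c0 <= order; c0++)
                acc1 += wx[c0] * c[off1 + ix[c0]];
            acc2 += wy[c1] * acc1;
        }
        acc += wz[c2] * acc2;
    }
    return acc;
}

// [[Rcpp::export]]
NumericVector cpp_spline_prefilter(NumericVector input, IntegerVector dim,
                                   int order) {
    int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    std::vector<double> a(input.begin(), input.end());
    prefilter3(a, d0, d1, d2, order);
    NumericVector out(a.begin(), a.end());
    return out;
}

// Resample a 3-D volume through an affine map:
// input voxel coords (0-based, continuous) = A %*% (i, j, k, 1) for
// 0-based output voxel (i, j, k).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector input, IntegerVector dim,
                                  NumericMatrix A, IntegerVector outDim,
                                  int order) {
    int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    int o0 = outDim[0], o1 = outDim[1], o2 = outDim[2];
    std::vector<double> c(input.begin(), input.end());
    prefilter3(c, d0, d1, d2, order);
    NumericVector out((size_t)o0 * o1 * o2);
    double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2), a03 = A(0, 3);
    double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2), a13 = A(1, 3);
    double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2), a23 = A(2, 3);
    size_t idx = 0;
    for (int k = 0; k < o2; k++)
        for (int j = 0; j < o1; j++)
            for (int i = 0; i < o0; i++) {
                double x = a00 * i + a01 * j + a02 * k + a03;
                double y = a10 * i + a11 * j + a12 * k + a13;
                double z = a20 * i + a21 * j + a22 * k + a23;
                out[idx++] = sample3(c, d0, d1, d2, x, y, z, order);
            }
    return out;
}

// Interpolate a prefiltered (or raw, if prefilter=true) volume at arbitrary
// 0-based continuous voxel coordinates (n x 3 matrix).
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector input, IntegerVector dim,
                                NumericMatrix pts, int order,
                                bool prefilter) {
    int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    std::vector<double> c(input.begin(), input.end());
    if (prefilter) prefilter3(c, d0, d1, d2, order);
    int n = pts.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; i++)
        out[i] = sample3(c, d0, d1, d2, pts(i, 0), pts(i, 1), pts(i, 2), order);
    return out;
}

// Background voxels 6-connected to the volume border (exterior background).
// [[Rcpp::export]]
LogicalVector cpp_exterior_background(LogicalVector mask, IntegerVector dim) {
    int d0 = dim[0], d1 = dim[1], d2 = dim[2];
    size_t n = (size_t)d0 * d1 * d2;
    std::vector<char> ext(n, 0);
    std::vector<size_t> stack;
    stack.reserve(n / 8 + 1);
    auto idx = [&](int i, int j, int k) {
        return (size_t)k * d0 * d1 + (size_t)j * d0 + i;
    };
    auto push_if = [&](int i, int j, int k) {
        size_t id = idx(i, j, k);
        if (!ext[id] && !mask[id]) {
            ext[id] = 1;
            stack.push_back(id);
        }
    };
    for (int k = 0; k < d2; k++)
        for (int j = 0; j < d1; j++)
            for (int i = 0; i < d0; i++)
                if (i == 0 || j == 0 || k == 0 || i == d0 - 1 ||
                    j == d1 - 1 || k == d2 - 1)
                    push_if(i, j, k);
    while (!stack.empty()) {
        size_t id = stack.back();
        stack.pop_back();
        int k = (int)(id / ((size_t)d0 * d1));
        size_t rem = id % ((size_t)d0 * d1);
        int j = (int)(rem / d0), i = (int)(rem % d0);
        if (i > 0) push_if(i - 1, j, k);
        if (i < d0 - 1) push_if(i + 1, j, k);
        if (j > 0) push_if(i, j - 1, k);
        if (j < d1 - 1) push_if(i, j + 1, k);
        if (k > 0) push_if(i, j, k - 1);
        if (k < d2 - 1) push_if(i, j, k + 1);
    }
    LogicalVector out(n);
    for (size_t i = 0; i < n; i++) out[i] = (ext[i] != 0);
    return out;
}
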