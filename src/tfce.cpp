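#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement on a masked 3D grid.
//
// For voxel p with statistic v(p) > 0,
//   TFCE(p) = sum_{h = dh, 2dh, ..., <= v(p)} e_h(p)^E * h^H * dh
// where e_h(p) is the voxel count of the connected component containing p
// in the suprathreshold set {v >= h}. Negative values are enhanced on the
// negated map and re-signed by the caller-facing wrapper logic below.
//
// values : statistic for each masked voxel
// voxel  : 0-based linear index of each masked voxel into the full grid
// dims   : grid dimensions (x, y, z); linear index is x-fastest
// conn   : 6, 18 or 26 neighbourhood

static void enhance_one_sign(const std::vector<double>& w,
                             const std::vector<std::vector<int> >& nbr,
                             double E, double H, double dh,
                             std::vector<double>& out)
{
    const int n = (int) w.size();
    double vmax = 0.0;
    for (int i = 0; i < n; ++i) if (w[i] > vmax) vmax = w[i];
    if (vmax <= 0.0 || dh <= 0.0) return;

    const int nsteps = (int) std::floor(vmax / dh + 1e-9);
    std::vector<int> stamp(n, -1);
    std::vector<int> comp;
    comp.reserve(n);

    for (int k = 1; k <= nsteps; ++k) {
        const double h = k * dh;
        const double add_h = std::pow(h, H) * dh;
        for (int i = 0; i < n; ++i) {
            if (w[i] + 1e-12 < h || stamp[i] == k) continue;
            // BFS over the component containing i at threshold h
            comp.clear();
            std::queue<int> q;
            q.push(i);
            stamp[i] = k;
            while (!q.empty()) {
                int u = q.front(); q.pop();
                comp.push_back(u);
                const std::vector<int>& nb = nbr[u];
                for (size_t m = 0; m < nb.size(); ++m) {
                    int v = nb[m];
                    if (stamp[v] != k && w[v] + 1e-12 >= h) {
                        stamp[v] = k;
                        q.push(v);
                    }
                }
            }
            const double add = std::pow((double) comp.size(), E) * add_h;
            for (size_t m = 0; m < comp.size(); ++m) out[comp[m]] += add;
        }
    }
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerVector voxel,
                       IntegerVector dims, double E, double H, double dh,
                       int connectivity)
{
    const int n = values.size();
    if (voxel.size() != n) stop("values and voxel index lengths differ");
    if (dims.size() != 3) stop("dims must have length 3");
    if (dh <= 0) stop("dh must be positive");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const long long nfull = (long long) nx * ny * nz;
    std::vector<int> row((size_t) nfull, -1);
    for (int i = 0; i < n; ++i) {
        long long id = voxel[i];
        if (id < 0 || id >= nfull) stop("voxel index out of range");
        row[(size_t) id] = i;
    }

    // neighbour offsets for the requested connectivity
    std::vector<int> dx, dy, dz;
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                int s = std::abs(a) + std::abs(b) + std::abs(c);
                if (s == 0) continue;
                if (connectivity == 6 && s > 1) continue;
                if (connectivity == 18 && s > 2) continue;
                dx.push_back(a); dy.push_back(b); dz.push_back(c);
            }

    std::vector<std::vector<int> > nbr(n);
    for (int i = 0; i < n; ++i) {
        long long id = voxel[i];
        int x = (int) (id % nx);
        int y = (int) ((id / nx) % ny);
        int z = (int) (id / ((long long) nx * ny));
        for (size_t m = 0; m < dx.size(); ++m) {
            int xx = x + dx[m], yy = y + dy[m], zz = z + dz[m];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
            long long jd = (long long) zz * nx * ny + (long long) yy * nx + xx;
            int j = row[(size_t) jd];
            if (j >= 0) nbr[i].push_back(j);
        }
    }

    std::vector<double> pos(n, 0.0), neg(n, 0.0), w(n);
    for (int i = 0; i < n; ++i) w[i] = values[i] > 0 ? values[i] : 0.0;
    enhance_one_sign(w, nbr, E, H, dh, pos);
    for (int i = 0; i < n; ++i) w[i] = values[i] < 0 ? -values[i] : 0.0;
    enhance_one_sign(w, nbr, E, H, dh, neg);

    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = pos[i] - neg[i];
    return out;
}
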