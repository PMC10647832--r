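#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-wise 3D Haralick texture over a set of target voxels.
//
// For each target voxel: take the window of half-width `half` centered at
// the voxel, clipped at the volume boundary; rescale its intensities to
// integer grey levels 0..255 (min -> 0, max -> 255, rounded
// half-away-from-zero; constant window -> all 0); bin levels as
// floor(level * nbins / 256); accumulate a (symmetrized) GLCM over all
// in-window voxel pairs separated by each offset; normalize; reduce to
// contrast, correlation, energy, entropy, homogeneity. Correlation of a
// zero-variance GLCM is defined as 0. Entropy uses the natural log.
//
// The GLCM is kept as a dense nbins*nbins accumulator, but only touched
// cells are visited for the feature sums and reset, so the per-voxel cost
// scales with the number of distinct co-occurring pairs.
// [[Rcpp::export]]
NumericMatrix texture_maps_cpp(NumericVector vol, IntegerVector dim,
                               IntegerMatrix voxels, int half, int nbins,
                               IntegerMatrix offsets, bool symmetric) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = voxels.nrow();
    const int noff = offsets.nrow();
    const int wmax = 2 * half + 1;
    const int wcap = wmax * wmax * wmax;

    NumericMatrix out(n, 5);
    std::vector<double> glcm((size_t)nbins * nbins, 0.0);
    std::vector<int> touched;
    touched.reserve(4096);
    std::vector<int> bins(wcap);
    std::vector<double> wvals(wcap);

    for (int v = 0; v < n; ++v) {
        const int cx = voxels(v, 0) - 1;
        const int cy = voxels(v, 1) - 1;
        const int cz = voxels(v, 2) - 1;
        const int x0 = std::max(0, cx - half), x1 = std::min(nx - 1, cx + half);
        const int y0 = std::max(0, cy - half), y1 = std::min(ny - 1, cy + half);
        const int z0 = std::max(0, cz - half), z1 = std::min(nz - 1, cz + half);
        const int wx = x1 - x0 + 1, wy = y1 - y0 + 1, wz = z1 - z0 + 1;
        const int wn = wx * wy * wz;

        // gather window, find min/max
        double lo = R_PosInf, hi = R_NegInf;
        int idx = 0;
        for (int z = z0; z <= z1; ++z)
            for (int y = y0; y <= y1; ++y)
                for (int x = x0; x <= x1; ++x) {
                    double val = vol[(size_t)z * nx * ny + (size_t)y * nx + x];
                    wvals[idx++] = val;
                    if (val < lo) lo = val;
                    if (val > hi) hi = val;
                }
        // local 0-255 rescale, then bin
        if (hi > lo) {
            const double sc = 255.0 / (hi - lo);
            for (int i = 0; i < wn; ++i) {
                int level = (int)std::floor((wvals[i] - lo) * sc + 0.5);
                bins[i] = (level * nbins) >> 8;  // floor(level * nbins / 256)
            }
        } else {
            for (int i = 0; i < wn; ++i) bins[i] = 0;
        }

        // accumulate GLCM over offsets (pairs fully inside the window)
        touched.clear();
        double total = 0.0;
        for (int k = 0; k < noff; ++k) {
            const int dx = offsets(k, 0), dy = offsets(k, 1), dz = offsets(k, 2);
            const int ax0 = std::max(0, -dx), ax1 = std::min(wx - 1, wx - 1 - dx);
            const int ay0 = std::max(0, -dy), ay1 = std::min(wy - 1, wy - 1 - dy);
            const int az0 = std::max(0, -dz), az1 = std::min(wz - 1, wz - 1 - dz);
            for (int z = az0; z <= az1; ++z)
                for (int y = ay0; y <= ay1; ++y)
                    for (int x = ax0; x <= ax1; ++x) {
                        const int b1 = bins[(z * wy + y) * wx + x];
                        const int b2 = bins[((z + dz) * wy + (y + dy)) * wx + (x + dx)];
                        int cell = b1 * nbins + b2;
                        if (glcm[cell] == 0.0) touched.push_back(cell);
                        glcm[cell] += 1.0;
                        total += 1.0;
                        if (symmetric) {
                            cell = b2 * nbins + b1;
                            if (glcm[cell] == 0.0) touched.push_back(cell);
                            glcm[cell] += 1.0;
                            total += 1.0;
                        }
                    }
        }

        double con = 0.0, cor = 0.0, ene = 0.0, ent = 0.0, hom = 0.0;
        if (total > 0.0) {
            double mui = 0.0, muj = 0.0;
            for (size_t t = 0; t < touched.size(); ++t) {
                const int cell = touched[t];
                const double p = glcm[cell] / total;
                const int i = cell / nbins + 1, j = cell % nbins + 1;
                const double d = (double)(i - j);
                ene += p * p;
                ent -= p * std::log(p);
                con += d * d * p;
                hom += p / (1.0 + d * d);
                mui += i * p;
                muj += j * p;
            }
            // centered second pass for the correlation moments, matching
            // the definition sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j)
            double vi = 0.0, vj = 0.0, cij = 0.0;
            for (size_t t = 0; t < touched.size(); ++t) {
                const int cell = touched[t];
                const double p = glcm[cell] / total;
                const int i = cell / nbins + 1, j = cell % nbins + 1;
                vi += (i - mui) * (i - mui) * p;
                vj += (j - muj) * (j - muj) * p;
                cij += (i - mui) * (j - muj) * p;
            }
            cor = (vi > 0.0 && vj > 0.0) ? cij / std::sqrt(vi * vj) : 0.0;
        } else {
            // no admissible pairs: treat as a constant window
            ene = 1.0; hom = 1.0;
        }
        out(v, 0) = con;
        out(v, 1) = cor;
        out(v, 2) = ene;
        out(v, 3) = ent;
        out(v, 4) = hom;

        for (size_t t = 0; t < touched.size(); ++t) glcm[touched[t]] = 0.0;
    }
    return out;
}
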