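#ifndef SPV_CORE_H
#define SPV_CORE_H

#include <vector>
#include <cmath>
#include <cstddef>

// One Voronoi cell of the periodic tessellation, in coordinates relative to
// its own generator. Vertices are CCW; edge k runs v[k] -> v[k+1] and is a
// piece of the bisector between the generator and the owner point stored in
// (ex, ey) (relative coords) with base index eb (0-based, may equal the cell
// itself when the cell touches one of its periodic images).
struct VCell {
  double area;
  double perim;
  std::vector<double> vx, vy;
  std::vector<int>    eb;
  std::vector<double> ex, ey;
};

// Periodic Voronoi tessellation of the square box [0,L)^2.
// Throws (Rcpp::stop) on coincident generators.
void compute_voronoi(const std::vector<double>& px,
                     const std::vector<double>& py,
                     double L,
                     std::vector<VCell>& cells);

// Row indices of the per-type parameter matrix (columns = types).
enum ParRow {
  PAR_A0 = 0, PAR_P0, PAR_GAMMA, PAR_K, PAR_LAM, PAR_BETA,
  PAR_RB0, PAR_RD0, PAR_V0, PAR_DR, PAR_MU, PAR_NROW
};

inline double wrap_coord(double x, double L) {
  x -= L * std::floor(x / L);
  if (x < 0) x += L;
  if (x >= L) x -= L; // guard against rounding at the boundary
  return x;
}

#endif
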