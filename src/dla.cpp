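#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice diffusion-limited aggregation.
//
// A seed particle is frozen at the grid centre; walkers are released one at
// a time from a launch circle of radius (cluster radius + annulus margin),
// perform a nearest-neighbour random walk, and freeze on first contact with
// the cluster (4- or 8-neighbour sticking). Walkers straying beyond the
// kill radius (kill_factor x launch radius) or off the grid are discarded
// and relaunched. Growth stops when the cluster radius reaches
// stop_fraction x (smaller half-extent) or the particle budget is spent.
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix dla_grow_cpp(int height, int width, int budget,
                           double stop_fraction, double annulus_margin,
                           double kill_factor, bool eight_neighbour) {
  IntegerMatrix grid(height, width);
  const int cy = height / 2, cx = width / 2;  // 0-based centre
  grid(cy, cx) = 1;
  const double rstop = stop_fraction * (std::min(height, width) / 2.0);
  double rcluster = 0.0;
  int placed = 1;  // the seed counts against the particle budget

  const int dx4[4] = {1, -1, 0, 0};
  const int dy4[4] = {0, 0, 1, -1};
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nstick = eight_neighbour ? 8 : 4;
  const int *sdx = eight_neighbour ? dx8 : dx4;
  const int *sdy = eight_neighbour ? dy8 : dy4;

  while (placed < budget && rcluster < rstop) {
    const double rl = rcluster + annulus_margin;
    const double rk = kill_factor * rl;
    const double rk2 = rk * rk;
    const double th = unif_rand() * 2.0 * M_PI;
    int x = (int) std::lround(cx + rl * std::cos(th));
    int y = (int) std::lround(cy + rl * std::sin(th));
    if (x < 0 || x >= width || y < 0 || y >= height) continue;

    while (true) {
      const int step = std::min(3, (int)(unif_rand() * 4.0));
      x += dx4[step];
      y += dy4[step];
      if (x < 0 || x >= width || y < 0 || y >= height) break;  // killed
      const double ddx = x - cx, ddy = y - cy;
      if (ddx * ddx + ddy * ddy > rk2) break;                  // killed
      bool stuck = false;
      for (int k = 0; k < nstick; ++k) {
        const int nx = x + sdx[k], ny = y + sdy[k];
        if (nx >= 0 && nx < width && ny >= 0 && ny < height &&
            grid(ny, nx) == 1) {
          stuck = true;
          break;
        }
      }
      if (stuck) {
        grid(y, x) = 1;
        ++placed;
        const double r = std::sqrt(ddx * ddx + ddy * ddy);
        if (r > rcluster) rcluster = r;
        break;
      }
    }
  }
  return grid;
}
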