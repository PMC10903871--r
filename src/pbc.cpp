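#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays with dim = (z, y, x); 1-based linear index
// lin = z + (y-1)*Z + (x-1)*Z*Y. All kernels take node lists as 1-based
// linear indices into that layout.

namespace {

struct Offsets {
  std::vector<int> dz, dy, dx;
};

// connectivity 6/18/26: neighbors within one grid step whose nonzero
// axis count is <= 1 / 2 / 3
Offsets make_offsets(int connectivity) {
  int maxn;
  switch (connectivity) {
    case 6:  maxn = 1; break;
    case 18: maxn = 2; break;
    case 26: maxn = 3; break;
    default: stop("connectivity must be 6, 18 or 26");
  }
  Offsets o;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int n = (dz != 0) + (dy != 0) + (dx != 0);
        if (n >= 1 && n <= maxn) {
          o.dz.push_back(dz); o.dy.push_back(dy); o.dx.push_back(dx);
        }
      }
  return o;
}

inline int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

} // namespace

// ToMATo sweep over foreground voxels.
// nodes: 1-based linear indices, already sorted by processing order
//   (decreasing density, ties by lexicographic (z,y,x));
// dens: density in that same order.
// Returns per-node fine labels (1-based, in founding order), the coarse root
// fine id of every fine cluster after delta-merging, and elder-rule
// birth/death per fine cluster (death NA only until filled with the
// component minimum for component-global peaks).
// [[Rcpp::export]]
List tomato_cpp(IntegerVector dim, IntegerVector nodes, NumericVector dens,
                int connectivity, double delta) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = nodes.size();
  if (n == 0) stop("empty node set");
  Offsets off = make_offsets(connectivity);
  const int noff = (int)off.dz.size();

  // map linear voxel index -> processing position (1-based), 0 = background
  std::vector<int> pos((size_t)Z * Y * X, 0);
  for (R_xlen_t i = 0; i < n; ++i) pos[nodes[i] - 1] = (int)i + 1;

  std::vector<int> fine(n, 0);             // fine cluster id per node
  std::vector<int> peak_pos;               // founding position per fine cluster
  std::vector<double> birth, death;        // elder-rule pairs per fine cluster
  std::vector<int> cparent;                // union-find over fine ids: delta-merged clusters
  std::vector<int> kparent;                // union-find over fine ids: connected components
  std::vector<int> kpeak;                  // elder peak (fine id) of each component root
  std::vector<double> klast;               // density of last node merged into component

  std::vector<int> nbr_roots; nbr_roots.reserve(noff);

  for (R_xlen_t i = 0; i < n; ++i) {
    const int lin0 = nodes[i] - 1;
    const int z = lin0 % Z, y = (lin0 / Z) % Y, x = lin0 / (Z * Y);
    const double fv = dens[i];

    int best = -1; // processed neighbor with smallest position = steepest
    nbr_roots.clear();
    for (int k = 0; k < noff; ++k) {
      const int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      const int p = pos[(size_t)zz + (size_t)yy * Z + (size_t)xx * Z * Y];
      if (p == 0 || p > (int)i + 1) continue; // background or not yet processed
      const int j = p - 1;
      if (best < 0 || j < best) best = j;
      const int r = uf_find(cparent, fine[j] - 1);
      bool seen = false;
      for (int q : nbr_roots) if (q == r) { seen = true; break; }
      if (!seen) nbr_roots.push_back(r);
    }

    if (best < 0) {
      // new peak: founds a fine cluster, its own coarse cluster and component
      const int f = (int)peak_pos.size();
      peak_pos.push_back((int)i + 1);
      birth.push_back(fv);
      death.push_back(NA_REAL);
      cparent.push_back(f);
      kparent.push_back(f);
      kpeak.push_back(f);
      klast.push_back(fv);
      fine[i] = f + 1;
      continue;
    }

    fine[i] = fine[best];

    // delta rule: among the coarse roots meeting at v, the root with the
    // highest peak survives (ties by lexicographically smaller peak, i.e.
    // smaller processing position); any other root whose prominence at v
    // is below delta is merged into it.
    int rmax = nbr_roots[0];
    for (int r : nbr_roots) if (peak_pos[r] < peak_pos[rmax]) rmax = r;
    for (int r : nbr_roots) {
      if (r == rmax) continue;
      if (birth[r] - fv < delta) cparent[r] = rmax;
    }

    // elder rule on components: when components join at v, the one whose
    // elder peak is younger dies at f(v)
    int kr = uf_find(kparent, fine[best] - 1);
    for (int r : nbr_roots) {
      int k2 = uf_find(kparent, r);
      if (k2 == kr) continue;
      int elder = kpeak[kr], younger = kpeak[k2];
      if (peak_pos[younger] < peak_pos[elder]) std::swap(elder, younger);
      death[younger] = fv;
      kparent[k2] = kr;
      kpeak[kr] = elder;
    }
    klast[kr] = fv; // nodes processed in decreasing density: running minimum
  }

  const int nf = (int)peak_pos.size();
  IntegerVector coarse_root(nf);
  NumericVector births(nf), deaths(nf);
  IntegerVector peak_node(nf), comp_root(nf);
  for (int f = 0; f < nf; ++f) {
    coarse_root[f] = uf_find(cparent, f) + 1;
    const int kr = uf_find(kparent, f);
    comp_root[f] = kr + 1;
    births[f] = birth[f];
    deaths[f] = R_IsNA(death[f]) ? klast[kr] : death[f];
    peak_node[f] = nodes[peak_pos[f] - 1];
  }

  return List::create(
    _["fine"] = IntegerVector(fine.begin(), fine.end()),
    _["coarse_root"] = coarse_root,
    _["comp_root"] = comp_root,
    _["birth"] = births,
    _["death"] = deaths,
    _["peak_node"] = peak_node);
}

// Multi-source shortest-path partition of a voxel set. seed_of: per node,
// 0 = unseeded, else seed (nucleus) id. Edge length = Euclidean grid step
// scaled by spacing (z, y, x) in um. Ties go to the smaller seed id.
// [[Rcpp::export]]
IntegerVector geodesic_partition_cpp(IntegerVector dim, IntegerVector nodes,
                                     IntegerVector seed_of, NumericVector spacing,
                                     int connectivity) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  const R_xlen_t n = nodes.size();
  Offsets off = make_offsets(connectivity);
  const int noff = (int)off.dz.size();
  std::vector<double> wlen(noff);
  for (int k = 0; k < noff; ++k) {
    const double dz = off.dz[k] * spacing[0], dy = off.dy[k] * spacing[1],
                 dx = off.dx[k] * spacing[2];
    wlen[k] = std::sqrt(dz * dz + dy * dy + dx * dx);
  }

  std::vector<int> id((size_t)Z * Y * X, 0); // voxel -> node index + 1
  for (R_xlen_t i = 0; i < n; ++i) id[nodes[i] - 1] = (int)i + 1;

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> assign(n, 0);
  // priority queue ordered by (distance, seed id): on equal distance the
  // smaller seed settles the voxel
  typedef std::tuple<double, int, int> Ent; // (dist, seed, node)
  std::priority_queue<Ent, std::vector<Ent>, std::greater<Ent> > pq;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seed_of[i] > 0) {
      dist[i] = 0.0; assign[i] = seed_of[i];
      pq.push(Ent(0.0, seed_of[i], (int)i));
    }
  if (pq.empty()) stop("no seed voxels");

  std::vector<bool> done(n, false);
  while (!pq.empty()) {
    Ent e = pq.top(); pq.pop();
    const double d = std::get<0>(e);
    const int s = std::get<1>(e), i = std::get<2>(e);
    if (done[i]) continue;
    if (d > dist[i] || (d == dist[i] && s > assign[i])) continue;
    done[i] = true;
    const int lin0 = nodes[i] - 1;
    const int z = lin0 % Z, y = (lin0 / Z) % Y, x = lin0 / (Z * Y);
    for (int k = 0; k < noff; ++k) {
      const int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      const int j = id[(size_t)zz + (size_t)yy * Z + (size_t)xx * Z * Y] - 1;
      if (j < 0 || done[j]) continue;
      const double nd = d + wlen[k];
      if (nd < dist[j] || (nd == dist[j] && s < assign[j])) {
        dist[j] = nd; assign[j] = s;
        pq.push(Ent(nd, s, j));
      }
    }
  }
  return IntegerVector(assign.begin(), assign.end());
}

// Number of adjacent voxel pairs (a in A, b in B) at the given connectivity.
// [[Rcpp::export]]
double count_adjacent_pairs_cpp(IntegerVector dim, IntegerVector idx_a,
                                IntegerVector idx_b, int connectivity) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  Offsets off = make_offsets(connectivity);
  const int noff = (int)off.dz.size();
  std::vector<char> inb((size_t)Z * Y * X, 0);
  for (R_xlen_t i = 0; i < idx_b.size(); ++i) inb[idx_b[i] - 1] = 1;
  double cnt = 0;
  for (R_xlen_t i = 0; i < idx_a.size(); ++i) {
    const int lin0 = idx_a[i] - 1;
    const int z = lin0 % Z, y = (lin0 / Z) % Y, x = lin0 / (Z * Y);
    for (int k = 0; k < noff; ++k) {
      const int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      if (inb[(size_t)zz + (size_t)yy * Z + (size_t)xx * Z * Y]) cnt += 1;
    }
  }
  return cnt;
}

// Enumerate undirected grid-adjacency edges among the listed voxels,
// as pairs of node positions (1-based into `nodes`), each edge once (i < j).
// [[Rcpp::export]]
IntegerMatrix voxel_edges_cpp(IntegerVector dim, IntegerVector nodes,
                              int connectivity) {
  const int Z = dim[0], Y = dim[1], X = dim[2];
  Offsets off = make_offsets(connectivity);
  const int noff = (int)off.dz.size();
  std::vector<int> id((size_t)Z * Y * X, 0);
  for (R_xlen_t i = 0; i < nodes.size(); ++i) id[nodes[i] - 1] = (int)i + 1;
  std::vector<int> ei, ej;
  for (R_xlen_t i = 0; i < nodes.size(); ++i) {
    const int lin0 = nodes[i] - 1;
    const int z = lin0 % Z, y = (lin0 / Z) % Y, x = lin0 / (Z * Y);
    for (int k = 0; k < noff; ++k) {
      const int zz = z + off.dz[k], yy = y + off.dy[k], xx = x + off.dx[k];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      const int j = id[(size_t)zz + (size_t)yy * Z + (size_t)xx * Z * Y];
      if (j > (int)i + 1) { ei.push_back((int)i + 1); ej.push_back(j); }
    }
  }
  IntegerMatrix out((int)ei.size(), 2);
  for (size_t r = 0; r < ei.size(); ++r) { out(r, 0) = ei[r]; out(r, 1) = ej[r]; }
  return out;
}
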