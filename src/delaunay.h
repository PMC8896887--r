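#ifndef FLUCTSORT_DELAUNAY_H
#define FLUCTSORT_DELAUNAY_H

#include <vector>
#include <utility>

// 3D Delaunay tetrahedralization (Bowyer-Watson). Returns unique edges
// (0-based index pairs). If hull_vertices is non-null, fills it with the
// vertices of boundary faces (the convex hull). Input: n points, xyz
// interleaved. Throws std::runtime_error on degenerate (coplanar) input.
std::vector<std::pair<int,int> > delaunay3_edges(const std::vector<double>& pts,
                                                 int n,
                                                 std::vector<int>* hull_vertices,
                                                 std::vector<std::pair<int,int> >* hull_edges = 0);

// 2D Delaunay triangulation; returns triangles as index triples (flattened,
// 0-based). Input: n points, xy interleaved.
std::vector<int> delaunay2_tris(const std::vector<double>& pts, int n);

#endif
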