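# curvomesh

Reliable per-triangle estimation of surface normals, principal directions and
principal curvatures on triangle meshes extracted from binary voxel
segmentations — the kind of data produced when cellular membranes are
segmented from cryo-electron tomograms (and, more generally, from light
microscopy or MRI). Such meshes carry *quantization noise* (triangles follow
the voxel steps) and *open borders* (missing-wedge artifacts, segmentation
holes), which defeat classical one-ring curvature operators. curvomesh is for
researchers who need quantitative membrane morphology — curvature
distributions per organelle, detection of high-curvature features — straight
from segmentation masks.

## Method

From a *compartment segmentation* (membrane mask + filled lumen mask) a
signed, single-layer triangle mesh is extracted: the joined binary volume is
smoothed with a Gaussian kernel (σ = 1 voxel), isosurfaced with Marching
Cubes at the half-maximum level, and masked back to within 3 voxels of the
membrane. Normals point into the filled compartment (inwards on a convex
surface).

The mesh is mapped to a **surface graph**: one vertex per triangle at its
centroid, *strong* edges between triangles sharing an edge, *weak* edges
between triangles sharing a vertex, edge lengths = centroid distances.
Dijkstra shortest paths over this graph approximate geodesic distances;
border triangles are those with fewer than three strong edges, and triangles
within a chosen geodesic distance of a border can be removed.

Estimation is by **tensor voting** over the geodesic neighborhood of each
triangle, with a single scale parameter `radius_hit` (rh ≈ 1/max estimable
curvature; neighborhood reach g_max = π·rh/2, weight decay 3σ = g_max):

* normals (**VV**): each neighbor's normal is transported along the shortest
  circular arc, n_i = n_ci + 2 cos θ_i · v̂c_i, and accumulated as
  V_v = Σ w_i n_i n_iᵀ with w_i = (a_i/a_max)·exp(−g_i/σ); the dominant
  eigenvector, re-signed by the original orientation, is the estimate;
* curvatures (**RVV**/**AVV**/**NVV**): each neighbor casts κ_i t_i t_iᵀ with
  tangent t_i and arc curvature |κ_i| = 2 sin(φ_i/2)/‖vv_i‖ signed by the
  bending direction, into B_v = (1/2π) Σ w_i κ_i t_i t_iᵀ, Σw_i = 2π; the
  eigenvector most parallel to the normal is discarded (b₃ ≈ 0) and
  κ₁ = 3b₁ − b₂, κ₂ = 3b₂ − b₁. AVV (area-weighted votes, default) is the
  most robust on irregular and quantization-noise meshes;
* **SSVV**: eight surface samples at tangent distance rh (line–mesh
  intersections parallel to the normal), each contributing the osculating-
  circle curvature κ_i = 2h/(rh² + h²) — exact on spheres.

Derived measures per triangle: mean and Gaussian curvature, curvedness, and
Koenderink's shape index. Accuracy on benchmark surfaces is summarized by the
normalized area under the cumulative histogram of errors (vector error
1 − |v_t·v_e|; relative curvature error |κ_t − κ_e|/|κ_t|).

## Worked example

The standard quantization-noise benchmark: a binary ball of radius 10 voxels
in a 25³ volume, isosurfaced without smoothing, AVV at rh = 10 voxels.

```r
library(curvomesh)

sphere <- make_voxel_sphere(r = 10, box = 25)
graph  <- build_surface_graph(sphere$mesh)
print(graph)
#> <surface_graph> 3800 vertices, 5700 strong + 17942 weak edges, 0 border

mesh <- estimate_normals(sphere$mesh, graph, rh = 10)
mesh <- estimate_curvature(mesh, graph, rh = 10, algorithm = "AVV")
tibble::as_tibble(mesh)[, c("triangle", "area", "kappa_1", "kappa_2",
                            "mean_curvature", "shape_index")]
#> # A tibble: 3,800 x 6
#>   triangle  area kappa_1 kappa_2 mean_curvature shape_index
#>      <int> <dbl>   <dbl>   <dbl>          <dbl>       <dbl>
#> 1        1 0.217  0.0981  0.0911         0.0946       0.976
#> 2        2 0.217  0.102   0.0959         0.0992       0.979
#> 3        3 0.217  0.102   0.0963         0.0994       0.980
#> 4        4 0.217  0.0987  0.0909         0.0948       0.974
#> # i 3,796 more rows

ev <- evaluate_against_truth(mesh, sphere$truth)
median(mesh$data$kappa_1) # truth: 1/r = 0.1 voxel^-1
#> [1] 0.1019
100 * cumulative_auc(c(ev$err_kappa_1, ev$err_kappa_2))
#> [1] 97.46
```

Both principal curvatures land on the true 0.1 voxel⁻¹ despite the voxel
staircase (shape index ≈ 1: a spherical cap everywhere), and the pooled
cumulative-histogram area is 97.5%. `run_benchmark_table()` produces the full
algorithm × rh accuracy table for any benchmark surface, and
`plot_error_histogram()` draws the cumulative error curves.

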