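---
title: "Mesh-based Monte Carlo photon transport: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesh-based Monte Carlo photon transport: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`photonmesh` simulates light transport in turbid biological tissue by Monte
Carlo integration of the radiative transfer equation over a labeled
tetrahedral mesh.  This vignette is the package's own account of the models
it implements, the parameters that matter, and the places where a design
decision was genuinely open — together with what the test suite does and
does not demonstrate.

## The transport model

Photons are simulated as packets carrying a statistical weight, initialized
at 1.  A packet in a region with scattering coefficient $\mu_s$ travels a
free path $s = -\ln(u)/\mu_s$ to its next scattering site; a non-scattering
region ($\mu_s = 0$) propagates ballistically to the boundary.  Along every
traversed segment the weight is attenuated continuously,
$w \leftarrow w\,e^{-\mu_a s}$, rather than by discrete albedo splitting at
scattering sites: continuous attenuation has lower variance and keeps the
absorbed-energy ledger exact.  At a scattering site the new direction is
drawn from the Henyey–Greenstein phase function,

$$\cos\theta = \frac{1}{2g}\left[1 + g^2 -
  \left(\frac{1-g^2}{1-g+2gu}\right)^2\right],\qquad g \neq 0,$$

with $\cos\theta$ uniform on $[-1,1]$ for $g=0$ and the azimuth uniform on
$[0, 2\pi)$.  Elapsed time advances by $s\,n/c$ with
$c = 299.792458$ mm/ns.  Packets are terminated by escape through the outer
boundary, by reaching the end of the time gate (booked *truncated*), or by
Russian roulette: below a weight threshold ($10^{-4}$ by default) the packet
survives with probability $p = 0.1$ and is reweighted by $1/p$, an unbiased
termination rule.

When reflection handling is enabled, every face crossing into a region of
different refractive index evaluates the unpolarized Fresnel reflectance
(the s/p average), reflects specularly with that probability and otherwise
refracts by Snell's law; beyond the critical angle the reflectance is 1.
With reflection off, boundaries transmit without deflection — useful for
matched-boundary validation against diffusion theory.  The exterior medium
defaults to air ($n = 1$, no interaction).

### Ray–tetrahedron traversal

Traversal uses barycentric gradients.  For the current tetrahedron the
barycentric coordinates $\lambda_i(p)$ and their directional derivatives
$d\lambda_i = \nabla\lambda_i \cdot \hat d$ are evaluated from a precomputed
$3\times 3$ gradient matrix per element; the exit face is the face whose
coordinate first reaches zero, $t_{\mathrm{exit}} = \min_{d\lambda_i<0}
(-\lambda_i/d\lambda_i)$, and the face index directly addresses a
precomputed face-adjacency table.  The same $\lambda$ values split each
segment's deposit among the element's four nodes at the segment midpoint.
Degenerate cases (a ray running exactly in a face plane) are handled by a
stuck-packet guard: a packet that crosses faces repeatedly without advancing
is terminated and its weight booked as *lost*, which is reported and must
stay below $10^{-5}$ of the launched weight (it is identically zero in all
packaged benchmarks).

### Fluence estimator and normalization

The per-segment deposit is

$$U = w\,\frac{1 - e^{-\mu_a s}}{\mu_a},$$

whose $\mu_a \to 0$ limit is the track-length estimator $w\,s$ (the
implementation switches to the series form below $\mu_a s \approx 10^{-8}$).
This single expression is equal to absorbed energy divided by $\mu_a$
wherever $\mu_a > 0$ and remains finite in non-absorbing regions, so no
per-region special-casing or "which region does a node belong to" rule is
needed at interfaces.  With normalization on, the reported fluence rate is
$\Phi(\mathrm{node}, \mathrm{gate}) = U / (V_{\mathrm{node}}\,
N_{\mathrm{photon}}\, \Delta t)$ with $V_{\mathrm{node}}$ a quarter of the
volume of the adjacent tetrahedra — i.e. fluence rate per unit launched
energy; multiplying by the gate width and summing over gates recovers the
continuous-wave fluence.

Weight accounting is an exact identity: Russian-roulette kills are booked
into the absorbed bucket and survival reweighting is subtracted from it, so
*absorbed + escaped + truncated + lost = launched* holds to floating-point
round-off on every run, not merely in expectation.

### Determinism

The core is single-threaded and driven by a self-contained PCG32 generator
seeded from `sim_settings(seed =)`; identical inputs reproduce the fluence
map bitwise on any platform.  Surface randomization and hair generation use
R's own RNG through `set.seed()` and restore the caller's RNG state
afterwards.

## Meshing

Scenes are ordered lists of labeled shape predicates over a bounding box,
with later regions overriding earlier ones — an embedded vessel overrides
its host layer.  All predicates are half-open (closed low side, open high
side), which makes point membership a total, deterministic function; a point
exactly on a layer cut belongs to the layer above it.  A `unit_scale` factor
(mm per model unit, e.g. mm per voxel) is applied exactly once at scene
construction, so every downstream quantity is in mm and the scale cannot be
applied twice.

Tetrahedralization is a body lattice: the bounding box is divided into
hexahedral cells of pitch $h = (6 V_{\max})^{1/3}$ — so the stated maximum
element volume holds exactly — with the z grid snapped to every layer
interface; each cell is split into the six Kuhn tetrahedra around its main
diagonal.  Because all cells use the same diagonal in index space, each
shared quad face is cut along the diagonal through its lexicographic min/max
corners in both neighbors, so the global mesh is face-conforming with no
Steiner points and no alternation bookkeeping.  Each tetrahedron takes the
label of its centroid; outside elements (label 0) and then unreferenced
nodes are dropped.  Labeled volumes mesh the same way with one cell per
voxel (optionally subdivided to honor a smaller volume bound), so nonzero
voxels inherit their labels exactly and neighboring voxels share nodes.

The consequences are deliberate: planar layer interfaces are represented
*exactly* (snapped z planes), while curved boundaries are voxelized at pitch
$h$, so per-region volumes of smooth shapes converge at rate $O(h)$ — the
test suite verifies monotone convergence of the vessel-cylinder volume under
pitch halving.  A boundary-conforming Delaunay mesher would converge faster
on curved interfaces; the lattice was chosen for robustness (no
self-intersection or sliver failure modes) and exact volume conservation,
which the suite checks to $10^{-9}$ relative.  If the pitch exceeds the
thinnest layer it is halved (with a warning) up to six times before failing.

## File formats

Meshes travel as JSON/JMesh documents: `MeshVertex3` ($N_n \times 3$, mm),
`MeshTri3`, and `MeshTet4` with the region label stored as a fifth column —
one of two plausible encodings (the alternative being a separate construct);
the column form was chosen and is stated here for cross-tool interchange.
Indices are 1-based in files and 1-based in memory (R's native convention),
so no index translation exists anywhere.  Arrays may be plain nested JSON,
typed annotated objects (type tag, size tag, row-major payload) or
compressed annotations whose payload is the little-endian binary array,
zlib-compressed (RFC 1950) and base64-encoded (RFC 4648); all three decode
to identical matrices, and plain/annotated reals are printed with 17
significant digits so every writer round-trips bit-exactly.  Unknown keys
are preserved verbatim in metadata.  Volumes are NIfTI-1 (isotropic voxels
only; anisotropy is rejected, not resampled) or text JNIfTI; non-integer
volume data is rejected, never rounded.

## Rough surfaces

A rough interface is a subdivided plane: `cuts = k` interior cuts per edge
give $(k+1)^2$ quad cells, i.e. a $41\times 41$ vertex grid for the
40-segment surface used in the packaged rough-skin benchmark.  Each vertex
height is drawn independently and uniformly on $[-a, +a]$ — a bounded,
normal-direction-constrained random move.  Roughness is quantified by the
arithmetic mean deviation of the depth profile; on the grid this is the mean
of $|Z - \bar Z|$ over all vertices (heights measured from their mean, which
makes the statistic translation invariant).  The definition is a 1-D profile
integral; computing it over all grid vertices yields the single surface-wide
value reported per surface.  For uniform offsets $E[\mathrm{Ra}] = a/2$, so
the benchmark amplitude $a = 0.5\ \mu m$ gives the expected
$\mathrm{Ra} = 0.25\ \mu m$; the acceptance script averages the statistic
over 200 independently seeded surfaces.  A documented companion case with
$\mathrm{Ra} = 1.5\ \mu m$ does not pin down its amplitude, so the amplitude
is left a free parameter ($a = 3\ \mu m$ would give that expectation) and no
check is attached to it.  The randomized grid enters scenes as a half-open
height-field region (inside iff $z < z_0 + Z(x,y)$, bilinear interpolation),
so a zero-amplitude surface is exactly equivalent to a planar layer cut.

## Hair geometry

Hair fibers are polylines grown from roots sampled area-uniformly on a host
surface (triangle chosen proportional to area, square-root barycentric
sampling within).  The base direction is the surface normal rotated by a
fixed tilt angle toward a tilt axis; a "randomness" parameter $r \in [0,1]$
perturbs each fiber by a random rotation of angle uniform in
$[0, r \cdot 90^\circ]$ about a uniform azimuth — a bounded cone, chosen
because the upstream tools leave the semantics of their randomness knob
undocumented, and a bounded cone is testable.  Gravity bending is a
deterministic progressive rotation: segment $k$ (0-indexed from the root)
rotates toward $(0,0,-1)$ by $g\,k\,\Delta$ with
$\Delta = 90^\circ/\mathrm{segments}$, clamped so a segment never rotates
past straight down.  The clamp (rather than a fixed $90^\circ$ cap) is what
makes strong gravity drive terminal segments to $(0,0,-1)$ regardless of the
initial tilt, and rotation preserves each segment's length, so bending is
isometric and root-preserving.  This replaces mass–spring hair dynamics: the
dynamics are used upstream only to produce plausible curved geometry, and a
parametric bend produces comparable shapes deterministically.  Fibers are
exported as a JMesh vertex list plus per-fiber index runs and a radius
annotation; optical transport through hairs is out of scope here (the
geometry feeds implicit-MC tools).

## Packaged benchmarks

* **skinvessel** — three skin layers (cuts at 0.10 and 0.16 mm) plus a
  0.1 mm-radius vessel along y in a 1 mm cube (unit scale 0.005 mm/voxel);
  disk source, radius 50 voxels, at $(100, 100, -10)$ voxels pointing $+z$.
  The bottom layer's published coefficients ($\mu_a = 0$, $\mu_s = 1$,
  $g = 1$ — an effectively non-interacting layer) are reproduced verbatim
  rather than corrected.
* **skinvessel_rough** — the same model at unit scale 0.0005 (domain shrunk
  10×), the lower interface roughened (39 cuts, amplitude one model unit
  = 0.5 µm) and the tilted disk source ($150^\circ$ about x, radius 25 µm).
* **slab_hair** — a $20 \times 50 \times 34.51$ mm three-layer head slab
  (12.44 mm scalp/skull, 2.07 mm CSF, 20 mm brain) with 1000 straight hairs
  on the top face.  The layer optics are not published for this geometry;
  the scalp/CSF/gray-matter rows of the head-atlas table are used, a choice
  made once and recorded here.
* **colin27 / digimouse** — the head-atlas and mouse-atlas optical tables
  and sources are packaged, but the atlas surface mesh / labeled volume are
  user-supplied external inputs; without them the pipeline fails with an
  actionable message, and no test depends on them.

Default photon counts are $10^5$ for desk-scale runs; the published
benchmark figures use far larger counts, which are a parameter away
(`nphoton`).

## Problem sizes and numerical tolerances

The test suite runs the skin-vessel benchmark at $2\times 10^4$ photons and
coarse lattice pitches (0.05–0.1 mm), the Beer–Lambert slab at $10^5$, the
diffusion-limit validation at $10^6$ photons on a 40 mm box at 2 mm pitch,
and Henyey–Greenstein moments at $10^6$ draws — sizes chosen so the whole
suite completes in minutes on one core while leaving the statistical
tolerances meaningful ($3\sigma$ bands for stochastic checks, $10^{-9}$
relative for exact conservation identities, 10% for the diffusion
comparison in $r \in [3, 10]$ mm with the pencil source treated as an
isotropic point displaced one transport mean free path).  The diffusion
check uses $g = 0$ at $\mu_s' = 1$/mm: diffusion depends on $\mu_s' =
\mu_s(1-g)$ only, and isotropic scattering reaches the asymptotic regime
with an order of magnitude fewer scattering events than $g = 0.9$ at equal
$\mu_s'$.

Numerical guards worth knowing: face-exit candidates tolerate barycentric
coordinates down to $-10^{-12}$ before a face is considered crossed;
tetrahedra are re-oriented at construction so all signed volumes are
positive, and degenerate (zero-volume) elements are rejected; scene bounds
checks use a $10^{-9}$ relative tolerance; z-interface deduplication merges
planes within $10^{-9}$ mm.

## What the tests do and do not show

The synthetic scenes and oracles exercise every contract of the pipeline —
format fidelity, mesh conformity and conservation, transport physics against
closed forms (Beer–Lambert, Fresnel, Henyey–Greenstein moments) and against
the diffusion approximation in its regime of validity.  They do not
demonstrate accuracy on curved anatomical boundaries at coarse pitch (the
lattice voxelizes them; refine the pitch), polarization, fluorescence or
wide-field sources (not modeled), or hair *optical* effects (geometry export
only).  The published mesh-size figures for the atlas benchmarks depend on
the specific Delaunay mesher and its version and are not reproduced by the
lattice mesher by design.
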