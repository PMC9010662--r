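# Tetrahedral meshing.
#
# Scenes and labeled volumes are tessellated on a rectilinear body lattice:
# each hexahedral cell is split into the six Kuhn tetrahedra sharing the
# cell's main diagonal.  Because every cell uses the same diagonal in index
# space, each shared quad face is cut along the diagonal through its
# lexicographic min/max corners in both adjacent cells, so the global mesh is
# face-conforming without Steiner points.  Element labels come from the
# region membership of each tetrahedron centroid; label-0 (outside) elements
# and then unreferenced nodes are removed.

# local corner order of a hexahedral cell (unit cube):
# 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0) 5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
.cube_corner_offsets <- matrix(c(
  0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
  0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1), ncol = 3, byrow = TRUE)

# the six Kuhn tetrahedra around the diagonal corner1 -> corner7
.cube_tet_indices <- matrix(c(
  1, 2, 3, 7,
  1, 2, 6, 7,
  1, 4, 3, 7,
  1, 4, 8, 7,
  1, 5, 6, 7,
  1, 5, 8, 7), ncol = 4, byrow = TRUE)

#' Decompose a rectangular box into six tetrahedra
#'
#' Splits a box given by its 8 corners (canonical order: bottom face
#' counter-clockwise, then top face) into the six tetrahedra sharing the main
#' diagonal.  No nodes are added; the six signed volumes are positive and sum
#' to the box volume, and the induced boundary is 12 triangles (two per
#' face).
#'
#' @param corners numeric `8 x 3` matrix of box corner coordinates.
#' @return a [tet_mesh()] with 8 nodes, 6 elements (label 1) and 12 boundary
#'   triangles.
#' @export
cube_to_tets <- function(corners) {
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(8, 3))) stop("corners must be an 8 x 3 matrix")
  e1 <- corners[2, ] - corners[1, ]
  e2 <- corners[4, ] - corners[1, ]
  e3 <- corners[5, ] - corners[1, ]
  if (any(abs(c(sum(e1 * e2), sum(e1 * e3), sum(e2 * e3))) >
          1e-9 * max(sum(e1^2), sum(e2^2), sum(e3^2))))
    stop("corners do not form a rectangular box")
  if (min(sum(e1^2), sum(e2^2), sum(e3^2)) == 0)
    stop("degenerate box: zero-length edge")
  tet_mesh(corners, .cube_tet_indices, labels = rep(1L, 6))
}

# signed volumes of tets (elem is Ne x 4, 1-based)
.tet_signed_volume <- function(node, elem) {
  a <- node[elem[, 1], , drop = FALSE]
  b <- node[elem[, 2], , drop = FALSE] - a
  c_ <- node[elem[, 3], , drop = FALSE] - a
  d <- node[elem[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Tetrahedron volumes of a mesh
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of positive element volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  .tet_signed_volume(mesh$node, mesh$elem)
}

#' Construct a labeled tetrahedral mesh
#'
#' Validates indices, canonicalizes element orientation so every signed
#' volume is positive, checks that every node is referenced, and extracts the
#' domain boundary (triangles belonging to exactly one element) into `$face`.
#'
#' @param node numeric `Nn x 3` coordinate matrix (mm).
#' @param elem integer `Ne x 4` matrix of 1-based node indices.
#' @param labels integer vector of per-element region labels (default all 1).
#' @return an object of class `tet_mesh` with fields `node`, `elem`,
#'   `label`, `face` and `neighbor` (per-element face adjacency, 0 at the
#'   boundary).
#' @export
tet_mesh <- function(node, elem, labels = NULL) {
  node <- as.matrix(node)
  storage.mode(node) <- "double"
  elem <- as.matrix(elem)
  storage.mode(elem) <- "integer"
  if (ncol(node) != 3 || ncol(elem) != 4) stop("node must be Nn x 3, elem Ne x 4")
  if (any(elem < 1L) || any(elem > nrow(node))) stop("element index out of range")
  if (is.null(labels)) labels <- rep(1L, nrow(elem))
  labels <- as.integer(labels)
  if (length(labels) != nrow(elem)) stop("labels must match element count")
  sv <- .tet_signed_volume(node, elem)
  flip <- sv < 0
  if (any(flip)) elem[flip, c(3, 4)] <- elem[flip, c(4, 3)]
  if (any(abs(sv) == 0)) stop("mesh contains a degenerate element")
  refd <- tabulate(elem, nbins = nrow(node))
  if (any(refd == 0))
    stop(sum(refd == 0), " node(s) are referenced by no element")
  nb <- cpp_tet_adjacency(elem, nrow(node))
  face <- .boundary_faces(node, elem, nb)
  structure(list(node = node, elem = elem, label = labels, face = face,
                 neighbor = nb), class = "tet_mesh")
}

# faces opposite local vertex f, for boundary extraction
.face_opposite <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))

# boundary triangles, wound so their normals point out of the mesh
.boundary_faces <- function(node, elem, nb) {
  out <- vector("list", 4)
  opp <- vector("list", 4)
  for (f in 1:4) {
    sel <- nb[, f] == 0L
    out[[f]] <- elem[sel, .face_opposite[[f]], drop = FALSE]
    opp[[f]] <- elem[sel, f]
  }
  tri <- do.call(rbind, out)
  opp <- unlist(opp)
  if (nrow(tri) == 0) return(tri)
  a <- node[tri[, 1], , drop = FALSE]
  b <- node[tri[, 2], , drop = FALSE]
  c_ <- node[tri[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) -
                 (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) -
                 (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) -
                 (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  inward <- node[opp, , drop = FALSE] - a
  flip <- rowSums(nrm * inward) > 0 # normal points toward the opposite vertex
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$node), "nodes,", nrow(x$elem),
      "elements,", nrow(x$face), "boundary triangles\n")
  tab <- table(x$label)
  cat("  labels:", paste(names(tab), "(", tab, ")", collapse = ", "), "\n")
  invisible(x)
}

#' Meshing options
#'
#' @param max_tet_volume upper bound on element volume (cubic model units,
#'   the meshing `Vmax`); mapped to lattice pitch `h = (6 Vmax)^(1/3)` so
#'   `h^3/6 <= Vmax` holds exactly for lattice tetrahedra.
#' @param pitch_override optional lattice pitch in mm, bypassing the Vmax
#'   mapping.
#' @return an object of class `meshing_options`.
#' @export
meshing_options <- function(max_tet_volume = 30, pitch_override = NULL) {
  if (max_tet_volume <= 0) stop("max_tet_volume must be > 0")
  structure(list(max_tet_volume = max_tet_volume,
                 pitch_override = pitch_override),
            class = "meshing_options")
}

# Build a lattice mesh from grid-line vectors and a per-cell label function.
# xs, ys, zs are ascending node coordinate vectors (mm).  label_fun receives
# an Ncells*6 x 3 matrix of tet centroids and returns integer labels.
.lattice_mesh <- function(xs, ys, zs, label_fun) {
  nx <- length(xs) - 1; ny <- length(ys) - 1; nz <- length(zs) - 1
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (length(xs)) * (j - 1) +
    (length(xs)) * (length(ys)) * (k - 1)
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz),
                       KEEP.OUT.ATTRS = FALSE)
  corner_ids <- matrix(0L, nrow(cells), 8)
  for (c8 in 1:8) {
    off <- .cube_corner_offsets[c8, ]
    corner_ids[, c8] <- nid(cells$i + off[1], cells$j + off[2],
                            cells$k + off[3])
  }
  elem <- do.call(rbind, lapply(1:6, function(t6)
    corner_ids[, .cube_tet_indices[t6, ], drop = FALSE]))
  cent <- (nodes[elem[, 1], , drop = FALSE] + nodes[elem[, 2], , drop = FALSE] +
           nodes[elem[, 3], , drop = FALSE] + nodes[elem[, 4], , drop = FALSE]) / 4
  lab <- as.integer(label_fun(cent))
  keep <- lab > 0L
  if (!any(keep)) stop("no foreground: every element is labeled 0")
  elem <- elem[keep, , drop = FALSE]
  lab <- lab[keep]
  used <- sort(unique(as.vector(elem)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  elem <- matrix(remap[elem], ncol = 4)
  tet_mesh(nodes[used, , drop = FALSE], elem, lab)
}

# subdivide [lo, hi] so that interior planes `cuts` are hit exactly and no
# interval exceeds pitch
.snapped_axis <- function(lo, hi, cuts, pitch) {
  planes <- sort(unique(c(lo, hi, cuts[cuts > lo & cuts < hi])))
  out <- numeric(0)
  for (i in seq_len(length(planes) - 1)) {
    a <- planes[i]; b <- planes[i + 1]
    n <- max(1L, ceiling((b - a) / pitch - 1e-9))
    out <- c(out, seq(a, b, length.out = n + 1)[-(n + 1)])
  }
  c(out, hi)
}

#' Tessellate a region scene into a labeled tetrahedral mesh
#'
#' Builds a rectilinear lattice over the scene bounds with pitch
#' `h = (6 Vmax)^(1/3)` (so the element-volume bound holds exactly), snapping
#' the z grid to every layer interface reported by [scene_interfaces_z()].
#' Each cell is split into six tetrahedra and each tetrahedron receives the
#' label of its centroid under [label_point()]; outside elements are
#' discarded.  Curved boundaries are therefore voxelized at pitch `h` --
#' refine the pitch to tighten them.
#'
#' @param scene a [build_scene()] result.
#' @param opts a [meshing_options()]; `max_tet_volume` is interpreted in
#'   cubic model units of the scene.
#' @return a [tet_mesh()].
#' @export
tetrahedralize_scene <- function(scene, opts = meshing_options()) {
  stopifnot(inherits(scene, "region_scene"), inherits(opts, "meshing_options"))
  h <- if (!is.null(opts$pitch_override)) opts$pitch_override else
    (6 * opts$max_tet_volume)^(1 / 3) * scene$unit_scale
  zplanes <- scene_interfaces_z(scene)
  min_gap <- min(diff(zplanes))
  halvings <- 0
  while (h > min_gap + 1e-12 && halvings < 6) {
    h <- h / 2
    halvings <- halvings + 1
  }
  if (halvings > 0)
    warning("lattice pitch exceeded the thinnest layer (", signif(min_gap, 4),
            " mm); halved ", halvings, " time(s) to ", signif(h, 4), " mm")
  if (h > min_gap + 1e-12)
    stop("cannot resolve layer of thickness ", signif(min_gap, 4),
         " mm after 6 pitch halvings")
  lo <- scene$bounds$lo; hi <- scene$bounds$hi
  ax <- function(k) {
    n <- max(1L, ceiling((hi[k] - lo[k]) / h - 1e-9))
    seq(lo[k], hi[k], length.out = n + 1)
  }
  xs <- ax(1); ys <- ax(2)
  zs <- .snapped_axis(lo[3], hi[3], zplanes, h)
  .lattice_mesh(xs, ys, zs, function(cent) label_point(scene, cent))
}

#' Convert a labeled voxel volume to a tetrahedral mesh
#'
#' Splits every nonzero voxel into six tetrahedra inheriting the voxel's
#' label; coordinates are scaled by the voxel size and nodes shared between
#' voxels are merged exactly.  If `opts$max_tet_volume` (in mm^3) is smaller
#' than a sixth of the voxel volume, each voxel is first subdivided into
#' `m^3` subcells with the smallest `m` restoring the bound.
#'
#' @param vol a [labeled_volume()].
#' @param opts a [meshing_options()]; `max_tet_volume` here is in mm^3.
#' @return a [tet_mesh()].
#' @export
volume_to_tetmesh <- function(vol, opts = meshing_options(max_tet_volume = Inf)) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (all(vol$voxels == 0L)) stop("no foreground: volume is all zeros")
  vs <- vol$voxel_size
  m <- 1L
  if (is.finite(opts$max_tet_volume))
    m <- max(1L, as.integer(ceiling((vs^3 / (6 * opts$max_tet_volume))^(1 / 3) - 1e-9)))
  d <- dim(vol$voxels)
  xs <- vol$origin[1] + seq(0, d[1]) * vs
  ys <- vol$origin[2] + seq(0, d[2]) * vs
  zs <- vol$origin[3] + seq(0, d[3]) * vs
  if (m > 1L) {
    refine <- function(v) {
      out <- unique(sort(c(v, unlist(lapply(seq_len(length(v) - 1), function(i)
        seq(v[i], v[i + 1], length.out = m + 1L))))))
      out
    }
    xs <- refine(xs); ys <- refine(ys); zs <- refine(zs)
  }
  lab_fun <- function(cent) {
    i <- pmin(pmax(floor((cent[, 1] - vol$origin[1]) / vs), 0), d[1] - 1) + 1
    j <- pmin(pmax(floor((cent[, 2] - vol$origin[2]) / vs), 0), d[2] - 1) + 1
    k <- pmin(pmax(floor((cent[, 3] - vol$origin[3]) / vs), 0), d[3] - 1) + 1
    vol$voxels[cbind(i, j, k)]
  }
  .lattice_mesh(xs, ys, zs, lab_fun)
}

#' Extract the boundary shell of one region
#'
#' Returns the closed triangular surface bounding the union of the
#' tetrahedra carrying a given label: the faces that belong to exactly one
#' element of that region.  The shell is watertight (every edge borders
#' exactly two triangles) whenever the region itself is a solid body.
#'
#' @param mesh a [tet_mesh()].
#' @param label region label present in the mesh.
#' @return a [surf_mesh()] with vertices compacted to those used.
#' @export
extract_region_surface <- function(mesh, label) {
  stopifnot(inherits(mesh, "tet_mesh"))
  if (!label %in% mesh$label)
    stop("label ", label, " not in mesh; available: ",
         paste(sort(unique(mesh$label)), collapse = ", "))
  sel <- mesh$label == label
  sub <- mesh$elem[sel, , drop = FALSE]
  nb <- cpp_tet_adjacency(sub, nrow(mesh$node))
  tri <- .boundary_faces(mesh$node, sub, nb)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(mesh$node))
  remap[used] <- seq_along(used)
  surf_mesh(mesh$node[used, , drop = FALSE], matrix(remap[tri], ncol = 3))
}

#' Summary statistics of a tetrahedral mesh
#'
#' @param mesh a [tet_mesh()].
#' @return a list with `nodes`, `elems`, `volume` (total, mm^3), `min_tet`,
#'   `max_tet`, and `per_label` (data.frame of element counts and volumes per
#'   region; the per-label volumes sum to the total).
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  v <- tet_volumes(mesh)
  per <- data.frame(label = sort(unique(mesh$label)))
  per$elems <- vapply(per$label, function(l) sum(mesh$label == l), integer(1))
  per$volume <- vapply(per$label, function(l) sum(v[mesh$label == l]),
                       numeric(1))
  list(nodes = nrow(mesh$node), elems = nrow(mesh$elem), volume = sum(v),
       min_tet = min(v), max_tet = max(v), per_label = per)
}
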