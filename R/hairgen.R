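# Hair-fiber geometry over a mesh surface.
#
# Fibers are polylines grown from area-uniformly sampled roots: the base
# direction is the surface normal tilted by a fixed angle toward a chosen
# axis, an optional bounded random cone perturbs each fiber, and a
# deterministic progressive rotation toward -z emulates gravity bending
# while preserving every segment length.  The geometry is exported for
# downstream implicit Monte Carlo hair-transport tools; no optical transport
# happens here.

#' Hair generation parameters
#'
#' @param count number of fibers.
#' @param length fiber arc length in mm.
#' @param segments straight segments per fiber (>= 1).
#' @param tilt_axis unit vector the fibers tilt toward (e.g. `c(1, 0, 0)`
#'   for +x).
#' @param tilt_angle tilt from the surface normal, degrees in [0, 90).
#' @param randomness in [0, 1]; each fiber is perturbed by a random rotation
#'   of angle uniform in `[0, randomness * 90]` degrees about a uniform
#'   azimuth.
#' @param gravity bend factor >= 0 (0 = straight).
#' @param seed integer RNG seed.
#' @return an object of class `hair_params`.
#' @export
hair_params <- function(count = 1000, length = 5, segments = 8,
                        tilt_axis = c(1, 0, 0), tilt_angle = 0,
                        randomness = 0, gravity = 0, seed = 1L) {
  if (count < 1) stop("count must be >= 1")
  if (segments < 1) stop("segments must be >= 1")
  if (tilt_angle < 0 || tilt_angle >= 90)
    stop("tilt_angle must lie in [0, 90) degrees")
  if (randomness < 0 || randomness > 1) stop("randomness must lie in [0, 1]")
  if (gravity < 0) stop("gravity must be >= 0")
  structure(list(count = as.integer(count), length = as.numeric(length),
                 segments = as.integer(segments),
                 tilt_axis = as.numeric(tilt_axis) /
                   sqrt(sum(as.numeric(tilt_axis)^2)),
                 tilt_angle = as.numeric(tilt_angle),
                 randomness = as.numeric(randomness),
                 gravity = as.numeric(gravity), seed = as.integer(seed)),
            class = "hair_params")
}

#' Sample area-uniform root points on a surface
#'
#' Chooses a triangle with probability proportional to its area and a point
#' uniformly within it (square-root barycentric sampling); deterministic per
#' seed.
#'
#' @param surface a [surf_mesh()].
#' @param count number of roots.
#' @param seed integer RNG seed.
#' @return list with `points` (`count x 3` matrix on the surface) and
#'   `triangles` (index of the host triangle per root).
#' @export
sample_roots <- function(surface, count, seed = 1L) {
  stopifnot(inherits(surface, "surf_mesh"))
  if (nrow(surface$faces) == 0) stop("surface has no triangles")
  v1 <- surface$vertices[surface$faces[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$faces[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$faces[, 3], , drop = FALSE]
  cr <- .cross_rows(v2 - v1, v3 - v1)
  area <- sqrt(rowSums(cr^2)) / 2
  if (sum(area) == 0) stop("surface has zero area")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tri <- sample.int(nrow(surface$faces), count, replace = TRUE,
                    prob = area / sum(area))
  r1 <- sqrt(runif(count)); r2 <- runif(count)
  a <- 1 - r1; b <- r1 * (1 - r2); c_ <- r1 * r2
  pts <- v1[tri, , drop = FALSE] * a + v2[tri, , drop = FALSE] * b +
    v3[tri, , drop = FALSE] * c_
  list(points = pts, triangles = tri)
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# outward-ish unit normals of the triangles of a surf_mesh
.triangle_normals <- function(surface) {
  v1 <- surface$vertices[surface$faces[, 1], , drop = FALSE]
  v2 <- surface$vertices[surface$faces[, 2], , drop = FALSE]
  v3 <- surface$vertices[surface$faces[, 3], , drop = FALSE]
  cr <- .cross_rows(v2 - v1, v3 - v1)
  cr / sqrt(rowSums(cr^2))
}

# rotate vector v toward target by angle (radians), in their common plane
.rotate_toward <- function(v, target, angle) {
  v <- v / sqrt(sum(v^2)); target <- target / sqrt(sum(target^2))
  ct <- max(-1, min(1, sum(v * target)))
  theta <- acos(ct) # angle between v and target
  if (theta < 1e-12 || angle <= 0) return(v)
  angle <- min(angle, theta) # never overshoot the target
  # orthonormal component of target against v spans the rotation plane
  perp <- target - ct * v
  pn <- sqrt(sum(perp^2))
  if (pn < 1e-12) {
    # v and target are antiparallel: pick any perpendicular
    perp <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * v) * v
    pn <- sqrt(sum(perp^2))
  }
  perp <- perp / pn
  cos(angle) * v + sin(angle) * perp
}

# random rotation of v by `angle` about a uniform azimuth around v
.cone_perturb <- function(v, angle, u_az) {
  if (angle <= 0) return(v)
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  phi <- 2 * pi * u_az
  cos(angle) * v + sin(angle) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Grow straight hair fibers from root points
#'
#' Each fiber starts at its root; the base direction is the host-triangle
#' normal rotated by `tilt_angle` toward `tilt_axis`, then perturbed by an
#' independent random cone rotation of angle uniform in
#' `[0, randomness * 90]` degrees.  The fiber is a straight polyline of
#' `segments` equal steps totaling `length`.
#'
#' @param roots a [sample_roots()] result.
#' @param surface the host [surf_mesh()] (for normals).
#' @param params a [hair_params()].
#' @return an object of class `hair_set`: `fibers` (list of
#'   `(segments+1) x 3` polyline matrices), `roots`, `radius` (metadata,
#'   mm), `params`.
#' @export
grow_hairs <- function(roots, surface, params) {
  stopifnot(inherits(params, "hair_params"), inherits(surface, "surf_mesh"))
  normals <- .triangle_normals(surface)
  n <- nrow(roots$points)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed + 1L)
  u_cone <- runif(n); u_az <- runif(n)
  step <- params$length / params$segments
  tilt <- params$tilt_angle * pi / 180
  fibers <- vector("list", n)
  for (i in seq_len(n)) {
    d <- normals[roots$triangles[i], ]
    if (tilt > 0) d <- .rotate_toward(d, params$tilt_axis, tilt)
    if (params$randomness > 0)
      d <- .cone_perturb(d, u_cone[i] * params$randomness * pi / 2, u_az[i])
    pts <- matrix(0, params$segments + 1, 3)
    pts[1, ] <- roots$points[i, ]
    for (k in seq_len(params$segments))
      pts[k + 1, ] <- pts[k, ] + step * d
    fibers[[i]] <- pts
  }
  structure(list(fibers = fibers, roots = roots$points, radius = 0.03,
                 params = params), class = "hair_set")
}

#' @export
print.hair_set <- function(x, ...) {
  cat("Hair set:", length(x$fibers), "fibers,",
      nrow(x$fibers[[1]]) - 1, "segments each, length",
      x$params$length, "mm\n")
  invisible(x)
}

#' Bend hair fibers under gravity
#'
#' Deterministic progressive bend: segment `k` (0-indexed from the root) of
#' each fiber is rotated toward (0, 0, -1) by `gravity * k * delta` with
#' `delta = 90 / segments` degrees, clamped so a segment never rotates past
#' -z.  Rotation preserves each segment's length, so the root point and
#' total arc length are unchanged; `gravity = 0` is the identity and large
#' gravity drives the terminal segments to (0, 0, -1).
#'
#' @param hairs a `hair_set`.
#' @param gravity bend factor >= 0.
#' @return the bent `hair_set`.
#' @export
apply_gravity_bend <- function(hairs, gravity) {
  stopifnot(inherits(hairs, "hair_set"))
  if (gravity < 0) stop("gravity must be >= 0")
  if (gravity == 0) return(hairs)
  down <- c(0, 0, -1)
  segs <- nrow(hairs$fibers[[1]]) - 1
  delta <- (pi / 2) / segs
  hairs$fibers <- lapply(hairs$fibers, function(pts) {
    out <- pts
    for (k in seq_len(segs)) {
      d <- pts[k + 1, ] - pts[k, ]
      len <- sqrt(sum(d^2))
      d <- .rotate_toward(d / len, down, gravity * (k - 1) * delta)
      out[k + 1, ] <- out[k, ] + len * d
    }
    out
  })
  hairs
}

#' Export hair fibers to a JMesh document
#'
#' All fiber vertices are concatenated into `MeshVertex3`; per-fiber index
#' runs (1-based, consecutive) are stored under the `HairIndices` metadata
#' construct together with the fiber radius, so connectivity round-trips
#' through [read_mesh_document()].
#'
#' @param hairs a `hair_set`.
#' @param path output `.jmsh` path.
#' @param dialect array dialect for [write_mesh_document()].
#' @return `path`, invisibly.
#' @export
export_hairs <- function(hairs, path, dialect = "plain") {
  stopifnot(inherits(hairs, "hair_set"))
  verts <- do.call(rbind, hairs$fibers)
  npts <- vapply(hairs$fibers, nrow, integer(1))
  ends <- cumsum(npts)
  starts <- ends - npts + 1
  runs <- lapply(seq_along(npts), function(i) seq(starts[i], ends[i]))
  doc <- mesh_document(vertices = verts,
                       metadata = list(HairIndices = runs,
                                       HairRadius = hairs$radius))
  write_mesh_document(doc, path, dialect = dialect)
  invisible(path)
}
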