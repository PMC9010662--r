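# Constructive region scenes.
#
# A scene is an ordered list of labeled geometric predicates over an
# axis-aligned bounding box.  Later regions take precedence at overlapping
# points (an embedded vessel overrides its host layer).  All shape predicates
# follow a half-open boundary convention -- closed on the low side, open on
# the high side of every interval/half-space -- so that point membership is a
# total, deterministic function.  Geometry may be entered in model units
# (e.g. voxels); the `unit_scale` factor ("mm per model unit") is applied
# exactly once at construction and everything downstream is in mm.

#' Axis-aligned box shape
#'
#' @param lo,hi numeric length-3 low/high corners (model units).
#' @return a `shape_spec`.
#' @export
shape_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (any(hi <= lo)) stop("box requires hi > lo on every axis")
  structure(list(kind = "box", lo = lo, hi = hi), class = "shape_spec")
}

#' Horizontal layer (z-slab) shape
#'
#' Fills the whole scene cross-section between two z cuts, `zmin <= z < zmax`.
#'
#' @param zmin,zmax layer bounds (model units).
#' @return a `shape_spec`.
#' @export
shape_zslab <- function(zmin, zmax) {
  if (zmax <= zmin) stop("zslab requires zmin < zmax")
  structure(list(kind = "zslab", zmin = as.numeric(zmin),
                 zmax = as.numeric(zmax)), class = "shape_spec")
}

#' Finite cylinder shape
#'
#' @param point axis start point (model units).
#' @param axis axis direction (normalized internally).
#' @param radius cylinder radius > 0 (model units).
#' @param length axis length > 0 (model units).
#' @return a `shape_spec`.
#' @export
shape_cylinder <- function(point, axis, radius, length) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("cylinder axis must be nonzero")
  if (radius <= 0 || length <= 0) stop("cylinder radius and length must be > 0")
  structure(list(kind = "cylinder", point = as.numeric(point),
                 axis = axis / nrm, radius = as.numeric(radius),
                 length = as.numeric(length)), class = "shape_spec")
}

#' Height-field half-space shape
#'
#' Points below a bilinearly interpolated interface `z = base_z + Z(x, y)`
#' are inside.  Built from a [make_grid_surface()] via [surface_to_region()],
#' this is how randomized rough interfaces enter a scene.
#'
#' @param heights matrix of interface offsets Z (mm after unit scaling).
#' @param extent length-2 `(Lx, Ly)` of the height grid (model units).
#' @param base_z nominal interface height (model units).
#' @param origin xy position (model units) of the grid's low corner.
#' @return a `shape_spec`.
#' @export
shape_heightfield_below <- function(heights, extent, base_z, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (any(!is.finite(heights))) stop("heights must be finite")
  if (any(extent <= 0)) stop("extent must be positive")
  structure(list(kind = "heightfield_below", heights = heights,
                 extent = as.numeric(extent), base_z = as.numeric(base_z),
                 origin = as.numeric(origin)), class = "shape_spec")
}

# scale every length in a shape by s (model units -> mm); heights in a
# height-field scale with the out-of-plane axis
.scale_shape <- function(shape, s) {
  sc <- shape
  for (f in names(shape)) {
    if (f %in% c("kind")) next
    if (f == "axis") next # direction, dimensionless
    sc[[f]] <- shape[[f]] * s
  }
  sc
}

# axis-aligned bounding box of a shape, in mm, for the containment check
.shape_bbox <- function(shape, bounds) {
  switch(shape$kind,
    box = list(lo = shape$lo, hi = shape$hi),
    zslab = list(lo = c(bounds$lo[1], bounds$lo[2], shape$zmin),
                 hi = c(bounds$hi[1], bounds$hi[2], shape$zmax)),
    cylinder = {
      p0 <- shape$point; p1 <- shape$point + shape$axis * shape$length
      r <- shape$radius
      pad <- r * sqrt(pmax(0, 1 - shape$axis^2))
      list(lo = pmin(p0, p1) - pad, hi = pmax(p0, p1) + pad)
    },
    heightfield_below = list(
      lo = c(shape$origin, bounds$lo[3]),
      hi = c(shape$origin + shape$extent,
             shape$base_z + max(shape$heights))
    ),
    stop("unknown shape kind: ", shape$kind)
  )
}

# vectorized membership: pts is an n x 3 matrix in mm
.shape_inside <- function(shape, pts) {
  switch(shape$kind,
    box = pts[, 1] >= shape$lo[1] & pts[, 1] < shape$hi[1] &
          pts[, 2] >= shape$lo[2] & pts[, 2] < shape$hi[2] &
          pts[, 3] >= shape$lo[3] & pts[, 3] < shape$hi[3],
    zslab = pts[, 3] >= shape$zmin & pts[, 3] < shape$zmax,
    cylinder = {
      rel <- sweep(pts, 2, shape$point)
      t <- rel %*% shape$axis
      perp2 <- rowSums(rel^2) - t^2
      as.vector(t >= 0 & t < shape$length & perp2 < shape$radius^2)
    },
    heightfield_below = {
      h <- .bilinear(shape$heights, shape$extent, shape$origin,
                     pts[, 1], pts[, 2])
      pts[, 3] < shape$base_z + h
    },
    stop("unknown shape kind: ", shape$kind)
  )
}

# bilinear interpolation of a height grid; queries outside the grid clamp to
# the border value
.bilinear <- function(Z, extent, origin, x, y) {
  nx <- nrow(Z); ny <- ncol(Z)
  u <- (x - origin[1]) / extent[1] * (nx - 1)
  v <- (y - origin[2]) / extent[2] * (ny - 1)
  u <- pmin(pmax(u, 0), nx - 1)
  v <- pmin(pmax(v, 0), ny - 1)
  i <- pmin(floor(u), nx - 2); j <- pmin(floor(v), ny - 2)
  fu <- u - i; fv <- v - j
  i <- i + 1; j <- j + 1 # to 1-based
  Z[cbind(i, j)] * (1 - fu) * (1 - fv) +
    Z[cbind(i + 1, j)] * fu * (1 - fv) +
    Z[cbind(i, j + 1)] * (1 - fu) * fv +
    Z[cbind(i + 1, j + 1)] * fu * fv
}

#' Build a labeled region scene
#'
#' Assembles an ordered list of labeled shapes over an axis-aligned bounding
#' box.  `unit_scale` (mm per model unit, the "unitinmm" factor) is applied
#' once here; every downstream quantity is in mm.  Later regions override
#' earlier ones where they overlap.
#'
#' @param bounds_lo,bounds_hi low/high corners of the domain (model units).
#' @param regions list of entries `list(label =, shape =, name =)`; labels
#'   must be unique positive integers (0 is reserved for "outside").
#' @param unit_scale mm per model unit (default 1).
#' @return an object of class `region_scene`.
#' @export
build_scene <- function(bounds_lo, bounds_hi, regions, unit_scale = 1) {
  if (length(regions) == 0) stop("regions must be nonempty")
  if (unit_scale <= 0) stop("unit_scale must be positive")
  lo <- as.numeric(bounds_lo) * unit_scale
  hi <- as.numeric(bounds_hi) * unit_scale
  if (any(hi <= lo)) stop("bounds must have positive extent")
  bounds <- list(lo = lo, hi = hi)
  labels <- vapply(regions, function(r) as.integer(r$label), integer(1))
  if (any(labels <= 0L)) stop("labels must be positive integers")
  if (anyDuplicated(labels))
    stop("duplicate label: ", labels[duplicated(labels)][1])
  regs <- lapply(regions, function(r) {
    if (!inherits(r$shape, "shape_spec")) stop("each region needs a shape_spec")
    sh <- .scale_shape(r$shape, unit_scale)
    bb <- .shape_bbox(sh, bounds)
    tol <- 1e-9 * max(hi - lo)
    if (any(bb$lo < lo - tol) || any(bb$hi > hi + tol))
      stop("shape for label ", r$label, " (",
           if (is.null(r$name)) sh$kind else r$name, ") lies outside bounds")
    list(label = as.integer(r$label), shape = sh,
         name = if (is.null(r$name)) paste0("region_", r$label) else r$name)
  })
  structure(list(bounds = bounds, regions = regs,
                 unit_scale = as.numeric(unit_scale)),
            class = "region_scene")
}

#' @export
print.region_scene <- function(x, ...) {
  cat("Region scene, bounds [", paste(signif(x$bounds$lo, 6), collapse = ", "),
      "] - [", paste(signif(x$bounds$hi, 6), collapse = ", "), "] mm\n")
  for (r in x$regions)
    cat("  label", r$label, "-", r$name, "(", r$shape$kind, ")\n")
  invisible(x)
}

#' Label of the region containing each point
#'
#' Total membership function of a scene: returns the label of the last
#' declared region containing each query point, or 0 for points in no region
#' or outside the scene bounds.  The boundary convention is half-open
#' (closed low side, open high side), so points exactly on a cut plane
#' belong to the region above it.
#'
#' @param scene a [build_scene()] result.
#' @param pts numeric vector of length 3, or an `n x 3` matrix (mm).
#' @return integer vector of labels.
#' @export
label_point <- function(scene, pts) {
  stopifnot(inherits(scene, "region_scene"))
  if (is.null(dim(pts))) pts <- matrix(as.numeric(pts), ncol = 3)
  out <- integer(nrow(pts))
  inb <- pts[, 1] >= scene$bounds$lo[1] & pts[, 1] <= scene$bounds$hi[1] &
         pts[, 2] >= scene$bounds$lo[2] & pts[, 2] <= scene$bounds$hi[2] &
         pts[, 3] >= scene$bounds$lo[3] & pts[, 3] <= scene$bounds$hi[3]
  for (r in scene$regions) {
    ins <- .shape_inside(r$shape, pts)
    out[ins & inb] <- r$label
  }
  out
}

#' Axis-aligned z-cut planes of a scene
#'
#' All z coordinates where a `zslab` region starts or ends, plus the two
#' horizontal bounding faces, sorted ascending and deduplicated within
#' 1e-9 mm.  The lattice mesher snaps its z grid to these planes so layer
#' interfaces are represented exactly.
#'
#' @param scene a [build_scene()] result.
#' @return sorted numeric vector of z planes (mm).
#' @export
scene_interfaces_z <- function(scene) {
  stopifnot(inherits(scene, "region_scene"))
  z <- c(scene$bounds$lo[3], scene$bounds$hi[3])
  for (r in scene$regions)
    if (r$shape$kind == "zslab") z <- c(z, r$shape$zmin, r$shape$zmax)
  z <- sort(z)
  z[c(TRUE, diff(z) > 1e-9)]
}

#' Write a scene description to JSON
#'
#' Serializes bounds, unit scale and the ordered region list (kind,
#' parameters, label, name) to the scene configuration format consumed by
#' the command-line `mesh` subcommand.  Note the stored geometry is already
#' in mm (unit scaling happened at construction), so the file records
#' `unit_scale` for provenance and is re-read with scale 1.
#'
#' @param scene a [build_scene()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  stopifnot(inherits(scene, "region_scene"))
  regs <- lapply(scene$regions, function(r) {
    par <- r$shape[setdiff(names(r$shape), "kind")]
    par <- lapply(par, function(v) if (is.matrix(v)) apply(v, 1, c, simplify = FALSE) else v)
    list(label = r$label, name = r$name, kind = r$shape$kind, parameters = par)
  })
  out <- list(bounds_lo = scene$bounds$lo, bounds_hi = scene$bounds$hi,
              unit_scale_applied = scene$unit_scale, length_unit = "mm",
              regions = regs)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Read a scene description from JSON
#'
#' @param path JSON file written by [write_scene_json()] (or hand-authored in
#'   the same layout, with geometry in mm).
#' @return a `region_scene`.
#' @export
read_scene_json <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = "\n"), simplifyVector = FALSE)
  regions <- lapply(doc$regions, function(r) {
    par <- lapply(r$parameters, function(v) {
      if (is.list(v)) matrix(unlist(lapply(v, as.numeric)),
                             nrow = length(v), byrow = TRUE)
      else as.numeric(v)
    })
    shape <- structure(c(list(kind = r$kind), par), class = "shape_spec")
    list(label = r$label, shape = shape, name = r$name)
  })
  build_scene(as.numeric(unlist(doc$bounds_lo)),
              as.numeric(unlist(doc$bounds_hi)), regions, unit_scale = 1)
}
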