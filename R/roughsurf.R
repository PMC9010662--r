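# Randomized rough interfaces and the Ra roughness statistic.
#
# A rough tissue interface is modeled as a subdivided plane whose vertices
# receive independent, normal-direction-constrained random offsets bounded
# by an amplitude a.  Roughness is quantified by Ra, the arithmetic mean
# deviation of the depth profile; for uniform offsets on [-a, a] the
# expected Ra is a/2.

#' Create a flat subdivided grid surface
#'
#' `cuts = k` interior cuts per edge produce `(k+1)` segments, hence
#' `(k+1)^2` quad cells and `(k+2)` grid lines per side; all heights start
#' at zero.
#'
#' @param extent length-2 `(Lx, Ly)` surface extent in mm.
#' @param cuts number of interior subdivision cuts per edge (>= 0).
#' @param base_z nominal interface height in mm (default 0).
#' @param origin xy coordinate of the grid's low corner.
#' @return an object of class `grid_surface`: `heights` (a
#'   `(k+2) x (k+2)` matrix of out-of-plane offsets, mm), `extent`,
#'   `base_z`, `origin`.
#' @export
make_grid_surface <- function(extent, cuts, base_z = 0, origin = c(0, 0)) {
  if (cuts < 0) stop("cuts must be >= 0")
  if (any(extent <= 0)) stop("extent must be positive")
  n <- as.integer(cuts) + 2L
  structure(list(heights = matrix(0, n, n), extent = as.numeric(extent),
                 base_z = as.numeric(base_z), origin = as.numeric(origin)),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  n <- nrow(x$heights)
  cat("Grid surface:", n, "x", n, "vertices (", n - 1, "x", n - 1,
      "cells ) over", paste(x$extent, collapse = " x "), "mm; Ra =",
      signif(compute_ra(x), 4), "mm\n")
  invisible(x)
}

#' Apply random normal-direction offsets to a grid surface
#'
#' Draws each grid height independently and uniformly on `[-a, +a]`
#' (a bounded, normal-direction-constrained random movement), so
#' `max |Z| <= a` always and `E[Ra] = a/2`.  Deterministic for a fixed seed.
#'
#' @param surface a [make_grid_surface()] result.
#' @param amplitude maximum offset `a` in mm (>= 0).
#' @param seed integer RNG seed.
#' @return the surface with randomized `heights`.
#' @export
randomize_normals <- function(surface, amplitude, seed = 1L) {
  stopifnot(inherits(surface, "grid_surface"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(surface)
  n <- nrow(surface$heights)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  surface$heights <- matrix(runif(n * n, -amplitude, amplitude), n, n)
  surface
}

# save/restore the global RNG state so package randomness does not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Arithmetic mean deviation (Ra) of a surface
#'
#' Discrete arithmetic mean deviation of the depth profile: the mean over
#' all grid vertices of `|Z - mean(Z)|`, where heights are measured from
#' their average.  Translation invariant by construction; a flat surface has
#' `Ra = 0`.
#'
#' @param surface a `grid_surface`.
#' @return Ra in mm.
#' @export
compute_ra <- function(surface) {
  stopifnot(inherits(surface, "grid_surface"))
  z <- surface$heights
  if (length(z) < 2) stop("Ra needs at least 2 grid vertices")
  mean(abs(z - mean(z)))
}

#' Convert a grid surface to a height-field region shape
#'
#' Wraps the surface as a `heightfield_below` shape: a point is inside the
#' region iff `z < base_z + Z(x, y)` with `Z` bilinearly interpolated.  A
#' flat surface is therefore equivalent to a `zslab` cut at `base_z`, and a
#' point exactly on the interface is outside (half-open convention).
#'
#' @param surface a `grid_surface`.
#' @return a `shape_spec` usable in [build_scene()].
#' @export
surface_to_region <- function(surface) {
  stopifnot(inherits(surface, "grid_surface"))
  shape_heightfield_below(surface$heights, surface$extent, surface$base_z,
                          surface$origin)
}
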