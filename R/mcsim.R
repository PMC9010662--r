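# Monte Carlo photon transport: configuration objects, reference
# implementations of the elementary physics (used directly and as the
# cross-check for the compiled core), and the simulation driver.

#' Per-region optical properties
#'
#' One record per region label: absorption coefficient `mua` (1/mm),
#' scattering coefficient `mus` (1/mm), scattering anisotropy `g` (mean
#' cosine of the deflection angle, in [-1, 1]) and refractive index `n`
#' (>= 1).  The exterior medium (outside the mesh) defaults to vacuum/air:
#' `n = 1`, no absorption or scattering.
#'
#' @param label integer vector of region labels.
#' @param mua,mus,g,n numeric vectors (recycled) of coefficients.
#' @param n_exterior refractive index of the surrounding medium.
#' @return an object of class `optical_props` (a data.frame with an
#'   `n_exterior` attribute).
#' @export
optical_props <- function(label, mua, mus, g, n, n_exterior = 1) {
  df <- data.frame(label = as.integer(label), mua = as.numeric(mua),
                   mus = as.numeric(mus), g = as.numeric(g), n = as.numeric(n))
  if (anyDuplicated(df$label)) stop("duplicate region label in optical_props")
  if (any(df$mua < 0) || any(df$mus < 0)) stop("mua and mus must be >= 0")
  if (any(df$g < -1 | df$g > 1)) stop("g must lie in [-1, 1]")
  if (any(df$n < 1) || n_exterior < 1) stop("refractive index must be >= 1")
  attr(df, "n_exterior") <- as.numeric(n_exterior)
  class(df) <- c("optical_props", "data.frame")
  df
}

#' Photon source definition
#'
#' Pencil sources launch every packet from `position` along the source
#' direction; disk sources launch uniformly over the disk of radius
#' `srcparam1[1] * unit_scale` perpendicular to the direction.  The
#' direction may be given as a vector or as a unit quaternion (`c(w, x, y,
#' z)`) rotating the reference direction (0, 0, -1), mirroring how scene
#' tools store light orientations.
#'
#' @param position source position in mm.
#' @param direction unit direction vector (normalized internally), or `NULL`
#'   if `quaternion` is given.
#' @param quaternion unit quaternion `c(w, x, y, z)`; used when `direction`
#'   is `NULL`.
#' @param srctype `"pencil"` or `"disk"`.
#' @param srcparam1 numeric 4-vector; for disk sources the first element is
#'   the radius in model units (the remaining elements are ignored).
#' @param unit_scale mm per model unit applied to `srcparam1` (the
#'   "unitinmm" source property).
#' @param nphoton number of photon packets to launch.
#' @return an object of class `photon_source`.
#' @export
photon_source <- function(position, direction = NULL, quaternion = NULL,
                          srctype = c("pencil", "disk"),
                          srcparam1 = c(0, 0, 0, 0), unit_scale = 1,
                          nphoton = 1e5) {
  srctype <- match.arg(srctype)
  if (is.null(direction)) {
    if (is.null(quaternion)) stop("give either direction or quaternion")
    direction <- quaternion_to_direction(quaternion)
  }
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stop("direction must be nonzero")
    direction <- direction / nrm
  }
  if (nphoton < 1) stop("nphoton must be >= 1")
  structure(list(position = as.numeric(position), direction = direction,
                 srctype = srctype, srcparam1 = as.numeric(srcparam1),
                 unit_scale = as.numeric(unit_scale),
                 nphoton = as.numeric(nphoton)),
            class = "photon_source")
}

#' Global simulation settings
#'
#' @param seed integer RNG seed; a fixed seed reproduces the fluence map
#'   bitwise (the transport core is single threaded).
#' @param time_gates `c(tstart, tend, tstep)` in seconds; the default is a
#'   single (0, 5 ns) gate.  Packets still in flight at `tend` are stopped
#'   and booked as time-truncated.
#' @param do_reflection apply Fresnel reflection/refraction at interfaces
#'   where the refractive index changes (and at the outer boundary).  When
#'   off, boundaries transmit without deflection.
#' @param do_normalize convert deposited energy to fluence rate,
#'   `U / (V_node * nphoton * tstep)` with `V_node` a quarter of the volume
#'   of the tetrahedra adjacent to the node; otherwise raw deposited weight
#'   sums are returned.
#' @param roulette_threshold weight below which Russian roulette triggers.
#' @param roulette_survival survival probability; survivors are reweighted
#'   by its inverse, keeping termination unbiased.
#' @return an object of class `sim_settings`.
#' @export
sim_settings <- function(seed = 1L, time_gates = c(0, 5e-9, 5e-9),
                         do_reflection = TRUE, do_normalize = TRUE,
                         roulette_threshold = 1e-4, roulette_survival = 0.1) {
  if (length(time_gates) != 3 || time_gates[2] <= time_gates[1])
    stop("time_gates must be c(tstart, tend, tstep) with tend > tstart")
  if (roulette_survival <= 0 || roulette_survival > 1)
    stop("roulette_survival must lie in (0, 1]")
  structure(list(seed = as.integer(seed), time_gates = as.numeric(time_gates),
                 do_reflection = isTRUE(do_reflection),
                 do_normalize = isTRUE(do_normalize),
                 roulette_threshold = as.numeric(roulette_threshold),
                 roulette_survival = as.numeric(roulette_survival)),
            class = "sim_settings")
}

#' Convert a unit quaternion to a direction vector
#'
#' Rotates the reference direction (0, 0, -1) -- a downward-pointing source
#' -- by the quaternion `c(w, x, y, z)`.
#'
#' @param q numeric quaternion, unit norm within 1e-6.
#' @return unit length-3 direction vector.
#' @export
quaternion_to_direction <- function(q) {
  q <- as.numeric(q)
  nrm <- sqrt(sum(q^2))
  if (nrm == 0) stop("zero quaternion has no direction")
  if (abs(nrm - 1) > 1e-6) stop("quaternion must be unit norm")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  as.vector(R %*% c(0, 0, -1))
}

#' Direction vector for a rotation about a coordinate axis
#'
#' Convenience wrapper building the quaternion for a rotation of
#' `angle_deg` about `axis` and applying it to the (0, 0, -1) reference
#' direction; this mirrors how scene light orientations are specified as
#' per-axis Euler angles.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg rotation angle in degrees.
#' @return unit direction vector.
#' @export
axis_rotation_direction <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  v <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  quaternion_to_direction(c(cos(a / 2), sin(a / 2) * v))
}

#' Sample a free path to the next scattering event
#'
#' Inverse-CDF sample of the exponential path-length distribution:
#' `-log(u) / mus`.  A non-scattering medium (`mus = 0`) returns `Inf`
#' (ballistic propagation to the boundary).
#'
#' @param mus scattering coefficient (1/mm).
#' @param u uniform variate in (0, 1).
#' @return path length in mm.
#' @export
sample_free_path <- function(mus, u) {
  if (any(u <= 0 | u >= 1)) stop("u must lie in (0, 1)")
  if (mus == 0) return(rep(Inf, length(u)))
  -log(u) / mus
}

#' Sample a Henyey-Greenstein scattering direction
#'
#' Draws the deflection cosine from the Henyey-Greenstein phase function
#' (`cos theta = (1 + g^2 - ((1 - g^2)/(1 - g + 2 g u1))^2) / (2g)`, uniform
#' for `g = 0`), the azimuth uniformly, and rotates the incident direction
#' accordingly.
#'
#' @param g anisotropy in [-1, 1].
#' @param u1,u2 uniform variates in (0, 1); may be vectors of equal length.
#' @param incoming incident unit direction (default +z).
#' @return unit scattered direction(s): a length-3 vector for scalar input,
#'   otherwise an `n x 3` matrix.
#' @export
sample_hg <- function(g, u1, u2, incoming = c(0, 0, 1)) {
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  ct <- if (abs(g) < 1e-12) {
    2 * u1 - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
    pmax(-1, pmin(1, (1 + g^2 - tmp^2) / (2 * g)))
  }
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * u2
  cp <- cos(phi); sp <- sin(phi)
  d <- as.numeric(incoming)
  d <- d / sqrt(sum(d^2))
  if (abs(d[3]) > 0.999999) {
    out <- cbind(st * cp, st * sp, ct * sign(d[3]))
  } else {
    den <- sqrt(1 - d[3]^2)
    out <- cbind(
      st * (d[1] * d[3] * cp - d[2] * sp) / den + d[1] * ct,
      st * (d[2] * d[3] * cp + d[1] * sp) / den + d[2] * ct,
      -st * cp * den + d[3] * ct)
  }
  out <- out / sqrt(rowSums(out^2))
  if (length(u1) == 1) as.vector(out) else out
}

#' Fresnel reflection or Snell refraction at an index boundary
#'
#' Computes the unpolarized Fresnel reflectance (the s/p average) for the
#' given incidence; the packet reflects specularly with that probability and
#' otherwise refracts by Snell's law.  Beyond the critical angle the
#' reflectance is 1.
#'
#' @param n1,n2 refractive indices on the incident/far side.
#' @param dir incident unit direction.
#' @param normal boundary unit normal (either orientation).
#' @param u uniform variate deciding reflect (u < R) vs refract.
#' @return list with `action` (`"reflect"` or `"refract"`), `direction`, and
#'   the reflectance `R`.
#' @export
fresnel_boundary <- function(n1, n2, dir, normal, u) {
  dir <- as.numeric(dir); normal <- as.numeric(normal)
  dn <- sum(dir * normal)
  ci <- abs(dn)
  R <- if (n1 == n2) 0 else {
    s2 <- (n1 / n2)^2 * (1 - ci^2)
    if (s2 >= 1) 1 else {
      ct <- sqrt(1 - s2)
      rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
      rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
      (rs^2 + rp^2) / 2
    }
  }
  if (u < R) {
    list(action = "reflect", direction = dir - 2 * dn * normal, R = R)
  } else if (n1 == n2) {
    list(action = "refract", direction = dir, R = R)
  } else {
    eta <- n1 / n2
    ct <- sqrt(max(0, 1 - eta^2 * (1 - ci^2)))
    out <- eta * dir + (ct - eta * ci) * sign(dn) * normal
    list(action = "refract", direction = out / sqrt(sum(out^2)), R = R)
  }
}

#' Run a mesh-based Monte Carlo photon simulation
#'
#' Launches `nphoton` weighted packets from the source, propagates them
#' through the labeled tetrahedral mesh (exponential free paths,
#' Henyey-Greenstein scattering, continuous absorption `exp(-mua s)` along
#' each traversed segment, optional Fresnel boundaries, Russian roulette)
#' and accumulates fluence at the mesh nodes, split by barycentric
#' coordinates of each segment midpoint and binned by elapsed time
#' (`t += s n / c`).  The per-segment deposit is
#' `w (1 - exp(-mua s)) / mua`, whose `mua -> 0` limit `w s` is the
#' track-length estimator, so non-absorbing regions are handled without a
#' special case.
#'
#' A pencil source must start inside the mesh; a disk source may sit outside
#' and its packets propagate through the exterior (vacuum flight) until they
#' enter the domain.
#'
#' @param mesh a [tet_mesh()].
#' @param props an [optical_props()] covering every mesh label.
#' @param source a [photon_source()].
#' @param settings a [sim_settings()].
#' @return an object of class `fluence_map`: `values` (`Nn x n_gates`
#'   matrix, fluence rate per node per time gate when normalized), `stats`
#'   (launched weight and absorbed/escaped/truncated/lost fractions),
#'   `gates`, `normalized`, `seed`.
#' @export
run_simulation <- function(mesh, props, source, settings = sim_settings()) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(props, "optical_props"),
            inherits(source, "photon_source"), inherits(settings, "sim_settings"))
  labs <- sort(unique(mesh$label))
  missing <- setdiff(labs, props$label)
  if (length(missing) > 0)
    stop("no optical properties for label(s): ", paste(missing, collapse = ", "))
  # compact labels to 1..L for the core
  remap <- match(mesh$label, labs)
  pr <- props[match(labs, props$label), , drop = FALSE]
  pmat <- as.matrix(pr[, c("mua", "mus", "g", "n")])
  radius <- if (source$srctype == "disk")
    source$srcparam1[1] * source$unit_scale else 0
  if (source$srctype == "pencil") {
    inside <- cpp_locate_points(mesh$node, mesh$elem,
                                matrix(source$position, ncol = 3))
    if (inside[1] == 0L)
      stop("pencil source position lies outside the mesh")
  }
  tg_ns <- settings$time_gates * 1e9
  res <- cpp_run_mc(mesh$node, mesh$elem, remap, mesh$neighbor, pmat,
                    attr(props, "n_exterior"), source$position,
                    source$direction, ifelse(source$srctype == "disk", 1L, 0L),
                    radius, source$nphoton, settings$seed,
                    tg_ns[1], tg_ns[2], tg_ns[3],
                    settings$do_reflection, settings$roulette_threshold,
                    settings$roulette_survival)
  values <- res$deposit
  if (settings$do_normalize) {
    vnode <- node_volumes(mesh)
    values <- values / (vnode * source$nphoton * settings$time_gates[3])
  }
  stats <- c(launched = res$launched,
             absorbed = res$absorbed / res$launched,
             escaped = res$escaped / res$launched,
             truncated = res$truncated / res$launched,
             lost = res$lost / res$launched)
  structure(list(values = values, stats = stats,
                 gates = settings$time_gates, normalized = settings$do_normalize,
                 seed = settings$seed),
            class = "fluence_map")
}

#' Nodal volumes of a tetrahedral mesh
#'
#' A quarter of the summed volume of the tetrahedra adjacent to each node --
#' the normalization volume of the nodal fluence estimator.
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of length `Nn` (mm^3).
#' @export
node_volumes <- function(mesh) {
  v <- tet_volumes(mesh)
  out <- numeric(nrow(mesh$node))
  for (j in 1:4) {
    s <- rowsum(v, mesh$elem[, j])
    idx <- as.integer(rownames(s))
    out[idx] <- out[idx] + s[, 1]
  }
  out / 4
}

#' @export
print.fluence_map <- function(x, ...) {
  cat("Fluence map:", nrow(x$values), "nodes x", ncol(x$values), "gate(s),",
      if (x$normalized) "normalized fluence rate" else "raw deposits", "\n")
  s <- x$stats
  cat(sprintf("  launched %g; absorbed %.4f, escaped %.4f, truncated %.4f, lost %g\n",
              s["launched"], s["absorbed"], s["escaped"], s["truncated"],
              s["lost"]))
  invisible(x)
}

#' Log-10 display transform of a fluence map
#'
#' `log10(max(value, floor))` per node for the selected gate -- the standard
#' rendering transform for fluence maps, monotone in the input.
#'
#' @param fluence a `fluence_map` or numeric vector.
#' @param floor positive display floor.
#' @param gate time-gate column (default 1).
#' @return numeric vector of display values.
#' @export
log10_display <- function(fluence, floor = 1e-12, gate = 1L) {
  if (floor <= 0) stop("floor must be > 0")
  v <- if (inherits(fluence, "fluence_map")) fluence$values[, gate] else
    as.numeric(fluence)
  log10(pmax(v, floor))
}
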