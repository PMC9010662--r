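# Packaged benchmark specifications.
#
# Three self-contained benchmarks (skinvessel, skinvessel_rough, slab_hair)
# carry their full geometry, optical-property tables and source definitions;
# colin27 and digimouse describe the published head-atlas and mouse-atlas
# configurations but require a user-supplied surface mesh / labeled volume
# and fail with an actionable message without one.

# SkinVessel optical properties: a three-layer skin slab with an embedded
# blood-vessel cylinder, all refractive indices 1.37.  The bottom layer is
# listed with mua = 0, mus = 1, g = 1 -- an effectively non-interacting
# layer -- and is reproduced verbatim rather than "corrected".
.skinvessel_props <- function() {
  optical_props(
    label = 1:4,
    mua = c(0, 1.657, 0.046, 23.054),
    mus = c(1, 37.594, 35.654, 9.398),
    g = c(1, 0.9, 0.9, 0.9),
    n = c(1.37, 1.37, 1.37, 1.37))
}

# Colin27 head-atlas tissue optics: scalp, CSF, gray matter, white matter.
.colin27_props <- function() {
  optical_props(
    label = 1:4,
    mua = c(0.019, 0.004, 0.02, 0.08),
    mus = c(7.818, 0.009, 9.0, 40.9),
    g = rep(0.89, 4),
    n = rep(1.37, 4))
}

.colin27_tissues <- c("scalp", "CSF", "gray matter", "white matter")

# Digimouse mouse-atlas optics, 21 labeled tissues.
.digimouse_props <- function() {
  optical_props(
    label = 1:21,
    mua = c(0.0191, 0.0136, 0.0026, 0.0186, 0.0186, 0.0186, 0.0186, 0.0186,
            0.024, 0.0026, 0.024, 0.024, 0.024, 0.024, 0.024, 0.072, 0.072,
            0.072, 0.05, 0.024, 0.076),
    mus = c(6.6, 8.6, 0.01, 11.1, 11.1, 11.1, 11.1, 11.1, 8.9, 0.01, 8.9,
            8.9, 8.9, 8.9, 8.9, 5.6, 5.6, 5.6, 5.4, 8.9, 10.9),
    g = rep(0.9, 21),
    n = rep(1.37, 21))
}

.digimouse_tissues <- c(
  "skin", "skeleton", "eye", "medulla", "cerebellum", "olfactory bulbs",
  "external cerebrum", "striatum", "heart", "rest of the brain",
  "masseter muscles", "lachrymal glands", "bladder", "testis", "stomach",
  "spleen", "pancreas", "liver", "kidneys", "adrenal glands", "lungs")

# SkinVessel constructive geometry in voxel units: a 200-voxel cube cut at
# z = 20 and z = 32 into low/mid/high slabs, with a radius-20 cylinder along
# y through the cube center.
.skinvessel_scene <- function(unit_scale, rough_surface = NULL) {
  low_shape <- if (is.null(rough_surface)) shape_zslab(0, 20) else
    surface_to_region(rough_surface)
  build_scene(
    bounds_lo = c(0, 0, 0), bounds_hi = c(200, 200, 200),
    unit_scale = unit_scale,
    regions = list(
      list(label = 3L, shape = shape_zslab(0, 200), name = "High-slab"),
      list(label = 2L, shape = shape_zslab(0, 32), name = "Mid-slab"),
      list(label = 1L, shape = low_shape, name = "Low-slab"),
      list(label = 4L,
           shape = shape_cylinder(point = c(100, 0, 100), axis = c(0, 1, 0),
                                  radius = 20, length = 200),
           name = "Cylinder")))
}

#' Build a packaged benchmark specification
#'
#' Returns the fully populated scene/optics/source/settings bundle for one
#' of the named benchmarks:
#'
#' * `skinvessel` -- three-layer skin slab (1 mm cube, unit scale 0.005
#'   mm/voxel) with an embedded vessel; disk source of radius 50 voxels at
#'   (100, 100, -10) voxels pointing +z (a 180-degree rotation of the
#'   downward reference direction).
#' * `skinvessel_rough` -- the same model shrunk 10x (unit scale 0.0005) with
#'   the lower interface replaced by a randomized rough surface (subdivision
#'   39, amplitude 1 voxel = 0.5 um) and the tilted "source-2" disk source
#'   (150-degree rotation about x).
#' * `slab_hair` -- a 20 x 50 x 34.51 mm three-layer head slab (12.44 mm
#'   scalp/skull, 2.07 mm CSF, 20 mm brain) with 1000 straight hairs grown
#'   on the top surface.
#' * `colin27` -- head-atlas optics and source; needs a user-supplied
#'   surface-derived mesh (`external_path`).
#' * `digimouse` -- mouse-atlas optics and source; needs a user-supplied
#'   labeled volume (`external_path`).
#'
#' @param name benchmark name.
#' @param nphoton photon count (default 1e5 for desk-scale runs).
#' @param seed RNG seed for the simulation and any geometry randomness.
#' @param external_path path to the external mesh/volume required by
#'   `colin27`/`digimouse`.
#' @return an object of class `benchmark_spec`.
#' @export
build_benchmark <- function(name = c("skinvessel", "skinvessel_rough",
                                     "slab_hair", "colin27", "digimouse"),
                            nphoton = 1e5, seed = 1L, external_path = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown benchmark '", name[1], "'; available: skinvessel, ",
         "skinvessel_rough, slab_hair, colin27, digimouse", call. = FALSE))
  spec <- switch(name,
    skinvessel = list(
      scene = .skinvessel_scene(unit_scale = 0.005),
      props = .skinvessel_props(),
      meshing = meshing_options(max_tet_volume = 30),
      source = photon_source(
        position = c(100, 100, -10) * 0.005,
        direction = axis_rotation_direction("x", 180),
        srctype = "disk", srcparam1 = c(50, 0, 0, 0), unit_scale = 0.005,
        nphoton = nphoton),
      settings = sim_settings(seed = seed)),
    skinvessel_rough = {
      surf <- make_grid_surface(extent = c(200, 200), cuts = 39, base_z = 20)
      surf <- randomize_normals(surf, amplitude = 1, seed = seed)
      list(
        scene = .skinvessel_scene(unit_scale = 0.0005, rough_surface = surf),
        props = .skinvessel_props(),
        meshing = meshing_options(max_tet_volume = 30),
        rough_surface = surf,
        source = photon_source(
          position = c(100, 50, -50) * 0.0005,
          direction = axis_rotation_direction("x", 150),
          srctype = "disk", srcparam1 = c(50, 0, 0, 0), unit_scale = 0.0005,
          nphoton = nphoton),
        settings = sim_settings(seed = seed))
    },
    slab_hair = list(
      scene = build_scene(
        bounds_lo = c(0, 0, 0), bounds_hi = c(20, 50, 34.51),
        regions = list(
          list(label = 3L, shape = shape_zslab(0, 20), name = "brain"),
          list(label = 2L, shape = shape_zslab(20, 22.07), name = "CSF"),
          list(label = 1L, shape = shape_zslab(22.07, 34.51),
               name = "scalp/skull"))),
      props = optical_props(label = 1:3,
                            mua = c(0.019, 0.004, 0.02),
                            mus = c(7.818, 0.009, 9.0),
                            g = rep(0.89, 3), n = rep(1.37, 3)),
      meshing = meshing_options(max_tet_volume = 10),
      hair = hair_params(count = 1000, length = 8, segments = 8, seed = seed),
      source = photon_source(position = c(10, 25, 40), direction = c(0, 0, -1),
                             srctype = "disk", srcparam1 = c(1, 0, 0, 0),
                             nphoton = nphoton),
      settings = sim_settings(seed = seed)),
    colin27 = list(
      external = "surface mesh (JMesh)",
      external_path = external_path,
      props = .colin27_props(),
      tissues = .colin27_tissues,
      meshing = meshing_options(max_tet_volume = 100),
      source = photon_source(position = c(75.76, 66.99, 168.21),
                             direction = c(0.1636, 0.4569, -0.873),
                             srctype = "pencil", nphoton = nphoton),
      settings = sim_settings(seed = seed)),
    digimouse = list(
      external = "labeled volume (NIfTI/JNIfTI, 0.8 mm isotropic)",
      external_path = external_path,
      props = .digimouse_props(),
      tissues = .digimouse_tissues,
      meshing = meshing_options(max_tet_volume = 100),
      source = photon_source(position = c(40, 160, 80),
                             direction = c(0, 0, -1),
                             srctype = "pencil", unit_scale = 0.8,
                             nphoton = nphoton),
      settings = sim_settings(seed = seed))
  )
  spec$name <- name
  structure(spec, class = "benchmark_spec")
}

#' @export
print.benchmark_spec <- function(x, ...) {
  cat("Benchmark:", x$name, "\n")
  if (!is.null(x$scene)) print(x$scene)
  if (!is.null(x$external))
    cat("  requires external input:", x$external,
        if (is.null(x$external_path)) "(not supplied)" else x$external_path,
        "\n")
  cat("  regions with optical properties:", nrow(x$props), "\n")
  invisible(x)
}
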