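# Lattice tetrahedralization, labeling, surface extraction, metrics.

test_that("a unit cube decomposes into 6 positive tets totaling the box volume, with a 12-triangle boundary", {
  m <- unit_cube_mesh()
  expect_equal(nrow(m$node), 8)
  expect_equal(nrow(m$elem), 6)
  expect_equal(nrow(m$face), 12)
  v <- tet_volumes(m)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1.0, tolerance = 1e-12)
  # each Kuhn tet holds exactly 1/6 of the cube (independent determinant oracle)
  for (i in 1:6)
    expect_equal(oracle_tet_volume(m$node, m$elem[i, ]), 1 / 6,
                 tolerance = 1e-12)
})

test_that("box decomposition scales and rejects degenerate input", {
  m2 <- cube_to_tets(box_corners(2, 1, 1))
  expect_equal(sum(tet_volumes(m2)), 2.0, tolerance = 1e-12)
  expect_error(cube_to_tets(box_corners(0, 1, 1)), "degenerate|rectangular")
  expect_error(cube_to_tets(matrix(rnorm(24), 8, 3)), "rectangular")
})

test_that("a unit box scene at coarse Vmax reproduces the 8/12/6 decomposition", {
  sc <- build_scene(c(0, 0, 0), c(1, 1, 1),
                    list(list(label = 1L, shape = shape_box(c(0, 0, 0), c(1, 1, 1)))))
  m <- tetrahedralize_scene(sc, meshing_options(max_tet_volume = 1 / 6))
  expect_equal(nrow(m$node), 8)
  expect_equal(nrow(m$elem), 6)
  expect_equal(nrow(m$face), 12)
})

test_that("the skin-vessel lattice mesh conserves volume exactly and labels all four regions", {
  b <- build_benchmark("skinvessel")
  m <- tetrahedralize_scene(b$scene, b$meshing)
  expect_setequal(unique(m$label), 1:4)
  expect_equal(sum(tet_volumes(m)), 1.0, tolerance = 1e-9)
  # element volume bound: Vmax = 30 voxel^3 at 0.005 mm/voxel
  expect_lte(max(tet_volumes(m)), 30 * 0.005^3 + 1e-15)
})

test_that("meshes are conforming (interior faces shared by exactly two tets) and labels match centroids", {
  b <- build_benchmark("skinvessel")
  m <- tetrahedralize_scene(b$scene, meshing_options(pitch_override = 0.05))
  inc <- face_incidence(m$elem)
  expect_true(all(inc %in% c(1L, 2L)))
  expect_equal(sum(inc == 1L), nrow(m$face))
  cent <- (m$node[m$elem[, 1], ] + m$node[m$elem[, 2], ] +
           m$node[m$elem[, 3], ] + m$node[m$elem[, 4], ]) / 4
  expect_identical(label_point(b$scene, cent), m$label)
})

test_that("cylinder-region volume converges monotonically to pi r^2 l under pitch halving", {
  b <- build_benchmark("skinvessel")
  true_v <- pi * 0.1^2 * 1
  err <- vapply(c(0.05, 0.025, 0.0125), function(h) {
    m <- tetrahedralize_scene(b$scene, meshing_options(pitch_override = h))
    v <- sum(tet_volumes(m)[m$label == 4L])
    abs(v - true_v)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.15 * true_v)
})

test_that("voxel volumes convert to conforming labeled meshes with exact node sharing", {
  # single labeled voxel
  v1 <- labeled_volume(array(1L, c(1, 1, 1)), voxel_size = 1)
  m1 <- volume_to_tetmesh(v1)
  expect_equal(nrow(m1$elem), 6)
  expect_equal(nrow(m1$node), 8)
  expect_equal(sum(tet_volumes(m1)), 1.0, tolerance = 1e-12)

  # 2x1x1 with two labels: shared face must reuse nodes (12 total, not 16)
  a <- array(1L, c(2, 1, 1)); a[2, 1, 1] <- 2L
  m2 <- volume_to_tetmesh(labeled_volume(a, voxel_size = 1))
  expect_equal(nrow(m2$elem), 12)
  expect_setequal(unique(m2$label), c(1L, 2L))
  expect_equal(nrow(m2$node), 12)
  expect_true(all(face_incidence(m2$elem) %in% c(1L, 2L)))

  # 4x4x4 all-ones at 0.8 mm: conservation
  m3 <- volume_to_tetmesh(labeled_volume(array(1L, c(4, 4, 4)), voxel_size = 0.8))
  expect_equal(sum(tet_volumes(m3)), 64 * 0.8^3, tolerance = 1e-9)

  expect_error(volume_to_tetmesh(labeled_volume(array(0L, c(2, 2, 2)))),
               "no foreground")
})

test_that("region surfaces are closed, watertight shells", {
  # whole-cube shell
  m <- unit_cube_mesh()
  s <- extract_region_surface(m, 1)
  expect_equal(nrow(s$faces), 12)
  expect_true(all(edge_incidence(s$faces) == 2L))

  # two-voxel two-label mesh: label 1 shell is a watertight cube
  a <- array(1L, c(2, 1, 1)); a[2, 1, 1] <- 2L
  m2 <- volume_to_tetmesh(labeled_volume(a, voxel_size = 1))
  s1 <- extract_region_surface(m2, 1)
  expect_equal(nrow(s1$faces), 12)
  expect_true(all(edge_incidence(s1$faces) == 2L))

  # skin-vessel cylinder shell: watertight and topologically a sphere
  b <- build_benchmark("skinvessel")
  mv <- tetrahedralize_scene(b$scene, meshing_options(pitch_override = 0.05))
  sc <- extract_region_surface(mv, 4)
  expect_true(all(edge_incidence(sc$faces) == 2L))
  V <- nrow(sc$vertices); F <- nrow(sc$faces); E <- length(edge_incidence(sc$faces))
  expect_equal(V - E + F, 2)

  expect_error(extract_region_surface(m, 9), "available")
})

test_that("mesh metrics partition volume by label and are translation invariant", {
  m <- unit_cube_mesh()
  mm <- mesh_metrics(m)
  expect_equal(mm$nodes, 8)
  expect_equal(mm$elems, 6)
  expect_equal(mm$volume, 1.0, tolerance = 1e-12)

  b <- build_benchmark("skinvessel")
  mv <- tetrahedralize_scene(b$scene, meshing_options(pitch_override = 0.05))
  mmv <- mesh_metrics(mv)
  expect_equal(sum(mmv$per_label$volume), mmv$volume, tolerance = 1e-12)

  shifted <- tet_mesh(sweep(mv$node, 2, c(5, -3, 2), "+"), mv$elem, mv$label)
  mms <- mesh_metrics(shifted)
  expect_equal(mms$volume, mmv$volume, tolerance = 1e-12)
  expect_equal(mms$per_label$volume, mmv$per_label$volume, tolerance = 1e-12)
})

test_that("an over-coarse pitch is halved with a warning until layers resolve", {
  sc <- build_scene(c(0, 0, 0), c(1, 1, 1), list(
    list(label = 1L, shape = shape_zslab(0, 0.3)),
    list(label = 2L, shape = shape_zslab(0.3, 1))))
  expect_warning(m <- tetrahedralize_scene(sc, meshing_options(pitch_override = 1)),
                 "halved")
  expect_setequal(unique(m$label), c(1L, 2L))
})
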