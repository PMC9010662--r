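# Elementary transport physics and the Monte Carlo driver.

test_that("quaternions rotate the downward reference direction as the rotation matrix oracle predicts", {
  expect_equal(quaternion_to_direction(c(1, 0, 0, 0)), c(0, 0, -1))
  # 180 degrees about x flips the beam upward
  expect_equal(quaternion_to_direction(c(0, 1, 0, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  # 150 degrees about x: the tilted source-2 orientation
  d <- axis_rotation_direction("x", 150)
  expect_equal(d, c(0, sin(150 * pi / 180), -cos(150 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(d, c(0, 0.5, 0.8660254), tolerance = 1e-7)
  # oracle: build the rotation matrix for a random axis/angle and compare
  set.seed(4)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
  q <- c(cos(th / 2), sin(th / 2) * ax)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K # Rodrigues
  expect_equal(quaternion_to_direction(q), as.vector(R %*% c(0, 0, -1)),
               tolerance = 1e-12)
  expect_error(quaternion_to_direction(c(0, 0, 0, 0)), "zero quaternion")
})

test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_free_path(1, exp(-1)), 1.0)
  expect_identical(sample_free_path(0, 0.5), Inf)
  # mean of 1e6 draws at the mid-slab scattering coefficient
  set.seed(11)
  u <- runif(1e6)
  mus <- 37.594
  s <- sample_free_path(mus, u)
  se <- 1 / (mus * sqrt(1e6)) # sd of exp(mus) is 1/mus
  expect_lt(abs(mean(s) - 1 / mus), 3 * se)
})

test_that("Henyey-Greenstein sampling has the right first moment and isotropic limit", {
  set.seed(21)
  n <- 1e5
  # g = 0: cos(theta) uniform on [-1, 1]
  d0 <- sample_hg(0, runif(n), runif(n), incoming = c(0, 0, 1))
  ks <- suppressWarnings(stats::ks.test(d0[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # forward limit
  expect_gt(sample_hg(0.99999, 0.5, 0.3)[3], 0.99)
  # directions always unit norm
  expect_equal(rowSums(d0^2), rep(1, n), tolerance = 1e-9)
})

test_that("Fresnel boundaries reproduce the closed-form reflectance, critical angle and matched limit", {
  # matched media: always refract, direction unchanged
  r <- fresnel_boundary(1.37, 1.37, c(0, 0, -1), c(0, 0, 1), u = 0.999999)
  expect_equal(r$action, "refract")
  expect_equal(r$direction, c(0, 0, -1))
  expect_equal(r$R, 0)

  # normal incidence air -> tissue (n = 1.37)
  r <- fresnel_boundary(1, 1.37, c(0, 0, -1), c(0, 0, 1), u = 0.5)
  expect_equal(r$R, ((1 - 1.37) / (1 + 1.37))^2, tolerance = 1e-12)

  # 60 degrees incidence from tissue to air is beyond the ~46.9-degree
  # critical angle: total internal reflection
  th <- 60 * pi / 180
  dir <- c(sin(th), 0, -cos(th))
  r <- fresnel_boundary(1.37, 1, dir, c(0, 0, 1), u = 0.999999)
  expect_equal(r$R, 1)
  expect_equal(r$action, "reflect")
  # reflection is specular: tangential kept, normal flipped
  expect_equal(r$direction, c(sin(th), 0, cos(th)), tolerance = 1e-12)

  # below the critical angle, Snell's law holds for the refracted ray
  th <- 20 * pi / 180
  r <- fresnel_boundary(1.37, 1, c(sin(th), 0, -cos(th)), c(0, 0, -1), u = 0.999999)
  expect_equal(r$action, "refract")
  sin_t <- sqrt(sum(r$direction[1:2]^2))
  expect_equal(sin_t, 1.37 * sin(th), tolerance = 1e-12)
})

test_that("a purely absorbing slab transmits exactly the Beer-Lambert fraction", {
  m <- slab_mesh(side = 1, pitch = 0.5)
  props <- optical_props(1, mua = 1, mus = 0, g = 0, n = 1)
  src <- photon_source(position = c(0.52, 0.47, 1), direction = c(0, 0, -1),
                       nphoton = 1e4)
  fl <- run_simulation(m, props, src,
                       sim_settings(seed = 3, do_reflection = FALSE))
  expect_equal(unname(fl$stats["escaped"]), exp(-1), tolerance = 1e-9)
  expect_equal(unname(fl$stats["absorbed"]), 1 - exp(-1), tolerance = 1e-9)
})

test_that("weight accounting sums to the launched weight and fluence is nonnegative", {
  b <- build_benchmark("skinvessel", nphoton = 3000, seed = 5)
  mesh <- tetrahedralize_scene(b$scene, meshing_options(pitch_override = 0.05))
  fl <- run_simulation(mesh, b$props, b$source, b$settings)
  s <- fl$stats
  expect_lt(abs(s["absorbed"] + s["escaped"] + s["truncated"] + s["lost"] - 1),
            1e-6)
  expect_true(all(fl$values >= 0))
  expect_lt(s[["lost"]], 1e-5)
})

test_that("fixed seeds reproduce fluence maps bitwise; different seeds differ", {
  m <- slab_mesh(side = 1, pitch = 0.25)
  props <- optical_props(1, mua = 0.1, mus = 5, g = 0.8, n = 1.37)
  src <- photon_source(position = c(0.52, 0.47, 1), direction = c(0, 0, -1),
                       nphoton = 2000)
  f1 <- run_simulation(m, props, src, sim_settings(seed = 42))
  f2 <- run_simulation(m, props, src, sim_settings(seed = 42))
  f3 <- run_simulation(m, props, src, sim_settings(seed = 43))
  expect_identical(f1$values, f2$values)
  expect_identical(f1$stats, f2$stats)
  expect_false(identical(f1$values, f3$values))
})

test_that("a ballistic packet crosses face-adjacent tetrahedra in a straight line", {
  # with mus = 0 and mua = 0 everything escapes on the far side and the
  # deposits (track-length estimator) lie only on nodes near the beam line
  m <- slab_mesh(side = 1, pitch = 0.25)
  props <- optical_props(1, mua = 0, mus = 0, g = 0, n = 1)
  src <- photon_source(position = c(0.51, 0.52, 1), direction = c(0, 0, -1),
                       nphoton = 10)
  fl <- run_simulation(m, props, src,
                       sim_settings(seed = 1, do_reflection = FALSE,
                                    do_normalize = FALSE))
  expect_equal(unname(fl$stats["escaped"]), 1, tolerance = 1e-12)
  hit <- which(fl$values[, 1] > 0)
  # every touched node sits within one cell pitch of the beam line
  d_xy <- sqrt((m$node[hit, 1] - 0.51)^2 + (m$node[hit, 2] - 0.52)^2)
  expect_true(all(d_xy < 0.26 * sqrt(2) + 1e-12))
  # total track length deposited equals slab thickness per unit weight
  expect_equal(sum(fl$values[, 1]) / 10, 1, tolerance = 1e-9)
})

test_that("refractive mismatch with reflection on traps more light than matched boundaries", {
  m <- slab_mesh(side = 2, pitch = 0.5)
  src <- photon_source(position = c(1.01, 0.97, 2), direction = c(0, 0, -1),
                       nphoton = 5000)
  pr_matched <- optical_props(1, mua = 0.05, mus = 10, g = 0.9, n = 1)
  pr_mismatch <- optical_props(1, mua = 0.05, mus = 10, g = 0.9, n = 1.37)
  a1 <- run_simulation(m, pr_matched, src,
                       sim_settings(seed = 9, do_reflection = TRUE))$stats["absorbed"]
  a2 <- run_simulation(m, pr_mismatch, src,
                       sim_settings(seed = 9, do_reflection = TRUE))$stats["absorbed"]
  expect_gt(a2, a1)
})

test_that("pencil sources must start inside the mesh and every label needs properties", {
  m <- slab_mesh()
  expect_error(run_simulation(
    m, optical_props(1, 0.1, 1, 0, 1.37),
    photon_source(position = c(5, 5, 5), direction = c(0, 0, -1), nphoton = 10),
    sim_settings()), "outside the mesh")
  expect_error(run_simulation(
    m, optical_props(2, 0.1, 1, 0, 1.37),
    photon_source(position = c(0.5, 0.5, 0.5), direction = c(0, 0, -1),
                  nphoton = 10),
    sim_settings()), "no optical properties")
})

test_that("the log-10 display transform floors, maps decades and preserves order", {
  expect_equal(log10_display(100), 2)
  expect_equal(log10_display(0, floor = 1e-12), -12)
  x <- c(0, 1e-15, 3e-4, 0.2, 7, 1e4)
  d <- log10_display(x)
  expect_true(all(diff(d[order(x)]) >= 0))
  expect_error(log10_display(1, floor = 0), "floor")
})

test_that("time gating books late packets as truncated and bins early deposits", {
  m <- slab_mesh(side = 2, pitch = 0.5)
  props <- optical_props(1, mua = 0.001, mus = 20, g = 0.9, n = 1.37)
  src <- photon_source(position = c(1.01, 0.97, 2), direction = c(0, 0, -1),
                       nphoton = 2000)
  # a 3 ps gate cuts most diffusing packets short
  fl <- run_simulation(m, props, src,
                       sim_settings(seed = 2, time_gates = c(0, 3e-12, 1e-12)))
  expect_equal(ncol(fl$values), 3)
  expect_gt(unname(fl$stats["truncated"]), 0.5)
  s <- fl$stats
  expect_lt(abs(s["absorbed"] + s["escaped"] + s["truncated"] + s["lost"] - 1),
            1e-6)
})
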