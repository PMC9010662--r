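# Hair-fiber geometry: rooting, growth, bending, export.

# flat square surface at z = 1, split into triangles, normals +z
flat_surface <- function(n = 4, side = 10) {
  g <- seq(0, side, length.out = n + 1)
  verts <- as.matrix(expand.grid(x = g, y = g))
  verts <- cbind(verts, 1)
  dimnames(verts) <- NULL
  id <- function(i, j) i + (n + 1) * (j - 1)
  tri <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, lapply(seq_len(n), function(j)
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))))))
  surf_mesh(verts, tri)
}

test_that("root sampling returns the exact count, on-surface and area-uniform", {
  surf <- flat_surface(4, 10)
  roots <- sample_roots(surf, 1000, seed = 3)
  expect_equal(nrow(roots$points), 1000)
  expect_true(all(abs(roots$points[, 3] - 1) < 1e-9)) # on the z = 1 plane
  expect_true(all(roots$points[, 1:2] >= -1e-9 & roots$points[, 1:2] <= 10 + 1e-9))

  # equal-area halves differ by less than 4 sqrt(n)
  left <- sum(roots$points[, 1] < 5)
  expect_lt(abs(left - 500), 4 * sqrt(1000))

  # determinism
  expect_identical(sample_roots(surf, 100, seed = 5)$points,
                   sample_roots(surf, 100, seed = 5)$points)
  expect_error(sample_roots(surf_mesh(matrix(0, 1, 3)[0, , drop = FALSE],
                                      matrix(0L, 0, 3)), 10), "no triangles")
})

test_that("root distribution passes a chi-square uniformity check over equal-area quadrants", {
  surf <- flat_surface(2, 8) # 4 quadrant cells of equal area
  roots <- sample_roots(surf, 1e4, seed = 11)
  q <- paste(roots$points[, 1] < 4, roots$points[, 2] < 4)
  p <- stats::chisq.test(table(q), p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("hairs grow along tilted normals with the requested arc length", {
  surf <- flat_surface(2, 4)
  roots <- sample_roots(surf, 50, seed = 1)

  # no tilt, no randomness: all fibers parallel to the +z normal
  p0 <- hair_params(count = 50, length = 3, segments = 6, tilt_angle = 0,
                    randomness = 0, seed = 1)
  h0 <- grow_hairs(roots, surf, p0)
  for (f in h0$fibers) {
    d <- f[nrow(f), ] - f[1, ]
    expect_equal(d / sqrt(sum(d^2)), c(0, 0, 1), tolerance = 1e-12)
  }

  # 45-degree tilt toward +x: every fiber at exactly 45 degrees from normal
  p45 <- hair_params(count = 50, length = 3, segments = 6, tilt_angle = 45,
                     tilt_axis = c(1, 0, 0), randomness = 0, seed = 1)
  h45 <- grow_hairs(roots, surf, p45)
  for (f in h45$fibers) {
    d <- f[2, ] - f[1, ]
    d <- d / sqrt(sum(d^2))
    expect_equal(sum(d * c(0, 0, 1)), cos(pi / 4), tolerance = 1e-12)
    expect_gt(d[1], 0) # tilted toward +x
  }

  # arc length equals params$length for every fiber
  arc <- function(f) sum(sqrt(rowSums(diff(f)^2)))
  expect_true(all(abs(vapply(h45$fibers, arc, numeric(1)) - 3) < 1e-9))

  # fibers start at their roots
  starts <- t(vapply(h45$fibers, function(f) f[1, ], numeric(3)))
  expect_equal(starts, unname(roots$points), tolerance = 1e-12)

  expect_error(hair_params(tilt_angle = 95), "tilt_angle")
})

test_that("randomness perturbs directions within the bounded cone", {
  surf <- flat_surface(2, 4)
  roots <- sample_roots(surf, 200, seed = 2)
  p <- hair_params(count = 200, length = 2, segments = 4, randomness = 0.2,
                   seed = 9)
  h <- grow_hairs(roots, surf, p)
  ang <- vapply(h$fibers, function(f) {
    d <- f[2, ] - f[1, ]
    acos(min(1, (d / sqrt(sum(d^2)))[3]))
  }, numeric(1))
  expect_true(all(ang <= 0.2 * pi / 2 + 1e-9)) # within randomness * 90 deg
  expect_gt(stats::sd(ang), 0) # actually perturbed
})

test_that("gravity bending is isometric, root-preserving, identity at zero and downward in the limit", {
  surf <- flat_surface(2, 4)
  roots <- sample_roots(surf, 20, seed = 4)
  p <- hair_params(count = 20, length = 5, segments = 10, tilt_angle = 30,
                   tilt_axis = c(1, 0, 0), seed = 4)
  h <- grow_hairs(roots, surf, p)

  expect_identical(apply_gravity_bend(h, 0)$fibers, h$fibers)

  arc <- function(f) sum(sqrt(rowSums(diff(f)^2)))
  for (g in c(0.3, 1, 5)) {
    hb <- apply_gravity_bend(h, g)
    expect_equal(vapply(hb$fibers, arc, numeric(1)),
                 vapply(h$fibers, arc, numeric(1)), tolerance = 1e-9)
    starts <- t(vapply(hb$fibers, function(f) f[1, ], numeric(3)))
    expect_equal(starts, unname(roots$points), tolerance = 1e-12)
  }

  # strong gravity: terminal segment points essentially straight down
  hb <- apply_gravity_bend(h, 50)
  for (f in hb$fibers) {
    d <- f[nrow(f), ] - f[nrow(f) - 1, ]
    expect_equal(d / sqrt(sum(d^2)), c(0, 0, -1), tolerance = 1e-9)
  }
})

test_that("hair export counts vertices, preserves coordinates and partitions the index runs", {
  surf <- flat_surface(2, 4)
  roots <- sample_roots(surf, 30, seed = 6)
  p <- hair_params(count = 30, length = 2, segments = 5, seed = 6)
  h <- grow_hairs(roots, surf, p)
  f <- withr::local_tempfile(fileext = ".jmsh")
  export_hairs(h, f)
  back <- read_mesh_document(f)
  expect_equal(nrow(back$vertices), 30 * (5 + 1))
  expect_equal(back$vertices, do.call(rbind, h$fibers), tolerance = 1e-15)
  runs <- lapply(back$metadata$HairIndices, function(r) as.integer(unlist(r)))
  expect_length(runs, 30)
  # runs partition 1..Nv with no gaps or overlaps
  expect_identical(sort(unlist(runs)), seq_len(nrow(back$vertices)))
  expect_true(all(vapply(runs, function(r) all(diff(r) == 1L), logical(1))))
})
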