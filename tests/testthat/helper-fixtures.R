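# Shared fixtures and independent oracles used across the test files.

# canonical corner order for a box [0,sx] x [0,sy] x [0,sz]
box_corners <- function(sx = 1, sy = 1, sz = 1) {
  m <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  dimnames(m) <- NULL
  m %*% diag(c(sx, sy, sz))
}

# independent signed-volume oracle (direct determinant, no package code)
oracle_tet_volume <- function(node, quad) {
  a <- node[quad[1], ]; b <- node[quad[2], ]
  c_ <- node[quad[3], ]; d <- node[quad[4], ]
  det(rbind(b - a, c_ - a, d - a)) / 6
}

# edge incidence table of a triangle soup: how many triangles borders each edge
edge_incidence <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  table(paste(e[, 1], e[, 2]))
}

# brute-force face incidence: how many tets share each triangular face
face_incidence <- function(elem) {
  f <- rbind(elem[, c(2, 3, 4)], elem[, c(1, 3, 4)],
             elem[, c(1, 2, 4)], elem[, c(1, 2, 3)])
  f <- t(apply(f, 1, sort))
  table(paste(f[, 1], f[, 2], f[, 3]))
}

unit_cube_mesh <- function() cube_to_tets(box_corners())

# small homogeneous box mesh for transport tests
slab_mesh <- function(side = 1, pitch = 0.5) {
  sc <- build_scene(c(0, 0, 0), c(side, side, side),
                    list(list(label = 1L,
                              shape = shape_box(c(0, 0, 0), rep(side, 3)))))
  tetrahedralize_scene(sc, meshing_options(pitch_override = pitch))
}
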