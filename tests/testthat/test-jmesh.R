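# JMesh / JNIfTI / NIfTI reading and writing.

cube_doc <- function() {
  m <- unit_cube_mesh()
  mesh_document(m$node, m$face, m$elem, labels = m$label)
}

test_that("packaged unit-cube fixtures decode to 8 vertices, 12 triangles, 6 tets in every dialect", {
  docs <- lapply(c("plain", "annotated", "compressed"), function(d) {
    f <- system.file("extdata", paste0("unitcube_", d, ".jmsh"),
                     package = "photonmesh")
    read_mesh_document(f)
  })
  for (doc in docs) {
    expect_equal(nrow(doc$vertices), 8)
    expect_equal(nrow(doc$triangles), 12)
    expect_equal(nrow(doc$tetrahedra), 6)
  }
  # dialect equivalence: element-wise identical decodes
  for (i in 2:3) {
    expect_equal(docs[[i]]$vertices, docs[[1]]$vertices)
    expect_identical(docs[[i]]$triangles, docs[[1]]$triangles)
    expect_identical(docs[[i]]$tetrahedra, docs[[1]]$tetrahedra)
    expect_identical(docs[[i]]$labels, docs[[1]]$labels)
  }
})

test_that("compressed annotation decodes to what an independent zlib+base64 encode stores", {
  # build the compressed payload by hand (writeBin + memCompress + base64)
  # and check the reader's decode against the known matrix
  m <- matrix(c(0.25, -1.5, 3, 42), nrow = 2, byrow = TRUE)
  payload <- jsonlite::base64_enc(
    memCompress(writeBin(as.vector(t(m)), raw(), size = 8, endian = "little"),
                type = "gzip"))
  txt <- jsonlite::toJSON(list(
    MeshVertex3 = list(`_ArrayType_` = "double", `_ArraySize_` = c(4, 3),
                       `_ArrayData_` = rep(0, 12)),
    NodeData = list(`_ArrayType_` = "double", `_ArraySize_` = c(4),
                    `_ArrayData_` = rep(1, 4)),
    Extra = list(`_ArrayType_` = "double", `_ArraySize_` = c(2, 2),
                 `_ArrayZipType_` = "zlib", `_ArrayZipSize_` = c(2, 2),
                 `_ArrayZipData_` = payload)), auto_unbox = TRUE)
  doc <- read_mesh_document(as.character(txt))
  expect_equal(photonmesh:::.decode_jdata_array(doc$metadata$Extra, "test"), m)
})

test_that("write/read round-trips are identities in every dialect, including node data", {
  doc <- cube_doc()
  doc$node_data <- seq_len(8) / 7 # awkward binary fractions on purpose
  for (d in c("plain", "annotated", "compressed")) {
    f <- withr::local_tempfile(fileext = ".jmsh")
    write_mesh_document(doc, f, dialect = d)
    back <- read_mesh_document(f)
    expect_identical(back$triangles, doc$triangles, label = d)
    expect_identical(back$tetrahedra, doc$tetrahedra, label = d)
    expect_identical(back$labels, doc$labels, label = d)
    expect_equal(back$vertices, doc$vertices, tolerance = 1e-15, label = d)
    expect_equal(back$node_data, doc$node_data, tolerance = 1e-15, label = d)
  }
})

test_that("vertex-only documents, malformed JSON and bad indices raise the documented errors", {
  v <- matrix(rnorm(9), 3, 3)
  only <- mesh_document(v)
  f <- withr::local_tempfile(fileext = ".jmsh")
  write_mesh_document(only, f)
  back <- read_mesh_document(f)
  expect_null(back$triangles)
  expect_null(back$tetrahedra)

  expect_error(read_mesh_document("{ not json !"), "malformed JSON")
  expect_error(mesh_document(v, triangles = matrix(c(1, 2, 5), 1)),
               "index out of")
  bad <- only
  bad$vertices[2, 1] <- NaN
  expect_error(write_mesh_document(bad, f), "non-finite")
  # annotation size inconsistent with payload
  txt <- '{"MeshVertex3":{"_ArrayType_":"double","_ArraySize_":[2,3],"_ArrayData_":[1,2,3]}}'
  expect_error(read_mesh_document(txt), "dialect error")
})

test_that("unknown JSON keys survive a round trip in metadata", {
  doc <- cube_doc()
  doc$metadata <- list(MyAnnotation = list(a = 1, b = "x"))
  f <- withr::local_tempfile(fileext = ".jmsh")
  write_mesh_document(doc, f)
  back <- read_mesh_document(f)
  expect_equal(back$metadata$MyAnnotation$b, "x")
})

test_that("NIfTI and JNIfTI volumes read identically; floats and anisotropy are rejected", {
  a <- array(0L, c(4, 4, 4))
  a[2:3, 2:3, 2:3] <- 1L
  vol <- labeled_volume(a, voxel_size = 1)
  fn <- withr::local_tempfile(fileext = ".nii")
  fj <- withr::local_tempfile(fileext = ".jnii")
  write_volume(vol, fn)
  write_volume(vol, fj)
  vn <- read_volume(fn)
  vj <- read_volume(fj)
  expect_equal(vn$voxel_size, 1.0)
  expect_identical(vn$voxels, a)
  expect_identical(vj$voxels, vn$voxels)

  expect_error(labeled_volume(array(0.5, c(2, 2, 2))), "non-integer")
  expect_error(read_volume(withr::local_tempfile(fileext = ".mat")),
               "accepted formats")
  # anisotropic header
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(1, 1, 2)
  fa <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, fa)
  expect_error(read_volume(fa), "anisotropic")
})

test_that("fluence writing stores node data and a log-10 display field consistently", {
  m <- unit_cube_mesh()
  f <- withr::local_tempfile(fileext = ".jmsh")

  # arbitrary fluence round-trips
  fl <- c(0, 0, 1e-3, 0.5, 2, 100, 0, 7)
  write_fluence(m, fl, f)
  back <- read_mesh_document(f)
  expect_equal(back$node_data, fl)
  expect_equal(as.numeric(unlist(back$metadata$NodeDataLog10)),
               log10(pmax(fl, 1e-12)))

  # all-zero fluence: display pinned at the floor
  write_fluence(m, rep(0, 8), f, floor = 1e-12)
  back <- read_mesh_document(f)
  expect_true(all(abs(as.numeric(unlist(back$metadata$NodeDataLog10)) + 12) < 1e-12))

  # one positive node
  one <- rep(0, 8); one[3] <- 100
  write_fluence(m, one, f)
  back <- read_mesh_document(f)
  expect_equal(as.numeric(unlist(back$metadata$NodeDataLog10))[3], 2)

  expect_error(write_fluence(m, 1:5, f), "does not match mesh node count")
})

test_that("OFF import reads a triangulated square", {
  f <- withr::local_tempfile(fileext = ".off")
  writeLines(c("OFF", "4 2 0",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "3 0 1 2", "3 0 2 3"), f)
  s <- read_off(f)
  expect_equal(nrow(s$vertices), 4)
  expect_identical(s$faces, matrix(c(1L, 2L, 3L, 1L, 3L, 4L), 2, byrow = TRUE))
})
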