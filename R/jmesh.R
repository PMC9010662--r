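# JMesh / JNIfTI / NIfTI input-output.
#
# JMesh stores meshes as JSON "name"/"value" constructs: "MeshVertex3" (node
# coordinates, Nn x 3), "MeshTri3" (surface triangles, Nt x 3) and "MeshTet4"
# (tetrahedra, Ne x 4, optionally with a 5th region-label column).  Node
# indices start from 1 in the file; the in-memory representation keeps the
# same 1-based convention (R's native indexing), so no conversion happens at
# I/O.  Arrays may be written in three dialects:
#   plain      - nested JSON arrays;
#   annotated  - a JSON object with "_ArrayType_", "_ArraySize_" and a
#                row-major "_ArrayData_" payload;
#   compressed - as annotated, but the payload is the little-endian binary
#                array, zlib-compressed (RFC 1950) and base64-encoded (RFC
#                4648) under "_ArrayZipType_"/"_ArrayZipSize_"/"_ArrayZipData_".

.jdata_type <- function(type) {
  switch(type,
    double = list(what = "double", size = 8L),
    single = list(what = "double", size = 4L),
    int32 = list(what = "integer", size = 4L),
    int16 = list(what = "integer", size = 2L),
    int8 = list(what = "integer", size = 1L),
    uint8 = list(what = "integer", size = 1L),
    stop("unsupported JData array type: ", type)
  )
}

# Decode one JData array (any dialect) to a numeric matrix/array.
.decode_jdata_array <- function(x, what = "array") {
  if (is.null(x)) return(NULL)
  if (is.list(x) && !is.null(x[["_ArrayType_"]])) {
    type <- x[["_ArrayType_"]]
    dims <- as.integer(unlist(x[["_ArraySize_"]]))
    n <- prod(dims)
    if (!is.null(x[["_ArrayZipData_"]])) {
      zt <- x[["_ArrayZipType_"]]
      if (!is.null(zt) && !identical(zt, "zlib"))
        stop("dialect error in ", what, ": unsupported compression '", zt, "'")
      info <- .jdata_type(type)
      raw <- jsonlite::base64_dec(gsub("\\s", "", x[["_ArrayZipData_"]]))
      bytes <- memDecompress(raw, type = "gzip")
      if (length(bytes) != n * info$size)
        stop("dialect error in ", what, ": compressed payload holds ",
             length(bytes) / info$size, " values but the size tag implies ", n)
      vals <- readBin(bytes, what = info$what, n = n, size = info$size,
                      endian = "little")
    } else {
      vals <- as.numeric(unlist(x[["_ArrayData_"]]))
      if (length(vals) != n)
        stop("dialect error in ", what, ": payload length ", length(vals),
             " does not match size tag ", paste(dims, collapse = "x"))
    }
    if (length(dims) == 2) {
      return(matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE))
    }
    # N-d: payload is row-major (last index fastest)
    a <- array(vals, dim = rev(dims))
    return(aperm(a, rev(seq_along(dims))))
  }
  # plain nested lists: list of equal-length rows
  if (is.list(x)) {
    rows <- lapply(x, function(r) as.numeric(unlist(r)))
    ncol <- unique(lengths(rows))
    if (length(ncol) != 1)
      stop("dialect error in ", what, ": ragged plain array")
    return(matrix(unlist(rows), ncol = ncol, byrow = TRUE))
  }
  as.numeric(x)
}

.encode_jdata_array <- function(m, type, dialect) {
  if (dialect == "plain") {
    if (is.matrix(m)) return(apply(m, 1, function(r) as.vector(r), simplify = FALSE))
    return(as.vector(m))
  }
  dims <- if (is.matrix(m)) dim(m) else length(m)
  flat <- if (is.matrix(m)) as.vector(t(m)) else as.vector(m)
  if (dialect == "annotated") {
    return(list(`_ArrayType_` = type, `_ArraySize_` = dims,
                `_ArrayData_` = flat))
  }
  info <- .jdata_type(type)
  if (info$what == "integer") flat <- as.integer(flat)
  bytes <- writeBin(flat, raw(), size = info$size, endian = "little")
  z <- memCompress(bytes, type = "gzip") # RFC 1950 zlib stream
  list(`_ArrayType_` = type, `_ArraySize_` = dims,
       `_ArrayZipType_` = "zlib", `_ArrayZipSize_` = dims,
       `_ArrayZipData_` = jsonlite::base64_enc(z))
}

#' Construct an in-memory JMesh document
#'
#' Bundles a mesh (vertices, surface triangles, tetrahedra with an optional
#' region-label column), optional per-node data and free-form metadata into
#' the document structure written to and read from `.jmsh` files.  Node
#' indices are 1-based, matching both the file convention and R indexing.
#'
#' @param vertices numeric matrix `Nn x 3` of node coordinates (mm).
#' @param triangles integer matrix `Nt x 3` of 1-based vertex indices, or
#'   `NULL`.
#' @param tetrahedra integer matrix `Ne x 4` of 1-based vertex indices, or
#'   `NULL`.
#' @param labels optional integer vector of per-tetrahedron region labels
#'   (written as a 5th `MeshTet4` column).
#' @param node_data optional numeric vector of length `Nn` (for example a
#'   nodal fluence map).
#' @param metadata named list of additional key/value annotations preserved
#'   verbatim in the file.
#' @return an object of class `mesh_document`.
#' @export
mesh_document <- function(vertices, triangles = NULL, tetrahedra = NULL,
                          labels = NULL, node_data = NULL, metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must be an Nn x 3 matrix")
  bad <- which(!is.finite(vertices), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite vertex coordinate at row ", bad[1, 1], ", column ",
         bad[1, 2])
  nn <- nrow(vertices)
  chk_idx <- function(m, name, k) {
    if (is.null(m) || length(m) == 0) return(NULL)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != k) stop(name, " must have ", k, " columns")
    off <- which(m < 1L | m > nn, arr.ind = TRUE)
    if (nrow(off) > 0)
      stop("index out of [1, ", nn, "] in ", name, " element ", off[1, 1])
    m
  }
  triangles <- chk_idx(triangles, "triangles", 3L)
  tetrahedra <- chk_idx(tetrahedra, "tetrahedra", 4L)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (is.null(tetrahedra) || length(labels) != nrow(tetrahedra))
      stop("labels must match the number of tetrahedra")
    if (any(labels < 0L)) stop("region labels must be nonnegative integers")
  }
  if (!is.null(node_data)) {
    node_data <- as.numeric(node_data)
    if (length(node_data) != nn)
      stop("node_data length ", length(node_data),
           " does not match vertex count ", nn)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 tetrahedra = tetrahedra, labels = labels,
                 node_data = node_data, metadata = metadata),
            class = "mesh_document")
}

#' @export
print.mesh_document <- function(x, ...) {
  cat("JMesh document:", nrow(x$vertices), "vertices,",
      if (is.null(x$triangles)) 0 else nrow(x$triangles), "triangles,",
      if (is.null(x$tetrahedra)) 0 else nrow(x$tetrahedra), "tetrahedra\n")
  if (!is.null(x$labels))
    cat("  region labels:", paste(sort(unique(x$labels)), collapse = ", "), "\n")
  if (!is.null(x$node_data)) cat("  per-node data attached\n")
  invisible(x)
}

#' Read a JMesh document
#'
#' Parses a `.jmsh`/JSON mesh file (or raw JSON text) holding `MeshVertex3`,
#' `MeshTri3` and `MeshTet4` constructs.  All three array dialects -- plain
#' nested arrays, typed annotated arrays and zlib-compressed annotated arrays
#' -- decode to identical matrices.  Unknown keys are preserved in
#' `$metadata`.
#'
#' @param path_or_text path to a file, or a length-1 character string that
#'   starts with `{` (raw JSON).
#' @return a [mesh_document()].
#' @export
read_mesh_document <- function(path_or_text) {
  txt <- if (length(path_or_text) == 1 && grepl("^\\s*\\{", path_or_text)) {
    path_or_text
  } else {
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON: ", conditionMessage(e),
                             call. = FALSE)
  )
  verts <- .decode_jdata_array(doc[["MeshVertex3"]], "MeshVertex3")
  if (is.null(verts)) stop("document has no MeshVertex3 construct")
  tris <- .decode_jdata_array(doc[["MeshTri3"]], "MeshTri3")
  tets <- .decode_jdata_array(doc[["MeshTet4"]], "MeshTet4")
  labels <- NULL
  if (!is.null(tets) && ncol(tets) == 5) {
    labels <- as.integer(tets[, 5])
    tets <- tets[, 1:4, drop = FALSE]
  }
  node_data <- doc[["NodeData"]]
  if (!is.null(node_data)) node_data <- as.numeric(.decode_jdata_array(node_data, "NodeData"))
  known <- c("MeshVertex3", "MeshTri3", "MeshTet4", "NodeData")
  meta <- doc[setdiff(names(doc), known)]
  mesh_document(vertices = verts, triangles = tris, tetrahedra = tets,
                labels = labels, node_data = node_data, metadata = meta)
}

#' Write a JMesh document
#'
#' Emits a `.jmsh` JSON file in one of the three supported array dialects.
#' Written files round-trip through [read_mesh_document()]: integer arrays
#' exactly, real arrays to full stored precision (compressed/annotated
#' dialects store binary doubles; the plain dialect prints 17 significant
#' digits).
#'
#' @param doc a [mesh_document()].
#' @param path output file path.
#' @param dialect one of `"plain"`, `"annotated"`, `"compressed"`.
#' @return `path`, invisibly.
#' @export
write_mesh_document <- function(doc, path,
                                dialect = c("plain", "annotated", "compressed")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(doc, "mesh_document"))
  bad <- which(!is.finite(doc$vertices), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("refusing to write non-finite coordinate at vertex ", bad[1, 1],
         ", axis ", bad[1, 2])
  out <- list()
  out$MeshVertex3 <- .encode_jdata_array(doc$vertices, "double", dialect)
  if (!is.null(doc$triangles) && nrow(doc$triangles) > 0)
    out$MeshTri3 <- .encode_jdata_array(doc$triangles, "int32", dialect)
  if (!is.null(doc$tetrahedra) && nrow(doc$tetrahedra) > 0) {
    tet <- doc$tetrahedra
    if (!is.null(doc$labels)) tet <- cbind(tet, as.integer(doc$labels))
    out$MeshTet4 <- .encode_jdata_array(tet, "int32", dialect)
  }
  if (!is.null(doc$node_data))
    out$NodeData <- .encode_jdata_array(doc$node_data, "double", dialect)
  out <- c(out, doc$metadata)
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Construct a labeled voxel volume
#'
#' @param voxels integer 3-D array of region labels; 0 is background.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param origin coordinate (mm) of the volume's low corner.
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, voxel_size = 1, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-D array")
  v <- as.array(voxels)
  if (is.double(v)) {
    if (any(v != round(v))) stop("volume holds non-integer values")
    storage.mode(v) <- "integer"
  }
  if (!is.integer(v)) stop("volume must be integer-valued")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar (mm)")
  structure(list(voxels = v, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("Labeled volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels,", x$voxel_size, "mm isotropic; labels:",
      paste(sort(unique(as.vector(x$voxels))), collapse = ", "), "\n")
  invisible(x)
}

#' Read a labeled volume from NIfTI or text JNIfTI
#'
#' Accepts NIfTI-1 (`.nii`, `.nii.gz`) and text JNIfTI (`.jnii`) files
#' carrying an integer-valued 3-D array; the voxel size comes from the file
#' header and must be isotropic.  Non-integer data is rejected, never
#' rounded.
#'
#' @param path input file.
#' @return a [labeled_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      stop("anisotropic voxels (", paste(signif(pd, 6), collapse = " x "),
           " mm) are not supported")
    arr <- as.array(img)
    d <- dim(arr)[seq_len(min(3, length(dim(arr))))]
    arr <- array(as.vector(arr), dim = d) # drop niftiImage attributes
    return(labeled_volume(arr, voxel_size = pd[1]))
  }
  if (grepl("\\.jnii$", path, ignore.case = TRUE)) {
    doc <- tryCatch(
      jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                         simplifyVector = FALSE),
      error = function(e) stop("malformed JSON: ", conditionMessage(e),
                               call. = FALSE)
    )
    hdr <- doc[["NIFTIHeader"]]
    dims <- as.integer(unlist(hdr[["Dim"]]))
    vs <- as.numeric(unlist(hdr[["VoxelSize"]]))
    if (length(vs) == 0) vs <- 1
    if (length(vs) > 1 && (max(vs) - min(vs)) > 1e-6 * max(vs))
      stop("anisotropic voxels are not supported")
    dat <- .decode_jdata_array(doc[["NIFTIData"]], "NIFTIData")
    if (is.matrix(dat) || is.null(dim(dat))) {
      # plain nested arrays collapse to a matrix of x-slabs: rebuild
      dat <- .reshape_nested_volume(doc[["NIFTIData"]], dims)
    }
    if (!all(dim(dat) == dims))
      stop("NIFTIData dimensions do not match header Dim")
    return(labeled_volume(dat, voxel_size = vs[1]))
  }
  stop("unsupported volume format '", path,
       "': accepted formats are NIfTI (.nii, .nii.gz) and text JNIfTI (.jnii)")
}

# nested [x][y][z] lists -> array
.reshape_nested_volume <- function(x, dims) {
  flat <- as.numeric(unlist(x))
  if (length(flat) != prod(dims)) stop("NIFTIData payload length mismatch")
  # nested lists flatten with the last axis fastest (row-major)
  aperm(array(flat, dim = rev(dims)), rev(seq_along(dims)))
}

#' Write a labeled volume to NIfTI or text JNIfTI
#'
#' Companion writer to [read_volume()]; `.nii`/`.nii.gz` go through the
#' NIfTI-1 library, `.jnii` is JSON with an annotated row-major payload.
#'
#' @param vol a [labeled_volume()].
#' @param path output path ending in `.nii`, `.nii.gz` or `.jnii`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- rep(vol$voxel_size, 3)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.jnii$", path, ignore.case = TRUE)) {
    dims <- dim(vol$voxels)
    flat <- as.vector(aperm(vol$voxels, c(3, 2, 1))) # row-major
    out <- list(
      NIFTIHeader = list(Dim = dims, VoxelSize = rep(vol$voxel_size, 3)),
      NIFTIData = list(`_ArrayType_` = "int32", `_ArraySize_` = dims,
                       `_ArrayData_` = as.integer(flat))
    )
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(17)), path)
    return(invisible(path))
  }
  stop("unsupported volume format: ", path)
}

#' Write a nodal fluence map alongside its mesh
#'
#' Stores the mesh constructs plus the selected time gate of the fluence map
#' as `NodeData`, and a companion `NodeDataLog10` field holding the log-10
#' display transform (see [log10_display()]).
#'
#' @param mesh a [tet_mesh()].
#' @param fluence a `fluence_map` from [run_simulation()], or a numeric
#'   vector with one value per mesh node.
#' @param path output `.jmsh` path.
#' @param gate time-gate column to store (default 1).
#' @param floor positive floor applied inside the log-10 transform.
#' @param dialect array dialect passed to [write_mesh_document()].
#' @return `path`, invisibly.
#' @export
write_fluence <- function(mesh, fluence, path, gate = 1L, floor = 1e-12,
                          dialect = "plain") {
  stopifnot(inherits(mesh, "tet_mesh"))
  vals <- if (inherits(fluence, "fluence_map")) fluence$values[, gate] else
    as.numeric(fluence)
  if (length(vals) != nrow(mesh$node))
    stop("fluence length ", length(vals), " does not match mesh node count ",
         nrow(mesh$node))
  doc <- mesh_document(vertices = mesh$node, triangles = mesh$face,
                       tetrahedra = mesh$elem, labels = mesh$label,
                       node_data = vals,
                       metadata = list(NodeDataLog10 = log10(pmax(vals, floor)),
                                       LengthUnit = "mm"))
  write_mesh_document(doc, path, dialect = dialect)
}

#' Read a triangular surface mesh in OFF format
#'
#' Import convenience for the plain-text Object File Format; returns the
#' vertex/face pair used by the scene and hair modules.
#'
#' @param path `.off` file path.
#' @return a `surf_mesh` (list with `vertices` and `faces`).
#' @export
read_off <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: missing header")
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vmat <- matrix(as.numeric(unlist(strsplit(ln[3:(2 + nv)], "\\s+"))),
                 ncol = 3, byrow = TRUE)
  fl <- strsplit(ln[(3 + nv):(2 + nv + nf)], "\\s+")
  faces <- t(vapply(fl, function(r) {
    r <- as.integer(r)
    if (r[1] != 3) stop("only triangular faces are supported")
    r[2:4] + 1L # OFF is 0-based
  }, integer(3)))
  surf_mesh(vmat, faces)
}

#' Construct a triangular surface mesh
#'
#' @param vertices numeric `Nn x 3` matrix (mm).
#' @param faces integer `Nt x 3` matrix of 1-based vertex indices.
#' @return an object of class `surf_mesh`.
#' @export
surf_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices must be Nn x 3 and faces Nt x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "surf_mesh")
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles\n")
  invisible(x)
}
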