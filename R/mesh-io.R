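# Mesh and image I/O: STL (binary and ASCII) and PLY (ASCII) for
# surfaces, NIfTI-1 for voxel grids. Mesh files carry no units; a JSON
# sidecar (<file>.json, field "units") records that coordinates are cm.

#' Read a triangle mesh from STL or PLY
#'
#' Binary and ASCII STL and ASCII PLY are supported; the format is taken
#' from the file extension. STL files carry no connectivity, so vertices
#' are welded by exact coordinate match. If a JSON sidecar `<file>.json`
#' exists its `units` field must be `"cm"`.
#'
#' @param path File path (`.stl` or `.ply`).
#' @param validate Run closed-surface validation (default TRUE).
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path, validate = TRUE) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$units) && !identical(meta$units, "cm"))
      stop("mesh sidecar declares units '", meta$units, "'; expected cm")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = readSTL(path, validate),
         ply = readPLY(path, validate),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh A [TriangleMesh-class] (cm).
#' @param path Output path (`.stl` or `.ply`).
#' @param binary For STL: write the binary variant (default TRUE).
#' @param sidecar Write the `<file>.json` units sidecar.
#' @return Invisibly `path`.
#' @export
writeMesh <- function(mesh, path, binary = TRUE, sidecar = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = writeSTL(mesh, path, binary),
         ply = writePLY(mesh, path),
         stop("unsupported mesh format: .", ext))
  if (sidecar)
    jsonlite::write_json(list(units = "cm"), paste0(path, ".json"),
                         auto_unbox = TRUE)
  invisible(path)
}

faceSoup <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  list(a = v[f[, 1], , drop = FALSE], b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

weldSoup <- function(tri) {
  # tri: 3n x 3 matrix of corner coordinates, consecutive triples = faces
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uk <- unique(key)
  idx <- match(key, uk)
  verts <- tri[match(uk, key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

writeSTL <- function(mesh, path, binary = TRUE) {
  fs <- faceSoup(mesh)
  n <- crossRows(fs$b - fs$a, fs$c - fs$a)
  len <- sqrt(rowSums(n * n)); len[len == 0] <- 1
  n <- n / len
  nf <- nrow(n)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    dat <- t(cbind(n, fs$a, fs$b, fs$c))  # 12 floats per face
    for (i in seq_len(nf)) {
      writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nf)) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g", fs$a[i, 1], fs$a[i, 2], fs$a[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", fs$b[i, 1], fs$b[i, 2], fs$b[i, 3]),
                   sprintf("      vertex %.9g %.9g %.9g", fs$c[i, 1], fs$c[i, 2], fs$c[i, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

readSTL <- function(path, validate = TRUE) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80)
  isAscii <- grepl("^solid", rawToChar(header[1:5]))
  if (!isAscii) {
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    expected <- 84 + nf * 50
    isAscii <- !isTRUE(file.size(path) == expected)
  }
  close(con)
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb"); on.exit(close(con))
    readBin(con, "raw", 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    tri <- matrix(NA_real_, 3 * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      tri[3 * i - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  w <- weldSoup(tri)
  TriangleMesh(w$vertices, w$faces, validate = validate)
}

writePLY <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@faces)
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh@vertices[, 1], mesh@vertices[, 2],
                     mesh@vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L,
                     mesh@faces[, 3] - 1L), con)
  invisible(path)
}

readPLY <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[1], "ply") || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  endh <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vparts <- strsplit(trimws(lines[endh + seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(lines[endh + nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) as.integer(p[2:4]) + 1L))
  TriangleMesh(verts, faces, validate = validate)
}

#' Export / import a voxel grid as NIfTI-1
#'
#' Values are written as float32 with the grid spacing (mm) in the pixdim
#' header fields; axes follow the internal array order (RAS-like: the
#' first index increases to the right, second anterior, third superior).
#'
#' @param x An [OccupancyGrid-class], [ActivityVolume-class] or [VOI-class].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `writeVolumeNIfTI()` invisibly returns `path`;
#'   `readVolumeNIfTI()` returns an object of class `class`.
#' @export
writeVolumeNIfTI <- function(x, path) {
  img <- RNifti::asNifti(x@values, internal = FALSE)
  RNifti::pixdim(img) <- x@spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname writeVolumeNIfTI
#' @param class Class of the returned grid object.
#' @param origin Grid origin (mm) to restore, not stored in the header.
#' @export
readVolumeNIfTI <- function(path, class = "ActivityVolume",
                            origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  new(class, origin = origin, spacing = as.numeric(sp),
      values = array(as.numeric(img), dim(img)))
}
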