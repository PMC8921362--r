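#' Construct a triangle mesh
#'
#' Builds a [TriangleMesh-class] from a vertex matrix (cm) and a face index
#' matrix, checking watertightness, consistent outward orientation and the
#' absence of degenerate faces unless `validate = FALSE`.
#'
#' @param vertices Numeric n x 3 matrix of vertex positions in cm.
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param validate Run the full closed-surface checks (default TRUE).
#' @return A [TriangleMesh-class].
#' @examples
#' m <- cubeMesh(1)
#' enclosedVolume(m)
#' @export
TriangleMesh <- function(vertices, faces, validate = TRUE) {
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- new("TriangleMesh", vertices = vertices, faces = faces)
  if (validate) assertClosedMesh(mesh)
  mesh
}

#' Check that a mesh is a closed, outward-oriented surface
#'
#' A mesh is accepted when every edge is shared by exactly two faces with
#' opposite traversal direction (watertight, consistently oriented), no
#' face is degenerate (area below `1e-12` of the largest), and the signed
#' volume is positive (outward normals). Violations raise an error with a
#' diagnostic; an inward-oriented mesh is reported as such with the advice
#' to reverse the face winding rather than being silently fixed.
#'
#' @param mesh A [TriangleMesh-class].
#' @return Invisibly `TRUE`.
#' @export
assertClosedMesh <- function(mesh) {
  f <- mesh@faces
  # directed edges; watertight + consistent orientation <=> every undirected
  # edge appears exactly twice, once in each direction
  e1 <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("mesh is not watertight: ", sum(cnt != 2L),
         " edge(s) are not shared by exactly 2 faces")
  dirkey <- paste(e1[, 1], e1[, 2])
  if (anyDuplicated(dirkey))
    stop("mesh orientation is inconsistent: some edge is traversed twice ",
         "in the same direction")
  a <- triangleAreas(mesh)
  if (any(a <= 1e-12 * max(a)))
    stop("mesh has ", sum(a <= 1e-12 * max(a)), " degenerate (zero-area) face(s)")
  if (signedVolume(mesh) <= 0)
    stop("mesh is inward-oriented (negative signed volume); ",
         "reverse the face winding (reorientMesh()) so normals point outward")
  invisible(TRUE)
}

# per-face corner coordinate matrices (internal)
faceCorners <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

crossRows <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

triangleAreas <- function(mesh) {
  fc <- faceCorners(mesh)
  n <- crossRows(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(n * n))
}

signedVolume <- function(mesh) {
  fc <- faceCorners(mesh)
  sum(rowSums(fc$a * crossRows(fc$b, fc$c))) / 6
}

#' @rdname surfaceArea
setMethod("surfaceArea", "TriangleMesh", function(mesh, ...) {
  assertClosedMesh(mesh)
  sum(triangleAreas(mesh))
})

#' @rdname enclosedVolume
setMethod("enclosedVolume", "TriangleMesh", function(mesh, ...) {
  assertClosedMesh(mesh)
  signedVolume(mesh)
})

#' @rdname saToV
setMethod("saToV", "TriangleMesh", function(x, ...) {
  v <- enclosedVolume(x)
  if (v <= 0) stop("SA:V undefined: enclosed volume must be positive")
  surfaceArea(x) / v
})

#' Rigid and affine mesh helpers
#'
#' `translateMesh` shifts all vertices by `offset` (cm); `scaleMesh`
#' scales about a fixed point (default the origin); `reorientMesh`
#' reverses the face winding, flipping all normals.
#'
#' @param mesh A [TriangleMesh-class].
#' @param offset Numeric length-3 translation in cm.
#' @param factor Scalar scale factor.
#' @param center Point (cm) the scaling is applied about.
#' @return A transformed [TriangleMesh-class].
#' @name meshTransforms
#' @export
translateMesh <- function(mesh, offset) {
  TriangleMesh(sweep(mesh@vertices, 2, offset, "+"), mesh@faces, validate = FALSE)
}

#' @rdname meshTransforms
#' @export
scaleMesh <- function(mesh, factor, center = c(0, 0, 0)) {
  v <- sweep(mesh@vertices, 2, center, "-") * factor
  TriangleMesh(sweep(v, 2, center, "+"), mesh@faces, validate = FALSE)
}

#' @rdname meshTransforms
#' @export
reorientMesh <- function(mesh) {
  TriangleMesh(mesh@vertices, mesh@faces[, c(1, 3, 2)], validate = FALSE)
}

meshCentroid <- function(mesh) {
  # volume centroid via divergence theorem (exact for closed meshes):
  # C_k = (1/(2V)) * sum_f n_k * ((a_k+b_k)^2 + (b_k+c_k)^2 + (c_k+a_k)^2) / 24
  fc <- faceCorners(mesh)
  n <- crossRows(fc$b - fc$a, fc$c - fc$a)  # 2 * area * outward normal
  num <- colSums(n * (((fc$a + fc$b)^2 + (fc$b + fc$c)^2 + (fc$c + fc$a)^2) / 24))
  num / (2 * signedVolume(mesh))
}

#' Offset a mesh along its vertex normals
#'
#' Moves every vertex by `distance` along its area-weighted vertex normal;
#' used to grow the inactive wall shell around a cavity. Accurate for
#' smooth meshes and offsets small relative to local curvature radii.
#'
#' @param mesh A [TriangleMesh-class] (cm).
#' @param distance Offset in cm (positive = outward).
#' @return An offset [TriangleMesh-class].
#' @export
offsetMesh <- function(mesh, distance) {
  fc <- faceCorners(mesh)
  n <- crossRows(fc$b - fc$a, fc$c - fc$a)  # area-weighted face normals
  # accumulate area-weighted normals per vertex (vectorized scatter-add)
  vn <- matrix(0, nrow(mesh@vertices), 3)
  idx <- as.vector(mesh@faces)
  for (k in 1:3) {
    acc <- rowsum(rep(n[, k], 3L), idx)
    vn[as.integer(rownames(acc)), k] <- acc
  }
  len <- sqrt(rowSums(vn * vn))
  len[len == 0] <- 1
  vn <- vn / len
  TriangleMesh(mesh@vertices + distance * vn, mesh@faces, validate = FALSE)
}
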