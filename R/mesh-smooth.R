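#' @rdname smoothMesh
setMethod("smoothMesh", "TriangleMesh", function(mesh, strength = 20, ...) {
  if (length(strength) != 1L || is.na(strength) || strength < 0 || strength > 100)
    stop("strength must be a scalar in [0, 100]")
  assertClosedMesh(mesh)
  iters <- as.integer(round(strength))
  if (iters == 0L) return(mesh)
  v0 <- enclosedVolume(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  # Taubin lambda/mu smoothing with cotangent (Laplace-Beltrami) weights:
  # the shrink/inflate pair removes surface detail with little low-frequency
  # distortion, and the geometric weights keep the flow independent of the
  # combinatorics of the triangulation
  lambda <- 0.5; mu <- -0.5263
  for (i in seq_len(iters)) {
    v <- v + lambda * (cotanAverage(v, f) - v)
    v <- v + mu * (cotanAverage(v, f) - v)
  }
  out <- TriangleMesh(v, f, validate = FALSE)
  # volume compensation: uniform rescale about the volume centroid
  vs <- signedVolume(out)
  if (vs <= 0) stop("smoothing collapsed the mesh (non-positive volume)")
  out <- scaleMesh(out, (v0 / vs)^(1 / 3), center = meshCentroid(out))
  assertClosedMesh(out)
  out
})

# cotangent-weighted neighbour average of vertex positions; negative
# weights (obtuse triangles) are clamped to zero, with a uniform fallback
# for vertices whose weights all vanish
cotanAverage <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  cr <- crossRows(b - a, c - a)
  area2 <- sqrt(rowSums(cr * cr))           # 2 * triangle area
  area2 <- pmax(area2, 1e-30)
  cotA <- rowSums((b - a) * (c - a)) / area2  # cot of angle at a (edge b-c)
  cotB <- rowSums((a - b) * (c - b)) / area2
  cotC <- rowSums((a - c) * (b - c)) / area2
  from <- c(f[, 2], f[, 3], f[, 1], f[, 3], f[, 1], f[, 2])
  to   <- c(f[, 3], f[, 2], f[, 3], f[, 1], f[, 2], f[, 1])
  w <- pmax(c(cotA, cotA, cotB, cotB, cotC, cotC), 0)
  n <- nrow(v)
  wsum <- numeric(n)
  acc <- rowsum(w, from)
  wsum[as.integer(rownames(acc))] <- acc
  out <- matrix(0, n, 3)
  for (k in 1:3) {
    acc <- rowsum(w * v[to, k], from)
    out[as.integer(rownames(acc)), k] <- acc
  }
  ok <- wsum > 1e-12
  out[ok, ] <- out[ok, ] / wsum[ok]
  if (any(!ok)) {
    # uniform fallback for degenerate one-rings
    cnt <- numeric(n); su <- matrix(0, n, 3)
    acc <- rowsum(rep(1, length(from)), from)
    cnt[as.integer(rownames(acc))] <- acc
    for (k in 1:3) {
      acc <- rowsum(v[to, k], from)
      su[as.integer(rownames(acc)), k] <- acc
    }
    out[!ok, ] <- su[!ok, , drop = FALSE] / pmax(cnt[!ok], 1)
  }
  out
}
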