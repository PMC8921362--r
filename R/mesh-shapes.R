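#' Axis-aligned cube mesh
#'
#' A cube of the given edge length (cm), centred at `center`, triangulated
#' into 12 outward-oriented faces. Mainly a closed-form reference shape for
#' tests (area `6*edge^2`, volume `edge^3`).
#'
#' @param edge Edge length in cm.
#' @param center Cube centre (cm).
#' @return A [TriangleMesh-class].
#' @export
cubeMesh <- function(edge = 1, center = c(0, 0, 0)) {
  h <- edge / 2
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  v <- sweep(v, 2, center, "+")
  # faces with outward orientation (vertex order from expand.grid:
  # 1:(---) 2:(+--) 3:(-+-) 4:(++-) 5:(--+) 6:(+-+) 7:(-++) 8:(+++))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  TriangleMesh(unname(v), f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere. Subdivision level `n`
#' gives `20 * 4^n` faces; at level 4 the area and volume agree with
#' `4*pi*r^2` and `4/3*pi*r^3` to better than 0.2%.
#'
#' @param subdivisions Number of 1-to-4 subdivision rounds (>= 0).
#' @param radius Sphere radius in cm.
#' @param center Sphere centre (cm).
#' @return A [TriangleMesh-class].
#' @export
icosphere <- function(subdivisions = 4, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(subdivisions)) {
    sub <- subdivideTriangles(v, f)
    v <- sub$vertices; f <- sub$faces
  }
  v <- v / sqrt(rowSums(v * v)) * radius
  TriangleMesh(sweep(v, 2, center, "+"), f)
}

# one round of loop-style 1->4 topological subdivision with midpoint dedup
subdivideTriangles <- function(v, f) {
  nv <- nrow(v)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(key)
  mid_id <- nv + match(key, uk)
  first <- match(uk, key)
  mids <- (v[edges[first, 1], , drop = FALSE] + v[edges[first, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  mab <- mid_id[1:nf]; mbc <- mid_id[nf + 1:nf]; mca <- mid_id[2 * nf + 1:nf]
  fnew <- rbind(cbind(f[, 1], mab, mca),
                cbind(f[, 2], mbc, mab),
                cbind(f[, 3], mca, mbc),
                cbind(mab, mbc, mca))
  list(vertices = rbind(v, mids), faces = fnew)
}

# radial (star-convex) mesh: deform an icosphere by a radius function of
# direction; rfun takes an n x 3 matrix of unit directions, returns radii (cm)
radialMesh <- function(rfun, subdivisions = 4, center = c(0, 0, 0)) {
  base <- icosphere(subdivisions, 1)
  u <- base@vertices
  u <- u / sqrt(rowSums(u * u))
  r <- rfun(u)
  if (any(r <= 0)) stop("radial function produced non-positive radii")
  TriangleMesh(sweep(u * r, 2, center, "+"), base@faces)
}

# superellipsoid radius in direction u for semi-axes (a,b,c) and exponents
# (e1 vertical, e2 horizontal); implicit form is homogeneous in r, so the
# boundary radius has the closed form below
superellipsoidRadius <- function(u, a, b, c, e1 = 1, e2 = 1) {
  A <- (abs(u[, 1] / a))^(2 / e2) + (abs(u[, 2] / b))^(2 / e2)
  B <- (abs(u[, 3] / c))^(2 / e1)
  (A^(e2 / e1) + B)^(-e1 / 2)
}

#' Prolate spheroid matched to a printed volume and surface area
#'
#' Reconstructs a prolate spheroid (semi-axes a = b < c) whose analytic
#' volume `4/3*pi*a^2*c` and surface area
#' `2*pi*a^2*(1 + (c/(a*e))*asin(e))`, `e = sqrt(1 - a^2/c^2)`,
#' match the requested values, then meshes it as a scaled icosphere. Used
#' to rebuild the ellipsoidal reference phantom from its published volume
#' and surface area, which are the only quantities reported for it.
#'
#' @param volume Target enclosed volume, cm^3.
#' @param area Target surface area, cm^2; must be at least the sphere
#'   minimum `(36*pi*volume^2)^(1/3)` (up to a 0.2% tolerance, below which
#'   a sphere is returned).
#' @param subdivisions Icosphere subdivision level of the mesh.
#' @return A [TriangleMesh-class] whose recomputed volume and area match
#'   the inputs within 0.5%.
#' @examples
#' m <- spheroidMatching(212.5, 180.2)
#' saToV(m)   # ~ 0.848
#' @export
spheroidMatching <- function(volume, area, subdivisions = 4) {
  if (volume <= 0) stop("volume must be positive")
  amin <- (36 * pi * volume^2)^(1 / 3)
  if (area < amin * (1 - 0.002))
    stop(sprintf(paste0("infeasible: surface area %.1f cm^2 is below the ",
                        "sphere minimum %.1f cm^2 for volume %.1f cm^3"),
                 area, amin, volume))
  sphereA <- function(q) {  # analytic prolate spheroid area at aspect q = c/a
    a <- (3 * volume / (4 * pi * q))^(1 / 3)
    c <- q * a
    if (q <= 1 + 1e-12) return(4 * pi * a^2)
    e <- sqrt(1 - (a / c)^2)
    2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
  }
  if (area <= amin * (1 + 2e-4)) {
    q <- 1
  } else {
    q <- stats::uniroot(function(q) sphereA(q) - area, c(1 + 1e-9, 50),
                        tol = 1e-12)$root
  }
  a <- (3 * volume / (4 * pi * q))^(1 / 3)
  base <- icosphere(subdivisions, 1)
  v <- base@vertices
  v <- v / sqrt(rowSums(v * v))
  TriangleMesh(cbind(v[, 1] * a, v[, 2] * a, v[, 3] * a * q), base@faces)
}
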