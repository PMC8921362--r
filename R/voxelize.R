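#' @rdname voxelize
setMethod("voxelize", "TriangleMesh", function(mesh, spacing = 1,
                                               supersampling = 3,
                                               padding = 30, ...) {
  if (spacing <= 0) stop("spacing must be positive (mm)")
  if (supersampling < 1) stop("supersampling must be >= 1")
  assertClosedMesh(mesh)
  vmm <- mesh@vertices * 10  # cm -> mm at the discretization boundary
  lo <- apply(vmm, 2, min) - padding
  hi <- apply(vmm, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing))
  if (prod(as.double(dims)) > 6e7)
    stop(sprintf("mesh larger than allowed grid extent: %d x %d x %d voxels at %.2f mm",
                 dims[1], dims[2], dims[3], spacing))
  origin <- lo + spacing / 2
  occ <- rayCastOccupancy(vmm, mesh@faces, origin, rep(spacing, 3), dims,
                          as.integer(supersampling))
  new("OccupancyGrid", origin = origin, spacing = rep(spacing, 3), values = occ)
})

# Fractional occupancy by z-ray casting.
#
# Sub-rays are cast on an s x s grid per voxel in x/y (with a fixed tiny
# deterministic offset to dodge vertex/edge hits); intersections with the
# surface give exact in/out z-intervals per ray, so the z coverage of every
# voxel is exact and only x/y are sampled.
rayCastOccupancy <- function(vmm, faces, origin, spacing, dims, s) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  d <- spacing[1]
  dsub <- d / s
  jit <- 0.31830989 * dsub * 1e-3  # fixed sub-resolution offset, 1/pi scaled
  gx0 <- origin[1] - d / 2; gy0 <- origin[2] - d / 2; gz0 <- origin[3] - d / 2
  nxs <- nx * s

  p1 <- vmm[faces[, 1], , drop = FALSE]
  p2 <- vmm[faces[, 2], , drop = FALSE]
  p3 <- vmm[faces[, 3], , drop = FALSE]
  denom <- (p2[, 2] - p3[, 2]) * (p1[, 1] - p3[, 1]) +
           (p3[, 1] - p2[, 1]) * (p1[, 2] - p3[, 2])
  txmin <- pmin(p1[, 1], p2[, 1], p3[, 1]); txmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
  tymin <- pmin(p1[, 2], p2[, 2], p3[, 2]); tymax <- pmax(p1[, 2], p2[, 2], p3[, 2])

  ray_l <- vector("list", nrow(faces))
  z_l <- vector("list", nrow(faces))
  for (t in seq_len(nrow(faces))) {
    if (abs(denom[t]) < 1e-12) next  # projection degenerate: face parallel to z
    kx0 <- ceiling((txmin[t] - gx0 - jit) / dsub + 0.5 - 1e-12)
    kx1 <- floor((txmax[t] - gx0 - jit) / dsub + 0.5 + 1e-12)
    ky0 <- ceiling((tymin[t] - gy0 - jit) / dsub + 0.5 - 1e-12)
    ky1 <- floor((tymax[t] - gy0 - jit) / dsub + 0.5 + 1e-12)
    kx0 <- max(kx0, 1L); kx1 <- min(kx1, nxs)
    ky0 <- max(ky0, 1L); ky1 <- min(ky1, ny * s)
    if (kx0 > kx1 || ky0 > ky1) next
    kx <- kx0:kx1; ky <- ky0:ky1
    xs <- gx0 + (kx - 0.5) * dsub + jit
    ys <- gy0 + (ky - 0.5) * dsub + jit
    nkx <- length(kx); nky <- length(ky)
    X <- rep(xs, times = nky); Y <- rep(ys, each = nkx)
    w1 <- ((p2[t, 2] - p3[t, 2]) * (X - p3[t, 1]) +
           (p3[t, 1] - p2[t, 1]) * (Y - p3[t, 2])) / denom[t]
    w2 <- ((p3[t, 2] - p1[t, 2]) * (X - p3[t, 1]) +
           (p1[t, 1] - p3[t, 1]) * (Y - p3[t, 2])) / denom[t]
    w3 <- 1 - w1 - w2
    ins <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(ins)) next
    zhit <- w1[ins] * p1[t, 3] + w2[ins] * p2[t, 3] + w3[ins] * p3[t, 3]
    rid <- (rep(ky, each = nkx)[ins] - 1) * nxs + rep(kx, times = nky)[ins]
    ray_l[[t]] <- rid
    z_l[[t]] <- zhit
  }
  ray <- unlist(ray_l, use.names = FALSE)
  if (is.null(ray) || length(ray) == 0L)
    return(array(0, dims))
  zz <- unlist(z_l, use.names = FALSE)
  od <- order(ray, zz)
  ray <- ray[od]; zz <- zz[od]
  runs <- rle(ray)
  if (any(runs$lengths %% 2L != 0L))
    stop("ray casting found an odd crossing count; mesh may not be watertight")
  pos <- sequence(runs$lengths)
  ent <- pos %% 2L == 1L
  z0 <- (zz[ent] - gz0) / d      # in voxel units from the grid z start
  z1 <- (zz[!ent] - gz0) / d
  rpair <- ray[ent]
  z0 <- pmin(pmax(z0, 0), nz)
  z1 <- pmin(pmax(z1, 0), nz)
  keep <- z1 > z0
  z0 <- z0[keep]; z1 <- z1[keep]; rpair <- rpair[keep]

  kxr <- (rpair - 1L) %% nxs + 1L
  kyr <- (rpair - 1L) %/% nxs + 1L
  vx <- (kxr - 1L) %/% s + 1L
  vy <- (kyr - 1L) %/% s + 1L
  xyid <- (vy - 1L) * nx + vx
  nxy <- nx * ny

  scatterAdd <- function(target, idx, val) {
    acc <- rowsum(val, idx)
    ii <- as.integer(rownames(acc))
    target[ii] <- target[ii] + acc[, 1]
    target
  }

  occ <- numeric(nxy * nz)
  ka <- floor(z0) + 1          # layer containing the entry point
  kb <- ceiling(z1)            # layer containing the exit point
  kb[kb < ka] <- ka[kb < ka]
  single <- ka == kb
  if (any(single))
    occ <- scatterAdd(occ, (ka[single] - 1) * nxy + xyid[single],
                      z1[single] - z0[single])
  multi <- !single
  if (any(multi)) {
    occ <- scatterAdd(occ, (ka[multi] - 1) * nxy + xyid[multi],
                      ka[multi] - z0[multi])
    occ <- scatterAdd(occ, (kb[multi] - 1) * nxy + xyid[multi],
                      z1[multi] - (kb[multi] - 1))
    # full interior layers via a difference array cumulated along z
    full <- multi & (kb - ka >= 2L)
    if (any(full)) {
      D <- numeric(nxy * (nz + 1L))
      D <- scatterAdd(D, ka[full] * nxy + xyid[full], rep(1, sum(full)))
      D <- scatterAdd(D, (kb[full] - 1L) * nxy + xyid[full], rep(-1, sum(full)))
      D <- matrix(D, nxy, nz + 1L)
      for (k in 2:nz) D[, k] <- D[, k] + D[, k - 1]
      occ <- occ + as.vector(D[, 1:nz])
    }
  }
  occ <- occ / (s * s)
  occ[occ > 1] <- 1  # guard against fp accumulation at exactly-full voxels
  array(occ, dims)
}

#' Resample a voxel grid by exact fractional overlap
#'
#' Volume-weighted (mean-preserving) resampling onto a coarser or finer
#' axis-aligned lattice covering the same physical extent, computed as a
#' separable product of 1-D interval-overlap matrices. Used to transfer a
#' VOI or image between the simulation grid and a scanner-like grid.
#'
#' @param x An [OccupancyGrid-class], [ActivityVolume-class] or [VOI-class].
#' @param spacing New isotropic voxel size in mm.
#' @return An object of the same class on the new lattice.
#' @export
resampleToGrid <- function(x, spacing) {
  oldsp <- x@spacing
  d <- dim(x@values)
  lo <- x@origin - oldsp / 2
  hi <- lo + oldsp * d
  ndim <- as.integer(ceiling((hi - lo) / spacing - 1e-9))
  ov <- function(ax) {
    n_new <- ndim[ax]
    starts_new <- lo[ax] + (seq_len(n_new) - 1) * spacing
    starts_old <- lo[ax] + (seq_len(d[ax]) - 1) * oldsp[ax]
    M <- matrix(0, n_new, d[ax])
    for (i in seq_len(n_new)) {
      o <- pmin(starts_new[i] + spacing, starts_old + oldsp[ax]) -
           pmax(starts_new[i], starts_old)
      M[i, ] <- pmax(o, 0) / spacing  # fraction of the new voxel covered
    }
    M
  }
  M1 <- ov(1); M2 <- ov(2); M3 <- ov(3)
  vals <- tensorApply(x@values, M1, M2, M3)
  # fraction of each new voxel covered by the old grid (edges may be partial)
  cover <- tensorApply(array(1, d), M1, M2, M3)
  vals <- ifelse(cover > 1e-12, vals / pmax(cover, 1e-12), 0)
  neworig <- lo + spacing / 2
  cls <- class(x)
  if (cls == "VOI")
    new("VOI", origin = neworig, spacing = rep(spacing, 3),
        values = pmin(pmax(vals, 0), 1), threshold = x@threshold)
  else
    new(cls, origin = neworig, spacing = rep(spacing, 3),
        values = pmin(pmax(vals, 0), if (cls == "OccupancyGrid") 1 else Inf))
}

# apply matrices along each dimension of a 3-D array: out = A1 x1 A2 x2 A3 x3 arr
tensorApply <- function(arr, M1, M2, M3) {
  d <- dim(arr)
  a <- M1 %*% matrix(arr, d[1], d[2] * d[3])          # (n1, d2*d3)
  n1 <- nrow(M1)
  a <- array(a, c(n1, d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- M2 %*% matrix(a, d[2], n1 * d[3])
  n2 <- nrow(M2)
  a <- array(a, c(n2, n1, d[3]))
  a <- aperm(a, c(3, 2, 1))                           # (d3, n1, n2)
  a <- M3 %*% matrix(a, d[3], n1 * n2)
  n3 <- nrow(M3)
  a <- array(a, c(n3, n1, n2))
  aperm(a, c(2, 3, 1))
}
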