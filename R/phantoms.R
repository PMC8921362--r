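#' Construct a phantom specification from a cavity mesh
#'
#' @param id Character identifier.
#' @param kind `"whole-parenchyma"`, `"cortex-only"` or `"ellipsoid"`.
#' @param mesh Cavity [TriangleMesh-class] (cm).
#' @param wallThickness Inactive wall thickness in mm (default 1.2, the
#'   printed phantom wall).
#' @return A [PhantomSpec-class] with fill volume, surface area and SA:V
#'   derived from the mesh.
#' @export
PhantomSpec <- function(id, kind, mesh, wallThickness = 1.2) {
  v <- enclosedVolume(mesh)
  a <- surfaceArea(mesh)
  new("PhantomSpec", id = id, kind = kind, mesh = mesh, fillVolume = v,
      surfaceArea = a, sav = a / v, wallThickness = wallThickness)
}

# ---- seeded shape ingredients -------------------------------------------

# smooth random direction field: sum of a few low-order polynomials in the
# direction cosines; zero-mean-ish, O(1) amplitude
randomLowOrderField <- function(ncomp = 6) {
  dirs <- matrix(stats::rnorm(3 * ncomp), ncomp, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pow <- sample(2:3, ncomp, replace = TRUE)
  coef <- stats::runif(ncomp, -1, 1)
  function(u) {
    s <- numeric(nrow(u))
    for (i in seq_len(ncomp)) s <- s + coef[i] * (u %*% dirs[i, ])^pow[i]
    as.vector(s)
  }
}

# mid-frequency lobulation field: sum of plane waves across the direction
# sphere; freq is the angular frequency (higher = finer lobes)
randomLobeField <- function(ncomp, freq) {
  dirs <- matrix(stats::rnorm(3 * ncomp), ncomp, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  phase <- stats::runif(ncomp, 0, 2 * pi)
  f <- freq * stats::runif(ncomp, 0.85, 1.15)
  function(u) {
    s <- numeric(nrow(u))
    for (i in seq_len(ncomp)) s <- s + sin(f[i] * (u %*% dirs[i, ]) + phase[i])
    as.vector(s / sqrt(ncomp / 2))   # ~ unit variance
  }
}

# kidney-like outer radius function (unit scale): flattened, elongated
# superellipsoid with a concave hilum indentation and seeded low-order
# perturbations
kidneyBaseRadius <- function() {
  pert <- randomLowOrderField(6)
  pamp <- stats::runif(1, 0.02, 0.05)
  hilumDir <- c(stats::runif(1, -0.25, 0.25), -1, stats::runif(1, -0.2, 0.2))
  hilumDir <- hilumDir / sqrt(sum(hilumDir^2))
  hdepth <- stats::runif(1, 0.18, 0.28)
  hwidth <- stats::runif(1, 0.45, 0.6)
  b <- stats::runif(1, 0.52, 0.60)    # width/length semi-axis ratio
  c <- stats::runif(1, 0.30, 0.38)    # thickness/length semi-axis ratio
  function(u) {
    r <- superellipsoidRadius(u, 1, b, c, e1 = 0.95, e2 = 0.85)
    ang <- acos(pmin(pmax(as.vector(u %*% hilumDir), -1), 1))
    r <- r * (1 - hdepth * exp(-0.5 * (ang / hwidth)^2))
    as.vector(r * (1 + pamp * pert(u)))
  }
}

# scale a mesh so its enclosed volume equals `target` exactly
scaleToVolume <- function(mesh, target) {
  scaleMesh(mesh, (target / enclosedVolume(mesh))^(1 / 3),
            center = meshCentroid(mesh))
}

# secant iteration on a scalar parameter until fn(p) is within tol of 0
secantSolve <- function(fn, p0, p1, tol, maxit = 10, lower = -Inf, upper = Inf) {
  f0 <- fn(p0); if (abs(f0) <= tol) return(p0)
  f1 <- fn(p1); if (abs(f1) <= tol) return(p1)
  for (i in seq_len(maxit)) {
    if (f1 == f0) break
    p2 <- min(max(p1 - f1 * (p1 - p0) / (f1 - f0), lower), upper)
    f2 <- fn(p2)
    if (abs(f2) <= tol) return(p2)
    p0 <- p1; f0 <- f1; p1 <- p2; f1 <- f2
  }
  p1
}

# ---- generators ----------------------------------------------------------

#' Generate a whole-parenchyma kidney-like phantom
#'
#' Seeded synthetic stand-in for a patient-derived whole-parenchyma
#' (medulla + cortex) cavity: a flattened, elongated superellipsoid with a
#' concave hilum, seeded low-order shape perturbations and a mid-frequency
#' surface undulation whose amplitude is solved so the smoothed, scaled
#' mesh hits the requested SA:V ratio. The same seed always yields a
#' byte-identical mesh.
#'
#' @param seed Integer seed.
#' @param targetVolume Fill volume in cm^3, within `[120, 220]`.
#' @param targetSav Target SA:V in cm^-1 (default drawn near the
#'   whole-parenchyma ratio 1.4-1.5); must lie in `[1.3, 1.6]`.
#' @param subdivisions Icosphere subdivision level of the mesh.
#' @return A [PhantomSpec-class] with `kind = "whole-parenchyma"`, volume
#'   equal to `targetVolume` (exact by construction) and SA:V within 0.02
#'   of the target.
#' @export
generateParenchyma <- function(seed, targetVolume, targetSav = NULL,
                               subdivisions = 4) {
  if (targetVolume < 120 || targetVolume > 220)
    stop("targetVolume must lie in [120, 220] cm^3 for whole-parenchyma phantoms")
  withLocalSeed(seed, {
    if (is.null(targetSav)) targetSav <- stats::runif(1, 1.38, 1.52)
    if (targetSav < 1.3 || targetSav > 1.6)
      stop("targetSav outside the whole-parenchyma range [1.3, 1.6] cm^-1")
    base <- kidneyBaseRadius()
    ripple <- randomLobeField(4, stats::runif(1, 7, 9))
    build <- function(alpha) {
      m <- radialMesh(function(u) pmax(base(u) * (1 + alpha * ripple(u)), 0.05),
                      subdivisions)
      m <- smoothMesh(m, 20)
      scaleToVolume(m, targetVolume)
    }
    alpha <- secantSolve(function(a) saToV(build(a)) - targetSav,
                         0.02, 0.1, tol = 0.015, lower = 0, upper = 0.35)
    m <- build(alpha)
    sav <- saToV(m)
    if (sav < 1.3 || sav > 1.6)
      stop(sprintf("could not reach SA:V %.2f (achieved %.2f, allowed [1.3, 1.6])",
                   targetSav, sav))
    PhantomSpec(sprintf("SynPar%d", seed), "whole-parenchyma", m)
  })
}

#' Generate a cortex-only kidney shell phantom
#'
#' Seeded synthetic stand-in for a cortex-only cavity: a single fillable
#' compartment bounded by a kidney-like outer surface and a lobed inner
#' core surface (emulating the medullary pyramids that make real cortex
#' cavities fine-structured). The inner core radius is
#' `beta * r_outer * (1 - lobes)`; the core scale is solved for the shell
#' volume and the lobe amplitude for the SA:V target.
#'
#' @param seed Integer seed.
#' @param targetVolume Shell fill volume in cm^3, within `[60, 170]`.
#' @param targetSav Target SA:V in cm^-1 (default drawn from the printed
#'   cortex range); must lie in `[2.3, 4.0]`.
#' @param subdivisions Icosphere subdivision level per boundary sheet.
#' @return A [PhantomSpec-class] with `kind = "cortex-only"`, a closed
#'   two-sheeted boundary mesh, exact target volume, SA:V within 0.05 of
#'   target and mean shell thickness >= 4 mm.
#' @export
generateCortex <- function(seed, targetVolume, targetSav = NULL,
                           subdivisions = 4) {
  if (targetVolume < 60 || targetVolume > 170)
    stop("targetVolume must lie in [60, 170] cm^3 for cortex-only phantoms")
  withLocalSeed(seed, {
    if (is.null(targetSav)) targetSav <- stats::runif(1, 2.7, 3.5)
    if (targetSav < 2.3 || targetSav > 4.0)
      stop("targetSav outside the cortex-only range [2.3, 4.0] cm^-1")
    base <- kidneyBaseRadius()
    lobes <- randomLobeField(6, stats::runif(1, 5, 7))
    aout <- stats::runif(1, 0.10, 0.16)   # outer lobulation amplitude
    ico <- icosphere(subdivisions, 1)
    u <- ico@vertices / sqrt(rowSums(ico@vertices^2))
    lob <- lobes(u)
    lob <- (lob - min(lob)) / (max(lob) - min(lob)) - 0.5   # centered [-0.5, 0.5]
    # the cortex cavity is a folded sheet: outer and inner surfaces share
    # the lobulation (the shell bends with the renal lobes) and the sheet
    # thickness fraction (1 - beta) sets SA:V ~ 2 / thickness
    rout_unit <- pmax(base(u), 0.05) * (1 + aout * lob)
    outer0 <- radialFromRadii(u, ico@faces, rout_unit)
    outerScale <- (2.2 * targetVolume / enclosedVolume(outer0))^(1 / 3)
    rout <- rout_unit * outerScale
    buildShell <- function(beta) {
      rin <- rout * pmax(min(beta, 0.975), 0.10)
      outer <- radialFromRadii(u, ico@faces, rout)
      inner <- reorientMesh(radialFromRadii(u, ico@faces, rin))
      shell <- TriangleMesh(rbind(outer@vertices, inner@vertices),
                            rbind(outer@faces, inner@faces + nrow(outer@vertices)),
                            validate = FALSE)
      scaleToVolume(smoothMesh(shell, 20), targetVolume)
    }
    beta <- secantSolve(function(b) saToV(buildShell(b)) - targetSav,
                        0.75, 0.88, tol = 0.03, maxit = 14,
                        lower = 0.40, upper = 0.965)
    m <- buildShell(beta)
    sav <- saToV(m)
    if (sav < 2.3 || sav > 4.0)
      stop(sprintf("could not reach SA:V %.2f (achieved %.2f, allowed [2.3, 4.0])",
                   targetSav, sav))
    th <- meanShellThickness(m)
    if (th < 0.4)
      stop(sprintf("mean shell thickness %.2f cm below the 4 mm minimum", th))
    PhantomSpec(sprintf("SynCor%d", seed), "cortex-only", m)
  })
}

# star-convex mesh from per-direction radii on a fixed icosphere topology
radialFromRadii <- function(u, faces, r) {
  TriangleMesh(u * r, faces, validate = FALSE)
}

# mean radial thickness of a two-sheeted shell mesh built from matched
# outer/inner radial sheets (first/second half of the vertices)
meanShellThickness <- function(mesh) {
  nv <- nrow(mesh@vertices) / 2
  ro <- sqrt(rowSums(mesh@vertices[seq_len(nv), , drop = FALSE]^2))
  ri <- sqrt(rowSums(mesh@vertices[nv + seq_len(nv), , drop = FALSE]^2))
  mean(ro - ri)
}

#' Generate a seeded cohort of digital kidney phantoms
#'
#' Emulates the published phantom set: whole-parenchyma and cortex-only
#' target volumes and SA:V ratios are drawn by seeded stratified jittering
#' across the printed ranges (volumes 152-188 and 70-162 cm^3, SA:V
#' 1.35-1.55 and 2.45-3.85 cm^-1), so that any cohort of the published
#' size spans the published envelope; the ellipsoidal reference phantom is
#' rebuilt from its printed volume (212.5 cm^3) and surface area
#' (180.2 cm^2) via [spheroidMatching()].
#'
#' @param nParenchyma Number of whole-parenchyma phantoms.
#' @param nCortex Number of cortex-only phantoms.
#' @param includeEllipsoid Append the matched spheroid reference phantom.
#' @param seed Integer cohort seed; per-phantom seeds are derived by fixed
#'   splitting, so cohorts are reproducible and extensible.
#' @return A list of [PhantomSpec-class] objects.
#' @examples
#' \donttest{
#' cohort <- generateCohort(2, 1, TRUE, seed = 7)
#' sapply(cohort, saToV)
#' }
#' @export
generateCohort <- function(nParenchyma = 10, nCortex = 9,
                           includeEllipsoid = TRUE, seed = 42) {
  if (nParenchyma < 0 || nCortex < 0) stop("cohort sizes must be >= 0")
  stratified <- function(n, lo, hi) {
    if (n == 0L) return(numeric(0))
    q <- (seq_len(n) - 0.5 + stats::runif(n, -0.3, 0.3)) / n
    x <- lo + q * (hi - lo)
    x[sample.int(n)]
  }
  draws <- withLocalSeed(seed, list(
    vp = stratified(nParenchyma, 152, 188),
    sp = stratified(nParenchyma, 1.35, 1.55),
    vc = stratified(nCortex, 70, 162),
    sc = stratified(nCortex, 2.45, 3.85)))
  cohort <- list()
  for (i in seq_len(nParenchyma)) {
    p <- generateParenchyma(childSeed(seed, i), draws$vp[i], draws$sp[i])
    p@id <- sprintf("SynPar%02d", i)
    cohort[[length(cohort) + 1L]] <- p
  }
  for (i in seq_len(nCortex)) {
    p <- generateCortex(childSeed(seed, 100 + i), draws$vc[i], draws$sc[i])
    p@id <- sprintf("SynCor%02d", i)
    cohort[[length(cohort) + 1L]] <- p
  }
  if (includeEllipsoid)
    cohort[[length(cohort) + 1L]] <- PhantomSpec("Ellipsoid", "ellipsoid",
                                                 spheroidMatching(212.5, 180.2))
  cohort
}

#' Summarize a phantom cohort
#'
#' @param cohort List of [PhantomSpec-class] objects.
#' @return A data frame with one row per phantom (id, kind, volume_cm3,
#'   surface_cm2, sav_cm1).
#' @export
cohortTable <- function(cohort) {
  data.frame(
    id = vapply(cohort, phantomId, character(1)),
    kind = vapply(cohort, phantomKind, character(1)),
    volume_cm3 = vapply(cohort, fillVolume, numeric(1)),
    surface_cm2 = vapply(cohort, function(p) p@surfaceArea, numeric(1)),
    sav_cm1 = vapply(cohort, saToV, numeric(1)),
    stringsAsFactors = FALSE)
}
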