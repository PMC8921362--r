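#' Closed oriented triangle surface of a phantom cavity
#'
#' A watertight, consistently outward-oriented triangle mesh with vertex
#' coordinates in cm. It is the source of the three geometric quantities
#' the surrogate model rests on: surface area (cm^2), enclosed volume
#' (cm^3) and their ratio SA:V (cm^-1).
#'
#' Structural validity (dimensions, index range, finiteness) is enforced on
#' every object; the more expensive watertightness, orientation and
#' degeneracy checks run in the constructor and in operations that require
#' them (see [assertClosedMesh()]).
#'
#' @slot vertices Numeric matrix, one row per vertex, columns x/y/z in cm.
#' @slot faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @seealso [TriangleMesh()], [surfaceArea()], [enclosedVolume()], [saToV()]
#' @aliases TriangleMesh-class
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be an n x 3 numeric matrix")
    if (!is.numeric(f) || ncol(f) != 3L) return("faces must be an m x 3 index matrix")
    if (nrow(f) < 4L) return("a closed surface needs at least 4 faces")
    if (anyNA(v) || any(!is.finite(v))) return("vertex coordinates must be finite")
    fi <- as.integer(f)
    if (any(fi < 1L) || any(fi > nrow(v))) return("face indices out of range")
    TRUE
  })

#' Regular voxel lattice (virtual base class)
#'
#' Physical lattice shared by occupancy grids, activity volumes and VOIs:
#' an `origin` (mm, position of the centre of voxel `[1,1,1]`), per-axis
#' `spacing` (mm) and a 3-D `values` array.
#'
#' @slot origin Numeric length-3, mm.
#' @slot spacing Numeric length-3, mm, all positive.
#' @slot values 3-D numeric array.
#' @aliases VoxelGrid-class
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric", values = "array", "VIRTUAL"),
  validity = function(object) {
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
    TRUE
  })

#' Fractional occupancy of a mesh on a voxel lattice
#'
#' Per-voxel fraction (in `[0,1]`) of the voxel volume lying inside the
#' cavity, obtained by supersampled ray casting; the occupancy-weighted
#' voxel volume sum approximates the enclosed volume.
#'
#' @aliases OccupancyGrid-class
#' @exportClass OccupancyGrid
setClass("OccupancyGrid", contains = "VoxelGrid",
  validity = function(object) {
    rng <- range(object@values)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("occupancy values must lie in [0,1]")
    TRUE
  })

#' Voxel map of activity concentration
#'
#' Quantitative image surrogate: per-voxel activity concentration in
#' kBq/ml on a physical lattice, padded well beyond the phantom so that
#' PSF blurring conserves total activity.
#'
#' @aliases ActivityVolume-class
#' @exportClass ActivityVolume
setClass("ActivityVolume", contains = "VoxelGrid",
  validity = function(object) {
    if (min(object@values) < -1e-9) return("activity concentrations must be non-negative")
    TRUE
  })

#' Volume of interest on a voxel lattice
#'
#' Per-voxel inclusion fraction in `[0,1]` together with the isocontour
#' threshold (as a fraction of the reference maximum) that produced it.
#'
#' @slot threshold Isocontour threshold as a fraction of the reference
#'   image maximum (NA for VOIs not produced by thresholding).
#' @aliases VOI-class
#' @exportClass VOI
setClass("VOI", contains = "VoxelGrid",
  representation(threshold = "numeric"),
  prototype(threshold = NA_real_),
  validity = function(object) {
    rng <- range(object@values)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) return("inclusion fractions must lie in [0,1]")
    TRUE
  })

#' Identity and geometry of one digital phantom
#'
#' Couples a cavity mesh with its derived fill volume, surface area and
#' SA:V ratio, the phantom type and the (inactive) wall thickness.
#'
#' @slot id Character identifier.
#' @slot kind One of `"whole-parenchyma"`, `"cortex-only"`, `"ellipsoid"`.
#' @slot mesh The cavity [TriangleMesh-class] (cm).
#' @slot fillVolume Fillable cavity volume, cm^3.
#' @slot surfaceArea Cavity surface area, cm^2.
#' @slot sav SA:V ratio, cm^-1.
#' @slot wallThickness Inactive wall thickness, mm (default 1.2).
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(id = "character", kind = "character", mesh = "TriangleMesh",
                 fillVolume = "numeric", surfaceArea = "numeric",
                 sav = "numeric", wallThickness = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("whole-parenchyma", "cortex-only", "ellipsoid"))
      return("kind must be whole-parenchyma, cortex-only or ellipsoid")
    if (object@wallThickness < 0) return("wallThickness must be >= 0")
    if (object@fillVolume <= 0) return("fillVolume must be positive")
    if (abs(object@sav - object@surfaceArea / object@fillVolume) > 1e-6 * object@sav)
      return("sav must equal surfaceArea / fillVolume")
    TRUE
  })

#' Acquisition and forward-model configuration
#'
#' Holds the point-spread-function FWHM, grid spacing, target and
#' background activity concentrations, the target-to-background-ratio
#' label, the cold-wall switch and the (optional, seeded) Poisson noise
#' surrogate for count statistics.
#'
#' @slot psfFwhm Net system resolution FWHM, mm.
#' @slot voxel Simulation voxel size, mm (isotropic).
#' @slot targetConc Cavity concentration, kBq/ml.
#' @slot backgroundConc Background concentration, kBq/ml (0 for the
#'   cold-background "infinity" TBR).
#' @slot tbrLabel One of `"infinity"`, `"10:1"`, `"5:1"`.
#' @slot wallEnabled Model the inactive 1.2 mm wall (displaces background).
#' @slot noiseEnabled Apply the Poisson count-noise surrogate.
#' @slot countsPerKbqMlVoxel Noise scale: expected counts per kBq/ml per voxel.
#' @slot seed Integer seed for the noise draw.
#' @aliases AcquisitionConfig-class
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(psfFwhm = "numeric", voxel = "numeric", targetConc = "numeric",
                 backgroundConc = "numeric", tbrLabel = "character",
                 wallEnabled = "logical", noiseEnabled = "logical",
                 countsPerKbqMlVoxel = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@psfFwhm < 0) return("psfFwhm must be >= 0")
    if (object@targetConc <= 0) return("targetConc must be > 0")
    if (object@backgroundConc < 0) return("backgroundConc must be >= 0")
    if (!object@tbrLabel %in% c("infinity", "10:1", "5:1"))
      return("tbrLabel must be one of infinity, 10:1, 5:1")
    if (object@tbrLabel == "infinity" && object@backgroundConc != 0)
      return("the infinity TBR requires a cold (zero) background")
    if (object@countsPerKbqMlVoxel <= 0) return("countsPerKbqMlVoxel must be > 0")
    TRUE
  })

#' Ordinary-least-squares fit of RC versus SA:V
#'
#' Slope (percent per cm^-1), intercept (percent), coefficient of
#' determination, residual standard deviation and the internal moments
#' (`meanX`, `sxx`) needed for Student-t prediction intervals.
#'
#' @slot slope,intercept,rSquared,residualSd Numeric scalars.
#' @slot n Number of points.
#' @slot meanX,sxx First and centred second moment of the predictor.
#' @aliases RegressionFit-class
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(slope = "numeric", intercept = "numeric", rSquared = "numeric",
                 residualSd = "numeric", n = "integer", meanX = "numeric",
                 sxx = "numeric"),
  validity = function(object) {
    if (object@n < 3L) return("a fit needs at least 3 points")
    if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
      return("rSquared must lie in [0,1]")
    TRUE
  })

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  cat(sprintf("  surface area %.2f cm^2, volume %.2f cm^3, SA:V %.3f cm^-1\n",
              surfaceArea(object), enclosedVolume(object), saToV(object)))
})

setMethod("show", "OccupancyGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("OccupancyGrid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  occupied volume %.2f ml\n", sum(object@values) * voxelVolumeMl(object)))
})

setMethod("show", "ActivityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ActivityVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  concentration range %.2f - %.2f kBq/ml, total activity %.1f kBq\n",
              min(object@values), max(object@values),
              sum(object@values) * voxelVolumeMl(object)))
})

setMethod("show", "VOI", function(object) {
  cat(sprintf("VOI: volume %.2f ml (threshold %.3f of reference max)\n",
              sum(object@values) * voxelVolumeMl(object), object@threshold))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s' (%s)\n", object@id, object@kind))
  cat(sprintf("  fill volume %.1f cm^3, surface %.1f cm^2, SA:V %.2f cm^-1, wall %.1f mm\n",
              object@fillVolume, object@surfaceArea, object@sav, object@wallThickness))
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf("AcquisitionConfig: TBR %s (target %.2f, background %.2f kBq/ml)\n",
              object@tbrLabel, object@targetConc, object@backgroundConc))
  cat(sprintf("  PSF FWHM %.1f mm, voxel %.1f mm, wall %s, noise %s\n",
              object@psfFwhm, object@voxel,
              if (object@wallEnabled) "on" else "off",
              if (object@noiseEnabled) "on" else "off"))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit (n = %d): RC [%%] = %.1f %+.1f * SA:V [cm^-1]\n",
              object@n, object@intercept, object@slope))
  cat(sprintf("  R^2 = %.3f, residual SD = %.2f %%\n",
              object@rSquared, object@residualSd))
})

# ---- accessors ----

#' Mesh accessors
#'
#' @param mesh A [TriangleMesh-class].
#' @return `meshVertices()` the n x 3 vertex matrix (cm); `meshFaces()`
#'   the m x 3 face index matrix.
#' @name meshAccessors
#' @aliases meshVertices meshFaces
NULL

#' @rdname meshAccessors
setMethod("meshVertices", "TriangleMesh", function(mesh) mesh@vertices)

#' @rdname meshAccessors
setMethod("meshFaces", "TriangleMesh", function(mesh) mesh@faces)

#' Voxel-grid accessors
#'
#' @param x A [VoxelGrid-class] derivative.
#' @return `gridValues()` the 3-D array; `gridSpacing()`/`gridOrigin()`
#'   mm vectors; `voxelVolumeMl()` the volume of one voxel in ml.
#' @name gridAccessors
#' @aliases gridValues gridSpacing gridOrigin voxelVolumeMl
NULL

#' @rdname gridAccessors
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname gridAccessors
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname gridAccessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)

#' @rdname gridAccessors
setMethod("voxelVolumeMl", "VoxelGrid", function(x) prod(x@spacing) / 1000)

#' Accessors for phantom specifications
#'
#' @param x A [PhantomSpec-class].
#' @return The corresponding slot value.
#' @name phantomAccessors
#' @export
phantomId <- function(x) x@id

#' @rdname phantomAccessors
#' @export
phantomKind <- function(x) x@kind

#' @rdname phantomAccessors
#' @export
phantomMesh <- function(x) x@mesh

#' @rdname phantomAccessors
#' @export
fillVolume <- function(x) x@fillVolume

#' @rdname phantomAccessors
#' @export
wallThickness <- function(x) x@wallThickness

#' @rdname phantomAccessors
#' @export
setMethod("saToV", "PhantomSpec", function(x, ...) x@sav)

#' Accessors for regression fits
#'
#' @param fit A [RegressionFit-class].
#' @return The corresponding component.
#' @name fitAccessors
#' @export
fitSlope <- function(fit) fit@slope

#' @rdname fitAccessors
#' @export
fitIntercept <- function(fit) fit@intercept

#' @rdname fitAccessors
#' @export
fitRSquared <- function(fit) fit@rSquared

#' @rdname fitAccessors
#' @export
fitResidualSd <- function(fit) fit@residualSd
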