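## Core S4 classes.
##
## Coordinate convention (used everywhere in the package):
##   - labels array is indexed [col, row, slice], 1-based;
##   - col index increases subject-left -> subject-right (x),
##   - row index increases anterior -> posterior (y),
##   - slice index increases caudal -> cranial (z);
##   - the physical centre of voxel (i, j) in-plane is
##     ((i - 0.5) * inPlaneSpacing, (j - 0.5) * inPlaneSpacing) mm.
## Slice ranges bounded by the pelvic floor and the diaphragm are inclusive
## on both ends (both boundary slices contribute).

.LABELS <- c(background = 0L, asat = 1L, other = 2L, outOfFov = 3L)

#' LabelVolume: a labeled axial voxel volume
#'
#' Container for a segmented abdominal volume. Voxels carry one of four
#' integer labels: 0 background (air), 1 abdominal subcutaneous adipose
#' tissue (ASAT), 2 other tissue (everything inside the abdominal wall),
#' 3 out-of-FOV (data lost to field-of-view truncation). Physical geometry
#' is carried as isotropic in-plane spacing and an effective slice spacing
#' (slice thickness plus gap; 10.5 mm by default throughout the package).
#'
#' @slot labels integer 3D array `[col, row, slice]` with values in 0:3.
#' @slot inPlaneSpacing numeric(1), mm per voxel in-plane (isotropic).
#' @slot sliceSpacing numeric(1), effective axial spacing in mm.
#' @export
setClass("LabelVolume",
  representation(
    labels = "array",
    inPlaneSpacing = "numeric",
    sliceSpacing = "numeric"
  )
)

setValidity("LabelVolume", function(object) {
  msgs <- character(0)
  d <- dim(object@labels)
  if (length(d) != 3L || any(d < 1L))
    msgs <- c(msgs, "labels must be a non-empty 3D array")
  if (!is.integer(object@labels))
    msgs <- c(msgs, "labels must be an integer array")
  else {
    bad <- setdiff(unique(as.vector(object@labels)), .LABELS)
    if (length(bad))
      msgs <- c(msgs, sprintf("unknown label value(s): %s",
                              paste(sort(bad), collapse = ", ")))
  }
  for (nm in c("inPlaneSpacing", "sliceSpacing")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("%s must be a single positive number", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabelVolume
#'
#' @param labels integer 3D array `[col, row, slice]`, values in 0:3.
#' @param inPlaneSpacing in-plane voxel spacing in mm.
#' @param sliceSpacing effective slice spacing in mm (default 10.5).
#' @return A validated [LabelVolume-class] object.
#' @examples
#' arr <- array(0L, dim = c(8, 8, 3))
#' arr[3:6, 3:6, ] <- 1L
#' LabelVolume(arr, inPlaneSpacing = 2)
#' @export
LabelVolume <- function(labels, inPlaneSpacing, sliceSpacing = 10.5) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels,
      inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing))
}

#' LandmarkSet: bilateral landmarks and axial bounds for one subject
#'
#' Holds the bilateral femoral-head (FH) centres and anterior superior
#' iliac spine (ASIS) points in voxel indices (col, row, slice; 1-based),
#' plus the diaphragm and pelvic-floor slice indices that bound the
#' reference volume. Landmarks are stored in voxel indices, not mm;
#' conversion to physical units happens inside the measurement code using
#' the volume's spacings.
#'
#' @slot fhLeft,fhRight,asisLeft,asisRight integer(3): (col, row, slice).
#' @slot diaphragmSlice,pelvicFloorSlice integer(1) slice indices.
#' @export
setClass("LandmarkSet",
  representation(
    fhLeft = "integer", fhRight = "integer",
    asisLeft = "integer", asisRight = "integer",
    diaphragmSlice = "integer", pelvicFloorSlice = "integer"
  )
)

setValidity("LandmarkSet", function(object) {
  msgs <- character(0)
  pts <- list(fhLeft = object@fhLeft, fhRight = object@fhRight,
              asisLeft = object@asisLeft, asisRight = object@asisRight)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (length(p) != 3L || anyNA(p) || any(p < 1L))
      msgs <- c(msgs, sprintf("%s must be three positive voxel indices (col, row, slice)", nm))
  }
  if (!length(msgs)) {
    if (object@fhLeft[3L] != object@fhRight[3L])
      msgs <- c(msgs, "femoral-head landmarks must share a slice")
    if (object@asisLeft[3L] != object@asisRight[3L])
      msgs <- c(msgs, "ASIS landmarks must share a slice")
    if (object@fhLeft[1L] >= object@fhRight[1L])
      msgs <- c(msgs, "fhLeft column must be strictly left of fhRight")
    if (object@asisLeft[1L] >= object@asisRight[1L])
      msgs <- c(msgs, "asisLeft column must be strictly left of asisRight")
  }
  if (length(object@pelvicFloorSlice) != 1L || length(object@diaphragmSlice) != 1L ||
      anyNA(c(object@pelvicFloorSlice, object@diaphragmSlice)))
    msgs <- c(msgs, "slice bounds must be single integers")
  else if (object@pelvicFloorSlice > object@diaphragmSlice)
    msgs <- c(msgs, "pelvicFloorSlice must be <= diaphragmSlice")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LandmarkSet
#'
#' @param fhLeft,fhRight,asisLeft,asisRight length-3 integer vectors
#'   (col, row, slice), 1-based voxel indices.
#' @param diaphragmSlice,pelvicFloorSlice slice indices bounding the
#'   reference volume (inclusive on both ends).
#' @return A validated [LandmarkSet-class].
#' @export
LandmarkSet <- function(fhLeft, fhRight, asisLeft, asisRight,
                        diaphragmSlice, pelvicFloorSlice) {
  new("LandmarkSet",
      fhLeft = as.integer(fhLeft), fhRight = as.integer(fhRight),
      asisLeft = as.integer(asisLeft), asisRight = as.integer(asisRight),
      diaphragmSlice = as.integer(diaphragmSlice),
      pelvicFloorSlice = as.integer(pelvicFloorSlice))
}

#' PhantomSpec: geometric recipe for one synthetic subject
#'
#' Describes an abdominal phantom as a stack of concentric-ellipse fat
#' rings: per slice, an outer ellipse (skin) and an inner ellipse (the
#' abdominal wall enclosing all non-subcutaneous tissue) whose centre is
#' displaced dorsally so the subcutaneous ring is ventrally thicker, as in
#' real abdomens. All lengths in mm. A zero-thickness ring (equal inner and
#' outer axes) is permitted and yields zero ASAT.
#'
#' @slot subjectId character(1).
#' @slot sex `"female"` or `"male"`.
#' @slot nSlices integer(1) number of axial slices.
#' @slot inPlaneSpacing,sliceSpacing numeric(1), mm.
#' @slot outerA,outerB,innerA,innerB numeric(nSlices): per-slice semi-axes
#'   (A lateral/x, B anteroposterior/y), mm.
#' @slot innerDorsalOffset numeric(nSlices): posterior displacement of the
#'   inner-ellipse centre, mm.
#' @slot asisSlice,fhSlice,diaphragmSlice,pelvicFloorSlice integer(1).
#' @export
setClass("PhantomSpec",
  representation(
    subjectId = "character", sex = "character",
    nSlices = "integer", inPlaneSpacing = "numeric", sliceSpacing = "numeric",
    outerA = "numeric", outerB = "numeric",
    innerA = "numeric", innerB = "numeric",
    innerDorsalOffset = "numeric",
    asisSlice = "integer", fhSlice = "integer",
    diaphragmSlice = "integer", pelvicFloorSlice = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character(0)
  n <- object@nSlices
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("nSlices must be a positive integer")
  if (!object@sex %in% c("female", "male"))
    msgs <- c(msgs, "sex must be 'female' or 'male'")
  for (nm in c("outerA", "outerB", "innerA", "innerB", "innerDorsalOffset")) {
    v <- slot(object, nm)
    if (length(v) != n || anyNA(v))
      msgs <- c(msgs, sprintf("%s must have one finite value per slice", nm))
  }
  if (!length(msgs)) {
    if (any(object@innerA <= 0) || any(object@innerB <= 0) ||
        any(object@outerA <= 0) || any(object@outerB <= 0))
      msgs <- c(msgs, "semi-axes must be positive on every slice")
    if (any(object@innerA > object@outerA) || any(object@innerB > object@outerB))
      msgs <- c(msgs, "inner semi-axes must not exceed outer semi-axes (inverted ring)")
    if (any(object@innerDorsalOffset < 0))
      msgs <- c(msgs, "innerDorsalOffset must be >= 0")
  }
  lms <- c(pelvicFloor = object@pelvicFloorSlice, fh = object@fhSlice,
           asis = object@asisSlice, diaphragm = object@diaphragmSlice)
  if (any(lms < 1L) || any(lms > n))
    msgs <- c(msgs, "all landmark slices must lie within [1, nSlices]")
  if (!(object@pelvicFloorSlice <= object@fhSlice &&
        object@fhSlice <= object@asisSlice &&
        object@asisSlice <= object@diaphragmSlice))
    msgs <- c(msgs, "require pelvicFloorSlice <= fhSlice <= asisSlice <= diaphragmSlice")
  for (nm in c("inPlaneSpacing", "sliceSpacing")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("%s must be a single positive number", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomSpec
#'
#' Scalar semi-axis arguments are recycled across slices (a constant
#' profile), which is the common case in oracle tests.
#'
#' @param subjectId subject identifier.
#' @param sex `"female"` or `"male"`.
#' @param nSlices number of axial slices.
#' @param outerA,outerB,innerA,innerB semi-axes in mm, scalar or
#'   length-`nSlices`.
#' @param innerDorsalOffset dorsal displacement of the inner centre in mm,
#'   scalar or per-slice.
#' @param asisSlice,fhSlice,diaphragmSlice,pelvicFloorSlice landmark slice
#'   indices; defaults span slice 2 to `nSlices - 1`.
#' @param inPlaneSpacing,sliceSpacing voxel spacings in mm.
#' @return A validated [PhantomSpec-class].
#' @examples
#' PhantomSpec("P1", "female", nSlices = 45, outerA = 170, outerB = 130,
#'             innerA = 135, innerB = 95, innerDorsalOffset = 10)
#' @export
PhantomSpec <- function(subjectId, sex, nSlices,
                        outerA, outerB, innerA, innerB,
                        innerDorsalOffset = 0,
                        pelvicFloorSlice = 2L,
                        fhSlice = max(2L, round(nSlices * 0.25)),
                        asisSlice = max(2L, round(nSlices * 0.5)),
                        diaphragmSlice = nSlices - 1L,
                        inPlaneSpacing = 2, sliceSpacing = 10.5) {
  n <- as.integer(nSlices)
  rec <- function(v) if (length(v) == 1L) rep(as.numeric(v), n) else as.numeric(v)
  new("PhantomSpec",
      subjectId = as.character(subjectId), sex = as.character(sex),
      nSlices = n,
      inPlaneSpacing = as.numeric(inPlaneSpacing),
      sliceSpacing = as.numeric(sliceSpacing),
      outerA = rec(outerA), outerB = rec(outerB),
      innerA = rec(innerA), innerB = rec(innerB),
      innerDorsalOffset = rec(innerDorsalOffset),
      asisSlice = as.integer(asisSlice), fhSlice = as.integer(fhSlice),
      diaphragmSlice = as.integer(diaphragmSlice),
      pelvicFloorSlice = as.integer(pelvicFloorSlice))
}

#' CohortSpec: statistical description of a synthetic cohort
#'
#' Defaults emulate an overweight/obese study population of 193 subjects
#' (116 female, 77 male) whose BMI follows a Gaussian 32.1 +/- 3.7 kg/m^2
#' truncated to the observed range 24.8-41.2 kg/m^2. BMI acts purely as a
#' latent size score driving frame size and fat-ring thickness;
#' `profileHeterogeneity` scales per-subject random axial and ventral
#' modulation of the ring, which is what makes single-slice surrogates
#' weaker predictors of total volume than partial volumes.
#'
#' @slot nFemale,nMale integer counts.
#' @slot bmiMean,bmiSd numeric, kg/m^2.
#' @slot bmiRange numeric(2), kg/m^2, ordered.
#' @slot profileHeterogeneity numeric(1) >= 0, dimensionless.
#' @slot seed integer(1) RNG seed.
#' @export
setClass("CohortSpec",
  representation(
    nFemale = "integer", nMale = "integer",
    bmiMean = "numeric", bmiSd = "numeric", bmiRange = "numeric",
    profileHeterogeneity = "numeric", seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  if (object@nFemale < 0L || object@nMale < 0L)
    msgs <- c(msgs, "subject counts must be >= 0")
  if (!is.finite(object@bmiSd) || object@bmiSd <= 0)
    msgs <- c(msgs, "bmiSd must be > 0")
  if (length(object@bmiRange) != 2L || diff(object@bmiRange) < 0)
    msgs <- c(msgs, "bmiRange must be an ordered pair")
  if (object@profileHeterogeneity < 0)
    msgs <- c(msgs, "profileHeterogeneity must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortSpec
#'
#' @param nFemale,nMale subject counts (defaults 116 and 77).
#' @param bmiMean,bmiSd BMI Gaussian parameters in kg/m^2.
#' @param bmiRange truncation range for the BMI draw, kg/m^2.
#' @param profileHeterogeneity >= 0; strength of per-subject random axial
#'   and ventral ring modulation (0 = every subject a clean scaled ring).
#' @param seed RNG seed; the cohort is a pure function of this spec.
#' @return A validated [CohortSpec-class].
#' @export
CohortSpec <- function(nFemale = 116L, nMale = 77L,
                       bmiMean = 32.1, bmiSd = 3.7,
                       bmiRange = c(24.8, 41.2),
                       profileHeterogeneity = 0.35,
                       seed = 1L) {
  new("CohortSpec",
      nFemale = as.integer(nFemale), nMale = as.integer(nMale),
      bmiMean = as.numeric(bmiMean), bmiSd = as.numeric(bmiSd),
      bmiRange = as.numeric(bmiRange),
      profileHeterogeneity = as.numeric(profileHeterogeneity),
      seed = as.integer(seed))
}

#' PhantomGroundTruth: analytic truth for one phantom
#'
#' Closed-form per-slice ring areas and the exact reference ASAT volume of
#' a phantom, used as the oracle against voxel-counted measurements.
#'
#' @slot perSliceRingArea numeric(nSlices), cm^2.
#' @slot trueVasat numeric(1), litres; the analytic ring areas integrated
#'   over the inclusive pelvic-floor..diaphragm slice range.
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomGroundTruth",
  representation(
    perSliceRingArea = "numeric",
    trueVasat = "numeric",
    spec = "PhantomSpec"
  )
)

setValidity("PhantomGroundTruth", function(object) {
  msgs <- character(0)
  sp <- object@spec
  if (length(object@perSliceRingArea) != sp@nSlices)
    msgs <- c(msgs, "perSliceRingArea must have one value per slice")
  if (any(object@perSliceRingArea < 0))
    msgs <- c(msgs, "ring areas must be >= 0")
  rng <- sp@pelvicFloorSlice:sp@diaphragmSlice
  expect <- sum(object@perSliceRingArea[rng]) * sp@sliceSpacing / 10 / 1000
  if (!isTRUE(all.equal(expect, object@trueVasat, tolerance = 1e-8)))
    msgs <- c(msgs, "trueVasat inconsistent with per-slice areas and spacing")
  if (length(msgs)) msgs else TRUE
})
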