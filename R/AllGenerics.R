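## Accessors and show methods.

#' @rdname LabelVolume-class
#' @param object,x a `LabelVolume`
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname LabelVolume-class
#' @export
setGeneric("inPlaneSpacing", function(x) standardGeneric("inPlaneSpacing"))

#' @rdname LabelVolume-class
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' @rdname PhantomGroundTruth-class
#' @param x a `PhantomGroundTruth`
#' @export
setGeneric("trueVasat", function(x) standardGeneric("trueVasat"))

#' @rdname PhantomGroundTruth-class
#' @export
setGeneric("perSliceRingArea", function(x) standardGeneric("perSliceRingArea"))

#' @rdname LabelVolume-class
#' @export
setMethod("labelArray", "LabelVolume", function(x) x@labels)

#' @rdname LabelVolume-class
#' @export
setMethod("inPlaneSpacing", "LabelVolume", function(x) x@inPlaneSpacing)

#' @rdname LabelVolume-class
#' @export
setMethod("sliceSpacing", "LabelVolume", function(x) x@sliceSpacing)

#' @rdname PhantomGroundTruth-class
#' @export
setMethod("trueVasat", "PhantomGroundTruth", function(x) x@trueVasat)

#' @rdname PhantomGroundTruth-class
#' @export
setMethod("perSliceRingArea", "PhantomGroundTruth", function(x) x@perSliceRingArea)

#' @rdname LabelVolume-class
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  counts <- tabulate(as.vector(object@labels) + 1L, nbins = 4L)
  cat(sprintf("LabelVolume: %d x %d x %d voxels (%g mm in-plane, %g mm slices)\n",
              d[1], d[2], d[3], object@inPlaneSpacing, object@sliceSpacing))
  cat(sprintf("  labels: background %d | ASAT %d | other %d | out-of-FOV %d\n",
              counts[1], counts[2], counts[3], counts[4]))
})

setMethod("show", "LandmarkSet", function(object) {
  fmt <- function(p) sprintf("(%d, %d, %d)", p[1], p[2], p[3])
  cat("LandmarkSet (col, row, slice):\n")
  cat("  FH   L", fmt(object@fhLeft),   " R", fmt(object@fhRight), "\n")
  cat("  ASIS L", fmt(object@asisLeft), " R", fmt(object@asisRight), "\n")
  cat(sprintf("  slices: pelvic floor %d .. diaphragm %d (inclusive)\n",
              object@pelvicFloorSlice, object@diaphragmSlice))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s' (%s): %d slices @ %g/%g mm\n",
              object@subjectId, object@sex, object@nSlices,
              object@inPlaneSpacing, object@sliceSpacing))
  cat(sprintf("  outer semi-axes %.0f-%.0f x %.0f-%.0f mm; ring %0.f-%.0f mm lateral\n",
              min(object@outerA), max(object@outerA),
              min(object@outerB), max(object@outerB),
              min(object@outerA - object@innerA), max(object@outerA - object@innerA)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d female + %d male, BMI %g +/- %g in [%g, %g] kg/m^2\n",
              object@nFemale, object@nMale, object@bmiMean, object@bmiSd,
              object@bmiRange[1], object@bmiRange[2]))
  cat(sprintf("  profile heterogeneity %g, seed %d\n",
              object@profileHeterogeneity, object@seed))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf("PhantomGroundTruth '%s': V_ASAT = %.3f L over slices %d..%d\n",
              object@spec@subjectId, object@trueVasat,
              object@spec@pelvicFloorSlice, object@spec@diaphragmSlice))
})
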