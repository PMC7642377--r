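## Synthetic abdominal phantoms: dorsally-offset concentric-ellipse fat
## rings with analytic ground truth, plus the field-of-view truncation
## operator. The phantom family is an explicit geometric stand-in that
## exercises every measurement operator with closed-form oracles; it makes
## no claim of anatomical realism beyond the ventrally-thicker ring.

#' Analytic area of a concentric-ellipse ring
#'
#' Area between an outer ellipse with semi-axes (`aOut`, `bOut`) and an
#' inner ellipse with semi-axes (`aIn`, `bIn`) lying fully inside it:
#' `pi * (aOut*bOut - aIn*bIn)`, converted from mm^2 to cm^2. The area is
#' independent of any offset of the inner centre, so it is also the
#' ground-truth ring area of the dorsally-offset phantoms. Equal inner and
#' outer axes (zero-thickness ring) give 0.
#'
#' @param aOut,bOut outer semi-axes, mm.
#' @param aIn,bIn inner semi-axes, mm.
#' @return Ring area in cm^2 (vectorised over slices).
#' @examples
#' analyticRingArea(180, 130, 150, 100)  # 263.89 cm^2
#' @export
analyticRingArea <- function(aOut, bOut, aIn, bIn) {
  if (any(c(aOut, bOut, aIn, bIn) <= 0))
    invalidGeometryError("semi-axes must be positive")
  if (any(aIn > aOut) || any(bIn > bOut))
    invalidGeometryError("inner semi-axes exceed outer semi-axes (inverted ring)")
  pi * (aOut * bOut - aIn * bIn) / 100
}

## In-plane voxel-centre coordinates of a grid, relative to an origin (mm)
.voxelCentres <- function(n, spacing) (seq_len(n) - 0.5) * spacing

## mm coordinate -> voxel index (centre convention)
.toVoxel <- function(coord, spacing) as.integer(round(coord / spacing + 0.5))

#' Render a phantom subject from its geometric spec
#'
#' Builds the labeled volume, the deterministic landmark set and the
#' analytic ground truth for one [PhantomSpec-class]. A voxel (by its
#' centre) is labeled ASAT iff it lies inside the outer ellipse and outside
#' the inner ellipse of its slice; inside the inner ellipse it is labeled
#' other tissue; elsewhere background. The inner-ellipse centre is displaced
#' posteriorly by `innerDorsalOffset`, making the ring ventrally thicker.
#'
#' Landmark placement is a fixed rule of the phantom family: the ASIS
#' points sit on the inner boundary of the ASIS slice at 45 degrees
#' anterolateral; the femoral-head centres sit at +/- 0.6 * innerA
#' laterally and 0.15 * innerB posterior of the inner centre on the FH
#' slice.
#'
#' @param spec a [PhantomSpec-class].
#' @param gridDim optional integer(2) (nCol, nRow) forcing the in-plane
#'   grid size; an ellipse exceeding it raises a geometry-overflow error.
#' @param marginMM margin added around the widest ellipse when the grid is
#'   auto-sized (default 10 mm).
#' @return A list with elements `volume` ([LabelVolume-class]),
#'   `landmarks` ([LandmarkSet-class]) and `groundTruth`
#'   ([PhantomGroundTruth-class]).
#' @export
makePhantom <- function(spec, gridDim = NULL, marginMM = 10) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  sp <- spec@inPlaneSpacing
  n <- spec@nSlices

  ## containment: inner boundary (offset posteriorly) must stay inside outer
  th <- seq(0, 2 * pi, length.out = 73L)[-73L]
  for (s in seq_len(n)) {
    bx <- spec@innerA[s] * cos(th)
    by <- spec@innerB[s] * sin(th) + spec@innerDorsalOffset[s]
    if (any((bx / spec@outerA[s])^2 + (by / spec@outerB[s])^2 > 1 + 1e-9))
      invalidGeometryError(
        "inner ellipse (with dorsal offset) not contained in outer ellipse on slice %d", s)
  }

  halfW <- max(spec@outerA)
  halfH <- max(spec@outerB, spec@innerB + spec@innerDorsalOffset)
  if (is.null(gridDim)) {
    nx <- ceiling(2 * (halfW + marginMM) / sp)
    ny <- ceiling(2 * (halfH + marginMM) / sp)
  } else {
    nx <- as.integer(gridDim[1]); ny <- as.integer(gridDim[2])
    if (nx * sp < 2 * halfW || ny * sp < 2 * halfH)
      geometryOverflowError(
        "ellipse extent (%.1f x %.1f mm) exceeds grid (%.1f x %.1f mm)",
        2 * halfW, 2 * halfH, nx * sp, ny * sp)
  }
  cx <- nx * sp / 2
  cy <- ny * sp / 2

  xs <- .voxelCentres(nx, sp) - cx          # lateral, subject-left negative
  ys <- .voxelCentres(ny, sp) - cy          # anteroposterior, anterior negative
  labels <- array(0L, dim = c(nx, ny, n))
  for (s in seq_len(n)) {
    fOut <- outer((xs / spec@outerA[s])^2, (ys / spec@outerB[s])^2, "+")
    fIn <- outer((xs / spec@innerA[s])^2,
                 ((ys - spec@innerDorsalOffset[s]) / spec@innerB[s])^2, "+")
    sl <- matrix(0L, nx, ny)
    sl[fOut <= 1] <- 1L
    sl[fIn <= 1] <- 2L
    labels[, , s] <- sl
  }
  volume <- LabelVolume(labels, inPlaneSpacing = sp,
                        sliceSpacing = spec@sliceSpacing)

  ## deterministic landmarks
  sA <- spec@asisSlice
  asisY <- cy + spec@innerDorsalOffset[sA] - spec@innerB[sA] / sqrt(2)
  asisX <- spec@innerA[sA] / sqrt(2)
  sF <- spec@fhSlice
  fhY <- cy + spec@innerDorsalOffset[sF] + 0.15 * spec@innerB[sF]
  fhX <- 0.6 * spec@innerA[sF]
  landmarks <- LandmarkSet(
    fhLeft   = c(.toVoxel(cx - fhX, sp), .toVoxel(fhY, sp), sF),
    fhRight  = c(.toVoxel(cx + fhX, sp), .toVoxel(fhY, sp), sF),
    asisLeft = c(.toVoxel(cx - asisX, sp), .toVoxel(asisY, sp), sA),
    asisRight = c(.toVoxel(cx + asisX, sp), .toVoxel(asisY, sp), sA),
    diaphragmSlice = spec@diaphragmSlice,
    pelvicFloorSlice = spec@pelvicFloorSlice)

  areas <- analyticRingArea(spec@outerA, spec@outerB, spec@innerA, spec@innerB)
  rng <- spec@pelvicFloorSlice:spec@diaphragmSlice
  gt <- new("PhantomGroundTruth",
            perSliceRingArea = areas,
            trueVasat = sum(areas[rng]) * spec@sliceSpacing / 10 / 1000,
            spec = spec)

  list(volume = volume, landmarks = landmarks, groundTruth = gt)
}

#' Apply field-of-view truncation to a labeled volume
#'
#' Emulates the restricted imaging FOV of large subjects: tissue voxels
#' (labels 1 and 2) whose in-plane position falls outside a centred
#' left-right band of width `fovWidth`, or outside an elliptical FOV whose
#' centre sits in the dorsal quarter of the grid (so that ventrolateral
#' corners are clipped first, where truncation occurs in practice), are
#' relabeled out-of-FOV (label 3). Background is left untouched, voxels are
#' never moved, added or removed, and the operator is idempotent.
#'
#' @param volume a [LabelVolume-class].
#' @param fovWidth width of the preserved left-right band, mm.
#' @return A [LabelVolume-class] with the same grid and spacings.
#' @export
applyFovTruncation <- function(volume, fovWidth) {
  stopifnot(is(volume, "LabelVolume"))
  if (!is.finite(fovWidth) || fovWidth <= 0)
    validationError("fovWidth must be a positive width in mm")
  sp <- volume@inPlaneSpacing
  d <- dim(volume@labels)
  nx <- d[1]; ny <- d[2]
  H <- ny * sp
  xs <- .voxelCentres(nx, sp) - nx * sp / 2
  ys <- .voxelCentres(ny, sp) - H / 2
  ## elliptical FOV: centre displaced dorsally by H/4, semi-axes
  ## (fovWidth/2, 0.75 H); the band |x| <= fovWidth/2 is implied laterally
  ## but kept explicit.
  inFov <- outer((xs / (fovWidth / 2))^2, ((ys - H / 4) / (0.75 * H))^2, "+") <= 1 &
    matrix(abs(xs) <= fovWidth / 2, nx, ny)
  labels <- volume@labels
  tissue <- labels == 1L | labels == 2L
  out <- tissue & !as.vector(inFov)    # recycles the in-plane mask over slices
  labels[out] <- 3L
  LabelVolume(labels, inPlaneSpacing = sp, sliceSpacing = volume@sliceSpacing)
}
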