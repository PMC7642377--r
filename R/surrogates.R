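## The reference ASAT volume and the six surrogate measures.
##
## All six surrogates are designed to be computable on FOV-truncated data
## as long as the truncation stays clear of their measurement region: the
## two thickness measures use narrow bands on the ASIS slice, the partial
## areas/volumes use a dorsal rectangular box anchored on the bilateral
## landmarks. The reference volume, by contrast, is undefined as soon as
## any out-of-FOV voxel appears in the diaphragm..pelvic-floor range
## (mirroring the exclusion of subjects with visibly missing tissue).

.sliceAreaCm2 <- function(count, inPlaneSpacing) count * inPlaneSpacing^2 / 100

## shared volume arithmetic: identical code path for reference and partial
## volumes so the whole-grid box reproduces the reference bit-for-bit
.boxVolumeL <- function(volume, landmarks, cols, rows, errorFun, what) {
  lab <- volume@labels
  slices <- landmarks@pelvicFloorSlice:landmarks@diaphragmSlice
  areas <- vapply(slices, function(s) {
    sub <- lab[cols[1]:cols[2], rows[1]:rows[2], s]
    if (any(sub == 3L))
      errorFun("out-of-FOV voxels intersect the %s region on slice %d", what, s)
    .sliceAreaCm2(sum(sub == 1L), volume@inPlaneSpacing)
  }, numeric(1))
  sum(areas) * volume@sliceSpacing / 10 / 1000
}

#' Reference ASAT volume from full segmentation
#'
#' Sums the segmented ASAT area of every slice between pelvic floor and
#' diaphragm (inclusive on both ends) times the effective slice spacing.
#' Any out-of-FOV voxel in that range makes the reference undefined and
#' raises a truncated-reference condition: a truncated subject has no
#' ground-truth volume.
#'
#' @param volume a [LabelVolume-class].
#' @param landmarks a [LandmarkSet-class] providing the slice bounds.
#' @return Reference ASAT volume in litres.
#' @export
measureReferenceVolume <- function(volume, landmarks) {
  stopifnot(is(volume, "LabelVolume"), is(landmarks, "LandmarkSet"))
  .checkLandmarksInGrid(landmarks, volume)
  d <- dim(volume@labels)
  .boxVolumeL(volume, landmarks, cols = c(1L, d[1]), rows = c(1L, d[2]),
              errorFun = truncatedReferenceError, what = "reference-volume")
}

## midline column (mm) = centroid of non-background voxels on a slice
.bodyMidlineMM <- function(sliceLab, inPlaneSpacing) {
  body <- sliceLab != 0L & sliceLab != 3L
  counts <- rowSums(body)
  if (!sum(counts)) validationError("no tissue on slice; cannot locate midline")
  xs <- .voxelCentres(nrow(sliceLab), inPlaneSpacing)
  sum(xs * counts) / sum(counts)
}

## length (voxels) of the most anterior contiguous ASAT run in a column,
## i.e. the run that terminates at the skin surface
.anteriorAsatRun <- function(colVals) {
  r <- rle(colVals)
  tissue <- which(r$values != 0L)
  if (!length(tissue)) return(0L)
  first <- tissue[1L]
  if (r$values[first] == 1L) r$lengths[first] else 0L
}

#' Abdominal wall fat thickness (AWF) at the ASIS level
#'
#' On the ASIS slice, for every column whose lateral distance from the
#' body midline lies in (2, 30] mm (the paramedian band), the contiguous
#' ASAT run that ends at the skin surface is measured along the anterior
#' direction; the maximum run length times the in-plane spacing is
#' returned, in mm. The midline is the centroid column of all
#' non-background voxels on the slice.
#'
#' @inheritParams measureReferenceVolume
#' @return AWF thickness in mm; 0 with a warning if the band holds no ASAT.
#' @export
measureAwf <- function(volume, landmarks) {
  stopifnot(is(volume, "LabelVolume"), is(landmarks, "LandmarkSet"))
  .checkLandmarksInGrid(landmarks, volume)
  sp <- volume@inPlaneSpacing
  s <- landmarks@asisLeft[3L]
  sl <- volume@labels[, , s]
  mid <- .bodyMidlineMM(sl, sp)
  xs <- .voxelCentres(nrow(sl), sp)
  band <- which(abs(xs - mid) > 2 & abs(xs - mid) <= 30)
  if (!length(band)) validationError("paramedian band holds no columns at %g mm spacing", sp)
  if (any(sl[band, ] == 3L))
    truncationAffectsMeasureError("out-of-FOV voxels intersect the AWF paramedian band")
  runs <- vapply(band, function(i) .anteriorAsatRun(sl[i, ]), integer(1))
  best <- max(runs)
  if (best == 0L) {
    warning("no ASAT in the AWF paramedian band; returning 0 mm")
    return(0)
  }
  best * sp
}

## maximal contiguous ASAT run (voxels) within a lateral span
.maxAsatRun <- function(vals) {
  r <- rle(vals)
  hit <- r$lengths[r$values == 1L]
  if (length(hit)) max(hit) else 0L
}

#' Hip girdle fat thickness (HGF) at the ASIS level
#'
#' On the ASIS slice the lateral tangent of each side is approximated by
#' the vertical line through the most lateral inner-tissue (non-ASAT)
#' voxel. For every row within +/- 30 mm of the ASIS row, the contiguous
#' ASAT run between that tangent and the skin is measured horizontally;
#' the maximum run over both sides times the in-plane spacing is returned,
#' in mm.
#'
#' @inheritParams measureReferenceVolume
#' @return HGF thickness in mm; 0 with a warning if the bands hold no ASAT.
#' @export
measureHgf <- function(volume, landmarks) {
  stopifnot(is(volume, "LabelVolume"), is(landmarks, "LandmarkSet"))
  .checkLandmarksInGrid(landmarks, volume)
  sp <- volume@inPlaneSpacing
  s <- landmarks@asisLeft[3L]
  sl <- volume@labels[, , s]
  innerCols <- which(apply(sl == 2L, 1L, any))
  if (!length(innerCols))
    validationError("no inner tissue on the ASIS slice; HGF tangent undefined")
  ys <- .voxelCentres(ncol(sl), sp)
  asisRow <- round(mean(c(landmarks@asisLeft[2L], landmarks@asisRight[2L])))
  rows <- which(abs(ys - ys[asisRow]) <= 30)
  tanL <- min(innerCols)
  tanR <- max(innerCols)
  spanL <- sl[tanL:1, rows, drop = FALSE]          # marching laterally leftwards
  spanR <- sl[tanR:nrow(sl), rows, drop = FALSE]   # and rightwards
  if (any(spanL == 3L) || any(spanR == 3L))
    truncationAffectsMeasureError("out-of-FOV voxels intersect the HGF lateral bands")
  best <- max(c(apply(spanL, 2L, .maxAsatRun), apply(spanR, 2L, .maxAsatRun)))
  if (best == 0L) {
    warning("no ASAT in the HGF lateral bands; returning 0 mm")
    return(0)
  }
  best * sp
}

#' Landmark-bounded measurement box
#'
#' The axial rectangle used for partial areas and volumes: lateral edges
#' at the two landmark columns (inclusive), anterior edge at the rounded
#' mean of the two landmark rows, posterior edge at the grid boundary. The
#' same rectangle is reused on every slice (a dorsal prism).
#'
#' @param landmarks a [LandmarkSet-class].
#' @param mode `"FH"` or `"ASIS"`: which landmark pair anchors the box.
#' @param volume the [LabelVolume-class] the box will be applied to
#'   (provides the posterior boundary).
#' @return A list with `cols = c(left, right)`, `rows = c(anterior,
#'   posterior)` and `slice` (the landmark pair's own slice).
#' @export
landmarkBox <- function(landmarks, mode = c("FH", "ASIS"), volume) {
  mode <- match.arg(mode)
  stopifnot(is(landmarks, "LandmarkSet"), is(volume, "LabelVolume"))
  .checkLandmarksInGrid(landmarks, volume)
  p1 <- if (mode == "FH") landmarks@fhLeft else landmarks@asisLeft
  p2 <- if (mode == "FH") landmarks@fhRight else landmarks@asisRight
  if (p1[1L] >= p2[1L])
    invalidGeometryError("degenerate %s box: left column %d >= right column %d",
                         mode, p1[1L], p2[1L])
  anterior <- as.integer(round(mean(c(p1[2L], p2[2L]))))
  list(cols = c(p1[1L], p2[1L]),
       rows = c(anterior, dim(volume@labels)[2L]),
       slice = p1[3L])
}

#' Partial ASAT area within the landmark box on one slice
#'
#' ASAT voxel count inside the [landmarkBox()] on the given slice, times
#' the squared in-plane spacing, in cm^2. By default the area is taken at
#' the landmark pair's own slice (the single-slice surrogates A_p-FH and
#' A_p-ASIS).
#'
#' @inheritParams landmarkBox
#' @param sliceIndex slice to measure; defaults to the landmark's slice.
#' @return Partial ASAT area in cm^2.
#' @export
measurePartialArea <- function(volume, landmarks, mode = c("FH", "ASIS"),
                               sliceIndex = NULL) {
  mode <- match.arg(mode)
  box <- landmarkBox(landmarks, mode, volume)
  s <- if (is.null(sliceIndex)) box$slice else as.integer(sliceIndex)
  d <- dim(volume@labels)
  if (s < 1L || s > d[3L])
    validationError("slice %d outside grid with %d slices", s, d[3L])
  sub <- volume@labels[box$cols[1]:box$cols[2], box$rows[1]:box$rows[2], s]
  if (any(sub == 3L))
    truncationAffectsMeasureError(
      "out-of-FOV voxels inside the %s box on slice %d", mode, s)
  .sliceAreaCm2(sum(sub == 1L), volume@inPlaneSpacing)
}

#' Partial ASAT volume within the landmark box
#'
#' Sums the in-box partial ASAT area of every slice between pelvic floor
#' and diaphragm (inclusive) times the effective slice spacing, in litres.
#' Unlike the reference volume this remains defined under ventrolateral
#' FOV truncation as long as the box itself stays intact.
#'
#' @inheritParams landmarkBox
#' @return Partial ASAT volume in litres.
#' @export
measurePartialVolume <- function(volume, landmarks, mode = c("FH", "ASIS")) {
  mode <- match.arg(mode)
  box <- landmarkBox(landmarks, mode, volume)
  .boxVolumeL(volume, landmarks, cols = box$cols, rows = box$rows,
              errorFun = truncationAffectsMeasureError,
              what = paste0(mode, "-box"))
}

#' Assemble the full surrogate panel row for one subject
#'
#' Computes the reference volume and all six surrogates. A truncated
#' reference is a first-class state, not an error: if the reference raises
#' the truncated-reference condition, `v_asat_L` is recorded as `NA` and
#' the surrogates are still computed (this is precisely the use case for
#' surrogate measures). Failures of any surrogate itself propagate as
#' errors carrying the measure name.
#'
#' @inheritParams measureReferenceVolume
#' @param subjectId,sex identifiers copied into the row.
#' @return A one-row data.frame with columns `subject_id`, `sex`,
#'   `v_asat_L`, `awf_asis_mm`, `hgf_asis_mm`, `a_p_fh_cm2`,
#'   `a_p_asis_cm2`, `v_p_fh_L`, `v_p_asis_L`.
#' @export
measurePanel <- function(volume, landmarks, subjectId, sex) {
  wrap <- function(name, expr) {
    tryCatch(expr, fovfatError = function(e) {
      .fovStop(class(e)[1L], "measure %s failed for subject %s: %s",
               name, subjectId, conditionMessage(e))
    })
  }
  vasat <- tryCatch(measureReferenceVolume(volume, landmarks),
                    truncatedReferenceError = function(e) NA_real_)
  data.frame(
    subject_id = subjectId,
    sex = sex,
    v_asat_L = vasat,
    awf_asis_mm = wrap("awf_asis", measureAwf(volume, landmarks)),
    hgf_asis_mm = wrap("hgf_asis", measureHgf(volume, landmarks)),
    a_p_fh_cm2 = wrap("a_p_fh", measurePartialArea(volume, landmarks, "FH")),
    a_p_asis_cm2 = wrap("a_p_asis", measurePartialArea(volume, landmarks, "ASIS")),
    v_p_fh_L = wrap("v_p_fh", measurePartialVolume(volume, landmarks, "FH")),
    v_p_asis_L = wrap("v_p_asis", measurePartialVolume(volume, landmarks, "ASIS")),
    stringsAsFactors = FALSE)
}
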