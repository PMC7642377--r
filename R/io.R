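## Readers and writers for the pipeline's artifacts. All readers validate
## strictly and reject rather than repair: unknown labels, missing or
## non-positive spacings, malformed landmark files and inconsistent panels
## are errors, never silently coerced.

.PANEL_COLS <- c("subject_id", "sex", "v_asat_L", "awf_asis_mm",
                 "hgf_asis_mm", "a_p_fh_cm2", "a_p_asis_cm2",
                 "v_p_fh_L", "v_p_asis_L")

#' Write / read a label volume as NIfTI-1
#'
#' Volumes are stored as int16 NIfTI-1 with the in-plane spacing in
#' `pixdim[1:2]` and the effective slice spacing in `pixdim[3]`. The array
#' is written in the package's native axis order (col, row, slice), so a
#' write/read round trip is the identity on labels and spacings.
#'
#' @param volume a [LabelVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `writeLabelVolume` returns `path` invisibly; `readLabelVolume`
#'   returns a validated [LabelVolume-class].
#' @export
writeLabelVolume <- function(volume, path) {
  stopifnot(is(volume, "LabelVolume"))
  img <- RNifti::asNifti(volume@labels)
  RNifti::pixdim(img) <- c(volume@inPlaneSpacing, volume@inPlaneSpacing,
                           volume@sliceSpacing)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname writeLabelVolume
#' @export
readLabelVolume <- function(path) {
  if (!file.exists(path)) validationError("no such file: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    validationError("expected a 3D volume in %s, got %d dims",
                    path, length(dim(arr)))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || anyNA(pd[1:3]) || any(pd[1:3] <= 0))
    validationError("missing or non-positive voxel spacing in NIfTI header of %s", path)
  if (abs(pd[1] - pd[2]) > 1e-6)
    validationError("in-plane spacing must be isotropic (got %g x %g mm)", pd[1], pd[2])
  vals <- unique(as.vector(arr))
  bad <- setdiff(vals, .LABELS)
  if (length(bad))
    validationError("unknown label value(s) in %s: %s", path,
                    paste(sort(bad), collapse = ", "))
  labels <- array(as.integer(arr), dim = dim(arr))  # drop image attributes
  LabelVolume(labels, inPlaneSpacing = pd[1], sliceSpacing = pd[3])
}

#' Write / read a landmark set as JSON
#'
#' Landmarks are stored in 1-based voxel indices (col, row, slice), not mm,
#' so files are unambiguous with respect to header affines; conversion to
#' physical units happens only inside the measurement code.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path JSON file path.
#' @return `writeLandmarks` returns `path` invisibly; `readLandmarks`
#'   returns a validated [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  pt <- function(p) list(col = p[1], row = p[2], slice = p[3])
  obj <- list(fh_left = pt(landmarks@fhLeft), fh_right = pt(landmarks@fhRight),
              asis_left = pt(landmarks@asisLeft), asis_right = pt(landmarks@asisRight),
              diaphragm_slice = landmarks@diaphragmSlice,
              pelvic_floor_slice = landmarks@pelvicFloorSlice)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) validationError("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fh_left", "fh_right", "asis_left", "asis_right",
            "diaphragm_slice", "pelvic_floor_slice")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    schemaError("landmark file %s missing key(s): %s", path,
                paste(miss, collapse = ", "))
  pt <- function(nm) {
    p <- obj[[nm]]
    if (!all(c("col", "row", "slice") %in% names(p)))
      schemaError("landmark %s must have col, row, slice", nm)
    as.integer(c(p$col, p$row, p$slice))
  }
  LandmarkSet(fhLeft = pt("fh_left"), fhRight = pt("fh_right"),
              asisLeft = pt("asis_left"), asisRight = pt("asis_right"),
              diaphragmSlice = obj$diaphragm_slice,
              pelvicFloorSlice = obj$pelvic_floor_slice)
}

## bounds check of a landmark set against a concrete volume (use site)
.checkLandmarksInGrid <- function(landmarks, volume) {
  d <- dim(volume@labels)
  pts <- list(fhLeft = landmarks@fhLeft, fhRight = landmarks@fhRight,
              asisLeft = landmarks@asisLeft, asisRight = landmarks@asisRight)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (any(p > d) || any(p < 1L))
      validationError("landmark %s (%d, %d, %d) outside grid %d x %d x %d",
                      nm, p[1], p[2], p[3], d[1], d[2], d[3])
  }
  if (landmarks@diaphragmSlice > d[3] || landmarks@pelvicFloorSlice < 1L)
    validationError("slice bounds [%d, %d] outside grid with %d slices",
                    landmarks@pelvicFloorSlice, landmarks@diaphragmSlice, d[3])
  invisible(TRUE)
}

#' Write / read a surrogate panel as CSV
#'
#' One row per subject with the reference volume and the six surrogate
#' measures. `v_asat_L` may be `NA` (reference undefined on truncated
#' data); negative values and duplicated subject ids are rejected.
#'
#' @param panel a data.frame with the panel columns.
#' @param path CSV file path.
#' @return `writePanel` returns `path` invisibly; `readPanel` returns the
#'   validated data.frame.
#' @export
writePanel <- function(panel, path) {
  .validatePanel(panel)
  utils::write.csv(panel[, .PANEL_COLS, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  if (!file.exists(path)) validationError("no such file: %s", path)
  panel <- utils::read.csv(path, colClasses = c(
    subject_id = "character", sex = "character", v_asat_L = "numeric",
    awf_asis_mm = "numeric", hgf_asis_mm = "numeric",
    a_p_fh_cm2 = "numeric", a_p_asis_cm2 = "numeric",
    v_p_fh_L = "numeric", v_p_asis_L = "numeric"))
  .validatePanel(panel)
  panel
}

.validatePanel <- function(panel) {
  miss <- setdiff(.PANEL_COLS, names(panel))
  if (length(miss))
    schemaError("panel missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$subject_id))
    validationError("duplicate subject_id: %s",
                    paste(unique(panel$subject_id[duplicated(panel$subject_id)]),
                          collapse = ", "))
  if (nrow(panel) && !all(panel$sex %in% c("female", "male")))
    validationError("sex must be 'female' or 'male'")
  num <- setdiff(.PANEL_COLS, c("subject_id", "sex"))
  for (nm in num) {
    v <- panel[[nm]]
    if (any(!is.na(v) & v < 0))
      validationError("negative value(s) in %s", nm)
  }
  if (nrow(panel)) {
    musts <- setdiff(num, "v_asat_L")   # only the reference may be missing
    for (nm in musts)
      if (anyNA(panel[[nm]]))
        validationError("missing value(s) in %s", nm)
  }
  invisible(TRUE)
}

#' Write / read the analytic ground truth of a phantom as JSON
#'
#' @param groundTruth a [PhantomGroundTruth-class].
#' @param path JSON file path.
#' @return The path (write, invisibly) or a list with `per_slice_ring_area_cm2`,
#'   `true_v_asat_L` and `subject_id` (read).
#' @export
writeGroundTruth <- function(groundTruth, path) {
  stopifnot(is(groundTruth, "PhantomGroundTruth"))
  obj <- list(subject_id = groundTruth@spec@subjectId,
              per_slice_ring_area_cm2 = groundTruth@perSliceRingArea,
              true_v_asat_L = groundTruth@trueVasat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path)) validationError("no such file: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML mirrors [CohortSpec()] fields (`n_female`, `n_male`,
#' `bmi_mean`, `bmi_sd`, `bmi_range`, `profile_heterogeneity`, `seed`)
#' under `cohort:`, plus optional `truncation: {fov_width: <mm>}`,
#' `output_dir`, `groups` and `in_plane_spacing`.
#'
#' @param path YAML file path.
#' @return A list with elements `cohort` ([CohortSpec-class]),
#'   `truncation` (NULL or fov width in mm), `outputDir`, `groups`,
#'   `inPlaneSpacing` and `seed`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) validationError("no such file: %s", path)
  cfg <- yaml::read_yaml(path)
  co <- cfg$cohort
  if (is.null(co)) co <- list()
  pick <- function(nm, default) if (is.null(co[[nm]])) default else co[[nm]]
  cohort <- CohortSpec(
    nFemale = pick("n_female", 116L), nMale = pick("n_male", 77L),
    bmiMean = pick("bmi_mean", 32.1), bmiSd = pick("bmi_sd", 3.7),
    bmiRange = unlist(pick("bmi_range", c(24.8, 41.2))),
    profileHeterogeneity = pick("profile_heterogeneity", 0.35),
    seed = pick("seed", 1L))
  list(cohort = cohort,
       truncation = if (!is.null(cfg$truncation)) as.numeric(cfg$truncation$fov_width),
       outputDir = if (is.null(cfg$output_dir)) "." else cfg$output_dir,
       groups = if (is.null(cfg$groups)) c("female", "male", "total") else unlist(cfg$groups),
       inPlaneSpacing = if (is.null(cfg$in_plane_spacing)) 2 else cfg$in_plane_spacing,
       seed = cohort@seed)
}
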