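# Shared fixtures, all generated in code.

# constant-profile phantom spec with convenient round geometry
constantSpec <- function(id = "T01", sex = "female", nSlices = 20,
                         outerA = 150, outerB = 110, innerA = 120,
                         innerB = 80, offset = 10, spacing = 2) {
  PhantomSpec(id, sex, nSlices = nSlices,
              outerA = outerA, outerB = outerB,
              innerA = innerA, innerB = innerB,
              innerDorsalOffset = offset,
              inPlaneSpacing = spacing)
}

# dense-grid numerical oracle: area (cm^2) of the ring clipped to an
# optional axial rectangle [x1,x2] x [y1,y2] (mm, grid coordinates),
# integrated on a fine grid independent of the voxel path
denseRingArea <- function(spec, sliceIdx, cx, cy, clip = NULL, step = 0.25) {
  aO <- spec@outerA[sliceIdx]; bO <- spec@outerB[sliceIdx]
  aI <- spec@innerA[sliceIdx]; bI <- spec@innerB[sliceIdx]
  off <- spec@innerDorsalOffset[sliceIdx]
  xr <- c(cx - aO, cx + aO); yr <- c(cy - bO, cy + bO + off)
  if (!is.null(clip)) {
    xr <- c(max(xr[1], clip[1]), min(xr[2], clip[2]))
    yr <- c(max(yr[1], clip[3]), min(yr[2], clip[4]))
  }
  if (diff(xr) <= 0 || diff(yr) <= 0) return(0)
  xs <- seq(xr[1] + step / 2, xr[2], by = step) - cx
  ys <- seq(yr[1] + step / 2, yr[2], by = step) - cy
  fOut <- outer((xs / aO)^2, (ys / bO)^2, "+") <= 1
  fIn <- outer((xs / aI)^2, ((ys - off) / bI)^2, "+") <= 1
  sum(fOut & !fIn) * step^2 / 100
}

# grid centre (mm) of a phantom volume, matching makePhantom's layout
gridCentre <- function(volume) {
  d <- dim(volume)
  c(d[1] * inPlaneSpacing(volume) / 2, d[2] * inPlaneSpacing(volume) / 2)
}

# phantom whose mid-abdominal slices bulge laterally beyond the (narrower)
# ASIS/FH levels: the configuration in which FOV truncation can cut fat
# while sparing every measurement region on the landmark slices
bulgeSpec <- function(id = "B01", nSlices = 12, aBase = 140, bBase = 105,
                      tLat = 30, tVen = 40, tDor = 22, bulge = 1.2,
                      spacing = 2) {
  u <- (seq_len(nSlices) - 0.5) / nSlices
  prof <- 1 + (bulge - 1) * sin(pi * u)^2
  fh <- max(2L, round(0.10 * nSlices))
  asis <- max(fh, round(0.22 * nSlices))
  tAb <- (tVen + tDor) / 2
  PhantomSpec(id, "female", nSlices,
              outerA = aBase * prof, outerB = bBase * prof,
              innerA = aBase * prof - tLat, innerB = bBase * prof - tAb,
              innerDorsalOffset = (tVen - tDor) / 2,
              pelvicFloorSlice = 2L, fhSlice = fh, asisSlice = asis,
              diaphragmSlice = nSlices - 1L, inPlaneSpacing = spacing)
}

# smallest FOV width that keeps every tissue voxel of the ASIS slice
# in-FOV, scaled by `factor`; mirrors the elliptical-FOV geometry of
# applyFovTruncation
fovWidthSparingAsisSlice <- function(volume, landmarks, factor = 1.03) {
  sp <- inPlaneSpacing(volume)
  d <- dim(volume)
  sl <- labelArray(volume)[, , landmarks@asisLeft[3]]
  H <- d[2] * sp
  xs <- abs((seq_len(d[1]) - 0.5) * sp - d[1] * sp / 2)
  ys <- (seq_len(d[2]) - 0.5) * sp - H / 2
  yTerm <- ((ys - H / 4) / (0.75 * H))^2
  tissue <- which(sl == 1L | sl == 2L, arr.ind = TRUE)
  need <- xs[tissue[, 1]] / sqrt(pmax(1e-12, 1 - yTerm[tissue[, 2]]))
  2 * max(need) * factor
}

# the default study-sized run is expensive; compute once per test run
.runCache <- new.env(parent = emptyenv())
defaultRun <- function() {
  if (is.null(.runCache$res))
    .runCache$res <- suppressMessages(analyzeCohort(CohortSpec(seed = 1)))
  .runCache$res
}

# a tiny panel with an exact linear law, for calibration tests
exactPanel <- function(n = 12, seed = 99) {
  set.seed(seed)
  s <- seq(0.5, 3, length.out = n)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    v_asat_L = 5 * s + 1,
    awf_asis_mm = 10 * s, hgf_asis_mm = 8 * s,
    a_p_fh_cm2 = 30 * s, a_p_asis_cm2 = 40 * s,
    v_p_fh_L = s, v_p_asis_L = 1.2 * s,
    stringsAsFactors = FALSE)
}
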