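## Cohort sampling: turns the statistical description of the study
## population into a list of per-subject phantom specs. BMI is drawn from
## a truncated Gaussian (reject-and-resample, avoiding boundary atoms) and
## acts as a latent size score: it drives frame size weakly and fat-ring
## thickness strongly. Independent subject-level noise decouples volume
## from BMI, and `profileHeterogeneity` injects smooth random axial and
## ventral modulation of the ring so that single-slice measures carry
## slice-sampling noise that integrated (partial-volume) measures average
## out.

## sex-specific base geometry (mm): males have the larger frame and the
## thinner subcutaneous ring, females the reverse. Ring thickness is
## parametrised by azimuthal sector: lateral (tLat), dorsal (tDor) and
## ventral (tVen) base thicknesses; ventral > dorsal reflects the
## ventrally thicker abdominal wall.
.BASE <- list(
  female = list(A = 170, B = 128, tLat = 38, tDor = 30, tVen = 52),
  male   = list(A = 186, B = 136, tLat = 28, tDor = 23, tVen = 38)
)

## subject-level sector log-SDs. Azimuthal heterogeneity is what a
## single-location caliper cannot average away: the dorsal depot carries
## the largest between-subject variance (captured by the integrated
## dorsal-box measures), while the ventral wall's variability is mostly
## axial (see the modulation amplitudes below) and so hits single-slice
## ventral measures hardest.
.SECTOR_SD <- c(lat = 0.12, dor = 0.12, ven = 0.15)

.truncNorm <- function(mean, sd, range) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

## smooth random axial modulation in [-1, 1]-ish: two low-order cosines
.smoothProfile <- function(n) {
  u <- (seq_len(n) - 0.5) / n
  a1 <- stats::runif(1L, 0.4, 1.0)
  a2 <- stats::runif(1L, 0.2, 0.6)
  p1 <- stats::runif(1L, 0, 2 * pi)
  p2 <- stats::runif(1L, 0, 2 * pi)
  (a1 * cos(pi * u + p1) + a2 * cos(2 * pi * u + p2)) / (a1 + a2)
}

.sampleSubject <- function(id, sex, cohort, inPlaneSpacing) {
  base <- .BASE[[sex]]
  h <- cohort@profileHeterogeneity
  bmi <- .truncNorm(cohort@bmiMean, cohort@bmiSd, cohort@bmiRange)
  z <- (bmi - cohort@bmiMean) / cohort@bmiSd

  ## shared adiposity scale (BMI-driven plus subject noise) and
  ## semi-independent azimuthal sector multipliers; frame size varies
  ## independently of adiposity (a thickness caliper cannot see the
  ## perimeter, an area or volume measure can)
  frame <- 1 + 0.05 * z + 0.07 * stats::rnorm(1L)
  adipo <- pmax(0.35, 1 + 0.22 * z + 0.12 * stats::rnorm(1L))
  sLat <- exp(stats::rnorm(1L, 0, .SECTOR_SD[["lat"]]))
  sDor <- exp(stats::rnorm(1L, 0, .SECTOR_SD[["dor"]]))
  sVen <- exp(stats::rnorm(1L, 0, .SECTOR_SD[["ven"]]))

  A <- base$A * frame
  B <- base$B * frame
  tLat <- base$tLat * adipo * sLat
  tDor <- base$tDor * adipo * sDor
  tVen <- base$tVen * adipo * sVen

  n <- sample(40:50, 1L)
  u <- (seq_len(n) - 0.5) / n
  ## axial taper: widest at mid-abdomen, narrower toward the pelvis and
  ## the diaphragm
  taper <- 0.82 + 0.18 * sin(pi * u)

  ## per-sector axial modulation of ring thickness: a smooth component
  ## (overall fat distribution along the trunk; the ventral wall varies
  ## most, the dorsal least) plus short-scale slice-to-slice ripple that
  ## integrated measures average away but single-slice measures sample at
  ## full strength
  ripple <- function() pmax(0.3, 1 + 0.5 * h * stats::rnorm(n))
  mLat <- pmax(0.25, 1 + 1.0 * h * .smoothProfile(n)) * ripple()
  mDor <- pmax(0.25, 1 + 0.8 * h * .smoothProfile(n)) * ripple()
  mVen <- pmax(0.25, 1 + 1.2 * h * .smoothProfile(n)) * ripple()

  outerA <- A * taper
  outerB <- B * taper
  innerA <- pmax(20, outerA - tLat * mLat)
  ## anteroposterior geometry: ventral thickness tVen and dorsal thickness
  ## tDor are realised through the inner semi-axis B and the dorsal offset
  ## of the inner centre: ventral = (outerB - innerB) + off,
  ## dorsal = (outerB - innerB) - off
  venS <- tVen * mVen
  dorS <- tDor * mDor
  tAb <- (venS + dorS) / 2
  innerB <- pmax(20, outerB - tAb)
  off <- pmax(0, (venS - dorS) / 2)
  off <- pmin(off, 0.55 * (outerB - innerB))

  pf <- 2L
  dia <- n - 1L
  fh <- pf + as.integer(round(0.12 * n))
  asis <- pf + as.integer(round(0.40 * n))

  PhantomSpec(subjectId = id, sex = sex, nSlices = n,
              outerA = outerA, outerB = outerB,
              innerA = innerA, innerB = innerB,
              innerDorsalOffset = off,
              pelvicFloorSlice = pf, fhSlice = fh,
              asisSlice = asis, diaphragmSlice = dia,
              inPlaneSpacing = inPlaneSpacing)
}

#' Sample a synthetic phantom cohort
#'
#' Draws `nFemale + nMale` subject specs from a [CohortSpec-class]. The
#' result is a pure function of the spec (including its seed): the RNG
#' state is saved and restored around the call.
#'
#' @param cohort a [CohortSpec-class].
#' @param inPlaneSpacing in-plane voxel spacing for the generated phantoms,
#'   mm (default 2).
#' @return A list of [PhantomSpec-class], females first (ids `F001`, ...),
#'   then males (`M001`, ...).
#' @examples
#' specs <- sampleCohort(CohortSpec(nFemale = 3, nMale = 2, seed = 7))
#' length(specs)
#' @export
sampleCohort <- function(cohort, inPlaneSpacing = 2) {
  stopifnot(is(cohort, "CohortSpec"))
  validObject(cohort)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cohort@seed)
  ids <- c(if (cohort@nFemale > 0) sprintf("F%03d", seq_len(cohort@nFemale)),
           if (cohort@nMale > 0) sprintf("M%03d", seq_len(cohort@nMale)))
  sexes <- rep(c("female", "male"), c(cohort@nFemale, cohort@nMale))
  mapply(function(id, sex) .sampleSubject(id, sex, cohort, inPlaneSpacing),
         ids, sexes, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
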