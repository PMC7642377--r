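## Structured error conditions used across the package. Every error raised by
## fovfat carries a specific class plus "fovfatError" so callers can
## discriminate validation failures from geometry/truncation conditions.

.fovStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "fovfatError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

invalidGeometryError       <- function(fmt, ...) .fovStop("invalidGeometryError", fmt, ...)
geometryOverflowError      <- function(fmt, ...) .fovStop("geometryOverflowError", fmt, ...)
truncatedReferenceError    <- function(fmt, ...) .fovStop("truncatedReferenceError", fmt, ...)
truncationAffectsMeasureError <- function(fmt, ...) .fovStop("truncationAffectsMeasureError", fmt, ...)
validationError            <- function(fmt, ...) .fovStop("validationError", fmt, ...)
schemaError                <- function(fmt, ...) .fovStop("schemaError", fmt, ...)
insufficientDataError      <- function(fmt, ...) .fovStop("insufficientDataError", fmt, ...)
degeneratePredictorError   <- function(fmt, ...) .fovStop("degeneratePredictorError", fmt, ...)
invalidReferenceError      <- function(fmt, ...) .fovStop("invalidReferenceError", fmt, ...)
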