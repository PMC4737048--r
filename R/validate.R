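# Internal argument checking.  Errors name the offending field so that
# spec-construction mistakes are immediately attributable.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (integer && x != round(x))
    abort_field(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) abort_field(field, sprintf("must be > %g", lower))
  } else if (x < lower) {
    abort_field(field, sprintf("must be >= %g", lower))
  }
  if (x > upper) abort_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

# Coerce a binary mask (logical or 0/1 numeric matrix) to logical.
as_mask <- function(mask, field = "mask") {
  if (!is.matrix(mask)) abort_field(field, "must be a matrix")
  if (anyNA(mask)) abort_field(field, "must not contain NA")
  if (is.logical(mask)) return(mask)
  if (!is.numeric(mask)) abort_field(field, "must be logical or numeric 0/1")
  if (!all(mask == 0 | mask == 1))
    abort_field(field, "numeric mask values must be 0 or 1")
  mask != 0
}

check_intensity_matrix <- function(x, field) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_field(field, "must be a numeric matrix")
  if (!all(is.finite(x))) abort_field(field, "intensities must be finite")
  if (any(x < 0)) abort_field(field, "intensities must be >= 0")
  invisible(x)
}
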