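#' Construct a multichannel fluorescence field
#'
#' Bundles the three channels of one field of view: a mitochondrial marker
#' (e.g. an outer-membrane import receptor stain), a diffuse cytoplasm marker,
#' and a nuclear counterstain.
#'
#' @param mito,cyto,nuclei Numeric intensity matrices of equal dimensions,
#'   finite and non-negative.
#' @param pixel_size_um Physical pixel size in micrometres (default 1; all
#'   morphometry is reported in pixel units).
#' @return An object of class `field_image`.
#' @export
field_image <- function(mito, cyto, nuclei, pixel_size_um = 1) {
  check_intensity_matrix(mito, "mito")
  check_intensity_matrix(cyto, "cyto")
  check_intensity_matrix(nuclei, "nuclei")
  if (!all(dim(mito) == dim(cyto)) || !all(dim(mito) == dim(nuclei)))
    abort_field("channels", "mito, cyto and nuclei must have equal dimensions")
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(mito = mito, cyto = cyto, nuclei = nuclei,
                 pixel_size_um = pixel_size_um),
            class = "field_image")
}

#' Construct a binarized field
#'
#' @param mito_mask,cyto_mask,nuclei_mask Binary matrices of equal dimensions.
#' @return An object of class `binary_field`.
#' @export
binary_field <- function(mito_mask, cyto_mask, nuclei_mask) {
  m <- as_mask(mito_mask, "mito_mask")
  c_ <- as_mask(cyto_mask, "cyto_mask")
  n <- as_mask(nuclei_mask, "nuclei_mask")
  if (!all(dim(m) == dim(c_)) || !all(dim(m) == dim(n)))
    abort_field("masks", "all masks must have equal dimensions")
  structure(list(mito_mask = m, cyto_mask = c_, nuclei_mask = n),
            class = "binary_field")
}

#' Otsu threshold of an intensity matrix
#'
#' Histogram-based threshold maximizing between-class variance over `n_bins`
#' equal-width bins spanning the observed intensity range.  Returns `NA` for a
#' constant image (no threshold separates anything; callers treat this as an
#' empty foreground).
#'
#' @param x Numeric matrix or vector of finite intensities.
#' @param n_bins Number of histogram bins (default 256, the convention for
#'   8-bit-derived fluorescence data).
#' @return Threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) abort_field("x", "intensities must be finite")
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / length(x)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance at each candidate split (after bin k)
  k <- seq_len(n_bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  k_star <- which.max(sigma_b)
  breaks[k_star + 1L]
}

#' Binarize a multichannel field
#'
#' Converts each channel of a [field_image] into a foreground mask, either by
#' per-channel Otsu thresholding (default) or by user-supplied fixed
#' thresholds.  A pixel is foreground when its intensity is strictly above the
#' channel threshold; a constant channel yields an empty mask.
#'
#' @param img A [field_image].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_thresholds For `method = "fixed"`: a single number or a named
#'   numeric vector with entries `mito`, `cyto`, `nuclei`.
#' @return A [binary_field].
#' @export
binarize_field <- function(img, method = c("otsu", "fixed"),
                           fixed_thresholds = NULL) {
  if (!inherits(img, "field_image"))
    img <- field_image(img$mito, img$cyto, img$nuclei)
  method <- match.arg(method)
  channels <- c("mito", "cyto", "nuclei")
  if (method == "fixed") {
    if (is.null(fixed_thresholds))
      abort_field("fixed_thresholds", "required when method = \"fixed\"")
    if (length(fixed_thresholds) == 1L && is.null(names(fixed_thresholds)))
      fixed_thresholds <- setNames(rep(fixed_thresholds, 3L), channels)
    if (!all(channels %in% names(fixed_thresholds)))
      abort_field("fixed_thresholds",
                  "must name thresholds for mito, cyto and nuclei")
  }
  masks <- lapply(channels, function(ch) {
    x <- img[[ch]]
    thr <- if (method == "otsu") otsu_threshold(x) else fixed_thresholds[[ch]]
    if (is.na(thr)) {
      matrix(FALSE, nrow(x), ncol(x))
    } else {
      x > thr
    }
  })
  binary_field(masks[[1L]], masks[[2L]], masks[[3L]])
}
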