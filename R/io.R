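# Plain-file interchange: multipage TIFF + JSON sidecar for fields,
# CSV + JSON for oxygraph runs.

#' Write a synthetic field (image, masks, truth) to disk
#'
#' The intensity field goes to `<name>.tif` as a multipage 32-bit float TIFF
#' (page order mito, cyto, nuclei; intensities divided by the scale recorded
#' in the sidecar), the truth masks to `<name>_masks.tif` as 8-bit pages, and
#' the spec plus truth summary to `<name>.json`.
#'
#' @param field A result of [generate_field()].
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @param spec Optional [image_spec()] recorded in the sidecar.
#' @return Invisibly, the sidecar path.
#' @export
write_field <- function(field, dir, name = "field", spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- field$image
  truth <- field$truth
  scale <- max(1, img$mito, img$cyto, img$nuclei)
  tiff::writeTIFF(list(img$mito / scale, img$cyto / scale,
                       img$nuclei / scale),
                  file.path(dir, paste0(name, ".tif")),
                  bits.per.sample = 32L)
  tiff::writeTIFF(lapply(truth[c("mito_mask", "cyto_mask", "nuclei_mask")],
                         function(m) matrix(as.numeric(m), nrow(m))),
                  file.path(dir, paste0(name, "_masks.tif")),
                  bits.per.sample = 8L)
  sidecar <- list(
    intensity_scale = scale,
    pixel_size_um = img$pixel_size_um,
    spec = if (is.null(spec)) NULL else unclass(spec),
    truth = truth[c("true_component_count", "true_edge_length",
                    "true_network_area", "true_cytoplasm_area",
                    "true_n_nuclei")]
  )
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a synthetic field written by [write_field()]
#'
#' @param dir Directory holding the files.
#' @param name File stem used when writing.
#' @return A list with `image` ([field_image]), `truth` (masks plus truth
#'   statistics) and `spec` (plain list or `NULL`).
#' @export
read_field <- function(dir, name = "field") {
  side <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  scale <- side$intensity_scale
  img <- field_image(pages[[1L]] * scale, pages[[2L]] * scale,
                     pages[[3L]] * scale,
                     pixel_size_um = side$pixel_size_um %||% 1)
  mpages <- tiff::readTIFF(file.path(dir, paste0(name, "_masks.tif")),
                           all = TRUE)
  truth <- c(list(mito_mask = mpages[[1L]] > 0.5,
                  cyto_mask = mpages[[2L]] > 0.5,
                  nuclei_mask = mpages[[3L]] > 0.5),
             lapply(side$truth, as.integer))
  class(truth) <- "field_ground_truth"
  list(image = img, truth = truth, spec = side$spec)
}

#' Write an oxygraph trace to CSV + JSON
#'
#' `<name>_trace.csv` holds `time_s`, `o2_nmol_per_ml`,
#' `flux_pmol_s_per_million`; `<name>_events.csv` holds `time_s`, `label`;
#' `<name>_meta.json` holds chamber volume, cell count and the normalization
#' flag.
#'
#' @param trace An [oxygraph_trace].
#' @param dir Output directory.
#' @param name File stem.
#' @return Invisibly, the metadata path.
#' @export
write_trace <- function(trace, dir, name = "run") {
  if (!inherits(trace, "oxygraph_trace"))
    abort_field("trace", "must be an oxygraph_trace")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(time_s = trace$time_s)
  if (!is.null(trace$o2_nmol_per_ml))
    df$o2_nmol_per_ml <- trace$o2_nmol_per_ml
  if (!is.null(trace$flux_pmol_s_per_million))
    df$flux_pmol_s_per_million <- trace$flux_pmol_s_per_million
  write.csv(df, file.path(dir, paste0(name, "_trace.csv")),
            row.names = FALSE)
  write.csv(trace$events, file.path(dir, paste0(name, "_events.csv")),
            row.names = FALSE)
  meta <- list(chamber_volume_ml = trace$chamber_volume_ml,
               cell_count_millions = trace$cell_count_millions,
               flux_normalized = trace$flux_normalized)
  path <- file.path(dir, paste0(name, "_meta.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an oxygraph trace written by [write_trace()]
#'
#' @param dir Directory holding the files.
#' @param name File stem used when writing.
#' @return An [oxygraph_trace].
#' @export
read_trace <- function(dir, name = "run") {
  df <- read.csv(file.path(dir, paste0(name, "_trace.csv")))
  ev <- read.csv(file.path(dir, paste0(name, "_events.csv")),
                 stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  oxygraph_trace(time_s = df$time_s,
                 o2_nmol_per_ml = df$o2_nmol_per_ml,
                 flux_pmol_s_per_million = df$flux_pmol_s_per_million,
                 events = ev,
                 chamber_volume_ml = meta$chamber_volume_ml,
                 cell_count_millions = meta$cell_count_millions,
                 flux_normalized = meta$flux_normalized)
}

#' Measure a group of generated fields into records
#'
#' Binarizes and measures every field of a generated group, producing the
#' per-field record table the downstream filtering/normalization/summary
#' steps consume.
#'
#' @param fields List of [generate_field()] results (e.g. from
#'   [generate_group()]).
#' @param group_label Group label applied to all records.
#' @param method,fixed_thresholds Passed to [binarize_field()].
#' @return Data frame of morphometry records, one row per field.
#' @export
measure_group <- function(fields, group_label = "group", method = "otsu",
                          fixed_thresholds = NULL) {
  recs <- lapply(seq_along(fields), function(i) {
    bf <- binarize_field(fields[[i]]$image, method = method,
                         fixed_thresholds = fixed_thresholds)
    measure_field(bf, group_label = group_label,
                  field_id = sprintf("%s_f%02d", group_label, i))
  })
  do.call(rbind, recs)
}
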