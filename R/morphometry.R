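#' Parameters recorded per field of view
#'
#' The morphometric parameter set recorded for every field and used by the
#' multi-parameter outlier filter: average perimeter per mitochondrion,
#' fraction of cytoplasm filled, total network edge length, total network
#' area, total cytoplasm area, number of nuclei, and the per-cell averages of
#' network and cytoplasm area.
#'
#' @return Character vector of record column names.
#' @export
morphometry_parameters <- function() {
  c("avg_perimeter_per_mito", "fraction_filled", "total_edge_length",
    "total_network_area", "total_cytoplasm_area", "n_nuclei",
    "avg_network_area_per_cell", "avg_cytoplasm_area_per_cell")
}

#' Measure morphometry of one binarized field
#'
#' Computes the per-field parameter vector: mitochondria are 8-connected
#' components of the mitochondrial mask, the network perimeter is the exposed
#' pixel-edge count ([boundary_edge_length()]), the average perimeter per
#' mitochondrion is total edge length / number of mitochondria, the fraction
#' of cytoplasm filled is network area / cytoplasm area, nuclei are counted as
#' 8-connected components of the nuclear mask, and per-cell averages divide by
#' the nucleus count.  `mean_cell_size` (total cytoplasm area / nuclei) is the
#' cell-size proxy used downstream for size normalization.
#'
#' @param bf A [binary_field], or any list with `mito_mask`, `cyto_mask` and
#'   `nuclei_mask` entries (e.g. the ground truth of [generate_field()]).
#' @param group_label,field_id Identifiers carried into the record.
#' @return A one-row data frame (a morphometry record).  An empty
#'   mitochondrial mask yields `n_mitochondria = 0` with
#'   `avg_perimeter_per_mito = NA` and a warning; an empty cytoplasm mask or a
#'   field without nuclei is rejected with an error.
#' @export
measure_field <- function(bf, group_label = "group", field_id = "field") {
  if (!inherits(bf, "binary_field"))
    bf <- binary_field(bf$mito_mask, bf$cyto_mask, bf$nuclei_mask)
  total_cyto <- as.integer(sum(bf$cyto_mask))
  if (total_cyto == 0L)
    stop(sprintf("field '%s': empty cytoplasm mask, record rejected", field_id),
         call. = FALSE)
  n_nuclei <- count_components(bf$nuclei_mask, 8)
  if (n_nuclei < 1L)
    stop(sprintf("field '%s': no nuclei detected, record rejected", field_id),
         call. = FALSE)
  n_mito <- count_components(bf$mito_mask, 8)
  edge <- boundary_edge_length(bf$mito_mask)
  area <- as.integer(sum(bf$mito_mask))
  if (n_mito == 0L)
    warning(sprintf(
      "field '%s': empty mitochondrial mask; avg_perimeter_per_mito undefined",
      field_id), call. = FALSE)
  frac <- area / total_cyto
  data.frame(
    group_label = group_label,
    field_id = field_id,
    total_edge_length = edge,
    n_mitochondria = n_mito,
    avg_perimeter_per_mito = if (n_mito > 0L) edge / n_mito else NA_real_,
    total_network_area = area,
    total_cytoplasm_area = total_cyto,
    n_nuclei = n_nuclei,
    fraction_filled = frac,
    fraction_filled_normalized = frac,
    avg_network_area_per_cell = area / n_nuclei,
    avg_cytoplasm_area_per_cell = total_cyto / n_nuclei,
    mean_cell_size = total_cyto / n_nuclei,
    stringsAsFactors = FALSE
  )
}

check_records <- function(records, min_rows = 1L) {
  if (!is.data.frame(records) || nrow(records) < min_rows)
    abort_field("records",
                sprintf("must be a data frame with >= %d records", min_rows))
  needed <- c("group_label", "field_id", morphometry_parameters(),
              "mean_cell_size", "fraction_filled_normalized")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L)
    abort_field("records",
                paste("missing columns:", paste(missing, collapse = ", ")))
  invisible(records)
}

#' Normalize the fill fraction to median cell size
#'
#' Mitochondrial content (fraction of cytoplasm filled) correlates with the
#' inverse of average cell size; to prevent random variation in the size of
#' the cells sampled from masquerading as content changes, the fill fraction
#' is adjusted to the group's median cell size.  Within each group, ordinary
#' least squares fits `fraction_filled ~ 1/mean_cell_size`; each record's
#' `fraction_filled_normalized` is its fill fraction minus the slope times its
#' deviation from `1/median(mean_cell_size)`.  The average perimeter per
#' mitochondrion is deliberately not adjusted (it shows no cell-size
#' correlation).  If all cell sizes in a group are identical the slope is
#' undefined and the records are returned unchanged with a message.
#'
#' @param records Data frame of morphometry records ([measure_field()] rows),
#'   at least 3 per group, all with positive `mean_cell_size`.
#' @return The records with `fraction_filled_normalized` updated.
#' @export
normalize_fill_fraction <- function(records) {
  check_records(records, min_rows = 3L)
  if (any(!is.finite(records$mean_cell_size) | records$mean_cell_size <= 0))
    abort_field("records", "all records need mean_cell_size > 0")
  for (grp in unique(records$group_label)) {
    sel <- records$group_label == grp
    if (sum(sel) < 3L)
      abort_field("records",
                  sprintf("group '%s' has < 3 records; cannot fit", grp))
    x <- 1 / records$mean_cell_size[sel]
    y <- records$fraction_filled[sel]
    if (sd(x) == 0) {
      message(sprintf(
        "group '%s': all cell sizes identical; normalization is the identity",
        grp))
      records$fraction_filled_normalized[sel] <- y
      next
    }
    b <- coef(lm(y ~ x))[[2L]]
    x_med <- 1 / median(records$mean_cell_size[sel])
    records$fraction_filled_normalized[sel] <- y - b * (x - x_med)
  }
  records
}

#' Discard multi-parameter outlier fields
#'
#' Single-pass rule: within each group, a record is discarded when any of the
#' listed parameters lies more than `k` sample standard deviations from the
#' group mean.  A parameter with zero spread excludes nobody.  The pass is not
#' iterated and the result does not depend on record order.
#'
#' @param records Data frame of morphometry records (>= 2 per group).
#' @param k Threshold in standard deviations (default 2).
#' @param parameters Parameter columns examined (default
#'   [morphometry_parameters()]).
#' @return A list with data frames `kept` and `discarded`.
#' @export
filter_outliers <- function(records, k = 2,
                            parameters = morphometry_parameters()) {
  check_records(records, min_rows = 2L)
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  missing <- setdiff(parameters, names(records))
  if (length(missing) > 0L)
    abort_field("parameters",
                paste("not in records:", paste(missing, collapse = ", ")))
  drop <- rep(FALSE, nrow(records))
  for (grp in unique(records$group_label)) {
    sel <- which(records$group_label == grp)
    if (length(sel) < 2L)
      abort_field("records",
                  sprintf("group '%s' has < 2 records", grp))
    for (p in parameters) {
      v <- records[[p]][sel]
      m <- mean(v, na.rm = TRUE)
      s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      out <- !is.na(v) & abs(v - m) > k * s
      drop[sel][out] <- TRUE
    }
  }
  list(kept = records[!drop, , drop = FALSE],
       discarded = records[drop, , drop = FALSE])
}

#' Summarize retained records as group mean and SEM
#'
#' @param records Data frame of retained morphometry records (>= 2 per
#'   group).  Parameters that are `NA` for a record (e.g. the average
#'   perimeter of a field with no detected mitochondria) are excluded from
#'   that parameter's summary.
#' @param discarded Optional data frame of discarded records (as returned by
#'   [filter_outliers()]) used to report exclusion counts.
#' @param parameters Columns to summarize; defaults to the recorded parameter
#'   set plus the normalized fill fraction and the cell-size proxy.
#' @return An object of class `group_summary`: a list with `stats` (long data
#'   frame: group_label, parameter, n, mean, sem), `counts` (per-group
#'   retained/discarded) and `discarded_field_ids`.
#' @export
summarize_group <- function(records, discarded = NULL,
                            parameters = c(morphometry_parameters(),
                                           "fraction_filled_normalized",
                                           "mean_cell_size")) {
  check_records(records, min_rows = 2L)
  rows <- list()
  for (grp in unique(records$group_label)) {
    sel <- records$group_label == grp
    if (sum(sel) < 2L)
      stop(sprintf("group '%s' has < 2 retained records", grp), call. = FALSE)
    for (p in parameters) {
      v <- records[[p]][sel]
      v <- v[!is.na(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group_label = grp, parameter = p, n = n,
        mean = if (n > 0L) mean(v) else NA_real_,
        sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  stats <- do.call(rbind, rows)
  n_disc <- if (is.null(discarded)) 0L else nrow(discarded)
  counts <- data.frame(
    group_label = unique(records$group_label),
    n_retained = vapply(unique(records$group_label),
                        function(g) sum(records$group_label == g), integer(1)),
    n_discarded = vapply(unique(records$group_label), function(g) {
      if (is.null(discarded)) 0L else sum(discarded$group_label == g)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    stats = stats,
    counts = counts,
    discarded_field_ids = if (n_disc > 0L) discarded$field_id else character(0)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (mean +/- SEM over retained fields)\n")
  print(x$stats, row.names = FALSE)
  cat("\nRetained/discarded per group:\n")
  print(x$counts, row.names = FALSE)
  if (length(x$discarded_field_ids) > 0L)
    cat("Discarded fields:", paste(x$discarded_field_ids, collapse = ", "),
        "\n")
  invisible(x)
}

#' Full morphometry pipeline over measured records
#'
#' Applies, in order: the multi-parameter outlier filter (so outlying fields
#' cannot steer the regression), the cell-size normalization of the fill
#' fraction fitted on retained records, and the group mean/SEM summary.
#'
#' @param records Data frame of morphometry records.
#' @param k Outlier threshold in standard deviations.
#' @return A list with `records` (retained, normalized), `discarded`, and
#'   `summary` (a `group_summary`).
#' @export
morphometry_pipeline <- function(records, k = 2) {
  flt <- filter_outliers(records, k = k)
  kept <- normalize_fill_fraction(flt$kept)
  list(records = kept, discarded = flt$discarded,
       summary = summarize_group(kept, flt$discarded))
}
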