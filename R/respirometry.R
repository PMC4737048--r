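#' Derive oxygen flux from a concentration trace
#'
#' Supports concentration-dialect inputs: the flux is the negative time
#' derivative of the oxygen concentration (central differences, boxcar
#' smoothed over `smooth_window_s`), scaled to pmol s^-1 (10^6 cells)^-1 via
#' flux = -d\[O2\]/dt x chamber_volume_ml x 1000 / cell_count_millions.
#'
#' @param trace An [oxygraph_trace] with an `o2_nmol_per_ml` series on an
#'   (approximately) uniform time grid; sampling jitter beyond 10% of the
#'   median interval is rejected.
#' @param smooth_window_s Boxcar window in seconds (at least two sample
#'   intervals).
#' @return The trace with `flux_pmol_s_per_million` set and
#'   `flux_normalized = TRUE`.
#' @export
concentration_to_flux <- function(trace, smooth_window_s = 10) {
  if (!inherits(trace, "oxygraph_trace"))
    abort_field("trace", "must be an oxygraph_trace")
  if (is.null(trace$o2_nmol_per_ml))
    stop("trace has no o2_nmol_per_ml series", call. = FALSE)
  t <- trace$time_s
  dt <- diff(t)
  dt_med <- median(dt)
  if (max(abs(dt - dt_med)) > 0.1 * dt_med)
    stop("nonuniform sampling: jitter exceeds 10% of the median interval",
         call. = FALSE)
  if (smooth_window_s < 2 * dt_med)
    abort_field("smooth_window_s", "must cover at least two sample intervals")
  o2 <- trace$o2_nmol_per_ml
  n <- length(o2)
  d <- numeric(n)
  d[1L] <- (o2[2L] - o2[1L]) / (t[2L] - t[1L])
  d[n] <- (o2[n] - o2[n - 1L]) / (t[n] - t[n - 1L])
  idx <- 2L:(n - 1L)
  d[idx] <- (o2[idx + 1L] - o2[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  d <- boxcar_smooth(d, max(1L, round(smooth_window_s / dt_med)))
  flux <- -d * trace$chamber_volume_ml * 1000 / trace$cell_count_millions
  trace$flux_pmol_s_per_million <- flux
  trace$flux_normalized <- TRUE
  trace
}

# centered boxcar mean with shrinking windows at the edges (preserves
# constants exactly everywhere)
boxcar_smooth <- function(x, width) {
  if (width <= 1L) return(x)
  half <- floor(width / 2)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect stable respiration plateaus
#'
#' Finds maximal intervals of at least `min_duration_s` (default 180 s, i.e.
#' the three-minutes-or-longer rule) over which the flux is consistent: the
#' fitted linear slope does not exceed `slope_tol` of the interval mean per
#' minute and the coefficient of variation stays within `cv_tol`.
#'
#' Candidate intervals are found by flagging samples whose local trend (a
#' central difference of the boxcar-smoothed flux across `slope_window_s`) is
#' small, closing gaps shorter than `gap_close_s`, and then verifying each
#' candidate run against the slope and CV tolerances computed on the raw
#' flux.
#'
#' @param trace An [oxygraph_trace] with a flux series (run
#'   [concentration_to_flux()] first if only concentration is available).
#' @param min_duration_s Minimum plateau duration, seconds.
#' @param slope_tol Maximum |fitted slope| as a fraction of the interval mean
#'   per minute (default 0.01 = 1%/min).
#' @param cv_tol Maximum coefficient of variation within the interval.
#' @param smooth_window_s,slope_window_s,gap_close_s Detection tuning: boxcar
#'   width for the smoothed series, span of the local trend estimate, and the
#'   longest unstable gap closed inside a run.
#' @param split_at Optional times (seconds) that no plateau may straddle.
#'   Substrate additions are instantaneous interventions, so a steady stretch
#'   must not be pooled across one even when the rate change it causes is too
#'   small for the slope criterion to notice (e.g. a subtle cytochrome-c
#'   response); [analyze_trace()] passes the event times here.
#' @return Data frame of segments ordered by start time, with columns
#'   `start_s`, `end_s`, `mean_flux`, `slope` (per second) and `cv`.
#' @export
detect_plateaus <- function(trace, min_duration_s = 180, slope_tol = 0.01,
                            cv_tol = 0.05, smooth_window_s = 15,
                            slope_window_s = 60, gap_close_s = 20,
                            split_at = NULL) {
  if (!inherits(trace, "oxygraph_trace"))
    abort_field("trace", "must be an oxygraph_trace")
  f <- trace$flux_pmol_s_per_million
  if (is.null(f))
    stop("trace has no flux series; run concentration_to_flux() first",
         call. = FALSE)
  t <- trace$time_s
  n <- length(f)
  if (t[n] - t[1L] < min_duration_s)
    abort_field("trace", "shorter than min_duration_s")
  if (!is.null(split_at) && length(split_at) > 0L) {
    chunk <- findInterval(t, sort(unique(split_at)))
    segs <- lapply(unique(chunk), function(ci) {
      sel <- chunk == ci
      if (t[max(which(sel))] - t[min(which(sel))] < min_duration_s)
        return(NULL)
      detect_plateaus_core(t[sel], f[sel], min_duration_s, slope_tol, cv_tol,
                           smooth_window_s, slope_window_s, gap_close_s)
    })
    segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
    if (is.null(segs) || nrow(segs) == 0L)
      return(empty_segments())
    return(segs[order(segs$start_s), , drop = FALSE])
  }
  detect_plateaus_core(t, f, min_duration_s, slope_tol, cv_tol,
                       smooth_window_s, slope_window_s, gap_close_s)
}

empty_segments <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             mean_flux = numeric(0), slope = numeric(0), cv = numeric(0))
}

detect_plateaus_core <- function(t, f, min_duration_s, slope_tol, cv_tol,
                                 smooth_window_s, slope_window_s,
                                 gap_close_s) {
  n <- length(f)
  dt <- median(diff(t))

  fs <- boxcar_smooth(f, max(1L, round(smooth_window_s / dt)))
  k <- max(1L, round(slope_window_s / 2 / dt))
  hi <- pmin(seq_len(n) + k, n)
  lo <- pmax(seq_len(n) - k, 1L)
  local_slope <- (fs[hi] - fs[lo]) / (t[hi] - t[lo])
  level <- pmax(abs(fs), 1e-9)
  # generous per-sample flag; candidate runs are re-verified strictly below
  stable <- abs(local_slope) * 60 <= 4 * slope_tol * level

  # close short unstable gaps so isolated noise flips cannot split a plateau
  r <- rle(stable)
  gap_n <- max(1L, round(gap_close_s / dt))
  if (length(r$lengths) > 2L) {
    interior <- 2L:(length(r$lengths) - 1L)
    flip <- interior[!r$values[interior] & r$lengths[interior] <= gap_n]
    r$values[flip] <- TRUE
  }
  stable <- inverse.rle(r)

  segs <- list()
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    a <- starts[i]
    b <- ends[i]
    # trim transition bleed-in: drop edge samples whose smoothed value sits
    # away from the run's plateau level
    med <- median(fs[a:b])
    tol <- slope_tol * max(abs(med), 1e-9)
    while (a < b && abs(fs[a] - med) > tol) a <- a + 1L
    while (b > a && abs(fs[b] - med) > tol) b <- b - 1L
    if (t[b] - t[a] < min_duration_s) next
    seg_f <- f[a:b]
    seg_t <- t[a:b]
    m <- mean(seg_f)
    slope <- sum((seg_t - mean(seg_t)) * (seg_f - m)) /
      sum((seg_t - mean(seg_t))^2)
    s <- sd(seg_f)
    cv <- if (abs(m) > 1e-12) s / abs(m) else if (s == 0) 0 else Inf
    if (abs(slope) * 60 > slope_tol * abs(m) + 1e-12) next
    if (cv > cv_tol + 1e-12) next
    segs[[length(segs) + 1L]] <- data.frame(
      start_s = seg_t[1L], end_s = seg_t[length(seg_t)],
      mean_flux = m, slope = slope, cv = cv
    )
  }
  if (length(segs) == 0L) return(empty_segments())
  out <- do.call(rbind, segs)
  out[order(out$start_s), , drop = FALSE]
}

#' Assign respiration states from plateaus and substrate events
#'
#' Each substrate addition opens a window lasting until the next addition.
#' A state's rate is the mean flux of the last qualifying plateau lying
#' wholly inside its window (the cells are given time to stabilize, so the
#' latest stable stretch is the representative one).  The uncoupled rate is
#' the maximum plateau mean across all FCCP titration steps, matching
#' stepwise addition until maximal uncoupling; an FCCP overdose in the final
#' step therefore cannot drag the estimate down.  States without a qualifying
#' plateau are flagged missing (`NA`).
#'
#' @param segments Plateau data frame from [detect_plateaus()].
#' @param events Event data frame (`time_s`, `label`) in protocol order
#'   (PMG, ADP, SUCC, OLIGO, FCCP...; CYTC after SUCC).
#' @param end_time_s End of the recording; defaults to the last plateau end.
#' @param normalized Whether the flux series was per 10^6 cells.
#' @return An object of class `state_rates` with fields `s2_pmg`, `s3_pmg`,
#'   `s3_pmgs`, `s4_pmgs`, `uncoupled`, `cytc_rate`, `rcr` (NA until
#'   [compute_rcr()]) and `normalized`.
#' @export
assign_states <- function(segments, events, end_time_s = NULL,
                          normalized = TRUE) {
  if (!is.data.frame(events) || nrow(events) == 0L ||
      !all(c("time_s", "label") %in% names(events)))
    abort_field("events", "must be a non-empty data frame (time_s, label)")
  check_protocol_order(events)
  if (!is.data.frame(segments))
    abort_field("segments", "must be a data frame from detect_plateaus()")
  if (nrow(segments) == 0L)
    stop("no plateaus detected; cannot assign states", call. = FALSE)
  ev <- events[order(events$time_s), , drop = FALSE]
  if (is.null(end_time_s)) end_time_s <- max(segments$end_s)
  bounds <- c(ev$time_s, max(end_time_s, max(ev$time_s)))

  last_plateau_in <- function(t0, t1) {
    sel <- segments$start_s >= t0 - 1e-9 & segments$end_s <= t1 + 1e-9
    if (!any(sel)) return(NA_real_)
    cand <- segments[sel, , drop = FALSE]
    cand <- cand[order(cand$start_s), , drop = FALSE]
    cand$mean_flux[nrow(cand)]
  }

  rate_for <- function(label) {
    i <- which(ev$label == label)
    if (length(i) == 0L) return(NA_real_)
    i <- i[1L]
    last_plateau_in(bounds[i], bounds[i + 1L])
  }

  fccp_idx <- which(ev$label == "FCCP")
  uncoupled <- NA_real_
  if (length(fccp_idx) > 0L) {
    step_rates <- vapply(fccp_idx, function(i) {
      last_plateau_in(bounds[i], bounds[i + 1L])
    }, numeric(1))
    if (any(!is.na(step_rates))) uncoupled <- max(step_rates, na.rm = TRUE)
  }

  structure(list(
    s2_pmg = rate_for("PMG"),
    s3_pmg = rate_for("ADP"),
    s3_pmgs = rate_for("SUCC"),
    s4_pmgs = rate_for("OLIGO"),
    uncoupled = uncoupled,
    cytc_rate = rate_for("CYTC"),
    rcr = NA_real_,
    normalized = isTRUE(normalized)
  ), class = "state_rates")
}

#' Normalize per-chamber rates to cell count
#'
#' Cells are recounted from the chamber after the run and the per-chamber
#' rates (pmol/s) divided by the count to yield pmol s^-1 (10^6 cells)^-1.
#' Applying this to already-normalized rates is an error.
#'
#' @param rates A `state_rates` object with `normalized = FALSE`.
#' @param cell_count_millions Recounted cells, in units of 10^6.
#' @return The normalized `state_rates`.
#' @export
normalize_to_cells <- function(rates, cell_count_millions) {
  if (!inherits(rates, "state_rates"))
    abort_field("rates", "must be a state_rates object")
  check_number(cell_count_millions, "cell_count_millions", lower = 0,
               strict_lower = TRUE)
  if (isTRUE(rates$normalized))
    stop("rates are already normalized to cell count", call. = FALSE)
  for (nm in c("s2_pmg", "s3_pmg", "s3_pmgs", "s4_pmgs", "uncoupled",
               "cytc_rate"))
    rates[[nm]] <- rates[[nm]] / cell_count_millions
  if (!is.na(rates$rcr)) rates$rcr <- rates$s3_pmgs / rates$s4_pmgs
  rates$normalized <- TRUE
  rates
}

#' Respiratory control ratio of one run
#'
#' RCR = state 3 PMGS / state 4 PMGS.  It is computed per run; cohort-level
#' RCR should average these per-run ratios, never take the ratio of
#' state-rate group means (the two differ whenever rates vary across runs).
#'
#' @param rates A `state_rates` object with `s3_pmgs` and `s4_pmgs` present
#'   and `s4_pmgs > 0`.
#' @return The ratio (a single number).
#' @export
compute_rcr <- function(rates) {
  if (!inherits(rates, "state_rates"))
    abort_field("rates", "must be a state_rates object")
  if (is.na(rates$s3_pmgs) || is.na(rates$s4_pmgs))
    stop("s3_pmgs and s4_pmgs must both be present", call. = FALSE)
  if (rates$s4_pmgs <= 0)
    stop("s4_pmgs must be > 0 to form an RCR", call. = FALSE)
  rates$s3_pmgs / rates$s4_pmgs
}

#' Cytochrome-c membrane-integrity check
#'
#' Exogenous cytochrome c can only stimulate respiration if the outer
#' mitochondrial membrane is damaged.  Membranes are called intact when the
#' fractional rise of the post-cytochrome-c rate over the preceding state 3
#' (PMGS) rate does not exceed `max_fractional_increase`.
#'
#' @param rates A `state_rates` with positive `s3_pmgs` and a `cytc_rate`.
#' @param max_fractional_increase Tolerated fractional increase (default 0.10).
#' @return `TRUE` (intact) or `FALSE` (membrane damage).
#' @export
cytochrome_c_check <- function(rates, max_fractional_increase = 0.10) {
  if (!inherits(rates, "state_rates"))
    abort_field("rates", "must be a state_rates object")
  check_number(max_fractional_increase, "max_fractional_increase", lower = 0)
  if (is.na(rates$cytc_rate) || is.na(rates$s3_pmgs))
    stop("cytc_rate and s3_pmgs must both be present", call. = FALSE)
  if (rates$s3_pmgs <= 0)
    stop("reference state 3 rate must be > 0", call. = FALSE)
  (rates$cytc_rate - rates$s3_pmgs) / rates$s3_pmgs <= max_fractional_increase
}

#' Analyze one oxygraph run end to end
#'
#' Convenience wrapper: derives flux if only concentration is present,
#' detects plateaus, assigns states, computes the per-run RCR, and runs the
#' cytochrome-c check when a CYTC event is present.
#'
#' @param trace An [oxygraph_trace].
#' @param min_duration_s,slope_tol,cv_tol Passed to [detect_plateaus()].
#' @param max_fractional_increase Passed to [cytochrome_c_check()].
#' @return A `state_rates` object with `rcr` filled in and, when applicable,
#'   a logical `cytc_intact` field.
#' @export
analyze_trace <- function(trace, min_duration_s = 180, slope_tol = 0.01,
                          cv_tol = 0.05, max_fractional_increase = 0.10) {
  if (!inherits(trace, "oxygraph_trace"))
    abort_field("trace", "must be an oxygraph_trace")
  if (is.null(trace$flux_pmol_s_per_million))
    trace <- concentration_to_flux(trace)
  segs <- detect_plateaus(trace, min_duration_s = min_duration_s,
                          slope_tol = slope_tol, cv_tol = cv_tol,
                          split_at = trace$events$time_s)
  rates <- assign_states(segs, trace$events,
                         end_time_s = max(trace$time_s),
                         normalized = trace$flux_normalized)
  if (!is.na(rates$s3_pmgs) && !is.na(rates$s4_pmgs) && rates$s4_pmgs > 0)
    rates$rcr <- compute_rcr(rates)
  if (!is.na(rates$cytc_rate) && !is.na(rates$s3_pmgs) && rates$s3_pmgs > 0)
    rates$cytc_intact <- cytochrome_c_check(rates, max_fractional_increase)
  rates
}

#' Tabulate state rates across runs
#'
#' @param rates_list List of `state_rates` objects.
#' @param group_labels Group label per run (recycled if length 1).
#' @param run_ids Optional run identifiers.
#' @return Data frame with one row per run: `group_label`, `run_id`, the six
#'   state rates and `rcr`.
#' @export
rates_table <- function(rates_list, group_labels = "group", run_ids = NULL) {
  if (!is.list(rates_list) || length(rates_list) == 0L)
    abort_field("rates_list", "must be a non-empty list of state_rates")
  n <- length(rates_list)
  group_labels <- rep_len(group_labels, n)
  if (is.null(run_ids)) run_ids <- sprintf("run%02d", seq_len(n))
  cols <- c("s2_pmg", "s3_pmg", "s3_pmgs", "s4_pmgs", "uncoupled",
            "cytc_rate", "rcr")
  out <- data.frame(group_label = group_labels, run_id = run_ids,
                    stringsAsFactors = FALSE)
  for (cn in cols)
    out[[cn]] <- vapply(rates_list, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  out
}

#' @export
print.state_rates <- function(x, ...) {
  unit <- if (isTRUE(x$normalized)) "pmol/s/10^6 cells" else "pmol/s (chamber)"
  cat(sprintf("Respiration state rates [%s]\n", unit))
  lab <- c(s2_pmg = "S2 (PMG)", s3_pmg = "S3 (PMG)", s3_pmgs = "S3 (PMG/S)",
           s4_pmgs = "S4 (PMG/S)", uncoupled = "Uncoupled",
           cytc_rate = "Cytochrome c", rcr = "RCR")
  for (nm in names(lab))
    cat(sprintf("  %-13s %s\n", lab[[nm]],
                ifelse(is.na(x[[nm]]), "missing", format(x[[nm]]))))
  if (!is.null(x$cytc_intact))
    cat(sprintf("  membranes intact: %s\n", x$cytc_intact))
  invisible(x)
}
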