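#' Default respiration state plan
#'
#' The substrate-inhibitor-uncoupler sequence of a permeabilized-cell
#' protocol: pyruvate/malate/glutamate (state 2), ADP (state 3 PMG),
#' succinate (state 3 PMGS), oligomycin (state 4 PMGS), then stepwise FCCP
#' titration until maximal uncoupling.  Default rates are typical
#' permeabilized smooth-muscle-cell magnitudes in
#' pmol O2 s^-1 (10^6 cells)^-1.
#'
#' @param rates Named numeric vector of true plateau rates for states
#'   `S2_PMG`, `S3_PMG`, `S3_PMGS`, `S4_PMGS` and at least one `FCCP<i>` step.
#' @param duration_s Plateau duration applied to every state.
#' @return A data frame with columns `label`, `rate`, `duration_s`.
#' @export
default_state_plan <- function(rates = c(S2_PMG = 30, S3_PMG = 154,
                                         S3_PMGS = 241, S4_PMGS = 53,
                                         FCCP1 = 300, FCCP2 = 375,
                                         FCCP3 = 350),
                               duration_s = 300) {
  data.frame(label = names(rates), rate = as.numeric(rates),
             duration_s = duration_s, stringsAsFactors = FALSE)
}

# map plan state labels to the substrate-addition event that opens them
state_event_label <- function(state_label) {
  if (state_label == "S2_PMG") return("PMG")
  if (state_label == "S3_PMG") return("ADP")
  if (state_label == "S3_PMGS") return("SUCC")
  if (state_label == "S4_PMGS") return("OLIGO")
  if (state_label == "CYTC") return("CYTC")
  if (grepl("^FCCP", state_label)) return("FCCP")
  abort_field("state_plan", sprintf("unknown state label '%s'", state_label))
}

#' Specification for a synthetic oxygraph run
#'
#' Describes a simulated 2 mL chamber run: an ordered plan of respiration
#' states with true plateau rates, linear ramps between states (mixing and
#' response time after each addition), additive measurement noise, optional
#' sensor drift, and the chamber geometry used to integrate flux into an
#' oxygen concentration series.  When `include_cytc` is `TRUE`, a cytochrome-c
#' window is inserted after state 3 PMGS with rate
#' `S3_PMGS * (1 + cytc_fractional_increase)`, so the membrane-integrity check
#' can be exercised in both intact and damaged modes.
#'
#' @param state_plan Data frame as from [default_state_plan()].
#' @param ramp_s Transition time between consecutive states, seconds.
#' @param noise_sd Additive Gaussian noise SD on flux, absolute units.
#' @param noise_rel If > 0, overrides `noise_sd` with noise proportional to
#'   the local true rate (SD = `noise_rel * |rate|`).
#' @param drift_per_s Linear drift added to the true flux, units per second.
#' @param sample_interval_s Sampling interval, seconds.
#' @param cell_count_millions Cells in the chamber, in units of 10^6.
#' @param chamber_volume_ml Chamber volume (default 2 mL).
#' @param cytc_fractional_increase Fractional rate increase after cytochrome c
#'   (0 = perfectly intact membranes).
#' @param include_cytc Insert the cytochrome-c window? Requires an `S3_PMGS`
#'   state in the plan.
#' @param cytc_duration_s Duration of the cytochrome-c window.
#' @param o2_start_nmol_per_ml Initial chamber oxygen concentration.
#' @param seed Integer seed.
#' @return An object of class `synthetic_trace_spec`.
#' @export
trace_spec <- function(state_plan = default_state_plan(), ramp_s = 20,
                       noise_sd = 1, noise_rel = 0, drift_per_s = 0,
                       sample_interval_s = 1, cell_count_millions = 0.75,
                       chamber_volume_ml = 2, cytc_fractional_increase = 0.03,
                       include_cytc = TRUE, cytc_duration_s = 300,
                       o2_start_nmol_per_ml = 400, seed = 1) {
  if (!is.data.frame(state_plan) ||
      !all(c("label", "rate", "duration_s") %in% names(state_plan)) ||
      nrow(state_plan) < 1L)
    abort_field("state_plan",
                "must be a data frame with columns label, rate, duration_s")
  if (anyDuplicated(state_plan$label))
    abort_field("state_plan", "state labels must be unique")
  if (any(!is.finite(state_plan$duration_s)) || any(state_plan$duration_s <= 0))
    abort_field("state_plan", "durations must be positive")
  if (any(!is.finite(state_plan$rate)))
    abort_field("state_plan", "rates must be finite")
  vapply(state_plan$label, state_event_label, character(1))  # validates labels
  check_number(ramp_s, "ramp_s", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(noise_rel, "noise_rel", lower = 0)
  check_number(drift_per_s, "drift_per_s")
  check_number(sample_interval_s, "sample_interval_s", lower = 0,
               strict_lower = TRUE)
  check_number(cell_count_millions, "cell_count_millions", lower = 0,
               strict_lower = TRUE)
  check_number(chamber_volume_ml, "chamber_volume_ml", lower = 0,
               strict_lower = TRUE)
  check_number(cytc_fractional_increase, "cytc_fractional_increase", lower = 0)
  check_number(cytc_duration_s, "cytc_duration_s", lower = 0,
               strict_lower = TRUE)
  check_number(o2_start_nmol_per_ml, "o2_start_nmol_per_ml", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  if (include_cytc && !"S3_PMGS" %in% state_plan$label)
    abort_field("include_cytc", "requires an S3_PMGS state in the plan")
  structure(list(state_plan = state_plan, ramp_s = ramp_s,
                 noise_sd = noise_sd, noise_rel = noise_rel,
                 drift_per_s = drift_per_s,
                 sample_interval_s = sample_interval_s,
                 cell_count_millions = cell_count_millions,
                 chamber_volume_ml = chamber_volume_ml,
                 cytc_fractional_increase = cytc_fractional_increase,
                 include_cytc = isTRUE(include_cytc),
                 cytc_duration_s = cytc_duration_s,
                 o2_start_nmol_per_ml = o2_start_nmol_per_ml,
                 seed = as.integer(seed)),
            class = "synthetic_trace_spec")
}

#' Construct an oxygraph trace object
#'
#' @param time_s Strictly increasing sample times, seconds.
#' @param o2_nmol_per_ml Optional oxygen concentration series.
#' @param flux_pmol_s_per_million Optional flux series in
#'   pmol s^-1 (10^6 cells)^-1; at least one of the two series is required.
#' @param events Data frame with columns `time_s` and `label` (labels among
#'   PMG, ADP, SUCC, OLIGO, FCCP, CYTC; FCCP may repeat).
#' @param chamber_volume_ml Chamber volume in mL.
#' @param cell_count_millions Recounted cells, units of 10^6.
#' @param flux_normalized Is the flux series already per 10^6 cells?
#' @return An object of class `oxygraph_trace`.
#' @export
oxygraph_trace <- function(time_s, o2_nmol_per_ml = NULL,
                           flux_pmol_s_per_million = NULL, events,
                           chamber_volume_ml = 2, cell_count_millions = 1,
                           flux_normalized = TRUE) {
  if (!is.numeric(time_s) || length(time_s) < 2L || anyNA(time_s) ||
      any(diff(time_s) <= 0))
    abort_field("time_s", "must be strictly increasing with >= 2 samples")
  if (is.null(o2_nmol_per_ml) && is.null(flux_pmol_s_per_million))
    abort_field("trace", "at least one of o2 or flux series is required")
  for (nm in c("o2_nmol_per_ml", "flux_pmol_s_per_million")) {
    x <- get(nm)
    if (!is.null(x) && (length(x) != length(time_s) || anyNA(x)))
      abort_field(nm, "must match time_s in length with no NA")
  }
  if (!is.data.frame(events) || !all(c("time_s", "label") %in% names(events)))
    abort_field("events", "must be a data frame with time_s and label")
  allowed <- c("PMG", "ADP", "SUCC", "OLIGO", "FCCP", "CYTC")
  if (!all(events$label %in% allowed))
    abort_field("events",
                paste("labels must be among", paste(allowed, collapse = ", ")))
  if (nrow(events) > 0L &&
      (min(events$time_s) < min(time_s) || max(events$time_s) > max(time_s)))
    abort_field("events", "event times must lie within the trace time range")
  check_protocol_order(events)
  check_number(chamber_volume_ml, "chamber_volume_ml", lower = 0,
               strict_lower = TRUE)
  check_number(cell_count_millions, "cell_count_millions", lower = 0,
               strict_lower = TRUE)
  structure(list(time_s = as.numeric(time_s),
                 o2_nmol_per_ml = o2_nmol_per_ml,
                 flux_pmol_s_per_million = flux_pmol_s_per_million,
                 events = events[order(events$time_s), , drop = FALSE],
                 chamber_volume_ml = chamber_volume_ml,
                 cell_count_millions = cell_count_millions,
                 flux_normalized = isTRUE(flux_normalized)),
            class = "oxygraph_trace")
}

# Protocol order: PMG < ADP < SUCC < OLIGO < FCCP (repeatable); CYTC anywhere
# after SUCC (it is added once state 3 PMGS has stabilized).
check_protocol_order <- function(events) {
  ev <- events[order(events$time_s), , drop = FALSE]
  rank <- c(PMG = 1, ADP = 2, SUCC = 3, OLIGO = 4, FCCP = 5)
  core <- ev$label[ev$label != "CYTC"]
  r <- rank[core]
  if (any(diff(r) < 0))
    stop("events out of protocol order (expected PMG, ADP, SUCC, OLIGO, FCCP...)",
         call. = FALSE)
  if (anyDuplicated(core[core != "FCCP"]))
    stop("events out of protocol order: only FCCP may repeat", call. = FALSE)
  if ("CYTC" %in% ev$label) {
    t_cytc <- ev$time_s[ev$label == "CYTC"][1L]
    if ("SUCC" %in% ev$label && t_cytc < ev$time_s[ev$label == "SUCC"][1L])
      stop("events out of protocol order: CYTC must follow SUCC", call. = FALSE)
  }
  invisible(TRUE)
}

# cumulative trapezoidal integral
cumtrapz <- function(t, y) {
  c(0, cumsum((y[-1L] + y[-length(y)]) / 2 * diff(t)))
}

#' Generate a synthetic oxygraph trace with known true rates
#'
#' Builds the piecewise true flux (plateaus joined by linear ramps, plus
#' drift), adds seeded Gaussian noise, and integrates the sampled flux into a
#' consistent oxygen concentration series using
#' flux x cell_count / (volume x 1000) = -d\[O2\]/dt.  One event is emitted at
#' the start of each state transition.
#'
#' @param spec A [trace_spec()].
#' @return A list with elements `trace` (an [oxygraph_trace] with both series,
#'   flux per 10^6 cells) and `true_rates`, a named vector of the plateau
#'   rates actually simulated (including the cytochrome-c window if present).
#' @export
generate_trace <- function(spec) {
  if (!inherits(spec, "synthetic_trace_spec"))
    abort_field("spec", "must be created by trace_spec()")
  plan <- spec$state_plan
  if (spec$include_cytc) {
    i <- match("S3_PMGS", plan$label)
    cytc <- data.frame(label = "CYTC",
                       rate = plan$rate[i] * (1 + spec$cytc_fractional_increase),
                       duration_s = spec$cytc_duration_s,
                       stringsAsFactors = FALSE)
    plan <- rbind(plan[seq_len(i), ], cytc,
                  plan[-seq_len(i), , drop = FALSE])
    rownames(plan) <- NULL
  }
  n_states <- nrow(plan)
  # state k occupies [start_k, start_k + duration_k]; ramps precede states 2..n
  starts <- numeric(n_states)
  t0 <- 0
  for (k in seq_len(n_states)) {
    if (k > 1L) t0 <- t0 + spec$ramp_s
    starts[k] <- t0
    t0 <- t0 + plan$duration_s[k]
  }
  total <- t0
  time_s <- seq(0, total, by = spec$sample_interval_s)

  true_flux <- vapply(time_s, function(t) {
    for (k in seq_len(n_states)) {
      s <- starts[k]
      e <- s + plan$duration_s[k]
      if (t <= e + 1e-9) {
        if (t >= s - 1e-9 || k == 1L) return(plan$rate[k])
        # inside the ramp from state k-1 into state k
        r0 <- plan$rate[k - 1L]
        frac <- (t - (s - spec$ramp_s)) / spec$ramp_s
        return(r0 + frac * (plan$rate[k] - r0))
      }
    }
    plan$rate[n_states]
  }, numeric(1))
  true_flux <- true_flux + spec$drift_per_s * time_s

  flux <- withr::with_seed(spec$seed, {
    if (spec$noise_rel > 0) {
      true_flux + rnorm(length(true_flux), 0,
                        spec$noise_rel * pmax(abs(true_flux), 1e-12))
    } else if (spec$noise_sd > 0) {
      true_flux + rnorm(length(true_flux), 0, spec$noise_sd)
    } else {
      true_flux
    }
  })

  scale <- spec$cell_count_millions / (spec$chamber_volume_ml * 1000)
  o2 <- spec$o2_start_nmol_per_ml - cumtrapz(time_s, flux) * scale

  # event at the moment each addition is made (start of the ramp)
  ev_time <- c(0, starts[-1L] - spec$ramp_s)
  events <- data.frame(
    time_s = ev_time,
    label = vapply(plan$label, state_event_label, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(events) <- NULL

  trace <- oxygraph_trace(time_s = time_s, o2_nmol_per_ml = o2,
                          flux_pmol_s_per_million = flux, events = events,
                          chamber_volume_ml = spec$chamber_volume_ml,
                          cell_count_millions = spec$cell_count_millions,
                          flux_normalized = TRUE)
  list(trace = trace, true_rates = setNames(plan$rate, plan$label))
}
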