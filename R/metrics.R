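#' Classify a startle response by latency
#'
#' Responses initiated within 15 ms of the stimulus are short-latency C-bends
#' (SLC); slower responses are long-latency C-bends (LLC). The 15 ms boundary
#' is a fixed package convention (tracking software classifies responses
#' upstream in the real assay).
#'
#' @param latency_ms numeric latency vector; must be `NA` exactly where
#'   `responded` is `FALSE`.
#' @param responded logical vector.
#' @param boundary_ms classification boundary (default 15 ms).
#' @return Character vector with values `"SLC"`, `"LLC"`, `"none"`.
#' @export
classify_response <- function(latency_ms, responded, boundary_ms = 15) {
  if (length(latency_ms) != length(responded))
    .stopf("classify_response: argument lengths differ")
  if (any(responded & is.na(latency_ms)))
    .stopf("classify_response: responded rows must carry a latency")
  if (any(!responded & !is.na(latency_ms)))
    .stopf("classify_response: non-responded rows must have NA latency")
  if (any(latency_ms < 0, na.rm = TRUE))
    .stopf("classify_response: negative latency")
  ifelse(!responded, "none", ifelse(latency_ms < boundary_ms, "SLC", "LLC"))
}

# check one-larva event table covers the schedule exactly once
.check_coverage <- function(events, schedule) {
  idx <- schedule$events$index
  dt <- as.data.table(events)
  cov <- dt[, .(miss = paste(setdiff(idx, stimulus_index), collapse = ","),
                dup = anyDuplicated(stimulus_index) > 0L), by = larva_id]
  bad <- cov[miss != "" | dup == TRUE]
  if (nrow(bad))
    .stopf("event table does not cover the schedule once per larva: %s",
           paste(sprintf("%s (missing: %s%s)", bad$larva_id,
                         ifelse(bad$miss == "", "none", bad$miss),
                         ifelse(bad$dup, ", duplicated indices", "")),
                 collapse = "; "))
  invisible(TRUE)
}

#' Apply the non-responder exclusion rule
#'
#' A larva is excluded when it fails to initiate any movement to 60% or more
#' of the stimuli in the assay (ties at exactly 60% are excluded).
#'
#' @param events response-event table covering every schedule index per larva.
#' @param schedule the [assay_schedule] the events were collected under.
#' @return list with character vectors `kept` and `excluded`.
#' @export
exclude_nonresponders <- function(events, schedule) {
  stopifnot(inherits(schedule, "assay_schedule"))
  dt <- as.data.table(events)
  .check_coverage(dt, schedule)
  N <- nrow(schedule$events)
  tab <- dt[, .(n_nonresp = sum(!responded)), by = larva_id]
  excluded <- tab[n_nonresp >= 0.60 * N, larva_id]
  list(kept = setdiff(tab$larva_id, excluded), excluded = excluded)
}

# subset of a one-larva table restricted to a window, with checks
.one_larva_window <- function(events, indices, what) {
  if (length(indices) == 0L) .stopf("%s: empty stimulus index set", what)
  dt <- as.data.table(events)
  if (anyDuplicated(dt$stimulus_index))
    .stopf("%s: expected a single larva's events (duplicated stimulus_index)", what)
  dt[stimulus_index %in% indices]
}

#' Initiation percentage over a stimulus window
#'
#' `100 * (number of matching initiations) / (window size)` for one larva.
#'
#' @param events one larva's response events.
#' @param indices stimulus-index window.
#' @param response_filter `"SLC"` counts SLC initiations only; `"any"` counts
#'   all movement initiations (SLC + LLC).
#' @return percentage in \[0, 100\].
#' @export
initiation_percent <- function(events, indices, response_filter = c("SLC", "any")) {
  response_filter <- match.arg(response_filter)
  w <- .one_larva_window(events, indices, "initiation_percent")
  hits <- if (response_filter == "SLC") sum(w$response_class == "SLC") else sum(w$responded)
  100 * hits / length(indices)
}

#' Habituation percentage
#'
#' `100 * (1 - SLC_rate(late_window) / SLC_rate(first_window))` for one
#' larva. Undefined (`NA`) when the larva initiated no SLC in the first
#' window; such larvae are dropped from group averaging rather than coerced
#' to 0 or 100. Values are not clamped: facilitation yields negative
#' percentages.
#'
#' @param events one larva's response events.
#' @param first_window,late_window disjoint stimulus-index windows.
#' @return percentage (<= 100) or `NA_real_`.
#' @export
habituation_percent <- function(events, first_window, late_window) {
  if (length(intersect(first_window, late_window)))
    .stopf("habituation_percent: windows overlap")
  f <- .one_larva_window(events, first_window, "habituation_percent")
  l <- .one_larva_window(events, late_window, "habituation_percent")
  n_first <- sum(f$response_class == "SLC")
  if (n_first == 0L) return(NA_real_)
  rate_first <- n_first / length(first_window)
  rate_late <- sum(l$response_class == "SLC") / length(late_window)
  100 * (1 - rate_late / rate_first)
}

#' Prepulse-inhibition percentage
#'
#' `100 * (1 - SLC_rate(paired) / SLC_rate(unpaired))` for one larva.
#' Undefined (`NA`) when no SLC was initiated to unpaired high stimuli.
#'
#' @param events one larva's response events.
#' @param paired_high,unpaired_high disjoint stimulus-index windows.
#' @return percentage (<= 100) or `NA_real_`.
#' @export
ppi_percent <- function(events, paired_high, unpaired_high) {
  if (length(intersect(paired_high, unpaired_high)))
    .stopf("ppi_percent: windows overlap")
  p <- .one_larva_window(events, paired_high, "ppi_percent")
  u <- .one_larva_window(events, unpaired_high, "ppi_percent")
  n_unpaired <- sum(u$response_class == "SLC")
  if (n_unpaired == 0L) return(NA_real_)
  rate_u <- n_unpaired / length(unpaired_high)
  rate_p <- sum(p$response_class == "SLC") / length(paired_high)
  100 * (1 - rate_p / rate_u)
}

#' Per-larva kinematic means over a stimulus window
#'
#' Mean turn angle, maximum angular velocity and distance over responded
#' stimuli in the window; all-`NA` when the larva did not respond in the
#' window.
#'
#' @param events one larva's response events.
#' @param indices stimulus-index window.
#' @return Named numeric: `turn_angle_deg`, `max_ang_vel_deg_per_ms`,
#'   `distance_mm`.
#' @export
kinematic_summary <- function(events, indices) {
  w <- .one_larva_window(events, indices, "kinematic_summary")
  w <- w[responded == TRUE]
  if (nrow(w) == 0L)
    return(c(turn_angle_deg = NA_real_, max_ang_vel_deg_per_ms = NA_real_,
             distance_mm = NA_real_))
  c(turn_angle_deg = mean(w$turn_angle_deg),
    max_ang_vel_deg_per_ms = mean(w$max_ang_vel_deg_per_ms),
    distance_mm = mean(w$distance_mm))
}

#' Per-larva behavioral summary table
#'
#' Applies the exclusion rule, then computes every per-larva statistic the
#' assay defines: SLC and any-movement initiation percentages to the low- and
#' high-intensity baseline windows, habituation (two windows for the screen
#' assay, one for the habituation assay), PPI (screen assay only) and
#' kinematic means over the ten baseline high-intensity stimuli. Metrics are
#' computed for excluded larvae too (flagged), but group summaries use kept
#' larvae only.
#'
#' @param events response-event table (any number of larvae).
#' @param schedule the [assay_schedule] used.
#' @return `data.table`, one row per larva, with an `excluded` flag and metric
#'   columns (`NA` where a metric is undefined for that larva).
#' @export
summarize_behavior <- function(events, schedule) {
  stopifnot(inherits(schedule, "assay_schedule"))
  dt <- as.data.table(events)
  .check_coverage(dt, schedule)
  excl <- exclude_nonresponders(dt, schedule)

  if (schedule$name == "screen") {
    w_low <- get_window(schedule, "baseline_low")
    w_high <- get_window(schedule, "baseline_high")
    w_paired <- get_window(schedule, "paired_high")
    hab_windows <- list(habituation_41_50 = get_window(schedule, "hab_41_50"),
                        habituation_51_60 = get_window(schedule, "hab_51_60"))
  } else {
    w_low <- get_window(schedule, "prehab_low")
    w_high <- get_window(schedule, "prehab_high")
    w_paired <- NULL
    hab_windows <- list(habituation = get_window(schedule, "hab_final"))
  }

  slc_count <- function(w)
    dt[stimulus_index %in% w, .(n = sum(response_class == "SLC")), by = larva_id]
  any_count <- function(w)
    dt[stimulus_index %in% w, .(n = sum(responded)), by = larva_id]

  out <- dt[, .(larva_id = unique(larva_id))]
  setkey(out, larva_id)
  add <- function(tab, col, denom) {
    setkey(tab, larva_id)
    out[tab, (col) := 100 * i.n / denom]
  }
  add(slc_count(w_low), "slc_init_low_pct", length(w_low))
  add(slc_count(w_high), "slc_init_high_pct", length(w_high))
  add(any_count(w_low), "any_init_low_pct", length(w_low))
  add(any_count(w_high), "any_init_high_pct", length(w_high))

  first <- slc_count(w_high); setkey(first, larva_id)
  out[first, first_n := i.n]
  for (nm in names(hab_windows)) {
    late <- slc_count(hab_windows[[nm]]); setkey(late, larva_id)
    out[late, late_n := i.n]
    out[, (nm) := ifelse(first_n == 0L, NA_real_,
                         100 * (1 - (late_n / length(hab_windows[[nm]])) /
                                  (first_n / length(w_high))))]
    out[, late_n := NULL]
  }
  if (!is.null(w_paired)) {
    pair <- slc_count(w_paired); setkey(pair, larva_id)
    out[pair, pair_n := i.n]
    out[, ppi_pct := ifelse(first_n == 0L, NA_real_,
                            100 * (1 - (pair_n / length(w_paired)) /
                                     (first_n / length(w_high))))]
    out[, pair_n := NULL]
  }
  out[, first_n := NULL]

  kin <- dt[stimulus_index %in% w_high & responded == TRUE,
            .(kin_turn_angle_deg = mean(turn_angle_deg),
              kin_max_ang_vel = mean(max_ang_vel_deg_per_ms),
              kin_distance_mm = mean(distance_mm)), by = larva_id]
  setkey(kin, larva_id)
  out[kin, `:=`(kin_turn_angle_deg = i.kin_turn_angle_deg,
                kin_max_ang_vel = i.kin_max_ang_vel,
                kin_distance_mm = i.kin_distance_mm)]
  out[, excluded := larva_id %in% excl$excluded]
  setcolorder(out, c("larva_id", "excluded"))
  out[]
}

#' Group mean and SEM per behavioral metric
#'
#' Averages per-larva summaries over non-excluded larvae, skipping undefined
#' (`NA`) per-larva values, and reports the n actually used per metric.
#'
#' @param summaries output of [summarize_behavior()] (optionally with extra
#'   metadata columns, which are ignored).
#' @return `data.table` with columns `metric`, `n`, `mean`, `sem` (`sem` is
#'   `NA` when `n < 2`).
#' @export
group_summary <- function(summaries) {
  dt <- as.data.table(summaries)
  kept <- dt[excluded == FALSE]
  if (nrow(kept) == 0L) .stopf("group_summary: all larvae excluded")
  metrics <- setdiff(names(kept), c("larva_id", "excluded"))
  metrics <- metrics[vapply(kept[, ..metrics], is.numeric, logical(1))]
  res <- lapply(metrics, function(m) {
    v <- kept[[m]]; v <- v[!is.na(v)]
    data.table(metric = m, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_)
  })
  rbindlist(res)
}
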