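#' Assay schedules
#'
#' An assay schedule is the ordered list of acoustic stimuli delivered to each
#' larva, plus the named stimulus-index windows on which every behavioral
#' statistic is defined. Two schedules are used:
#'
#' * **screen** (60 stimuli): a prepulse-inhibition (PPI) phase of stimuli
#'   1-30 cycling low, high, paired low+high at 20 s inter-stimulus intervals
#'   (each type repeated ten times), followed by a habituation phase of 30
#'   high-intensity stimuli (31-60) at 1.5 s ISIs. The paired presentation
#'   occupies one stimulus index; its low prepulse precedes the scored high
#'   pulse by 400 ms (`pulse_time_s - time_s == 0.4`).
#' * **habituation** (50 stimuli): a pre-habituation phase of ten low then ten
#'   high stimuli at 30 s ISIs, followed by 30 high stimuli (21-50) at 3 s
#'   ISIs. This assay is the more sensitive habituation readout.
#'
#' Stimulus indices are 1-based; `time_s` is onset-to-onset time with event 1
#' at 0 s. Construction is pure: repeated calls return identical schedules.
#'
#' @return An object of class `assay_schedule`: a list with elements `name`
#'   (`"screen"` or `"habituation"`), `events` (a `data.frame` with columns
#'   `index`, `time_s`, `intensity`, `phase`, `paired`, `pair_id`,
#'   `pulse_time_s`) and `windows` (named list of integer index vectors).
#'
#' @examples
#' sched <- build_screen_schedule()
#' nrow(sched$events)            # 60
#' get_window(sched, "hab_41_50")
#' @name assay_schedule
NULL

new_assay_schedule <- function(name, events, windows) {
  stopifnot(all(events$index == seq_len(nrow(events))),
            !is.unsorted(events$time_s, strictly = TRUE))
  bad <- vapply(windows, function(w) any(!w %in% events$index), logical(1))
  if (any(bad)) .stopf("window(s) reference unknown stimulus indices: %s",
                       paste(names(windows)[bad], collapse = ", "))
  structure(list(name = name, events = events, windows = windows),
            class = "assay_schedule")
}

#' @rdname assay_schedule
#' @export
build_screen_schedule <- function() {
  idx <- 1:60
  phase <- rep(c("ppi", "habituation"), each = 30L)
  kind <- rep(c("low", "high", "paired"), times = 10L)   # PPI-phase cycle
  intensity <- c(ifelse(kind == "low", "low", "high"), rep("high", 30L))
  paired <- c(kind == "paired", rep(FALSE, 30L))
  pair_id <- rep(NA_integer_, 60L)
  pair_id[paired] <- seq_len(sum(paired))
  time_s <- c((0:29) * 20, 29 * 20 + (1:30) * 1.5)
  pulse_time_s <- time_s + ifelse(paired, 0.4, 0)
  events <- data.frame(index = idx, time_s = time_s, intensity = intensity,
                       phase = phase, paired = paired, pair_id = pair_id,
                       pulse_time_s = pulse_time_s)
  windows <- list(
    baseline_low  = seq(1L, 28L, by = 3L),
    baseline_high = seq(2L, 29L, by = 3L),
    paired_high   = seq(3L, 30L, by = 3L),
    baseline_all  = sort(c(seq(1L, 28L, by = 3L), seq(2L, 29L, by = 3L))),
    hab_41_50     = 41:50,
    hab_51_60     = 51:60
  )
  new_assay_schedule("screen", events, windows)
}

#' @rdname assay_schedule
#' @export
build_habituation_schedule <- function() {
  idx <- 1:50
  intensity <- c(rep("low", 10L), rep("high", 40L))
  phase <- c(rep("prehab", 20L), rep("habituation", 30L))
  time_s <- c((0:19) * 30, 19 * 30 + (1:30) * 3)
  events <- data.frame(index = idx, time_s = time_s, intensity = intensity,
                       phase = phase, paired = FALSE, pair_id = NA_integer_,
                       pulse_time_s = time_s)
  windows <- list(
    prehab_low  = 1:10,
    prehab_high = 11:20,
    hab_final   = 41:50
  )
  new_assay_schedule("habituation", events, windows)
}

#' Look up a named stimulus-index window
#'
#' @param schedule an `assay_schedule`.
#' @param name window name, e.g. `"baseline_high"` or `"hab_41_50"`.
#' @return Integer vector of stimulus indices (a copy; mutating it does not
#'   alter the schedule).
#' @export
get_window <- function(schedule, name) {
  stopifnot(inherits(schedule, "assay_schedule"))
  if (!is.character(name) || length(name) != 1L || !name %in% names(schedule$windows))
    .stopf("unknown window '%s' for the %s schedule; available: %s",
           as.character(name)[1], schedule$name,
           paste(names(schedule$windows), collapse = ", "))
  as.integer(schedule$windows[[name]])
}

#' @export
print.assay_schedule <- function(x, ...) {
  cat(sprintf("<assay_schedule '%s': %d stimuli, windows: %s>\n",
              x$name, nrow(x$events), paste(names(x$windows), collapse = ", ")))
  invisible(x)
}
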