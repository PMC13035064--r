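#' Read and write response-event tables
#'
#' The canonical dialect is UTF-8 TSV with a header row and 1-based stimulus
#' indices; CSV is accepted on read (dialect inferred from content).
#' Validation errors name the offending data rows (1-based, excluding the
#' header).
#'
#' @param events a response-event table (see [simulate_cohort()] for the
#'   schema).
#' @param path file path; `write_events` uses TSV unless the extension is
#'   `.csv`.
#' @return `read_events` returns a validated `data.table`; `write_events`
#'   returns `path` invisibly.
#' @name events_io
NULL

.event_cols <- c("larva_id", "stimulus_index", "responded", "response_class",
                 "latency_ms", "turn_angle_deg", "max_ang_vel_deg_per_ms",
                 "distance_mm")

validate_events <- function(dt) {
  missing_cols <- setdiff(.event_cols, names(dt))
  if (length(missing_cols))
    .stopf("event table missing column(s): %s", paste(missing_cols, collapse = ", "))
  rows <- function(bad) paste(head(which(bad), 5L), collapse = ", ")
  if (any(bad <- is.na(dt$stimulus_index) | dt$stimulus_index < 1 |
            dt$stimulus_index != round(dt$stimulus_index)))
    .stopf("stimulus_index must be a 1-based integer (rows %s)", rows(bad))
  if (!is.logical(dt$responded))
    .stopf("responded must be logical")
  if (any(bad <- !dt$response_class %in% c("SLC", "LLC", "none")))
    .stopf("response_class must be SLC/LLC/none (rows %s)", rows(bad))
  if (any(bad <- dt$responded & (dt$response_class == "none" | is.na(dt$latency_ms) |
                                   is.na(dt$turn_angle_deg))))
    .stopf("responded rows must carry a class, latency and kinematics (rows %s)",
           rows(bad))
  if (any(bad <- !dt$responded & (dt$response_class != "none" | !is.na(dt$latency_ms))))
    .stopf("non-responded rows must have class 'none' and NA latency (rows %s)",
           rows(bad))
  invisible(dt)
}

#' @rdname events_io
#' @export
write_events <- function(events, path) {
  dt <- as.data.table(events)
  validate_events(dt)
  dt <- dt[, .event_cols, with = FALSE]
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fwrite(dt, path, sep = sep)
  invisible(path)
}

#' @rdname events_io
#' @export
read_events <- function(path) {
  dt <- fread(path, colClasses = list(character = "larva_id"))
  if ("responded" %in% names(dt)) dt[, responded := as.logical(responded)]
  for (col in c("latency_ms", "turn_angle_deg", "max_ang_vel_deg_per_ms", "distance_mm"))
    if (col %in% names(dt)) dt[, (col) := as.numeric(get(col))]
  validate_events(dt)
  dt
}

#' Serialize an assay schedule
#'
#' `write_schedule_json` stores the full schedule (events and windows);
#' `write_schedule_tsv` stores the event table only.
#'
#' @param schedule an [assay_schedule].
#' @param path output path.
#' @return the path (writers, invisibly) or the reconstructed schedule
#'   (`read_schedule_json`).
#' @name schedule_io
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "assay_schedule"))
  jsonlite::write_json(list(name = schedule$name, events = schedule$events,
                            windows = schedule$windows),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname schedule_io
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(x$events)
  if (!"pair_id" %in% names(ev)) ev$pair_id <- NA_integer_
  ev$pair_id <- as.integer(ev$pair_id)
  ev <- ev[, c("index", "time_s", "intensity", "phase", "paired", "pair_id",
               "pulse_time_s")]
  new_assay_schedule(x$name, ev, lapply(x$windows, as.integer))
}

#' @rdname schedule_io
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "assay_schedule"))
  fwrite(as.data.table(schedule$events), path, sep = "\t")
  invisible(path)
}

#' Read and write 3D volumes as long-format CSV
#'
#' Text interchange format for stacks of registered ratio volumes: columns
#' `fish_id`, `group`, `x`, `y`, `z`, `value`, one row per voxel per fish.
#'
#' @param stacks list with `group_a` and `group_b` lists of 3D arrays (as
#'   from [simulate_brain_stacks()]).
#' @param path CSV path.
#' @return `read_stacks_csv` returns a list with `group_a`, `group_b`.
#' @name volume_io
#' @export
write_stacks_csv <- function(stacks, path) {
  long_one <- function(vol, fid, grp) {
    dims <- dim(vol)
    g <- as.data.table(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                   z = seq_len(dims[3])))
    g[, `:=`(fish_id = fid, group = grp, value = as.vector(vol))]
    g
  }
  parts <- c(
    lapply(seq_along(stacks$group_a),
           function(i) long_one(stacks$group_a[[i]], sprintf("A%02d", i), "A")),
    lapply(seq_along(stacks$group_b),
           function(i) long_one(stacks$group_b[[i]], sprintf("B%02d", i), "B"))
  )
  out <- rbindlist(parts)
  setcolorder(out, c("fish_id", "group", "x", "y", "z", "value"))
  fwrite(out, path)
  invisible(path)
}

#' @rdname volume_io
#' @export
read_stacks_csv <- function(path) {
  dt <- fread(path)
  dims <- c(max(dt$x), max(dt$y), max(dt$z))
  build <- function(sub) {
    setorder(sub, z, y, x)   # x fastest, matching as.vector() of an array
    array(sub$value, dim = dims)
  }
  list(group_a = lapply(split(dt[group == "A"], by = "fish_id", sorted = TRUE), build),
       group_b = lapply(split(dt[group == "B"], by = "fish_id", sorted = TRUE), build))
}

#' Read a run configuration from JSON
#'
#' A run configuration drives [run_pipeline()]. Required field: `seed`
#' (refused if absent — every run must be reproducible). Recognized fields
#' with defaults: `n_days` (4), `compounds_per_day` (14), `group_size` (32),
#' `dose` (10), `alpha` (0.01), `enrich_alpha` (0.05), `fdr_q` (5e-5),
#' `out_dir` ("startlescreen_run"), `class_sizes` (named list for
#' [make_library()]), `drug_effects` (see [behavior_config()]), plus any
#' [behavior_config()] scalar parameters under `behavior`.
#'
#' @param path JSON file path.
#' @return a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param x a named list of configuration values.
#' @export
as_run_config <- function(x) {
  if (is.null(x$seed)) .stopf("run config: an explicit integer 'seed' is required")
  defaults <- list(n_days = 4L, compounds_per_day = 14L, group_size = 32L,
                   dose = 10, alpha = 0.01, enrich_alpha = 0.05, fdr_q = 5e-5,
                   out_dir = "startlescreen_run", class_sizes = list(),
                   drug_effects = list(), behavior = list())
  cfg <- utils::modifyList(defaults, x)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
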