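#' Behavior model configuration
#'
#' Parameters of the synthetic startle-response generator. Defaults encode the
#' assay's stated design targets (low-intensity stimuli elicit short-latency
#' C-bends, SLCs, on ~25% of presentations; high-intensity on ~75%) plus
#' documented generator choices for everything the assay design does not pin
#' down (any-movement rates, per-genotype habituation capacity and prepulse
#' suppression, latency and kinematic distributions, the non-responder
#' fraction).
#'
#' Genotypes at the two nf1 loci are collapsed into three classes: `wt` (both
#' loci `+/+`), `hom` (both `-/-`), `het` (anything else carrying a mutant
#' allele). Habituation capacity `h_g` orders these wt > het > hom, the
#' qualitative ordering the analysis is designed to detect.
#'
#' During short-ISI habituation stimuli the SLC probability decays as
#' `p0 * ((1 - h_eff) + h_eff * exp(-j / tau))` where `j` counts habituation
#' stimuli from 1 and `h_eff` is the genotype capacity plus any dose-scaled
#' drug shift, clamped to \[0, 1\]. With `tau = 8` the last ten habituation
#' stimuli sit near asymptote, so expected habituation is close to `h_eff`.
#' Paired high pulses use `p_slc_high * (1 - ppi_eff)`. When an SLC does not
#' occur, a long-latency C-bend (LLC) occurs with the conditional probability
#' that makes total movement match `p_any`.
#'
#' @param p_slc_low,p_slc_high baseline SLC probability per stimulus intensity.
#' @param p_any_low,p_any_high baseline any-movement probability per intensity.
#' @param h_g named numeric, habituation capacity in \[0, 1\] for classes
#'   `wt`, `het`, `hom`.
#' @param ppi_g named numeric, prepulse suppression fraction per class.
#' @param tau habituation decay constant, in stimuli (> 0).
#' @param latency list with elements `slc` and `llc`, each
#'   `c(mean, sd, min, max)` in ms. Defaults keep SLC below and LLC above the
#'   15 ms classification boundary.
#' @param kinematics per-class list of `c(angle_mean, angle_sd, vel_mean,
#'   vel_sd, dist_mean, dist_sd)` — turn angle (deg), maximum angular velocity
#'   (deg/ms), distance travelled (mm).
#' @param drug_effects named list: `compound_id -> list(h_shift, ppi_shift,
#'   dose_ref)`. The additive shift applied to a treated larva is
#'   `shift * dose / dose_ref`. Compounds absent from the list are inert.
#' @param nonresponder_fraction fraction of larvae that are systematic
#'   non-responders; their response probabilities are multiplied by
#'   `nonresponder_scale` so they respond to well under 40% of stimuli and are
#'   caught by the exclusion rule.
#' @param nonresponder_scale multiplier applied to non-responder probabilities.
#' @param day_sd SD of an optional Gaussian day effect applied on the logit of
#'   baseline probabilities (0 = off).
#' @return An object of class `behavior_config`.
#' @export
behavior_config <- function(p_slc_low = 0.25, p_slc_high = 0.75,
                            p_any_low = 0.50, p_any_high = 0.95,
                            h_g = c(wt = 0.85, het = 0.55, hom = 0.25),
                            ppi_g = c(wt = 0.65, het = 0.50, hom = 0.35),
                            tau = 8,
                            latency = list(slc = c(mean = 8, sd = 2, min = 2, max = 14),
                                           llc = c(mean = 28, sd = 6, min = 16, max = Inf)),
                            kinematics = list(
                              wt  = c(angle_mean = 115, angle_sd = 20, vel_mean = 28,
                                      vel_sd = 5, dist_mean = 1.6, dist_sd = 0.4),
                              het = c(angle_mean = 108, angle_sd = 20, vel_mean = 26,
                                      vel_sd = 5, dist_mean = 1.4, dist_sd = 0.4),
                              hom = c(angle_mean = 95, angle_sd = 20, vel_mean = 22,
                                      vel_sd = 5, dist_mean = 1.1, dist_sd = 0.4)),
                            drug_effects = list(),
                            nonresponder_fraction = 0.05,
                            nonresponder_scale = 0.25,
                            day_sd = 0) {
  cfg <- structure(list(p_slc_low = p_slc_low, p_slc_high = p_slc_high,
                        p_any_low = p_any_low, p_any_high = p_any_high,
                        h_g = h_g, ppi_g = ppi_g, tau = tau, latency = latency,
                        kinematics = kinematics, drug_effects = drug_effects,
                        nonresponder_fraction = nonresponder_fraction,
                        nonresponder_scale = nonresponder_scale,
                        day_sd = day_sd),
                   class = "behavior_config")
  validate_behavior_config(cfg)
  cfg
}

validate_behavior_config <- function(cfg) {
  probs <- c(cfg$p_slc_low, cfg$p_slc_high, cfg$p_any_low, cfg$p_any_high,
             cfg$h_g, cfg$ppi_g, cfg$nonresponder_fraction, cfg$nonresponder_scale)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    .stopf("behavior_config: all probabilities/fractions must lie in [0, 1]")
  if (!is.numeric(cfg$tau) || length(cfg$tau) != 1L || cfg$tau <= 0)
    .stopf("behavior_config: tau must be a single positive number")
  for (cl in c("slc", "llc"))
    if (cfg$latency[[cl]][["sd"]] < 0)
      .stopf("behavior_config: latency sd for %s must be >= 0", cl)
  for (g in names(cfg$kinematics))
    if (any(cfg$kinematics[[g]][c("angle_sd", "vel_sd", "dist_sd")] < 0))
      .stopf("behavior_config: kinematic sds must be >= 0 (class %s)", g)
  if (!all(c("wt", "het", "hom") %in% names(cfg$h_g)) ||
      !all(c("wt", "het", "hom") %in% names(cfg$ppi_g)))
    .stopf("behavior_config: h_g and ppi_g need entries for wt, het, hom")
  if (cfg$day_sd < 0) .stopf("behavior_config: day_sd must be >= 0")
  invisible(cfg)
}

#' Collapse two-locus nf1 genotypes into model classes
#'
#' @param genotype_a,genotype_b character vectors with values `"+/+"`, `"+/-"`
#'   or `"-/-"`.
#' @return Character vector with values `"wt"`, `"het"` or `"hom"`.
#' @export
genotype_class <- function(genotype_a, genotype_b) {
  ok <- c("+/+", "+/-", "-/-")
  if (any(!genotype_a %in% ok) || any(!genotype_b %in% ok))
    .stopf("genotypes must be one of %s", paste(ok, collapse = ", "))
  ifelse(genotype_a == "+/+" & genotype_b == "+/+", "wt",
         ifelse(genotype_a == "-/-" & genotype_b == "-/-", "hom", "het"))
}

#' Draw offspring genotypes from a two-locus cross
#'
#' Samples genotype pairs from the Punnett expectation of the given cross
#' (see [punnett_expected()]). The default is the screening cross
#' `+/-;-/-  x  -/-;+/-`, whose offspring fall into four mutant classes at
#' 25% each.
#'
#' @param n number of larvae.
#' @param parent1,parent2 two-locus genotype strings, e.g. `"+/-;-/-"`.
#' @return `data.frame` with columns `genotype_a`, `genotype_b`.
#' @export
sample_cross_genotypes <- function(n, parent1 = "+/-;-/-", parent2 = "-/-;+/-") {
  pr <- punnett_expected(parent1, parent2)
  lab <- sample(names(pr), n, replace = TRUE, prob = as.numeric(pr))
  parts <- strsplit(lab, ";", fixed = TRUE)
  data.frame(genotype_a = vapply(parts, `[`, "", 1L),
             genotype_b = vapply(parts, `[`, "", 2L))
}

# effective habituation capacity / PPI suppression for one larva
.dose_shift <- function(compound_id, dose, drug_effects, field) {
  out <- numeric(length(compound_id))
  for (i in seq_along(compound_id)) {
    cid <- compound_id[i]
    if (is.na(cid) || is.null(drug_effects[[cid]])) next
    eff <- drug_effects[[cid]]
    shift <- if (is.null(eff[[field]])) 0 else eff[[field]]
    ref <- if (is.null(eff$dose_ref)) 10 else eff$dose_ref
    d <- if (is.na(dose[i])) ref else dose[i]
    out[i] <- shift * d / ref
  }
  out
}

#' Simulate per-larva startle responses for a cohort
#'
#' For every larva in `metas` and every stimulus in `schedule`, draws a
#' response (SLC / LLC / none) from the Bernoulli model described in
#' [behavior_config()], then draws a latency for responders and kinematics per
#' genotype class. Identical `(schedule, metas, config, seed)` give identical
#' output.
#'
#' @param schedule an [assay_schedule].
#' @param metas `data.frame` with columns `larva_id`, `genotype_a`,
#'   `genotype_b` and optionally `compound_id`, `dose` (µM), `day_id`,
#'   `group_id`.
#' @param config a [behavior_config()].
#' @param seed integer seed.
#' @return A `data.table` of response events with columns `larva_id`,
#'   `stimulus_index`, `responded`, `response_class`, `latency_ms`,
#'   `turn_angle_deg`, `max_ang_vel_deg_per_ms`, `distance_mm`. Kinematic and
#'   latency fields are `NA` on non-response rows.
#' @export
simulate_cohort <- function(schedule, metas, config = behavior_config(), seed = 1L) {
  stopifnot(inherits(schedule, "assay_schedule"))
  validate_behavior_config(config)
  if (nrow(metas) == 0L) .stopf("simulate_cohort: metas must be non-empty")
  if (anyDuplicated(metas$larva_id)) .stopf("simulate_cohort: duplicated larva_id")
  set.seed(as.integer(seed))

  ev <- schedule$events
  n <- nrow(metas)
  S <- nrow(ev)
  cls <- genotype_class(metas$genotype_a, metas$genotype_b)
  compound <- if ("compound_id" %in% names(metas)) as.character(metas$compound_id) else rep(NA_character_, n)
  dose <- if ("dose" %in% names(metas)) as.numeric(metas$dose) else rep(NA_real_, n)
  h_eff <- .clamp(unname(config$h_g[cls]) +
                    .dose_shift(compound, dose, config$drug_effects, "h_shift"))
  ppi_eff <- .clamp(unname(config$ppi_g[cls]) +
                      .dose_shift(compound, dose, config$drug_effects, "ppi_shift"))

  hab <- ev$phase == "habituation"
  j <- integer(S); j[hab] <- seq_len(sum(hab))
  decay <- ifelse(hab, exp(-j / config$tau), NA_real_)

  # n x S probability matrices
  p_slc <- matrix(0, n, S)
  p_any <- matrix(0, n, S)
  for (s in seq_len(S)) {
    if (ev$intensity[s] == "low") {
      p_slc[, s] <- config$p_slc_low
      p_any[, s] <- config$p_any_low
    } else {
      p_any[, s] <- config$p_any_high
      if (ev$paired[s]) {
        p_slc[, s] <- config$p_slc_high * (1 - ppi_eff)
      } else if (hab[s]) {
        p_slc[, s] <- config$p_slc_high * ((1 - h_eff) + h_eff * decay[s])
      } else {
        p_slc[, s] <- config$p_slc_high
      }
    }
  }

  if (config$day_sd > 0 && "day_id" %in% names(metas)) {
    days <- unique(metas$day_id)
    eps <- stats::setNames(rnorm(length(days), 0, config$day_sd), days)
    shift <- eps[metas$day_id]
    adj <- function(p) {
      inb <- p > 0 & p < 1
      p[inb] <- plogis(qlogis(p[inb]) + shift[row(p)[inb]])
      p
    }
    p_slc <- adj(p_slc); p_any <- adj(p_any)
  }

  nonresp <- runif(n) < config$nonresponder_fraction
  if (any(nonresp)) {
    p_slc[nonresp, ] <- p_slc[nonresp, , drop = FALSE] * config$nonresponder_scale
    p_any[nonresp, ] <- p_any[nonresp, , drop = FALSE] * config$nonresponder_scale
  }
  p_any <- pmax(p_any, p_slc)

  slc <- matrix(runif(n * S), n, S) < p_slc
  p_llc_cond <- ifelse(p_slc < 1, (p_any - p_slc) / (1 - p_slc), 0)
  llc <- !slc & (matrix(runif(n * S), n, S) < p_llc_cond)

  responded <- as.vector(t(slc | llc))                 # larva-major order
  is_slc <- as.vector(t(slc))
  response_class <- ifelse(!responded, "none", ifelse(is_slc, "SLC", "LLC"))

  latency <- rep(NA_real_, n * S)
  i_slc <- which(response_class == "SLC")
  i_llc <- which(response_class == "LLC")
  ls <- config$latency$slc; ll <- config$latency$llc
  latency[i_slc] <- .rtnorm(length(i_slc), ls[["mean"]], ls[["sd"]], ls[["min"]], ls[["max"]])
  latency[i_llc] <- .rtnorm(length(i_llc), ll[["mean"]], ll[["sd"]], ll[["min"]], ll[["max"]])

  kin_cls <- rep(cls, each = S)
  angle <- vel <- dist <- rep(NA_real_, n * S)
  for (g in unique(cls)) {
    k <- config$kinematics[[g]]
    idx <- which(responded & kin_cls == g)
    angle[idx] <- .rtnorm(length(idx), k[["angle_mean"]], k[["angle_sd"]], lower = 0)
    vel[idx] <- .rtnorm(length(idx), k[["vel_mean"]], k[["vel_sd"]], lower = 0)
    dist[idx] <- .rtnorm(length(idx), k[["dist_mean"]], k[["dist_sd"]], lower = 0)
  }

  data.table(
    larva_id = rep(as.character(metas$larva_id), each = S),
    stimulus_index = rep(ev$index, times = n),
    responded = responded,
    response_class = response_class,
    latency_ms = latency,
    turn_angle_deg = angle,
    max_ang_vel_deg_per_ms = vel,
    distance_mm = dist
  )
}

#' Simulate one experimental screening day
#'
#' Emits `n_compounds` treated groups plus exactly two non-treated control
#' groups of `group_size` larvae each, genotypes drawn at the screening
#' cross's expected 25%-each ratios, and simulates the full screen assay for
#' every larva in one reproducible draw.
#'
#' @param n_compounds number of treated groups (compounds tested that day).
#' @param group_size larvae per group (32 in the screen design).
#' @param config a [behavior_config()]; per-compound effects come from its
#'   `drug_effects`.
#' @param seed integer seed.
#' @param day_id day label.
#' @param compound_ids optional compound ids (defaults `C001`, ...).
#' @param dose treatment dose in µM applied to every treated group.
#' @param schedule assay schedule (defaults to the screen schedule).
#' @return list with `meta` (per-larva metadata, including `role` =
#'   `"treated"`/`"control"`) and `events` (response event `data.table`).
#' @export
simulate_screen_day <- function(n_compounds, group_size = 32L,
                                config = behavior_config(), seed = 1L,
                                day_id = "day01", compound_ids = NULL,
                                dose = 10, schedule = build_screen_schedule()) {
  if (group_size < 1L) .stopf("simulate_screen_day: group_size must be >= 1")
  if (n_compounds < 0L) .stopf("simulate_screen_day: n_compounds must be >= 0")
  if (is.null(compound_ids)) compound_ids <- sprintf("C%03d", seq_len(n_compounds))
  stopifnot(length(compound_ids) == n_compounds)
  set.seed(as.integer(seed))

  groups <- c(compound_ids, "control1", "control2")
  roles <- c(rep("treated", n_compounds), "control", "control")
  n_tot <- length(groups) * group_size
  geno <- sample_cross_genotypes(n_tot)
  meta <- data.table(
    larva_id = sprintf("%s_%s_L%02d", day_id, rep(groups, each = group_size),
                       rep(seq_len(group_size), times = length(groups))),
    genotype_a = geno$genotype_a, genotype_b = geno$genotype_b,
    compound_id = rep(c(compound_ids, NA_character_, NA_character_), each = group_size),
    dose = rep(c(rep(dose, n_compounds), NA_real_, NA_real_), each = group_size),
    day_id = day_id,
    group_id = sprintf("%s_%s", day_id, rep(groups, each = group_size)),
    role = rep(roles, each = group_size)
  )
  events <- simulate_cohort(schedule, meta, config,
                            seed = sample.int(.Machine$integer.max, 1L))
  list(meta = meta, events = events)
}

#' Simulate a multi-day screen
#'
#' Runs [simulate_screen_day()] for `n_days` days with distinct compounds per
#' day, deriving per-day seeds from the master seed.
#'
#' @param n_days number of experimental days.
#' @param compounds_per_day compounds tested per day.
#' @param group_size larvae per group.
#' @param config a [behavior_config()].
#' @param seed master seed.
#' @param dose treatment dose (µM).
#' @return list with pooled `meta` and `events` tables.
#' @export
simulate_screen <- function(n_days, compounds_per_day, group_size = 32L,
                            config = behavior_config(), seed = 1L, dose = 10) {
  set.seed(as.integer(seed))
  day_seeds <- sample.int(.Machine$integer.max, n_days)
  sched <- build_screen_schedule()
  metas <- vector("list", n_days); events <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    ids <- sprintf("C%04d", (d - 1L) * compounds_per_day + seq_len(compounds_per_day))
    day <- simulate_screen_day(compounds_per_day, group_size, config,
                               seed = day_seeds[d],
                               day_id = sprintf("day%02d", d),
                               compound_ids = ids, dose = dose,
                               schedule = sched)
    metas[[d]] <- day$meta; events[[d]] <- day$events
  }
  list(meta = rbindlist(metas), events = rbindlist(events))
}

#' Generate a compound library with target-class annotations
#'
#' @param n_compounds library size.
#' @param class_sizes named list/vector: target class -> number of compounds;
#'   the remainder is labelled `"other"`.
#' @param seed integer seed.
#' @return `data.table` with columns `compound_id`, `target_class`.
#' @export
make_library <- function(n_compounds, class_sizes = list(), seed = 1L) {
  sizes <- unlist(class_sizes)
  if (length(sizes) && sum(sizes) > n_compounds)
    .stopf("make_library: class sizes (%d) exceed library size (%d)",
           sum(sizes), n_compounds)
  set.seed(as.integer(seed))
  ids <- sprintf("C%04d", seq_len(n_compounds))
  classes <- rep("other", n_compounds)
  if (length(sizes)) {
    assign_to <- sample.int(n_compounds, sum(sizes))
    classes[assign_to] <- rep(names(sizes), times = sizes)
  }
  data.table(compound_id = ids, target_class = classes)
}

#' Spherical ROI mask
#'
#' @param shape integer vector of 3 volume dimensions.
#' @param center numeric length-3 voxel coordinates.
#' @param radius radius in voxels.
#' @return Logical 3D array.
#' @export
blob_mask <- function(shape, center, radius) {
  stopifnot(length(shape) == 3L, length(center) == 3L, radius > 0)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = shape)
}

#' Simulate registered brain ratio volumes with planted group differences
#'
#' Group A volumes are baseline 1.0 plus Gaussian noise; group B volumes add
#' the stated shift inside each effect ROI. Stands in for registered
#' pERK/tERK ratio stacks; the true masks are returned for recovery tests.
#'
#' @param shape integer vector of 3 volume dimensions.
#' @param n_per_group stacks per group (>= 3).
#' @param effect_rois list of `list(mask = <logical array>, shift = <number>)`.
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return list with `group_a`, `group_b` (lists of 3D arrays) and `masks`.
#' @export
simulate_brain_stacks <- function(shape, n_per_group = 18L, effect_rois = list(),
                                  noise_sd = 0.1, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (n_per_group < 3L) .stopf("simulate_brain_stacks: n_per_group must be >= 3")
  for (roi in effect_rois) {
    if (!identical(dim(roi$mask), as.integer(shape)))
      .stopf("simulate_brain_stacks: effect ROI mask does not match volume shape")
  }
  set.seed(as.integer(seed))
  nv <- prod(shape)
  delta <- array(0, dim = shape)
  for (roi in effect_rois) delta[roi$mask] <- delta[roi$mask] + roi$shift
  draw <- function(add) array(rnorm(nv, 1, noise_sd), dim = shape) + add
  group_a <- lapply(seq_len(n_per_group), function(i) draw(0))
  group_b <- lapply(seq_len(n_per_group), function(i) draw(delta))
  list(group_a = group_a, group_b = group_b,
       masks = lapply(effect_rois, `[[`, "mask"))
}
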