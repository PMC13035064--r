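sched <- build_screen_schedule()

test_that("configuration is validated", {
  expect_error(behavior_config(p_slc_low = 1.2), "\\[0, 1\\]")
  expect_error(behavior_config(tau = -1), "tau")
  expect_error(behavior_config(nonresponder_fraction = -0.1), "\\[0, 1\\]")
  expect_s3_class(behavior_config(), "behavior_config")
})

test_that("simulate_cohort is deterministic and schema-valid", {
  metas <- make_metas(20)
  a <- simulate_cohort(sched, metas, behavior_config(), seed = 11)
  b <- simulate_cohort(sched, metas, behavior_config(), seed = 11)
  expect_identical(a, b)
  c <- simulate_cohort(sched, metas, behavior_config(), seed = 12)
  expect_false(identical(a, c))

  # response_class none <=> responded FALSE <=> kinematics/latency absent
  expect_identical(a$responded, a$response_class != "none")
  expect_identical(is.na(a$latency_ms), !a$responded)
  expect_identical(is.na(a$turn_angle_deg), !a$responded)
  # latency classes respect the 15 ms boundary by construction
  expect_true(all(a$latency_ms[a$response_class == "SLC"] < 15))
  expect_true(all(a$latency_ms[a$response_class == "LLC"] >= 16))
  expect_identical(
    classify_response(a$latency_ms, a$responded), a$response_class)
})

test_that("zero habituation capacity yields no decay; full PPI suppresses all paired SLCs", {
  cfg0 <- behavior_config(h_g = c(wt = 0, het = 0, hom = 0),
                          nonresponder_fraction = 0)
  ev <- simulate_cohort(sched, make_metas(400), cfg0, seed = 5)
  summ <- summarize_behavior(ev, sched)
  hab <- summ$habituation_41_50[!is.na(summ$habituation_41_50) & !summ$excluded]
  expect_lt(abs(mean(hab)), 4)   # expectation ~0 up to ratio-statistic noise

  cfg1 <- behavior_config(ppi_g = c(wt = 1, het = 1, hom = 1),
                          nonresponder_fraction = 0)
  ev1 <- simulate_cohort(sched, make_metas(100), cfg1, seed = 5)
  paired <- ev1[ev1$stimulus_index %in% get_window(sched, "paired_high"), ]
  expect_equal(sum(paired$response_class == "SLC"), 0L)
})

test_that("habituation increases monotonically with dose of a capacity-restoring drug", {
  eff <- list(DRUG = list(h_shift = 0.5, dose_ref = 10))
  cfg <- behavior_config(drug_effects = eff, nonresponder_fraction = 0)
  means <- vapply(c(0, 3, 10), function(d) {
    metas <- make_metas(600, genotype_a = "-/-", genotype_b = "-/-")
    metas$compound_id <- "DRUG"; metas$dose <- d
    ev <- simulate_cohort(sched, metas, cfg, seed = 100 + d)
    s <- summarize_behavior(ev, sched)
    mean(s$habituation_41_50[!s$excluded], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulated genotype frequencies match the Punnett expectation", {
  set.seed(42)
  g <- sample_cross_genotypes(4000)
  counts <- table(paste(g$genotype_a, g$genotype_b, sep = ";"))
  expected <- punnett_expected("+/-;-/-", "-/-;+/-")
  expect_setequal(names(counts), names(expected))
  chi <- stats::chisq.test(as.numeric(counts[names(expected)]),
                           p = as.numeric(expected))
  expect_gt(chi$p.value, 0.001)
})

test_that("nonresponder larvae respond to fewer than 40% of stimuli and are excluded", {
  cfg <- behavior_config(nonresponder_fraction = 1, nonresponder_scale = 0.25)
  ev <- simulate_cohort(sched, make_metas(50), cfg, seed = 9)
  resp_rate <- tapply(ev$responded, ev$larva_id, mean)
  expect_true(mean(resp_rate < 0.40) > 0.95)
  excl <- exclude_nonresponders(ev, sched)
  expect_gt(length(excl$excluded), 45)
})

test_that("simulate_screen_day emits treated plus exactly two control groups", {
  day <- simulate_screen_day(3, group_size = 8, seed = 2, day_id = "d1")
  expect_equal(sum(day$meta$role == "control"), 16L)
  expect_equal(length(unique(day$meta$group_id[day$meta$role == "control"])), 2L)
  expect_equal(length(unique(day$meta$group_id[day$meta$role == "treated"])), 3L)
  expect_true(all(is.na(day$meta$dose[day$meta$role == "control"])))
  expect_equal(nrow(day$events), nrow(day$meta) * 60L)

  none <- simulate_screen_day(0, group_size = 4, seed = 2)
  expect_equal(unique(none$meta$role), "control")

  again <- simulate_screen_day(3, group_size = 8, seed = 2, day_id = "d1")
  expect_identical(day, again)
})

test_that("make_library assigns classes reproducibly and validates sizes", {
  lib <- make_library(100, list(retinoid = 10, adrenergic = 5), seed = 3)
  expect_equal(nrow(lib), 100L)
  expect_equal(sum(lib$target_class == "retinoid"), 10L)
  expect_equal(sum(lib$target_class == "other"), 85L)
  expect_identical(lib, make_library(100, list(retinoid = 10, adrenergic = 5), seed = 3))
  expect_true(all(make_library(10, list(), seed = 1)$target_class == "other"))
  expect_error(make_library(10, list(big = 11), seed = 1), "exceed")
})

test_that("simulate_brain_stacks plants shifts inside the stated ROIs", {
  shape <- c(8L, 8L, 6L)
  blob <- blob_mask(shape, c(4, 4, 3), 2)
  st <- simulate_brain_stacks(shape, 4, list(list(mask = blob, shift = 0.5)),
                              noise_sd = 0.05, seed = 7)
  expect_length(st$group_a, 4)
  expect_identical(st, simulate_brain_stacks(shape, 4, list(list(mask = blob, shift = 0.5)),
                                             noise_sd = 0.05, seed = 7))
  mean_b <- Reduce(`+`, st$group_b) / 4
  expect_gt(mean(mean_b[blob]) - mean(mean_b[!blob]), 0.4)
  # null case: groups exchangeable
  nul <- simulate_brain_stacks(shape, 4, list(), noise_sd = 0.05, seed = 7)
  expect_lt(abs(mean(unlist(nul$group_a)) - mean(unlist(nul$group_b))), 0.01)
  expect_error(simulate_brain_stacks(shape, 4,
                                     list(list(mask = array(TRUE, c(2, 2, 2)), shift = 1))),
               "shape")
  expect_error(simulate_brain_stacks(shape, 2), ">= 3")
})
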