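sched <- build_screen_schedule()
hab_sched <- build_habituation_schedule()

test_that("classify_response applies the latency boundary and contracts", {
  expect_equal(classify_response(c(8, 28, NA), c(TRUE, TRUE, FALSE)),
               c("SLC", "LLC", "none"))
  expect_equal(classify_response(14.99, TRUE), "SLC")
  expect_equal(classify_response(15, TRUE), "LLC")
  expect_error(classify_response(-1, TRUE), "negative")
  expect_error(classify_response(NA, TRUE), "latency")
  expect_error(classify_response(8, FALSE), "NA latency")
})

test_that("exclusion rule: 60% or more non-responses excludes, below keeps", {
  all_resp <- make_larva_events(sched, slc_idx = 1:60, larva_id = "K")
  at_60 <- make_larva_events(sched, slc_idx = 1:24, larva_id = "X")   # 36/60 = 60%
  at_58 <- make_larva_events(sched, slc_idx = 1:25, larva_id = "Y")   # 35/60 = 58.3%
  ev <- rbind(all_resp, at_60, at_58)
  res <- exclude_nonresponders(ev, sched)
  expect_setequal(res$kept, c("K", "Y"))
  expect_equal(res$excluded, "X")
  # missing stimuli are an error naming the gaps
  expect_error(exclude_nonresponders(all_resp[-3, ], sched), "missing: 3")
})

test_that("initiation percentage is exact counting", {
  w <- get_window(sched, "baseline_all")  # 20 baseline stimuli
  ev <- make_larva_events(sched, slc_idx = c(1, 2, 4, 5, 7))
  expect_equal(initiation_percent(ev, w, "SLC"), 25)
  ev0 <- make_larva_events(sched)
  expect_equal(initiation_percent(ev0, w, "SLC"), 0)
  # 4 SLC + 6 LLC over a 10-stimulus window with filter "any" -> 100%
  w10 <- get_window(sched, "baseline_high")
  ev2 <- make_larva_events(sched, slc_idx = w10[1:4], llc_idx = w10[5:10])
  expect_equal(initiation_percent(ev2, w10, "any"), 100)
  expect_equal(initiation_percent(ev2, w10, "SLC"), 40)
  expect_error(initiation_percent(ev2, integer(0)), "empty")
})

test_that("habituation percentage matches hand-computed fixtures", {
  first <- get_window(sched, "baseline_high")
  late <- get_window(sched, "hab_41_50")
  # 10/10 then 0/10 -> 100%
  expect_equal(habituation_percent(make_larva_events(sched, slc_idx = first),
                                   first, late), 100)
  # 8/10 then 2/10 -> 1 - 0.2/0.8 = 75%
  expect_equal(habituation_percent(
    make_larva_events(sched, slc_idx = c(first[1:8], late[1:2])), first, late), 75)
  # 5/10 then 8/10 -> 1 - 1.6 = -60% (facilitation, not clamped)
  expect_equal(habituation_percent(
    make_larva_events(sched, slc_idx = c(first[1:5], late[1:8])), first, late), -60)
  # zero first-window SLCs -> undefined
  expect_true(is.na(habituation_percent(
    make_larva_events(sched, slc_idx = late[1:3]), first, late)))
  expect_error(habituation_percent(make_larva_events(sched), first, first), "overlap")
})

test_that("PPI percentage matches hand-computed fixtures", {
  unpaired <- get_window(sched, "baseline_high")
  paired <- get_window(sched, "paired_high")
  expect_equal(ppi_percent(make_larva_events(sched, slc_idx = unpaired),
                           paired, unpaired), 100)
  expect_equal(ppi_percent(
    make_larva_events(sched, slc_idx = c(paired[1:3], unpaired[1:6])),
    paired, unpaired), 50)
  expect_equal(ppi_percent(
    make_larva_events(sched, slc_idx = c(paired[1:6], unpaired[1:6])),
    paired, unpaired), 0)
  expect_true(is.na(ppi_percent(
    make_larva_events(sched, slc_idx = paired[1:2]), paired, unpaired)))
  expect_error(ppi_percent(make_larva_events(sched), paired, paired), "overlap")
})

test_that("kinematic summary averages responded stimuli only", {
  w <- get_window(sched, "baseline_high")
  ev <- make_larva_events(sched, slc_idx = w[1:2])
  ev[stimulus_index == w[1], turn_angle_deg := 100]
  ev[stimulus_index == w[2], turn_angle_deg := 140]
  k <- kinematic_summary(ev, w)
  expect_equal(unname(k["turn_angle_deg"]), 120)
  # window with no responses -> all NA
  k0 <- kinematic_summary(make_larva_events(sched), w)
  expect_true(all(is.na(k0)))
})

test_that("group_summary averages defined values and reports n", {
  s <- data.table(larva_id = c("a", "b", "c", "d"),
                  excluded = c(FALSE, FALSE, FALSE, TRUE),
                  habituation = c(100, 50, NA, 0))
  g <- group_summary(s)
  row <- g[g$metric == "habituation", ]
  expect_equal(row$mean, 75)       # NA skipped, excluded larva ignored
  expect_equal(row$sem, 25)
  expect_equal(row$n, 2L)
  one <- group_summary(data.table(larva_id = "a", excluded = FALSE, m = 5))
  expect_true(is.na(one$sem) && one$n == 1L)
  expect_error(group_summary(s[excluded == TRUE]), "all larvae excluded")
})

test_that("summarize_behavior agrees with the per-larva operations and is row-order invariant", {
  metas <- make_metas(25)
  ev <- simulate_cohort(sched, metas, behavior_config(nonresponder_fraction = 0.2),
                        seed = 77)
  summ <- summarize_behavior(ev, sched)
  first <- get_window(sched, "baseline_high")
  for (lid in sample(metas$larva_id, 10)) {
    one <- ev[larva_id == lid]
    row <- summ[larva_id == lid]
    expect_equal(row$slc_init_low_pct,
                 initiation_percent(one, get_window(sched, "baseline_low"), "SLC"))
    expect_equal(row$any_init_high_pct, initiation_percent(one, first, "any"))
    expect_equal(row$habituation_41_50,
                 habituation_percent(one, first, get_window(sched, "hab_41_50")))
    expect_equal(row$habituation_51_60,
                 habituation_percent(one, first, get_window(sched, "hab_51_60")))
    expect_equal(row$ppi_pct,
                 ppi_percent(one, get_window(sched, "paired_high"), first))
    expect_equal(unname(row$kin_turn_angle_deg),
                 unname(kinematic_summary(one, first)["turn_angle_deg"]))
  }
  # shuffling event rows leaves the summary unchanged
  shuffled <- ev[sample(nrow(ev))]
  summ2 <- summarize_behavior(shuffled, sched)
  setkey(summ, larva_id); setkey(summ2, larva_id)
  expect_equal(as.data.frame(summ), as.data.frame(summ2))
})

test_that("habituation-assay summaries use the pre-habituation windows", {
  first <- get_window(hab_sched, "prehab_high")
  late <- get_window(hab_sched, "hab_final")
  ev <- make_larva_events(hab_sched, slc_idx = c(first[1:8], late[1:2]))
  summ <- summarize_behavior(ev, hab_sched)
  expect_equal(summ$habituation, 75)
  expect_false("ppi_pct" %in% names(summ))
})

test_that("group-mean habituation matches the exact ratio-statistic expectation", {
  # single genotype class, no non-responders: X ~ Bin(10, 0.75) on the
  # baseline high window; late-window per-stimulus probabilities follow the
  # exponential decay at tau = 8, habituation stimuli j = 11..20
  cfg <- behavior_config(nonresponder_fraction = 0)
  h <- cfg$h_g[["het"]]
  p_late <- cfg$p_slc_high * ((1 - h) + h * exp(-(11:20) / cfg$tau))
  oracle <- hab_expectation_oracle(cfg$p_slc_high, p_late)
  ev <- simulate_cohort(sched, make_metas(3000), cfg, seed = 2024)
  summ <- summarize_behavior(ev, sched)
  kept <- summ[excluded == FALSE & !is.na(habituation_41_50)]
  sem <- sd(kept$habituation_41_50) / sqrt(nrow(kept))
  expect_lt(abs(mean(kept$habituation_41_50) - oracle), 4 * sem + 0.5)
})
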