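# Slot construction, QA reservation, packing, indicators, block baseline.

test_that("a 10-h day tiles into ten 60-slot blocks", {
  day <- build_day("08:00", "18:00", 60)
  expect_equal(nrow(day$blocks), 10)
  expect_true(all(day$blocks$length == 60))
  expect_equal(total_minutes(day), 600)
  expect_equal(free_minutes(day), 600)

  one <- build_day("08:00", "09:00")
  expect_equal(nrow(one$blocks), 1)
  expect_equal(one$blocks$length, 60)

  expect_error(build_day("08:00", "08:00"), "after open")
  # indivisible window: remainder forms a logged short final block
  short <- build_day("08:00", "17:30", 60)
  expect_equal(nrow(short$blocks), 10)
  expect_equal(short$blocks$length[10], 30)
  expect_match(short$log, "not divisible")
})

test_that("daily QA reserves the head of the first block", {
  day <- build_day("08:00", "18:00")
  after <- reserve_daily_qa(day, 20)
  expect_equal(free_minutes(after), 580)
  expect_true(all(after$occupant[1:20] == "daily_qa"))
  expect_true(all(is.na(after$occupant[21:600])))
  expect_identical(reserve_daily_qa(day, 0), day)
  expect_error(reserve_daily_qa(day, 61), "\\[10, 20\\]")
  expect_error(reserve_daily_qa(day, 5), "\\[10, 20\\]")
  expect_error(reserve_daily_qa(after, 20), "insufficient room")
  # a 15-min first block cannot hold a 20-min QA
  tiny <- build_day("08:00", "08:15", 15)
  expect_error(reserve_daily_qa(tiny, 20), "insufficient room")
})

test_that("first-fit packs appointments into the earliest adequate run", {
  day <- reserve_daily_qa(build_day("08:00", "18:00"), 20)
  day <- schedule_appointment(day, "P1", 18 * 60)
  a <- day$appointments
  expect_true(a$assigned[1])
  expect_equal(a$start_minute[1], 20)
  expect_equal(a$required_units[1], 18)
  expect_true(all(day$occupant[21:38] == "P1"))

  # no spanning: a 61-min appointment cannot fit a 60-min block
  day61 <- schedule_appointment(build_day("08:00", "18:00"), "P2", 61 * 60)
  expect_false(day61$appointments$assigned[1])
  span <- schedule_appointment(build_day("08:00", "18:00"), "P2", 61 * 60,
                               allow_spanning = TRUE)
  expect_true(span$appointments$assigned[1])

  # exact packing: two 30-min appointments fill one block completely
  one <- build_day("08:00", "09:00")
  one <- schedule_appointment(one, "A", 30 * 60)
  one <- schedule_appointment(one, "B", 30 * 60)
  expect_equal(free_minutes(one), 0)
  expect_true(all(one$appointments$assigned))

  # durations are ceiled to whole unit slots
  frac <- schedule_appointment(build_day("08:00", "09:00"), "C", 61)
  expect_equal(frac$appointments$required_units[1], 2)

  # best-fit prefers the tightest adequate run
  d <- build_day("08:00", "10:00")
  d <- schedule_appointment(d, "fill", 50 * 60)       # leaves 10 in block 1
  d <- schedule_appointment(d, "tight", 10 * 60, policy = "best_fit")
  expect_equal(d$appointments$start_minute[2], 50)
})

test_that("state indicators are total and follow the threshold precedence", {
  # helper: occupy the first k minutes of a one-block day
  .occupy_test <- function(d, k) {
    d$occupant[seq_len(k)] <- "x"
    d$occ_kind[seq_len(k)] <- "appointment"
    d
  }
  d <- build_day("08:00", "09:00")
  expect_equal(slot_state(d, 1)$color, "green")
  for (free in 0:60) {
    di <- if (free < 60) .occupy_test(d, 60 - free) else d
    st <- slot_state(di, 1)
    expect_equal(st$free_minutes, free)
    expected <- if (free < 5) "red" else if (free < 10) "orange"
    else if (free > 20) "green" else "orange"
    expect_equal(st$color, expected)
  }
  st25 <- slot_state(.occupy_test(d, 35), 1)
  expect_equal(st25$color, "green")
  expect_equal(slot_state(.occupy_test(d, 57), 1)$color, "red")
  expect_equal(slot_state(.occupy_test(d, 45), 1)$color, "orange")
  expect_error(slot_state(d, 1, thresholds = c(5, 10, 20)),
               "strictly decreasing")
  expect_error(slot_state(d, 99), "no block")
})

test_that("non-treatment tasks obey durations and placement rules", {
  # dosimetry verification (5-8 min) fits an 8-min gap
  d <- build_day("08:00", "09:00")
  d <- schedule_appointment(d, "P1", 52 * 60)  # 8 free minutes remain
  d <- assign_nontreatment_task(d, "dosimetry_verification", 6)
  tk <- d$tasks[d$tasks$category == "dosimetry_verification", ]
  expect_true(tk$assigned)
  expect_equal(tk$start_minute, 52)

  expect_error(assign_nontreatment_task(d, "dosimetry_verification", 9),
               "\\[5, 8\\]")
  expect_error(assign_nontreatment_task(d, "espresso_break", 5),
               "unknown task category")

  # weekend-only categories are rejected from workdays, reported not thrown
  wd <- build_day("08:00", "18:00")
  wd <- assign_nontreatment_task(wd, "routine_maintenance", 75)
  expect_false(wd$tasks$assigned[1])
  expect_equal(wd$tasks$reason[1], "weekend_only")
  we <- build_day("08:00", "18:00", weekend = TRUE)
  we <- assign_nontreatment_task(we, "routine_maintenance", 75)
  expect_true(we$tasks$assigned[1])
  expect_error(assign_nontreatment_task(we, "routine_maintenance", 95),
               "\\[60, 90\\]")
})

test_that("the block baseline books whole fixed slots and caps capacity", {
  day <- build_day("08:00", "18:00")
  apps <- random_appointments(41, 5 * 60, 15 * 60, seed = 1)
  blk <- block_baseline_schedule(day, apps, 60, 4)
  expect_equal(blk$n_fixed_slots, 40)
  expect_equal(blk$fixed_slot_length, 15)
  expect_equal(sum(blk$appointments$assigned), 40)
  expect_false(blk$appointments$assigned[41])

  # a 5-min appointment still burns a full 15-min slot
  one <- block_baseline_schedule(build_day("08:00", "09:00"),
                                 data.frame(patient_id = "P1",
                                            duration_s = 5 * 60), 60, 4)
  expect_equal(occupied_minutes(one), 15)
  rep1 <- utilization_report(one)
  expect_equal(rep1$internal_idle_minutes, 10)

  none <- block_baseline_schedule(build_day("08:00", "18:00"),
                                  random_appointments(0, 300, 300, 1), 60, 4)
  expect_equal(free_minutes(none), 600)
  expect_error(block_baseline_schedule(day, apps, 50, 4), "not divisible")
})

test_that("utilization reports conserve minutes and count outcomes", {
  empty <- build_day("08:00", "18:00")
  rep0 <- utilization_report(empty)
  expect_equal(rep0$occupied_minutes, 0)
  expect_equal(rep0$free_minutes, 600)

  for (seed in 1:25) {
    day <- reserve_daily_qa(build_day("08:00", "18:00"), 20)
    apps <- random_appointments(30 + seed, 4 * 60, 20 * 60, seed = seed)
    day <- schedule_cohort(day, apps)
    r <- utilization_report(day)
    expect_equal(r$occupied_minutes + r$free_minutes, r$total_minutes)
    # per-block conservation
    states <- day_states(day)
    occ_per_block <- vapply(seq_len(nrow(day$blocks)), function(i) {
      b <- day$blocks[i, ]
      sum(!is.na(day$occupant[seq.int(b$start + 1, b$start + b$length)]))
    }, numeric(1))
    expect_equal(occ_per_block + states$free_minutes, day$blocks$length)
    # contiguity and exclusivity: every assigned appointment owns exactly
    # its contiguous range and nothing else
    a <- day$appointments[day$appointments$assigned, ]
    for (j in seq_len(nrow(a))) {
      idx <- seq.int(a$start_minute[j] + 1, a$start_minute[j] + a$required_units[j])
      expect_true(all(day$occupant[idx] == a$patient_id[j]))
      expect_equal(sum(day$occupant == a$patient_id[j], na.rm = TRUE),
                   a$required_units[j])
    }
  }
})

test_that("minute-based packing dominates the block baseline", {
  for (seed in 1:30) {
    apps <- random_appointments(45, 3 * 60, 15 * 60, seed = seed)
    minute_day <- schedule_cohort(build_day("08:00", "18:00"), apps)
    block_day <- block_baseline_schedule(build_day("08:00", "18:00"), apps,
                                         60, 4)
    expect_gte(sum(minute_day$appointments$assigned),
               sum(block_day$appointments$assigned))
  }
})

test_that("emergency lookup returns the greenest block with the largest run", {
  day <- build_day("08:00", "10:00")
  day <- schedule_appointment(day, "P1", 45 * 60)  # block 1: 15 free
  expect_equal(find_emergency_slot(day), 2)
  day2 <- schedule_cohort(build_day("08:00", "09:00"),
                          data.frame(patient_id = "P1", duration_s = 58 * 60))
  expect_true(is.na(find_emergency_slot(day2)))
})

test_that("schedules serialize to JSON and flat CSV", {
  dir <- withr::local_tempdir()
  day <- reserve_daily_qa(build_day("08:00", "18:00"), 20)
  day <- schedule_cohort(day, random_appointments(10, 10 * 60, 20 * 60, 4))
  jpath <- file.path(dir, "schedule.json")
  write_schedule_json(day, jpath)
  js <- jsonlite::read_json(jpath)
  expect_equal(js$total_minutes, 600)
  expect_length(js$slots, 10)
  expect_equal(js$slots[[1]]$occupants[[1]]$id, "daily_qa")
  expect_equal(js$slots[[1]]$start, "08:00")

  cpath <- file.path(dir, "schedule.csv")
  write_schedule_csv(day, cpath)
  runs <- utils::read.csv(cpath)
  expect_equal(sum(runs$length), occupied_minutes(day))
})
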