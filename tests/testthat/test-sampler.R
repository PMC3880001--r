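test_that("draws are reproducible from the seed and differ across seeds", {
  w <- micro_world()
  d1 <- run_annual_sample(w$pop, plan = w$plan, seed = 77)
  d2 <- run_annual_sample(w$pop, plan = w$plan, seed = 77)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- run_annual_sample(w$pop, plan = w$plan, seed = 78)
  expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
})

test_that("roll and area meshblock sets are disjoint and households never yield two adults", {
  w <- micro_world()
  for (s in 1:150) {
    d <- run_annual_sample(w$pop, plan = w$plan, seed = 300 + s)
    roll_mbs <- unique(d$mb_id[d$frame_of_selection == "roll"])
    area_mbs <- unique(d$mb_id[d$frame_of_selection == "area"])
    expect_length(intersect(roll_mbs, area_mbs), 0)
    per_hh <- table(d$household_id, d$is_adult)
    expect_true(all(per_hh <= 1))
  }
})

test_that("roll stage takes all addresses when fewer than the per-MB quota", {
  w <- micro_world()
  # per-MB quota of 2; meshblocks with a single roll address yield it w.p. 1
  hit <- FALSE
  for (s in 1:80) {
    roll <- select_roll_sample(w$pop, w$plan, seed = s)
    small <- roll$mbs$mb_id[w$frame$roll_addresses[match(roll$mbs$mb_id, w$frame$mb_id)] <
                              w$design$roll_addresses_per_mb]
    for (mb in small) {
      hit <- TRUE
      got <- roll$households[roll$households$mb_id == mb, ]
      expect_equal(nrow(got), w$frame$roll_addresses[w$frame$mb_id == mb])
      expect_equal(got$pr_hh, rep(1, nrow(got)))
    }
  }
  expect_true(hit)
})

test_that("a population without roll addresses yields a pure area design", {
  cfg <- micro_config()
  cfg$ethnic_profile$prevalence <- c(0, 0, 0)
  cfg$descent_extra <- 0
  pop <- suppressMessages(generate_population(cfg))
  frame <- census_snapshot(pop, 0)
  design <- design_config(total_households = 8, within_mb_target = 3,
                          roll_share = 0.25, roll_addresses_per_mb = 2, seed = 1)
  d <- suppressMessages(run_annual_sample(pop, design, frame = frame, seed = 5))
  expect_true(all(d$frame_of_selection == "area"))
  expect_gt(nrow(d), 0)
})

test_that("roll share 0 gives a single-frame design", {
  w <- micro_world()
  design0 <- design_config(total_households = 8, within_mb_target = 3,
                           roll_share = 0, seed = 1)
  d <- run_annual_sample(w$pop, design0, frame = w$frame, seed = 5)
  expect_true(all(d$frame_of_selection == "area"))
})

test_that("roll meshblock PPS frequencies match size shares", {
  # 2 MBs with roll counts (30, 10), 1 drawn: MB-1 share 0.75
  pi <- certainty_peel(c(30, 10), 1)
  expect_equal(pi, c(0.75, 0.25))
  withr::with_seed(6, {
    hits <- sum(replicate(20000, pps_systematic(pi)[1]))
  })
  expect_lt(abs(hits / 20000 - 0.75), 3 * sqrt(0.75 * 0.25 / 20000))
})

test_that("area meshblock inclusion frequencies match the Eq-style probabilities", {
  sizes <- c(10, 25, 40, 15, 30)
  pi <- mb_selection_probabilities(sizes, 2)
  withr::with_seed(8, {
    hits <- rowSums(replicate(20000, pps_systematic(pi)))
  })
  se <- sqrt(pi * (1 - pi) / 20000)
  expect_true(all(abs(hits / 20000 - pi) < 3 * se))
})

test_that("within-household selection is uniform and blind to roll flags", {
  pop <- micro_world()$pop
  hh <- pop$households
  per <- pop$persons
  target <- hh$household_id[hh$n_adults >= 2][1]
  expect_false(is.na(target))
  n_a <- hh$n_adults[target]
  picks <- integer(20000)
  for (s in seq_len(20000)) {
    sel <- select_persons(pop, target, seed = s)
    picks[s] <- sel$person_id[per$is_adult[sel$person_id]]
  }
  freq <- table(picks) / 20000
  expect_length(freq, n_a)
  expect_true(all(abs(freq - 1 / n_a) < 3 * sqrt((1 / n_a) * (1 - 1 / n_a) / 20000)))
  # roll-flagged adults are not preferentially selected: the uniform check
  # above includes any mix of on-roll and off-roll adults in the household
  onroll <- per$on_roll_maori_descent[as.integer(names(freq))]
  if (any(onroll) && any(!onroll)) {
    expect_lt(abs(mean(freq[onroll]) - mean(freq[!onroll])), 0.02)
  }
  # single adult, no children: that adult, nothing else
  lone <- hh$household_id[hh$n_adults == 1 & hh$n_children == 0][1]
  if (!is.na(lone)) {
    sel <- select_persons(pop, lone, seed = 1)
    expect_equal(nrow(sel), 1L)
    expect_true(per$is_adult[sel$person_id])
  }
})

test_that("quarter assignment is balanced and uniform", {
  mbs <- tibble::tibble(mb_id = 1:8, stratum_id = rep(1, 8))
  q <- assign_quarters(mbs, 4, seed = 3)
  expect_equal(as.integer(table(q$quarter)), rep(2L, 4))
  expect_equal(assign_quarters(mbs, 1, seed = 3)$quarter, rep(1L, 8))
  withr::with_seed(5, {
    firsts <- replicate(4000, assign_quarters(mbs, 4, seed = sample.int(1e6, 1))$quarter[1])
  })
  expect_lt(abs(mean(firsts == 1) - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
})

test_that("the realized roll share of households matches the configured 15%", {
  reps <- world_replicates()
  expect_lt(abs(mean(reps$roll_share) - 0.15), 3 * sd(reps$roll_share))
})

test_that("the household response filter thins the sample as configured", {
  w <- micro_world()
  design_r <- design_config(total_households = 8, within_mb_target = 3,
                            roll_share = 0.25, roll_addresses_per_mb = 2,
                            response_prob = 0.5, seed = 1)
  plan_r <- design_plan(w$frame, design_r)
  n_full <- n_resp <- 0
  for (s in 1:300) {
    d <- run_annual_sample(w$pop, plan = plan_r, seed = 40000 + s)
    n_full <- n_full + attr(d, "n_sampled_households")
    n_resp <- n_resp + length(unique(d$household_id))
  }
  expect_lt(abs(n_resp / n_full - 0.5), 0.05)
})
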