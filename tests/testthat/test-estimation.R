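test_that("pooled probability is the product of stage probabilities in a single-frame design", {
  w <- micro_world()
  design0 <- design_config(total_households = 8, within_mb_target = 3,
                           roll_share = 0, seed = 1)
  plan0 <- design_plan(w$frame, design0)
  probs0 <- inclusion_probabilities(w$pop, plan0, seed = 2)
  # independent arithmetic: pi_area * (c/N*) * 1/n_adults per adult
  frame <- w$frame
  pi_area <- numeric(nrow(frame))
  for (st in plan0$strata) pi_area[st$rows] <- certainty_peel(st$size_area, st$m_h)
  hh <- w$pop$households
  at <- match(hh$mb_id, frame$mb_id)
  h_frac <- pmin(frame$dwellings_current * 3 / frame$census_dwellings,
                 frame$census_dwellings) / frame$census_dwellings
  p_hh_direct <- pi_area[at] * h_frac[at]
  per <- w$pop$persons
  adult <- per$is_adult
  p_direct <- p_hh_direct[per$household_id] / hh$n_adults[per$household_id]
  expect_equal(probs0$persons$p_pooled[adult], p_direct[adult],
               tolerance = 1e-12)
})

test_that("persons in meshblocks without roll addresses have pure area-path probabilities", {
  w <- micro_world()
  frame <- w$frame
  no_roll_mbs <- frame$mb_id[frame$roll_addresses == 0]
  expect_gt(length(no_roll_mbs), 0)
  per <- w$pop$persons
  hh <- w$pop$households
  sel <- per$is_adult & per$mb_id %in% no_roll_mbs
  mbp <- w$probs$meshblocks
  at <- match(per$mb_id[sel], mbp$mb_id)
  p_area_path <- mbp$p_area_pooled[at] * mbp$h_frac[at] /
    hh$n_adults[per$household_id[sel]]
  expect_equal(inclusion_probability(per[sel, ], w$probs), p_area_path,
               tolerance = 1e-12)
})

test_that("Hajek prevalence handles degenerate and equal-weight cases", {
  d <- tibble::tibble(weight = c(1, 2, 5), y = c(1, 1, 1),
                      is_adult = TRUE, eth_maori = FALSE,
                      eth_pacific = FALSE, eth_asian = FALSE)
  expect_equal(estimate_prevalence(d, "y")$prevalence, 1)
  d$y <- c(1, 0, 1)
  d$weight <- rep(3, 3)
  expect_equal(estimate_prevalence(d, "y")$prevalence, mean(d$y))
  expect_error(estimate_prevalence(d, "y", "maori"), "empty")
})

test_that("replicate weights reproduce stratum totals and give zero variance for invariant statistics", {
  w <- micro_world()
  d <- run_annual_sample(w$pop, plan = w$plan, seed = 9, probs = w$probs)
  d <- jackknife_replicates(d, G = 2, seed = 2)
  reps <- attr(d, "replicates")
  full <- rowsum(d$weight, d$stratum_id)
  for (g in seq_len(reps$G)) {
    expect_equal(rowsum(reps$weights[, g], d$stratum_id), full,
                 tolerance = 1e-12)
  }
  # Hajek mean of the all-ones variable is 1 in every replicate
  est <- estimate_prevalence(dplyr::mutate(d, ones = 1), "ones",
                             adults_only = FALSE)
  expect_equal(est$se, 0, tolerance = 1e-12)
  expect_error(jackknife_replicates(d, G = 1000), "exceeds")
})

test_that("delete-a-group with G = #PSUs equals a directly coded delete-one jackknife", {
  w <- micro_world()
  d <- run_annual_sample(w$pop, plan = w$plan, seed = 10, probs = w$probs)
  d <- d[d$is_adult, ]
  psus <- unique(paste(d$stratum_id, d$mb_id))
  dd <- jackknife_replicates(d, G = length(psus), seed = 3)
  reps <- attr(dd, "replicates")
  y <- as.numeric(dd$y)
  theta <- sum(dd$weight * y) / sum(dd$weight)
  theta_g <- colSums(reps$weights * y) / colSums(reps$weights)
  # oracle: delete each PSU, ratio-rescale within its stratum, recompute;
  # a stratum's only PSU is never deleted (no remaining weight to rescale)
  oracle <- vapply(psus, function(p) {
    del <- paste(d$stratum_id, d$mb_id) == p
    h <- d$stratum_id[del][1]
    wts <- d$weight
    in_h <- d$stratum_id == h
    if (!any(in_h & !del)) {
      return(sum(wts * y) / sum(wts))
    }
    scale <- sum(wts[in_h]) / sum(wts[in_h & !del])
    wts[del] <- 0
    wts[in_h & !del] <- wts[in_h & !del] * scale
    sum(wts * y) / sum(wts)
  }, numeric(1))
  expect_equal(sort(theta_g), sort(unname(oracle)), tolerance = 1e-12)
  expect_equal(jk_variance(theta_g, theta),
               (length(psus) - 1) / length(psus) * sum((oracle - theta)^2),
               tolerance = 1e-12)
})

test_that("jackknife variance tracks the closed form for stratified SRS", {
  # 2 strata, SRSWOR with small sampling fractions, statistic = Hajek mean
  withr::with_seed(42, {
    N_h <- c(500, 700)
    n_h <- c(25, 25)
    y_pop <- list(rbinom(N_h[1], 1, 0.3), rbinom(N_h[2], 1, 0.6))
    v_jk <- replicate(200, {
      rows <- lapply(1:2, function(h) sample.int(N_h[h], n_h[h]))
      d <- tibble::tibble(
        stratum_id = rep(1:2, n_h),
        mb_id = seq_len(sum(n_h)),            # each unit its own PSU
        weight = rep(N_h / n_h, n_h),
        y = c(y_pop[[1]][rows[[1]]], y_pop[[2]][rows[[2]]]),
        is_adult = TRUE)
      d <- jackknife_replicates(d, G = sum(n_h), seed = 1)
      reps <- attr(d, "replicates")
      theta <- sum(d$weight * d$y) / sum(d$weight)
      theta_g <- colSums(reps$weights * d$y) / colSums(reps$weights)
      jk_variance(theta_g, theta)
    })
  })
  # closed form for the stratified mean with fpc
  N <- sum(N_h)
  s2 <- vapply(y_pop, var, numeric(1))
  v_true <- sum((N_h / N)^2 * (1 - n_h / N_h) * s2 / n_h)
  expect_lt(abs(mean(v_jk) - v_true) / v_true, 0.2)
})

test_that("an equal-probability unclustered design has design effect near 1", {
  # Poisson sampling with equal probabilities; realized variance over reps
  # small sampling fraction: the finite-population correction would
  # otherwise pull the realized deff below 1
  withr::with_seed(11, {
    N <- 50000
    y <- rbinom(N, 1, 0.5)
    p <- 0.04
    ests <- replicate(500, {
      s <- runif(N) < p
      mean(y[s])
    })
  })
  n_bar <- N * p
  deff <- var(ests) / (0.5 * 0.5 / n_bar)
  expect_lt(abs(deff - 1), 0.15)
})

test_that("design effect arithmetic and guards", {
  expect_equal(design_effect(0.5, sqrt(0.25 / 100), 100), 1)
  expect_equal(design_effect(0.2, 2 * sqrt(0.16 / 400), 400), 4)
  expect_error(design_effect(1, 0.1, 50), "undefined")
})

test_that("ANOVA ICC returns its boundary values on degenerate groupings", {
  # identical meshblock means -> 0
  y <- rep(c(0, 1), 20)
  g <- rep(1:4, each = 10)
  expect_equal(icc_anova(y, g), 0)
  # constant within, differing across -> 1
  y <- rep(c(0, 1, 0, 1), each = 10)
  expect_equal(icc_anova(y, g), 1)
  expect_error(icc_anova(c(1, 2), c(1, 2)), "at least 2 groups")
})

test_that("RR3 includes the estimated-eligibility share of unknowns", {
  expect_equal(response_rate_rr3(c(interviews = 79, refusals = 21)), 0.79)
  expect_equal(response_rate_rr3(c(interviews = 80, refusals = 10, unknown = 20),
                                 eligibility_rate = 0.5), 0.8)
  # e = 0 drops unknowns entirely
  expect_equal(response_rate_rr3(c(interviews = 50, refusals = 50, unknown = 999),
                                 eligibility_rate = 0), 0.5)
  # default e from resolved cases: 90/(90+10) = 0.9
  rr <- response_rate_rr3(c(interviews = 60, refusals = 30, ineligible = 10,
                            unknown = 10))
  expect_equal(rr, 60 / (90 + 0.9 * 10))
  expect_error(response_rate_rr3(c(interviews = 0)), "denominator")
  expect_error(response_rate_rr3(c(foo = 2)), "unknown disposition")
})

test_that("the indicator table reports prevalence, SE, ICC and deff per subpopulation", {
  w <- world()
  d <- run_annual_sample(w$pop, plan = w$plan, seed = 99, probs = w$probs)
  est <- estimate_indicators(d, c("phys_active", "smoker"),
                             subpops = c("all", "maori"), G = 50, seed = 4)
  expect_s3_class(est, "df_estimates")
  expect_equal(nrow(est), 4L)
  expect_true(all(est$prevalence > 0 & est$prevalence < 1))
  expect_true(all(est$se > 0))
  expect_true(all(est$deff > 0))
  # the highly clustered indicator has the larger all-adults deff
  d_phys <- est$deff[est$outcome == "phys_active" & est$subpop == "all"]
  d_smoke <- est$deff[est$outcome == "smoker" & est$subpop == "all"]
  expect_gt(d_phys, d_smoke)
})
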