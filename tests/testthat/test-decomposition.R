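test_that("the weight-variation estimator matches hand arithmetic and is always >= 1", {
  # two units, w = 1, pi = (1, 1/3): (1 + 1/3)(1 + 3)/4 = 4/3
  d <- tibble::tibble(is_adult = TRUE, weight = 1,
                      p_pooled = c(1, 1 / 3),
                      eth_maori = FALSE, eth_pacific = FALSE, eth_asian = FALSE,
                      stratum_id = 1, n_hh_adults = 1)
  sm <- list(strata = tibble::tibble(stratum_id = 1, n_adults = 2,
                                     n_households_adult = 2),
             total_adults = 2)
  expect_equal(estimate_one_plus_c2(d, "all", "d", sm), 4 / 3)
  # equal probabilities -> exactly 1
  d$p_pooled <- c(0.2, 0.2)
  expect_equal(estimate_one_plus_c2(d, "all", "d", sm), 1)
  # Cauchy-Schwarz: >= 1 for arbitrary positive weights and probabilities
  withr::with_seed(13, {
    for (i in 1:25) {
      n <- sample(2:40, 1)
      d2 <- tibble::tibble(is_adult = TRUE, weight = rexp(n) + 0.1,
                           p_pooled = runif(n, 0.01, 1),
                           eth_maori = FALSE, eth_pacific = FALSE,
                           eth_asian = FALSE, stratum_id = 1, n_hh_adults = 1)
      sm2 <- list(strata = tibble::tibble(stratum_id = 1, n_adults = n,
                                          n_households_adult = n),
                  total_adults = n)
      expect_gte(estimate_one_plus_c2(d2, "all", "d", sm2), 1)
    }
  })
})

test_that("scaling probabilities moves only the sample-size factor, not 1 + C^2", {
  withr::with_seed(14, {
    n <- 30
    d <- tibble::tibble(is_adult = TRUE, weight = rexp(n) + 0.1,
                        p_pooled = runif(n, 0.05, 0.5),
                        eth_maori = FALSE, eth_pacific = FALSE,
                        eth_asian = FALSE, stratum_id = 1, n_hh_adults = 1)
  })
  sm <- list(strata = tibble::tibble(stratum_id = 1, n_adults = n,
                                     n_households_adult = n),
             total_adults = n)
  c2_1 <- estimate_one_plus_c2(d, "all", "d", sm)
  n_1 <- estimate_counterfactual_n(d, "all", "d", sm)
  d2 <- d
  d2$p_pooled <- d$p_pooled * 0.5
  expect_equal(estimate_one_plus_c2(d2, "all", "d", sm), c2_1)
  expect_equal(estimate_counterfactual_n(d2, "all", "d", sm), n_1 * 0.5)
})

test_that("counterfactual probabilities match enumeration on the micro-population", {
  w <- micro_world()
  d <- run_annual_sample(w$pop, plan = w$plan, seed = 21, probs = w$probs)
  sm <- frame_summaries(w$pop)
  ad <- d[d$is_adult, ]
  n <- nrow(ad)
  # design a: SRS of n from N persons; by symmetry every person's inclusion
  # probability is exactly n/N (hypergeometric marginal)
  expect_equal(counterfactual_pi(d, "a", sm),
               rep(n / sum(w$pop$persons$is_adult), n))
  # design b: stratified SRS with power-allocated n_h -> n_h/N_h exactly
  alloc <- power_allocation(
    tibble::tibble(stratum_id = sm$strata$stratum_id,
                   population = sm$strata$n_adults), n, 0.5)
  at <- match(ad$stratum_id, alloc$stratum_id)
  expect_equal(counterfactual_pi(d, "b", sm),
               alloc$m_h[at] / sm$strata$n_adults[at])
  # design c: stratified SRS of households-with-adults at rate n_h/H_h, one
  # adult each -> (n_h/H_h) * (1/adults) exactly
  expect_equal(counterfactual_pi(d, "c", sm),
               alloc$m_h[at] / sm$strata$n_households_adult[at] / ad$n_hh_adults)
  # design c collapses to design b when every household has one adult
  d1 <- d
  d1$n_hh_adults <- 1L
  sm1 <- sm
  sm1$strata$n_households_adult <- sm1$strata$n_adults
  expect_equal(counterfactual_pi(d1, "c", sm1), counterfactual_pi(d1, "b", sm1))
  # design d: the realized pooled probability
  expect_equal(counterfactual_pi(d, "d", sm), ad$p_pooled)
})

test_that("counterfactual sample-size estimates are self-consistent for the realized design", {
  w <- micro_world()
  sm <- frame_summaries(w$pop)
  # weights = 1/pi_d make n_hat(d) the exact count of sampled subpop adults
  d <- run_annual_sample(w$pop, plan = w$plan, seed = 22, probs = w$probs)
  ad <- d[d$is_adult, ]
  expect_equal(estimate_counterfactual_n(d, "all", "d", sm), nrow(ad))
  expect_equal(estimate_counterfactual_n(d, "maori", "d", sm),
               sum(ad$eth_maori))
  # design a over replicate draws: close to n * subpop share
  withr::with_seed(15, {
    vals <- replicate(150, {
      dr <- run_annual_sample(w$pop, plan = w$plan,
                              seed = sample.int(1e6, 1), probs = w$probs)
      c(estimate_counterfactual_n(dr, "maori", "a", sm),
        sum(dr$is_adult) * mean(w$pop$persons$eth_maori[w$pop$persons$is_adult]))
    })
  })
  diff <- vals[1, ] - vals[2, ]
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(ncol(vals)))
})

test_that("a null design decomposes into unit factors", {
  # single stratum, equal household probabilities, one adult per household
  cfg <- population_config(
    n_strata = 1, stratum_person_range = c(600, 600),
    mean_households_per_mb = 12, mb_size_cv = 0.5, mbs_per_au = 3,
    mean_household_size = 1, p_adult = 1, descent_extra = 0,
    ethnic_profile = tibble::tibble(
      ethnicity = c("maori", "pacific", "asian"),
      prevalence = c(0, 0, 0), clustering_sd = c(1, 1, 1),
      mean_household_size = c(1, 1, 1)),
    outcome_specs = list(outcome_spec("y", 0.5, 0)), seed = 5)
  pop <- suppressMessages(generate_population(cfg))
  frame <- census_snapshot(pop, 0)
  design <- design_config(total_households = 24, within_mb_target = 2,
                          roll_share = 0, seed = 1)
  plan <- design_plan(frame, design)
  probs <- inclusion_probabilities(pop, plan, seed = 2)
  d <- run_annual_sample(pop, plan = plan, seed = 31, probs = probs)
  expect_lt(max(d$pr_mb), 1)  # no certainty meshblocks: probabilities equal
  comp <- decompose_deff(d, frame_summaries(pop), subpops = "all")
  vals <- comp$all
  names(vals) <- comp$component
  # equal household probabilities, one adult each, fixed take: every factor
  # collapses to exactly 1
  expect_equal(unname(vals), rep(1, 7), tolerance = 1e-10)
})

test_that("variance-change summary converts products to percentages", {
  comp <- tibble::tibble(component = c("e", "f", "ef"),
                         all = c(1.17, 1.00, 1.17),
                         maori = c(1.14, 0.71, 0.81),
                         pacific = c(1.08, 0.68, 0.74),
                         asian = c(1.06, 0.91, 0.96))
  vc <- summarize_variance_change(comp)
  expect_equal(vc$pct_change, c(17, -19, -26, -4), tolerance = 1e-9)
  expect_equal(summarize_variance_change(
    tibble::tibble(component = "ef", x = 1))$pct_change, 0)
})

test_that("the published component table has the documented shape and product row", {
  pc <- published_deff_components()
  expect_equal(nrow(pc), 7L)
  expect_equal(pc$component, c("a", "b", "c", "d", "e", "f", "ef"))
  rp <- recompute_product_row(pc)
  # full-precision products of the printed e and f rows
  e <- as.numeric(pc[pc$component == "e", c("all", "maori", "pacific", "asian")])
  f <- as.numeric(pc[pc$component == "f", c("all", "maori", "pacific", "asian")])
  expect_equal(as.numeric(rp[rp$component == "ef",
                             c("all", "maori", "pacific", "asian")]), e * f)
})

test_that("decomposition tables tidy into long form", {
  comp <- published_deff_components()
  long <- tidy(comp)
  expect_equal(nrow(long), 7L * 4L)
  expect_true(all(c("component", "subpop", "value") %in% names(long)))
})
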