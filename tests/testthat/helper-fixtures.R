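# Shared fixtures. Expensive objects (the NZ-like world and the
# micro-population) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Micro-population: 2 strata, a couple of dozen households, roll addresses
# in one stratum, r_h <= 1 everywhere so pooled probabilities are exact.
micro_config <- function(seed = 42) {
  population_config(
    n_strata = 2, stratum_person_range = c(25, 40), scale = 1,
    mean_households_per_mb = 5, mb_size_cv = 0.4, mbs_per_au = 2,
    mean_household_size = 2.2,
    ethnic_profile = tibble::tibble(
      ethnicity = c("maori", "pacific", "asian"),
      prevalence = c(0.35, 0.15, 0.15),
      clustering_sd = c(0.8, 0.8, 0.8),
      mean_household_size = c(2.8, 3.0, 2.8)),
    target_density_correlations = c(pacific_asian = 0, maori_asian = 0,
                                    maori_pacific = 0),
    roll_coverage = 0.9, descent_extra = 0,
    outcome_specs = list(outcome_spec("y", 0.5, 0)),
    seed = seed)
}

micro_world <- function() {
  memo("micro", function() {
    pop <- generate_population(micro_config())
    frame <- census_snapshot(pop, 0)
    design <- design_config(total_households = 8, within_mb_target = 3,
                            roll_share = 0.25, roll_addresses_per_mb = 2,
                            seed = 1)
    plan <- design_plan(frame, design)
    stopifnot(nrow(pop$households) <= 30,
              all(plan$allocation$r_h <= 1))  # exact-conditioning regime
    probs <- inclusion_probabilities(pop, plan, seed = 7)
    list(pop = pop, frame = frame, design = design, plan = plan,
         probs = probs)
  })
}

# NZ-like world at ~50k persons: the scale used for recovery, unbiasedness
# and decomposition checks. 500 replicate draws with per-draw Hajek
# estimates are cached alongside.
world_population <- function() {
  memo("world_pop", function() {
    cfg <- population_config(
      total_persons = 50000, seed = 1,
      outcome_specs = c(default_outcome_specs(),
                        list(outcome_spec("flat", 0.5, 0))))
    generate_population(cfg)
  })
}

world <- function() {
  memo("world", function() {
    pop <- world_population()
    frame <- census_snapshot(pop, 0)
    design <- design_config(total_households = 1500, seed = 1)
    plan <- design_plan(frame, design)
    probs <- inclusion_probabilities(pop, plan, n_mc = 2000, seed = 1)
    summaries <- frame_summaries(pop)
    list(pop = pop, frame = frame, design = design, plan = plan,
         probs = probs, summaries = summaries)
  })
}

# 500 replicate draws from the world: per-draw Hajek estimates for every
# outcome x subpopulation, subpop sample sizes, roll shares, and
# design-effect components averaged over the first 40 draws.
world_replicates <- function() {
  memo("world_reps", function() {
    w <- world()
    outs <- c("phys_active", "veg_fruit", "smoker", "flat")
    sps <- c("all", "maori", "pacific", "asian")
    R <- 500
    est <- array(NA_real_, c(R, length(outs), length(sps)),
                 dimnames = list(NULL, outs, sps))
    nsub <- matrix(NA_real_, R, length(sps), dimnames = list(NULL, sps))
    roll_share <- numeric(R)
    comps <- vector("list", 40)
    for (r in seq_len(R)) {
      d <- run_annual_sample(w$pop, plan = w$plan, seed = 20000 + r,
                             probs = w$probs)
      roll_share[r] <- mean(d$frame_of_selection[!duplicated(d$household_id)] == "roll")
      ad <- d[d$is_adult, ]
      for (sp in sps) {
        keep <- if (sp == "all") rep(TRUE, nrow(ad)) else ad[[paste0("eth_", sp)]]
        nsub[r, sp] <- sum(keep)
        for (oc in outs) {
          est[r, oc, sp] <- sum(ad$weight[keep] * ad[[oc]][keep]) /
            sum(ad$weight[keep])
        }
      }
      if (r <= length(comps)) {
        comps[[r]] <- decompose_deff(d, w$summaries)
      }
    }
    sps_m <- c("all", "maori", "pacific", "asian")
    cmat <- Reduce(`+`, lapply(comps, function(x) as.matrix(x[, sps_m]))) /
      length(comps)
    rownames(cmat) <- comps[[1]]$component
    list(est = est, nsub = nsub, roll_share = roll_share, components = cmat,
         outcomes = outs, subpops = sps, R = R)
  })
}

# Population truth (adults 15+) for an outcome x subpopulation.
world_truth <- function(outcome, subpop) {
  adults <- world_population()$persons |> dplyr::filter(is_adult)
  keep <- if (subpop == "all") rep(TRUE, nrow(adults)) else adults[[paste0("eth_", subpop)]]
  list(p = mean(adults[[outcome]][keep]), share = mean(keep),
       n_pop = sum(keep))
}
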