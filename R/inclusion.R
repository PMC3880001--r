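# Pooled dual-frame inclusion probabilities and base weights.
#
# The draw selects roll meshblocks first, then excludes them from the area
# frame and renormalizes. A household's pooled selection probability is
# therefore, with S the (random) roll meshblock set of its stratum:
#
#   P(hh) = 1{roll-flagged} * pi_roll(i) * min(k, R_i)/R_i
#         + E_S[ 1{i not in S} * pi_area(i | S) ] * h_frac(i)
#
# where pi_area(i | S) is the certainty-peeled PPS probability on the
# reduced frame and h_frac(i) the within-meshblock household fraction.
# The expectation over S is computed exactly when r_h <= 1 (the roll draw's
# sample space is then the singletons, with P({j}) = pi_roll_j) and by
# Monte-Carlo conditioning otherwise; both routes depend only on the frame
# and design, so the result is computed once and reused across replicate
# draws.

#' Pooled inclusion probabilities for every person in the population
#'
#' Computes each person's probability of entering the pooled dual-frame
#' sample: the roll path (address flagged for Maori descent, roll meshblock
#' selected, address drawn) plus the area path (meshblock selected from the
#' roll-reduced frame, household drawn at rate `c / N*_i`), times the
#' within-household probability `1 / n_adults` (adults) or `1 / n_children`
#' (children). For a person in a meshblock with no roll addresses the pooled
#' probability reduces to the area-path product. If the design's household
#' response probability is below 1 it is folded into the probability so base
#' weights remain unbiased under the simulated nonresponse.
#'
#' @param population A `df_population`.
#' @param plan A [design_plan()] (or pass `frame` + `design` to
#'   [design_plan()] first).
#' @param n_mc Monte-Carlo replicates for the conditioning expectation in
#'   strata where `r_h >= 2`.
#' @param seed Seed for the Monte-Carlo conditioning (substream
#'   `inclusion_mc`).
#' @return A list of class `df_probs` with tibbles `meshblocks`
#'   (`pi_roll`, `p_addr`, `p_area_pooled`, `h_frac`), `households`
#'   (`p_hh_pooled`) and `persons` (`person_id`, `p_pooled`).
#' @export
inclusion_probabilities <- function(population, plan, n_mc = 2000, seed = 1L) {
  stopifnot(inherits(plan, "df_plan"))
  frame <- plan$frame
  n_frame <- nrow(frame)
  pi_roll <- numeric(n_frame)
  p_area <- numeric(n_frame)

  for (st in plan$strata) {
    pi_roll[st$rows] <- st$pi_roll
    p_area[st$rows] <- area_prob_pooled(st, n_mc = n_mc, seed = seed)
  }
  k_per <- plan$design$roll_addresses_per_mb
  p_addr <- ifelse(frame$roll_addresses > 0,
                   pmin(k_per, frame$roll_addresses) / frame$roll_addresses, 0)
  # Household fraction: expected take / available households; the take uses
  # the (possibly drifted) frame dwelling count, capped at what exists.
  h_actual <- tab_by(rep(1, nrow(population$households)),
                     population$households$mb_id, n_frame)
  exp_take <- pmin(frame$dwellings_current * plan$design$within_mb_target /
                     frame$census_dwellings, h_actual)
  h_frac <- ifelse(h_actual > 0, exp_take / h_actual, 0)

  mb_tbl <- tibble(mb_id = frame$mb_id, stratum_id = frame$stratum_id,
                   pi_roll = pi_roll, p_addr = p_addr,
                   p_area_pooled = p_area, h_frac = h_frac)

  hh <- population$households
  at <- match(hh$mb_id, frame$mb_id)
  p_hh <- hh$roll_flag * pi_roll[at] * p_addr[at] + p_area[at] * h_frac[at]
  p_resp <- resolve_response_prob(plan$design, population, hh$household_id)
  p_hh <- p_hh * p_resp

  per <- population$persons
  denom <- ifelse(per$is_adult, hh$n_adults[per$household_id],
                  hh$n_children[per$household_id])
  p_per <- p_hh[per$household_id] / denom
  if (any(p_per <= 0)) {
    inform(sprintf("%d person(s) have zero pooled inclusion probability (uncovered)",
                   sum(p_per <= 0)))
  }
  structure(
    list(meshblocks = mb_tbl,
         households = tibble(household_id = hh$household_id,
                             p_hh_pooled = p_hh),
         persons = tibble(person_id = per$person_id, p_pooled = p_per)),
    class = "df_probs"
  )
}

# E_S[1{i not in S} * pi_area(i | S)] for one stratum plan entry.
area_prob_pooled <- function(st, n_mc, seed) {
  size <- st$size_area
  if (all(st$pi_roll == 0)) {
    return(certainty_peel(size, st$m_h))
  }
  roll_support <- which(st$pi_roll > 0)
  n_sel <- round(sum(st$pi_roll))
  if (n_sel <= 1) {
    # Exact: the sample space is the singletons {j}, P({j}) = pi_roll_j.
    out <- numeric(length(size))
    for (j in roll_support) {
      pi_j <- certainty_peel(replace(size, j, 0), st$m_h)
      out <- out + st$pi_roll[j] * pi_j
    }
    out
  } else {
    acc <- numeric(length(size))
    with_substream(seed, paste0("inclusion_mc_", st$stratum_id), {
      for (r in seq_len(n_mc)) {
        s <- pps_systematic(st$pi_roll)
        acc <- acc + certainty_peel(size * !s, st$m_h)
      }
    })
    acc / n_mc
  }
}

#' Look up pooled inclusion probabilities for persons
#'
#' @param persons A data frame with a `person_id` column (e.g. a draw).
#' @param probs An [inclusion_probabilities()] result.
#' @return Numeric vector of pooled probabilities aligned with `persons`.
#' @export
inclusion_probability <- function(persons, probs) {
  stopifnot(inherits(probs, "df_probs"))
  p <- probs$persons$p_pooled[match(persons$person_id, probs$persons$person_id)]
  if (anyNA(p)) abort("some persons are missing from the probability table")
  p
}

# Attach p_pooled and base weight to a draw.
join_weights <- function(draw, probs) {
  draw$p_pooled <- inclusion_probability(draw, probs)
  if (any(draw$p_pooled <= 0)) {
    abort("a selected person has zero computed inclusion probability; increase n_mc")
  }
  draw$weight <- 1 / draw$p_pooled
  draw
}

#' Attach base weights to a draw
#'
#' Base weights are inverse pooled inclusion probabilities; their sum
#' estimates the covered population size (Horvitz-Thompson).
#'
#' @param draw A `df_draw`.
#' @param probs An [inclusion_probabilities()] result for the same frame and
#'   design.
#' @return The draw with `p_pooled` and `weight` columns.
#' @export
svy_weights <- function(draw, probs) {
  out <- join_weights(draw, probs)
  class(out) <- unique(c("df_draw", class(out)))
  out
}
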