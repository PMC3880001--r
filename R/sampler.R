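# Stochastic dual-frame draw: roll meshblocks and addresses first, then the
# non-overlapping area sample, then households, persons and quarters.
#
# The exported stage functions return tibbles; internally each stage has a
# base-R core so that replicated draws (the package's main loop) stay cheap.

#' Precompute the deterministic part of an annual draw
#'
#' Splits the frame by stratum and precomputes everything that does not
#' change between replicate draws: the per-stratum allocation (`m_h` area
#' meshblocks, `r_h` roll meshblocks), targeting factors, area size measures
#' `N*_i f_i`, and certainty-peeled roll selection probabilities. Passing the
#' resulting plan to [run_annual_sample()] avoids recomputing it for every
#' replicate.
#'
#' @param frame A [census_snapshot()] frame.
#' @param design A [design_config()].
#' @return An object of class `df_plan`.
#' @export
design_plan <- function(frame, design) {
  stopifnot(inherits(frame, "df_frame"), inherits(design, "df_design"))
  alloc <- design_allocation(frame, design)
  f <- targeting_factor(frame$dens_pacific, frame$dens_pacific_au,
                        frame$dens_asian, frame$dens_asian_au,
                        design$targeting_coefficients)
  rows_by_h <- split(seq_len(nrow(frame)), frame$stratum_id)
  strata <- lapply(seq_len(nrow(alloc)), function(k) {
    h <- alloc$stratum_id[k]
    rows <- rows_by_h[[as.character(h)]]
    r_h <- alloc$r_h[k]
    roll <- frame$roll_addresses[rows]
    pi_roll <- if (r_h > 0 && sum(roll) > 0) {
      certainty_peel(roll, min(r_h, sum(roll > 0)))
    } else {
      numeric(length(rows))
    }
    list(stratum_id = h, rows = rows, m_h = alloc$m_h[k], r_h = r_h,
         mb_id = frame$mb_id[rows],
         size_area = frame$census_dwellings[rows] * f[rows],
         pi_roll = pi_roll)
  })
  structure(list(allocation = alloc, strata = strata, design = design,
                 f = f, frame = frame),
            class = "df_plan")
}

# --- stage cores (base R, RNG state of the caller) -------------------------

# Roll meshblock + address draw. Returns frame rows of selected MBs with
# their probabilities, and selected household ids with stage fractions.
roll_core <- function(population, plan) {
  frame <- plan$frame
  idx <- population$index
  k_per <- plan$design$roll_addresses_per_mb
  mb_rows <- integer(0); pr_mb <- numeric(0)
  for (st in plan$strata) {
    if (all(st$pi_roll == 0)) next
    s <- pps_systematic(st$pi_roll)
    mb_rows <- c(mb_rows, st$rows[s])
    pr_mb <- c(pr_mb, st$pi_roll[s])
  }
  hh <- integer(0); hh_mb <- integer(0); pr_hh <- numeric(0)
  for (r in mb_rows) {
    mb <- frame$mb_id[r]
    avail <- idx$roll_rows[(idx$roll_ptr[mb] + 1L):(idx$roll_ptr[mb + 1L])]
    take <- avail[srs(length(avail), min(k_per, length(avail)))]
    hh <- c(hh, take)
    hh_mb <- c(hh_mb, rep.int(r, length(take)))
    pr_hh <- c(pr_hh, rep(min(k_per, length(avail)) / length(avail), length(take)))
  }
  list(mb_rows = mb_rows, pr_mb = pr_mb,
       hh = hh, hh_mb_row = hh_mb, pr_hh = pr_hh)
}

# Area meshblock + household draw on the roll-reduced frame.
area_core <- function(population, plan, excluded_rows) {
  frame <- plan$frame
  idx <- population$index
  c_target <- plan$design$within_mb_target
  mb_rows <- integer(0); pr_mb <- numeric(0)
  for (st in plan$strata) {
    keep <- !(st$rows %in% excluded_rows)
    if (sum(keep) < st$m_h) {
      abort(sprintf("stratum %s: m_h = %d exceeds the %d meshblocks left after roll exclusion",
                    st$stratum_id, st$m_h, sum(keep)))
    }
    pi <- certainty_peel(st$size_area * keep, st$m_h)
    s <- pps_systematic(pi)
    mb_rows <- c(mb_rows, st$rows[s])
    pr_mb <- c(pr_mb, pi[s])
  }
  takes <- within_mb_sample_size(frame$dwellings_current[mb_rows],
                                 frame$census_dwellings[mb_rows], c_target)
  hh <- integer(0); hh_mb <- integer(0); pr_hh <- numeric(0)
  for (j in seq_along(mb_rows)) {
    mb <- frame$mb_id[mb_rows[j]]
    lo <- idx$hh_ptr[mb] + 1L
    hi <- idx$hh_ptr[mb + 1L]
    h_act <- hi - lo + 1L
    if (h_act <= 0L) next
    take <- min(takes[j], h_act)
    if (take == 0L) next
    pick <- (lo:hi)[srs(h_act, take)]
    hh <- c(hh, pick)
    hh_mb <- c(hh_mb, rep.int(mb_rows[j], take))
    pr_hh <- c(pr_hh, rep(take / h_act, take))
  }
  list(mb_rows = mb_rows, pr_mb = pr_mb,
       hh = hh, hh_mb_row = hh_mb, pr_hh = pr_hh)
}

# One adult + one child per household; returns person rows (indices into
# population$persons), their household ids and within-household
# probabilities.
persons_core <- function(population, household_ids) {
  idx <- population$index
  hh <- population$households
  na <- hh$n_adults[household_ids]
  nc <- hh$n_children[household_ids]
  a_hh <- household_ids[na > 0]
  a_n <- na[na > 0]
  a_pick <- idx$adult_rows[idx$adult_ptr[a_hh] +
                             pmin(a_n, floor(runif(length(a_hh)) * a_n) + 1L)]
  c_hh <- household_ids[nc > 0]
  c_n <- nc[nc > 0]
  c_pick <- idx$child_rows[idx$child_ptr[c_hh] +
                             pmin(c_n, floor(runif(length(c_hh)) * c_n) + 1L)]
  list(rows = c(a_pick, c_pick), hh = c(a_hh, c_hh),
       pr = c(1 / a_n, 1 / c_n))
}

# Balanced random quarter assignment within stratum.
quarters_core <- function(stratum_of, quarters) {
  q <- integer(length(stratum_of))
  for (rows in split(seq_along(stratum_of), stratum_of)) {
    q[rows[sample.int(length(rows))]] <- rep_len(seq_len(quarters), length(rows))
  }
  q
}

# --- exported stage wrappers ----------------------------------------------

#' Select the electoral-roll meshblock and address sample
#'
#' First stage: within each stratum, a randomized-order systematic PPS draw
#' of `r_h` meshblocks with probability proportional to the number of
#' roll-flagged (Maori-descent) addresses. Second stage: a simple random
#' sample of `min(roll_addresses_per_mb, available)` roll addresses per
#' selected meshblock. Strata without roll addresses yield an empty roll
#' sample there.
#'
#' @param population A `df_population` (supplies the actual roll-flagged
#'   households behind the frame counts).
#' @param plan A [design_plan()].
#' @param seed Integer seed (stage substreams `roll`, `roll_addresses`).
#' @return List with tibbles `mbs` (mb_id, stratum_id, pr_mb) and
#'   `households` (household_id, mb_id, pr_hh).
#' @export
select_roll_sample <- function(population, plan, seed = 1L) {
  res <- with_substream(seed, "roll", roll_core(population, plan))
  frame <- plan$frame
  list(
    mbs = tibble(mb_id = frame$mb_id[res$mb_rows],
                 stratum_id = frame$stratum_id[res$mb_rows],
                 pr_mb = res$pr_mb),
    households = tibble(
      household_id = population$households$household_id[res$hh],
      mb_id = frame$mb_id[res$hh_mb_row],
      pr_hh = res$pr_hh)
  )
}

#' Select the area meshblock and household sample
#'
#' Within each stratum, the roll-selected meshblocks are excluded, selection
#' probabilities are recomputed on the reduced frame from the size measure
#' `N*_i f_i` (with iterative certainty treatment), and `m_h` meshblocks are
#' drawn by randomized-order systematic PPS. Within each selected meshblock,
#' `H_i c / N*_i` households (stochastically rounded, capped at the
#' available dwellings) are drawn by simple random sampling.
#'
#' @inheritParams select_roll_sample
#' @param excluded_mbs Integer vector of roll-selected meshblock ids.
#' @param seed Integer seed (stage substreams `area`, `households`).
#' @return List with tibbles `mbs` (mb_id, stratum_id, pr_mb) and
#'   `households` (household_id, mb_id, pr_hh).
#' @export
select_area_sample <- function(population, plan, excluded_mbs = integer(),
                               seed = 1L) {
  frame <- plan$frame
  ex_rows <- which(frame$mb_id %in% excluded_mbs)
  res <- with_substream(seed, "area", area_core(population, plan, ex_rows))
  list(
    mbs = tibble(mb_id = frame$mb_id[res$mb_rows],
                 stratum_id = frame$stratum_id[res$mb_rows],
                 pr_mb = res$pr_mb),
    households = tibble(
      household_id = population$households$household_id[res$hh],
      mb_id = frame$mb_id[res$hh_mb_row],
      pr_hh = res$pr_hh)
  )
}

#' Select one adult and one child per household
#'
#' Lists all members of each selected household and selects exactly one
#' adult (15+) uniformly at random if the household has any, and one child
#' (0-14) uniformly at random if it has any. Selection is made without
#' reference to the electoral roll, so Maori individuals are not
#' preferentially selected and within-household probabilities are exactly
#' `1 / n_adults` and `1 / n_children`. Households with no members are
#' skipped.
#'
#' @param population A `df_population`.
#' @param household_ids Integer ids of selected households.
#' @param seed Integer seed (stage substream `persons`).
#' @return Tibble with `person_id`, `household_id`, `pr_person`.
#' @export
select_persons <- function(population, household_ids, seed = 1L) {
  res <- with_substream(seed, "persons", persons_core(population, household_ids))
  tibble(person_id = population$persons$person_id[res$rows],
         household_id = res$hh, pr_person = res$pr)
}

#' Randomly assign selected meshblocks to quarters
#'
#' Meshblocks from both frames are shuffled within stratum and dealt to
#' quarters round-robin, so counts per quarter are equal up to remainder and
#' each quarter is itself a probability sample.
#'
#' @param mbs Tibble with columns `mb_id`, `stratum_id`.
#' @param quarters Number of quarters `Q >= 1`.
#' @param seed Integer seed (stage substream `quarters`).
#' @return `mbs` with an added integer `quarter` column.
#' @export
assign_quarters <- function(mbs, quarters = 4, seed = 1L) {
  stopifnot(quarters >= 1)
  mbs$quarter <- with_substream(seed, "quarters",
                                quarters_core(mbs$stratum_id, quarters))
  mbs
}

#' Draw one annual dual-frame sample
#'
#' Orchestrates the full draw: roll meshblocks and addresses, then the
#' non-overlapping area sample, household selection at rate `c / N*_i`,
#' one adult and one child per household, random quarter assignment, and an
#' independent Bernoulli household response filter. Every stage runs under a
#' named substream of `seed`, so draws are reproducible and stages can be
#' re-run independently.
#'
#' @param population A `df_population`.
#' @param design A [design_config()]; ignored if `plan` is supplied.
#' @param frame Optional [census_snapshot()]; defaults to a drift-free
#'   snapshot.
#' @param plan Optional precomputed [design_plan()] (recommended for
#'   replicated draws).
#' @param seed Integer seed for this draw; defaults to the design seed.
#' @param probs Optional [inclusion_probabilities()] table; if supplied, the
#'   pooled inclusion probability and base weight are joined onto the draw.
#' @return A tibble of class `df_draw`, one row per selected person, with
#'   ids, ethnicity flags, outcomes, frame of selection, quarter, and the
#'   stagewise probabilities `pr_mb`, `pr_hh`, `pr_person` (plus
#'   `p_pooled`/`weight` when `probs` is given). Attributes carry the
#'   allocation and counts of vacant/ineligible households.
#' @export
#' @examples
#' pop <- generate_population(population_config(
#'   n_strata = 2, total_persons = 2000, seed = 7))
#' design <- design_config(total_households = 60, within_mb_target = 5, seed = 7)
#' draw <- run_annual_sample(pop, design)
#' dplyr::count(draw, frame_of_selection, is_adult)
run_annual_sample <- function(population, design = design_config(),
                              frame = NULL, plan = NULL, seed = NULL,
                              probs = NULL) {
  stopifnot(inherits(population, "df_population"))
  if (is.null(plan)) {
    frame <- frame %||% census_snapshot(population, 0)
    plan <- design_plan(frame, design)
  }
  design <- plan$design
  seed <- seed %||% design$seed
  frame <- plan$frame

  roll <- with_substream(seed, "roll", roll_core(population, plan))
  area <- with_substream(seed, "area",
                         area_core(population, plan, roll$mb_rows))

  mb_rows <- c(roll$mb_rows, area$mb_rows)
  mb_frame_code <- rep(c("roll", "area"),
                       c(length(roll$mb_rows), length(area$mb_rows)))
  mb_pr <- c(roll$pr_mb, area$pr_mb)
  mb_quarter <- with_substream(seed, "quarters",
                               quarters_core(frame$stratum_id[mb_rows],
                                             design$quarters))

  hh_ids <- c(roll$hh, area$hh)
  hh_mb_row <- c(roll$hh_mb_row, area$hh_mb_row)
  hh_pr <- c(roll$pr_hh, area$pr_hh)

  # Household response filter (independent Bernoulli, optionally by ethnicity).
  n_sampled_hh <- length(hh_ids)
  p_resp <- resolve_response_prob(design, population, hh_ids)
  if (any(p_resp < 1)) {
    keep <- with_substream(seed, "response", runif(length(hh_ids)) < p_resp)
    hh_ids <- hh_ids[keep]
    hh_mb_row <- hh_mb_row[keep]
    hh_pr <- hh_pr[keep]
  }

  sel <- with_substream(seed, "persons", persons_core(population, hh_ids))
  n_empty <- n_sampled_hh - length(unique(sel$hh))

  out <- population$persons[sel$rows, ]
  at <- match(sel$hh, hh_ids)
  mb_at <- match(hh_mb_row[at], mb_rows)
  out$frame_of_selection <- mb_frame_code[mb_at]
  out$quarter <- mb_quarter[mb_at]
  out$pr_mb <- mb_pr[mb_at]
  out$pr_hh <- hh_pr[at]
  out$pr_person <- sel$pr
  out$n_hh_adults <- population$households$n_adults[sel$hh]
  out$n_hh_children <- population$households$n_children[sel$hh]
  if (!is.null(probs)) out <- join_weights(out, probs)
  attr(out, "allocation") <- plan$allocation
  attr(out, "seed") <- seed
  attr(out, "n_sampled_households") <- n_sampled_hh
  attr(out, "n_empty_households") <- n_empty
  class(out) <- c("df_draw", class(tibble()))
  out
}

# Per-household response probability from the design config.
resolve_response_prob <- function(design, population, household_ids) {
  rp <- design$response_prob
  if (length(rp) == 1L && is.null(names(rp))) {
    return(rep(rp, length(household_ids)))
  }
  base <- if ("base" %in% names(rp)) rp[["base"]] else 1
  p <- rep(base, length(household_ids))
  hh <- population$households
  for (e in intersect(names(rp), ETHNICITIES)) {
    flag <- hh[[paste0("eth_", e)]][household_ids]
    p[flag] <- p[flag] * rp[[e]]
  }
  pmin(pmax(p, 0), 1)
}
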