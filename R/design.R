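# Deterministic design engine: stratum allocation, targeting factors,
# meshblock selection probabilities, within-meshblock sample sizes.

#' Design configuration
#'
#' Collects the tunable parameters of the dual-frame, targeted multistage
#' household design. Defaults mirror the continuous NZ Health Survey design:
#' about 12,500 responding households per year, a within-meshblock target of
#' `c = 20` households, stratum (District Health Board) allocation
#' proportional to the square root of census population, targeting-factor
#' coefficients (0.31, 0.37, 0.09, 0.20) on the square roots of Pacific and
#' Asian meshblock/area-unit densities plus a constant 0.03, roughly 15% of
#' households drawn from the electoral-roll list frame at 10 addresses per
#' selected meshblock, and meshblocks spread over 4 quarters.
#'
#' @param total_households Target number of responding households per year.
#' @param within_mb_target Target household take `c` per area meshblock.
#' @param power_exponent Exponent `q` of the power allocation to strata,
#'   in (0, 1]; `q = 1` is proportional allocation, `q = 0.5` the square-root
#'   compromise between national and small-stratum precision.
#' @param targeting_coefficients Named numeric vector
#'   `(b_pac_mb, b_pac_au, b_asi_mb, b_asi_au, b_const)` applied to the square
#'   roots of Pacific/Asian meshblock and area-unit densities.
#' @param roll_share Proportion of selected households to draw from the
#'   electoral-roll list frame, in `[0, 1)`.
#' @param roll_addresses_per_mb Roll addresses taken per selected roll
#'   meshblock (all addresses if fewer are available).
#' @param quarters Number of enumeration quarters per year.
#' @param response_prob Household response probability applied as an
#'   independent Bernoulli filter; optionally a named vector with element
#'   `base` plus per-ethnicity multipliers (`maori`, `pacific`, `asian`) for
#'   sensitivity studies.
#' @param seed Integer seed for design-level randomness.
#' @return An object of class `df_design` (a list).
#' @export
#' @examples
#' design_config(total_households = 1500)
design_config <- function(total_households = 12500,
                          within_mb_target = 20,
                          power_exponent = 0.5,
                          targeting_coefficients = c(
                            b_pac_mb = 0.31, b_pac_au = 0.37,
                            b_asi_mb = 0.09, b_asi_au = 0.20,
                            b_const = 0.03
                          ),
                          roll_share = 0.15,
                          roll_addresses_per_mb = 10,
                          quarters = 4,
                          response_prob = 1,
                          seed = 1L) {
  stopifnot(total_households > 0, within_mb_target > 0,
            power_exponent > 0, power_exponent <= 1,
            roll_addresses_per_mb > 0, quarters >= 1)
  assert_prob(roll_share, "roll_share", open_right = TRUE)
  tc <- targeting_coefficients
  if (is.null(names(tc)) && length(tc) == 5L) {
    names(tc) <- c("b_pac_mb", "b_pac_au", "b_asi_mb", "b_asi_au", "b_const")
  }
  need <- c("b_pac_mb", "b_pac_au", "b_asi_mb", "b_asi_au", "b_const")
  if (!all(need %in% names(tc))) {
    abort("`targeting_coefficients` must contain b_pac_mb, b_pac_au, b_asi_mb, b_asi_au, b_const")
  }
  if (any(tc < 0)) abort("targeting coefficients must be non-negative")
  structure(
    list(
      total_households = total_households,
      within_mb_target = within_mb_target,
      power_exponent = power_exponent,
      targeting_coefficients = tc[need],
      roll_share = roll_share,
      roll_addresses_per_mb = roll_addresses_per_mb,
      quarters = as.integer(quarters),
      response_prob = response_prob,
      seed = as.integer(seed)
    ),
    class = "df_design"
  )
}

#' @export
print.df_design <- function(x, ...) {
  cat("<df_design>\n")
  cat(sprintf("  households/year: %s  (roll share %.0f%%, %d addresses/roll MB)\n",
              format(x$total_households, big.mark = ","), 100 * x$roll_share,
              x$roll_addresses_per_mb))
  cat(sprintf("  within-MB target c = %g, power exponent q = %g, quarters = %d\n",
              x$within_mb_target, x$power_exponent, x$quarters))
  cat(sprintf("  targeting f = %.2f*sqrt(pacMB) + %.2f*sqrt(pacAU) + %.2f*sqrt(asiMB) + %.2f*sqrt(asiAU) + %.2f\n",
              x$targeting_coefficients[1], x$targeting_coefficients[2],
              x$targeting_coefficients[3], x$targeting_coefficients[4],
              x$targeting_coefficients[5]))
  invisible(x)
}

#' Power allocation of a sample to strata
#'
#' Allocates `total` sampling units to strata proportionally to
#' `population^exponent`, the compromise between proportional allocation
#' (optimal for national estimates) and equal allocation (optimal for
#' per-stratum estimates). Fractional allocations are resolved by
#' largest-remainder rounding and every non-empty stratum receives at least
#' one unit.
#'
#' @param strata Data frame with columns `stratum_id` and `population`
#'   (or a bare numeric vector of populations).
#' @param total Integer total number of units to allocate.
#' @param exponent Power-allocation exponent in (0, 1].
#' @return A tibble with columns `stratum_id`, `population`, `share`, `m_h`.
#' @export
#' @examples
#' power_allocation(tibble::tibble(stratum_id = 1:2, population = c(100, 400)), 30)
power_allocation <- function(strata, total, exponent = 0.5) {
  if (is.numeric(strata)) {
    strata <- tibble(stratum_id = seq_along(strata), population = as.numeric(strata))
  }
  stopifnot(all(c("stratum_id", "population") %in% names(strata)))
  if (any(strata$population <= 0)) abort("stratum populations must be positive")
  stopifnot(exponent > 0, exponent <= 1)
  total <- as.integer(round(total))
  if (total < nrow(strata)) {
    abort(sprintf("total (%d) must be at least the number of strata (%d)",
                  total, nrow(strata)))
  }
  raw <- strata$population^exponent
  tibble(
    stratum_id = strata$stratum_id,
    population = strata$population,
    share = raw / sum(raw),
    m_h = largest_remainder(raw, total, min_one = TRUE)
  )
}

#' Targeting factor for a meshblock
#'
#' The multiplier on a meshblock's census size measure that raises its
#' selection probability where Pacific and Asian densities are higher:
#' \deqn{f_i = b_1\sqrt{p^{MB}_i} + b_2\sqrt{p^{AU}_i} + b_3\sqrt{a^{MB}_i} +
#'       b_4\sqrt{a^{AU}_i} + b_0.}
#' Square roots temper the targeting (over-targeted designs hurt
#' subpopulation precision); the area-unit densities stabilise it against
#' census outdatedness. With the default coefficients the factor is 0.03 at
#' zero densities and 1.00 when all densities are 1.
#'
#' @param pac_mb,pac_au,asi_mb,asi_au Pacific/Asian densities at meshblock
#'   and area-unit level, each in `[0, 1]`; vectors are recycled together.
#' @param coefficients Five named coefficients as in [design_config()].
#' @return Numeric vector of targeting factors.
#' @export
#' @examples
#' targeting_factor(0, 0, 0, 0)        # 0.03
#' targeting_factor(1, 1, 1, 1)        # 1.00
targeting_factor <- function(pac_mb, pac_au, asi_mb, asi_au,
                             coefficients = design_config()$targeting_coefficients) {
  d <- vctrs_recycle(pac_mb, pac_au, asi_mb, asi_au)
  if (any(unlist(d) < 0, na.rm = TRUE) || any(unlist(d) > 1, na.rm = TRUE)) {
    abort("densities must lie in [0, 1]")
  }
  b <- coefficients
  b[["b_pac_mb"]] * sqrt(d[[1]]) + b[["b_pac_au"]] * sqrt(d[[2]]) +
    b[["b_asi_mb"]] * sqrt(d[[3]]) + b[["b_asi_au"]] * sqrt(d[[4]]) +
    b[["b_const"]]
}

# Minimal common-length recycling for scalar-or-equal-length args.
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else if (length(x) == 1L) rep(x, n)
    else abort("arguments must have length 1 or a common length")
  })
}

#' Meshblock selection probabilities within a stratum
#'
#' Implements the PPS rule \eqn{\pi_i = m_h N^*_i f_i / \sum_j N^*_j f_j}
#' with iterative certainty treatment: any meshblock whose probability
#' reaches 1 is selected with certainty and the remaining probabilities are
#' re-solved so they still sum to `m_h`.
#'
#' @param size_measure Positive vector `N*_i * f_i` (census persons times
#'   targeting factor) for the meshblocks of one stratum.
#' @param m_h Number of meshblocks to select in the stratum.
#' @return Numeric vector of inclusion probabilities in `(0, 1]` summing to
#'   `m_h`.
#' @export
#' @examples
#' mb_selection_probabilities(c(10, 20, 30, 40), 2)
mb_selection_probabilities <- function(size_measure, m_h) {
  if (all(size_measure == 0)) abort("all meshblock size measures are zero")
  if (m_h > sum(size_measure > 0)) {
    abort("m_h exceeds the number of meshblocks with positive size")
  }
  certainty_peel(size_measure, as.integer(m_h))
}

#' Within-meshblock household sample size
#'
#' The design selects households at rate `c / N*_i` so that, if the meshblock
#' still had its census population, exactly `c` households would be taken.
#' With `H_i` dwellings at enumeration the take is `H_i * c / N*_i`,
#' realized by stochastic rounding (so its expectation is exact) and capped
#' at `H_i`.
#'
#' @param h_current Dwelling counts at enumeration time.
#' @param n_census Census person counts `N*_i` (positive).
#' @param c_target Within-meshblock target take `c`.
#' @return Integer vector of household takes.
#' @export
within_mb_sample_size <- function(h_current, n_census, c_target) {
  stopifnot(all(h_current >= 0), all(n_census > 0), c_target > 0)
  take <- stochastic_round(h_current * c_target / n_census)
  pmin(take, as.integer(h_current))
}

#' Annual meshblock allocation for both frames
#'
#' Translates the design configuration into per-stratum meshblock sample
#' sizes: area meshblocks `m_h` from a power allocation of
#' `total_households * (1 - roll_share) / c`, and roll meshblocks `r_h` from
#' a power allocation of `total_households * roll_share` divided by the
#' PPS-expected address take per selected roll meshblock (so the realized
#' roll share of households hits `roll_share`), zeroed (with a message) in
#' strata without roll addresses. Allocations are capped at each stratum's
#' meshblock supply with the excess re-apportioned.
#'
#' @param frame Meshblock frame as returned by [census_snapshot()].
#' @param design A [design_config()].
#' @return Tibble with columns `stratum_id`, `population`, `m_h` (area
#'   meshblocks), `r_h` (roll meshblocks), `expected_households`.
#' @export
design_allocation <- function(frame, design) {
  k_per <- design$roll_addresses_per_mb
  strata <- frame |>
    group_by(.data$stratum_id) |>
    summarise(population = sum(.data$census_persons),
              # PPS-expected address take per selected roll meshblock:
              # selection is proportional to R_i, the take min(k, R_i).
              roll_take_per_mb = if (sum(.data$roll_addresses) > 0) {
                sum(.data$roll_addresses * pmin(k_per, .data$roll_addresses)) /
                  sum(.data$roll_addresses)
              } else 0,
              roll_addresses = sum(.data$roll_addresses),
              n_mb = n(), .groups = "drop")
  m_total <- max(nrow(strata),
                 round(design$total_households * (1 - design$roll_share) /
                         design$within_mb_target))
  shares <- strata$population^design$power_exponent
  # Roll meshblocks per stratum: the stratum's share of the roll household
  # target divided by its expected address take per selected meshblock.
  raw_r <- ifelse(strata$roll_take_per_mb > 0,
                  design$roll_share * design$total_households *
                    shares / sum(shares) / strata$roll_take_per_mb, 0)
  r_total <- round(sum(raw_r))
  # Small strata can be exhausted; cap at the stratum meshblock supply
  # (reserving room for the roll draw) and re-apportion the excess.
  roll_eligible <- strata$roll_addresses > 0
  want_roll <- r_total > 0 & any(roll_eligible)
  reserve <- if (want_roll) pmin(strata$n_mb - 1L, roll_eligible * 1L) else 0L
  m_h <- capped_apportion(shares, min(m_total, sum(strata$n_mb - reserve)),
                          strata$n_mb - reserve)
  if (want_roll) {
    r_cap <- strata$n_mb - m_h
    r_want <- max(r_total, sum(roll_eligible))
    r_h <- capped_apportion(raw_r, min(r_want, sum(r_cap * roll_eligible)),
                            r_cap)
    if (any(!roll_eligible)) {
      inform(sprintf("%d stratum/strata without roll addresses receive no roll sample",
                     sum(!roll_eligible)))
    }
  } else {
    r_h <- rep(0L, nrow(strata))
  }
  if (any(m_h + r_h > strata$n_mb)) {
    abort("allocation exceeds the number of meshblocks in a stratum")
  }
  tibble(stratum_id = strata$stratum_id, population = strata$population,
         m_h = m_h, r_h = r_h,
         expected_households = m_h * design$within_mb_target +
           r_h * strata$roll_take_per_mb)
}
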