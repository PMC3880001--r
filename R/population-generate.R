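# Synthetic population generator: strata -> area units -> meshblocks ->
# households -> persons, with spatially clustered ethnic densities,
# electoral-roll flags and clustered binary outcomes.

ETHNICITIES <- c("maori", "pacific", "asian")

# Solve E[plogis(mu + s*Z)] = target for mu (Z standard normal); the latent
# logit-normal mean that delivers a desired marginal density.
calibrate_logit_mean <- function(target, s) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  zg <- qnorm(ppoints(301))
  f <- function(mu) mean(plogis(mu + s * zg)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

# Latent normal correlations are attenuated by the logit transform on the
# way to meshblock densities; inflate the targets to compensate, then
# project to the nearest correlation matrix. The inflation constant was
# calibrated once on large simulated fields of the default profile.
latent_correlation_matrix <- function(targets, inflation = 1.3) {
  r <- pmin(pmax(targets * inflation, -0.97), 0.97)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[["maori_pacific"]]
  R[1, 3] <- R[3, 1] <- r[["maori_asian"]]
  R[2, 3] <- R[3, 2] <- r[["pacific_asian"]]
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    R <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  R
}

rmvn_chol <- function(n, R) {
  matrix(rnorm(n * ncol(R)), n) %*% chol(R)
}

#' Generate a synthetic population
#'
#' Builds the full hierarchy the design operates on: strata with log-spaced
#' person counts spanning the configured range; meshblocks with lognormal
#' household counts grouped into area units; ethnic densities from a
#' two-level correlated logit-normal latent field (an area-unit component
#' shared by the meshblocks of an area unit, plus meshblock-level jitter
#' carrying the same cross-ethnicity correlations); households whose
#' ethnicity flags follow their meshblock's densities and whose sizes are
#' shifted-Poisson with ethnicity-dependent means (so one-person-per-
#' household sampling undersamples large-household ethnicities); one
#' guaranteed adult per household; electoral-roll Maori-descent flags on a
#' configurable fraction of Maori-descent adults' addresses (descent being
#' broader than ethnicity); and the configured binary outcomes. Fully
#' reproducible from the config seed via named substreams per stage.
#'
#' If the realized meshblock-level density correlations miss their targets by
#' more than 0.25 the achieved values are reported in a warning (the
#' requested correlations may be unattainable for very low prevalences).
#'
#' @param config A [population_config()].
#' @return An object of class `df_population`: a list of tibbles `strata`,
#'   `meshblocks`, `households`, `persons`, plus the config and fast
#'   selection indexes.
#' @export
#' @examples
#' pop <- generate_population(population_config(
#'   n_strata = 2, total_persons = 2000, seed = 7))
#' pop
generate_population <- function(config) {
  stopifnot(inherits(config, "df_popconfig"))
  seed <- config$seed
  prof <- config$ethnic_profile
  prof <- prof[match(ETHNICITIES, prof$ethnicity), ]

  ## --- structure: strata, meshblocks, area units -------------------------
  targets <- stratum_person_targets(config)
  str_tbl <- tibble(stratum_id = seq_len(config$n_strata),
                    target_persons = targets)
  mb <- with_substream(seed, "structure", {
    n_mb_h <- pmax(2L, as.integer(round(
      targets / config$mean_household_size / config$mean_households_per_mb)))
    sdlog <- sqrt(log(1 + config$mb_size_cv^2))
    meanlog <- log(config$mean_households_per_mb) - sdlog^2 / 2
    n_mb <- sum(n_mb_h)
    hh_counts <- pmax(1L, as.integer(round(stats::rlnorm(n_mb, meanlog, sdlog))))
    stratum_id <- rep.int(str_tbl$stratum_id, n_mb_h)
    au_local <- unlist(lapply(n_mb_h, function(k) ceiling(seq_len(k) / config$mbs_per_au)),
                       use.names = FALSE)
    au_id <- cumsum(!duplicated(paste(stratum_id, au_local)))
    tibble(mb_id = seq_len(n_mb), au_id = au_id, stratum_id = stratum_id,
           census_dwellings = hh_counts)
  })

  ## --- ethnic density field ----------------------------------------------
  n_au <- max(mb$au_id)
  # Household-level density target: person-level prevalence deflated by the
  # household-size inflation of flagged households.
  dens_target <- prof$prevalence * config$mean_household_size /
    prof$mean_household_size
  dens_target <- pmin(dens_target, 1)
  R <- latent_correlation_matrix(config$target_density_correlations)
  # The latent logit field has an area-unit component (spatial clustering
  # shared by the MBs of an AU) and a meshblock component; both carry the
  # same cross-ethnicity correlation so meshblock-level density
  # correlations survive the local jitter.
  w_au <- config$au_share_of_variance
  dens <- with_substream(seed, "densities", {
    z_au <- rmvn_chol(n_au, R)
    z_mb <- rmvn_chol(nrow(mb), R)
    d_au <- matrix(0, n_au, 3, dimnames = list(NULL, ETHNICITIES))
    d_mb <- matrix(0, nrow(mb), 3, dimnames = list(NULL, ETHNICITIES))
    for (k in seq_along(ETHNICITIES)) {
      s <- prof$clustering_sd[k]
      mu <- calibrate_logit_mean(dens_target[k], s)
      if (is.finite(mu)) {
        d_au[, k] <- plogis(mu + s * sqrt(w_au) * z_au[, k])
        d_mb[, k] <- plogis(mu + s * sqrt(w_au) * z_au[mb$au_id, k] +
                              s * sqrt(1 - w_au) * z_mb[, k])
      } else if (mu == Inf) {
        d_au[, k] <- 1
        d_mb[, k] <- 1
      } # mu == -Inf leaves zeros
    }
    list(au = d_au, mb = d_mb)
  })
  mb$dens_maori <- dens$mb[, "maori"]
  mb$dens_pacific <- dens$mb[, "pacific"]
  mb$dens_asian <- dens$mb[, "asian"]
  mb$dens_maori_au <- dens$au[mb$au_id, "maori"]
  mb$dens_pacific_au <- dens$au[mb$au_id, "pacific"]
  mb$dens_asian_au <- dens$au[mb$au_id, "asian"]

  check_density_correlations(mb, config)

  ## --- households ---------------------------------------------------------
  hh <- with_substream(seed, "households", {
    n_hh <- sum(mb$census_dwellings)
    mb_of_hh <- rep.int(mb$mb_id, mb$census_dwellings)
    eth <- matrix(FALSE, n_hh, 3, dimnames = list(NULL, ETHNICITIES))
    for (k in seq_along(ETHNICITIES)) {
      eth[, k] <- runif(n_hh) < dens$mb[mb_of_hh, k]
    }
    mean_size <- rep(config$mean_household_size, n_hh)
    for (k in seq_along(ETHNICITIES)) {
      bigger <- eth[, k] & prof$mean_household_size[k] > mean_size
      mean_size[bigger] <- prof$mean_household_size[k]
    }
    size <- 1L + rpois(n_hh, mean_size - 1)
    tibble(household_id = seq_len(n_hh), mb_id = mb_of_hh,
           au_id = mb$au_id[mb_of_hh], stratum_id = mb$stratum_id[mb_of_hh],
           n_persons = size,
           eth_maori = eth[, "maori"], eth_pacific = eth[, "pacific"],
           eth_asian = eth[, "asian"])
  })

  ## --- persons ------------------------------------------------------------
  per <- with_substream(seed, "persons", {
    n_per <- sum(hh$n_persons)
    hh_of <- rep.int(hh$household_id, hh$n_persons)
    pos <- sequence(hh$n_persons)
    is_adult <- pos == 1L | runif(n_per) < config$p_adult
    tibble(person_id = seq_len(n_per), household_id = hh_of,
           mb_id = hh$mb_id[hh_of], au_id = hh$au_id[hh_of],
           stratum_id = hh$stratum_id[hh_of],
           is_adult = is_adult,
           eth_maori = hh$eth_maori[hh_of], eth_pacific = hh$eth_pacific[hh_of],
           eth_asian = hh$eth_asian[hh_of])
  })

  ## --- electoral roll flags ----------------------------------------------
  per$on_roll_maori_descent <- with_substream(seed, "roll", {
    descent <- per$eth_maori | runif(nrow(per)) < config$descent_extra
    per$is_adult & descent & runif(nrow(per)) < config$roll_coverage
  })
  roll_by_hh <- rowsum(as.integer(per$on_roll_maori_descent), per$household_id,
                       reorder = FALSE)
  hh$roll_flag <- unname(roll_by_hh[, 1] > 0)
  hh$n_adults <- as.integer(rowsum(as.integer(per$is_adult), per$household_id,
                                   reorder = FALSE)[, 1])
  hh$n_children <- hh$n_persons - hh$n_adults
  mb$roll_addresses <- as.integer(tab_by(as.integer(hh$roll_flag), hh$mb_id, nrow(mb)))
  mb$census_persons <- as.integer(tab_by(hh$n_persons, hh$mb_id, nrow(mb)))

  str_real <- per |>
    count(.data$stratum_id, name = "persons") |>
    left_join(hh |> count(.data$stratum_id, name = "households"), by = "stratum_id")
  strata <- str_tbl |> left_join(str_real, by = "stratum_id")

  pop <- structure(
    list(strata = strata, meshblocks = mb, households = hh, persons = per,
         config = config),
    class = "df_population"
  )
  pop$index <- build_selection_index(pop)
  attach_outcomes(pop, config$outcome_specs)
}

# Sum `x` by integer group id 1..n (dense, zero-filled).
tab_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

check_density_correlations <- function(mb, config) {
  if (nrow(mb) < 30) return(invisible())  # too few MBs to assess
  tg <- config$target_density_correlations
  prev <- config$ethnic_profile$prevalence
  names(prev) <- config$ethnic_profile$ethnicity
  pairs <- list(pacific_asian = c("dens_pacific", "dens_asian"),
                maori_asian = c("dens_maori", "dens_asian"),
                maori_pacific = c("dens_maori", "dens_pacific"))
  for (nm in names(pairs)) {
    eths <- sub("dens_", "", pairs[[nm]])
    if (any(prev[eths] == 0)) next
    achieved <- stats::cor(mb[[pairs[[nm]][1]]], mb[[pairs[[nm]][2]]])
    if (is.na(achieved) || abs(achieved - tg[[nm]]) > 0.25) {
      warn(sprintf(
        "meshblock density correlation %s: achieved %.3f vs target %.3f (config may be infeasible)",
        nm, achieved, tg[[nm]]))
    }
  }
}

# CSR-style indexes for O(1) within-household and within-meshblock draws.
build_selection_index <- function(pop) {
  per <- pop$persons
  hh <- pop$households
  adult_rows <- which(per$is_adult)            # persons ordered by household
  child_rows <- which(!per$is_adult)
  list(
    adult_rows = adult_rows,
    adult_ptr = c(0L, cumsum(hh$n_adults)),
    child_rows = child_rows,
    child_ptr = c(0L, cumsum(hh$n_children)),
    hh_ptr = c(0L, cumsum(pop$meshblocks$census_dwellings)),  # hh ordered by MB
    roll_rows = which(hh$roll_flag),
    roll_ptr = c(0L, cumsum(tab_by(as.integer(hh$roll_flag), hh$mb_id,
                                   nrow(pop$meshblocks))))
  )
}

#' @export
print.df_population <- function(x, ...) {
  cat("<df_population>\n")
  cat(sprintf("  %d strata | %d area units | %s meshblocks | %s households | %s persons\n",
              nrow(x$strata), max(x$meshblocks$au_id),
              format(nrow(x$meshblocks), big.mark = ","),
              format(nrow(x$households), big.mark = ","),
              format(nrow(x$persons), big.mark = ",")))
  cat(sprintf("  adults: %s (%.0f%%) | roll-flagged households: %s\n",
              format(sum(x$persons$is_adult), big.mark = ","),
              100 * mean(x$persons$is_adult),
              format(sum(x$households$roll_flag), big.mark = ",")))
  outs <- setdiff(names(x$persons),
                  c("person_id", "household_id", "mb_id", "au_id", "stratum_id",
                    "is_adult", "eth_maori", "eth_pacific", "eth_asian",
                    "on_roll_maori_descent"))
  if (length(outs)) cat("  outcomes:", paste(outs, collapse = ", "), "\n")
  invisible(x)
}

#' Attach clustered binary outcomes to a population
#'
#' Each outcome is generated from meshblock-level random prevalences
#' `p_i ~ Beta(a, b)` with mean equal to the specified prevalence and
#' variance `icc * p * (1 - p)`, so the within-meshblock intra-class
#' correlation of the binary outcome equals `icc` exactly in expectation;
#' persons are then independent Bernoulli draws given their meshblock.
#' Per-ethnicity log-odds shifts, if specified, are applied person-wise.
#' Re-attaching an outcome with the same name overwrites it; generation is
#' reproducible via a named substream per outcome.
#'
#' @param population A `df_population`.
#' @param outcome_specs List of [outcome_spec()] objects.
#' @return The population with one added logical column per outcome.
#' @export
attach_outcomes <- function(population, outcome_specs) {
  stopifnot(inherits(population, "df_population"))
  per <- population$persons
  n_mb <- nrow(population$meshblocks)
  seed <- population$config$seed
  for (spec in outcome_specs) {
    if (!inherits(spec, "df_outcome_spec")) {
      abort("outcome_specs must be built with outcome_spec()")
    }
    p <- spec$prevalence
    rho <- spec$icc
    y <- with_substream(seed, paste0("outcome_", spec$name), {
      p_mb <- if (rho == 0) {
        rep(p, n_mb)
      } else {
        nu <- (1 - rho) / rho   # Beta precision: var = p(1-p)/(nu+1) * ... = rho p(1-p)
        rbeta(n_mb, p * nu, (1 - p) * nu)
      }
      pp <- p_mb[per$mb_id]
      if (!is.null(spec$shifts)) {
        lo <- qlogis(pmin(pmax(pp, 1e-12), 1 - 1e-12))
        for (e in names(spec$shifts)) {
          flag <- per[[paste0("eth_", e)]]
          if (is.null(flag)) abort(sprintf("unknown ethnicity '%s' in outcome shifts", e))
          lo <- lo + spec$shifts[[e]] * flag
        }
        pp <- plogis(lo)
      }
      runif(nrow(per)) < pp
    })
    per[[spec$name]] <- y
  }
  population$persons <- per
  population
}

#' Take a census snapshot of a population as a sampling frame
#'
#' Returns the meshblock-level frame the design engine consumes: census
#' person counts `N*_i`, census dwelling counts, ethnic densities at
#' meshblock and area-unit level, and roll address counts. `drift` emulates
#' an out-of-date census: current dwelling counts `H_i` are perturbed around
#' the census values by a mean relative change of `drift`, while `N*_i` and
#' the densities keep their generation-time values (drift 0 returns the
#' frame equal to the truth). Drifted dwelling counts feed the
#' within-meshblock take `H_i c / N*_i` at draw time.
#'
#' @param population A `df_population`.
#' @param drift Non-negative mean relative perturbation of current dwelling
#'   counts.
#' @param seed Optional seed for the drift draw (defaults to the population
#'   seed's `census_drift` substream).
#' @return A tibble of class `df_frame`, one row per meshblock.
#' @export
census_snapshot <- function(population, drift = 0, seed = NULL) {
  stopifnot(inherits(population, "df_population"), drift >= 0)
  frame <- population$meshblocks
  if (drift == 0) {
    frame$dwellings_current <- frame$census_dwellings
  } else {
    seed <- seed %||% population$config$seed
    frame$dwellings_current <- with_substream(seed, "census_drift", {
      # E|N(0, s)| = s * sqrt(2/pi); choose s so the mean |relative change|
      # equals `drift`.
      factor <- 1 + rnorm(nrow(frame), 0, drift * sqrt(pi / 2))
      pmax(0L, as.integer(round(frame$census_dwellings * factor)))
    })
  }
  class(frame) <- c("df_frame", class(tibble()))
  frame
}
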