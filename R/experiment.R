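# Reproducible experiment runner: population -> replicated draws ->
# estimates -> aggregated Monte-Carlo summaries and report tables.

#' Experiment configuration
#'
#' Bundles everything a reproducible design experiment needs: the population
#' and design configurations, the number of replicate draws, which outcomes
#' and subpopulations to report, the census drift applied to the frame, and
#' a master seed from which all per-replicate seeds are derived.
#'
#' @param population_config A [population_config()].
#' @param design_config A [design_config()].
#' @param replicates Number of replicate draws (>= 1).
#' @param outcomes Outcome columns to estimate; defaults to the population
#'   config's outcome names.
#' @param subpops Subpopulations to report.
#' @param census_drift Drift passed to [census_snapshot()].
#' @param n_mc Monte-Carlo replicates for pooled inclusion probabilities.
#' @param decompose_draws Number of leading draws over which design-effect
#'   components are averaged.
#' @param seed Master seed.
#' @return An object of class `df_expconfig`.
#' @export
experiment_config <- function(population_config, design_config,
                              replicates = 100, outcomes = NULL,
                              subpops = SUBPOPS, census_drift = 0,
                              n_mc = 1000, decompose_draws = 25, seed = 1L) {
  stopifnot(inherits(population_config, "df_popconfig"),
            inherits(design_config, "df_design"), replicates >= 1)
  outcomes <- outcomes %||%
    vapply(population_config$outcome_specs, `[[`, "", "name")
  structure(
    list(population_config = population_config, design_config = design_config,
         replicates = as.integer(replicates), outcomes = outcomes,
         subpops = subpops, census_drift = census_drift, n_mc = n_mc,
         decompose_draws = as.integer(decompose_draws),
         seed = as.integer(seed)),
    class = "df_expconfig"
  )
}

#' Run a design experiment
#'
#' Generates the population, repeats draw-and-estimate over the configured
#' replicates, and aggregates: per-indicator Monte-Carlo mean, bias against
#' population truth, Monte-Carlo SE and realized design effect; a
#' single-draw indicator table with jackknife SEs (the survey's reporting
#' layout); design-effect components averaged over leading draws; and the
#' net variance-change summary. Replicate `r` draws under a seed derived
#' from the master seed, so replicates are independent and individually
#' re-runnable; the bundle embeds its config hash, seed and package version.
#'
#' With `replicates = 1` the Monte-Carlo summary is omitted (a single draw
#' cannot estimate sampling variance).
#'
#' @param config An [experiment_config()].
#' @return A list of class `df_experiment` with elements `indicators`,
#'   `mc_summary` (NULL when `replicates = 1`), `components`,
#'   `variance_change`, `truth`, `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "df_expconfig"))
  pop <- generate_population(config$population_config)
  frame <- census_snapshot(pop, config$census_drift,
                           seed = substream_seed(config$seed, "drift"))
  plan <- design_plan(frame, config$design_config)
  probs <- inclusion_probabilities(pop, plan, n_mc = config$n_mc,
                                   seed = substream_seed(config$seed, "probs"))
  summaries <- frame_summaries(pop)
  adults <- pop$persons[pop$persons$is_adult, ]
  truth <- purrr::map_dfr(config$outcomes, function(oc) {
    purrr::map_dfr(config$subpops, function(sp) {
      keep <- subpop_mask(adults, sp)
      tibble(outcome = oc, subpop = sp,
             truth = mean(adults[[oc]][keep]), n_pop = sum(keep))
    })
  })

  ests <- vector("list", config$replicates)
  n_subs <- vector("list", config$replicates)
  comps <- vector("list", min(config$replicates, config$decompose_draws))
  for (r in seq_len(config$replicates)) {
    draw <- run_annual_sample(pop, plan = plan,
                              seed = substream_seed(config$seed, paste0("rep_", r)),
                              probs = probs)
    est <- purrr::map_dfr(config$outcomes, function(oc) {
      purrr::map_dfr(config$subpops, function(sp) {
        estimate_prevalence(draw, oc, sp)
      })
    })
    ests[[r]] <- est$prevalence
    n_subs[[r]] <- est$n
    if (r <= length(comps)) {
      comps[[r]] <- decompose_deff(draw, summaries, subpops = config$subpops,
                                   exponent = config$design_config$power_exponent)
    }
    if (r == 1L) {
      first_draw <- draw
    }
  }
  grid <- tidyr::expand_grid(outcome = config$outcomes, subpop = config$subpops)

  mc_summary <- NULL
  if (config$replicates > 1L) {
    est_mat <- do.call(rbind, ests)
    n_mat <- do.call(rbind, n_subs)
    mc_summary <- grid |>
      mutate(
        mean_estimate = colMeans(est_mat),
        mc_se = apply(est_mat, 2, sd) / sqrt(nrow(est_mat)),
        sd_estimate = apply(est_mat, 2, sd),
        mean_n = colMeans(n_mat)
      ) |>
      left_join(truth, by = c("outcome", "subpop")) |>
      mutate(
        bias = .data$mean_estimate - .data$truth,
        realized_deff = .data$sd_estimate^2 /
          (.data$mean_estimate * (1 - .data$mean_estimate) / .data$mean_n)
      )
  }

  num <- config$subpops
  comp_avg <- comps[[1]]
  if (length(comps) > 1L) {
    vals <- Reduce(`+`, lapply(comps, function(x) as.matrix(x[, num])))
    comp_avg[, num] <- as_tibble(vals / length(comps))
  }

  indicators <- estimate_indicators(first_draw, config$outcomes,
                                    subpops = config$subpops,
                                    seed = substream_seed(config$seed, "jk"))

  structure(
    list(indicators = indicators,
         mc_summary = mc_summary,
         components = comp_avg,
         variance_change = summarize_variance_change(comp_avg),
         truth = truth,
         provenance = list(
           seed = config$seed,
           config_hash = rlang::hash(config),
           replicates = config$replicates,
           package_version = as.character(utils::packageVersion("dualframe")))),
    class = "df_experiment"
  )
}

#' @export
print.df_experiment <- function(x, ...) {
  cat("<df_experiment>", x$provenance$replicates, "replicate draw(s), seed",
      x$provenance$seed, "\n")
  cat("  variance change from within-stratum targeting + dual frame:\n")
  vc <- x$variance_change
  cat(paste(sprintf("    %-8s %+.0f%%", vc$subpop, vc$pct_change), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Write the report tables of an experiment
#'
#' Renders the bundle's tables to a directory: `indicators` (prevalence, SE,
#' ICC, design effect per subpopulation), `mc_summary` (when present),
#' `components` (the 7-row design-effect component table),
#' `variance_change`, and a `meta.json` with the provenance. `format`
#' `"tsv"` writes tab-separated files; `"text"` writes aligned
#' human-readable tables. Empty cells are written as missing, not zero.
#'
#' @param bundle A `df_experiment`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"text"`.
#' @return Invisibly, the written file paths.
#' @export
render_tables <- function(bundle, dir, format = c("tsv", "text")) {
  stopifnot(inherits(bundle, "df_experiment"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(indicators = bundle$indicators,
               mc_summary = bundle$mc_summary,
               components = bundle$components,
               variance_change = bundle$variance_change)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  ext <- if (format == "tsv") ".tsv" else ".txt"
  paths <- character(0)
  for (nm in names(tabs)) {
    path <- file.path(dir, paste0(nm, ext))
    if (format == "tsv") {
      readr::write_tsv(tabs[[nm]], path)
    } else {
      writeLines(utils::capture.output(print(as.data.frame(tabs[[nm]]), digits = 4)),
                 path)
    }
    paths <- c(paths, path)
  }
  meta <- file.path(dir, "meta.json")
  jsonlite::write_json(bundle$provenance, meta, auto_unbox = TRUE)
  invisible(c(paths, meta))
}
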