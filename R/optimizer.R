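# Numerical choice of targeting-factor coefficients: minimise a weighted
# combination of anticipated subpopulation variances under the Kish
# variance model, evaluated on a frame.

#' Objective specification for targeting-coefficient optimisation
#'
#' Defines what "best coefficients" means: importance weights over the
#' subpopulations, anticipated outcome prevalences (variance scale
#' `p (1 - p)` per subpopulation), the evaluation frame, and the fixed
#' design parameters (stratum allocation and within-meshblock take). The
#' anticipated variance of a subpopulation mean follows the Kish model
#' `(1 + C^2_sub) / n_sub * S^2_sub`, computed from the frame-level
#' selection probabilities a candidate coefficient vector induces; it is a
#' surrogate for evaluation against historical survey data, which a design
#' study on synthetic frames does not have.
#'
#' @param population A `df_population` (supplies person-level structure).
#' @param frame A [census_snapshot()] frame.
#' @param design A [design_config()] carrying the fixed parameters.
#' @param importance Named non-negative weights over
#'   `c("all", "maori", "pacific", "asian")`; not all zero. The objective is
#'   invariant to rescaling these by a positive constant.
#' @param prevalences Named anticipated prevalences per subpopulation
#'   (default 0.5 each, the most conservative variance scale).
#' @return An object of class `df_objective`.
#' @export
objective_spec <- function(population, frame, design = design_config(),
                           importance = c(all = 1, maori = 1, pacific = 1, asian = 1),
                           prevalences = c(all = 0.5, maori = 0.5,
                                           pacific = 0.5, asian = 0.5)) {
  stopifnot(inherits(population, "df_population"), inherits(frame, "df_frame"))
  if (any(importance < 0) || all(importance == 0)) {
    abort("importance weights must be non-negative and not all zero")
  }
  subpops <- names(importance)
  if (!all(subpops %in% SUBPOPS)) abort("importance names must be among all/maori/pacific/asian")
  alloc <- design_allocation(frame, design)

  # Per-meshblock, per-subpopulation aggregates over adults, so each
  # objective evaluation is O(#meshblocks):
  #   n_sub   = sum_i p_hh(i) * A[i]   with A[i] = sum_{sub adults in i} 1/a_hh
  #   T_sub   = sum_i B[i] / p_hh(i)   with B[i] = sum_{sub adults in i} a_hh
  #   N_sub   = sum_i M[i]
  per <- population$persons[population$persons$is_adult, ]
  a_hh <- population$households$n_adults[per$household_id]
  n_mb <- nrow(frame)
  agg <- lapply(setNames(subpops, subpops), function(sp) {
    keep <- if (sp == "all") rep(TRUE, nrow(per)) else per[[paste0("eth_", sp)]]
    list(A = tab_by((1 / a_hh)[keep], per$mb_id[keep], n_mb),
         B = tab_by(a_hh[keep], per$mb_id[keep], n_mb),
         M = sum(keep))
  })
  structure(
    list(frame = frame, design = design, allocation = alloc,
         importance = importance, prevalences = prevalences,
         subpops = subpops, agg = agg,
         stratum_of = frame$stratum_id),
    class = "df_objective"
  )
}

#' Anticipated subpopulation variances for candidate coefficients
#'
#' Evaluates the Kish variance model for each subpopulation under the
#' area-frame selection probabilities a candidate coefficient vector
#' induces: meshblock probabilities from the PPS rule with targeting factor
#' `f`, household fraction `c / N*_i`, one adult per household. Returns the
#' per-subpopulation variance proxies and the weighted objective.
#'
#' @param coefficients Five non-negative coefficients
#'   `(b_pac_mb, b_pac_au, b_asi_mb, b_asi_au, b_const)` on the unit simplex
#'   (they are normalised to sum to 1).
#' @param spec An [objective_spec()].
#' @return A list with `objective` (scalar), `proxies` (tibble: subpop,
#'   n_sub, one_plus_c2, variance).
#' @export
anticipated_variance <- function(coefficients, spec) {
  stopifnot(inherits(spec, "df_objective"))
  b <- coefficients
  if (any(b < 0)) abort("coefficients must be non-negative")
  if (sum(b) <= 0) abort("coefficients must not be all zero")
  b <- b / sum(b)
  frame <- spec$frame
  f <- targeting_factor(frame$dens_pacific, frame$dens_pacific_au,
                        frame$dens_asian, frame$dens_asian_au,
                        setNames(b, c("b_pac_mb", "b_pac_au", "b_asi_mb",
                                      "b_asi_au", "b_const")))
  size <- frame$census_dwellings * f
  if (any(size <= 0)) {
    abort("candidate coefficients give zero selection probability for some meshblocks")
  }
  pi_mb <- numeric(nrow(frame))
  for (k in seq_len(nrow(spec$allocation))) {
    h <- spec$allocation$stratum_id[k]
    rows <- which(spec$stratum_of == h)
    pi_mb[rows] <- certainty_peel(size[rows], spec$allocation$m_h[k])
  }
  p_hh <- pi_mb * pmin(1, spec$design$within_mb_target / frame$census_dwellings)
  proxies <- purrr::map_dfr(spec$subpops, function(sp) {
    agg <- spec$agg[[sp]]
    pos <- p_hh > 0 & (agg$A > 0 | agg$B > 0)
    n_sub <- sum(p_hh[pos] * agg$A[pos])
    t_sub <- sum(agg$B[pos] / p_hh[pos])
    one_c2 <- n_sub * t_sub / agg$M^2
    p <- spec$prevalences[[sp]]
    tibble(subpop = sp, n_sub = n_sub, one_plus_c2 = one_c2,
           variance = one_c2 / n_sub * p * (1 - p))
  })
  list(objective = sum(spec$importance * proxies$variance),
       proxies = proxies)
}

#' Optimise targeting-factor coefficients
#'
#' Derivative-free minimisation of the anticipated-variance objective over
#' the coefficient simplex, via Nelder-Mead on a softmax parameterisation
#' with multiple starts (the published defaults, the uniform vector, the
#' near-pure-constant vector, and seeded random starts). Coefficients may be
#' restricted to a subset via `free`; the rest are fixed at zero.
#'
#' @param spec An [objective_spec()].
#' @param free Character subset of
#'   `c("b_pac_mb", "b_pac_au", "b_asi_mb", "b_asi_au", "b_const")` to
#'   optimise over (default: all five).
#' @param n_random_starts Number of additional random starts.
#' @param seed Seed for the random starts (substream `optimizer`).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `df_coefopt`: `coefficients` (full named
#'   vector summing to 1), `objective`, `proxies` at the optimum, `trace`
#'   (tibble of evaluations), `convergence`.
#' @export
optimize_coefficients <- function(spec, free = names(design_config()$targeting_coefficients),
                                  n_random_starts = 4, seed = 1L,
                                  maxit = 400) {
  all_names <- names(design_config()$targeting_coefficients)
  stopifnot(all(free %in% all_names), length(free) >= 1)
  trace_env <- new.env()
  trace_env$rows <- list()

  expand <- function(theta) {
    b <- setNames(numeric(5), all_names)
    w <- exp(theta - max(theta))
    b[free] <- w / sum(w)
    b
  }
  obj <- function(theta) {
    b <- expand(theta)
    val <- tryCatch(anticipated_variance(b, spec)$objective,
                    error = function(e) Inf)
    trace_env$rows[[length(trace_env$rows) + 1L]] <- c(val, b)
    val
  }

  defaults <- design_config()$targeting_coefficients
  to_theta <- function(b) log(pmax(b[free], 1e-4))
  starts <- list(to_theta(defaults / sum(defaults)),
                 rep(0, length(free)),
                 to_theta(setNames(c(0.01, 0.01, 0.01, 0.01, 0.96), all_names)))
  starts <- c(starts, with_substream(seed, "optimizer", {
    lapply(seq_len(n_random_starts), function(i) rnorm(length(free)))
  }))

  best <- NULL
  convergence <- 1L
  for (s in starts) {
    fit <- if (length(free) == 1L) {
      list(par = s, value = obj(s), convergence = 0L)
    } else {
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    }
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      convergence <- fit$convergence
    }
  }
  if (convergence != 0L) {
    warn("optimizer did not fully converge; returning the best point found")
  }
  coef_best <- expand(best$par)
  av <- anticipated_variance(coef_best, spec)
  tr <- do.call(rbind, trace_env$rows)
  colnames(tr) <- c("objective", all_names)
  structure(
    list(coefficients = coef_best, objective = av$objective,
         proxies = av$proxies, trace = as_tibble(as.data.frame(tr)),
         convergence = convergence, free = free),
    class = "df_coefopt"
  )
}

#' @export
print.df_coefopt <- function(x, ...) {
  cat("<df_coefopt>\n  coefficients:",
      paste(sprintf("%s=%.3f", names(x$coefficients), x$coefficients),
            collapse = " "), "\n")
  cat(sprintf("  objective: %.6g (%d evaluations, convergence %d)\n",
              x$objective, nrow(x$trace), x$convergence))
  invisible(x)
}
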