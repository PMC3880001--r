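# Estimation from a weighted draw: Hajek prevalences, delete-a-group
# jackknife replicate weights, design effects, ANOVA intra-class
# correlations, and the RR3 response rate.

SUBPOPS <- c("all", "maori", "pacific", "asian")

subpop_mask <- function(data, subpop) {
  subpop <- match.arg(subpop, SUBPOPS)
  if (subpop == "all") rep(TRUE, nrow(data)) else data[[paste0("eth_", subpop)]]
}

#' Hajek (ratio) prevalence estimate
#'
#' Weighted mean of a binary outcome over the respondents flagged for a
#' subpopulation, with the weighted count in the denominator (the Hajek
#' estimator; survey denominators are estimated in practice, and the ratio
#' form is what survey weights are designed for). If the draw carries
#' jackknife replicate weights (see [jackknife_replicates()]) a replication
#' standard error and design effect are included.
#'
#' @param data A weighted draw (`df_draw` with a `weight` column).
#' @param outcome Name of a logical/0-1 outcome column.
#' @param subpop One of `"all"`, `"maori"`, `"pacific"`, `"asian"`.
#' @param adults_only Restrict to respondents aged 15+ (the default; the
#'   indicator machinery is defined on adults).
#' @return One-row tibble: `subpop`, `outcome`, `prevalence`, `se`, `n`,
#'   `deff` (`se` and `deff` are `NA` without replicate weights).
#' @export
estimate_prevalence <- function(data, outcome, subpop = "all",
                                adults_only = TRUE) {
  stopifnot("weight" %in% names(data), outcome %in% names(data))
  keep <- subpop_mask(data, subpop) & (!adults_only | data$is_adult)
  d <- data[keep, ]
  if (nrow(d) == 0L) abort(sprintf("empty subpopulation sample: %s", subpop))
  y <- as.numeric(d[[outcome]])
  w <- d$weight
  p <- sum(w * y) / sum(w)
  se <- NA_real_
  deff <- NA_real_
  reps <- attr(data, "replicates")
  if (!is.null(reps)) {
    rw <- reps$weights[keep, , drop = FALSE]
    theta <- colSums(rw * y) / colSums(rw)
    v <- jk_variance(theta, p, reps$G)
    se <- sqrt(v)
    if (p > 0 && p < 1) deff <- design_effect(p, se, nrow(d))
  }
  tibble(subpop = subpop, outcome = outcome, prevalence = p, se = se,
         n = nrow(d), deff = deff)
}

#' Delete-a-group jackknife replicate weights
#'
#' Groups the primary sampling units (meshblocks, from both frames) randomly
#' into `G` groups, spreading each stratum's PSUs across groups. Replicate
#' `g` zeroes the weights of its PSUs and rescales the remaining weights
#' within each stratum by the ratio of the full-sample to the remaining
#' stratum weight total, so every replicate column reproduces the
#' full-sample weighted stratum totals exactly. The variance of a statistic
#' is `(G - 1) / G * sum_g (theta_g - theta)^2`.
#'
#' Strata with a single PSU contribute no variance (their PSU is never
#' deleted); a message reports how many.
#'
#' @param data A weighted draw.
#' @param G Number of replicate groups (default 100); `G` equal to the
#'   number of PSUs gives the delete-one jackknife.
#' @param seed Seed for the random grouping (substream `jackknife`).
#' @return `data` with a `replicates` attribute: list of `weights`
#'   (n x G matrix), `G`, and the PSU group assignment.
#' @export
jackknife_replicates <- function(data, G = 100, seed = 1L) {
  stopifnot("weight" %in% names(data))
  psu <- paste(data$stratum_id, data$mb_id)
  psus <- unique(psu)
  if (G > length(psus)) {
    abort(sprintf("G = %d exceeds the number of PSUs (%d)", G, length(psus)))
  }
  psu_stratum <- data$stratum_id[match(psus, psu)]
  group_of <- integer(length(psus))
  with_substream(seed, "jackknife", {
    start <- sample.int(G, 1L)
    for (rows in split(seq_along(psus), psu_stratum)) {
      # Round-robin over a shuffled order with a random rotating start, so no
      # group ever contains all PSUs of a multi-PSU stratum.
      g <- (start + seq_along(rows) - 2L) %% G + 1L
      group_of[rows[sample.int(length(rows))]] <- g
      start <- start + length(rows)
    }
  })
  g_i <- group_of[match(psu, psus)]
  h_i <- as.character(data$stratum_id)
  w <- data$weight
  tot_h <- rowsum(w, h_i)
  rw <- matrix(w, nrow(data), G)
  single <- 0L
  for (h in rownames(tot_h)) {
    rows <- which(h_i == h)
    if (length(unique(g_i[rows])) == 1L && length(rows) > 0L &&
        length(unique(psu[rows])) == 1L) {
      single <- single + 1L
      next # lone PSU: never deleted
    }
    for (g in unique(g_i[rows])) {
      del <- rows[g_i[rows] == g]
      keepw <- tot_h[h, 1] - sum(w[del])
      if (keepw <= 0) next
      rw[del, g] <- 0
      scale <- tot_h[h, 1] / keepw
      rw[setdiff(rows, del), g] <- w[setdiff(rows, del)] * scale
    }
  }
  if (single > 0) inform(sprintf("%d stratum/strata have a single PSU and contribute no variance", single))
  attr(data, "replicates") <- list(weights = rw, G = G,
                                   psu = psus, group = group_of)
  data
}

#' Jackknife variance from replicate estimates
#'
#' @param theta_reps Vector of `G` replicate estimates.
#' @param theta Full-sample estimate.
#' @param G Number of groups.
#' @return The delete-a-group jackknife variance
#'   `(G - 1) / G * sum((theta_reps - theta)^2)`.
#' @export
jk_variance <- function(theta_reps, theta, G = length(theta_reps)) {
  (G - 1) / G * sum((theta_reps - theta)^2)
}

#' Design effect of a prevalence estimate
#'
#' Ratio of the complex-design variance to the binomial variance a simple
#' random sample of the same size would achieve:
#' `deff = se^2 / (p (1 - p) / n)`.
#'
#' @param prevalence Estimated prevalence in (0, 1).
#' @param se Estimated standard error.
#' @param n Subpopulation sample size.
#' @return The design effect.
#' @export
design_effect <- function(prevalence, se, n) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("design_effect is undefined for prevalence 0 or 1")
  }
  se^2 / (prevalence * (1 - prevalence) / n)
}

#' ANOVA estimator of the intra-class correlation
#'
#' One-way random-effects ANOVA estimator on values grouped by cluster
#' (meshblock): `(MSB - MSW) / (MSB + (k0 - 1) MSW)` with
#' `k0 = (N - sum n_i^2 / N) / (a - 1)` the unequal-group-size adjustment,
#' clipped to `[0, 1]`.
#'
#' @param data Data frame containing the outcome and group columns (or pass
#'   two vectors via `y` and `group` directly).
#' @param outcome Outcome column name (binary or numeric).
#' @param group Grouping column name (default `mb_id`).
#' @return The ICC estimate (scalar).
#' @export
icc_anova <- function(data, outcome = "y", group = "mb_id") {
  if (is.data.frame(data)) {
    y <- as.numeric(data[[outcome]])
    g <- data[[group]]
  } else {
    y <- as.numeric(data)
    g <- outcome
  }
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- as.character(g[ok])
  n_i <- table(g)
  a <- length(n_i)
  N <- length(y)
  if (a < 2L || N <= a) abort("need at least 2 groups and more observations than groups")
  means <- rowsum(y, g) / as.numeric(n_i[order(names(n_i))])
  # rowsum orders by group name; align n_i the same way
  n_srt <- as.numeric(n_i[rownames(means)])
  gm <- mean(y)
  ssb <- sum(n_srt * (means[, 1] - gm)^2)
  ssw <- sum((y - means[match(g, rownames(means)), 1])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(n_srt^2) / N) / (a - 1)
  if (msw == 0 && msb == 0) return(0)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  min(max(icc, 0), 1)
}

#' AAPOR RR3 response rate
#'
#' Interviews divided by interviews plus eligible non-interviews plus an
#' estimated-eligible share `e` of cases of unknown eligibility. By default
#' `e` is the eligibility rate among resolved cases,
#' `(I + R + O) / (I + R + O + ineligible)`.
#'
#' @param dispositions Named vector or one-row data frame of counts with
#'   elements `interviews`, `refusals`, `other_eligible`, `unknown`,
#'   `ineligible` (missing elements default to 0).
#' @param eligibility_rate Optional override for `e` in `[0, 1]`.
#' @return The RR3 response rate in `[0, 1]`.
#' @export
#' @examples
#' response_rate_rr3(c(interviews = 79, refusals = 21))  # 0.79
response_rate_rr3 <- function(dispositions, eligibility_rate = NULL) {
  if (is.data.frame(dispositions)) dispositions <- unlist(dispositions[1, ])
  d <- c(interviews = 0, refusals = 0, other_eligible = 0, unknown = 0,
         ineligible = 0)
  unknown_names <- setdiff(names(dispositions), names(d))
  if (length(unknown_names)) {
    abort(paste("unknown disposition(s):", paste(unknown_names, collapse = ", ")))
  }
  if (any(dispositions < 0)) abort("disposition counts must be non-negative")
  d[names(dispositions)] <- dispositions
  resolved_eligible <- d[["interviews"]] + d[["refusals"]] + d[["other_eligible"]]
  e <- eligibility_rate %||%
    (if (resolved_eligible + d[["ineligible"]] > 0) {
      resolved_eligible / (resolved_eligible + d[["ineligible"]])
    } else 0)
  assert_prob(e, "eligibility_rate")
  denom <- resolved_eligible + e * d[["unknown"]]
  if (denom == 0) abort("empty denominator: no eligible or estimated-eligible cases")
  unname(d[["interviews"]] / denom)
}

#' Indicator table in the survey's reporting layout
#'
#' Computes, for each outcome and subpopulation, the Hajek prevalence, its
#' jackknife SE, the design effect, and the population ANOVA ICC of the
#' outcome within meshblocks (estimated from the sample's adults grouped by
#' meshblock).
#'
#' @param data A weighted draw with replicate weights (or `G`/`seed` to add
#'   them here).
#' @param outcomes Character vector of outcome columns.
#' @param subpops Subset of `"all"`, `"maori"`, `"pacific"`, `"asian"`.
#' @param G,seed Passed to [jackknife_replicates()] when `data` lacks them.
#' @return A tibble of class `df_estimates` with one row per outcome x
#'   subpopulation.
#' @export
estimate_indicators <- function(data, outcomes,
                                subpops = SUBPOPS, G = 100, seed = 1L) {
  if (is.null(attr(data, "replicates"))) {
    G <- min(G, length(unique(paste(data$stratum_id, data$mb_id))))
    data <- jackknife_replicates(data, G = G, seed = seed)
  }
  grid <- tidyr::expand_grid(outcome = outcomes, subpop = subpops)
  out <- purrr::pmap_dfr(grid, function(outcome, subpop) {
    est <- estimate_prevalence(data, outcome, subpop)
    adults <- data[data$is_adult & subpop_mask(data, subpop), ]
    est$icc <- tryCatch(icc_anova(adults, outcome, "mb_id"),
                        error = function(e) NA_real_)
    est
  })
  class(out) <- c("df_estimates", class(out))
  out
}
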