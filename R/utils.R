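# Internal helpers: seeded substreams, rounding rules, systematic PPS.

#' Derive a reproducible substream seed
#'
#' A single master seed drives every stochastic stage (population generation,
#' roll draw, area draw, household and person selection, quarter assignment,
#' replicate grouping). Each stage draws from its own substream whose seed is
#' a deterministic hash of the master seed and a stage label, so any stage can
#' be re-run in isolation and stages do not consume each other's random
#' numbers.
#'
#' @param seed Integer master seed.
#' @param label Character stage label, e.g. `"roll"`, `"area"`.
#' @return An integer seed in `[0, 2^28)`.
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  hex <- substr(rlang::hash(list(as.integer(seed), label)), 1L, 7L)
  strtoi(hex, base = 16L)
}

# Evaluate `expr` under the substream RNG without disturbing the caller's
# RNG state. Hand-rolled save/restore: this sits on the hot path of
# replicated draws, where the generic helpers cost more than the draw.
with_substream <- function(seed, label, expr) {
  # force the promise first: evaluating `seed` may itself consume random
  # numbers in the caller's stream, which must happen before the state is
  # saved for restoration
  sub <- substream_seed(seed, label)
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(sub)
  expr
}

#' Largest-remainder apportionment
#'
#' Rounds fractional allocations to integers summing exactly to `total`.
#' Optionally guarantees at least one unit per class (every non-empty stratum
#' must receive some sample).
#'
#' @param shares Non-negative numeric vector of raw (unnormalised) shares.
#' @param total Integer total to apportion.
#' @param min_one Guarantee >= 1 per positive share?
#' @return Integer vector summing to `total`.
#' @keywords internal
largest_remainder <- function(shares, total, min_one = TRUE) {
  stopifnot(all(shares >= 0), total >= 0)
  if (sum(shares) == 0) {
    return(rep(0L, length(shares)))
  }
  base <- rep(0L, length(shares))
  if (min_one) {
    base[shares > 0] <- 1L
    if (sum(base) > total) {
      abort(sprintf("total (%d) is smaller than the number of non-empty classes (%d)",
                    total, sum(base)))
    }
  }
  remainder <- total - sum(base)
  quota <- shares / sum(shares) * remainder
  fl <- floor(quota)
  out <- base + as.integer(fl)
  left <- remainder - sum(fl)
  if (left > 0) {
    frac <- quota - fl
    top <- order(frac, decreasing = TRUE)[seq_len(left)]
    out[top] <- out[top] + 1L
  }
  out
}

#' Stochastic rounding
#'
#' Rounds `x` to `floor(x)` or `ceiling(x)` with probability equal to the
#' fractional part, so `E[round] = x`. Used for fractional within-meshblock
#' household takes, which keeps household selection probabilities exactly
#' proportional to the design's targeting factor (deterministic rounding would
#' bias them).
#'
#' @param x Non-negative numeric vector.
#' @return Integer vector with expectation `x`.
#' @keywords internal
stochastic_round <- function(x) {
  stopifnot(all(x >= 0))
  fl <- floor(x)
  frac <- x - fl
  as.integer(fl + (runif(length(x)) < frac))
}

#' Certainty-peeled inclusion probabilities
#'
#' Computes PPS inclusion probabilities `m * size / sum(size)` and resolves
#' units whose probability reaches 1 ("certainty" units, e.g. very large
#' meshblocks) by fixing them at exactly 1 and re-solving the remainder with
#' `m - #certainties`, iterating until all probabilities lie in (0, 1].
#'
#' @param size Positive size measures (zero-size units get probability 0).
#' @param m Integer number of units to select.
#' @return Numeric vector of inclusion probabilities summing to `m`.
#' @keywords internal
certainty_peel <- function(size, m) {
  stopifnot(all(size >= 0), m >= 0, m <= sum(size > 0))
  n <- length(size)
  pi <- numeric(n)
  active <- size > 0
  m_left <- m
  repeat {
    if (m_left == 0 || !any(active)) break
    p <- m_left * size[active] / sum(size[active])
    if (all(p < 1)) {
      pi[active] <- p
      break
    }
    cert <- active
    cert[active] <- p >= 1
    pi[cert] <- 1
    m_left <- m_left - sum(cert)
    active <- active & !cert
  }
  pi
}

#' Randomized-order systematic PPS draw
#'
#' Selects units with the given target inclusion probabilities using
#' systematic sampling on a randomly permuted frame. Certainty units
#' (`pi == 1`) are always selected; the remainder are drawn systematically so
#' that realized inclusion probabilities equal `pi` exactly.
#'
#' @param pi Inclusion probabilities in `[0, 1]` summing to an integer.
#' @return Logical selection indicator.
#' @keywords internal
pps_systematic <- function(pi) {
  stopifnot(all(pi >= 0), all(pi <= 1 + 1e-9))
  sel <- pi >= 1 - 1e-12
  rest <- which(!sel & pi > 0)
  if (length(rest)) {
    p <- pi[rest]
    m <- sum(p)
    m_int <- round(m)
    if (abs(m - m_int) > 1e-6) {
      abort("non-certainty selection probabilities must sum to an integer")
    }
    if (m_int > 0) {
      ord <- rest[sample.int(length(rest))]
      cum <- cumsum(pi[ord])
      u <- runif(1)
      hits <- findInterval(u + seq_len(m_int) - 1, c(0, cum), left.open = TRUE)
      sel[ord[hits]] <- TRUE
    }
  }
  sel
}

# Largest-remainder apportionment with per-class caps: classes that hit
# their cap are frozen and the excess re-apportioned among the rest.
capped_apportion <- function(shares, total, cap) {
  stopifnot(total <= sum(cap))
  out <- rep(0L, length(shares))
  active <- shares > 0 & cap > 0
  left <- as.integer(total)
  repeat {
    if (left == 0L || !any(active)) break
    alloc <- largest_remainder(shares * active, left,
                               min_one = left >= sum(active))
    over <- active & alloc >= cap
    out[over] <- cap[over]
    if (!any(over)) {
      out[active] <- alloc[active]
      break
    }
    left <- left - sum(cap[over])
    active <- active & !over
  }
  as.integer(out)
}

# Simple SRSWOR of k out of n indices; sample.int guard for n == 1.
srs <- function(n, k) {
  if (k >= n) return(seq_len(n))
  sample.int(n, k)
}

# Check a scalar probability / proportion.
assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a single value in %s0, 1%s",
                  name, if (open_left) "(" else "[", if (open_right) ")" else "]"))
  }
  invisible(x)
}
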