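# Simultaneous-decision baselines: the weighted-majority optimality property,
# log-odds weight regions for three voters, unweighted majority accuracy
# (Condorcet), and the effective number of independent voters matching the
# sequential performance ceiling.

#' Check the weighted-majority optimality property
#'
#' A weight vector is optimal for simultaneous voting when, for every split
#' of the voters into a set `S` voting one option and the complement `T`
#' voting the other, the side with the larger total weight is also the side
#' with the larger likelihood of being correct (larger product of odds
#' ratios). Log-odds weights always satisfy this; equal weights fail as soon
#' as one voter's log-odds exceeds the combined log-odds of a majority
#' coalition. Checked by brute force over all `2^N` bipartitions.
#'
#' @inheritParams pair_likelihoods
#' @param weights Numeric vector of non-negative vote weights, one per
#'   voter; normalised to sum to one internally (must sum to a positive
#'   finite value).
#' @param tol Numeric slack for weight comparisons.
#' @return `TRUE` if the property holds for every bipartition, else `FALSE`.
#' @examples
#' prof <- ability_profile(c(0.99, 0.6, 0.6))
#' is_optimal_weighting(prof, prof$log_odds)  # TRUE
#' is_optimal_weighting(prof, rep(1, 3))      # FALSE
#' @export
is_optimal_weighting <- function(profile, weights, tol = 1e-12) {
  profile <- as_ability_profile(profile, strict = FALSE)
  n <- nrow(profile)
  if (n > 20L) abort("brute-force bipartition check limited to N <= 20.")
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    abort("`weights` must be non-negative, one per voter, with positive sum.")
  }
  w <- weights / sum(weights)
  r <- profile$log_odds
  for (mask in 0:(2^n - 1)) {
    in_S <- bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L
    wd <- sum(w[in_S]) - sum(w[!in_S])
    rd <- sum(r[in_S]) - sum(r[!in_S])
    if ((wd > tol && rd <= 0) || (wd < -tol && rd >= 0)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Classify the optimum-weight region for three voters
#'
#' For three independent voters the simplex of optimal weight vectors has
#' four regions: if one voter's log-odds ratio exceeds the sum of the other
#' two, only expert-rule weights (`w_k > 0.5`) are optimal; otherwise the
#' interior (unweighted-majority-compatible) region applies.
#'
#' @param p1,p2,p3 Abilities of the three voters, each in (0.5, 1).
#' @param tol Boundary tolerance; equality within `tol` is reported as
#'   `majority_interior` with a warning.
#' @return A one-row tibble with columns `p1`, `p2`, `p3`, `region` (one of
#'   `"expert_1"`, `"expert_2"`, `"expert_3"`, `"majority_interior"`).
#' @examples
#' classify_weight_region(0.95, 0.6, 0.6)
#' @export
classify_weight_region <- function(p1, p2, p3, tol = 1e-9) {
  p <- c(p1, p2, p3)
  if (any(p <= 0.5) || any(p >= 1)) abort("abilities must lie in (0.5, 1).")
  r <- log_odds(p)
  excess <- r - (sum(r) - r)  # r_k minus sum of the other two
  region <- "majority_interior"
  if (any(abs(excess) <= tol)) {
    warn("ability triple lies on a region boundary (within tol); classifying as majority_interior.")
  } else if (any(excess > 0)) {
    region <- paste0("expert_", which(excess > 0))
  }
  tibble(p1 = p1, p2 = p2, p3 = p3, region = region)
}

#' Accuracy of a simultaneous unweighted majority vote
#'
#' Probability that the majority of `n` independent voters, each correct
#' with probability `p`, is correct: the upper binomial tail
#' \eqn{\sum_{m=(n+1)/2}^{n} \binom{n}{m} p^m (1-p)^{n-m}}. Strictly
#' increasing in odd `n` for `p > 0.5` and converging to 1 (the Condorcet
#' jury theorem).
#'
#' @param p Individual ability, in (0, 1); vectorised.
#' @param n Odd number of voters; vectorised.
#' @return Majority accuracy, same length as the longer of `p`, `n`.
#' @examples
#' majority_accuracy(0.7, c(1, 3, 5))
#' @export
majority_accuracy <- function(p, n) {
  if (any(n < 1) || any(n != round(n)) || any(n %% 2 == 0)) {
    abort("`n` must be odd positive integer(s).")
  }
  if (any(p <= 0) || any(p >= 1)) abort("`p` must lie in (0, 1).")
  pbinom((n - 1) / 2, size = n, prob = p, lower.tail = FALSE)
}

#' Effective number of independent voters
#'
#' The smallest odd `n` for which the accuracy of a simultaneous unweighted
#' majority of `n` independent voters of ability `p` reaches the ceiling
#' `pi_max(p)` of mean performance in an arbitrarily long equal-ability
#' sequential chain. This is the number of truly independent opinions that
#' an infinite sequential chain is worth.
#'
#' @param p Common ability, in (0.5, 1); vectorised.
#' @param n_max Search cap (odd); an error is thrown if the ceiling is not
#'   reached below it.
#' @return Integer vector of odd voter counts.
#' @examples
#' effective_voters(c(0.7, 0.9))
#' @export
effective_voters <- function(p, n_max = 999L) {
  if (any(p <= 0.5) || any(p >= 1)) abort("`p` must lie in (0.5, 1).")
  vapply(p, function(pp) {
    target <- pi_max(pp)
    for (n in seq(1L, n_max, by = 2L)) {
      if (majority_accuracy(pp, n) >= target) return(as.integer(n))
    }
    abort(sprintf("majority accuracy did not reach pi_max(%g) below n_max = %d.", pp, n_max))
  }, integer(1))
}

#' Grid sweep of the effective number of voters
#'
#' @param p_grid Numeric vector of abilities in (0.5, 1).
#' @inheritParams effective_voters
#' @return A tibble with columns `p`, `pi_max`, `n_e`, `majority_at_ne`.
#' @examples
#' effective_voters_curve(seq(0.55, 0.95, by = 0.1))
#' @export
effective_voters_curve <- function(p_grid, n_max = 999L) {
  n_e <- effective_voters(p_grid, n_max)
  tibble(
    p = p_grid,
    pi_max = pi_max(p_grid),
    n_e = n_e,
    majority_at_ne = majority_accuracy(p_grid, n_e)
  )
}

#' Ability at which an n-voter majority matches the sequential ceiling
#'
#' Root of `majority_accuracy(p, n) - pi_max(p)` in (0.5, 1), found by
#' bisection. For `n = 5` the root is \eqn{(3 + \sqrt{3})/6 \approx 0.79}:
#' below it a majority of five independent voters falls short of the
#' sequential ceiling, above it five suffice. For `n = 3` no interior root
#' exists (a majority of three never reaches the ceiling inside the
#' interval).
#'
#' @param n Odd number of voters (the primary use is `n = 5`).
#' @param tol Bisection tolerance on `p`.
#' @return The root, a probability in (0.5, 1).
#' @examples
#' crossing_ability(5)
#' @export
crossing_ability <- function(n = 5L, tol = 1e-10) {
  if (length(n) != 1L || n < 1 || n %% 2 == 0) abort("`n` must be a single odd integer.")
  f <- function(p) majority_accuracy(p, n) - pi_max(p)
  lo <- 0.5 + 1e-6
  hi <- 1 - 1e-6
  if (sign(f(lo)) == sign(f(hi))) {
    abort(sprintf("no sign change of majority_accuracy(p, %d) - pi_max(p) inside (0.5, 1).", n))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
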