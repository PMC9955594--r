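# Exact mean performance by enumeration over primary-choice outcomes.
#
# The enumeration works in the absolute truth frame: for each respondent the
# primary choice is either correct (probability p_n) or not, and the running
# state is D, the signed log-odds evidence accumulated by casting voters
# (positive means the casting voters' answers point at the correct option).
# A respondent is a casting voter exactly when |D| <= r*_n (+ tol), in which
# case the recursion branches on their primary; a non-casting voter answers
# deterministically with the sign of D, so the branch does not split. Cost is
# therefore 2^(number of casting voters along the path), not 2^N.

.exact_engine <- function(profile, tol = 1e-9) {
  r <- profile$log_odds
  p <- profile$ability
  n_tot <- nrow(profile)
  correct <- numeric(n_tot)   # P(respondent n answers correctly)
  casting <- numeric(n_tot)   # P(respondent n is a casting voter)
  recurse <- function(n, D, prob) {
    if (n > n_tot) return(invisible(NULL))
    if (abs(D) - r[n] <= tol) {
      casting[n] <<- casting[n] + prob
      correct[n] <<- correct[n] + prob * p[n]
      recurse(n + 1L, D + r[n], prob * p[n])
      recurse(n + 1L, D - r[n], prob * (1 - p[n]))
    } else {
      if (D > 0) correct[n] <<- correct[n] + prob
      recurse(n + 1L, D, prob)
    }
    invisible(NULL)
  }
  recurse(1L, 0, 1)
  list(correct = correct, casting = casting)
}

#' Exact performance curve by enumeration
#'
#' Enumerates every primary-choice outcome of the chain (with
#' casting-branch pruning: non-casting voters answer deterministically, so
#' only casting voters split the recursion) and returns, for each decision
#' order, the exact probability of a correct answer and of being a casting
#' voter. This is the ground-truth oracle against which the closed forms and
#' the Monte-Carlo simulator are checked.
#'
#' @inheritParams pair_likelihoods
#' @param tol Tie tolerance on the log-odds scale (ties count as casting,
#'   i.e. the primary choice is adopted).
#' @return A tibble with columns `order`, `ability`, `performance` (exact
#'   mean performance \eqn{E[\pi_n]}) and `casting_prob`.
#' @examples
#' exact_curve(generate_profile("equal", n = 4, p = 0.7))
#' @export
exact_curve <- function(profile, tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  if (nrow(profile) > 25L) {
    abort("exact enumeration limited to N <= 25; use simulate_chain() for longer chains.")
  }
  res <- .exact_engine(profile, tol)
  tibble(
    order = profile$order,
    ability = profile$ability,
    performance = res$correct,
    casting_prob = res$casting
  )
}

#' Exact mean performance of one respondent
#'
#' @inheritParams exact_curve
#' @param n Decision order of the focal respondent.
#' @return The exact mean performance \eqn{E[\pi_n]}, a probability.
#' @examples
#' exact_mean_performance(ability_profile(c(0.6, 0.8)), n = 2)  # 0.8
#' @export
exact_mean_performance <- function(profile, n, tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  if (length(n) != 1L || n < 1 || n > nrow(profile)) {
    abort("`n` must be a single decision order within the profile.")
  }
  exact_curve(profile, tol)$performance[as.integer(n)]
}
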