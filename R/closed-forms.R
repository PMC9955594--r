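# Closed-form performance results: the equal-ability chain and its ceiling,
# the single-expert chain (aware and unaware), and the complete three-person
# case analysis.

#' Performance ceiling of an equal-ability sequential chain
#'
#' \eqn{\pi_{\max}(p) = p^2 / (p^2 + (1-p)^2)}: the supremum of mean
#' performance of late respondents in an arbitrarily long chain of equals of
#' ability `p`. It is the posterior probability of the leading option when
#' two independent votes of ability `p` agree — the best evidence the
#' absorbed chain can ever carry.
#'
#' @param p Ability in (0, 1); vectorised.
#' @return Probability vector.
#' @examples
#' pi_max(c(0.5, 0.7, 0.9))
#' @export
pi_max <- function(p) {
  if (any(p <= 0) || any(p >= 1)) abort("`p` must lie in (0, 1).")
  p^2 / (p^2 + (1 - p)^2)
}

# Parity convention shared by the equal-ability and expert closed forms:
# k = (n + 1) / 2 for odd n, k = n / 2 for even n. k counts the steps of the
# damping factor (2 p (1 - p))^(k - 1).
.k_of <- function(n) {
  if (any(n < 1) || any(n != round(n))) abort("`n` must be positive integer(s).")
  ifelse(n %% 2 == 1, (n + 1) / 2, n / 2)
}

#' Mean performance in an equal-ability chain
#'
#' Closed form for the mean performance of the `n`-th respondent when all
#' respondents share ability `p`:
#' \deqn{E[\pi_n] = \frac{p^2 + p(1-p)(1-2p)\,(2p(1-p))^{k-1}}{p^2 + (1-p)^2},}
#' with \eqn{k = (n+1)/2} for odd `n` and \eqn{k = n/2} for even `n`. Equals
#' `p` at `n = 1, 2`, increases at every odd step (the correction term
#' \eqn{p(1-p)(1-2p)} is negative and the damping factor \eqn{2p(1-p) < 1}),
#' and converges to [pi_max()].
#'
#' @param p Common ability in (0.5, 1).
#' @param n Decision order(s), positive integers; vectorised.
#' @return Probability vector of mean performances.
#' @examples
#' mean_performance_equal(0.7, 1:9)
#' @export
mean_performance_equal <- function(p, n) {
  if (any(p <= 0.5) || any(p >= 1)) abort("`p` must lie in (0.5, 1).")
  k <- .k_of(n)
  (p^2 + p * (1 - p) * (1 - 2 * p) * (2 * p * (1 - p))^(k - 1)) /
    (p^2 + (1 - p)^2)
}

#' Mean performance of a single expert among equals
#'
#' One respondent (the expert) has ability `q > p` while everyone else has
#' ability `p`. If the expert knows their own ability (`aware = TRUE`) and
#' `q >= pi_max(p)`, their best play is to always answer their primary
#' choice, so performance is `q` at every order. Otherwise — the aware
#' expert with `q < pi_max(p)`, or any unaware expert who believes their own
#' ability is `p` — the expert behaves like an equal and earns the damped
#' form \eqn{\pi_{\max}(p) - (\pi_{\max}(p) - q)(2p(1-p))^{k-1}} at order
#' `n` (same parity convention for `k` as [mean_performance_equal()]). For
#' an unaware expert with `q > pi_max(p)` this *decreases* with `n`:
#' unrecognised talent should answer early.
#'
#' @param p Common ability of the non-experts, in (0.5, 1).
#' @param q Expert ability; must satisfy `q > p`.
#' @param n Expert's decision order(s); vectorised.
#' @param aware Logical; does the expert know their ability is `q`?
#' @return Probability vector of expert mean performances.
#' @examples
#' expert_performance(0.7, 0.95, n = 1:5, aware = FALSE)
#' @export
expert_performance <- function(p, q, n, aware = TRUE) {
  if (p <= 0.5 || p >= 1) abort("`p` must lie in (0.5, 1).")
  if (q <= p || q >= 1) abort("expert ability `q` must satisfy p < q < 1.")
  pm <- pi_max(p)
  damped <- pm - (pm - q) * (2 * p * (1 - p))^(.k_of(n) - 1)
  if (aware && q >= pm) rep(q, length(n)) else damped
}

#' Three-person case analysis
#'
#' Full classification of optimal behaviour and mean performances for a
#' chain of three respondents with abilities `p1`, `p2`, `p3`. When
#' `p2 > p1` the first two respondents are both casting voters and the
#' third effectively faces a simultaneous three-way vote:
#' `third_independent` (the third's log-odds dominates: \eqn{E[\pi_3] = p_3}),
#' `follow_second` (the second dominates: \eqn{E[\pi_3] = p_2}), or
#' `simple_majority` (\eqn{E[\pi_3] = M}, the unweighted majority accuracy
#' \eqn{M = p_1p_2p_3 + (1-p_1)p_2p_3 + p_1(1-p_2)p_3 + p_1p_2(1-p_3)}).
#' When `p1 > p2` the second respondent merely follows the first
#' (\eqn{E[\pi_2] = p_1}) and the third either joins the cascade
#' (`follow_first_cascade`, \eqn{E[\pi_3] = p_1}, when `p1 > p3`) or answers
#' independently (`third_overrides_cascade`, \eqn{E[\pi_3] = p_3}, when
#' `p3 > p1`). \eqn{E[\pi_1] = p_1} always.
#'
#' @param p1,p2,p3 Abilities in (0.5, 1), pairwise distinct beyond `tol`.
#' @param tol Tie tolerance; ability ties within `tol` trigger a warning and
#'   are resolved in favour of the earlier respondent (the primary-choice
#'   tie rule makes the earlier respondent's follower casting).
#' @return A one-row tibble: `p1`, `p2`, `p3`, `case`, `e_pi1`, `e_pi2`,
#'   `e_pi3`.
#' @examples
#' three_person_analysis(0.7, 0.75, 0.72)
#' three_person_analysis(0.8, 0.6, 0.7)
#' @export
three_person_analysis <- function(p1, p2, p3, tol = 1e-9) {
  p <- c(p1, p2, p3)
  if (any(p <= 0.5) || any(p >= 1)) abort("abilities must lie in (0.5, 1).")
  r <- log_odds(p)
  if (abs(r[1] - r[2]) <= tol || abs(abs(r[1] - r[2]) - r[3]) <= tol) {
    warn("ability tie within tol; resolving by the primary-choice tie rule (earlier/self wins).")
  }
  if (r[2] > r[1]) {
    # first two are casting voters; the third sees three independent votes
    if (r[3] > r[1] + r[2] + tol) {
      case <- "third_independent"
      e3 <- p3
    } else if (r[2] > r[1] + r[3] + tol) {
      case <- "follow_second"
      e3 <- p2
    } else {
      case <- "simple_majority"
      e3 <- p1 * p2 * p3 + (1 - p1) * p2 * p3 + p1 * (1 - p2) * p3 +
        p1 * p2 * (1 - p3)
    }
    e2 <- p2
  } else {
    # the second follows the first; the third compares only r1 vs r3
    e2 <- p1
    if (r[1] > r[3]) {
      case <- "follow_first_cascade"
      e3 <- p1
    } else {
      case <- "third_overrides_cascade"
      e3 <- p3
    }
  }
  tibble(p1 = p1, p2 = p2, p3 = p3, case = case,
         e_pi1 = p1, e_pi2 = e2, e_pi3 = e3)
}

#' Three-person phase grid
#'
#' Evaluates [three_person_analysis()] over a `(p1, p2)` grid at fixed
#' `p3`, producing the phase structure of the third respondent's mean
#' performance as data (including the performance drop across the
#' `p1 = p2` diagonal). Grid points with `p1 = p2` are skipped (non-generic
#' ties).
#'
#' @param p3 Ability of the third respondent.
#' @param step Grid spacing over (0.5, 1) for `p1` and `p2`.
#' @return A tibble with columns `p1`, `p2`, `case`, `e_pi2`, `e_pi3`.
#' @examples
#' head(three_person_grid(0.7, step = 0.05))
#' @export
three_person_grid <- function(p3 = 0.7, step = 0.01) {
  g <- seq(0.5 + step, 1 - step, by = step)
  grid <- tidyr::expand_grid(p1 = g, p2 = g)
  grid <- dplyr::filter(grid, abs(.data$p1 - .data$p2) > 1e-12)
  res <- purrr::pmap_dfr(grid, function(p1, p2) {
    three_person_analysis(p1, p2, p3)[, c("case", "e_pi2", "e_pi3")]
  })
  dplyr::bind_cols(grid, res)
}
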