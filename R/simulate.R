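# Seeded Monte-Carlo simulation of sequential decision chains.
#
# The engine is vectorised across runs. Each run lives in the absolute truth
# frame: z_n = +1 when respondent n's primary choice is correct (probability
# p_n), -1 otherwise. D is the signed log-odds evidence accumulated by
# casting voters; respondent n is casting iff |D| <= r*_n (+ tol), answers
# their primary (correct iff z_n > 0) and moves D by r*_n z_n; otherwise the
# answer follows the sign of D and D is unchanged.

.simulate_engine <- function(profile, n_runs, seed = NULL, tol = 1e-9) {
  if (!is.null(seed)) set.seed(seed)
  p <- profile$ability
  r <- profile$log_odds
  n_tot <- nrow(profile)
  D <- numeric(n_runs)
  correct <- matrix(FALSE, n_runs, n_tot)
  casting <- matrix(FALSE, n_runs, n_tot)
  d_count <- matrix(0L, n_runs, n_tot)  # |S|-|T| count difference (truth sign)
  dc <- integer(n_runs)
  for (n in seq_len(n_tot)) {
    d_count[, n] <- dc
    z <- ifelse(rbinom(n_runs, 1L, p[n]) == 1L, 1L, -1L)
    is_cast <- abs(D) - r[n] <= tol
    casting[, n] <- is_cast
    correct[, n] <- ifelse(is_cast, z > 0L, D > 0)
    D <- D + ifelse(is_cast, r[n] * z, 0)
    dc <- dc + ifelse(is_cast, z, 0L)
  }
  list(correct = correct, casting = casting, d_count = d_count)
}

#' Simulate sequential decision chains
#'
#' Draws each respondent's primary-choice correctness independently with
#' probability equal to their ability, runs the casting-voter algorithm per
#' replicate, and aggregates per-order accuracy (with binomial standard
#' errors), casting-voter fractions, the maximum absolute casting-vote count
#' difference \eqn{|d_n| = ||S| - |T||}, and the information-cascade rate
#' (fraction of runs in which every answer equals the first answer). Fully
#' deterministic given `(profile, n_runs, seed)`.
#'
#' @inheritParams pair_likelihoods
#' @param n_runs Number of Monte-Carlo replicates (default 10,000).
#' @param seed Integer seed; recorded in the report.
#' @param tol Tie tolerance on the log-odds scale.
#' @return An object of class `simulation_report`: a list with `per_order`
#'   (tibble: `order`, `ability`, `accuracy`, `se`, `casting_fraction`),
#'   `max_abs_d`, `cascade_rate`, `n_runs`, `seed`, `profile`.
#' @examples
#' rep <- simulate_chain(generate_profile("equal", n = 9, p = 0.7),
#'                       n_runs = 2000, seed = 1)
#' tidy(rep)
#' glance(rep)
#' @export
simulate_chain <- function(profile, n_runs = 10000L, seed = NULL, tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    abort("`n_runs` must be a single count >= 1.")
  }
  n_runs <- as.integer(n_runs)
  eng <- .simulate_engine(profile, n_runs, seed, tol)
  acc <- colMeans(eng$correct)
  per_order <- tibble(
    order = profile$order,
    ability = profile$ability,
    accuracy = acc,
    se = sqrt(acc * (1 - acc) / n_runs),
    casting_fraction = colMeans(eng$casting)
  )
  structure(
    list(
      per_order = per_order,
      max_abs_d = max(abs(eng$d_count)),
      cascade_rate = mean(rowSums(eng$correct != eng$correct[, 1]) == 0L),
      n_runs = n_runs,
      seed = seed,
      profile = profile
    ),
    class = "simulation_report"
  )
}

#' @export
tidy.simulation_report <- function(x, ...) x$per_order

#' @export
glance.simulation_report <- function(x, ...) {
  tibble(
    n = nrow(x$per_order),
    n_runs = x$n_runs,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    max_abs_d = x$max_abs_d,
    cascade_rate = x$cascade_rate,
    final_accuracy = x$per_order$accuracy[nrow(x$per_order)]
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  cat(sprintf(
    "<simulation_report: %d respondents x %d runs (seed %s); max |d| = %d, cascade rate = %.4f>\n",
    nrow(x$per_order), x$n_runs,
    if (is.null(x$seed)) "unset" else x$seed, x$max_abs_d, x$cascade_rate
  ))
  print(x$per_order)
  invisible(x)
}

#' Casting-vote difference walk statistics
#'
#' For equal-ability chains the casting-vote count difference
#' \eqn{d_n = |S_{n-1}| - |T_{n-1}|} is a random walk on the integers that is
#' absorbed at \eqn{\pm 2}: while \eqn{|d_n| \le 1} the n-th respondent is a
#' casting voter and moves the walk by one step; once \eqn{|d_n| = 2} every
#' later respondent ignores their primary and the walk is frozen. This
#' function simulates the walk (through the same general casting-voter
#' engine used by [simulate_chain()] — the absorption at 2 is a consequence
#' of the log-odds rule, not an assumption) and reports the maximum
#' \eqn{|d_n|} observed, the distribution of the order at which \eqn{|d|}
#' first reaches 2, and whether the walk ever moved after absorption.
#'
#' @inheritParams simulate_chain
#' @return A list of class `d_walk_stats`: `max_abs_d`,
#'   `absorption` (tibble `order`, `count` of first passage to `|d| = 2`;
#'   runs that never absorb are excluded), `frozen_after_absorption`
#'   (logical), `prop_absorbed`, `n_runs`, `seed`.
#' @examples
#' d_walk_statistics(generate_profile("equal", n = 10, p = 0.7),
#'                   n_runs = 1000, seed = 1)
#' @export
d_walk_statistics <- function(profile, n_runs = 10000L, seed = NULL, tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  if (length(unique(profile$ability)) != 1L) {
    abort("`d_walk_statistics()` requires an equal-ability profile.")
  }
  eng <- .simulate_engine(profile, as.integer(n_runs), seed, tol)
  d <- abs(eng$d_count)
  hit <- d >= 2L
  first_hit <- apply(hit, 1L, function(x) if (any(x)) which(x)[1] else NA_integer_)
  frozen <- TRUE
  for (i in which(!is.na(first_hit))) {
    traj <- eng$d_count[i, first_hit[i]:ncol(d)]
    if (length(unique(traj)) != 1L) {
      frozen <- FALSE
      break
    }
  }
  absorbed <- first_hit[!is.na(first_hit)]
  structure(
    list(
      max_abs_d = max(d),
      absorption = dplyr::count(tibble(order = absorbed), .data$order,
                                name = "count"),
      frozen_after_absorption = frozen,
      prop_absorbed = mean(!is.na(first_hit)),
      n_runs = as.integer(n_runs),
      seed = seed
    ),
    class = "d_walk_stats"
  )
}

#' @export
print.d_walk_stats <- function(x, ...) {
  cat(sprintf(
    "<d_walk_stats: %d runs (seed %s); max |d| = %d, absorbed %.3f, frozen after absorption: %s>\n",
    x$n_runs, if (is.null(x$seed)) "unset" else x$seed,
    x$max_abs_d, x$prop_absorbed, x$frozen_after_absorption
  ))
  print(x$absorption)
  invisible(x)
}
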