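# Core decision-chain machinery: casting-vote likelihoods, the optimal-answer
# rule, the recursive classification algorithm, and conditional performance.
#
# Conventions. Options are labelled relative to the first respondent's answer:
# "s" = same option as respondent 1, "t" = the other option. Casting voters
# are respondents whose optimal answer equals their own primary choice; their
# answers therefore reveal their primary choices, and they are the only
# respondents whose abilities enter any downstream likelihood.

.check_label <- function(x, arg = "primary") {
  if (!is.character(x) || length(x) != 1L || !x %in% c("s", "t")) {
    abort(sprintf("`%s` must be a single label, either \"s\" or \"t\".", arg))
  }
  x
}

.check_partition <- function(profile, S, T, R = integer(), n_seen = NULL) {
  S <- as.integer(S); T <- as.integer(T); R <- as.integer(R)
  all_idx <- c(S, T, R)
  if (anyDuplicated(all_idx) > 0L) {
    abort("S, T and R must be mutually disjoint.")
  }
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > nrow(profile))) {
    abort("partition indices out of range for this profile.")
  }
  if (is.null(n_seen)) n_seen <- length(all_idx)
  if (length(all_idx) && !setequal(all_idx, seq_len(n_seen))) {
    abort("S, T and R must jointly cover respondents 1..n_seen.")
  }
  if (n_seen >= 1L && !(1L %in% S)) {
    abort("respondent 1 always belongs to S (the \"s\" frame is defined by their answer).")
  }
  list(S = sort(S), T = sort(T), R = sort(R), n_seen = n_seen)
}

# Log-likelihoods of the two hypotheses given the casting-voter partition:
# log L_s = sum_{m in S} log p_m + sum_{m in T} log(1 - p_m), and symmetrically
# for L_t. Comparisons are done in the log domain to stay stable in long
# chains; empty-set sums are 0 (likelihood 1).
.log_pair <- function(profile, S, T) {
  p <- profile$ability
  c(
    s = sum(log(p[S])) + sum(log1p(-p[T])),
    t = sum(log1p(-p[S])) + sum(log(p[T]))
  )
}

#' Likelihoods of the two options given the casting-voter partition
#'
#' Given the sets `S` and `T` of antecedent casting voters who answered "s"
#' and "t", the probability of observing that answer pattern is
#' \eqn{L_s = \prod_{m \in S} p_m \prod_{m \in T} (1 - p_m)} when "s" is the
#' correct option, and \eqn{L_t} with the roles of \eqn{p_m} and
#' \eqn{1 - p_m} swapped when "t" is correct. Non-casting voters merely echo
#' their antecedents, so their abilities contribute nothing.
#'
#' @param profile An [ability_profile()] (or numeric vector of abilities).
#' @param S,T Integer vectors of casting-voter indices answering "s" and "t".
#' @param R Integer vector of non-casting voter indices (validated, ignored
#'   in the likelihood).
#' @return A tibble with columns `hypothesis` (`"s"`, `"t"`) and
#'   `likelihood`.
#' @examples
#' pair_likelihoods(ability_profile(c(0.6, 0.8)), S = 1, T = 2)
#' @export
pair_likelihoods <- function(profile, S, T = integer(), R = integer()) {
  profile <- as_ability_profile(profile, strict = FALSE)
  part <- .check_partition(profile, S, T, R)
  ll <- .log_pair(profile, part$S, part$T)
  tibble(hypothesis = c("s", "t"), likelihood = exp(unname(ll)))
}

#' Optimal answer of the n-th respondent
#'
#' Applies the log-odds decision rule: with
#' \eqn{\Delta = \sum_{m \in S} r^*_m - \sum_{m \in T} r^*_m}, the n-th
#' respondent's primary choice is a casting vote when
#' \eqn{|\Delta| < r^*_n} (the antecedent evidence is too close to call), in
#' which case the answer equals the primary choice. Otherwise the respondent
#' ignores the primary choice and answers "s" when \eqn{\Delta > 0}, "t"
#' when \eqn{\Delta < 0}. Ties within `tol` of the casting threshold resolve
#' to the primary choice.
#'
#' @inheritParams pair_likelihoods
#' @param n Decision order of the focal respondent (`n >= 2`); `S`, `T`, `R`
#'   must partition `1..(n-1)`.
#' @param primary The focal respondent's primary choice, `"s"` or `"t"`.
#' @param tol Tolerance for tie detection on the log-odds scale.
#' @return A one-row tibble with columns `order`, `primary`, `answer`,
#'   `is_casting`.
#' @examples
#' prof <- ability_profile(c(0.6, 0.8))
#' optimal_answer(prof, n = 2, S = 1, primary = "t")
#' @export
optimal_answer <- function(profile, n, S, T = integer(), R = integer(),
                           primary = "s", tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n > nrow(profile)) {
    abort("`n` must be a single index in 2..N (respondent 1 answers their primary).")
  }
  n <- as.integer(n)
  .check_label(primary)
  part <- .check_partition(profile, S, T, R, n_seen = n - 1L)
  delta <- sum(profile$log_odds[part$S]) - sum(profile$log_odds[part$T])
  res <- .decide(delta, profile$log_odds[n], primary, tol)
  tibble(order = n, primary = primary, answer = res$answer,
         is_casting = res$is_casting)
}

# Decision kernel shared by optimal_answer() and run_sequence().
# delta: log-odds evidence for "s" minus "t" among antecedent casting voters.
.decide <- function(delta, r_n, primary, tol) {
  if (abs(delta) - r_n > tol) {
    list(answer = if (delta > 0) "s" else "t", is_casting = FALSE)
  } else {
    list(answer = primary, is_casting = TRUE)
  }
}

#' Run one sequential decision chain
#'
#' Reproduces the recursive classification algorithm: start with
#' `S = {1}`, `T = {}`, `R = {}` (the first respondent answers their primary
#' choice, which defines the "s" label); for each later respondent apply the
#' log-odds rule of [optimal_answer()] and file them into `S` or `T` (casting
#' voters, by their primary) or `R` (non-casting voters). Non-casting
#' voters' answers never depend on their own primaries.
#'
#' @inheritParams pair_likelihoods
#' @param primaries Character vector of primary choices (`"s"`/`"t"`), one
#'   per respondent, in the frame of the first respondent's answer; the
#'   first entry must be `"s"` by definition of the frame.
#' @param tol Tie tolerance on the log-odds scale.
#' @return A tibble of class `seq_result`, one row per respondent, with
#'   columns `order`, `ability`, `primary`, `answer`, `is_casting`,
#'   `conditional_performance`. The final partition is attached as
#'   attribute `"partition"` (a list with `S`, `T`, `R`).
#' @examples
#' prof <- generate_profile("equal", n = 5, p = 0.7)
#' run_sequence(prof, c("s", "t", "t", "t", "s"))
#' @export
run_sequence <- function(profile, primaries, tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  n_tot <- nrow(profile)
  if (length(primaries) != n_tot) {
    abort("`primaries` must have one entry per respondent.")
  }
  if (!is.character(primaries) || !all(primaries %in% c("s", "t"))) {
    abort("`primaries` entries must be \"s\" or \"t\".")
  }
  if (primaries[1] != "s") {
    abort("the first primary must be \"s\": the frame is defined by the first answer.")
  }
  r <- profile$log_odds
  S <- 1L; T <- integer(); R <- integer()
  answer <- character(n_tot)
  casting <- logical(n_tot)
  perf <- numeric(n_tot)
  answer[1] <- "s"; casting[1] <- TRUE
  perf[1] <- max(profile$ability[1], 1 - profile$ability[1])
  if (n_tot >= 2L) {
    for (n in 2:n_tot) {
      delta <- sum(r[S]) - sum(r[T])
      # ties are the defined convention for equal abilities; only worth a
      # warning when abilities are pairwise distinct and a tie still occurs
      if (abs(abs(delta) - r[n]) <= tol && !anyDuplicated(profile$ability)) {
        warn(sprintf(
          "tie at respondent %d (|Delta| within tol of r*_n); resolved to the primary choice.",
          n
        ))
      }
      d <- .decide(delta, r[n], primaries[n], tol)
      answer[n] <- d$answer
      casting[n] <- d$is_casting
      perf[n] <- conditional_performance(profile, n, S, T, R,
                                         primary = primaries[n])
      if (d$is_casting) {
        if (primaries[n] == "s") S <- c(S, n) else T <- c(T, n)
      } else {
        R <- c(R, n)
      }
    }
  }
  out <- tibble(
    order = seq_len(n_tot),
    ability = profile$ability,
    primary = primaries,
    answer = answer,
    is_casting = casting,
    conditional_performance = perf
  )
  class(out) <- c("seq_result", class(out))
  attr(out, "partition") <- list(S = S, T = sort(T), R = sort(R))
  attr(out, "tol") <- tol
  out
}

#' Conditional performance of the n-th respondent
#'
#' The maximised probability that respondent `n` answers correctly, given
#' the observed antecedent answers (through the casting-voter partition) and
#' their own primary choice: the larger of the two hypothesis joint
#' probabilities (each including the focal respondent's own primary-choice
#' factor \eqn{p_n} or \eqn{1 - p_n}) divided by their sum. Always lies in
#' \eqn{[0.5, 1]}.
#'
#' @inheritParams optimal_answer
#' @return A single probability.
#' @examples
#' conditional_performance(ability_profile(c(0.6, 0.8, 0.7)), n = 3,
#'                         S = 1, T = 2, primary = "s")
#' @export
conditional_performance <- function(profile, n, S, T = integer(),
                                    R = integer(), primary = "s", tol = 1e-9) {
  profile <- as_ability_profile(profile, strict = FALSE)
  n <- as.integer(n)
  .check_label(primary)
  part <- .check_partition(profile, S, T, R, n_seen = n - 1L)
  ll <- .log_pair(profile, part$S, part$T)
  p_n <- profile$ability[n]
  if (primary == "s") {
    la <- ll[["s"]] + log(p_n)
    lb <- ll[["t"]] + log1p(-p_n)
  } else {
    la <- ll[["s"]] + log1p(-p_n)
    lb <- ll[["t"]] + log(p_n)
  }
  # max(a, b) / (a + b) computed stably in the log domain
  1 / (1 + exp(-abs(la - lb)))
}

#' @export
tidy.seq_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "seq_result")
  attr(out, "partition") <- NULL
  attr(out, "tol") <- NULL
  out
}

#' @export
glance.seq_result <- function(x, ...) {
  part <- attr(x, "partition")
  tibble(
    n = nrow(x),
    n_casting = sum(x$is_casting),
    n_s = length(part$S),
    n_t = length(part$T),
    n_noncasting = length(part$R),
    cascade = all(x$answer == x$answer[1])
  )
}

#' @export
print.seq_result <- function(x, ...) {
  part <- attr(x, "partition")
  cat(sprintf(
    "<seq_result: %d respondents, casting S = {%s}, T = {%s}, non-casting R = {%s}>\n",
    nrow(x), toString(part$S), toString(part$T), toString(part$R)
  ))
  NextMethod()
}
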