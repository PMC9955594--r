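#' Log-odds ratio of a success probability
#'
#' The log-odds ratio \eqn{r^* = \log(p / (1 - p))} is the optimal vote weight
#' for an independent voter with ability `p` in a simultaneous weighted
#' majority vote, and the currency in which sequential respondents compare
#' the evidence carried by antecedent casting voters.
#'
#' @param p Numeric vector of probabilities, each strictly inside (0, 1).
#' @return Numeric vector of log-odds ratios; positive exactly where
#'   `p > 0.5`, zero at `p = 0.5`.
#' @examples
#' log_odds(c(0.5, 0.7, 0.8))
#' @export
log_odds <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must be numeric with every entry strictly inside (0, 1).")
  }
  log(p / (1 - p))
}

#' Construct an ability profile
#'
#' An ability profile is the ordered list of per-respondent success
#' probabilities in a sequential decision chain: respondent `n` makes an
#' independent "primary choice" that is correct with probability
#' `abilities[n]`. The profile is stored as a tibble with one row per
#' respondent (columns `order`, `ability`, `log_odds`) so it pipes directly
#' into the rest of the package.
#'
#' @param abilities Numeric vector of success probabilities, one per
#'   respondent in decision order. In strict mode every entry must lie
#'   strictly in (0.5, 1): 0.5 is a coin flip and 1 would make a respondent
#'   infallible, both of which degenerate the model.
#' @param strict Logical; enforce the open interval (0.5, 1). With
#'   `strict = FALSE` any abilities in (0, 1) are accepted, which is useful
#'   for boundary exploration. Whether abilities are pairwise distinct (so
#'   that subset odds products are generically distinct) is recorded in the
#'   `strict_distinct` attribute; ties, wherever they arise, are resolved by
#'   the primary-choice rule.
#' @return A tibble of class `ability_profile` with columns `order`
#'   (integer, 1-based), `ability` and `log_odds`.
#' @examples
#' ability_profile(c(0.6, 0.8, 0.7))
#' @export
ability_profile <- function(abilities, strict = TRUE) {
  if (is_ability_profile(abilities)) {
    return(abilities)
  }
  if (!is.numeric(abilities) || length(abilities) < 1L) {
    abort("`abilities` must be a numeric vector of length >= 1.")
  }
  if (any(!is.finite(abilities)) || any(abilities <= 0) || any(abilities >= 1)) {
    abort("abilities must lie strictly inside (0, 1).")
  }
  if (strict && (any(abilities <= 0.5))) {
    abort(paste(
      "in strict mode every ability must exceed 0.5",
      "(0.5 is the coin-flip floor); use strict = FALSE to relax."
    ))
  }
  out <- tibble(
    order = seq_along(abilities),
    ability = as.numeric(abilities),
    log_odds = log_odds(abilities)
  )
  class(out) <- c("ability_profile", class(out))
  attr(out, "strict") <- strict
  # subset odds products can only be asserted distinct when abilities are
  # pairwise distinct (the full 2^N check is exponential); ties otherwise
  # fall back to the primary-choice rule
  attr(out, "strict_distinct") <- anyDuplicated(abilities) == 0L
  out
}

#' @rdname ability_profile
#' @param x Object to test or coerce.
#' @export
is_ability_profile <- function(x) inherits(x, "ability_profile")

#' @rdname ability_profile
#' @export
as_ability_profile <- function(x, strict = TRUE) {
  if (is_ability_profile(x)) {
    x
  } else if (is.data.frame(x) && "ability" %in% names(x)) {
    ability_profile(x$ability, strict = strict)
  } else {
    ability_profile(x, strict = strict)
  }
}

#' Generate standard ability profiles
#'
#' Fixture generator for the three scenario families studied with this model:
#' a chain of equals, a chain of equals with a single higher-ability expert
#' placed at a chosen decision order, and a chain of random pairwise-distinct
#' abilities.
#'
#' @param kind One of `"equal"`, `"one_expert"`, `"random_distinct"`.
#' @param n Number of respondents.
#' @param p Common ability (all kinds). Default 0.7.
#' @param q Expert ability, required for `"one_expert"`; must exceed `p`.
#' @param expert_order Decision order of the expert (1-based), for
#'   `"one_expert"`.
#' @param seed Integer seed for `"random_distinct"`; draws are rejected until
#'   all pairwise gaps reach `min_gap`, keeping subset odds products
#'   generically distinct.
#' @param range Length-2 numeric, the open sampling interval for
#'   `"random_distinct"`; must sit inside (0.5, 1).
#' @param min_gap Minimum pairwise ability gap for `"random_distinct"`.
#' @return An [ability_profile()].
#' @examples
#' generate_profile("equal", n = 5, p = 0.7)
#' generate_profile("one_expert", n = 5, p = 0.7, q = 0.95, expert_order = 3)
#' generate_profile("random_distinct", n = 4, seed = 1)
#' @export
generate_profile <- function(kind = c("equal", "one_expert", "random_distinct"),
                             n, p = 0.7, q = NULL, expert_order = 1L,
                             seed = NULL, range = c(0.55, 0.95),
                             min_gap = 0.01) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  n <- as.integer(n)
  switch(kind,
    equal = ability_profile(rep(p, n)),
    one_expert = {
      if (is.null(q)) abort("`q` (expert ability) is required for kind = 'one_expert'.")
      if (q <= p) abort("expert ability `q` must exceed the common ability `p`.")
      if (expert_order < 1L || expert_order > n) {
        abort("`expert_order` must be between 1 and `n`.")
      }
      ab <- rep(p, n)
      ab[expert_order] <- q
      ability_profile(ab)
    },
    random_distinct = {
      if (length(range) != 2L || range[1] <= 0.5 || range[2] >= 1 ||
          range[1] >= range[2]) {
        abort("`range` must be an increasing pair inside (0.5, 1).")
      }
      if (min_gap * (n - 1) >= diff(range)) {
        abort("`min_gap` too large for the requested `range` and `n`.")
      }
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
      }
      ab <- numeric(0)
      tries <- 0L
      while (length(ab) < n) {
        cand <- stats::runif(1, range[1], range[2])
        if (!length(ab) || min(abs(ab - cand)) >= min_gap) {
          ab <- c(ab, cand)
        }
        tries <- tries + 1L
        if (tries > 10000L) abort("rejection sampling failed; loosen `min_gap`.")
      }
      ability_profile(ab)
    }
  )
}
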