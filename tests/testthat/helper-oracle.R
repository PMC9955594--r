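# Independent oracles used to validate the casting-voter machinery.
#
# (1) A full-Bayes oracle that never forms casting-voter sets: the n-th
#     respondent's answer is computed by marginalising over every hidden
#     primary-choice vector of the antecedents that is consistent with the
#     observed answer string (antecedent behaviour defined recursively by
#     the same rule). This is brute force in the purest sense and is the
#     ground truth the casting-vote shortcut must reproduce.
#
# (2) A full 2^N outcome enumeration of mean performance driven through
#     run_sequence() in the relative s/t frame, used to validate the
#     truth-frame pruned recursion in exact_curve().
#
# (3) A d-walk enumeration for an "unaware expert": everyone (including the
#     expert) decides as if all abilities were p, but the expert's primary
#     is correct with probability q.

oracle_answers_bayes <- function(p, primaries, tol = 1e-9) {
  n_tot <- length(p)
  memo_ans <- new.env(parent = emptyenv())
  # answers generated by the Bayes-optimal rule for a full primary vector
  gen_answers <- function(x) {
    key <- paste(x, collapse = "")
    if (!is.null(memo_ans[[key]])) return(memo_ans[[key]])
    y <- character(length(x))
    y[1] <- "s"
    for (m in seq_len(length(x))[-1]) {
      y[m] <- bayes_answer(m, y[seq_len(m - 1)], x[m])
    }
    memo_ans[[key]] <- y
    y
  }
  # marginal likelihood of the observed answer string under each hypothesis,
  # summing over all hidden antecedent primaries
  bayes_answer <- function(m, y_prev, x_m) {
    hyp <- c(s = 0, t = 0)
    k <- m - 1L
    cand <- as.matrix(expand.grid(rep(list(c("s", "t")), max(k - 1L, 0L)),
                                  stringsAsFactors = FALSE))
    for (i in seq_len(max(nrow(cand), 1L))) {
      x_cand <- c("s", if (k > 1L) cand[i, ])
      if (!identical(gen_answers(x_cand)[seq_len(k)], y_prev)) next
      pr_s <- prod(ifelse(x_cand == "s", p[seq_len(k)], 1 - p[seq_len(k)]))
      pr_t <- prod(ifelse(x_cand == "t", p[seq_len(k)], 1 - p[seq_len(k)]))
      hyp["s"] <- hyp["s"] + pr_s
      hyp["t"] <- hyp["t"] + pr_t
    }
    ls <- log(hyp["s"]) + log(if (x_m == "s") p[m] else 1 - p[m])
    lt <- log(hyp["t"]) + log(if (x_m == "t") p[m] else 1 - p[m])
    if (abs(ls - lt) <= tol) x_m else if (ls > lt) "s" else "t"
  }
  gen_answers(primaries)
}

# Exact mean performance by full 2^N enumeration through run_sequence() in
# the s/t frame (no pruning, no truth-frame bookkeeping).
full_enumeration_curve <- function(p, tol = 1e-9) {
  n_tot <- length(p)
  correct <- numeric(n_tot)
  z_grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_tot)))
  for (i in seq_len(nrow(z_grid))) {
    z <- z_grid[i, ]
    prob <- prod(ifelse(z, p, 1 - p))
    primaries <- ifelse(z == z[1], "s", "t")
    res <- suppressWarnings(run_sequence(p, primaries, tol = tol))
    correct <- correct + prob * ((res$answer == "s") == z[1])
  }
  correct
}

# Mean performance of an unaware expert (order n_e, true ability q, believed
# ability p) among equals of ability p: enumeration over the casting-vote
# difference walk, which everyone runs with the common weight r*(p).
enum_unaware_expert <- function(p, q, expert_order, n_tot) {
  acc <- 0
  recurse <- function(m, d, prob) {
    if (m > n_tot) return(invisible(NULL))
    pr <- if (m == expert_order) q else p
    if (abs(d) <= 1L) {
      if (m == expert_order) acc <<- acc + prob * pr
      recurse(m + 1L, d + 1L, prob * pr)
      recurse(m + 1L, d - 1L, prob * (1 - pr))
    } else {
      if (m == expert_order && d > 1L) acc <<- acc + prob
      recurse(m + 1L, d, prob)
    }
    invisible(NULL)
  }
  recurse(1L, 0L, 1)
  acc
}

# all primary-choice vectors of length n in the s/t frame (first entry "s")
all_primary_vectors <- function(n) {
  if (n == 1L) return(list("s"))
  tails <- expand.grid(rep(list(c("s", "t")), n - 1L), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tails)), function(i) c("s", unlist(tails[i, ], use.names = FALSE)))
}
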