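test_that("pair likelihoods depend only on casting voters", {
  lik <- pair_likelihoods(ability_profile(c(0.6, 0.8)), S = 1, T = 2)
  expect_equal(lik$likelihood, c(0.12, 0.32))

  lone <- pair_likelihoods(ability_profile(0.9), S = 1)
  expect_equal(lone$likelihood, c(0.9, 0.1))

  # a non-casting voter's ability must not enter, however extreme
  with_r <- pair_likelihoods(ability_profile(c(0.6, 0.8, 0.99)),
                             S = 1, T = 2, R = 3)
  expect_equal(with_r$likelihood, lik$likelihood)

  expect_error(pair_likelihoods(ability_profile(c(0.6, 0.8)), S = 1, T = 5),
               "out of range")
  expect_error(pair_likelihoods(ability_profile(c(0.6, 0.8)), S = 2, T = 1),
               "respondent 1")
  expect_error(pair_likelihoods(ability_profile(c(0.6, 0.8)), S = c(1, 2), T = 2),
               "disjoint")
})

test_that("the second respondent follows the abler of the first pair", {
  # abler first: always copy, regardless of own primary
  res <- optimal_answer(ability_profile(c(0.8, 0.6)), n = 2, S = 1, primary = "t")
  expect_equal(res$answer, "s")
  expect_false(res$is_casting)
  # abler second: always keep the primary
  res <- optimal_answer(ability_profile(c(0.6, 0.8)), n = 2, S = 1, primary = "t")
  expect_equal(res$answer, "t")
  expect_true(res$is_casting)
  # third overruled by the antecedent log-odds gap
  res <- optimal_answer(ability_profile(c(0.6, 0.8, 0.7)), n = 3,
                        S = 1, T = 2, primary = "s")
  expect_equal(res$answer, "t")
  expect_false(res$is_casting)

  expect_error(optimal_answer(ability_profile(c(0.6, 0.8)), n = 1, S = 1),
               "2..N")
})

test_that("run_sequence reproduces the recursive classification", {
  # equal-ability chain: d reaches -2 after three t-votes, absorbing order 5
  res <- run_sequence(generate_profile("equal", n = 5, p = 0.7),
                      c("s", "t", "t", "t", "s"))
  expect_equal(res$answer, c("s", "t", "t", "t", "t"))
  expect_equal(res$is_casting, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(res, "partition")$R, 5L)

  # strongest first: everyone else becomes a non-casting follower
  res <- run_sequence(ability_profile(c(0.9, 0.6, 0.7)), c("s", "t", "t"))
  expect_equal(res$answer, rep("s", 3))
  expect_equal(attr(res, "partition")$R, c(2L, 3L))
  expect_true(glance(res)$cascade)

  # single respondent answers the primary
  res <- run_sequence(ability_profile(0.85), "s")
  expect_equal(res$answer, "s")
  expect_true(res$is_casting)
  expect_equal(res$conditional_performance, 0.85)

  expect_error(run_sequence(ability_profile(c(0.6, 0.7)), c("t", "s")),
               "first primary")
  expect_error(run_sequence(ability_profile(c(0.6, 0.7)), "s"),
               "one entry per respondent")
})

test_that("casting voters always answer their primary choice", {
  for (seed in 1:5) {
    prof <- generate_profile("random_distinct", n = 7, seed = seed)
    for (primaries in all_primary_vectors(7)[c(1, 20, 40, 64)]) {
      res <- run_sequence(prof, primaries)
      expect_true(all(res$answer[res$is_casting] ==
                        res$primary[res$is_casting]))
      # partition covers everyone, once
      part <- attr(res, "partition")
      expect_setequal(c(part$S, part$T, part$R), 1:7)
    }
  }
})

test_that("perturbing a non-casting voter's ability changes nothing downstream", {
  prof <- ability_profile(c(0.9, 0.6, 0.7, 0.65))
  primaries <- c("s", "t", "t", "t")
  base <- run_sequence(prof, primaries)
  part <- attr(base, "partition")
  expect_true(length(part$R) > 0)
  for (idx in part$R) {
    ab <- prof$ability
    ab[idx] <- 0.51 + 0.2 * (idx %% 2)  # still below everyone who matters
    bumped <- run_sequence(ability_profile(ab), primaries)
    expect_identical(bumped$answer, base$answer)
    expect_identical(attr(bumped, "partition"), part)
    keep <- setdiff(seq_len(4), idx)
    expect_equal(bumped$conditional_performance[keep],
                 base$conditional_performance[keep])
  }
})

test_that("conditional performance matches the posterior of the better hypothesis", {
  expect_equal(
    conditional_performance(ability_profile(c(0.6, 0.8, 0.7)), n = 3,
                            S = 1, T = 2, primary = "s"),
    0.096 / 0.18
  )
  # T empty reduces to the two-agree posterior
  expect_equal(
    conditional_performance(ability_profile(c(0.6, 0.8)), n = 2, S = 1,
                            primary = "s"),
    0.48 / 0.56
  )
  # symmetric evidence floors at 1/2
  expect_equal(
    conditional_performance(ability_profile(c(0.7, 0.7)), n = 2, S = 1,
                            primary = "t"),
    0.5
  )
})

test_that("conditional performance is >= 0.5 and >= blind-primary accuracy", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    prof <- generate_profile("random_distinct", n = n, seed = rep)
    primaries <- c("s", sample(c("s", "t"), n - 1, replace = TRUE))
    res <- run_sequence(prof, primaries)
    expect_true(all(res$conditional_performance >= 0.5 - 1e-12))
    expect_true(all(res$conditional_performance <= 1 + 1e-12))
    # blind accuracy: posterior mass of the hypothesis matching the primary
    part <- list(S = 1L, T = integer(), R = integer())
    for (m in 2:n) {
      lik <- pair_likelihoods(prof, part$S, part$T, part$R)$likelihood
      p_m <- prof$ability[m]
      blind <- if (primaries[m] == "s") {
        lik[1] * p_m / (lik[1] * p_m + lik[2] * (1 - p_m))
      } else {
        lik[2] * p_m / (lik[2] * p_m + lik[1] * (1 - p_m))
      }
      expect_gte(res$conditional_performance[m], blind - 1e-12)
      if (res$is_casting[m]) {
        if (primaries[m] == "s") part$S <- c(part$S, m) else part$T <- c(part$T, m)
      } else {
        part$R <- c(part$R, m)
      }
    }
  }
})

test_that("a log-odds tie in a distinct-ability chain warns and keeps the primary", {
  # r*_3 equals r*_2 - r*_1 exactly: the third respondent faces a dead heat
  r3 <- log_odds(0.8) - log_odds(0.6)
  p3 <- 1 / (1 + exp(-r3))
  prof <- ability_profile(c(0.6, 0.8, p3))
  expect_warning(res <- run_sequence(prof, c("s", "t", "s")), "tie")
  expect_true(res$is_casting[3])
  expect_equal(res$answer[3], "s")
  expect_equal(res$conditional_performance[3], 0.5)
})
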