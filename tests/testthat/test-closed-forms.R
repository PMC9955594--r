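test_that("pi_max is the two-agree posterior", {
  expect_equal(pi_max(0.5), 0.5)
  expect_equal(pi_max(0.7), 0.49 / 0.58)
  expect_equal(pi_max(0.9), 0.81 / 0.82)
})

test_that("equal-ability mean performance: anchors, parity, limit", {
  expect_equal(mean_performance_equal(0.7, 1), 0.7)
  expect_equal(mean_performance_equal(0.7, 2), 0.7)
  expect_equal(mean_performance_equal(0.7, 3), 0.784)
  expect_equal(mean_performance_equal(0.7, 9), 0.8403209, tolerance = 1e-6)
  for (p in c(0.55, 0.65, 0.75, 0.85, 0.95)) {
    # the correction term is negative and the damping factor below one,
    # which forces odd-step growth toward the ceiling
    expect_lt(p * (1 - p) * (1 - 2 * p), 0)
    expect_lt(2 * p * (1 - p), 1)
    odd <- mean_performance_equal(p, seq(1, 31, by = 2))
    expect_true(all(diff(odd) >= 0))
    expect_true(all(diff(odd[1:6]) > 0))
    expect_true(all(odd <= pi_max(p)))      # saturates in double precision
    expect_true(all(odd[1:6] < pi_max(p)))
    # even orders repeat the previous odd value
    expect_equal(mean_performance_equal(p, seq(2, 30, by = 2)),
                 odd[-length(odd)])
    expect_equal(mean_performance_equal(p, 401), pi_max(p), tolerance = 1e-10)
  }
})

test_that("expert mean performance covers aware and unaware regimes", {
  # gifted and aware: order-independent, equal to own ability
  expect_equal(expert_performance(0.7, 0.95, n = 1:7, aware = TRUE),
               rep(0.95, 7))
  # unaware: damping factor is 1 at n = 1
  expect_equal(expert_performance(0.7, 0.95, n = 1, aware = FALSE), 0.95)
  expect_equal(expert_performance(0.7, 0.95, n = 3, aware = FALSE),
               0.84482759 + (0.95 - 0.84482759) * 0.42,
               tolerance = 1e-7)
  # unrecognised talent decays with order when q > pi_max(p)
  unaware <- expert_performance(0.7, 0.95, n = seq(1, 13, 2), aware = FALSE)
  expect_true(all(diff(unaware) < 0))
  # modest expert (q < pi_max): aware and unaware coincide, increase with n
  modest_aw <- expert_performance(0.7, 0.8, n = 1:10, aware = TRUE)
  modest_un <- expert_performance(0.7, 0.8, n = 1:10, aware = FALSE)
  expect_equal(modest_aw, modest_un)
  expect_true(all(diff(modest_aw[seq(1, 9, 2)]) > 0))
  # awareness never hurts
  for (q in c(0.75, 0.85, 0.9, 0.99)) {
    expect_true(all(expert_performance(0.7, q, 1:9, aware = TRUE) >=
                      expert_performance(0.7, q, 1:9, aware = FALSE) - 1e-12))
  }
  expect_error(expert_performance(0.7, 0.6, 1), "must satisfy")
})

test_that("expert closed form degenerates to the equal-ability form as q -> p", {
  for (p in c(0.6, 0.75, 0.9)) {
    expect_equal(expert_performance(p, p + 1e-9, n = 1:12, aware = FALSE),
                 mean_performance_equal(p, 1:12),
                 tolerance = 1e-7)
  }
})

test_that("three-person analysis reproduces the case partition", {
  res <- three_person_analysis(0.7, 0.75, 0.72)
  expect_equal(res$case, "simple_majority")
  expect_equal(res$e_pi3, 0.813)
  expect_equal(res$e_pi2, 0.75)

  res <- three_person_analysis(0.8, 0.6, 0.7)
  expect_equal(res$case, "follow_first_cascade")
  expect_equal(c(res$e_pi2, res$e_pi3), c(0.8, 0.8))

  res <- three_person_analysis(0.6, 0.7, 0.8)
  expect_equal(res$case, "third_independent")
  expect_equal(res$e_pi3, 0.8)

  res <- three_person_analysis(0.55, 0.95, 0.56)
  expect_equal(res$case, "follow_second")
  expect_equal(res$e_pi3, 0.95)

  res <- three_person_analysis(0.6, 0.65, 0.95)
  expect_equal(res$case, "third_independent")

  res <- three_person_analysis(0.7, 0.6, 0.8)
  expect_equal(res$case, "third_overrides_cascade")
  expect_equal(res$e_pi3, 0.8)
})

test_that("the unweighted majority beats the non-expert individuals", {
  # M > p1 whenever the first is not an expert (r1 < r2 + r3)
  set.seed(3)
  for (i in 1:30) {
    p <- sort(runif(3, 0.55, 0.95))
    p <- c(p[1], p[3], p[2])  # p2 > p1 so the majority branch is reachable
    res <- suppressWarnings(three_person_analysis(p[1], p[2], p[3]))
    r <- log_odds(p)
    if (res$case == "simple_majority") {
      expect_gt(res$e_pi3, p[1])
      if (r[3] < r[1] + r[2]) expect_gt(res$e_pi3, p[3])
    }
  }
})

test_that("mean performance of the third drops across the p1 = p2 diagonal", {
  eps <- 1e-3
  above <- three_person_analysis(0.7 - eps, 0.7, 0.7)   # p2 > p1, interior
  below <- three_person_analysis(0.7 + eps, 0.7, 0.7)   # p1 > p2, cascade
  expect_equal(above$case, "simple_majority")
  expect_equal(below$case, "follow_first_cascade")
  expect_gt(above$e_pi3, below$e_pi3)
  # the drop survives to the diagonal limit: M(0.7, 0.7, 0.7) = 0.784 > 0.7
  expect_gt(above$e_pi3 - below$e_pi3, 0.07)
})

test_that("three_person_grid emits the phase structure as data", {
  grid <- three_person_grid(0.7, step = 0.05)
  expect_named(grid, c("p1", "p2", "case", "e_pi2", "e_pi3"))
  expect_true(all(grid$case %in% c(
    "third_independent", "follow_second", "simple_majority",
    "follow_first_cascade", "third_overrides_cascade"
  )))
  # below the diagonal there is no simple-majority region
  expect_false(any(grid$case[grid$p1 > grid$p2] == "simple_majority"))
  # the five regions all materialise at p3 = 0.7
  expect_setequal(unique(grid$case), c(
    "third_independent", "follow_second", "simple_majority",
    "follow_first_cascade", "third_overrides_cascade"
  ))
})
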