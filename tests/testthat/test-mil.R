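# Classical bag label, pooling, and the alpha/beta decision rule.

test_that("classical_bag_label matches the at-least-one-positive convention", {
  expect_identical(classical_bag_label(c(0, 0, 0)), 0L)
  expect_identical(classical_bag_label(c(0, 1, 0)), 1L)
  expect_error(classical_bag_label(integer(0)), "empty-bag")
})

test_that("pool computes max/mean and max dominates mean", {
  expect_equal(pool(c(0.2, 0.9, 0.4), "max"), 0.9)
  expect_equal(pool(c(0.2, 0.9, 0.4), "mean"), 0.5)
  expect_error(pool(numeric(0), "max"), "empty-bag")
  set.seed(12)
  for (rep in 1:20) {
    s <- runif(sample(1:10, 1))
    expect_gte(pool(s, "max"), pool(s, "mean"))
    expect_equal(pool(s, "mean"), pool(sample(s), "mean"))  # permutation-invariant
  }
})

test_that("decide_bag reproduces the worked criterion examples", {
  cfg <- decision_config(alpha = 0.95, beta = 2)
  d1 <- decide_bag(fast_scored_bag(c(0.96, 0.97, 0.20)), cfg)
  expect_equal(d1$count_above_alpha, 2L)
  expect_true(d1$criterion_majority)
  expect_equal(d1$label, 1L)

  d2 <- decide_bag(fast_scored_bag(c(0, 0, 0)), cfg)
  expect_equal(d2$label, 0L)
  expect_equal(d2$count_depressive, 0L)

  d3 <- decide_bag(fast_scored_bag(c(0.6, 0.6, 0.6)), cfg)
  expect_false(d3$criterion_majority)
  expect_true(d3$criterion_count)  # 3 depressive > beta = 2
  expect_equal(d3$label, 1L)

  d4 <- decide_bag(fast_scored_bag(c(0.6, 0.4, 0.4)), cfg)
  expect_false(d4$criterion_majority)
  expect_false(d4$criterion_count)
  expect_equal(d4$label, 0L)
})

test_that("boundary equality does not fire a flag; counts match flags", {
  d <- decide_bag(fast_scored_bag(c(0.95, 0.5, 0.96)),
                  decision_config(alpha = 0.95, beta = 0))
  expect_equal(d$count_above_alpha, 1L)   # 0.95 == alpha does not exceed it
  expect_equal(d$count_depressive, 2L)    # 0.5 == cutoff does not count
  expect_equal(sum(d$per_instance_flags$above_alpha), d$count_above_alpha)
  expect_equal(sum(d$per_instance_flags$depressive), d$count_depressive)
})

test_that("decide_bag is permutation-invariant and monotone in scores", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    s <- runif(n)
    cfg <- decision_config(alpha = sample(c(0.5, 0.75, 0.95), 1),
                           beta = sample(0:3, 1))
    base <- decide_bag(fast_scored_bag(s), cfg)
    perm <- decide_bag(fast_scored_bag(sample(s)), cfg)
    expect_identical(base$label, perm$label)
    # raising one score never flips 1 -> 0
    j <- sample(n, 1)
    s2 <- s; s2[j] <- min(1, s2[j] + runif(1))
    up <- decide_bag(fast_scored_bag(s2), cfg)
    expect_gte(up$label, base$label)
  }
})

test_that("alpha and beta act monotonically on the criteria", {
  set.seed(17)
  for (rep in 1:30) {
    s <- runif(sample(2:8, 1))
    a1 <- sort(runif(2, 0.1, 1))
    d_lo <- decide_bag(fast_scored_bag(s), decision_config(alpha = a1[1], beta = 1))
    d_hi <- decide_bag(fast_scored_bag(s), decision_config(alpha = a1[2], beta = 1))
    expect_gte(d_lo$count_above_alpha, d_hi$count_above_alpha)
    b <- sample(0:5, 2)
    d_b1 <- decide_bag(fast_scored_bag(s),
                       decision_config(alpha = 0.9, beta = min(b)))
    d_b2 <- decide_bag(fast_scored_bag(s),
                       decision_config(alpha = 0.9, beta = max(b)))
    expect_gte(d_b1$label, d_b2$label)
  }
})

test_that("count_only with beta 0 recovers the classical rule under the 0.5 cutoff", {
  cfg <- decision_config(alpha = 0.95, beta = 0, variant = "count_only")
  set.seed(21)
  for (rep in 1:40) {
    s <- runif(sample(1:9, 1))
    inst_labels <- as.integer(s > 0.5)
    got <- decide_bag(fast_scored_bag(s), cfg)$label
    want <- if (all(inst_labels == 0)) 0L else classical_bag_label(inst_labels)
    expect_identical(got, want)
  }
})

test_that("single_or_count flags a bag on one high-confidence instance", {
  cfg <- decision_config(alpha = 0.9, beta = 10, variant = "single_or_count")
  expect_equal(decide_bag(fast_scored_bag(c(0.2, 0.95, 0.1)), cfg)$label, 1L)
  expect_equal(decide_bag(fast_scored_bag(c(0.2, 0.85, 0.1)), cfg)$label, 0L)
  # majority reading would say no here: 1 of 3 is not more than half
  cfg_m <- decision_config(alpha = 0.9, beta = 10, variant = "majority_or_count")
  expect_equal(decide_bag(fast_scored_bag(c(0.2, 0.95, 0.1)), cfg_m)$label, 0L)
})

test_that("fractional beta thresholds scale with bag size", {
  cfg <- decision_config(alpha = 0.95, beta = 0.25, beta_fraction = TRUE)
  # 2 of 4 depressive: 2 > 0.25*4 = 1 -> positive
  expect_equal(decide_bag(fast_scored_bag(c(0.6, 0.6, 0.1, 0.1)), cfg)$label, 1L)
  # 1 of 4: 1 > 1 is false -> negative
  expect_equal(decide_bag(fast_scored_bag(c(0.6, 0.1, 0.1, 0.1)), cfg)$label, 0L)
})

test_that("decide_dataset tallies confusion counts and tolerates unlabeled bags", {
  cfg <- decision_config(alpha = 0.95, beta = 0)
  bags <- list(
    as_scored_bag(c(0.9, 0.6), participant_id = "tp", label = 1),
    as_scored_bag(c(0.1, 0.2), participant_id = "tn", label = 0),
    as_scored_bag(c(0.7, 0.1), participant_id = "fp", label = 0),
    as_scored_bag(c(0.2, 0.3), participant_id = "fn", label = 1),
    as_scored_bag(c(0.9, 0.9), participant_id = "unl")
  )
  res <- decide_dataset(bags, cfg)
  expect_equal(res$confusion$TP, 1L)
  expect_equal(res$confusion$TN, 1L)
  expect_equal(res$confusion$FP, 1L)
  expect_equal(res$confusion$FN, 1L)
  expect_equal(res$n_unlabeled, 1L)
  expect_length(res$decisions, 5L)
  expect_equal(res$confusion$TP + res$confusion$FP + res$confusion$TN +
                 res$confusion$FN, 4L)
})

test_that("invalid configurations are parameter errors", {
  expect_error(decision_config(alpha = 0), "alpha")
  expect_error(decision_config(alpha = 1.2), "alpha")
  expect_error(decision_config(beta = -1), "beta")
  expect_error(decide_bag(fast_scored_bag(numeric(0)), decision_config()),
               "empty-bag")
})
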