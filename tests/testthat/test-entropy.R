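test_that("transition counting conditions on the previous outcome", {
  tr <- make_trials(c("adv", "adv", "disadv", "disadv", "adv"),
                    c("gain", "loss", "loss", "gain", "gain"))
  num <- count_transitions(tr)$num
  # hand count: t1->t2 Stay|gain, t2->t3 Shift|loss, t3->t4 Stay|loss,
  # t4->t5 Shift|gain
  expect_identical(num["stay", "gain"], 1L)
  expect_identical(num["shift", "gain"], 1L)
  expect_identical(num["stay", "loss"], 1L)
  expect_identical(num["shift", "loss"], 1L)

  # a fully deterministic stayer: 39 stay transitions, no shifts
  tr <- make_trials(rep("adv", 40), rep(c("gain", "loss"), 20))
  num <- count_transitions(tr)$num
  expect_identical(sum(num["stay", ]), 39L)
  expect_identical(sum(num["shift", ]), 0L)

  # all timeouts: nothing to count
  tr <- make_trials(rep("none", 10), rep("loss", 10))
  expect_identical(sum(count_transitions(tr)$num), 0L)
  expect_identical(sum(count_transitions(tr[0, ])$num), 0L)
})

test_that("timeout trials break the Stay/Shift chain on both sides", {
  tr <- make_trials(c("adv", "none", "adv", "adv"),
                    c("gain", "loss", "gain", "gain"))
  num <- count_transitions(tr)$num
  # only t3->t4 is a valid transition (Stay under gain)
  expect_identical(sum(num), 1L)
  expect_identical(num["stay", "gain"], 1L)
})

test_that("smoothed conditional probabilities follow the count formula", {
  expect_equal(as.numeric(conditional_policy(counts_object(0, 0, 0, 0))),
               rep(0.5, 4))
  p <- conditional_policy(counts_object(3, 1, 0, 0))
  expect_equal(p["stay", "gain"], 4 / 6, tolerance = 1e-12)
  p <- conditional_policy(counts_object(0, 0, 39, 0))
  expect_equal(p["stay", "loss"], 40 / 41, tolerance = 1e-12)
  expect_true(all(abs(colSums(p) - 1) < 1e-12))
  expect_error(conditional_policy(counts_object(0, 0, 1, 1, c = 0)),
               "undefined")
})

test_that("entropy matches a brute-force enumeration of the four terms", {
  # uniform policy scores exactly 1
  expect_equal(entropy(counts_object(10, 10, 10, 10)), 1)
  expect_identical(entropy(counts_object(0, 0, 0, 0)), 1)
  # stay probabilities (2/3, 1/2): mean of h(2/3) and 1
  pol <- structure(matrix(c(2 / 3, 1 / 3, 1 / 2, 1 / 2), 2,
                          dimnames = list(c("stay", "shift"),
                                          c("gain", "loss"))),
                   class = "conditional_policy")
  expect_equal(entropy(pol), 0.9591479, tolerance = 1e-6)
  # oracle equivalence on random count tables
  set.seed(99)
  for (i in 1:100) {
    k <- sample(0:40, 4, replace = TRUE)
    cc <- sample(c(0.5, 1, 2), 1)
    expect_equal(entropy(counts_object(k[1], k[2], k[3], k[4], c = cc)),
                 brute_force_entropy(k[1], k[2], k[3], k[4], c = cc),
                 tolerance = 1e-12)
  }
})

test_that("smoothing keeps entropy strictly positive for fixed strategies", {
  # constant chooser with both outcome states populated: stay
  # probabilities ~ (n_S + 1)/(n_S + 2), H small but above zero
  tr <- make_trials(rep("adv", 40), rep(c("gain", "loss"), 20))
  h <- entropy(tr)
  expect_gt(h, 0)
  expect_lt(h, 0.3)
  # the two canonical fixed strategies reach exactly the same (minimal)
  # smoothed entropy: a constant stayer concentrates 39 transitions in
  # Stay|gain, a perfect loss-shifting WSLS run concentrates them in
  # Shift|loss, and H depends only on the per-state counts
  h_const <- entropy(make_trials(rep("adv", 40), rep("gain", 40)))
  h_wsls <- entropy(make_trials(rep(c("adv", "disadv"), 20),
                                rep("loss", 40)))
  expect_equal(h_wsls, h_const, tolerance = 1e-15)
})

test_that("behavioral indices count bias over responses and reward over all trials", {
  tr <- make_trials(c("adv", "adv", "none", "disadv"),
                    c("gain", "loss", "loss", "gain"))
  bi <- behavioral_indices(tr)
  expect_equal(bi$response_bias, 2 / 3)
  expect_equal(bi$reward_acquisition, 2 / 4) # timeout loss in denominator
  expect_equal(bi$n_responded, 2L + 1L)
  tr <- make_trials(rep("adv", 5), rep("gain", 5))
  expect_equal(behavioral_indices(tr)$reward_acquisition, 1)
  expect_error(
    behavioral_indices(make_trials(rep("none", 3), rep("loss", 3))),
    "no responded trials")
})

test_that("a strongly biased policy under 70/30 approaches the implied reward rate", {
  trials <- run_session(agent_biased_random(0.68),
                        task_config("contingent", trials_per_block = 10000,
                                    blocks = 1), seed = 21)
  implied <- 0.68 * 0.70 + 0.32 * 0.30 # = 0.572
  se <- sqrt(implied * (1 - implied) / 10000)
  expect_lt(abs(mean(trials$outcome == "gain") - implied), 3 * se)
})

test_that("condition summaries average per-block indices", {
  tr1 <- make_trials(rep(c("adv", "disadv"), 10),
                     rep(c("gain", "loss"), 10), block = 0L)
  tr2 <- make_trials(rep("adv", 20), rep("gain", 20), block = 1L)
  both <- dplyr::bind_rows(tr1, tr2)
  both$subject_id <- "S01"
  per_block <- score_trials(both)
  summ <- condition_summary(both)
  expect_equal(summ$entropy, mean(per_block$entropy))
  expect_equal(summ$response_bias, mean(per_block$response_bias))
  # three identical blocks: summary equals the per-block value
  tri <- dplyr::bind_rows(lapply(0:2, function(b)
    make_trials(rep(c("adv", "disadv"), 10), rep(c("gain", "loss"), 10),
                block = b)))
  tri$subject_id <- "S01"
  expect_equal(condition_summary(tri)$entropy,
               score_trials(tri)$entropy[1])
  # pooled aggregation pools counts, not block entropies
  pooled <- condition_summary(both, aggregate = "pooled")
  pooled_counts <- count_transitions(tr1)$num + count_transitions(tr2)$num
  expect_equal(pooled$entropy,
               entropy(counts_object(pooled_counts["stay", "gain"],
                                     pooled_counts["shift", "gain"],
                                     pooled_counts["stay", "loss"],
                                     pooled_counts["shift", "loss"])))
})

test_that("entropy is invariant to stimulus and side relabeling", {
  set.seed(10)
  tr <- make_trials(sample(c("adv", "disadv"), 60, replace = TRUE),
                    sample(c("gain", "loss"), 60, replace = TRUE))
  relabeled <- tr
  relabeled$choice <- c(adv = "disadv", disadv = "adv")[tr$choice]
  relabeled$side_adv <- c(L = "R", R = "L")[tr$side_adv]
  expect_equal(entropy(tr), entropy(relabeled), tolerance = 1e-15)
})
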