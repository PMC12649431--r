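test_that("state encoding is deterministic, total, and bit-local", {
  withr::with_seed(1, {
    feats <- matrix(runif(20 * 8), 20, 8)
  })
  enc <- fit_state_encoder(feats)
  # identical vectors share a key; degenerate identical features too
  expect_identical(encode_state(enc, feats[1, ]), encode_state(enc, feats[1, ]))
  same <- matrix(0.5, 4, 8)
  enc2 <- fit_state_encoder(same)
  keys <- encode_state(enc2, same)
  expect_length(unique(keys), 1)
  # two vectors straddling one median differ in exactly that bit
  v1 <- enc$thresholds + 0.01
  v2 <- v1; v2[3] <- enc$thresholds[3] - 0.01
  k1 <- strsplit(encode_state(enc, v1), "")[[1]]
  k2 <- strsplit(encode_state(enc, v2), "")[[1]]
  expect_identical(which(k1 != k2), 3L)
  # unseen vectors always encode
  expect_match(encode_state(enc, runif(8) * 100), "^[01]{8}$")
  expect_error(fit_state_encoder(feats[1, , drop = FALSE]), "at least 2")
})

test_that("epsilon-greedy selection exploits, explores, and tie-breaks low", {
  q <- new_q_table(3)
  q$table[["s"]] <- c(0.2, 0.9, 0.1)
  for (i in 1:20) expect_identical(select_action(q, "s", 0), 1L)
  # all-zero (unseen) row ties -> lowest index
  expect_identical(select_action(q, "unseen", 0), 0L)
  q$table[["t"]] <- c(0.5, 0.5, 0.1)
  expect_identical(select_action(q, "t", 0), 0L)
  # epsilon = 1 explores roughly uniformly
  q4 <- new_q_table(4)
  withr::with_seed(11, {
    draws <- replicate(4000, select_action(q4, "s", 1))
  })
  expect_gt(stats::chisq.test(table(factor(draws, levels = 0:3)))$p.value,
            0.01)
  expect_error(select_action(q, "s", 1.2), "epsilon")
})

test_that("rewards are +1/-1 on match/mismatch", {
  expect_identical(compute_reward(2, 2), 1)
  expect_identical(compute_reward(2, 3), -1)
})

test_that("the Bellman update matches hand arithmetic and the geometric fixed point", {
  q <- new_q_table(2)
  # first correct terminal update from zero at alpha = 0.1
  expect_equal(q_update(q, "s", 0, 1, terminal = TRUE, alpha = 0.1),
               0.1, tolerance = 1e-13)
  # mixed non-terminal case: 0.5 + 0.1 * (-1 + 0.6*0.5 - 0.5) = 0.38
  q2 <- new_q_table(2)
  q2$table[["a"]] <- c(0.5, 0)
  q2$table[["b"]] <- c(0.5, 0.2)
  expect_equal(q_update(q2, "a", 0, -1, "b", terminal = FALSE,
                        alpha = 0.1, gamma = 0.6),
               0.38, tolerance = 1e-13)
  # alpha = 0 is a no-op for any reward and successor
  q3 <- new_q_table(2)
  q3$table[["s"]] <- c(0.7, -0.2)
  q_update(q3, "s", 1, -1, "s", FALSE, alpha = 1e-300, gamma = 0.6)
  expect_equal(q_lookup(q3, "s"), c(0.7, -0.2), tolerance = 1e-12)
  # repeated correct terminal updates follow Q_n = 1 - 0.9^n
  q4 <- new_q_table(2)
  for (n in 1:50) {
    v <- q_update(q4, "s", 0, 1, terminal = TRUE, alpha = 0.1)
    expect_equal(v, 1 - 0.9^n, tolerance = 1e-12)
  }
  expect_error(q_update(q4, "s", 0, NaN, terminal = TRUE), "finite")
})

test_that("unseen lookups are exactly zero and values stay finite", {
  q <- new_q_table(5)
  expect_identical(q_lookup(q, "never"), numeric(5))
})

test_that("training logs per-episode rewards with the stated parity and bounds", {
  withr::with_seed(2, {
    feats <- matrix(runif(12 * 6), 12, 6)
    labels <- rep(0:2, 4)
  })
  cfg <- q_config(episodes = 30, max_steps = 21, seed = 5)
  ag <- train_agent(feats, labels, cfg)
  expect_identical(nrow(ag$episodes), 30L)
  expect_identical(nrow(ag$steps), 30L * 21L)
  # total = sum of step rewards, parity of max_steps, within [-steps, steps]
  sums <- tapply(ag$steps$reward, ag$steps$episode, sum)
  expect_equal(as.numeric(sums), ag$episodes$total_reward)
  expect_true(all(ag$episodes$total_reward %% 2 == 21 %% 2))
  expect_true(all(abs(ag$episodes$total_reward) <= 21))
  # Q-values bounded by |r|/(1-gamma) = 2.5
  vals <- unlist(lapply(ls(ag$q$table), function(k) ag$q$table[[k]]))
  expect_true(all(abs(vals) <= 1 / (1 - cfg$gamma) + 1e-12))
  # zero episodes -> empty table and logs
  ag0 <- train_agent(feats, labels, q_config(episodes = 0, seed = 1))
  expect_identical(nrow(ag0$episodes), 0L)
  expect_length(ls(ag0$q$table), 0)
})

test_that("training is reproducible under a fixed seed", {
  withr::with_seed(3, {
    feats <- matrix(runif(10 * 4), 10, 4)
    labels <- rep(0:1, 5)
  })
  a1 <- train_agent(feats, labels, q_config(episodes = 15, max_steps = 8,
                                            seed = 42))
  a2 <- train_agent(feats, labels, q_config(episodes = 15, max_steps = 8,
                                            seed = 42))
  expect_identical(a1$episodes, a2$episodes)
  expect_identical(a1$steps, a2$steps)
  keys <- sort(ls(a1$q$table))
  expect_identical(keys, sort(ls(a2$q$table)))
  for (k in keys) expect_identical(a1$q$table[[k]], a2$q$table[[k]])
})

test_that("greedy prediction is argmax with low tie-break and class-0 fallback", {
  q <- new_q_table(4)
  enc <- structure(list(thresholds = rep(0.5, 4), dim = 4L),
                   class = "state_encoder")
  f_seen <- c(1, 1, 0, 0)
  q$table[[encode_state(enc, f_seen)]] <- c(0, 0.7, 0.2, 0)
  expect_identical(as.integer(predict_action(q, enc, f_seen)), 1L)
  f_unseen <- c(0, 0, 1, 1)
  p <- predict_action(q, enc, f_unseen)
  expect_identical(as.integer(p), 0L)
  expect_identical(attr(p, "unseen_rate"), 1)
  expect_warning(predict_action(q, enc, f_unseen, warn_unseen = TRUE),
                 "unseen")
  # greedy prediction coincides with epsilon = 0 selection for every state
  for (f in list(f_seen, f_unseen, runif(4))) {
    expect_identical(as.integer(predict_action(q, enc, f)),
                     select_action(q, encode_state(enc, f), 0))
  }
})

test_that("evaluation reports percent accuracy and a consistent confusion matrix", {
  withr::with_seed(4, feats <- matrix(runif(20 * 6), 20, 6))
  labels <- rep(0:1, each = 10)
  ag <- train_agent(feats, labels, q_config(episodes = 50, max_steps = 20,
                                            seed = 9))
  ev <- evaluate_agent(ag, feats, labels)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 100)
  expect_identical(sum(ev$report$confusion), 20L)
  expect_equal(rowSums(ev$report$confusion), c(`0` = 10, `1` = 10))
  # Eq-9 arithmetic: 9 of 10 correct -> 90%
  rep9 <- classification_report(rep(0:1, 5), c(rep(0:1, 4), 0, 0), 2)
  expect_equal(rep9$overall_accuracy, 90)
  expect_error(evaluate_agent(ag, feats[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("the Q-table round-trips through JSON", {
  withr::with_seed(5, feats <- matrix(runif(8 * 4), 8, 4))
  ag <- train_agent(feats, rep(0:1, 4), q_config(episodes = 10, max_steps = 6,
                                                 seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_qtable(ag, path)
  back <- load_qtable(path)
  expect_identical(back$config$gamma, ag$config$gamma)
  expect_equal(back$encoder$thresholds, unname(ag$encoder$thresholds),
               tolerance = 1e-12)
  for (k in ls(ag$q$table))
    expect_equal(q_lookup(back$q, k), ag$q$table[[k]])
  # predictions agree after reload
  expect_identical(as.integer(predict_action(back$q, back$encoder, feats)),
                   as.integer(predict(ag, feats)))
})
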