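test_that("label_explore follows the running-maximum rule", {
  # p1: sees 10 (opt 0), then 20 (opt 1), then keeps picking the max
  tt <- tiny_trials(choice = c(0, 1, 1, 0, 1),
                    reward = c(10, 20, 20, 10, 20))
  lab <- label_explore(tt)$explore
  expect_identical(lab[1:2], c(NA_integer_, NA_integer_))  # warm-up
  expect_identical(lab[3:5], c(0L, 1L, 0L))  # exploit, explore, exploit

  # a revealed jump moves the running max: picking old favorite = explore
  tt2 <- tiny_trials(choice = c(0, 1, 0, 1),
                     reward = c(10, 20, 30, 20))
  lab2 <- label_explore(tt2)$explore
  expect_identical(lab2[3], 1L)   # explored the lower-observed option
  expect_identical(lab2[4], 1L)   # 20 < 30: old favorite now the explore

  # always picking the running max => all exploit after warm-up
  tt3 <- tiny_trials(choice = c(0, 1, 1, 1), reward = c(10, 20, 20, 20))
  expect_identical(label_explore(tt3)$explore[3:4], c(0L, 0L))
})

test_that("exploration_rate handles edge cases", {
  allex <- label_explore(tiny_trials(c(0, 1, 1, 1), c(10, 20, 20, 20)))
  expect_equal(exploration_rate(allex), 0)
  alt <- tiny_trials(c(0, 1, 0, 1, 0, 1), c(10, 20, 10, 20, 10, 20))
  expect_equal(exploration_rate(label_explore(alt)), 0.5)
  nolab <- tiny_trials(c(0, 0), c(10, 10))
  expect_error(exploration_rate(label_explore(nolab)), "no labelled")
})

test_that("performance scores against the true trajectory", {
  tr <- simulate_values(env_config(n_trials = 20000), seed = 41)
  best <- as.integer(tr$v1 > tr$v0)
  always_right <- tiny_trials(best, ifelse(best == 1, tr$v1, tr$v0))
  expect_equal(performance(always_right, truth = tr), 1)
  set.seed(42)
  rand <- tiny_trials(sample(0:1, 20000, TRUE), reward = rep(0, 20000))
  expect_equal(performance(rand, truth = tr), 0.5, tolerance = 0.03)
  onesided <- tiny_trials(rep(0L, 20000), reward = rep(0, 20000))
  expect_equal(performance(onesided, truth = tr), 0.5, tolerance = 0.1)
  expect_error(performance(onesided, truth = tr[1:10, ]), "length")
})

test_that("explore lags and the hazard curve aggregate correctly", {
  # explore exactly every 4th labelled trial
  ch <- c(0, 1, rep(c(1, 1, 1, 0), 5))
  rw <- c(10, 20, rep(c(20, 20, 20, 10), 5))
  tt <- add_explore_lag(label_explore(tiny_trials(ch, rw)))
  hc <- hazard_curve(tt, support_threshold = 2)
  expect_equal(hc$rate[hc$lag %in% 1:3], rep(0, 3))
  expect_equal(hc$rate[hc$lag == 4], 1)
  # bookkeeping identities
  expect_equal(sum(hc$n_explore), sum(tt$explore, na.rm = TRUE))
  expect_equal(sum(hc$n_at_risk), sum(!is.na(tt$explore)))

  # before_first = "exclude" drops pre-first-explore trials
  ex <- add_explore_lag(label_explore(tiny_trials(ch, rw)),
                        before_first = "exclude")
  first_explore <- which(label_explore(tiny_trials(ch, rw))$explore == 1)[1]
  expect_true(all(is.na(ex$ell[seq_len(first_explore)])))
})

test_that("a constant-probability explorer yields a flat curve and recovers epsilon", {
  eps <- 0.15
  tt <- label_explore(pool_agents("reflexive", 40, seed = 43, epsilon = eps))
  r <- exploration_rate(tt)
  n <- sum(!is.na(tt$explore))
  # generative rate recovered within binomial error (after warm-up the
  # label coincides with the generative explore indicator)
  expect_lt(abs(r - eps), 3 * sqrt(eps * (1 - eps) / n))
  hc <- hazard_curve(tt, support_threshold = 200)
  sup <- hc[hc$supported, ]
  se <- sqrt(r * (1 - r) / sup$n_at_risk)
  expect_true(all(abs(sup$rate - r) < 4 * se))
})

test_that("trials_since_observed_jump counts and resets correctly", {
  # constant rewards: no jump ever observed, counter just increments
  tt <- tiny_trials(c(0, 1, 0, 1, 0), c(10, 20, 10, 20, 10))
  expect_identical(trials_since_observed_jump(tt)$s_obs, 0:4)

  # reward 30 after last-seen 10 on option 0: reset at that trial
  tt2 <- tiny_trials(c(0, 1, 1, 0, 1), c(10, 20, 20, 30, 20))
  expect_identical(trials_since_observed_jump(tt2)$s_obs,
                   c(0L, 1L, 2L, 0L, 1L))

  # two observed jumps seven trials apart: reaches 6, then resets
  ch <- c(0, 1, 0, rep(1, 6), 0)
  rw <- c(10, 20, 30, rep(20, 6), 50)
  s <- trials_since_observed_jump(tiny_trials(ch, rw))$s_obs
  expect_identical(s[3], 0L)
  expect_identical(s[9], 6L)
  expect_identical(s[10], 0L)

  # explore-count alternative: counter advances only on exploratory choices
  tt3 <- label_explore(tiny_trials(c(0, 1, 0, 1, 0, 0),
                                   c(10, 20, 30, 20, 30, 30)))
  se <- trials_since_observed_jump(tt3, count = "explores")$s_obs
  expect_identical(se[3], 0L)            # jump observed here
  expect_true(all(diff(se[3:6]) %in% 0:1))

  bad <- tiny_trials(c(0, 0), c(30, 10))
  expect_error(trials_since_observed_jump(bad), "decreasing")
})

test_that("median_rt summarises per participant", {
  tt <- rbind(tiny_trials(c(0, 1, 1), c(10, 20, 20), participant_id = "a",
                          rt_ms = c(400, 500, 600)),
              tiny_trials(c(0, 1), c(10, 20), participant_id = "b",
                          rt_ms = c(321, NA)))
  m <- median_rt(tt)
  expect_equal(m$median_rt[m$participant_id == "a"], 500)
  expect_equal(m$median_rt[m$participant_id == "b"], 321)
})

test_that("trial tables round-trip through CSV with NA as empty", {
  tt <- label_explore(run_agent(env_config(), agent_config("reflexive",
                                                           epsilon = 0.2),
                                seed = 44))
  path <- file.path(tempdir(), "tt.csv")
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(back$explore, tt$explore)
  expect_equal(back$reward, tt$reward)
  expect_true(is.na(back$rt_ms[1]))

  broken <- tt[, setdiff(names(tt), "reward")]
  path2 <- file.path(tempdir(), "broken.csv")
  utils::write.csv(broken, path2, row.names = FALSE, na = "")
  expect_error(read_trial_table(path2), "reward")

  gap <- tt; gap$trial[5] <- 999
  expect_error(validate_trial_table(gap), "contiguous")
})
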