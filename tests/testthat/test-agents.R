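test_that("parity_update matches hand values and the brute-force oracle", {
  expect_equal(parity_update(0, 0.075), 0.075)
  expect_equal(parity_update(0.5, 0.3), 0.5)       # symmetric fixed point
  expect_equal(parity_update(0.2, 0.1), 0.26)      # 0.2*0.9 + 0.8*0.1
  # recursion vs enumeration over all jump sequences, mixed hazards
  set.seed(4)
  for (k in c(3, 6, 8)) {
    h <- runif(k, 0, 0.3)
    expect_equal(Reduce(parity_update, h, accumulate = FALSE, init = 0),
                 odd_parity_brute(h))
  }
})

test_that("q increases monotonically toward 0.5 between observations", {
  q <- 0.02
  for (i in 1:200) {
    q2 <- parity_update(q, 0.075)
    expect_gt(q2, q)
    expect_lte(q2, 0.5)
    q <- q2
  }
  expect_equal(q, 0.5, tolerance = 1e-6)
})

test_that("believed_hazard follows each agent's internal model", {
  env <- env_config()
  ideal <- agent_config("reflective_ideal")
  fall <- agent_config("reflective_fallacy")
  b <- belief_init(env, ideal)
  expect_equal(believed_hazard(b, ideal, env), 0.075)
  b$s_obs <- 40L
  expect_equal(believed_hazard(b, ideal, env), 0.075)  # constant belief
  b$s_obs <- 0L
  expect_equal(believed_hazard(b, fall), 0.01)
  b$s_obs <- 30L
  expect_equal(believed_hazard(b, fall), 0.31)
  b$s_obs <- 200L
  expect_equal(believed_hazard(b, fall), 1)
  expect_error(believed_hazard(b, agent_config("reflexive")), "not defined")
  # dependent-regime default constant belief is the ramp's marginal rate
  dep <- env_config("dependent")
  expect_equal(believed_hazard(belief_init(dep, ideal), ideal, dep),
               1 / sum(seq_along(ramp_pmf()) * ramp_pmf()),
               tolerance = 1e-8)
})

test_that("observe updates last_obs, favorite, s_obs and resets q", {
  env <- env_config()
  cfg <- agent_config("reflective_ideal")
  b <- belief_init(env, cfg)            # last_obs (10, 20), favorite 1
  expect_identical(b$favorite, 1L)

  # exploit favorite, no jump: s_obs increments, q untouched
  b$q <- 0.3
  b2 <- observe(b, 1L, 20, cfg, env)
  expect_identical(b2$s_obs, 1L)
  expect_equal(b2$q, 0.3)

  # explore the non-favorite and reveal a jump: reset s_obs and q,
  # favorite switches
  b3 <- observe(b2, 0L, 30, cfg, env)
  expect_identical(b3$s_obs, 0L)
  expect_identical(b3$favorite, 0L)
  expect_equal(b3$q, 0.075)

  # exploratory look with no jump also resets q
  b3$q <- 0.4
  b4 <- observe(b3, 1L, 20, cfg, env)
  expect_equal(b4$q, 0.075)
  expect_identical(b4$favorite, 0L)

  # first observation of an option is never an observed jump
  b5 <- b
  b5$last_obs <- c(NA_real_, 20)
  b5$favorite <- 1L
  b6 <- observe(b5, 0L, 10, cfg, env)
  expect_identical(b6$s_obs, b5$s_obs + 1L)
  expect_equal(b6$last_obs, c(10, 20))

  # values never decrease
  expect_error(observe(b3, 0L, 10, cfg, env), "never decrease")
})

test_that("choose_option implements the threshold-plus-lapse policy", {
  env <- env_config()
  refl <- agent_config("reflexive", epsilon = 0)
  b <- belief_init(env, refl)
  expect_true(all(replicate(50, choose_option(b, refl)) == 1L))

  thr <- agent_config("reflective_ideal", epsilon = 0, theta = 0.3)
  b$q <- 0.4
  expect_identical(choose_option(b, thr), 0L)   # explore: q >= theta
  b$q <- 0.1
  expect_identical(choose_option(b, thr), 1L)   # exploit

  set.seed(9)
  eps <- agent_config("reflexive", epsilon = 0.17)
  picks <- replicate(10000, choose_option(b, eps))
  expect_equal(mean(picks == 0L), 0.17, tolerance = 0.1)
})

test_that("run_agent is reproducible and internally consistent", {
  env <- env_config()
  a <- agent_config("reflective_ideal")
  t1 <- run_agent(env, a, seed = 31)
  t2 <- run_agent(env, a, seed = 31)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 200)
  # reward is the post-jump value of the chosen option
  vmat <- cbind(t1$v0, t1$v1)
  expect_equal(t1$reward, vmat[cbind(seq_len(200), t1$choice + 1L)])
  expect_equal(t1$correct, as.integer(t1$choice == t1$best))
})

test_that("theta defaults resolve per kind and hazard regime", {
  ind <- env_config(); dep <- env_config("dependent")
  ideal <- agent_config("reflective_ideal")
  expect_null(ideal$theta)
  expect_equal(resolve_theta(ideal, ind)$theta, 0.32)
  expect_equal(resolve_theta(ideal, dep)$theta, 0.34)
  fall <- agent_config("reflective_fallacy")
  expect_equal(resolve_theta(fall, ind)$theta, 0.415)
  expect_equal(resolve_theta(fall, dep)$theta, 0.355)
  # explicit theta wins
  expect_equal(resolve_theta(agent_config("reflective_ideal", theta = 0.2),
                             ind)$theta, 0.2)
})

test_that("reflexive exploration shows no lag dependence", {
  tt <- label_explore(pool_agents("reflexive", 60, seed = 33))
  tt <- add_explore_lag(tt)
  d <- tt[!is.na(tt$explore), ]
  fit <- glm(explore ~ ell, data = d, family = binomial())
  z <- coef(summary(fit))["ell", "z value"]
  expect_lt(abs(z), 2.5)
})

test_that("agent configs round-trip through JSON and YAML", {
  cfg <- agent_config("reflective_fallacy", epsilon = 0.05,
                      believed_dh = 0.02)
  for (ext in c("json", "yaml")) {
    path <- file.path(tempdir(), paste0("agent.", ext))
    write_config(cfg, path)
    expect_equal(read_config(path), cfg)
  }
})
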