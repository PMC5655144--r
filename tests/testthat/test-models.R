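test_that("initial expectations are spaced equally between the extremes", {
  expect_equal(initial_esvs(0.85, 0.15),
               c(0.85, 0.85 - 0.7 / 3, 0.85 - 1.4 / 3, 0.15),
               tolerance = 1e-12)
  expect_equal(initial_esvs(0.4, 0.4), rep(0.4, 4))
  expect_equal(initial_esvs(1, 0), c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
})

test_that("prediction errors and learning updates follow the stated arithmetic", {
  expect_equal(compute_spe(1, 0.85), 0.15)
  expect_equal(compute_spe(0, 0.30), -0.30)
  expect_equal(compute_spe(-1, -0.50), -0.50)

  expect_equal(rw_update(0.50, 0.50, 0.04), 0.52)
  expect_equal(rw_update(0.3, 123, 0), 0.3)
  expect_equal(rw_update(0.85, -1.85, 0.10), 0.665)
})

test_that("softmax choice probability has the right fixed point and limits", {
  # 0.5 exactly whenever the summed drive is zero, at any temperature
  for (temp in c(0.01, 0.12, 1, 50)) {
    expect_identical(choice_prob(0.3, -0.3, temp), 0.5)
    expect_identical(choice_prob(-1.2, 1.2, temp), 0.5)
    expect_identical(choice_prob(0, 0, temp), 0.5)
  }
  # independent evaluation of the logistic at (0.58, 0.42, 0.12)
  expect_equal(choice_prob(0.58, 0.42, 0.12),
               1 / (1 + exp(-(0.58 + 0.42) / 0.12)), tolerance = 1e-12)
  expect_equal(choice_prob(0.58, 0.42, 0.12), 0.99976, tolerance = 1e-4)
  # infinite-temperature limit
  expect_equal(choice_prob(0.9, 0.5, 1e9), 0.5, tolerance = 1e-6)
  expect_error(choice_prob(0.5, 0, 0), "temperature")
  expect_error(choice_prob(0.5, 0, -1), "temperature")
})

test_that("increasing the response bias never decreases choice probability", {
  set.seed(41)
  for (i in 1:50) {
    esv <- runif(1, -1, 1)
    temp <- runif(1, 0.02, 2)
    b <- sort(runif(2, -2, 2))
    expect_gte(choice_prob(esv, b[2], temp), choice_prob(esv, b[1], temp))
  }
})

test_that("recursive kernel equals the explicit exponential sum", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(5:80, 1))
    gam <- runif(1)
    expect_equal(kernel_states(x, gam, "recursive"),
                 kernel_states(x, gam, "sum"), tolerance = 1e-12)
    # independent in-test oracle: direct double loop
    oracle <- sapply(seq_along(x), function(t)
      sum(gam ^ (t - 1:t) * x[1:t]))
    expect_equal(kernel_states(x, gam, "recursive"), oracle,
                 tolerance = 1e-12)
  }
})

test_that("per-probe predictions match hand-computed kernel sums", {
  # esv fixed at 0.85 (eta = 0); outcomes approve/none/approve give
  # SPEs 0.15, -0.85, 0.15; probe after trial 3 with gamma = 0.5:
  # 0.7 + 0.04 * (0.25*0.15 + 0.5*(-0.85) + 0.15) = 0.6905
  sched <- micro_schedule(c("approve", "none", "approve"))
  p <- agent_params(w0 = 0.7, w1 = 0.04, eta = 0, gamma = 0.5,
                    esv1_init = 0.85, esv4_init = 0.85)
  pred <- predict_self_esteem(sched, p, "M1")
  expect_equal(pred$esteem_pred, 0.6905, tolerance = 1e-12)

  # all-zero prediction errors: every prediction equals w0
  sched0 <- micro_schedule(rep("approve", 5))
  p0 <- agent_params(w0 = 0.6, w1 = 0.1, eta = 0.2, gamma = 0.7,
                     esv1_init = 1, esv4_init = 1)
  expect_equal(predict_self_esteem(sched0, p0, "M1")$esteem_pred, 0.6)

  # memoryless limit gamma = 0: w0 + w1 * SPE_t
  pg0 <- agent_params(w0 = 0.7, w1 = 0.04, eta = 0, gamma = 0,
                      esv1_init = 0.85, esv4_init = 0.85)
  expect_equal(predict_self_esteem(sched, pg0, "M1")$esteem_pred,
               0.7 + 0.04 * 0.15, tolerance = 1e-12)

  expect_error(model_trace(sched[0, ], p, "M1"))
})

test_that("valence-only model ignores group identity entirely", {
  s <- build_session(session_config(), seed = 5)
  p <- agent_params(w0 = 0.7, w1 = 0.05, gamma = 0.6)
  base_pred <- predict_self_esteem(s, p, "M6")$esteem_pred
  perm <- s
  relabel <- c(3L, 1L, 4L, 2L)
  perm$trials$group_id <- relabel[s$trials$group_id]
  expect_equal(predict_self_esteem(perm, p, "M6")$esteem_pred, base_pred)
})

test_that("simulated agents respect the noiseless and saturated-bias limits", {
  s <- build_session(session_config(), seed = 2)

  sim0 <- simulate_agent(s, agent_params(sigma = 1e-12), "M1", seed = 4)
  expect_equal(sim0$record$probe_rating[sim0$trace$probes$trial_index],
               sim0$trace$probes$esteem_pred, tolerance = 1e-9)

  simb <- simulate_agent(s, agent_params(eta = 0, esv0 = 10,
                                         temperature = 0.12),
                         "M1", seed = 4)
  expect_true(all(simb$record$choice == "liked"))

  sim <- simulate_agent(s, agent_params(), "M1", seed = 9)
  expect_equal(nrow(sim$record), 184)
  expect_equal(sum(!is.na(sim$record$probe_rating)), 78)
  expect_true(all(sim$record$probe_rating >= 0 &
                    sim$record$probe_rating <= 1, na.rm = TRUE))

  again <- simulate_agent(s, agent_params(), "M1", seed = 9)
  expect_identical(as.data.frame(sim$record), as.data.frame(again$record))

  expect_error(simulate_agent(s, agent_params(w2 = 0.1), "M1", seed = 1),
               "w2")
  expect_error(model_trace(s, agent_params(), "M4"), "requires w2")
})

test_that("learned expectations converge to the group's expected feedback", {
  # single group, p = 0.8: expected ESV tends to 2p - 1 = 0.6
  cfg <- session_config(n_groups = 1, approval_probs = 0.8,
                        feedback_trials_per_group = 2000,
                        no_feedback_per_group = 0, n_blocks = 1,
                        probe_gaps = rep(200, 10), max_run = 2001,
                        max_recurrence_gap = 2001)
  s <- build_session(cfg, seed = 6)
  tr <- model_trace(s, agent_params(eta = 0.1, esv1_init = 0,
                                    esv4_init = 0), "M1")
  expect_equal(mean(tr$trials$esv[1001:2000]), 0.6, tolerance = 0.05)
})

test_that("missed trials are dropped from likelihood, kernel and learning", {
  s <- build_session(session_config(), seed = 8)
  p <- agent_params()
  sim <- simulate_agent(s, p, "M1", seed = 3)
  rec <- sim$record
  rec$missed[c(10, 50)] <- TRUE
  tr <- model_trace(rec, p, "M1")
  expect_equal(nrow(tr$trials), 182)
  expect_false(any(tr$trials$trial_index %in% c(10, 50)))
  ll <- joint_loglik(rec, p, "M1")
  expect_equal(attr(ll, "n"), 182 + 74)
})
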