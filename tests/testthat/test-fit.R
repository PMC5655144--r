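test_that("joint log-likelihood matches hand computations", {
  s <- build_session(session_config(), seed = 1)
  sim <- simulate_agent(s, agent_params(), "M1", seed = 2)

  # maximum-entropy choices: zero drive everywhere, ratings excluded
  rec <- sim$record
  rec$probe_rating[] <- NA_real_
  p_flat <- agent_params(eta = 0, esv0 = 0, esv1_init = 0, esv4_init = 0)
  ll <- joint_loglik(rec, p_flat, "M1")
  expect_equal(attr(ll, "ll_choice"), 184 * log(0.5), tolerance = 1e-12)
  expect_equal(attr(ll, "ll_rating"), 0)

  # zero-residual Gaussian term: ratings equal to deterministic predictions
  sim0 <- simulate_agent(s, agent_params(sigma = 1e-12), "M6", seed = 3)
  recz <- sim0$record
  pz <- agent_params(w0 = 0.73, w1 = 0.04, gamma = 0.66, sigma = 0.1)
  llz <- joint_loglik(recz, pz, "M6")
  expect_equal(as.numeric(llz), 74 * log(1 / (0.1 * sqrt(2 * pi))),
               tolerance = 1e-6)
  expect_equal(attr(llz, "n"), 74)

  # three-trial, one-probe micro example against independent arithmetic
  mrec <- hand_record(outcomes = c("approve", "none", "disapprove"),
                      choices = c("liked", "liked", "disliked"),
                      ratings_at = 3, ratings = 0.62,
                      approval_probs = 0.8)
  p <- agent_params(w0 = 0.7, w1 = 0.04, sigma = 0.1, eta = 0.1,
                    esv0 = 0.2, temperature = 0.3,
                    esv1_init = 0.5, esv4_init = 0.5, gamma = 0.5)
  # trial 1: esv .5, spe .5, update -> .55; trial 2: none, spe -.55, no
  # update; trial 3: esv .55, spe -1.55
  pl <- plogis((c(0.5, 0.55, 0.55) + 0.2) / 0.3)
  ll_choice <- log(pl[1]) + log(pl[2]) + log(1 - pl[3])
  kernel <- 0.25 * 0.5 + 0.5 * (-0.55) + (-1.55)
  ll_rating <- dnorm(0.62, 0.7 + 0.04 * kernel, 0.1, log = TRUE)
  got <- joint_loglik(mrec, p, "M1")
  expect_equal(as.numeric(got), ll_choice + ll_rating, tolerance = 1e-12)
  expect_equal(attr(got, "n"), 4)

  # decomposition: total equals the sum of the two independent terms
  llf <- joint_loglik(sim$record, agent_params(), "M1")
  expect_equal(as.numeric(llf),
               attr(llf, "ll_choice") + attr(llf, "ll_rating"))
})

test_that("BIC follows ln(n) k - 2 logLik", {
  expect_equal(bic_score(0, 9, 258), 9 * log(258), tolerance = 1e-12)
  expect_equal(bic_score(-100, 0, 50), 200)
  # one extra parameter at unchanged likelihood costs ln(n)
  expect_equal(bic_score(-10, 5, 100) - bic_score(-10, 4, 100), log(100),
               tolerance = 1e-12)
  expect_error(bic_score(0, 1, 0), "n must be")
})

test_that("goodness-of-fit indices match direct computation", {
  pred <- c(0.2, 0.4, 0.6, 0.8)
  obs <- c(0.3, 0.4, 0.5, 0.9)
  rec <- hand_record(outcomes = rep("approve", 8),
                     choices = rep("liked", 8),
                     ratings_at = c(2, 4, 6, 8), ratings = obs)
  trace <- list(trials = data.frame(trial_index = 1:8, p_like = 0.5),
                probes = data.frame(probe = 1:4,
                                    trial_index = c(2, 4, 6, 8),
                                    modelable = TRUE, esteem_pred = pred))
  gof <- goodness_of_fit(rec, trace)
  expect_equal(gof$r2_esteem, cor(pred, obs) ^ 2)
  expect_equal(gof$mse_esteem, mean((obs - pred) ^ 2))
  expect_equal(gof$mse_esteem, 0.0075)

  perfect <- trace
  perfect$probes$esteem_pred <- obs
  gofp <- goodness_of_fit(rec, perfect)
  expect_equal(gofp$r2_esteem, 1)
  expect_equal(gofp$mse_esteem, 0)

  const_rec <- rec
  const_rec$probe_rating[c(2, 4, 6, 8)] <- 0.5
  expect_warning(gz <- goodness_of_fit(const_rec, trace), "zero variance")
  expect_true(is.na(gz$r2_esteem))
})

test_that("the optimiser matches a dense grid on a two-parameter problem", {
  s <- build_session(session_config(), seed = 4)
  true_p <- agent_params(w0 = 0.6, w1 = 0.05, sigma = 0.05, gamma = 0.5)
  rec <- simulate_agent(s, true_p, "M6", seed = 5)$record
  fixed <- list(gamma = 0.5, sigma = 0.05)
  fit <- fit_esteem(rec, "M6", n_restarts = 3, seed = 6, fixed = fixed)
  expect_equal(fit$k, 2)

  grid <- expand.grid(w0 = seq(0.4, 0.8, by = 0.005),
                      w1 = seq(0.0, 0.12, by = 0.002))
  grid_ll <- mapply(function(w0, w1)
    as.numeric(joint_loglik(rec, agent_params(w0 = w0, w1 = w1,
                                              sigma = 0.05, gamma = 0.5),
                            "M6")),
    grid$w0, grid$w1)
  best <- grid[which.max(grid_ll), ]
  expect_gte(fit$loglik, max(grid_ll) - 1e-6)
  # optimum within one grid step of the best grid point
  expect_lt(abs(coef(fit)["w0"] - best$w0), 0.005)
  expect_lt(abs(coef(fit)["w1"] - best$w1), 0.002)
})

test_that("constant ratings drive the valence-only model to the degenerate fit", {
  s <- build_session(session_config(), seed = 7)
  rec <- simulate_agent(s, agent_params(), "M1", seed = 8)$record
  rec$probe_rating[!is.na(rec$probe_rating)] <- 0.6
  suppressWarnings(fit <- fit_esteem(rec, "M6", n_restarts = 3, seed = 9))
  expect_equal(unname(coef(fit)["w0"]), 0.6, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["w1"]), 0, tolerance = 1e-3)
  expect_lt(fit$mse_esteem, 1e-6)
})

test_that("fitting is deterministic given record, model and seed", {
  s <- build_session(session_config(), seed = 10)
  rec <- simulate_agent(s, agent_params(), "M1", seed = 11)$record
  f1 <- fit_esteem(rec, "M2", n_restarts = 3, seed = 12)
  f2 <- fit_esteem(rec, "M2", n_restarts = 3, seed = 12)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
  expect_equal(f1$bic, bic_score(f1$loglik, f1$k, f1$n), tolerance = 1e-9)
  expect_equal(f1$n, 184 + 74)
})

test_that("richer nested models never fit worse in log-likelihood", {
  s <- build_session(session_config(), seed = 13)
  rec <- simulate_agent(s, agent_params(), "M1", seed = 14)$record
  f1 <- fit_esteem(rec, "M1", n_restarts = 6, seed = 15)
  f2 <- fit_esteem(rec, "M2", n_restarts = 6, seed = 15)
  expect_gte(f1$loglik, f2$loglik - 1e-6)
  expect_equal(f1$k, 9)
  expect_equal(f2$k, 8)
})

test_that("fit objects expose the standard modelling interface", {
  s <- build_session(session_config(), seed = 16)
  rec <- simulate_agent(s, agent_params(), "M1", seed = 17)$record
  fit <- fit_esteem(rec, "M1", n_restarts = 2, seed = 18)

  expect_s3_class(fit, "esteem_fit")
  expect_named(coef(fit), fit$free)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 9)
  expect_equal(attr(ll, "nobs"), 258)
  expect_equal(BIC(fit), fit$bic, tolerance = 1e-9)
  expect_length(predict(fit, type = "esteem"), 78)
  expect_length(predict(fit, type = "choice"), 184)
  expect_length(residuals(fit), 74)
  expect_equal(fitted(fit), predict(fit, type = "esteem"))
  sims <- simulate(fit, nsim = 2, seed = 19)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "esteem_record")
  expect_output(print(summary(fit)), "converged restarts")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
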