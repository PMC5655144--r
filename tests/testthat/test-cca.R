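make_blocks <- function(n = 60, seed = 1) {
  ch <- make_cohort(n = n, seed = seed,
                    coupling = vulnerability_coupling(1),
                    simulate_behavior = FALSE)
  cca_preprocess(ch$params[, c("w0", "w1", "sigma", "eta", "gamma", "esv0",
                               "temperature", "esv1_init", "esv4_init")],
                 ch$symptoms)
}

test_that("preprocessing substitutes, screens and z-scores as specified", {
  set.seed(31)
  n <- 60
  params <- data.frame(subject = 1:n,
                       w0 = rnorm(n, 0.7, 0.1),
                       w1 = rnorm(n, 0.05, 0.02),
                       esv1_init = rnorm(n, 0.85, 0.1),
                       esv4_init = rnorm(n, 0.15, 0.1))
  symptoms <- as.data.frame(matrix(rnorm(n * 11), n, 11))
  names(symptoms) <- symptom_spec()$scale_names

  inp <- cca_preprocess(params, symptoms)
  expect_setequal(colnames(inp$X), c("w0", "w1", "avg_init", "range_init"))
  # average/range substitution happens before z-scoring
  avg <- (params$esv1_init + params$esv4_init) / 2
  expect_equal(unname(inp$X[, "avg_init"]),
               unname(as.numeric(scale(avg))), tolerance = 1e-12)
  expect_true(all(abs(colMeans(inp$X)) < 1e-8))
  expect_true(all(abs(apply(inp$X, 2, sd) - 1) < 1e-8))
  expect_true(all(abs(colMeans(inp$Y)) < 1e-8))
  # Gaussian draws at this n should rarely trip the normality screen
  expect_lt(length(inp$log_transformed), 3)

  # a heavily skewed column is log-transformed
  skew <- params
  skew$w1 <- exp(rnorm(n, -3, 1))
  inp2 <- cca_preprocess(skew, symptoms)
  expect_true("w1" %in% inp2$log_transformed)

  const <- params
  const$w0 <- 0.7
  expect_error(cca_preprocess(const, symptoms), "zero-variance")
  expect_error(cca_preprocess(params[1:5, ], symptoms[1:5, ]), "subjects")
})

test_that("duplicated blocks give unit canonical correlations", {
  set.seed(32)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- paste0("v", 1:4)
  inp <- list(X = scale(X), Y = scale(X))
  colnames(inp$Y) <- paste0("w", 1:4)
  res <- esteem_cca(inp, orient_column = "w1")
  expect_equal(res$cor, rep(1, 4), tolerance = 1e-8)
})

test_that("canonical correlations are invariant to affine column rescaling", {
  inp <- make_blocks(n = 80, seed = 33)
  res <- esteem_cca(inp)
  set.seed(34)
  Xr <- sweep(inp$X, 2, runif(ncol(inp$X), 0.2, 5), "*")
  Xr <- sweep(Xr, 2, rnorm(ncol(inp$X)), "+")
  Yr <- sweep(inp$Y, 2, -runif(ncol(inp$Y), 0.2, 5), "*")
  res2 <- esteem_cca(list(X = scale(Xr), Y = scale(Yr)),
                     orient_column = "trait_self_esteem")
  expect_equal(res2$cor, res$cor, tolerance = 1e-8)

  # first canonical correlation dominates every single-pair correlation
  pairmax <- max(abs(cor(inp$X, inp$Y)))
  expect_gte(res$cor[1] + 1e-10, pairmax)
  expect_equal(length(res$cor), min(ncol(inp$X), ncol(inp$Y)))
  expect_true(all(diff(res$cor) <= 1e-12))
})

test_that("subject scores reduce correctly and obey the orientation rule", {
  set.seed(35)
  x <- rnorm(50)
  inp <- list(X = scale(matrix(x, dimnames = list(NULL, "p1"))),
              Y = scale(matrix(x, dimnames = list(NULL, "trait_self_esteem"))))
  res <- esteem_cca(inp)
  sc <- subject_scores(res, 1)
  expect_equal(abs(cor(sc, x)), 1, tolerance = 1e-8)
  # trait self-esteem weight is negative by convention
  expect_lt(res$y_coef["trait_self_esteem", 1], 0)
  expect_equal(sd(sc), 1, tolerance = 1e-8)

  # flipping every symptom column only flips the scores' sign, and the
  # orientation convention still pins the trait-self-esteem coefficient
  inp_flip <- list(X = inp$X, Y = -inp$Y)
  res_flip <- esteem_cca(inp_flip)
  sc_flip <- subject_scores(res_flip, 1)
  expect_equal(abs(cor(sc_flip, sc)), 1, tolerance = 1e-8)
  expect_lt(res_flip$y_coef["trait_self_esteem", 1], 0)
  expect_lt(cor(sc, x), 0)

  expect_error(subject_scores(res, 5))
})

test_that("Wilks-Rao p-values agree with a permutation test on a null", {
  set.seed(36)
  n <- 50
  X <- scale(matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("p", 1:4))))
  Y <- scale(matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("s", 1:5))))
  res <- esteem_cca(list(X = X, Y = Y), orient_column = "s1")
  stat_obs <- res$wilks$lambda[1]
  perm <- replicate(400, {
    Yp <- Y[sample.int(n), , drop = FALSE]
    cc <- cancor(X, Yp)
    prod(1 - cc$cor ^ 2)
  })
  p_perm <- mean(perm <= stat_obs)  # small lambda = strong association
  expect_lt(abs(res$wilks$p_value[1] - p_perm), 0.1)
})

test_that("a planted vulnerability factor is recovered by the CCA", {
  # wide bounds on the coupled parameters keep the closed-form planted
  # correlation exact (no truncation distortion)
  spec <- cohort_spec(n_subjects = 250, seed = 37,
                      coupling = vulnerability_coupling(1),
                      bounds = list(w0 = c(-10, 10), avg_init = c(-10, 10),
                                    range_init = c(-10, 10)))
  ch <- make_cohort(spec = spec, simulate_behavior = FALSE)
  inp <- cca_preprocess(ch$params[, c("w0", "w1", "sigma", "eta", "gamma",
                                      "esv0", "temperature", "avg_init",
                                      "range_init")],
                        ch$symptoms, alpha = 0)
  res <- esteem_cca(inp)
  rho <- planted_canonical_correlation(spec, ch$symptom_spec)
  expect_equal(res$cor[1], rho, tolerance = 0.05)
  expect_lt(res$wilks$p_value[1], 1e-6)

  sc <- subject_scores(res, 1)
  expect_gt(cor(sc, ch$vulnerability), 0.9)
  expect_lt(res$x_coef["w0", 1], 0)
  expect_gt(res$x_coef["w1", 1], 0)
  expect_lt(res$y_coef["trait_self_esteem", 1], 0)
  expect_gt(res$y_coef["depression_bdi", 1], 0)
})
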