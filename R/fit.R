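#' Joint log-likelihood of choices and self-esteem ratings
#'
#' Sums a Bernoulli term over non-missed choices (probability of predicting
#' approval from the biased softmax; omitted for ratings-only models M5/M6)
#' and a Gaussian log-density term over the modelable probe ratings
#' (untruncated density, matching the additive noise term of the generative
#' model).
#'
#' @param record An `"esteem_record"`.
#' @param params An `"esteem_params"`.
#' @param model Model id or `"esteem_model"`.
#' @return Scalar log-likelihood, with attributes `ll_choice`, `ll_rating`
#'   and `n` (likelihood observations: non-missed choices plus modelable
#'   ratings, or ratings only).
#' @export
joint_loglik <- function(record, params, model = "M1") {
  model <- model_spec(model)
  check_params(params)
  if (anyNA(record$outcome) || anyNA(record$group_id))
    stop("record contains NA in outcome or group_id")
  trace <- model_trace(record, params, model)

  ll_choice <- 0
  n_choice <- 0L
  if (model$fit_target == "choices_and_ratings") {
    kept <- record[!record$missed, , drop = FALSE]
    liked <- kept$choice == "liked"
    p <- trace$trials$p_like
    ll_choice <- sum(ifelse(liked, log(p), log1p(-p)))
    n_choice <- length(p)
  }

  probes <- trace$probes
  obs <- record$probe_rating[probes$trial_index]
  use <- probes$modelable & !is.na(obs)
  ll_rating <- sum(stats::dnorm(obs[use], probes$esteem_pred[use],
                                params$sigma, log = TRUE))
  n_rating <- sum(use)

  structure(ll_choice + ll_rating, ll_choice = ll_choice,
            ll_rating = ll_rating, n = n_choice + n_rating)
}

#' Bayesian Information Criterion
#'
#' \eqn{BIC = \ln(n) k - 2 \ln(\hat L)} (natural logarithm). Lower values
#' indicate a more parsimonious fit.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of fitted parameters.
#' @param n Number of likelihood observations.
#' @return Scalar BIC.
#' @examples
#' bic_score(0, 9, 258)
#' @export
bic_score <- function(loglik, k, n) {
  stopifnot(k >= 0)
  if (n < 1) stop("n must be >= 1")
  log(n) * k - 2 * loglik
}

#' Goodness-of-fit indices for a fitted trace
#'
#' @param record An `"esteem_record"`.
#' @param trace An `"esteem_trace"` computed under the parameters being
#'   assessed.
#' @return A list with `r2_esteem` (squared Pearson correlation between
#'   predicted and observed ratings over modelable probes), `r2_choice`
#'   (squared correlation between choice probabilities and the binary
#'   choices; `NA` for ratings-only models), and `mse_esteem`. Zero variance
#'   in the observations yields `NA` with a warning.
#' @export
goodness_of_fit <- function(record, trace) {
  probes <- trace$probes
  obs <- record$probe_rating[probes$trial_index]
  use <- probes$modelable & !is.na(obs)
  pred <- probes$esteem_pred[use]
  obs <- obs[use]
  mse <- mean((obs - pred) ^ 2)
  r2_esteem <- safe_r2(pred, obs, "ratings")

  r2_choice <- NA_real_
  kept <- record[!record$missed, , drop = FALSE]
  if (length(unique(trace$trials$p_like)) > 1 ||
      trace$trials$p_like[1] != 0.5) {
    liked <- as.numeric(kept$choice == "liked")
    r2_choice <- safe_r2(trace$trials$p_like, liked, "choices")
  }
  list(r2_esteem = r2_esteem, r2_choice = r2_choice, mse_esteem = mse)
}

safe_r2 <- function(pred, obs, what) {
  if (length(obs) < 2 || stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("zero variance in ", what, "; r-squared undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs) ^ 2
}

# --- parameter transforms: unconstrained optimisation space <-> natural ----

# eta, gamma through logit; sigma, temperature through log (with a small
# floor to keep the Gaussian density finite); remaining parameters free.
par_to_theta <- function(params, free) {
  vapply(free, function(nm) {
    v <- params[[nm]]
    switch(nm,
      eta = , gamma = stats::qlogis(min(max(v, 1e-6), 1 - 1e-6)),
      sigma = , temperature = log(max(v - 1e-6, 1e-8)),
      v)
  }, numeric(1))
}

theta_to_par <- function(theta, free, base) {
  p <- base
  theta <- unname(theta)
  for (i in seq_along(free)) {
    nm <- free[i]
    p[[nm]] <- switch(nm,
      eta = , gamma = stats::plogis(theta[i]),
      sigma = , temperature = 1e-6 + exp(theta[i]),
      theta[i])
  }
  p
}

# --- fast likelihood path used inside the optimiser --------------------------
# Precomputes every schedule-dependent index once per record so the inner
# objective is pure numeric work; agreement with joint_loglik() is asserted
# in the test suite and the final reported loglik is recomputed through
# joint_loglik().

make_fit_context <- function(record, model) {
  sched <- as_schedule(record)
  missed <- if ("missed" %in% names(sched)) as.logical(sched$missed)
            else rep(FALSE, nrow(sched))
  probes_all <- which(sched$probe_after)
  keep <- !missed
  tr <- sched[keep, , drop = FALSE]
  n <- nrow(tr)
  K <- max(sched$group_id)
  sf <- sf_code(tr$outcome)
  grp_idx <- lapply(seq_len(K), function(k) which(tr$group_id == k))
  upd_idx <- lapply(seq_len(K), function(k) {
    idx <- grp_idx[[k]]
    idx[tr$outcome[idx] != "none"]
  })
  n_before <- lapply(seq_len(K), function(k)
    findInterval(grp_idx[[k]] - 1L, upd_idx[[k]]))
  state_at <- findInterval(probes_all, tr$trial_index)
  obs <- record$probe_rating[probes_all]
  use <- sched$probe_modelable[probes_all] & !is.na(obs)
  kept_rec <- record[keep, , drop = FALSE]
  probs <- attr(sched, "approval_probs")
  list(n = n, K = K, sf = sf, grp_idx = grp_idx, upd_idx = upd_idx,
       n_before = n_before, state_at = state_at[use], obs = obs[use],
       liked = kept_rec$choice == "liked",
       approval_probs = if (is.null(probs)) rep(NA_real_, K) else probs)
}

ctx_loglik <- function(ctx, p, model) {
  init <- model_initial_esvs(p, model, ctx$approval_probs)
  eta <- if (model$learns) p$eta else 0
  esv <- numeric(ctx$n)
  for (k in seq_len(ctx$K)) {
    idx <- ctx$grp_idx[[k]]
    if (!length(idx)) next
    upd <- ctx$upd_idx[[k]]
    if (eta > 0 && length(upd)) {
      post <- stats::filter(eta * ctx$sf[upd], 1 - eta,
                            method = "recursive", init = init[k])
      esv[idx] <- c(init[k], post)[ctx$n_before[[k]] + 1L]
    } else {
      esv[idx] <- init[k]
    }
  }
  spe <- ctx$sf - esv
  kin <- if (model$valence_only) ctx$sf else spe
  ks <- stats::filter(kin, p$gamma, method = "recursive")
  pred <- p$w0 + p$w1 * ks[ctx$state_at]
  if (model$has_expectation_term) {
    ke <- stats::filter(esv, p$gamma, method = "recursive")
    pred <- pred + p$w2 * ke[ctx$state_at]
  }
  ll <- sum(stats::dnorm(ctx$obs, pred, p$sigma, log = TRUE))
  if (model$fit_target == "choices_and_ratings") {
    bias <- if (model$has_bias) p$esv0 else 0
    pl <- stats::plogis((esv + bias) / p$temperature)
    ll <- ll + sum(ifelse(ctx$liked, log(pl), log1p(-pl)))
  }
  ll
}

# Fixed values taken by parameters a model does not fit.
base_params <- function(model) {
  p <- agent_params()
  if (!model$learns) p$eta <- 0
  if (!model$has_bias) p$esv0 <- 0
  p$w2 <- if (model$has_expectation_term) 0.02 else NULL
  p
}

# Seeded draw of one natural-scale starting point within plausible ranges.
draw_start <- function(free) {
  ranges <- list(w0 = c(0.3, 0.9), w1 = c(0.005, 0.12), w2 = c(-0.05, 0.05),
                 sigma = c(0.03, 0.25), eta = c(0.01, 0.4),
                 esv0 = c(-0.3, 1), temperature = c(0.05, 0.6),
                 esv1_init = c(0.1, 0.95), esv4_init = c(-0.9, 0.6),
                 gamma = c(0.1, 0.95))
  vals <- lapply(free, function(nm) stats::runif(1, ranges[[nm]][1],
                                                 ranges[[nm]][2]))
  names(vals) <- free
  vals
}

#' Fit a self-esteem model to one subject's record
#'
#' Maximum-likelihood fitting (flat priors) of the joint choice + rating
#' likelihood (ratings only for M5/M6), by multi-start quasi-Newton
#' optimisation on transformed parameters: logit for `eta` and `gamma`, log
#' for `sigma` and `temperature`, untransformed otherwise. Restarts are
#' drawn from seeded uniform ranges; the best log-likelihood wins and a
#' warning flags disagreement between converged restarts larger than 1e-3.
#'
#' @param record An `"esteem_record"` (see [simulate_agent()],
#'   [read_behavior()]).
#' @param model Model id `"M1"`..`"M6"` or an `"esteem_model"`.
#' @param n_restarts Number of optimisation restarts.
#' @param seed Integer seed controlling the restart draws; fitting is
#'   deterministic given `(record, model, n_restarts, seed)`.
#' @param fixed Named list of parameters to hold fixed at given values
#'   (they are removed from the free set and from `k`).
#' @param control Passed to [stats::optim()] (`method = "BFGS"`); defaults
#'   to `list(maxit = 500, reltol = 1e-8)`.
#' @return An object of class `"esteem_fit"` with components `params`,
#'   `model`, `loglik`, `k`, `n`, `bic`, `r2_esteem`, `r2_choice`,
#'   `mse_esteem`, `trace`, `record`, `n_restarts_converged`,
#'   `restart_logliks`.
#' @seealso [compare_models()], [joint_loglik()], [bic_score()]
#' @export
fit_esteem <- function(record, model = "M1", n_restarts = 10, seed = 1L,
                       fixed = list(), control = list()) {
  model <- model_spec(model)
  stopifnot(inherits(record, "esteem_record") || is.data.frame(record))
  if (!any(!is.na(record$probe_rating)))
    stop("record has no probe ratings to fit")
  if (model$fit_target == "choices_and_ratings" && all(record$missed))
    stop("record has no non-missed choices to fit")
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-8), control)

  free <- setdiff(model$free, names(fixed))
  base <- base_params(model)
  for (nm in names(fixed)) base[[nm]] <- fixed[[nm]]

  ctx <- make_fit_context(record, model)
  negll <- function(theta) {
    p <- theta_to_par(theta, free, base)
    ll <- tryCatch(ctx_loglik(ctx, p, model), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  set.seed(as.integer(seed))
  best <- NULL
  lls <- rep(NA_real_, n_restarts)
  conv <- 0L
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1L) base[free] else draw_start(free)
    theta0 <- par_to_theta(start, free)
    opt <- tryCatch(stats::optim(theta0, negll, method = "BFGS",
                                 control = control),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$convergence == 0) conv <- conv + 1L
    lls[r] <- -opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimisation failed in all ", n_restarts, " restarts")
  if (sum(!is.na(lls)) > 1 &&
      diff(range(lls, na.rm = TRUE)) > 1e-3 &&
      stats::sd(lls, na.rm = TRUE) > 0) {
    top2 <- sort(lls, decreasing = TRUE)[1:2]
    if (top2[1] - top2[2] > 1e-3)
      warning("restarts disagree by more than 1e-3 in log-likelihood; ",
              "the objective may be multimodal")
  }

  params <- theta_to_par(best$par, free, base)
  class(params) <- "esteem_params"
  ll <- joint_loglik(record, params, model)
  trace <- model_trace(record, params, model)
  gof <- goodness_of_fit(record, trace)
  n_obs <- attr(ll, "n")
  structure(list(
    params = params, model = model, free = free,
    loglik = as.numeric(ll), ll_choice = attr(ll, "ll_choice"),
    ll_rating = attr(ll, "ll_rating"),
    k = length(free), n = n_obs,
    bic = bic_score(as.numeric(ll), length(free), n_obs),
    r2_esteem = gof$r2_esteem, r2_choice = gof$r2_choice,
    mse_esteem = gof$mse_esteem,
    trace = trace, record = record,
    n_restarts_converged = conv, restart_logliks = lls,
    seed = as.integer(seed)
  ), class = "esteem_fit")
}

#' @export
print.esteem_fit <- function(x, digits = 3, ...) {
  cat("Self-esteem model fit (", x$model$model_id, ")\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = digits + 2), " on k = ", x$k,
      " parameters, n = ", x$n, " observations; BIC ",
      format(x$bic, digits = digits + 2), "\n", sep = "")
  cat("  r2 ratings ", format(x$r2_esteem, digits = digits),
      if (!is.na(x$r2_choice))
        paste0(", r2 choices ", format(x$r2_choice, digits = digits)),
      ", mse ", format(x$mse_esteem, digits = digits), "\n", sep = "")
  cat("  parameters:\n")
  print(round(unlist(coef(x)), digits))
  invisible(x)
}

#' @export
coef.esteem_fit <- function(object, ...) {
  p <- object$params[object$free]
  stats::setNames(as.numeric(unlist(p)), names(p))
}

#' @export
logLik.esteem_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
summary.esteem_fit <- function(object, ...) {
  out <- list(fit = object,
              coef = coef(object),
              restart_spread = diff(range(object$restart_logliks,
                                          na.rm = TRUE)))
  class(out) <- "summary.esteem_fit"
  out
}

#' @export
print.summary.esteem_fit <- function(x, ...) {
  print(x$fit)
  cat("  converged restarts: ", x$fit$n_restarts_converged, "/",
      length(x$fit$restart_logliks), "; log-likelihood spread ",
      format(x$restart_spread, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
predict.esteem_fit <- function(object, newdata = NULL,
                               type = c("esteem", "choice"), ...) {
  type <- match.arg(type)
  record <- if (is.null(newdata)) object$record else newdata
  trace <- if (is.null(newdata)) object$trace
           else model_trace(record, object$params, object$model)
  if (type == "esteem") trace$probes$esteem_pred else trace$trials$p_like
}

#' @export
fitted.esteem_fit <- function(object, ...) {
  object$trace$probes$esteem_pred
}

#' @export
residuals.esteem_fit <- function(object, ...) {
  probes <- object$trace$probes
  obs <- object$record$probe_rating[probes$trial_index]
  res <- obs - probes$esteem_pred
  res[probes$modelable & !is.na(obs)]
}

#' @export
simulate.esteem_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  session <- record_as_session(object$record)
  lapply(seq_len(nsim), function(i)
    simulate_agent(session, object$params, object$model,
                   seed = derive_seed(seed, i))$record)
}

# Rebuild a minimal session wrapper from a record so that simulate() can
# replay the schedule.
record_as_session <- function(record) {
  probs <- attr(record, "approval_probs")
  if (is.null(probs)) probs <- sort(unique(record$group_id), decreasing = TRUE)
  cfg <- session_config()
  cfg$approval_probs <- probs
  cfg$n_groups <- length(probs)
  tr <- data.frame(trial_index = record$trial_index,
                   block = if ("block" %in% names(record)) record$block else 1L,
                   rater_id = sprintf("rater_%03d", record$trial_index),
                   rater_sex = "unknown",
                   group_id = record$group_id,
                   color = as.character(record$group_id),
                   scheduled_outcome = record$outcome,
                   probe_after = record$probe_after,
                   probe_modelable = record$probe_modelable,
                   stringsAsFactors = FALSE)
  structure(list(trials = tr,
                 probe_positions = tr$trial_index[tr$probe_after],
                 config = cfg, seed = NA_integer_),
            class = "esteem_session")
}

#' @export
plot.esteem_fit <- function(x, ...) {
  probes <- x$trace$probes
  obs <- x$record$probe_rating[probes$trial_index]
  graphics::plot(probes$trial_index, obs, type = "p", pch = 16,
                 col = "steelblue", ylim = c(0, 1),
                 xlab = "trial", ylab = "self-esteem",
                 main = paste("Observed and model-predicted self-esteem,",
                              x$model$model_id), ...)
  graphics::lines(probes$trial_index, probes$esteem_pred, col = "firebrick",
                  lwd = 2)
  graphics::legend("bottomleft", legend = c("observed", "model"),
                   col = c("steelblue", "firebrick"), pch = c(16, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Fit several models across a cohort and tabulate BIC
#'
#' Each model is fitted to every record; per-model BICs are summed across
#' subjects and reported with mean/median rating r-squared and the BIC
#' difference against the first listed model. Joint-likelihood models
#' (M1-M4) and ratings-only models (M5, M6) use different observation
#' counts, so they are typically compared within their own sub-family.
#'
#' @param records List of `"esteem_record"` objects.
#' @param models Character vector of model ids.
#' @param n_restarts,seed,control Passed to [fit_esteem()]; each subject x
#'   model fit gets a deterministic sub-seed.
#' @return A data frame of class `"esteem_model_comparison"` with one row
#'   per model: `model`, `fit_target`, `k`, `n_subjects`, `n_failed`,
#'   `mean_r2`, `median_r2`, `sum_bic`, `delta_bic`. The per-subject fits
#'   are attached as attribute `"fits"`.
#' @export
compare_models <- function(records, models = c("M1", "M2", "M3", "M4"),
                           n_restarts = 10, seed = 1L, control = list()) {
  stopifnot(length(records) >= 1)
  rows <- list()
  all_fits <- list()
  for (m in models) {
    spec <- model_spec(m)
    fits <- vector("list", length(records))
    for (i in seq_along(records)) {
      fits[[i]] <- tryCatch(
        fit_esteem(records[[i]], spec, n_restarts = n_restarts,
                   seed = derive_seed(seed, i * 131L + match(m, models)),
                   control = control),
        error = function(e) {
          warning("fit of ", m, " failed for subject ", i, ": ",
                  conditionMessage(e))
          NULL
        })
    }
    ok <- !vapply(fits, is.null, logical(1))
    r2 <- vapply(fits[ok], function(f) f$r2_esteem, numeric(1))
    rows[[m]] <- data.frame(
      model = m, fit_target = spec$fit_target, k = spec$k,
      n_subjects = sum(ok), n_failed = sum(!ok),
      mean_r2 = mean(r2, na.rm = TRUE),
      median_r2 = stats::median(r2, na.rm = TRUE),
      sum_bic = sum(vapply(fits[ok], function(f) f$bic, numeric(1))),
      stringsAsFactors = FALSE)
    all_fits[[m]] <- fits
  }
  tab <- do.call(rbind, rows)
  tab$delta_bic <- tab$sum_bic - tab$sum_bic[1]
  rownames(tab) <- NULL
  structure(tab, class = c("esteem_model_comparison", "data.frame"),
            fits = all_fits)
}

#' @export
print.esteem_model_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison (summed BIC across", x$n_subjects[1], "subjects;",
      "delta vs", x$model[1], ")\n")
  df <- as.data.frame(x)
  df$mean_r2 <- round(df$mean_r2, digits)
  df$median_r2 <- round(df$median_r2, digits)
  df$sum_bic <- round(df$sum_bic, 1)
  df$delta_bic <- round(df$delta_bic, 1)
  print(df, row.names = FALSE)
  invisible(x)
}

# Deterministic 32-bit sub-seed derivation.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}
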