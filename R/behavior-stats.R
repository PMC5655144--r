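#' Self-esteem change by rater group and feedback valence
#'
#' Model-free summary: the change between consecutive probe ratings is
#' attributed to the feedback received in between — by default to the most
#' recent feedback trial before the later probe (`attribution = "last"`),
#' optionally to every intervening feedback trial (`"all"`). Cell means are
#' formed within subject and then averaged across subjects.
#'
#' @param records List of `"esteem_record"` objects.
#' @param attribution `"last"` (single-feedback attribution) or `"all"`.
#' @return A list of class `"esteem_change_summary"`: `cells` (data frame
#'   with `group_id`, `valence`, `mean_change`, `sem`, `n_subjects`),
#'   `transitions` (pooled trial-level table), and per-group predicted-liked
#'   rates.
#' @export
esteem_change_by_condition <- function(records,
                                       attribution = c("last", "all")) {
  attribution <- match.arg(attribution)
  per_subject <- list()
  pooled <- list()
  liked_rates <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    tab <- probe_transitions(rec, attribution)
    if (is.null(tab)) {
      warning("record ", i, " has fewer than 2 ratings; skipped")
      next
    }
    tab$subject <- i
    pooled[[length(pooled) + 1L]] <- tab
    agg <- stats::aggregate(change ~ group_id + valence, tab, mean)
    agg$subject <- i
    per_subject[[length(per_subject) + 1L]] <- agg
    kept <- rec[!rec$missed, , drop = FALSE]
    liked_rates[[length(liked_rates) + 1L]] <-
      tapply(kept$choice == "liked", kept$group_id, mean)
  }
  if (!length(per_subject)) stop("no usable records")
  subj <- do.call(rbind, per_subject)
  cells <- stats::aggregate(change ~ group_id + valence, subj,
                            function(v) c(mean = mean(v),
                                          sem = stats::sd(v) / sqrt(length(v)),
                                          n = length(v)))
  cells <- data.frame(group_id = cells$group_id, valence = cells$valence,
                      mean_change = cells$change[, "mean"],
                      sem = cells$change[, "sem"],
                      n_subjects = cells$change[, "n"])
  structure(list(cells = cells,
                 transitions = do.call(rbind, pooled),
                 liked_rates = Reduce(`+`, liked_rates) / length(liked_rates)),
            class = "esteem_change_summary")
}

# Trial-level table of probe-to-probe changes: one row per (transition,
# attributed feedback trial), carrying the feedback valence and, when a
# trace column is present, the pre-outcome expectation.
probe_transitions <- function(record, attribution = "last", esv = NULL) {
  probe_ix <- which(record$probe_after & !is.na(record$probe_rating))
  if (length(probe_ix) < 2) return(NULL)
  ratings <- record$probe_rating[probe_ix]
  rows <- list()
  for (p in 2:length(probe_ix)) {
    window <- (probe_ix[p - 1] + 1L):probe_ix[p]
    fb <- window[record$outcome[window] != "none" & !record$missed[window]]
    if (!length(fb)) next
    use <- if (attribution == "last") fb[length(fb)] else fb
    rows[[length(rows) + 1L]] <- data.frame(
      trial_index = use,
      group_id = record$group_id[use],
      valence = ifelse(record$outcome[use] == "approve", "approve",
                       "disapprove"),
      sf = sf_code(record$outcome[use]),
      change = ratings[p] - ratings[p - 1],
      esv = if (is.null(esv)) NA_real_ else esv[use])
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.esteem_change_summary <- function(x, digits = 3, ...) {
  cat("Self-esteem change by group x valence (subject means +/- SEM)\n")
  df <- x$cells
  df$mean_change <- round(df$mean_change, digits)
  df$sem <- round(df$sem, digits)
  print(df, row.names = FALSE)
  cat("Predicted-liked rate by group:",
      paste(round(x$liked_rates, 2), collapse = ", "), "\n")
  invisible(x)
}

#' Valence and valence-partialled expectation correlations
#'
#' Pools probe-to-probe self-esteem changes over subjects, correlates them
#' with the valence of the attributed feedback, then residualises the
#' changes on valence by least squares and correlates the residuals with
#' the pre-outcome expectation (ESV) of the attributed trial. A positive
#' valence correlation together with a negative partialled expectation
#' correlation is the signature of prediction-error (rather than pure
#' valence) updating.
#'
#' @param records List of `"esteem_record"` objects.
#' @param traces List of matching `"esteem_trace"` objects supplying the
#'   trial-by-trial expectations.
#' @param pooling `"trials"` pools all subjects' transitions into one
#'   correlation (default); `"subjects"` computes per-subject correlations
#'   and reports their means.
#' @return A list of class `"esteem_valence_corr"` with `r_valence`,
#'   `p_valence`, `r_expectation_partial`, `p_expectation_partial`,
#'   `n_transitions`, and the pooled `table`.
#' @export
valence_partial_correlation <- function(records, traces,
                                        pooling = c("trials", "subjects")) {
  pooling <- match.arg(pooling)
  stopifnot(length(records) == length(traces))
  tabs <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    tt <- traces[[i]]$trials
    esv <- rep(NA_real_, max(rec$trial_index))
    esv[tt$trial_index] <- tt$esv
    tab <- probe_transitions(rec, "last", esv = esv)
    if (is.null(tab)) next
    tab$subject <- i
    tabs[[length(tabs) + 1L]] <- tab
  }
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || nrow(tab) < 3) stop("fewer than 3 usable transitions")

  corr_pair <- function(d) {
    r_v <- stats::cor(d$change, d$sf)
    resid <- stats::residuals(stats::lm(change ~ sf, data = d))
    r_e <- stats::cor(resid, d$esv)
    c(r_v, r_e, nrow(d))
  }
  if (pooling == "trials") {
    est <- corr_pair(tab)
  } else {
    per <- t(vapply(split(tab, tab$subject), corr_pair, numeric(3)))
    est <- c(colMeans(per[, 1:2, drop = FALSE], na.rm = TRUE), nrow(tab))
  }
  n <- nrow(tab)
  structure(list(r_valence = est[1],
                 p_valence = cor_pvalue(est[1], n),
                 r_expectation_partial = est[2],
                 p_expectation_partial = cor_pvalue(est[2], n),
                 n_transitions = n, pooling = pooling, table = tab),
            class = "esteem_valence_corr")
}

# Two-sided p-value for a correlation via the t transform.
cor_pvalue <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  tstat <- r * sqrt((n - 2) / (1 - r ^ 2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' @export
print.esteem_valence_corr <- function(x, digits = 3, ...) {
  cat("Probe-to-probe self-esteem change correlations (",
      x$n_transitions, " transitions, pooling = ", x$pooling, ")\n",
      sep = "")
  cat("  valence:              r = ", round(x$r_valence, digits),
      ", p = ", format.pval(x$p_valence, digits = 2), "\n", sep = "")
  cat("  expectation (partial): r = ", round(x$r_expectation_partial, digits),
      ", p = ", format.pval(x$p_expectation_partial, digits = 2), "\n",
      sep = "")
  invisible(x)
}
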