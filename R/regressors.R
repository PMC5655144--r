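#' Export trial-by-trial model quantities as event regressors
#'
#' Builds the event-table parametric modulators used in event-related GLMs.
#' `glm1` emits the expectation (`ESV`) at choice onset on every non-missed
#' trial, the prediction error (`SPE`) at feedback onset on revealed-feedback
#' trials, and the observed rating at probe onset. `glm2` emits the model's
#' inferred self-esteem at choice onset (pre-feedback kernel state) and at
#' feedback onset (post-feedback state) plus the observed rating at probe
#' onset. Every modulator column is z-scored within the session; a constant
#' modulator cannot be z-scored and is dropped with a warning. Onsets are
#' trial indices; multiply by your timing map for seconds.
#'
#' @param trace An `"esteem_trace"`.
#' @param record The matching `"esteem_record"`.
#' @param which `"glm1"` or `"glm2"`.
#' @return Data frame of class `"esteem_event_table"` with columns `onset`,
#'   `event_type` (`choice`, `feedback`, `probe`), `modulator`, `value`.
#' @export
export_event_regressors <- function(trace, record, which = c("glm1", "glm2")) {
  which <- match.arg(which)
  tt <- trace$trials
  if (!all(tt$trial_index %in% record$trial_index))
    stop("trace and record are not aligned")
  fb <- tt$sf != 0
  probes <- trace$probes
  obs <- record$probe_rating[probes$trial_index]
  keep_probe <- !is.na(obs)

  if (which == "glm1") {
    blocks <- list(
      list(onset = tt$trial_index, type = "choice", name = "ESV",
           value = tt$esv),
      list(onset = tt$trial_index[fb], type = "feedback", name = "SPE",
           value = tt$spe[fb]),
      list(onset = probes$trial_index[keep_probe], type = "probe",
           name = "rating", value = obs[keep_probe]))
  } else {
    p <- trace$params
    pre <- p$w0 + p$w1 * p$gamma * c(0, tt$kernel_spe[-nrow(tt)])
    post <- p$w0 + p$w1 * tt$kernel_spe
    if (!is.na(tt$kernel_esv[1])) {
      pre <- pre + p$w2 * p$gamma * c(0, tt$kernel_esv[-nrow(tt)])
      post <- post + p$w2 * tt$kernel_esv
    }
    blocks <- list(
      list(onset = tt$trial_index, type = "choice",
           name = "inferred_self_esteem_choice", value = pre),
      list(onset = tt$trial_index[fb], type = "feedback",
           name = "inferred_self_esteem_feedback", value = post[fb]),
      list(onset = probes$trial_index[keep_probe], type = "probe",
           name = "rating", value = obs[keep_probe]))
  }

  rows <- lapply(blocks, function(b) {
    if (!length(b$value)) return(NULL)
    if (stats::sd(b$value) == 0) {
      warning("modulator ", b$name, " at ", b$type,
              " onsets is constant; dropped (cannot be z-scored)")
      return(NULL)
    }
    data.frame(onset = b$onset, event_type = b$type, modulator = b$name,
               value = as.numeric(scale(b$value)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("esteem_event_table", "data.frame"))
}

#' Write an event table as BIDS-events-style TSV
#'
#' @param events An `"esteem_event_table"`.
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
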