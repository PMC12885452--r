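#' Build the lagged analysis table
#'
#' One row per participant per consecutive wave pair (t, t+1) in which the
#' outcome at t+1, the mediator at t and the outcome at t are all observed.
#' Carries the treatment indicator at the predicted wave (t+1) and the wave
#' index; construction is idempotent and invariant to the input row order.
#'
#' @param panel Long panel data.frame.
#' @param mediator Mediator column name.
#' @param outcome Outcome column name.
#' @return data.frame with columns `participant_id`, `cluster`, `sequence`,
#'   `wave` (= t+1), `treatment` (at t+1), `mediator_prev`, `outcome_prev`,
#'   `outcome_next`; empty if no complete pairs exist.
#' @export
build_lagged_rows <- function(panel, mediator, outcome) {
  for (col in c(mediator, outcome))
    if (!col %in% names(panel))
      stop(sprintf("column `%s` not found in panel", col), call. = FALSE)
  p <- panel[order(panel$participant_id, panel$wave), , drop = FALSE]
  cur <- p[, c("participant_id", "cluster", "sequence", "wave", "treatment",
               mediator, outcome)]
  names(cur)[6:7] <- c("mediator_prev", "outcome_prev")
  nxt <- p[, c("participant_id", "wave", "treatment", outcome)]
  names(nxt) <- c("participant_id", "wave_next", "treatment_next",
                  "outcome_next")
  nxt$wave <- nxt$wave_next - 1L
  lag <- merge(cur, nxt, by = c("participant_id", "wave"))
  lag <- lag[stats::complete.cases(
    lag[, c("mediator_prev", "outcome_prev", "outcome_next")]), , drop = FALSE]
  lag <- lag[order(lag$participant_id, lag$wave), , drop = FALSE]
  out <- data.frame(
    participant_id = lag$participant_id, cluster = lag$cluster,
    sequence = lag$sequence, wave = lag$wave_next,
    treatment = lag$treatment_next, mediator_prev = lag$mediator_prev,
    outcome_prev = lag$outcome_prev, outcome_next = lag$outcome_next,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Time-lagged mediator model
#'
#' Predicts the outcome at wave t+1 from the mediator at wave t, controlling
#' for the prior outcome, treatment and time, with random intercepts for
#' participant and cluster:
#' `outcome_next ~ mediator_prev + outcome_prev + treatment + wave`.
#' A negative coefficient means that a higher mediator value at one
#' assessment precedes a lower outcome at the next.
#'
#' @param panel Long panel data.frame.
#' @param mediator,outcome Column names.
#' @param random_effects Grouping columns (default participant and cluster).
#' @param treatment_at Use treatment at the predicted wave (`"next"`, the
#'   default) or at the prior wave (`"prev"`).
#' @param wave_as Enter the wave index as a `"linear"` fixed term (default)
#'   or as a `"factor"`.
#' @return An object of class `lagged_result`: `coefficient` (the
#'   mediator_prev effect), `se`, `ci` (Wald 95%), `p`, `n_lagged_rows`, and
#'   the underlying `fit` ([fit_lmm()] result).
#' @export
fit_lagged <- function(panel, mediator, outcome,
                       random_effects = c("participant_id", "cluster"),
                       treatment_at = c("next", "prev"),
                       wave_as = c("linear", "factor")) {
  treatment_at <- match.arg(treatment_at)
  wave_as <- match.arg(wave_as)
  lag <- build_lagged_rows(panel, mediator, outcome)
  if (!nrow(lag)) stop("no complete lagged pairs in panel", call. = FALSE)
  if (treatment_at == "prev") {
    prev_trt <- panel$treatment[match(
      paste(lag$participant_id, lag$wave - 1L),
      paste(panel$participant_id, panel$wave))]
    lag$treatment <- prev_trt
  }
  if (wave_as == "factor") lag$wave <- factor(lag$wave)
  fit <- fit_lmm(lag, "outcome_next",
                 c("mediator_prev", "outcome_prev", "treatment", "wave"),
                 random_effects = random_effects)
  est <- fit$coef[["mediator_prev"]]
  se <- fit$se[["mediator_prev"]]
  structure(list(
    mediator = mediator, outcome = outcome,
    coefficient = est, se = se,
    ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
    p = fit$p[["mediator_prev"]],
    n_lagged_rows = nrow(lag), fit = fit), class = "lagged_result")
}

#' @export
print.lagged_result <- function(x, ...) {
  cat(render_results(x, format = "text"), sep = "\n")
  invisible(x)
}
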