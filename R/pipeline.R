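#' Run the full mediation pipeline on a panel
#'
#' Ties the stages together: baseline table, univariate bootstrap mediation
#' for each requested mediator, the multivariate model with all mediators,
#' the two sensitivity models, and lagged models for selected mediators.
#' Every stage logs the sample sizes, seed and convergence bookkeeping; when
#' `out_dir` is given, JSON and CSV renderings plus a plain-text log are
#' written there.
#'
#' @param panel Long panel data.frame (e.g. from [generate_trial()] or
#'   [read_panel()]).
#' @param outcome Outcome column.
#' @param mediators Mediator columns (default: all nine).
#' @param lagged_mediators Mediators to fit lagged models for (default: the
#'   resilience and observing scores, the mechanisms with the most consistent
#'   concurrent associations).
#' @param n_boot,seed,workers Passed to the bootstrap stages.
#' @param out_dir Optional output directory.
#' @return List with `baseline`, `univariate` (named list), `multivariate`,
#'   `sensitivity`, `lagged` (named list), and `log` (character lines).
#' @export
run_pipeline <- function(panel, outcome = "pss",
                         mediators = mediator_columns(),
                         lagged_mediators = c("cd_risc", "ffmq_observe"),
                         n_boot = 1000, seed = 1L, workers = 1L,
                         out_dir = NULL) {
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
  }
  say("pipeline: outcome %s, %d mediators, n_boot %d, seed %d",
      outcome, length(mediators), n_boot, seed)

  panel <- attach_baseline(panel, outcome)
  say("baseline attached: %d rows, %d excluded participants",
      nrow(panel), attr(panel, "n_excluded"))

  baseline <- baseline_table(panel)
  say("baseline table: %d variables", nrow(baseline))

  univariate <- list()
  for (m in mediators) {
    res <- bootstrap_mediation(panel, model_spec(outcome, m),
                               n_boot = n_boot, seed = seed, workers = workers)
    univariate[[m]] <- res
    say("univariate %s: indirect %.3f [%.3f, %.3f], p %s, %d/%d draws",
        m, res$indirect$estimate, res$indirect$ci[1], res$indirect$ci[2],
        format_p(res$indirect$p, res$n_boot_used),
        res$n_boot_used, res$n_boot_requested)
  }

  multivariate <- NULL
  if (length(mediators) >= 2L) {
    multivariate <- multivariate_mediation(panel, mediators, outcome,
                                           n_boot = n_boot, seed = seed,
                                           workers = workers)
    say("multivariate: %d mediators, %d/%d draws", length(mediators),
        multivariate$n_boot_used, multivariate$n_boot_requested)
  }

  fam <- default_family_map()[mediators]
  sensitivity <- sensitivity_models(panel, univariate, outcome,
                                    family_map = fam, n_boot = n_boot,
                                    seed = seed, workers = workers)
  say("sensitivity: S1 = {%s}; S2 = {%s}",
      paste(sensitivity$s1_mediators, collapse = ", "),
      paste(sensitivity$s2_mediators, collapse = ", "))

  lagged <- list()
  for (m in intersect(lagged_mediators, mediators)) {
    lr <- fit_lagged(panel, m, outcome)
    lagged[[m]] <- lr
    say("lagged %s: coefficient %.3f, p %s, %d rows", m, lr$coefficient,
        format_p(lr$p), lr$n_lagged_rows)
  }

  out <- list(baseline = baseline, univariate = univariate,
              multivariate = multivariate, sensitivity = sensitivity,
              lagged = lagged, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$baseline),
                   file.path(out_dir, "baseline_table.csv"), row.names = FALSE)
  uni <- do.call(rbind, lapply(res$univariate, result_rows))
  utils::write.csv(uni, file.path(out_dir, "univariate.csv"),
                   row.names = FALSE)
  writeLines(vapply(res$univariate,
                    function(r) as.character(render_results(r, "json")),
                    character(1)),
             file.path(out_dir, "univariate.json"))
  if (!is.null(res$multivariate)) {
    utils::write.csv(result_rows(res$multivariate),
                     file.path(out_dir, "multivariate.csv"), row.names = FALSE)
    writeLines(as.character(render_results(res$multivariate, "json")),
               file.path(out_dir, "multivariate.json"))
  }
  if (length(res$lagged)) {
    lag <- do.call(rbind, lapply(res$lagged,
                                 function(r) render_results(r, "csv")))
    utils::write.csv(lag, file.path(out_dir, "lagged.csv"), row.names = FALSE)
  }
  writeLines(res$log, file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
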