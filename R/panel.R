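#' Read / write a long trial panel as CSV
#'
#' Missing score cells are encoded as empty fields; `read_panel` validates the
#' mandatory design and covariate columns, checks that `(participant_id,
#' wave)` is unique, and that every present score column parses as numeric.
#' Extra columns are preserved. `write_panel(read_panel(path))` round-trips
#' exactly, including missingness.
#'
#' @param path CSV file path.
#' @param panel Long panel data.frame.
#' @return `read_panel`: the validated data.frame. `write_panel`: `path`,
#'   invisibly.
#' @export
read_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  mandatory <- c(design_columns(), covariate_columns())
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("panel integrity error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- intersect(
    c("cluster", "sequence", "wave", "time_weeks", "treatment", "age",
      "trainee", score_columns()), names(raw))
  for (col in numeric_cols) {
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf(
        "panel parse error: non-numeric value '%s' in column `%s`, row %d",
        v[bad[1]], col, bad[1]), call. = FALSE)
    raw[[col]] <- num
  }
  for (col in c("cluster", "sequence", "wave", "treatment", "trainee"))
    raw[[col]] <- as.integer(raw[[col]])
  dup <- duplicated(raw[, c("participant_id", "wave")])
  if (any(dup))
    stop(sprintf(
      "panel integrity error: duplicate (participant_id, wave) pair: (%s, %d)",
      raw$participant_id[dup][1], raw$wave[dup][1]), call. = FALSE)
  validate_panel(raw)
  raw
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate structural invariants of a long panel
#'
#' Checks uniqueness of `(participant_id, wave)`, that every participant's
#' rows share one cluster, sequence and covariate set, that waves are positive
#' integers, that treatment is binary and non-decreasing within participant,
#' and (when a crossover `schedule` is supplied) that treatment matches the
#' sequence's crossover week.
#'
#' @param panel Long panel data.frame.
#' @param schedule Optional data.frame with columns `sequence` and
#'   `crossover_week` to check treatment against.
#' @return The panel, invisibly; stops with an informative error otherwise.
#' @export
validate_panel <- function(panel, schedule = NULL) {
  fail <- function(...) stop("panel integrity error: ", sprintf(...),
                             call. = FALSE)
  if (any(duplicated(panel[, c("participant_id", "wave")])))
    fail("duplicate (participant_id, wave) rows")
  if (any(panel$wave < 1, na.rm = TRUE)) fail("wave must be >= 1")
  if (!all(panel$treatment %in% c(0L, 1L))) fail("treatment must be 0/1")
  ord <- order(panel$participant_id, panel$wave)
  p <- panel[ord, , drop = FALSE]
  for (col in c("cluster", "sequence", covariate_columns())) {
    n_per <- tapply(p[[col]], p$participant_id,
                    function(x) length(unique(x)))
    if (any(n_per > 1))
      fail("column `%s` varies within participant %s", col,
           names(n_per)[which(n_per > 1)[1]])
  }
  tr_ok <- tapply(p$treatment, p$participant_id,
                  function(x) all(diff(x) >= 0))
  if (!all(tr_ok))
    fail("treatment reverses within participant %s",
         names(tr_ok)[which(!tr_ok)[1]])
  if (!is.null(schedule)) {
    cross <- schedule$crossover_week[match(p$sequence, schedule$sequence)]
    expect <- as.integer(p$time_weeks >= cross)
    bad <- which(p$treatment != expect)
    if (length(bad))
      fail("treatment inconsistent with crossover schedule for %s wave %d",
           p$participant_id[bad[1]], p$wave[bad[1]])
  }
  invisible(panel)
}

#' Attach the baseline level of a score as a covariate column
#'
#' Adds `<score>_baseline` (the wave-1 value, repeated on every row of the
#' participant) and a logical `analyzable` column flagging waves >= 2, the
#' rows entering the mediation models; baseline itself is only ever a
#' covariate. Participants without a wave-1 row are excluded; the exclusion
#' count is available as attribute `"n_excluded"` and reported via `message`.
#'
#' @param panel Long panel data.frame.
#' @param score_column Score column to baseline (e.g. the outcome).
#' @return The panel with the two extra columns.
#' @export
attach_baseline <- function(panel, score_column) {
  if (!score_column %in% names(panel))
    stop(sprintf("score column `%s` not present in panel", score_column),
         call. = FALSE)
  w1 <- panel[panel$wave == 1L, c("participant_id", score_column)]
  has_base <- unique(w1$participant_id)
  excluded <- setdiff(unique(panel$participant_id), has_base)
  if (length(excluded)) {
    message(sprintf("attach_baseline: excluded %d participant(s) without a wave-1 row",
                    length(excluded)))
    panel <- panel[panel$participant_id %in% has_base, , drop = FALSE]
  }
  base <- w1[[score_column]][match(panel$participant_id, w1$participant_id)]
  panel[[paste0(score_column, "_baseline")]] <- base
  panel$analyzable <- panel$wave >= 2L
  attr(panel, "n_excluded") <- length(excluded)
  attr(panel, "baseline_column") <- paste0(score_column, "_baseline")
  panel
}

#' Specify a mediation model
#'
#' Bundles the outcome, the mediator set, the adjustment covariates and the
#' random-effect structure used by [estimate_paths()] and
#' [bootstrap_mediation()]. The default covariate set is cluster, gender,
#' profession, age, contract type and trainee status; the baseline level of
#' the outcome is always added as a covariate (column
#' `<outcome>_baseline`, created by [attach_baseline()]).
#'
#' @param outcome Outcome column name.
#' @param mediators Character vector of mediator column names (length >= 1).
#' @param covariates Adjustment covariate column names.
#' @param random_effects Non-empty subset of `c("participant", "cluster")`.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("pss", "cd_risc")
model_spec <- function(outcome, mediators,
                       covariates = c("cluster", "gender", "profession",
                                      "age", "contract", "trainee"),
                       random_effects = "participant") {
  if (length(mediators) < 1L) stop("need at least one mediator", call. = FALSE)
  if (anyDuplicated(mediators)) stop("mediators must be distinct", call. = FALSE)
  if (outcome %in% mediators)
    stop("outcome must not appear among the mediators", call. = FALSE)
  if (!length(random_effects) ||
      !all(random_effects %in% c("participant", "cluster")))
    stop("random_effects must be a non-empty subset of {participant, cluster}",
         call. = FALSE)
  structure(list(outcome = outcome, mediators = mediators,
                 covariates = covariates,
                 baseline_column = paste0(outcome, "_baseline"),
                 random_effects = random_effects),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Mediation model spec: %s ~ {%s}\n", x$outcome,
              paste(x$mediators, collapse = ", ")))
  cat(sprintf("  covariates: %s + %s\n",
              paste(x$covariates, collapse = ", "), x$baseline_column))
  cat(sprintf("  random intercepts: %s\n",
              paste(x$random_effects, collapse = ", ")))
  invisible(x)
}
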