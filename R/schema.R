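#' Column dictionary for the long trial panel
#'
#' The canonical long-format panel has one row per participant per assessment
#' wave. Design columns identify the stepped-wedge cell, covariate columns are
#' constant within participant, and score columns hold questionnaire totals
#' (mediators and outcomes). Any score cell may be missing.
#'
#' @return A data.frame with one row per canonical column: `column`, `role`
#'   (design / covariate / mediator / outcome), `type`, and a short
#'   description including the instrument score range where applicable.
#' @export
#' @examples
#' panel_dictionary()
panel_dictionary <- function() {
  rbind(
    data.frame(
      column = c("participant_id", "cluster", "sequence", "wave",
                 "time_weeks", "treatment"),
      role = "design",
      type = c("character", "integer", "integer", "integer",
               "numeric", "integer"),
      description = c(
        "opaque participant identifier",
        "health-care cluster (6 default levels)",
        "stepped-wedge sequence (1-3)",
        "assessment wave (1..n_waves)",
        "weeks since the first assessment",
        "1 once the participant's cluster has crossed over, else 0")
    ),
    data.frame(
      column = c("gender", "age", "profession", "contract", "trainee"),
      role = "covariate",
      type = c("character", "numeric", "character", "character", "integer"),
      description = c(
        "female / male (reference female)",
        "age in years",
        "physician / nurse / other (reference physician)",
        "nontemporary / temporary (reference nontemporary)",
        "1 if trainee (resident), else 0")
    ),
    data.frame(
      column = mediator_columns(),
      role = "mediator",
      type = "numeric",
      description = c(
        "CD-RISC resilience total (0-40)",
        "FFMQ-15 observing facet mean (1-5)",
        "FFMQ-15 describing facet mean (1-5)",
        "FFMQ-15 acting-with-awareness facet mean (1-5)",
        "FFMQ-15 nonjudging facet mean (1-5)",
        "FFMQ-15 nonreacting facet mean (1-5)",
        "SOCS self-compassion total (20-100)",
        "SOCS compassion-for-others total (20-100)",
        "AAQ-II experiential avoidance total (7-49)")
    ),
    data.frame(
      column = outcome_columns(),
      role = "outcome",
      type = "numeric",
      description = c(
        "PSS-10 perceived stress total (0-40)",
        "PHQ-9 depression total (0-27)",
        "GAD-7 anxiety total (0-21)",
        "BSI-18 Global Severity Index (0-72)")
    )
  )
}

#' @rdname panel_dictionary
#' @export
mediator_columns <- function() {
  c("cd_risc", "ffmq_observe", "ffmq_describe", "ffmq_act",
    "ffmq_nonjudge", "ffmq_nonreact", "socs_self", "socs_other", "aaq2")
}

#' @rdname panel_dictionary
#' @export
outcome_columns <- function() {
  c("pss", "phq9", "gad7", "bsi_gsi")
}

score_columns <- function() c(mediator_columns(), outcome_columns())

design_columns <- function() {
  c("participant_id", "cluster", "sequence", "wave", "time_weeks", "treatment")
}

covariate_columns <- function() {
  c("gender", "age", "profession", "contract", "trainee")
}

#' Instrument score ranges
#'
#' @return Named list mapping each score column to its `c(min, max)` range.
#' @export
score_ranges <- function() {
  list(
    cd_risc = c(0, 40), ffmq_observe = c(1, 5), ffmq_describe = c(1, 5),
    ffmq_act = c(1, 5), ffmq_nonjudge = c(1, 5), ffmq_nonreact = c(1, 5),
    socs_self = c(20, 100), socs_other = c(20, 100), aaq2 = c(7, 49),
    pss = c(0, 40), phq9 = c(0, 27), gad7 = c(0, 21), bsi_gsi = c(0, 72)
  )
}

# Baseline sample marginals (mean, sd) used as generator defaults for score
# columns that are not given an explicit mediation role.
score_marginals <- function() {
  list(
    cd_risc = c(27.31, 6.79), ffmq_observe = c(2.84, 0.86),
    ffmq_describe = c(3.54, 0.84), ffmq_act = c(3.26, 0.91),
    ffmq_nonjudge = c(3.80, 0.87), ffmq_nonreact = c(3.01, 0.85),
    socs_self = c(53.53, 10.24), socs_other = c(61.90, 8.77),
    aaq2 = c(20.89, 8.33),
    pss = c(16.88, 6.33), phq9 = c(6.25, 4.36), gad7 = c(7.05, 4.23),
    bsi_gsi = c(12.34, 9.88)
  )
}

# Fixed reference levels for dummy coding, so coefficient signs are stable.
factor_references <- function() {
  list(cluster = "1", gender = "female", profession = "physician",
       contract = "nontemporary")
}

#' Default mediator families
#'
#' Maps each mediator column to its construct family, used by the
#' one-factor-per-mediator sensitivity model.
#'
#' @return Named character vector: mediator column -> family.
#' @export
default_family_map <- function() {
  c(cd_risc = "resilience",
    ffmq_observe = "mindfulness", ffmq_describe = "mindfulness",
    ffmq_act = "mindfulness", ffmq_nonjudge = "mindfulness",
    ffmq_nonreact = "mindfulness",
    socs_self = "compassion", socs_other = "compassion",
    aaq2 = "acceptance")
}
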