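#' Simulation configuration for a synthetic stepped-wedge trial
#'
#' Defines the design geometry (clusters, sequences, crossover schedule,
#' assessment waves) and the generative model for one focal mediation path:
#' `mediator = a * treatment + ...` and
#' `outcome = c_prime * treatment + sum(b_m * mediator_m) + ...`, both with
#' Gaussian participant random intercepts and residuals. Several mediators may
#' carry paths simultaneously by giving named vectors for `a_path` / `b_path`.
#'
#' Defaults reproduce the study conditions the package is built around:
#' 6 clusters of sizes 81/48/60/75/57/26 (347 participants) in 3 sequences
#' crossing over after 8/16/24 weeks, 5 assessments every 8 weeks, and path
#' coefficients a = 2.62, b = -0.48, c' = -2.77 on the resilience -> stress
#' pair (CD-RISC mediating PSS-10).
#'
#' @param cluster_sizes Positive integers, participants per cluster.
#' @param sequence_of_cluster Integer vector in 1..3, one entry per cluster.
#' @param crossover_weeks Strictly increasing weeks at which each sequence
#'   crosses over to the intervention.
#' @param n_waves Number of assessment waves (>= 2).
#' @param wave_spacing_weeks Weeks between consecutive assessments.
#' @param mediators Score columns carrying a generative mediation path.
#' @param outcome Focal outcome score column.
#' @param a_path Treatment -> mediator coefficient(s), mediator units. Scalar
#'   or named vector over `mediators`.
#' @param b_path Mediator -> outcome coefficient(s), outcome units per
#'   mediator unit. Scalar or named vector over `mediators`.
#' @param c_prime Direct treatment -> outcome coefficient.
#' @param time_slope_mediator,time_slope_outcome Secular linear trend per wave
#'   (default 0: the analysis models adjust for cluster and baseline but not
#'   calendar time, so nonzero slopes confound the a-path by design).
#' @param covariate_effects Named numeric vector of coefficients applied to
#'   both mediator and outcome; supported names: `female`, `age` (centred at
#'   45), `nurse`, `other`, `temporary`, `trainee`. Default none.
#' @param sd_participant_mediator,sd_participant_outcome Random-intercept SDs.
#' @param sd_resid_mediator,sd_resid_outcome Residual SDs (> 0).
#' @param sd_cluster_outcome Cluster random-intercept SD on the outcome
#'   (default 0; the mediation models adjust for cluster as a fixed covariate).
#' @param dropout_hazard_per_wave Per-wave probability of monotone dropout
#'   from wave 2 on, in `[0, 1)`.
#' @param clip_to_range Clip generated scores to instrument ranges (off by
#'   default so linear-model recovery is exact in expectation).
#' @param treatment_coding `"once_treated"` (exposure = post-crossover status,
#'   the default) or `"current"` (1 only during the 8-week program window).
#' @param seed Master seed; all draws derive from it deterministically.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_trial()], [make_design()], [true_paths()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' true_paths(cfg)
sim_config <- function(cluster_sizes = c(81L, 48L, 60L, 75L, 57L, 26L),
                       sequence_of_cluster = c(1L, 2L, 3L, 1L, 2L, 3L),
                       crossover_weeks = c(8, 16, 24),
                       n_waves = 5L,
                       wave_spacing_weeks = 8,
                       mediators = "cd_risc",
                       outcome = "pss",
                       a_path = 2.62,
                       b_path = -0.48,
                       c_prime = -2.77,
                       time_slope_mediator = 0,
                       time_slope_outcome = 0,
                       covariate_effects = numeric(0),
                       sd_participant_mediator = 5,
                       sd_participant_outcome = 4,
                       sd_resid_mediator = 4,
                       sd_resid_outcome = 3.5,
                       sd_cluster_outcome = 0,
                       dropout_hazard_per_wave = 0,
                       clip_to_range = FALSE,
                       treatment_coding = c("once_treated", "current"),
                       seed = 1L) {
  treatment_coding <- match.arg(treatment_coding)
  a_path <- expand_path(a_path, mediators, "a_path")
  b_path <- expand_path(b_path, mediators, "b_path")
  cfg <- structure(list(
    cluster_sizes = as.integer(cluster_sizes),
    sequence_of_cluster = as.integer(sequence_of_cluster),
    crossover_weeks = as.numeric(crossover_weeks),
    n_waves = as.integer(n_waves),
    wave_spacing_weeks = as.numeric(wave_spacing_weeks),
    mediators = mediators,
    outcome = outcome,
    a_path = a_path,
    b_path = b_path,
    c_prime = as.numeric(c_prime),
    time_slope_mediator = as.numeric(time_slope_mediator),
    time_slope_outcome = as.numeric(time_slope_outcome),
    covariate_effects = covariate_effects,
    sd_participant_mediator = as.numeric(sd_participant_mediator),
    sd_participant_outcome = as.numeric(sd_participant_outcome),
    sd_resid_mediator = as.numeric(sd_resid_mediator),
    sd_resid_outcome = as.numeric(sd_resid_outcome),
    sd_cluster_outcome = as.numeric(sd_cluster_outcome),
    dropout_hazard_per_wave = as.numeric(dropout_hazard_per_wave),
    clip_to_range = isTRUE(clip_to_range),
    treatment_coding = treatment_coding,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

expand_path <- function(x, mediators, what) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(mediators))
    if (length(x) != length(mediators))
      stop(sprintf("`%s` must be scalar or have one entry per mediator", what),
           call. = FALSE)
    names(x) <- mediators
  }
  if (!setequal(names(x), mediators))
    stop(sprintf("names of `%s` must match `mediators`", what), call. = FALSE)
  as.numeric(x[mediators]) -> out
  names(out) <- mediators
  out
}

validate_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid config field `%s`: %s", field, msg), call. = FALSE)
  if (length(cfg$cluster_sizes) < 1L || any(cfg$cluster_sizes < 1L))
    fail("cluster_sizes", "must be positive integers")
  if (length(cfg$sequence_of_cluster) != length(cfg$cluster_sizes))
    fail("sequence_of_cluster", "one sequence per cluster required")
  if (!all(cfg$sequence_of_cluster %in% seq_along(cfg$crossover_weeks)))
    fail("sequence_of_cluster",
         "every cluster must map to a sequence with a crossover week")
  if (any(diff(cfg$crossover_weeks) <= 0))
    fail("crossover_weeks", "must be strictly increasing across sequences")
  if (cfg$n_waves < 2L) fail("n_waves", "need at least 2 waves")
  if (cfg$wave_spacing_weeks <= 0) fail("wave_spacing_weeks", "must be > 0")
  if (!all(cfg$mediators %in% mediator_columns()))
    fail("mediators", paste("unknown mediator column(s):",
                            paste(setdiff(cfg$mediators, mediator_columns()),
                                  collapse = ", ")))
  if (anyDuplicated(cfg$mediators)) fail("mediators", "must be distinct")
  if (!cfg$outcome %in% outcome_columns())
    fail("outcome", paste("unknown outcome column:", cfg$outcome))
  for (f in c("sd_participant_mediator", "sd_participant_outcome",
              "sd_cluster_outcome"))
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  for (f in c("sd_resid_mediator", "sd_resid_outcome"))
    if (cfg[[f]] <= 0) fail(f, "must be > 0")
  if (cfg$dropout_hazard_per_wave < 0 || cfg$dropout_hazard_per_wave >= 1)
    fail("dropout_hazard_per_wave", "must lie in [0, 1)")
  ce <- cfg$covariate_effects
  ok_names <- c("female", "age", "nurse", "other", "temporary", "trainee")
  if (length(ce) && (is.null(names(ce)) || !all(names(ce) %in% ok_names)))
    fail("covariate_effects",
         paste("names must be among:", paste(ok_names, collapse = ", ")))
  invisible(cfg)
}

#' True path coefficients implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A list of class `true_paths` with elements `a`, `b` (named per
#'   mediator), `indirect = a * b`, `c_prime`, and
#'   `total = c_prime + sum(indirect)`.
#' @export
true_paths <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ind <- config$a_path * config$b_path
  structure(list(a = config$a_path, b = config$b_path, indirect = ind,
                 c_prime = config$c_prime,
                 total = config$c_prime + sum(ind)),
            class = "true_paths")
}

#' Read / write a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_config`: `path`, invisibly. `read_config`: a validated
#'   [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$a_path <- as.list(x$a_path)
  x$b_path <- as.list(x$b_path)
  x$covariate_effects <- as.list(x$covariate_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$a_path <- unlist(x$a_path)
  x$b_path <- unlist(x$b_path)
  x$covariate_effects <- unlist(x$covariate_effects)
  if (is.null(x$covariate_effects)) x$covariate_effects <- numeric(0)
  do.call(sim_config, x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Stepped-wedge simulation config\n")
  cat(sprintf("  clusters: %d (sizes %s), sequences %s\n",
              length(x$cluster_sizes),
              paste(x$cluster_sizes, collapse = "/"),
              paste(x$sequence_of_cluster, collapse = "/")))
  cat(sprintf("  waves: %d every %g wk; crossovers at %s wk\n", x$n_waves,
              x$wave_spacing_weeks, paste(x$crossover_weeks, collapse = "/")))
  cat(sprintf("  mediation: %s -> %s; a = %s, b = %s, c' = %.3g\n",
              paste(x$mediators, collapse = "+"), x$outcome,
              paste(signif(x$a_path, 3), collapse = "/"),
              paste(signif(x$b_path, 3), collapse = "/"), x$c_prime))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
print.true_paths <- function(x, ...) {
  cat("True mediation paths\n")
  for (m in names(x$a))
    cat(sprintf("  %s: a = %.4g, b = %.4g, a*b = %.4g\n",
                m, x$a[m], x$b[m], x$indirect[m]))
  cat(sprintf("  direct c' = %.4g, total = %.4g\n", x$c_prime, x$total))
  invisible(x)
}
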