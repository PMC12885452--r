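#' Build the stepped-wedge design grid
#'
#' Expands a [sim_config()] into one row per participant per wave with the
#' treatment indicator implied by the crossover schedule. Under the default
#' `"once_treated"` coding, `treatment` is 1 from the first wave at or after
#' the participant's sequence crossover week and stays 1 thereafter; under
#' `"current"` coding it is 1 only while the 8-week program window is open.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `participant_id`, `cluster`, `sequence`,
#'   `wave`, `time_weeks`, `treatment`.
#' @export
#' @examples
#' d <- make_design(sim_config())
#' nrow(d)  # 347 participants x 5 waves
make_design <- function(config) {
  validate_config(config)
  n_part <- sum(config$cluster_sizes)
  cluster <- rep(seq_along(config$cluster_sizes), config$cluster_sizes)
  seqc <- config$sequence_of_cluster[cluster]
  id <- sprintf("P%04d", seq_len(n_part))
  waves <- seq_len(config$n_waves)
  tw <- (waves - 1) * config$wave_spacing_weeks
  d <- data.frame(
    participant_id = rep(id, each = config$n_waves),
    cluster = rep(cluster, each = config$n_waves),
    sequence = rep(seqc, each = config$n_waves),
    wave = rep(waves, times = n_part),
    time_weeks = rep(tw, times = n_part),
    stringsAsFactors = FALSE
  )
  cross <- config$crossover_weeks[d$sequence]
  d$treatment <- if (config$treatment_coding == "once_treated") {
    as.integer(d$time_weeks >= cross)
  } else {
    as.integer(d$time_weeks >= cross & d$time_weeks < cross + 8)
  }
  d
}

# Derive a 32-bit sub-seed from the master seed and a unit index, so each
# participant (or cluster) owns an RNG stream independent of row order.
sub_seed <- function(seed, index, offset = 0) {
  as.integer((as.numeric(seed) + 104729 * (as.numeric(index) + offset)) %%
               2147483647)
}

# All participant-level randomness, drawn in one fixed order from the
# participant's own stream: covariates, one z per score column (random
# intercept), then an n_waves x n_scores innovation matrix.
draw_participant <- function(seed, n_waves) {
  cols <- score_columns()
  set.seed(seed)
  gender <- if (stats::runif(1) < 0.856) "female" else "male"
  age <- 0
  repeat {
    age <- stats::rnorm(1, 45.01, 11.17)
    if (age >= 18 && age <= 70) break
  }
  profession <- c("physician", "nurse", "other")[
    1L + findInterval(stats::runif(1), cumsum(c(0.424, 0.268)))]
  contract <- if (stats::runif(1) < 0.816) "nontemporary" else "temporary"
  trainee <- as.integer(stats::runif(1) < 0.098)
  z_int <- stats::rnorm(length(cols))
  names(z_int) <- cols
  z_res <- matrix(stats::rnorm(n_waves * length(cols)), n_waves,
                  dimnames = list(NULL, cols))
  list(gender = gender, age = age, profession = profession,
       contract = contract, trainee = trainee, z_int = z_int, z_res = z_res)
}

covariate_shift <- function(part, effects) {
  if (!length(effects)) return(0)
  g <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  g("female") * (part$gender == "female") +
    g("age") * (part$age - 45) +
    g("nurse") * (part$profession == "nurse") +
    g("other") * (part$profession == "other") +
    g("temporary") * (part$contract == "temporary") +
    g("trainee") * part$trainee
}

clip_scores <- function(panel) {
  rng <- score_ranges()
  for (col in intersect(names(rng), names(panel)))
    panel[[col]] <- pmin(pmax(panel[[col]], rng[[col]][1]), rng[[col]][2])
  panel
}

#' Generate a synthetic stepped-wedge mediation trial
#'
#' Produces a long panel with the canonical schema (see [panel_dictionary()]).
#' For each focal mediator m the generative model is
#' \deqn{M_m = \mu_m + a_m T + \gamma'x + \delta_M (w-1) + u_i^{(m)} + \epsilon}
#' and for the focal outcome
#' \deqn{Y = \beta_0 + c' T + \sum_m b_m M_m + \gamma'x + \delta_Y (w-1)
#'       + u_{cluster} + u_i + \epsilon'}
#' with independent Gaussian random intercepts and residuals, where
#' \eqn{\beta_0} is chosen so the marginal outcome mean matches the
#' instrument's baseline mean. The wave-1 outcome is generated as a
#' pre-intervention trait measurement (intercept plus noise, without the
#' mediator coupling), so that models adjusting for the baseline outcome are
#' correctly specified. Score columns without a mediation role are
#' generated as participant-intercept noise around their baseline marginals
#' (intraclass correlation 0.6). Identical seeds give bit-identical panels.
#'
#' @param config A [sim_config()].
#' @return A long data.frame panel; attribute `"true_paths"` carries the
#'   injected [true_paths()].
#' @export
#' @examples
#' p <- generate_trial(sim_config(seed = 7))
#' head(p[, c("participant_id", "wave", "treatment", "cd_risc", "pss")])
generate_trial <- function(config) {
  validate_config(config)
  design <- make_design(config)
  marg <- score_marginals()
  cols <- score_columns()
  nw <- config$n_waves
  n_part <- sum(config$cluster_sizes)
  cluster_of <- rep(seq_along(config$cluster_sizes), config$cluster_sizes)

  u_cluster <- vapply(seq_along(config$cluster_sizes), function(cl) {
    set.seed(sub_seed(config$seed, cl, offset = 1e6))
    stats::rnorm(1, 0, config$sd_cluster_outcome)
  }, numeric(1))

  rows <- vector("list", n_part)
  focal <- config$mediators
  beta0 <- marg[[config$outcome]][1] -
    sum(config$b_path * vapply(focal, function(m) marg[[m]][1], numeric(1)))

  for (i in seq_len(n_part)) {
    part <- draw_participant(sub_seed(config$seed, i), nw)
    xeff <- covariate_shift(part, config$covariate_effects)
    tvec <- design$treatment[design$participant_id == sprintf("P%04d", i)]
    wave0 <- seq_len(nw) - 1

    sc <- matrix(NA_real_, nw, length(cols), dimnames = list(NULL, cols))
    for (col in cols) {
      mu <- marg[[col]][1]
      if (col %in% focal) {
        sc[, col] <- mu + config$a_path[col] * tvec + xeff +
          config$time_slope_mediator * wave0 +
          config$sd_participant_mediator * part$z_int[col] +
          config$sd_resid_mediator * part$z_res[, col]
      } else if (col == config$outcome) {
        med_sum <- if (length(focal)) {
          drop(sc[, focal, drop = FALSE] %*% config$b_path)
        } else 0
        sc[, col] <- beta0 + config$c_prime * tvec + med_sum + xeff +
          config$time_slope_outcome * wave0 + u_cluster[cluster_of[i]] +
          config$sd_participant_outcome * part$z_int[col] +
          config$sd_resid_outcome * part$z_res[, col]
        # wave 1 is a pre-intervention trait measurement: intercept + noise,
        # no mediator coupling, so baseline-adjusted analysis models are
        # correctly specified and path recovery is exact in expectation
        sc[1, col] <- marg[[col]][1] + xeff + u_cluster[cluster_of[i]] +
          config$sd_participant_outcome * part$z_int[col] +
          config$sd_resid_outcome * part$z_res[1, col]
      } else {
        sd_tot <- marg[[col]][2]
        sc[, col] <- mu + sd_tot * sqrt(0.6) * part$z_int[col] +
          sd_tot * sqrt(0.4) * part$z_res[, col]
      }
    }
    rows[[i]] <- data.frame(
      gender = part$gender, age = part$age, profession = part$profession,
      contract = part$contract, trainee = part$trainee, sc,
      stringsAsFactors = FALSE)
  }
  panel <- cbind(design, do.call(rbind, rows))
  # focal outcome depends on focal mediators: recompute columnwise ordering
  panel <- panel[, c(design_columns(), covariate_columns(), cols)]
  if (config$clip_to_range) panel <- clip_scores(panel)
  if (config$dropout_hazard_per_wave > 0)
    panel <- apply_dropout(panel, config$dropout_hazard_per_wave,
                           seed = sub_seed(config$seed, 0, offset = 2e6))
  attr(panel, "true_paths") <- true_paths(config)
  panel
}

#' Generate a trial with a time-lagged mediator effect on the outcome
#'
#' The mediator is generated as in [generate_trial()]; the focal outcome
#' follows a first-order autoregressive process in which the previous wave's
#' mediator enters with coefficient `lag_coef`:
#' \deqn{Y_{t+1} = \beta_0 + \rho Y_t + \phi M_t + c' T_{t+1}
#'       + u_{cluster} + u_i + \epsilon}
#' Because the lagged estimator conditions on the prior outcome, a true
#' participant intercept on Y would induce dynamic-panel bias that the
#' estimator does not address; persistence is therefore carried by the AR
#' coefficient and `sd_participant_outcome` defaults to 0 here (overridable).
#'
#' @param config A [sim_config()] (its first mediator is used).
#' @param lag_coef True coefficient of mediator at wave t on outcome at t+1.
#' @param ar_coef AR(1) coefficient on the prior outcome, in (-1, 1).
#' @param sd_participant_outcome Participant intercept SD on the outcome.
#' @return A long panel as in [generate_trial()]; attribute `"true_lag"`
#'   records `lag_coef`.
#' @export
generate_lagged_trial <- function(config, lag_coef = -0.21, ar_coef = 0.5,
                                  sd_participant_outcome = 0) {
  validate_config(config)
  stopifnot(abs(ar_coef) < 1)
  design <- make_design(config)
  marg <- score_marginals()
  cols <- score_columns()
  med <- config$mediators[1]
  nw <- config$n_waves
  n_part <- sum(config$cluster_sizes)
  cluster_of <- rep(seq_along(config$cluster_sizes), config$cluster_sizes)

  u_cluster <- vapply(seq_along(config$cluster_sizes), function(cl) {
    set.seed(sub_seed(config$seed, cl, offset = 1e6))
    stats::rnorm(1, 0, config$sd_cluster_outcome)
  }, numeric(1))

  mu_m <- marg[[med]][1]
  mu_y <- marg[[config$outcome]][1]
  beta0 <- mu_y * (1 - ar_coef) - lag_coef * mu_m

  rows <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    part <- draw_participant(sub_seed(config$seed, i), nw)
    xeff <- covariate_shift(part, config$covariate_effects)
    tvec <- design$treatment[design$participant_id == sprintf("P%04d", i)]
    m <- mu_m + config$a_path[med] * tvec + xeff +
      config$sd_participant_mediator * part$z_int[med] +
      config$sd_resid_mediator * part$z_res[, med]
    u_i <- sd_participant_outcome * part$z_int[config$outcome]
    y <- numeric(nw)
    y[1] <- mu_y + xeff + u_cluster[cluster_of[i]] + u_i +
      config$sd_resid_outcome * part$z_res[1, config$outcome]
    for (w in seq_len(nw - 1)) {
      y[w + 1] <- beta0 + ar_coef * y[w] + lag_coef * m[w] +
        config$c_prime * tvec[w + 1] + u_cluster[cluster_of[i]] + u_i +
        config$sd_resid_outcome * part$z_res[w + 1, config$outcome]
    }
    sc <- matrix(NA_real_, nw, length(cols), dimnames = list(NULL, cols))
    for (col in cols) {
      if (col == med) sc[, col] <- m
      else if (col == config$outcome) sc[, col] <- y
      else {
        sd_tot <- marg[[col]][2]
        sc[, col] <- marg[[col]][1] + sd_tot * sqrt(0.6) * part$z_int[col] +
          sd_tot * sqrt(0.4) * part$z_res[, col]
      }
    }
    rows[[i]] <- data.frame(
      gender = part$gender, age = part$age, profession = part$profession,
      contract = part$contract, trainee = part$trainee, sc,
      stringsAsFactors = FALSE)
  }
  panel <- cbind(design, do.call(rbind, rows))
  panel <- panel[, c(design_columns(), covariate_columns(), cols)]
  if (config$clip_to_range) panel <- clip_scores(panel)
  attr(panel, "true_lag") <- lag_coef
  panel
}

#' Apply monotone participant dropout to a panel
#'
#' Once a participant misses a wave, all later waves are removed as well;
#' wave 1 is always retained. Under per-wave hazard h, the expected fraction
#' of participants retained at wave w is (1-h)^(w-1).
#'
#' @param panel Long panel data.frame.
#' @param hazard Per-wave dropout probability in `[0, 1)`.
#' @param seed Seed for the dropout draws.
#' @return The panel with dropped rows removed.
#' @export
apply_dropout <- function(panel, hazard, seed = 1L) {
  if (!is.numeric(hazard) || hazard < 0 || hazard >= 1)
    stop("`hazard` must lie in [0, 1)", call. = FALSE)
  if (hazard == 0) return(panel)
  ids <- unique(panel$participant_id)
  max_wave <- max(panel$wave)
  set.seed(as.integer(seed))
  first_missing <- vapply(ids, function(id) {
    u <- stats::runif(max_wave - 1)
    hit <- which(u < hazard)
    if (length(hit)) hit[1] + 1L else max_wave + 1L
  }, numeric(1))
  names(first_missing) <- ids
  keep <- panel$wave < first_missing[panel$participant_id]
  panel[keep, , drop = FALSE]
}
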