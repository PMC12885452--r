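# ---- bootstrap summary helpers ---------------------------------------------

#' Percentile bootstrap confidence interval
#'
#' The 2.5th and 97.5th percentiles (for `level = 0.95`) of the bootstrap
#' draws, using linear interpolation between order statistics by default
#' (`quantile_type = 7`); `quantile_type = 1` gives the nearest-rank
#' convention.
#'
#' @param draws Numeric vector of bootstrap statistics.
#' @param level Confidence level.
#' @param quantile_type Passed to [stats::quantile()].
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
boot_ci <- function(draws, level = 0.95, quantile_type = 7) {
  alpha <- (1 - level) / 2
  stats::quantile(draws, c(alpha, 1 - alpha), type = quantile_type,
                  names = FALSE)
}

#' Sign-crossing bootstrap p-value
#'
#' Two-sided p-value from the proportion of bootstrap draws on each side of
#' zero: `min(1, 2 * min(P(draw <= 0), P(draw >= 0)))`. If no draw crosses
#' zero the p-value is 0 and is rendered as `< 2/n_boot` in formatted output.
#'
#' @param draws Numeric vector of bootstrap statistics.
#' @return p-value in `[0, 1]`.
#' @export
boot_p <- function(draws) {
  min(1, 2 * min(mean(draws <= 0), mean(draws >= 0)))
}

path_summary <- function(estimate, draws, quantile_type = 7) {
  list(estimate = estimate,
       ci = boot_ci(draws, quantile_type = quantile_type),
       p = boot_p(draws),
       p_one_sided = min(mean(draws <= 0), mean(draws >= 0)))
}

# ---- model-matrix preparation ----------------------------------------------

# Build the fixed-effect matrices for the two mediation models once, plus
# per-participant row-index lists, so each bootstrap iteration is pure integer
# indexing + two profiled REML fits. Complete-case handling is per model.
prepare_mediation <- function(panel, spec) {
  if (!spec$baseline_column %in% names(panel))
    stop(sprintf("baseline column `%s` missing; call attach_baseline() first",
                 spec$baseline_column), call. = FALSE)
  rows <- if ("analyzable" %in% names(panel)) panel[panel$analyzable, , drop = FALSE]
          else panel[panel$wave >= 2L, , drop = FALSE]
  cov_terms <- c("treatment", spec$covariates, spec$baseline_column)
  cc_cov <- stats::complete.cases(rows[, cov_terms, drop = FALSE])
  rows <- rows[cc_cov, , drop = FALSE]
  CovX <- build_fixed_matrix(rows, cov_terms)
  trt_col <- match("treatment", colnames(CovX))

  med_mat <- as.matrix(rows[, spec$mediators, drop = FALSE])
  if (length(spec$mediators) > 1L) {
    cm <- suppressWarnings(stats::cor(med_mat, use = "pairwise.complete.obs"))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(abs(cm) > 0.999)) {
      ij <- which(abs(cm) > 0.999, arr.ind = TRUE)[1, ]
      pair <- sort(spec$mediators[ij])
      stop(sprintf("collinear mediators: `%s` and `%s`", pair[1], pair[2]),
           call. = FALSE)
    }
  }

  y_out <- as.numeric(rows[[spec$outcome]])
  maskB <- !is.na(y_out) & stats::complete.cases(med_mat)
  maskA <- lapply(spec$mediators, function(m) !is.na(rows[[m]]))
  names(maskA) <- spec$mediators

  pid <- rows$participant_id
  upid <- unique(pid)
  pidx <- match(pid, upid)
  all_rows <- split(seq_len(nrow(rows)), pidx)
  cluster_of <- rows$cluster[match(upid, pid)]

  # per participant, the usable row indices for each model
  idxA <- lapply(spec$mediators, function(m)
    lapply(all_rows, function(r) r[maskA[[m]][r]]))
  names(idxA) <- spec$mediators
  idxB <- lapply(all_rows, function(r) r[maskB[r]])

  XB <- cbind(med_mat, CovX)
  colnames(XB) <- c(spec$mediators, colnames(CovX))

  list(rows = rows, CovX = CovX, XB = XB, trt_col = trt_col,
       y_out = y_out, med_mat = med_mat, spec = spec,
       n_participants = length(upid), cluster_of = cluster_of,
       part_by_cluster = split(seq_along(upid), cluster_of),
       idxA = idxA, idxB = idxB)
}

# Fit both mediation models for one participant selection (`sel` = vector of
# participant positions, possibly with repeats). Returns named vector of
# a_m, b_m, indirect_m, direct, or NULL on a degenerate resample.
fit_selection <- function(prep, sel) {
  spec <- prep$spec
  nm <- length(spec$mediators)
  out <- numeric(3 * nm + 1)
  for (k in seq_len(nm)) {
    m <- spec$mediators[k]
    idx <- prep$idxA[[m]][sel]
    ridx <- unlist(idx, use.names = FALSE)
    grp <- rep.int(seq_along(sel), lengths(idx))
    fa <- try(lmm_profile_fit(prep$CovX[ridx, , drop = FALSE],
                              as.numeric(prep$med_mat[ridx, k]), grp),
              silent = TRUE)
    if (inherits(fa, "try-error")) return(NULL)
    out[k] <- fa$coef[prep$trt_col]
  }
  idx <- prep$idxB[sel]
  ridx <- unlist(idx, use.names = FALSE)
  grp <- rep.int(seq_along(sel), lengths(idx))
  fb <- try(lmm_profile_fit(prep$XB[ridx, , drop = FALSE],
                            prep$y_out[ridx], grp), silent = TRUE)
  if (inherits(fb, "try-error")) return(NULL)
  b <- fb$coef[seq_len(nm)]
  out[nm + seq_len(nm)] <- b
  out[2 * nm + seq_len(nm)] <- out[seq_len(nm)] * b
  out[3 * nm + 1] <- fb$coef[nm + prep$trt_col]
  names(out) <- c(paste0("a.", spec$mediators), paste0("b.", spec$mediators),
                  paste0("ind.", spec$mediators), "direct")
  out
}

draw_selection <- function(prep, seed) {
  set.seed(seed)
  unlist(lapply(prep$part_by_cluster,
                function(pp) pp[sample.int(length(pp), replace = TRUE)]),
         use.names = FALSE)
}

# ---- full-sample paths ------------------------------------------------------

#' Estimate mediation path coefficients on the full sample
#'
#' Fits, on the analyzable rows (waves >= 2, baseline as covariate):
#' model A per mediator, `mediator ~ treatment + covariates + baseline`,
#' and model B, `outcome ~ mediators + treatment + covariates + baseline`,
#' each with a participant random intercept. The a-path is model A's
#' treatment coefficient, the b-path model B's mediator coefficient, and the
#' direct effect model B's treatment coefficient.
#'
#' @param panel Long panel with the baseline column attached
#'   ([attach_baseline()]).
#' @param spec A [model_spec()].
#' @return List with `a_fits` (named list of [fit_lmm()] results, one per
#'   mediator), `y_fit`, and numeric `a`, `b`, `indirect` (named per
#'   mediator) and `direct`.
#' @export
estimate_paths <- function(panel, spec) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_mediation(panel, spec)
  est <- fit_selection(prep, seq_len(prep$n_participants))
  if (is.null(est))
    stop("full-sample mediation fit failed", call. = FALSE)
  nm <- length(spec$mediators)

  rows <- prep$rows
  cov_terms <- c("treatment", spec$covariates, spec$baseline_column)
  a_fits <- lapply(spec$mediators, function(m)
    fit_lmm(rows, m, cov_terms, random_effects = "participant_id"))
  names(a_fits) <- spec$mediators
  y_fit <- fit_lmm(rows, spec$outcome, c(spec$mediators, cov_terms),
                   random_effects = "participant_id")

  a <- est[seq_len(nm)]
  b <- est[nm + seq_len(nm)]
  names(a) <- names(b) <- spec$mediators
  list(a_fits = a_fits, y_fit = y_fit, a = a, b = b,
       indirect = a * b, direct = unname(est[3 * nm + 1]))
}

# ---- bootstrap engine -------------------------------------------------------

run_bootstrap <- function(prep, n_boot, seed, workers, max_retries = 3) {
  set.seed(as.integer(seed) %% 2147483647L)
  iter_seeds <- matrix(sample.int(2147483647L, n_boot * (max_retries + 1)),
                       nrow = n_boot)
  one_iter <- function(b) {
    for (r in seq_len(max_retries + 1)) {
      sel <- draw_selection(prep, iter_seeds[b, r])
      est <- fit_selection(prep, sel)
      if (!is.null(est)) return(est)
    }
    NULL
  }
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n_boot), one_iter, mc.cores = workers)
  } else {
    lapply(seq_len(n_boot), one_iter)
  }
  keep <- !vapply(res, is.null, logical(1))
  draws <- do.call(rbind, res[keep])
  n_used <- sum(keep)
  if (n_used < 0.95 * n_boot)
    stop(sprintf(
      "bootstrap failed: only %d of %d iterations converged after retries",
      n_used, n_boot), call. = FALSE)
  list(draws = draws, n_used = n_used)
}

#' Bootstrap product-of-coefficients mediation (univariate)
#'
#' Estimates the indirect effect of treatment on the outcome through one
#' mediator as the product of the two path coefficients, with inference from
#' a nonparametric bootstrap: each iteration resamples participants (whole
#' trajectories) with replacement, stratified by cluster so cluster sizes are
#' preserved, refits both random-intercept models, and records `a*b`. The
#' 95% CI is the 2.5th/97.5th percentile of the bootstrap distribution and
#' the p-value is the two-sided sign-crossing proportion ([boot_p()]).
#' Identical seeds give identical draws regardless of `workers`.
#'
#' @param panel Long panel with baseline attached.
#' @param spec A univariate [model_spec()].
#' @param n_boot Number of bootstrap iterations (>= 100; 1000 by default).
#' @param seed Integer seed driving all resampling.
#' @param workers Parallel workers (forked; results identical to serial).
#' @param resample_unit `"participant"` (cluster-stratified trajectory
#'   resampling, the default) or `"row"` (naive row resampling, for
#'   comparison only — it breaks the within-participant correlation
#'   structure).
#' @param quantile_type Percentile convention, see [boot_ci()].
#' @return An object of class `mediation_result` with per-path estimates,
#'   percentile CIs and sign-crossing p-values, the indirect-effect draw
#'   vector, and bookkeeping (`n_boot_requested`, `n_boot_used`, `seed`).
#' @export
bootstrap_mediation <- function(panel, spec, n_boot = 1000, seed = 1L,
                                workers = 1L,
                                resample_unit = c("participant", "row"),
                                quantile_type = 7) {
  resample_unit <- match.arg(resample_unit)
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$mediators) != 1L)
    stop("bootstrap_mediation is univariate; use multivariate_mediation",
         call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  prep <- prepare_mediation(panel, spec)
  if (resample_unit == "row") prep <- rowwise_prep(prep)
  full <- fit_selection(prep, seq_len(prep$n_participants))
  if (is.null(full)) stop("full-sample mediation fit failed", call. = FALSE)
  bt <- run_bootstrap(prep, n_boot, seed, workers)
  m <- spec$mediators
  structure(list(
    mediator = m, outcome = spec$outcome,
    a = path_summary(unname(full[paste0("a.", m)]),
                     bt$draws[, paste0("a.", m)], quantile_type),
    b = path_summary(unname(full[paste0("b.", m)]),
                     bt$draws[, paste0("b.", m)], quantile_type),
    indirect = path_summary(unname(full[paste0("a.", m)] * full[paste0("b.", m)]),
                            bt$draws[, paste0("ind.", m)], quantile_type),
    direct = path_summary(unname(full["direct"]), bt$draws[, "direct"],
                          quantile_type),
    draws = unname(bt$draws[, paste0("ind.", m)]),
    all_draws = bt$draws,
    n_boot_requested = as.integer(n_boot), n_boot_used = bt$n_used,
    n_participants = prep$n_participants, n_rows = nrow(prep$rows),
    seed = as.integer(seed), resample_unit = resample_unit),
    class = "mediation_result")
}

# Row-level resampling variant: the resampling unit becomes the single
# analyzable row. Every resampled row is its own grouping unit, so the random
# intercept is unidentified and the fit collapses to OLS -- which is exactly
# the (structure-breaking) behaviour this comparison flag is meant to expose.
rowwise_prep <- function(prep) {
  nr <- nrow(prep$rows)
  prep$n_participants <- nr
  prep$cluster_of <- prep$rows$cluster
  prep$part_by_cluster <- split(seq_len(nr), prep$cluster_of)
  pid <- match(prep$rows$participant_id, unique(prep$rows$participant_id))
  one <- function(mask) lapply(seq_len(nr), function(i) if (mask[i]) i else integer(0))
  for (m in names(prep$idxA)) {
    maskA <- !is.na(prep$med_mat[, m])
    prep$idxA[[m]] <- one(maskA)
  }
  maskB <- !is.na(prep$y_out) & stats::complete.cases(prep$med_mat)
  prep$idxB <- one(maskB)
  prep
}

#' Multivariate mediation: all mediators in one outcome model
#'
#' One a-path model per mediator and a single joint outcome model containing
#' all mediators; per-mediator indirect effects `a_m * b_m` are computed
#' within the same cluster-stratified participant resample in every bootstrap
#' iteration, so the decomposition is internally consistent.
#'
#' @param panel Long panel with baseline attached.
#' @param mediators Character vector of >= 2 mediator columns.
#' @param outcome Outcome column.
#' @param covariates Adjustment covariates (see [model_spec()]).
#' @param n_boot,seed,workers,quantile_type As [bootstrap_mediation()].
#' @return An object of class `multivariate_mediation_result`: per-mediator
#'   `paths` (list of a/b/indirect summaries), shared `direct` effect, draws,
#'   bookkeeping.
#' @export
multivariate_mediation <- function(panel, mediators, outcome,
                                   covariates = c("cluster", "gender",
                                                  "profession", "age",
                                                  "contract", "trainee"),
                                   n_boot = 1000, seed = 1L, workers = 1L,
                                   quantile_type = 7) {
  if (length(mediators) < 2L)
    stop("multivariate_mediation needs >= 2 mediators", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  spec <- model_spec(outcome, mediators, covariates)
  prep <- prepare_mediation(panel, spec)
  full <- fit_selection(prep, seq_len(prep$n_participants))
  if (is.null(full)) stop("full-sample mediation fit failed", call. = FALSE)
  bt <- run_bootstrap(prep, n_boot, seed, workers)
  paths <- lapply(mediators, function(m) list(
    mediator = m,
    a = path_summary(unname(full[paste0("a.", m)]),
                     bt$draws[, paste0("a.", m)], quantile_type),
    b = path_summary(unname(full[paste0("b.", m)]),
                     bt$draws[, paste0("b.", m)], quantile_type),
    indirect = path_summary(unname(full[paste0("a.", m)] * full[paste0("b.", m)]),
                            bt$draws[, paste0("ind.", m)], quantile_type)))
  names(paths) <- mediators
  structure(list(
    mediators = mediators, outcome = outcome, paths = paths,
    direct = path_summary(unname(full["direct"]), bt$draws[, "direct"],
                          quantile_type),
    all_draws = bt$draws,
    n_boot_requested = as.integer(n_boot), n_boot_used = bt$n_used,
    n_participants = prep$n_participants, n_rows = nrow(prep$rows),
    seed = as.integer(seed)),
    class = "multivariate_mediation_result")
}

# ---- sensitivity variants ---------------------------------------------------

#' Sensitivity multivariate mediation models
#'
#' Two restricted multivariate models: S1 keeps only the mediators whose
#' univariate bootstrap indirect-effect p-value is below `alpha`; S2 keeps one
#' mediator per construct family (resilience / mindfulness / compassion /
#' acceptance), choosing the most significant member — smallest univariate p,
#' ties broken by larger absolute indirect effect, then by name.
#'
#' @param panel Long panel with baseline attached.
#' @param univariate_results Named list of `mediation_result`s (names are
#'   mediator columns), or a data.frame with columns `mediator`, `p`,
#'   `indirect`.
#' @param outcome Outcome column.
#' @param family_map Named character vector mediator -> family
#'   ([default_family_map()]).
#' @param covariates,n_boot,seed,workers As [multivariate_mediation()].
#' @param alpha Univariate significance threshold for S1.
#' @return List with elements `s1` and `s2`; each is a
#'   `multivariate_mediation_result` (or a `mediation_result` when only one
#'   mediator qualifies). If no mediator passes the S1 filter, `s1` is an
#'   object of class `empty_mediation_result` carrying an explanatory status,
#'   not an error. Selected mediator sets are in `s1_mediators` /
#'   `s2_mediators`.
#' @export
sensitivity_models <- function(panel, univariate_results, outcome,
                               family_map = default_family_map(),
                               covariates = c("cluster", "gender", "profession",
                                              "age", "contract", "trainee"),
                               n_boot = 1000, seed = 1L, workers = 1L,
                               alpha = 0.05) {
  tab <- normalize_univariate(univariate_results)
  missing_fam <- setdiff(tab$mediator, names(family_map))
  if (length(missing_fam))
    stop("family_map lacks mediator(s): ",
         paste(missing_fam, collapse = ", "), call. = FALSE)

  s1_set <- tab$mediator[tab$p < alpha]
  s2_set <- select_per_family(tab, family_map)

  run_set <- function(meds, sd_offset) {
    if (length(meds) >= 2L)
      multivariate_mediation(panel, meds, outcome, covariates = covariates,
                             n_boot = n_boot, seed = seed + sd_offset,
                             workers = workers)
    else
      bootstrap_mediation(panel, model_spec(outcome, meds, covariates),
                          n_boot = n_boot, seed = seed + sd_offset,
                          workers = workers)
  }
  s1 <- if (!length(s1_set)) {
    structure(list(status = "empty",
                   message = sprintf(
                     "no mediator reached univariate p < %.2f; S1 model not fitted",
                     alpha)),
              class = "empty_mediation_result")
  } else run_set(s1_set, 0L)
  s2 <- run_set(s2_set, 1L)
  list(s1 = s1, s2 = s2, s1_mediators = s1_set, s2_mediators = s2_set)
}

normalize_univariate <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("mediator", "p", "indirect") %in% names(x)))
    return(x[, c("mediator", "p", "indirect")])
  }
  stopifnot(is.list(x), !is.null(names(x)))
  data.frame(
    mediator = names(x),
    p = vapply(x, function(r) r$indirect$p, numeric(1)),
    indirect = vapply(x, function(r) r$indirect$estimate, numeric(1)),
    row.names = NULL)
}

select_per_family <- function(tab, family_map) {
  tab$family <- family_map[tab$mediator]
  picks <- lapply(split(tab, tab$family), function(fm) {
    fm <- fm[order(fm$p, -abs(fm$indirect), fm$mediator), , drop = FALSE]
    fm$mediator[1]
  })
  fam_order <- unique(family_map[tab$mediator])
  unname(unlist(picks[fam_order]))
}

# ---- printing ---------------------------------------------------------------

#' @export
print.mediation_result <- function(x, ...) {
  cat(render_results(x, format = "text"), sep = "\n")
  invisible(x)
}

#' @export
print.multivariate_mediation_result <- function(x, ...) {
  cat(render_results(x, format = "text"), sep = "\n")
  invisible(x)
}

#' @export
print.empty_mediation_result <- function(x, ...) {
  cat(render_results(x, format = "text"), sep = "\n")
  invisible(x)
}
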