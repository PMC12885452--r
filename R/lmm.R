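# ---- fixed-effects design matrix -------------------------------------------

# Expand a term list into a numeric model matrix with fixed reference levels
# (cluster 1, female, physician, nontemporary) so coefficient signs are
# reproducible. Character/factor columns are dummy coded; `cluster` is always
# treated as categorical.
build_fixed_matrix <- function(data, terms) {
  if (!length(terms)) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  refs <- factor_references()
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (tm in terms) {
    if (!tm %in% names(data))
      stop(sprintf("model term `%s` not found in data", tm), call. = FALSE)
    v <- data[[tm]]
    if (tm %in% names(refs) || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- sort(unique(v))
      if (tm %in% names(refs) && refs[[tm]] %in% lev)
        lev <- c(refs[[tm]], setdiff(lev, refs[[tm]]))
      df[[tm]] <- factor(v, levels = lev)
    } else {
      df[[tm]] <- as.numeric(v)
    }
  }
  stats::model.matrix(~ ., data = df)
}

# ---- profiled REML for a single random intercept ---------------------------

# Quasi-demeaning fit: for variance ratio theta = var_group / var_resid the
# GLS estimate is OLS on y - lambda_g * ybar_g with
# lambda_g = 1 - 1/sqrt(1 + theta * n_g). The REML (or ML) deviance is
# profiled down to a 1-D search over log(theta). Agrees with lme4 REML fits
# to optimizer tolerance at a fraction of the cost, which is what makes the
# resampling loops tractable.
lmm_profile_fit <- function(X, y, group, reml = TRUE, tol = 1e-9) {
  gi <- match(group, unique(group))
  ni <- tabulate(gi)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("fewer observations than fixed-effect columns", call. = FALSE)
  ys <- rowsum(y, gi) / ni
  Xs <- rowsum(X, gi) / ni
  ysg <- ys[gi]
  Xsg <- Xs[gi, , drop = FALSE]
  dfree <- if (reml) n - p else n

  crit <- function(lt) {
    th <- exp(lt)
    lam <- 1 - 1 / sqrt(1 + th * ni)
    lg <- lam[gi]
    f <- .lm.fit(X - lg * Xsg, y - lg * ysg)
    rss <- sum(f$residuals^2)
    if (rss <= 0 || f$rank < p) return(Inf)
    val <- dfree * log(rss) + sum(log1p(th * ni))
    if (reml) val <- val + 2 * sum(log(abs(diag(f$qr)[seq_len(p)])))
    val
  }

  # constant-response / zero-residual degenerate case
  f0 <- lm.fit(X, y)
  rss0 <- sum(f0$residuals^2)
  if (f0$rank < p) {
    aliased <- colnames(X)[f0$qr$pivot[(f0$rank + 1):p]]
    stop("singular design: aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (rss0 < 1e-10 * max(1, sum(y^2))) {
    se <- rep(0, p)
    names(se) <- names(f0$coefficients)
    return(list(coef = f0$coefficients, se = se, var_group = 0,
                resid_var = 0, theta = 0, loglik = NA_real_, converged = TRUE,
                n_obs = n, n_groups = max(gi)))
  }

  o <- stats::optimize(crit, c(-15, 15), tol = tol)
  theta <- exp(o$minimum)
  # snap to the OLS boundary when it is at least as good
  c0 <- dfree * log(rss0) +
    if (reml) 2 * sum(log(abs(diag(f0$qr$qr)[seq_len(p)]))) else 0
  if (c0 <= o$objective + 1e-10) theta <- 0

  lam <- 1 - 1 / sqrt(1 + theta * ni)
  lg <- lam[gi]
  f <- lm.fit(X - lg * Xsg, y - lg * ysg)
  rss <- sum(f$residuals^2)
  s2 <- rss / dfree
  R <- qr.R(f$qr)
  cov_b <- s2 * chol2inv(R)
  se <- sqrt(diag(cov_b))
  names(se) <- colnames(X)
  cval <- dfree * log(rss) + sum(log1p(theta * ni)) +
    if (reml) 2 * sum(log(abs(diag(f$qr$qr)[seq_len(p)]))) else 0
  loglik <- -0.5 * (cval + dfree * (1 + log(2 * pi) - log(dfree)))
  cf <- f$coefficients
  names(cf) <- colnames(X)
  list(coef = cf, se = se, var_group = theta * s2, resid_var = s2,
       theta = theta, loglik = loglik, converged = is.finite(o$objective),
       n_obs = n, n_groups = max(gi))
}

# ---- public fitting contract -----------------------------------------------

#' Fit a random-intercept linear mixed model
#'
#' Fits `response ~ fixed_terms` with independent random intercepts for each
#' grouping factor in `random_effects`, by REML (default) or ML. Rows with a
#' missing response or missing fixed-term value are dropped (complete case)
#' and counted. A single-grouping fit uses the package's profiled-REML engine
#' (equivalent to `lme4::lmer` to optimizer tolerance); fits with both
#' participant and cluster intercepts delegate to `lme4::lmer`. If a grouping
#' factor has fewer than 2 levels the model falls back to ordinary least
#' squares with a warning.
#'
#' @param data Data.frame of model rows (e.g. the analyzable panel rows).
#' @param response Response column name (numeric).
#' @param fixed_terms Character vector of fixed-effect column names;
#'   categorical columns are dummy-expanded with fixed reference levels.
#' @param random_effects Grouping column names, e.g. `"participant_id"` or
#'   `c("participant_id", "cluster")`.
#' @param reml Use REML (default) or ML.
#' @param engine `"auto"` (profile engine for one grouping, lme4 otherwise),
#'   `"profile"`, or `"lme4"`.
#' @return An object of class `lmm_fit`: `coef`, `se`, `p` (Wald, normal
#'   approximation), `var_components`, `resid_var`, `converged`, `n_obs`,
#'   `n_groups`, `n_dropped`, `loglik`.
#' @export
fit_lmm <- function(data, response, fixed_terms, random_effects = "participant_id",
                    reml = TRUE, engine = c("auto", "profile", "lme4")) {
  engine <- match.arg(engine)
  used <- unique(c(response, fixed_terms, random_effects))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("column(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!cc)
  d <- data[cc, , drop = FALSE]
  y <- as.numeric(d[[response]])
  X <- build_fixed_matrix(d, fixed_terms)

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design: aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  n_levels <- vapply(random_effects, function(g) length(unique(d[[g]])),
                     integer(1))
  if (any(n_levels < 2L)) {
    warning(sprintf(
      "grouping factor(s) %s have < 2 levels; falling back to ordinary least squares",
      paste(random_effects[n_levels < 2L], collapse = ", ")), call. = FALSE)
    f <- stats::lm.fit(X, y)
    s2 <- sum(f$residuals^2) / (length(y) - ncol(X))
    se <- sqrt(s2 * diag(chol2inv(qr.R(f$qr))))
    names(se) <- colnames(X)
    vc <- rep(0, length(random_effects))
    names(vc) <- random_effects
    return(new_lmm_fit(f$coefficients, se, vc, s2, TRUE, length(y),
                       n_levels, n_dropped, NA_real_))
  }

  if (engine == "auto")
    engine <- if (length(random_effects) == 1L) "profile" else "lme4"

  if (engine == "profile") {
    if (length(random_effects) != 1L)
      stop("profile engine supports exactly one random intercept", call. = FALSE)
    # canonical row order (response, then design columns): the fit is then
    # bit-identical under any permutation of the input rows
    ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)),
                                            function(j) X[, j])))
    pf <- lmm_profile_fit(X[ord, , drop = FALSE], y[ord],
                          d[[random_effects]][ord], reml = reml)
    if (!pf$converged)
      stop("mixed-model fit failed to converge", call. = FALSE)
    vc <- pf$var_group
    names(vc) <- random_effects
    ng <- pf$n_groups
    names(ng) <- random_effects
    return(new_lmm_fit(pf$coef, pf$se, vc, pf$resid_var, TRUE, pf$n_obs,
                       ng, n_dropped, pf$loglik))
  }

  # lme4 path
  dd <- data.frame(.y = y, X[, -1, drop = FALSE], check.names = TRUE)
  xnames <- names(dd)[-1]
  for (g in random_effects) dd[[paste0(".g_", g)]] <- factor(d[[g]])
  fml <- stats::as.formula(paste(
    ".y ~", if (length(xnames)) paste(sprintf("`%s`", xnames), collapse = " + ")
            else "1",
    "+", paste(sprintf("(1 | .g_%s)", random_effects), collapse = " + ")))
  fit <- lme4::lmer(fml, data = dd, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (length(msgs) && any(grepl("failed to converge", msgs, ignore.case = TRUE)))
    stop("mixed-model fit failed to converge: ", paste(msgs, collapse = "; "),
         call. = FALSE)
  cf <- lme4::fixef(fit)
  names(cf) <- colnames(X)
  se <- stats::coef(summary(fit))[, "Std. Error"]
  names(se) <- colnames(X)
  vcl <- lme4::VarCorr(fit)
  vc <- vapply(random_effects, function(g)
    as.numeric(vcl[[paste0(".g_", g)]]), numeric(1))
  ng <- vapply(random_effects, function(g) length(unique(d[[g]])), integer(1))
  new_lmm_fit(cf, se, vc, stats::sigma(fit)^2, TRUE, nrow(dd), ng, n_dropped,
              as.numeric(stats::logLik(fit)))
}

new_lmm_fit <- function(coef, se, var_components, resid_var, converged,
                        n_obs, n_groups, n_dropped, loglik) {
  z <- ifelse(se > 0, coef / se, 0)
  structure(list(
    coef = coef, se = se,
    p = 2 * stats::pnorm(-abs(z)),
    var_components = var_components, resid_var = resid_var,
    converged = converged, n_obs = n_obs, n_groups = n_groups,
    n_dropped = n_dropped, loglik = loglik), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept linear mixed model (n = %d, groups = %s, dropped = %d)\n",
              x$n_obs, paste(x$n_groups, collapse = "/"), x$n_dropped))
  tab <- data.frame(estimate = signif(x$coef, digits),
                    se = signif(x$se, digits),
                    p = signif(x$p, 3))
  print(tab)
  cat(sprintf("Variance components: %s; residual %.4g\n",
              paste(sprintf("%s %.4g", names(x$var_components),
                            x$var_components), collapse = ", "),
              x$resid_var))
  invisible(x)
}
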