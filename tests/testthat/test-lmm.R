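make_lmm_data <- function(seed, np = 40, nw = 4, sd_u = 1.5, sd_e = 1) {
  set.seed(seed)
  g <- rep(seq_len(np), each = nw)
  n <- np * nw
  d <- data.frame(participant_id = sprintf("P%03d", g),
                  x1 = rnorm(n), x2 = rnorm(n),
                  grp = sample(c("a", "b", "c"), n, replace = TRUE))
  d$y <- 1 + 0.5 * d$x1 - 0.25 * d$x2 + (d$grp == "b") * 0.7 +
    rep(rnorm(np, 0, sd_u), each = nw) + rnorm(n, 0, sd_e)
  d
}

test_that("with zero random-intercept variance the fit equals OLS", {
  # residuals centred within participant: the between-participant variance is
  # below its null expectation, so the REML estimate sits at the boundary and
  # the mixed fit must coincide with OLS
  d <- make_lmm_data(1, sd_u = 0, sd_e = 0)
  set.seed(101)
  e <- rnorm(nrow(d))
  d$y <- d$y + e - ave(e, d$participant_id)
  f <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id")
  expect_equal(unname(f$var_components), 0)
  ols <- lm(y ~ x1 + x2 + grp, data = d)
  expect_equal(unname(f$coef), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-6)
})

test_that("profile engine agrees with lme4 on coefficients, SEs, variances and loglik", {
  d <- make_lmm_data(2)
  fp <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id",
                engine = "profile")
  fl <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id",
                engine = "lme4")
  expect_equal(fp$coef, fl$coef, tolerance = 1e-6)
  expect_equal(fp$se, fl$se, tolerance = 1e-6)
  expect_equal(fp$var_components, fl$var_components, tolerance = 1e-4)
  expect_equal(fp$resid_var, fl$resid_var, tolerance = 1e-5)
  expect_equal(fp$loglik, fl$loglik, tolerance = 1e-6)
  # and under ML as well
  fpm <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id",
                 engine = "profile", reml = FALSE)
  flm <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id",
                 engine = "lme4", reml = FALSE)
  expect_equal(fpm$coef, flm$coef, tolerance = 1e-6)
  expect_equal(fpm$loglik, flm$loglik, tolerance = 1e-6)
})

test_that("balanced intercept-only fit returns the grand mean exactly", {
  d <- make_lmm_data(3)
  f <- fit_lmm(d, "y", character(0), "participant_id")
  expect_equal(unname(f$coef[1]), mean(d$y), tolerance = 1e-10)
})

test_that("constant response yields zero slopes and zero variance components", {
  d <- make_lmm_data(4)
  d$y <- 7
  f <- fit_lmm(d, "y", c("x1", "x2"), "participant_id")
  expect_equal(unname(f$coef), c(7, 0, 0), tolerance = 1e-9)
  expect_equal(unname(f$var_components), 0)
  expect_equal(f$resid_var, 0)
})

test_that("row order does not change the estimates", {
  d <- make_lmm_data(5)
  f1 <- fit_lmm(d, "y", c("x1", "x2", "grp"), "participant_id")
  set.seed(99)
  f2 <- fit_lmm(d[sample(nrow(d)), ], "y", c("x1", "x2", "grp"),
                "participant_id")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
})

test_that("collinear fixed terms raise an error naming the aliased column", {
  d <- make_lmm_data(6)
  d$x3 <- d$x1
  expect_error(fit_lmm(d, "y", c("x1", "x2", "x3"), "participant_id"),
               "aliased.*x3")
})

test_that("a single grouping level falls back to OLS with a warning", {
  d <- make_lmm_data(7)
  d$participant_id <- "P001"
  expect_warning(f <- fit_lmm(d, "y", c("x1", "x2"), "participant_id"),
                 "ordinary least squares")
  ols <- lm(y ~ x1 + x2, data = d)
  expect_equal(unname(f$coef), unname(coef(ols)), tolerance = 1e-9)
  expect_equal(unname(f$var_components), 0)
})

test_that("complete-case rows are dropped and counted", {
  d <- make_lmm_data(8)
  d$y[1:3] <- NA
  d$x1[4] <- NA
  f <- fit_lmm(d, "y", c("x1", "x2"), "participant_id")
  expect_equal(f$n_dropped, 4L)
  expect_equal(f$n_obs, nrow(d) - 4L)
})

test_that("treatment effect on the mediator is recovered on average", {
  ests <- vapply(1:20, function(s) {
    p <- small_panel(seed = 100 + s)
    f <- fit_lmm(p[p$analyzable, ], "cd_risc",
                 c("treatment", "cluster", "gender", "profession", "age",
                   "contract", "trainee", "pss_baseline"),
                 "participant_id")
    unname(f$coef["treatment"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2.62), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("two-grouping fits estimate both variance components", {
  set.seed(20)
  np <- 60; nw <- 4
  cl <- rep(rep(1:6, each = 10), each = nw)
  g <- rep(seq_len(np), each = nw)
  d <- data.frame(participant_id = g, cluster = cl, x = rnorm(np * nw))
  d$y <- 2 + 0.5 * d$x + rep(rnorm(6, 0, 2), each = 10 * nw)[seq_len(np * nw)] +
    rep(rnorm(np, 0, 1.5), each = nw) + rnorm(np * nw)
  f <- fit_lmm(d, "y", "x", c("participant_id", "cluster"))
  expect_named(f$var_components, c("participant_id", "cluster"))
  expect_true(all(f$var_components >= 0))
  expect_equal(unname(f$n_groups), c(60L, 6L))
})
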