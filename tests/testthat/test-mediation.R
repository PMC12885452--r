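test_that("bootstrap indirect point estimate equals the full-sample product exactly", {
  p <- small_panel(seed = 21)
  spec <- model_spec("pss", "cd_risc")
  ep <- estimate_paths(p, spec)
  res <- bootstrap_mediation(p, spec, n_boot = 100, seed = 7)
  expect_identical(res$indirect$estimate, unname(ep$a * ep$b))
  expect_identical(res$a$estimate, unname(ep$a))
  expect_identical(res$b$estimate, unname(ep$b))
  expect_identical(res$direct$estimate, ep$direct)
})

test_that("negating mediator and outcome flips a and the indirect effect, not b", {
  p <- small_panel(seed = 22)
  spec <- model_spec("pss", "cd_risc")
  ep <- estimate_paths(p, spec)
  q <- p
  q$cd_risc <- -q$cd_risc
  q$pss <- -q$pss
  q$pss_baseline <- -q$pss_baseline
  eq <- estimate_paths(q, spec)
  expect_equal(unname(eq$a), -unname(ep$a), tolerance = 1e-8)
  expect_equal(unname(eq$b), unname(ep$b), tolerance = 1e-8)
  expect_equal(unname(eq$indirect), -unname(ep$indirect), tolerance = 1e-8)
  expect_equal(eq$direct, -ep$direct, tolerance = 1e-8)
})

test_that("percentile CI endpoints equal brute-force sorted quantiles of the draws", {
  p <- small_panel(seed = 23)
  res <- bootstrap_mediation(p, model_spec("pss", "cd_risc"),
                             n_boot = 150, seed = 3)
  expect_equal(res$indirect$ci,
               quantile_brute(res$draws, c(0.025, 0.975)), tolerance = 1e-12)
  expect_lte(res$indirect$ci[1], res$indirect$ci[2])
  # nearest-rank convention is available too
  res1 <- bootstrap_mediation(p, model_spec("pss", "cd_risc"),
                              n_boot = 150, seed = 3, quantile_type = 1)
  expect_equal(res1$indirect$ci,
               unname(quantile(res$draws, c(0.025, 0.975), type = 1)))
})

test_that("sign-crossing p-value follows the two-sided definition", {
  expect_identical(boot_p(c(-3, -2, -1, -0.5)), 0)
  expect_identical(boot_p(c(-2, -1, 1, 2)), 1)
  expect_equal(boot_p(c(-1, rep(1, 9))), 0.2)
  expect_equal(boot_p(rep(0.5, 10)), 0)
})

test_that("same seed reproduces draws bit-for-bit, across worker counts", {
  p <- small_panel(seed = 24)
  spec <- model_spec("pss", "cd_risc")
  r1 <- bootstrap_mediation(p, spec, n_boot = 100, seed = 11, workers = 1)
  r2 <- bootstrap_mediation(p, spec, n_boot = 100, seed = 11, workers = 1)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$indirect, r2$indirect)
  r3 <- bootstrap_mediation(p, spec, n_boot = 100, seed = 11, workers = 2)
  expect_identical(r1$draws, r3$draws)
  r4 <- bootstrap_mediation(p, spec, n_boot = 100, seed = 12)
  expect_false(identical(r1$draws, r4$draws))
})

test_that("cluster-stratified resampling preserves cluster sizes in every draw", {
  p <- small_panel(seed = 25)
  spec <- model_spec("pss", "cd_risc")
  prep <- swmediate:::prepare_mediation(p, spec)
  sel <- swmediate:::draw_selection(prep, 123L)
  expect_equal(unname(table(prep$cluster_of[sel])),
               unname(table(prep$cluster_of)))
})

test_that("n_boot below 100 and multivariate specs are rejected upfront", {
  p <- small_panel(seed = 26)
  expect_error(bootstrap_mediation(p, model_spec("pss", "cd_risc"), n_boot = 50),
               "at least 100")
  expect_error(bootstrap_mediation(p, model_spec("pss", c("cd_risc", "aaq2")),
                                   n_boot = 100), "univariate")
  expect_error(multivariate_mediation(p, "cd_risc", "pss", n_boot = 100),
               ">= 2 mediators")
})

test_that("a duplicated mediator column raises a collinearity error naming both", {
  p <- small_panel(seed = 27)
  p$socs_self <- p$cd_risc
  expect_error(
    multivariate_mediation(p, c("cd_risc", "socs_self"), "pss", n_boot = 100),
    "collinear mediators.*cd_risc.*socs_self")
})

test_that("joint two-mediator model recovers both paths and their sum", {
  # cd_risc carries the effect; socs_self has a null a-path but a real b-path
  reps <- t(sapply(1:12, function(s) {
    cfg <- small_config(seed = 400 + s, mediators = c("cd_risc", "socs_self"),
                        a_path = c(cd_risc = 2.62, socs_self = 0),
                        b_path = c(cd_risc = -0.48, socs_self = -0.2))
    p <- attach_baseline(generate_trial(cfg), "pss")
    ep <- estimate_paths(p, model_spec("pss", c("cd_risc", "socs_self")))
    c(ind1 = unname(ep$indirect["cd_risc"]),
      ind2 = unname(ep$indirect["socs_self"]),
      total = sum(ep$indirect))
  }))
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  mu <- colMeans(reps)
  expect_lt(abs(mu["ind1"] - 2.62 * -0.48), 3 * se["ind1"])
  expect_lt(abs(mu["ind2"]), 3 * se["ind2"])
  expect_lt(abs(mu["total"] - 2.62 * -0.48), 3 * se["total"])
})

test_that("multivariate bootstrap returns one internally consistent row per mediator", {
  cfg <- small_config(seed = 28, mediators = c("cd_risc", "aaq2"),
                      a_path = c(cd_risc = 2.62, aaq2 = -0.4),
                      b_path = c(cd_risc = -0.48, aaq2 = 0.3))
  p <- attach_baseline(generate_trial(cfg), "pss")
  res <- multivariate_mediation(p, c("cd_risc", "aaq2"), "pss",
                                n_boot = 100, seed = 5)
  expect_length(res$paths, 2L)
  for (m in res$mediators) {
    s <- res$paths[[m]]
    expect_identical(s$indirect$estimate, s$a$estimate * s$b$estimate)
    expect_equal(s$indirect$ci,
                 quantile_brute(res$all_draws[, paste0("ind.", m)],
                                c(0.025, 0.975)), tolerance = 1e-12)
  }
})

test_that("sensitivity S1 filters on univariate p and S2 picks one mediator per family", {
  # univariate indirect-effect p-value pattern of the concurrent analyses
  tab <- data.frame(
    mediator = c("cd_risc", "ffmq_observe", "ffmq_describe", "ffmq_nonreact",
                 "ffmq_act", "ffmq_nonjudge", "socs_other", "socs_self", "aaq2"),
    p = c(0.02, 0.04, 0.02, 0.01, 0.96, 0.85, 0.82, 0.23, 0.70),
    indirect = c(-1.41, -0.54, -0.77, -0.73, 0.03, -0.09, 0.03, -0.55, -0.22))
  norm <- swmediate:::normalize_univariate(tab)
  expect_equal(norm$mediator[norm$p < 0.05],
               c("cd_risc", "ffmq_observe", "ffmq_describe", "ffmq_nonreact"))
  sel <- swmediate:::select_per_family(norm, default_family_map())
  expect_setequal(sel, c("cd_risc", "ffmq_nonreact", "socs_self", "aaq2"))
  # ties: smaller p wins; equal p broken by larger |indirect|, then name
  tie <- data.frame(mediator = c("ffmq_observe", "ffmq_describe"),
                    p = c(0.02, 0.02), indirect = c(-0.54, -0.77))
  expect_equal(swmediate:::select_per_family(tie, default_family_map()),
               "ffmq_describe")
})

test_that("sensitivity models run end-to-end and report an empty S1 gracefully", {
  p <- small_panel(seed = 29)
  tab <- data.frame(mediator = c("cd_risc", "ffmq_observe", "socs_self", "aaq2"),
                    p = c(0.01, 0.03, 0.50, 0.70),
                    indirect = c(-1.2, -0.5, -0.1, -0.05))
  sm <- sensitivity_models(p, tab, "pss", n_boot = 100, seed = 2)
  expect_equal(sm$s1_mediators, c("cd_risc", "ffmq_observe"))
  expect_setequal(sm$s2_mediators,
                  c("cd_risc", "ffmq_observe", "socs_self", "aaq2"))
  expect_s3_class(sm$s1, "multivariate_mediation_result")

  tab$p <- c(0.5, 0.6, 0.7, 0.8)
  sm2 <- sensitivity_models(p, tab, "pss", n_boot = 100, seed = 2)
  expect_s3_class(sm2$s1, "empty_mediation_result")
  expect_match(sm2$s1$message, "no mediator")
  expect_s3_class(sm2$s2, "multivariate_mediation_result")
})

test_that("row-level resampling is available as an explicit comparison flag", {
  p <- small_panel(seed = 30)
  res <- bootstrap_mediation(p, model_spec("pss", "cd_risc"),
                             n_boot = 100, seed = 4, resample_unit = "row")
  expect_equal(res$resample_unit, "row")
  expect_length(res$draws, res$n_boot_used)
})
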