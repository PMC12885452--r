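test_that("default design expands to 347 participants x 5 waves with control start", {
  d <- make_design(sim_config())
  expect_equal(nrow(d), 347L * 5L)
  expect_equal(length(unique(d$participant_id)), 347L)
  expect_equal(unname(table(d$cluster[d$wave == 1])),
               c(81L, 48L, 60L, 75L, 57L, 26L), ignore_attr = TRUE)
  expect_true(all(d$treatment[d$wave == 1] == 0L))
  expect_equal(sort(unique(d$time_weeks)), c(0, 8, 16, 24, 32))
})

test_that("treatment switches at the sequence crossover and never reverts", {
  d <- make_design(tiny_config())
  seq1 <- d[d$sequence == 1 & d$participant_id == d$participant_id[d$sequence == 1][1], ]
  expect_equal(seq1$treatment[order(seq1$wave)], c(0L, 1L, 1L, 1L, 1L))
  seq3 <- d[d$sequence == 3, ]
  first3 <- seq3[seq3$participant_id == seq3$participant_id[1], ]
  expect_equal(first3$treatment[order(first3$wave)], c(0L, 0L, 0L, 1L, 1L))
  mono <- tapply(d$treatment[order(d$participant_id, d$wave)],
                 d$participant_id[order(d$participant_id, d$wave)],
                 function(x) all(diff(x) >= 0))
  expect_true(all(mono))
})

test_that("current-program treatment coding opens and closes the exposure window", {
  d <- make_design(tiny_config(treatment_coding = "current"))
  seq1 <- d[d$sequence == 1, ]
  one <- seq1[seq1$participant_id == seq1$participant_id[1], ]
  # crossover at week 8, 8-week program: only the wave at week 8 is exposed
  expect_equal(one$treatment[order(one$wave)], c(0L, 1L, 0L, 0L, 0L))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(cluster_sizes = c(10, 0)), "cluster_sizes")
  expect_error(sim_config(crossover_weeks = c(8, 8, 24)), "crossover_weeks")
  expect_error(sim_config(n_waves = 1), "n_waves")
  expect_error(sim_config(sd_resid_outcome = 0), "sd_resid_outcome")
  expect_error(sim_config(dropout_hazard_per_wave = 1), "dropout_hazard")
  expect_error(sim_config(sequence_of_cluster = c(1, 2, 3, 1, 2, 9)),
               "sequence_of_cluster")
  expect_error(sim_config(mediators = "nope"), "mediators")
})

test_that("true paths are exact products and a zero factor nulls the indirect effect", {
  tp <- true_paths(sim_config(a_path = 2.62, b_path = -0.48, c_prime = -2.77))
  expect_identical(unname(tp$indirect), 2.62 * -0.48)
  expect_identical(tp$total, -2.77 + 2.62 * -0.48)
  expect_equal(unname(true_paths(sim_config(a_path = 0))$indirect), 0)
  expect_equal(unname(true_paths(sim_config(b_path = 0))$indirect), 0)
})

test_that("identical seeds give bit-identical panels; different seeds differ", {
  p1 <- generate_trial(tiny_config(seed = 42))
  p2 <- generate_trial(tiny_config(seed = 42))
  expect_identical(p1, p2)
  p3 <- generate_trial(tiny_config(seed = 43))
  expect_false(identical(p1$cd_risc, p3$cd_risc))
})

test_that("treated-minus-control mediator difference matches the injected a-path", {
  # near-noiseless generator: closed-form expectation is a * treatment
  cfg <- small_config(seed = 2, a_path = 2.62,
                      sd_participant_mediator = 0, sd_participant_outcome = 0,
                      sd_resid_mediator = 0.01, sd_resid_outcome = 0.01)
  p <- generate_trial(cfg)
  w3 <- p[p$wave == 3, ]
  diff3 <- mean(w3$cd_risc[w3$treatment == 1]) - mean(w3$cd_risc[w3$treatment == 0])
  expect_equal(diff3, 2.62, tolerance = 0.01)
})

test_that("participant mean-score variance matches intercept + residual/n_waves", {
  cfg <- sim_config(cluster_sizes = 2000L, sequence_of_cluster = 1L,
                    a_path = 0, time_slope_mediator = 0, seed = 9)
  p <- generate_trial(cfg)
  v <- var(tapply(p$cd_risc, p$participant_id, mean))
  expected <- cfg$sd_participant_mediator^2 + cfg$sd_resid_mediator^2 / cfg$n_waves
  expect_equal(v, expected, tolerance = 0.1)
})

test_that("configurations round-trip through YAML", {
  cfg <- small_config(seed = 17, mediators = c("cd_risc", "aaq2"),
                      a_path = c(cd_risc = 2.62, aaq2 = -0.4),
                      b_path = c(cd_risc = -0.48, aaq2 = 0.3),
                      covariate_effects = c(age = -0.05))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
  expect_identical(generate_trial(cfg2), generate_trial(cfg))
})

test_that("score clipping respects instrument ranges only when requested", {
  cfg <- tiny_config(seed = 3, clip_to_range = TRUE,
                     a_path = 30)  # force excursions above the CD-RISC cap
  p <- generate_trial(cfg)
  expect_true(all(p$cd_risc <= 40 & p$cd_risc >= 0))
  expect_true(all(p$pss <= 40 & p$pss >= 0))
  p2 <- generate_trial(tiny_config(seed = 3, a_path = 30))
  expect_true(any(p2$cd_risc > 40))
})

test_that("dropout is monotone, spares wave 1, and matches geometric retention", {
  p <- generate_trial(tiny_config(seed = 4))
  expect_identical(apply_dropout(p, 0), p)
  expect_error(apply_dropout(p, 1.2), "hazard")

  cfg <- sim_config(cluster_sizes = 1000L, sequence_of_cluster = 1L, seed = 5)
  big <- generate_trial(cfg)
  dp <- apply_dropout(big, 0.2, seed = 6)
  expect_equal(sum(dp$wave == 1), 1000L)
  # monotone: observed waves per participant are a prefix 1..k
  pref <- tapply(dp$wave, dp$participant_id,
                 function(w) identical(sort(w), seq_along(w)))
  expect_true(all(pref))
  ret5 <- sum(dp$wave == 5) / 1000
  expect_equal(ret5, 0.8^4, tolerance = 4 * sqrt(0.4096 * 0.5904 / 1000))
  # reproducible under the same seed
  expect_identical(dp, apply_dropout(big, 0.2, seed = 6))
})
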