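test_that("judgment errors map wrapped angles onto the clock period", {
  expect_equal(judgment_error_ms(90, 135, 2560), 45 / 360 * 2560)  # +320 ms
  expect_equal(judgment_error_ms(120, 120), 0)
  # wrap across 0 degrees: 350 -> 10 is +20 degrees, not -340
  expect_equal(judgment_error_ms(350, 10, 2560), 20 / 360 * 2560,
               tolerance = 1e-12)
  # against an unwrapped oracle tracking cumulative dot angle
  unwrapped_err <- function(actual, reported_cum, period)
    (reported_cum - actual) / 360 * period
  expect_equal(judgment_error_ms(350, 10, 2560), unwrapped_err(350, 370, 2560))
  # antisymmetry
  set.seed(6)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  expect_equal(judgment_error_ms(a, b), -judgment_error_ms(b, a),
               tolerance = 1e-9)
})

test_that("noiseless injected shifts are recovered exactly", {
  trials <- generate_trials(trial_sim_config(action_shift_ms = 40,
                                             tone_shift_ms = -30,
                                             judgment_noise_sd_ms = 0, seed = 3))
  sc <- binding_scores(trials, "s1")
  expect_equal(sc$action_binding_ms, 40, tolerance = 1e-9)
  expect_equal(sc$tone_binding_ms, -30, tolerance = 1e-9)
  expect_equal(sc$total_binding_ms, 70, tolerance = 1e-9)
  zero <- generate_trials(trial_sim_config(judgment_noise_sd_ms = 0, seed = 3))
  sz <- binding_scores(zero, "s2")
  expect_equal(sz$total_binding_ms, 0, tolerance = 1e-9)
})

test_that("binding scores are order invariant and respect shift linearity", {
  trials <- generate_trials(trial_sim_config(action_shift_ms = 25,
                                             tone_shift_ms = -10, seed = 8))
  sc1 <- binding_scores(trials, "s")
  set.seed(1)
  sc2 <- binding_scores(trials[sample(nrow(trials)), ], "s")
  expect_equal(sc1$total_binding_ms, sc2$total_binding_ms)
  # adding c to every agency action report shifts action binding by c ms
  c_deg <- 9  # 64 ms at 2560 ms period
  shifted <- trials
  sel <- shifted$condition == "agency_judge_action"
  shifted$reported_deg[sel] <- (shifted$reported_deg[sel] + c_deg) %% 360
  sc3 <- binding_scores(shifted, "s")
  expect_equal(sc3$action_binding_ms - sc1$action_binding_ms,
               c_deg / 360 * 2560, tolerance = 1e-9)
})

test_that("missing reports are excluded with counts; empty conditions error", {
  trials <- generate_trials(trial_sim_config(seed = 5))
  trials$reported_deg[trials$condition == "action_only"][1:3] <- NA
  sc <- binding_scores(trials, "s")
  expect_equal(sc$n_action_only, 17)
  expect_equal(sc$n_excluded, 3)
  bad <- trials[trials$condition != "tone_only", ]
  expect_error(binding_scores(bad, "s"), "tone_only")
})

test_that("group table reports mean and sample SD per measure", {
  two <- data.frame(subject = c("a", "b"), group = "G",
                    action_binding_ms = c(0, 0), tone_binding_ms = c(0, 0),
                    total_binding_ms = c(100, 140))
  tab <- group_binding_table(two)
  tot <- tab[tab$measure == "total", ]
  expect_equal(tot$mean, 120)
  expect_equal(tot$sd, sqrt((20^2 + 20^2) / 1), tolerance = 1e-9)  # 28.28
  same <- data.frame(subject = c("a", "b", "c"), group = "G",
                     action_binding_ms = 5, tone_binding_ms = -2,
                     total_binding_ms = 7)
  expect_true(all(group_binding_table(same)$sd == 0))
  one <- data.frame(subject = "a", group = "G", action_binding_ms = 1,
                    tone_binding_ms = 1, total_binding_ms = 0)
  expect_true(all(is.na(group_binding_table(one)$sd)))
})

test_that("noisy shifts are recovered within 2 SEM over 200 replicates", {
  tot <- vapply(1:200, function(seed) {
    tr <- generate_trials(trial_sim_config(action_shift_ms = 40,
                                           tone_shift_ms = -30,
                                           judgment_noise_sd_ms = 70,
                                           seed = seed))
    binding_scores(tr, "s")$total_binding_ms
  }, numeric(1))
  sem <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 70), 2 * sem)
})

test_that("group-level simulation recovers the injected group means", {
  means <- c(SCR = 123, SLR = 51, CTR = 82)
  sds <- c(SCR = 75, SLR = 41, CTR = 54)
  set.seed(20)
  n <- 30
  for (g in names(means)) {
    true_ttb <- rnorm(n, means[[g]], sds[[g]])
    tot <- vapply(seq_len(n), function(i) {
      tr <- generate_trials(trial_sim_config(
        action_shift_ms = true_ttb[i] / 2, tone_shift_ms = -true_ttb[i] / 2,
        judgment_noise_sd_ms = 70, seed = 1000 * match(g, names(means)) + i))
      binding_scores(tr, "s")$total_binding_ms
    }, numeric(1))
    # the recovered group mean tracks the realised subject-level mean to
    # within 2 SEM of the per-subject measurement error
    meas_err <- tot - true_ttb
    expect_lt(abs(mean(tot) - mean(true_ttb)), 2 * sd(meas_err) / sqrt(n))
  }
})
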