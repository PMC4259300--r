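test_that("the hard slow cutoff removes strictly slower trials only", {
  trials <- make_session(list("2" = c(800, 10500, 900, 10000)))

  kept <- filter_slow_trials(trials, 10000)
  expect_equal(kept$latency_ms, c(800, 900, 10000))  # 10000 exactly stays
  expect_equal(attr(kept, "removed"), 1L)

  none <- filter_slow_trials(trials, 100)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "removed"), 4L)
})

test_that("warm-up removal drops the first four trials of scored blocks", {
  one_block <- make_session(list("2" = seq(500, 500 + 19 * 10, by = 10)))
  kept <- remove_warmup_trials(one_block)
  expect_equal(nrow(kept), 16)
  expect_true(all(kept$trial_index >= 4))

  session <- make_session(list("2" = rep(600, 20), "3" = rep(700, 20),
                               "4" = rep(600, 20), "5" = rep(700, 20)))
  kept <- remove_warmup_trials(session)
  expect_equal(nrow(kept), 64)                       # 20% reduction from 80
  expect_equal(attr(kept, "removed"), 16L)

  tiny <- make_session(list("2" = rep(600, 4)))
  expect_equal(nrow(remove_warmup_trials(tiny)), 0)

  practice <- make_session(list("1" = rep(600, 16)))
  expect_equal(nrow(remove_warmup_trials(practice)), 16)  # block 1 untouched
})

test_that("tail treatments recode or delete strictly beyond the boundary", {
  trials <- make_session(list("2" = c(350, 450, 400)))
  recoded <- apply_tail_treatment(trials, 400, "fast", "recode")
  expect_equal(recoded$latency_ms, c(400, 450, 400))
  expect_equal(attr(recoded, "recoded"), 1L)

  slow <- make_session(list("2" = c(1900, 2600, 2000)))
  deleted <- apply_tail_treatment(slow, 2000, "slow", "delete")
  expect_equal(deleted$latency_ms, c(1900, 2000))    # exactly 2000 stays
  expect_equal(attr(deleted, "removed"), 1L)

  recoded_slow <- apply_tail_treatment(slow, 2000, "slow", "recode")
  expect_equal(recoded_slow$latency_ms, c(1900, 2000, 2000))
})

test_that("recoding is idempotent, preserves cardinality; deletion subsets", {
  sim <- simulate_biat(biat_sim_params(n_subjects = 6), seed = 4)
  trials <- sim$trials

  once <- apply_tail_treatment(trials, 2000, "slow", "recode")
  twice <- apply_tail_treatment(once, 2000, "slow", "recode")
  expect_equal(once$latency_ms, twice$latency_ms)
  expect_equal(nrow(once), nrow(trials))

  cut <- apply_tail_treatment(trials, 2000, "slow", "delete")
  expect_lte(nrow(cut), nrow(trials))
  expect_true(all(cut$latency_ms %in% trials$latency_ms))
})

test_that("error-trial policy retains as-is or drops flagged trials", {
  trials <- make_session(list("2" = seq(500, 590, by = 10)))
  trials$error <- c(TRUE, TRUE, rep(FALSE, 8))

  expect_identical(handle_error_trials(trials, "retain")$latency_ms,
                   trials$latency_ms)
  removed <- handle_error_trials(trials, "remove")
  expect_equal(nrow(removed), 8)
  expect_false(any(removed$error))

  all_err <- dplyr::mutate(trials, error = TRUE)
  expect_equal(nrow(handle_error_trials(all_err, "remove")), 0)
})

test_that("fast fraction and error rate are direct counts", {
  trials <- make_session(list("2" = c(rep(250, 3), rep(600, 17))))
  expect_equal(compute_fast_fraction(trials, 300), 0.15)
  expect_equal(compute_fast_fraction(trials, 200), 0)

  set.seed(42)
  lat <- runif(64, 400, 900)
  fast_idx <- sample(64, 10)
  lat[fast_idx] <- runif(10, 150, 290)
  gen <- make_session(list("2" = lat))
  expect_equal(compute_fast_fraction(gen, 300),
               sum(lat < 300) / 64)        # brute-force count
  expect_equal(sum(lat < 300), 10)

  err <- make_session(list("2" = rep(600, 16)))
  err$error <- rep(c(TRUE, FALSE), c(4, 12))
  expect_equal(compute_error_rate(err), 0.25)
  expect_equal(compute_error_rate(handle_error_trials(err, "remove")), 0)

  set.seed(7)
  flags <- rbinom(64, 1, 0.5) == 1
  bern <- dplyr::mutate(make_session(list("2" = rep(600, 64))), error = flags)
  expect_equal(compute_error_rate(bern), mean(flags))

  empty <- make_session(list("2" = numeric(0)))
  expect_error(compute_fast_fraction(empty), "zero trials")
  expect_error(compute_error_rate(empty), "zero trials")
})

test_that("respondent exclusion uses strict thresholds and names the rule", {
  config <- biat_config(error_exclusion_threshold = 0.30)

  fast15 <- make_session(list("2" = c(rep(250, 3), rep(600, 17))))
  expect_equal(apply_respondent_exclusions(fast15, config),
               list(exclude = TRUE, reason = "fast"))

  fast10 <- make_session(list("2" = c(rep(250, 2), rep(600, 18))))
  expect_false(apply_respondent_exclusions(fast10, config)$exclude)  # exactly 10%

  erry <- make_session(list("2" = rep(600, 20)))
  erry$error <- rep(c(TRUE, FALSE), c(7, 13))                        # 35%
  expect_equal(apply_respondent_exclusions(erry, config),
               list(exclude = TRUE, reason = "error"))
  expect_false(
    apply_respondent_exclusions(erry, biat_config())$exclude)        # no error rule
})

test_that("manifest counts reconcile for a generated population", {
  sim <- simulate_biat(biat_sim_params(n_subjects = 40), seed = 13)
  scores <- score_sessions(sim$trials, biat_config(
    error_trials = "remove", slow_mode = "delete"))
  counts <- run_manifest(scores)$counts
  get <- function(s) counts$trials[counts$stage == s]
  expect_equal(
    get("input"),
    get("practice_block_set_aside") + get("slow_cutoff_removed") +
      get("warmup_removed") + get("error_removed") +
      get("fast_tail_removed") + get("slow_tail_removed") +
      get("retained_for_scoring")
  )
})

test_that("exclusion masks scores without changing retained values", {
  sim <- simulate_biat(biat_sim_params(n_subjects = 25,
                                       contaminant_fraction = 0.2), seed = 17)
  with_excl <- score_sessions(sim$trials, biat_config())
  without_excl <- score_sessions(sim$trials,
                                 biat_config(fast_exclusion_threshold = NULL))
  kept <- !with_excl$excluded
  expect_true(any(!kept))
  expect_equal(with_excl$score[kept], without_excl$score[kept])
  expect_equal(with_excl$pair1_score, without_excl$pair1_score)
})

test_that("recode-then-score differs from score-then-recode ordering", {
  # a session with slow-tail outliers: clipping before scoring must matter
  session <- make_standard_session(m1 = 700, m2 = 1200, spread = 900)
  clipped <- score_sessions(session, plain_config(slow_boundary_ms = 2000))
  raw <- score_sessions(session, plain_config())
  expect_false(isTRUE(all.equal(clipped$score, raw$score)))
})

test_that("configuration invariants are enforced", {
  expect_error(biat_config(fast_boundary_ms = 2500), "below")
  expect_error(biat_config(fast_exclusion_threshold = 1.2), "0, 1")
  expect_error(biat_config(slow_hard_cutoff_ms = -1), "positive")
})

test_that("configs round-trip through YAML", {
  config <- biat_config(error_trials = "remove", slow_boundary_ms = 3000,
                        slow_mode = "delete",
                        error_exclusion_threshold = 0.30)
  path <- withr::local_tempfile(fileext = ".yml")
  write_biat_config(config, path)
  back <- read_biat_config(path)
  expect_equal(unclass(back), unclass(config))
})
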