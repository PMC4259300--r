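test_that("Fisher-z averaging has its closed-form fixed points", {
  expect_equal(fisher_z_average(c(0.5, 0.5)), 0.5)
  expect_equal(fisher_z_average(c(0, 0.8)), 0.5)       # tanh(ln(3)/2) = 1/2
  expect_equal(fisher_z_average(c(-0.6, 0.6)), 0)
  expect_error(fisher_z_average(c(0.2, 1)), "\\|r\\| < 1")
})

test_that("Fisher-z average is bounded by its inputs and near-linear for small r", {
  set.seed(11)
  for (i in 1:50) {
    rs <- runif(sample(2:6, 1), -0.95, 0.95)
    avg <- fisher_z_average(rs)
    expect_gte(avg, min(rs))
    expect_lte(avg, max(rs))
  }
  small <- c(0.01, 0.03, -0.02)
  expect_equal(fisher_z_average(small), mean(small), tolerance = 1e-3)
})

test_that("split-half consistency recovers identity and Spearman-Brown", {
  h <- tibble::tibble(pair1_score = c(0.1, 0.5, 0.9, 0.3, 0.7))
  h$pair2_score <- h$pair1_score
  res <- split_half_consistency(h)
  expect_equal(res$half_r, 1)
  expect_equal(res$alpha, 1)

  # halves standardized by construction with an exact target correlation
  set.seed(23)
  n <- 400
  r_target <- 0.6
  z1 <- as.numeric(scale(rnorm(n)))
  e <- rnorm(n)
  e <- as.numeric(scale(residuals(lm(e ~ z1))))
  z2 <- r_target * z1 + sqrt(1 - r_target^2) * e
  halves <- tibble::tibble(pair1_score = z1, pair2_score = z2)
  res <- split_half_consistency(halves)
  expect_equal(res$half_r, 0.6, tolerance = 1e-10)
  expect_equal(res$spearman_brown, 2 * 0.6 / 1.6, tolerance = 1e-10)
  # equal-variance halves: Cronbach alpha coincides with Spearman-Brown
  expect_equal(res$alpha, res$spearman_brown, tolerance = 1e-10)
})

test_that("independent halves correlate near zero", {
  set.seed(29)
  halves <- tibble::tibble(pair1_score = rnorm(5000),
                           pair2_score = rnorm(5000))
  expect_lt(abs(split_half_consistency(halves)$half_r), 0.05)
})

test_that("split-half consistency rejects degenerate input", {
  expect_error(split_half_consistency(
    tibble::tibble(pair1_score = 1:2, pair2_score = 2:1)), "at least 3")
  expect_error(split_half_consistency(
    tibble::tibble(pair1_score = rep(1, 5), pair2_score = rnorm(5))),
    "zero variance")
})

test_that("main-effect d behaves like a standardized mean", {
  sym <- tibble::tibble(score = c(-0.4, -0.2, 0, 0.2, 0.4))
  expect_equal(main_effect_d(sym), 0)

  set.seed(5)
  x <- rnorm(50, 1, 2)
  d0 <- main_effect_d(tibble::tibble(score = x))
  dk <- main_effect_d(tibble::tibble(score = x + 3))
  expect_equal(dk, d0 + 3 / sd(x))

  sim <- simulate_biat(
    biat_sim_params(n_subjects = 120, mu_effect = -80,
                    contaminant_fraction = 0), seed = 67)
  scores <- score_sessions(sim$trials)
  expect_lt(main_effect_d(scores), 0)   # recovers the sign of the effect
})

test_that("criterion correlations join, code, and average correctly", {
  scores <- tibble::tibble(
    session_id = sprintf("s%03d", 1:40),
    score = rnorm(40)
  )
  covars <- tibble::tibble(
    session_id = scores$session_id,
    self = scores$score,                        # r = 1
    group = factor(rep(c("a", "b"), 20)),       # point-biserial path
    sparse = c(scores$score[1:2], rep(NA, 38))  # < 3 complete pairs
  )
  res <- criterion_correlations(scores, covars)
  expect_equal(res$r[res$covariate == "self"], 1)
  expect_true(is.na(res$r[res$covariate == "sparse"]))
  expect_equal(res$n[res$covariate == "sparse"], 2)
  expect_true(is.finite(res$r[res$covariate == "group"]))
  expect_true(is.finite(attr(res, "fisher_z_average")))
})

test_that("a permuted covariate correlates near zero", {
  set.seed(31)
  scores <- tibble::tibble(session_id = as.character(1:5000),
                           score = rnorm(5000))
  covars <- tibble::tibble(session_id = scores$session_id,
                           shuffled = sample(scores$score))
  res <- criterion_correlations(scores, covars)
  expect_lt(abs(res$r), 0.05)
})

test_that("LOC bins are near-equal, deterministic, and standardized", {
  expect_equal(biatscore:::loc_bin_sizes(23, 10),
               c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  set.seed(37)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    k <- sample(2:10, 1)
    sizes <- biatscore:::loc_bin_sizes(n, k)
    expect_equal(sum(sizes), n)
    expect_lte(max(sizes) - min(sizes), 1)
  }

  scores <- tibble::tibble(
    session_id = sprintf("s%03d", 1:23),
    score = rnorm(23, 0.5, 0.3),
    mean_latency_ms = runif(23, 500, 1500),
    excluded = FALSE
  )
  loc <- latency_operating_characteristic(scores)
  expect_equal(loc$n, c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  expect_equal(loc$d, loc$mean_score / sd(scores$score))
  expect_true(!is.unsorted(loc$mean_latency))
})

test_that("LOC is flat when scores are independent of speed", {
  set.seed(41)
  n <- 2000
  scores <- tibble::tibble(
    session_id = sprintf("s%04d", 1:n),
    score = rnorm(n, 0.4, 0.5),
    mean_latency_ms = runif(n, 500, 1500)
  )
  loc <- latency_operating_characteristic(scores)
  overall <- mean(scores$score) / sd(scores$score)
  expect_lt(max(abs(loc$d - overall)), 0.25)   # bin SE ~ 1/sqrt(200)

  flat <- dplyr::mutate(scores, score = 1)
  expect_error(latency_operating_characteristic(flat), "constant scores")
  expect_error(latency_operating_characteristic(scores[1:5, ]), "at least 10")
})

test_that("stability regression detects and quantifies latency trends", {
  set.seed(43)
  lat <- runif(300, 500, 1500)

  linear <- tibble::tibble(score = 0.002 * lat, mean_latency_ms = lat)
  res <- suppressWarnings(stability_regression(linear))  # exact fit
  expect_equal(res$multiple_R, 1, tolerance = 1e-8)

  x <- (lat - mean(lat)) / 500
  quartic <- tibble::tibble(
    score = 0.5 * x - 0.3 * x^2 + 0.2 * x^3 + 0.4 * x^4 + rnorm(300, 0, 1e-4),
    mean_latency_ms = lat
  )
  expect_gt(stability_regression(quartic)$multiple_R, 0.999)

  set.seed(47)
  null <- tibble::tibble(score = rnorm(5000),
                         mean_latency_ms = runif(5000, 500, 1500))
  res0 <- stability_regression(null)
  expect_lt(res0$multiple_R, 0.06)   # E[R] ~ sqrt(4/n) = 0.028 under the null
  expect_gt(res0$p, 0.001)
})

test_that("stability regression is invariant to affine latency rescaling", {
  set.seed(53)
  scores <- tibble::tibble(score = rnorm(200),
                           mean_latency_ms = runif(200, 500, 1500))
  a <- stability_regression(scores)
  rescaled <- dplyr::mutate(scores,
                            mean_latency_ms = 0.03 * mean_latency_ms - 11)
  b <- stability_regression(rescaled)
  expect_equal(a$multiple_R, b$multiple_R, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("extraneous influence is near zero for speed-independent scores", {
  set.seed(59)
  scores <- tibble::tibble(
    session_id = as.character(1:3000),
    score = rnorm(3000),
    mean_latency_ms = runif(3000, 500, 1500)
  )
  res <- extraneous_influence(scores)
  expect_equal(res$indicator,
               c("mean_latency", "mean_log_latency", "mean_reciprocal"))
  expect_true(all(abs(res$r) < 0.06))
})
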