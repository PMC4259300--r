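#' Parameters for the trial-level BIAT simulator
#'
#' The simulator emulates the statistical structure the scoring pipeline
#' assumes. Each subject i has a true association effect `a_i ~ N(mu_effect,
#' sd_effect)` (additive slowing, in ms, on condition-2 trials) and a
#' multiplicative speed factor `lambda_i`, log-normal with log-scale SD
#' `speed_sd_log`. A trial latency is
#'
#'     lambda_i * (base + a_i * [condition 2]) + lambda_i * exGaussian(mu, sigma, tau)
#'
#' so slower subjects (larger lambda) have proportionally larger trial
#' variance: the mean-variance coupling that makes unstandardized difference
#' scores speed-confounded. Errors occur with probability `error_base_rate`
#' and add an exponential correction delay (mean `error_correction_extra_ms`,
#' also scaled by lambda). A fraction of subjects are fast-guessing
#' contaminants who draw uniform latencies from
#' `contaminant_latency_range_ms` and err on half their trials. A standard
#' normal group covariate correlated with `a_i` at `group_effect_cor`
#' supports known-group sensitivity analyses.
#'
#' @param n_subjects Number of subjects.
#' @param mu_effect,sd_effect Population mean and SD of the true effect, ms.
#' @param base_latency_ms Baseline latency before speed scaling, ms.
#' @param speed_sd_log SD of `log(lambda_i)`.
#' @param noise_mu,noise_sigma,noise_tau Ex-Gaussian trial noise: Gaussian
#'   mean and SD plus exponential tail mean, ms (before speed scaling).
#' @param error_base_rate Per-trial error probability for cooperative
#'   subjects.
#' @param error_correction_extra_ms Mean added latency on error trials, ms.
#' @param group_effect_cor Correlation between `a_i` and the group covariate.
#' @param contaminant_fraction Expected fraction of fast-guessing subjects.
#' @param contaminant_latency_range_ms Length-2 range of contaminant
#'   latencies, ms.
#' @param polarities Focal polarities to administer per subject:
#'   `"good_focal"`, `"bad_focal"`, or both.
#' @param bad_focal_noise_multiplier Optional noise inflation for bad-focal
#'   blocks (polarity is otherwise a pure label).
#' @return An object of class `biat_sim_params`.
#' @export
biat_sim_params <- function(n_subjects = 1000,
                            mu_effect = 60,
                            sd_effect = 80,
                            base_latency_ms = 700,
                            speed_sd_log = 0.25,
                            noise_mu = 0,
                            noise_sigma = 100,
                            noise_tau = 150,
                            error_base_rate = 0.08,
                            error_correction_extra_ms = 300,
                            group_effect_cor = 0.5,
                            contaminant_fraction = 0.05,
                            contaminant_latency_range_ms = c(150, 350),
                            polarities = "good_focal",
                            bad_focal_noise_multiplier = 1) {
  params <- list(
    n_subjects = as.integer(n_subjects),
    mu_effect = mu_effect, sd_effect = sd_effect,
    base_latency_ms = base_latency_ms,
    speed_sd_log = speed_sd_log,
    noise_mu = noise_mu, noise_sigma = noise_sigma, noise_tau = noise_tau,
    error_base_rate = error_base_rate,
    error_correction_extra_ms = error_correction_extra_ms,
    group_effect_cor = group_effect_cor,
    contaminant_fraction = contaminant_fraction,
    contaminant_latency_range_ms = contaminant_latency_range_ms,
    polarities = polarities,
    bad_focal_noise_multiplier = bad_focal_noise_multiplier
  )
  if (params$n_subjects < 1) abort("`n_subjects` must be at least 1.")
  for (field in c("error_base_rate", "contaminant_fraction")) {
    if (params[[field]] < 0 || params[[field]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", field))
    }
  }
  if (abs(params$group_effect_cor) > 1) {
    abort("`group_effect_cor` must lie in [-1, 1].")
  }
  if (params$sd_effect < 0 || params$noise_sigma < 0 || params$noise_tau < 0 ||
      params$speed_sd_log < 0) {
    abort("spread parameters must be non-negative.")
  }
  if (length(params$contaminant_latency_range_ms) != 2 ||
      params$contaminant_latency_range_ms[1] <= 0 ||
      diff(params$contaminant_latency_range_ms) < 0) {
    abort("`contaminant_latency_range_ms` must be an increasing positive pair.")
  }
  if (!all(params$polarities %in% c("good_focal", "bad_focal"))) {
    abort("`polarities` must be drawn from good_focal / bad_focal.")
  }
  structure(params, class = "biat_sim_params")
}

# Minimum generated latency; keeps log/reciprocal transforms defined even in
# deep-left noise draws.
MIN_LATENCY_MS <- 100

#' Simulate a population of BIAT sessions
#'
#' Generates seeded trial-level sessions with the standard block structure
#' (16-trial practice block plus four 20-trial response blocks, each opening
#' with 4 warm-up trials; blocks 2/4 are condition 1 and 3/5 condition 2)
#' and the latency model described in [biat_sim_params()]. Each subject has
#' a deterministic RNG substream derived from `seed`, so enlarging
#' `n_subjects` leaves earlier subjects' data unchanged.
#'
#' @param params A [biat_sim_params()].
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return A list of class `biat_sim`: `trials` (trial tibble, includes the
#'   group covariate duplicated per trial-free `truth` table) and `truth`
#'   (one row per subject: `session_id`, `true_effect_ms`, `speed_factor`,
#'   `group`, `contaminant`).
#' @export
#' @examples
#' sim <- simulate_biat(biat_sim_params(n_subjects = 5), seed = 42)
#' nrow(sim$trials)   # 5 subjects x 96 trials
simulate_biat <- function(params = biat_sim_params(), seed = 1) {
  stopifnot(inherits(params, "biat_sim_params"))
  seed <- as.integer(seed)

  subjects <- purrr::map(seq_len(params$n_subjects), function(i) {
    simulate_subject(i, params, subject_seed(seed, i))
  })

  trials <- purrr::list_rbind(purrr::map(subjects, "trials"))
  truth <- purrr::list_rbind(purrr::map(subjects, "truth"))
  structure(list(trials = trials, truth = truth, seed = seed,
                 params = params),
            class = "biat_sim")
}

# Deterministic, collision-free for < 44,000 subjects at any base seed.
subject_seed <- function(seed, i) {
  (abs(seed) + 48271L * i) %% 2147483647L
}

simulate_subject <- function(i, params, sseed) {
  set.seed(sseed)
  session_id <- sprintf("s%05d", i)

  z1 <- rnorm(1)
  z2 <- rnorm(1)
  a_i <- params$mu_effect + params$sd_effect * z1
  rho <- params$group_effect_cor
  group <- rho * z1 + sqrt(1 - rho^2) * z2
  lambda <- exp(rnorm(1, 0, params$speed_sd_log))
  contaminant <- runif(1) < params$contaminant_fraction

  layout <- biat_block_layout()
  polar_trials <- purrr::map(params$polarities, function(polarity) {
    noise_mult <- if (polarity == "bad_focal") {
      params$bad_focal_noise_multiplier
    } else 1
    blocks <- purrr::map(seq_len(nrow(layout)), function(b) {
      n <- layout$n_trials[b]
      condition <- layout$condition[b] %||% "condition1"
      if (is.na(condition)) condition <- "condition1"
      if (contaminant) {
        lat <- runif(n, params$contaminant_latency_range_ms[1],
                     params$contaminant_latency_range_ms[2])
        err <- rbinom(n, 1, 0.5) == 1
      } else {
        shift <- if (condition == "condition2") a_i else 0
        noise <- rnorm(n, params$noise_mu, params$noise_sigma * noise_mult) +
          rexp(n, rate = 1 / max(params$noise_tau * noise_mult, 1e-9))
        lat <- lambda * (params$base_latency_ms + shift) + lambda * noise
        err <- rbinom(n, 1, params$error_base_rate) == 1
        if (any(err)) {
          lat[err] <- lat[err] +
            lambda * rexp(sum(err), rate = 1 / params$error_correction_extra_ms)
        }
      }
      tibble::tibble(
        session_id = session_id,
        topic = "synthetic",
        focal_polarity = polarity,
        block_index = layout$block_index[b],
        trial_index = seq_len(n) - 1L,
        condition = condition,
        latency_ms = pmax(lat, MIN_LATENCY_MS),
        error = err
      )
    })
    purrr::list_rbind(blocks)
  })

  list(
    trials = purrr::list_rbind(polar_trials),
    truth = tibble::tibble(
      session_id = session_id,
      true_effect_ms = a_i,
      speed_factor = lambda,
      group = group,
      contaminant = contaminant
    )
  )
}

#' @export
print.biat_sim <- function(x, ...) {
  cat(sprintf(
    "<biat_sim> %d subjects, %d trials, %d contaminant(s), seed %d\n",
    nrow(x$truth), nrow(x$trials), sum(x$truth$contaminant), x$seed))
  invisible(x)
}

#' Compare recovered scores with the simulator's hidden truth
#'
#' Joins a score table to a simulation truth table and reports how well the
#' pipeline recovered the generating quantities: the correlation between the
#' computed score and the true association effect among cooperative,
#' non-excluded subjects; the correlation between the score and the
#' subject speed factor (a speed-confound diagnostic); and the precision and
#' recall of the respondent-exclusion rule against the contaminant flag.
#'
#' @param scores A score tibble from [score_sessions()].
#' @param truth The `truth` tibble from [simulate_biat()].
#' @return A list with `effect_cor`, `speed_cor`, `exclusion_precision`,
#'   `exclusion_recall`, and the confusion counts.
#' @export
truth_recovery <- function(scores, truth) {
  joined <- dplyr::inner_join(scores, truth, by = "session_id")
  if (nrow(joined) == 0) {
    abort("scores and truth share no session_id; cannot join.")
  }
  clean <- joined |>
    dplyr::filter(!.data$contaminant, !.data$excluded, !is.na(.data$score))
  effect_cor <- if (nrow(clean) >= 3) {
    cor(clean$score, clean$true_effect_ms)
  } else NA_real_
  speed_cor <- if (nrow(clean) >= 3) {
    cor(clean$score, clean$speed_factor)
  } else NA_real_

  tp <- sum(joined$excluded & joined$contaminant)
  fp <- sum(joined$excluded & !joined$contaminant)
  fn <- sum(!joined$excluded & joined$contaminant)
  list(
    effect_cor = effect_cor,
    speed_cor = speed_cor,
    exclusion_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    exclusion_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    confusion = c(true_positive = tp, false_positive = fp,
                  false_negative = fn,
                  true_negative = sum(!joined$excluded & !joined$contaminant))
  )
}
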