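# Shared fixtures: hand-built sessions and an independent three-step oracle
# for the D statistic.

# Literal three-step D computation: pooled SD, condition means, ratio.
oracle_d <- function(lat1, lat2) {
  SD <- sd(c(lat1, lat2))
  M1 <- mean(lat1)
  M2 <- mean(lat2)
  (M2 - M1) / SD
}

# One session's trial table with explicit per-block latencies.
# `blocks` is a named list "1".."5" -> latency vector; block lengths are free
# so degenerate layouts can be built. Conditions follow the standard
# alternation (2,4 -> condition1; 3,5 -> condition2).
make_session <- function(blocks, session_id = "s1",
                         focal_polarity = "good_focal", error = FALSE) {
  condition_of <- c("condition1", "condition1", "condition2",
                    "condition1", "condition2")
  rows <- lapply(names(blocks), function(b) {
    bi <- as.integer(b)
    lat <- blocks[[b]]
    tibble::tibble(
      session_id = session_id,
      topic = "test",
      focal_polarity = focal_polarity,
      block_index = bi,
      trial_index = seq_along(lat) - 1L,
      condition = condition_of[bi],
      latency_ms = lat,
      error = rep_len(error, length(lat))
    )
  })
  dplyr::bind_rows(rows)
}

# A layout-conforming session: 16-trial practice block plus four 20-trial
# blocks at the given condition means (warm-up trials share the block mean).
make_standard_session <- function(session_id = "s1", m1 = 700, m2 = 900,
                                  spread = 60, focal_polarity = "good_focal",
                                  error = FALSE) {
  lat <- function(m, n) m + spread * seq(-1, 1, length.out = n)
  make_session(
    list("1" = lat(m1, 16),
         "2" = lat(m1, 20), "3" = lat(m2, 20),
         "4" = lat(m1, 20), "5" = lat(m2, 20)),
    session_id = session_id, focal_polarity = focal_polarity, error = error
  )
}

# Config with no tail treatment and no exclusions: scoring only.
plain_config <- function(...) {
  args <- utils::modifyList(
    list(fast_boundary_ms = NULL, slow_boundary_ms = NULL,
         fast_exclusion_threshold = NULL),
    list(...)
  )
  do.call(biat_config, args)
}
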