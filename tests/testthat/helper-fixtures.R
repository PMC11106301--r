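# shared fixtures and independent oracles

# brute-force O(n^2) DFT periodogram with a Hamming window, written
# independently of the package's FFT-based implementation: the reference
# for the Welch PSD
oracle_psd <- function(block, fs) {
  n <- length(block)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- block * w
  k <- 0:(n %/% 2)
  Wm <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  X <- as.vector(Wm %*% xw)
  p <- Mod(X)^2 / (fs * sum(w^2))
  dbl <- rep(2, length(k))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  data.frame(freq = k * fs / n, power = p * dbl)
}

sine_block <- function(freq, fs, amp = 1, phase = 0)
  amp * sin(2 * pi * freq * seq(0, 1 - 1 / fs, 1 / fs) + phase)

# annotation data.frame for hand-built behavioural scenarios
ann_df <- function(states_by_subject, huddle_by_subject = NULL) {
  T <- length(states_by_subject[[1]])
  do.call(rbind, lapply(names(states_by_subject), function(s) {
    data.frame(subject_id = s, second = seq_len(T),
               locomotive_state = states_by_subject[[s]],
               huddle_group_id = if (is.null(huddle_by_subject))
                 NA_character_ else huddle_by_subject[[s]])
  }))
}

# a small band-power series with planted low/high columns
bp_series <- function(low, high, subject = "s1", cohort = "c1",
                      condition = "group") {
  df <- data.frame(subject_id = subject, second = seq_along(low),
                   delta = low, theta = low, alpha = low, beta = low,
                   gamma = high, high_gamma = high,
                   low = low, high = high, valid = TRUE)
  structure(df, cohort_id = cohort, condition = condition,
            class = c("band_power_series", "data.frame"))
}

# hlr series straight from values (valid everywhere unless stated)
hlr_from_values <- function(v, subject = "s1", cohort = "c1",
                            condition = "group", valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(v))
  structure(data.frame(subject_id = subject, second = seq_along(v),
                       hlr = v, valid = valid),
            cohort_id = cohort, condition = condition,
            class = c("hlr_series", "data.frame"))
}

# config used by fast band-level cohort simulations in tests
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 600, fs = 512)
  do.call(cohort_sim_config, utils::modifyList(defaults, args))
}

# generator conditions that isolate directed influence for Granger
# recovery: state-independent spectra, no huddling, no shared modulator,
# white directed latents
influence_config <- function(edges, seed, duration_s = 10800,
                             cohort_id = "c01") {
  cohort_sim_config(
    duration_s = duration_s, cohort_id = cohort_id, seed = seed,
    coupling_strength = 0,
    huddle_params = list(formation_rate = 0),
    band_gains = list(low = c(inactive = 1, active_still = 1, active = 1),
                      high = c(inactive = 0, active_still = 0, active = 0)),
    leader_map = edges,
    noise = list(driver_ar = 0))
}

edge_df <- function(from = integer(), to = integer(), lag = 1L,
                    weight = 0.7) {
  if (length(from) == 0L)
    data.frame(from = integer(), to = integer(), lag = integer(),
               weight = numeric())
  else data.frame(from = from, to = to, lag = lag, weight = weight)
}

# experiment-level generator conditions used by the calibration and
# planted-effect experiments (band-power level, 30-min sessions)

# all couplings zero: no shared modulator, no directed influence, no
# huddle process (which would couple states)
uncoupled_cfg <- function(duration_s = 1800) function(cid, cond, seed)
  cohort_sim_config(duration_s = duration_s, cohort_id = cid,
                    condition = cond, seed = seed, coupling_strength = 0,
                    leader_map = edge_df(),
                    huddle_params = list(formation_rate = 0))

# default study conditions (shared modulation + huddling + leaders)
coupled_cfg <- function(duration_s = 1800) function(cid, cond, seed)
  cohort_sim_config(duration_s = duration_s, cohort_id = cid,
                    condition = cond, seed = seed)

# locomotion-mediated coupling only: states couple through the shared
# huddle process but log-HLR has no direct shared modulator
mediated_cfg <- function(duration_s = 10800) function(cid, cond, seed)
  cohort_sim_config(duration_s = duration_s, cohort_id = cid,
                    condition = cond, seed = seed, coupling_strength = 0,
                    leader_map = edge_df())

# mediation plus a direct shared log-HLR modulator
direct_cfg <- function(duration_s = 10800) function(cid, cond, seed)
  cohort_sim_config(duration_s = duration_s, cohort_id = cid,
                    condition = cond, seed = seed, coupling_strength = 0.6,
                    leader_map = edge_df())

# planted directed-influence experiment: per-cohort edge sets with every
# confounding coupling (shared modulator, huddle gating, state-dependent
# spectra, latent autocorrelation) switched off so that exact graph
# recovery is identifiable
recovery_edges <- list(
  c01 = data.frame(from = c(1, 1), to = c(2, 3), lag = 1, weight = 0.7),
  c02 = data.frame(from = 2, to = 4, lag = 1, weight = 0.7),
  c03 = data.frame(from = integer(), to = integer(), lag = integer(),
                   weight = numeric()))

recovery_cfg <- function(duration_s = 10800) function(cid, cond, seed)
  influence_config(recovery_edges[[cid]], seed = seed,
                   duration_s = duration_s, cohort_id = cid)

pool_hlr <- function(experiment)
  unlist(lapply(experiment, bundle_hlr), recursive = FALSE)
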