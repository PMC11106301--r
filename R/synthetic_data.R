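#' Configuration for a synthetic multi-animal cohort
#'
#' Defines the generative model for one recording session of up to four
#' mice. Behaviour is a per-second 3-state locomotive Markov chain
#' (`inactive`, `active_still`, `active`) gated, in group condition, by a
#' shared huddle on/off process: huddled seconds are drawn with an
#' inactive-enriched transition bias and non-huddled seconds with an
#' active-enriched bias. The LFP layer plants, per second, log band powers
#' for the low (0–12 Hz) and high (31–150 Hz) composites as a function of
#' (locomotive state, social context, huddle status), plus a cohort-shared
#' AR(1) modulator weighted by `coupling_strength` (interbrain coupling) and
#' a per-subject directed AR(1) latent coupled along `leader_map`
#' (leader-to-follower lag-1 influence detectable by Granger causality).
#'
#' @param n_subjects animals per cohort (1–4 by default design).
#' @param duration_s session length in seconds (default 10800, a 3-h
#'   session).
#' @param fs sampling rate in Hz for raw trace synthesis.
#' @param condition `"group"` or `"single"`. In single condition the huddle
#'   process, shared modulator and directed influence are all inactive:
#'   animals are recorded simultaneously but socially separated.
#' @param state_transition 3x3 row-stochastic Markov matrix over the
#'   locomotive states (rows/cols in the order inactive, active_still,
#'   active).
#' @param huddle_params list with `formation_rate` (episode onset
#'   probability per non-huddled second), `breakup_rate` (reciprocal mean
#'   episode excess duration), `min_persist_s` (episodes always exceed this,
#'   default 10 s, matching the trunk-to-trunk persistence rule) and
#'   `member_p` (per-episode participation probability per subject).
#' @param band_gains list with `low` and `high`: named per-state mean log
#'   band power (natural log, arbitrary density units), and
#'   `context_offset`: named additive log-HLR offsets for `single`,
#'   `group_huddled` and `group_non_huddled` seconds, applied half to the
#'   high band and minus half to the low band.
#' @param coupling_strength weight in `[0,1]` of the cohort-shared AR(1)
#'   log-HLR modulator (group condition only).
#' @param leader_map data.frame with columns `from`, `to` (subject
#'   indices), `lag` (seconds, >= 1) and `weight` in `[0,1]`: directed
#'   influence edges. `weight` is both the follower's per-second probability
#'   of adopting the leader's locomotive state at the given lag (outside
#'   huddled seconds) and the regression weight of the leader's latent
#'   driver in the follower's log-HLR driver.
#' @param noise list of nuisance scales: `driver_ar`, `driver_sd` (directed
#'   latent AR coefficient and innovation SD), `shared_ar` (shared modulator
#'   AR coefficient; unit marginal variance), `seg_sd` (independent
#'   per-second log-power jitter), `band_jitter_sd` (named-band jitter
#'   around the composite), `beta_sd` (extra beta-band noise), `pink_level`
#'   (1/f background PSD density at 1 Hz), `pink_exponent`, `white_floor`
#'   (white background PSD density) and `adc_gain` (integer scaling for
#'   hex-representable traces).
#' @param subject_ids,cohort_id identifiers.
#' @param seed integer seed making [simulate_cohort()] deterministic;
#'   `NULL` uses the current RNG state.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 4L,
                              duration_s = 10800,
                              fs = 1024,
                              condition = c("group", "single"),
                              state_transition = NULL,
                              huddle_params = list(),
                              band_gains = list(),
                              coupling_strength = 0.6,
                              leader_map = NULL,
                              noise = list(),
                              subject_ids = NULL,
                              cohort_id = "c01",
                              seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(state_transition))
    state_transition <- matrix(c(0.97, 0.02, 0.01,
                                 0.03, 0.93, 0.04,
                                 0.01, 0.05, 0.94),
                               nrow = 3, byrow = TRUE)
  dimnames(state_transition) <- list(.locomotive_states, .locomotive_states)
  if (any(state_transition < 0) ||
      any(abs(rowSums(state_transition) - 1) > 1e-8))
    stop("'state_transition' rows must be non-negative and sum to 1")
  if (duration_s < 60) stop("'duration_s' must be at least 60 s")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("'coupling_strength' must be in [0, 1]")

  hp <- utils::modifyList(
    list(formation_rate = 1 / 600, breakup_rate = 1 / 1200,
         min_persist_s = 10, member_p = 0.9), huddle_params)

  bg <- utils::modifyList(
    list(low  = c(inactive = 2.4, active_still = 1.2, active = 0.6),
         high = c(inactive = -1.2, active_still = 0.2, active = 0.9),
         context_offset = c(single = 0, group_huddled = 0.05,
                            group_non_huddled = 0.35)),
    band_gains)

  if (is.null(leader_map))
    leader_map <- if (condition == "group")
      data.frame(from = c(1L, 1L, 1L, 2L, 2L), to = c(2L, 3L, 4L, 3L, 4L),
                 lag = 1L, weight = 0.5)
    else
      data.frame(from = integer(), to = integer(), lag = integer(),
                 weight = numeric())
  leader_map <- leader_map[leader_map$from <= n_subjects &
                             leader_map$to <= n_subjects, , drop = FALSE]
  if (nrow(leader_map)) {
    if (any(leader_map$lag < 1)) stop("leader_map lags must be >= 1 s")
    if (any(leader_map$weight < 0 | leader_map$weight > 1))
      stop("leader_map weights must be in [0, 1]")
    if (any(leader_map$from == leader_map$to))
      stop("leader_map must not contain self-edges")
  }

  nz <- utils::modifyList(
    list(driver_ar = 0.3, driver_sd = 0.2, shared_ar = 0.9, seg_sd = 0.07,
         band_jitter_sd = 0.15, beta_sd = 0.4, pink_level = 0.5,
         pink_exponent = 1, white_floor = 0.01, adc_gain = 100), noise)

  if (is.null(subject_ids))
    subject_ids <- sprintf("%s_m%d", cohort_id, seq_len(n_subjects))
  if (length(subject_ids) != n_subjects)
    stop("'subject_ids' must have length n_subjects")

  structure(list(n_subjects = as.integer(n_subjects),
                 duration_s = as.integer(duration_s), fs = fs,
                 condition = condition, state_transition = state_transition,
                 huddle_params = hp, band_gains = bg,
                 coupling_strength = coupling_strength,
                 leader_map = leader_map, noise = nz,
                 subject_ids = subject_ids, cohort_id = cohort_id,
                 seed = seed),
            class = "cohort_sim_config")
}

#' @export
print.cohort_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_sim_config> cohort %s (%s): %d subjects, ",
                     "%d s @ %g Hz, coupling %.2f, %d influence edge(s)\n"),
              x$cohort_id, x$condition, x$n_subjects, x$duration_s, x$fs,
              x$coupling_strength, nrow(x$leader_map)))
  invisible(x)
}

## huddle on/off timeline with per-episode membership.
## Episodes have duration min_persist + 1 + Geom(breakup_rate), so every
## generated episode survives the >10 s persistence rule.
.sim_huddle <- function(config) {
  T <- config$duration_s
  n <- config$n_subjects
  hp <- config$huddle_params
  member <- matrix(NA_character_, nrow = T, ncol = n)
  if (config$condition == "single" || n < 2L || hp$formation_rate <= 0)
    return(member)
  t <- 1L
  ep <- 0L
  ## alternate non-huddled gaps and huddle episodes
  repeat {
    gap <- 1L + stats::rgeom(1L, min(1, hp$formation_rate))
    t <- t + gap
    if (t > T) break
    dur <- hp$min_persist_s + 1L +
      stats::rgeom(1L, min(1, max(hp$breakup_rate, 1e-12)))
    idx <- t:min(T, t + dur - 1L)
    if (length(idx) > hp$min_persist_s) {   # drop episodes truncated by
      ep <- ep + 1L                         # the session end
      members <- which(stats::runif(n) < hp$member_p)
      if (length(members) < 2L)
        members <- sample.int(n, 2L)
      member[idx, members] <- sprintf("h%03d", ep)
    }
    t <- t + dur
  }
  member
}

.bias_matrix <- function(P, bias) {
  B <- sweep(P, 2L, bias, `*`)
  B / rowSums(B)
}

#' Simulate per-second behaviour for one cohort session
#'
#' Draws the shared huddle process (group condition), then the per-subject
#' locomotive state chains with huddle-status-dependent transition bias, and
#' applies leader-to-follower state adoption at the configured lag and
#' probability outside huddled seconds. Uses the current RNG state; seed via
#' [simulate_cohort()] or `set.seed()`.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `annotations` (an [annotation_table()]) and `truth`
#'   (list with the integer state matrix, huddle membership matrix and the
#'   configured edge list).
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  T <- config$duration_s
  n <- config$n_subjects
  member <- .sim_huddle(config)
  huddled <- !is.na(member)

  P_hud <- .bias_matrix(config$state_transition, c(4, 1, 0.3))
  P_non <- .bias_matrix(config$state_transition, c(0.45, 1.1, 1.6))

  lm_edges <- config$leader_map
  leaders <- vector("list", n)            # first incoming edge per subject
  if (config$condition == "group" && nrow(lm_edges))
    for (j in seq_len(n)) {
      e <- which(lm_edges$to == j)
      if (length(e)) leaders[[j]] <- lm_edges[e[1L], ]
    }

  S <- matrix(0L, nrow = T, ncol = n)
  u01 <- matrix(stats::runif(T * n), nrow = T)       # adoption coin flips
  S[1L, ] <- ifelse(huddled[1L, ], 1L,
                    sample.int(3L, n, replace = TRUE, prob = c(1, 1, 1)))
  for (t in 2:T) {
    for (j in seq_len(n)) {
      led <- leaders[[j]]
      if (!is.null(led) && !huddled[t, j] && t > led$lag &&
          u01[t, j] < led$weight) {
        S[t, j] <- S[t - led$lag, led$from]
      } else {
        P <- if (huddled[t, j]) P_hud else P_non
        S[t, j] <- sample.int(3L, 1L, prob = P[S[t - 1L, j], ])
      }
    }
  }

  df <- data.frame(
    subject_id = rep(config$subject_ids, each = T),
    second = rep(seq_len(T), n),
    locomotive_state = .locomotive_states[as.vector(S)],
    huddle_group_id = as.vector(member))
  ann <- annotation_table(df, condition = config$condition, duration_s = T)
  list(annotations = ann,
       truth = list(states = S, huddle = member,
                    edges = config$leader_map,
                    coupling_strength = config$coupling_strength))
}

## Latent per-second log band powers for every subject.
## logP_high = g_high[state] + d/2,  logP_low = g_low[state] - d/2, where
## d = context_offset + coupling_strength * shared AR(1) + directed latent u
## (u_j(t) = ar*u_j(t-1) + sum_edges w*u_i(t-lag) + innovation), plus
## independent per-second jitter on each composite.
.sim_drivers <- function(states, huddled, config) {
  T <- nrow(states)
  n <- ncol(states)
  nz <- config$noise
  bg <- config$band_gains
  group <- config$condition == "group"

  s_mod <- if (group && config$coupling_strength > 0) {
    as.numeric(stats::arima.sim(list(ar = nz$shared_ar), T,
                                sd = sqrt(1 - nz$shared_ar^2)))
  } else numeric(T)

  U <- matrix(0, nrow = T, ncol = n)
  eta <- matrix(stats::rnorm(T * n, sd = nz$driver_sd), nrow = T)
  edges <- if (group) config$leader_map else
    config$leader_map[0, , drop = FALSE]
  maxlag <- if (nrow(edges)) max(edges$lag) else 0L
  U[1L, ] <- eta[1L, ]
  for (t in 2:T) {
    U[t, ] <- nz$driver_ar * U[t - 1L, ] + eta[t, ]
    if (nrow(edges)) for (e in seq_len(nrow(edges))) {
      lg <- edges$lag[e]
      if (t > lg)
        U[t, edges$to[e]] <- U[t, edges$to[e]] +
          edges$weight[e] * U[t - lg, edges$from[e]]
    }
  }

  ctx <- matrix(bg$context_offset[["single"]], nrow = T, ncol = n)
  if (group) {
    ctx[] <- bg$context_offset[["group_non_huddled"]]
    ctx[huddled] <- bg$context_offset[["group_huddled"]]
  }

  d <- ctx + config$coupling_strength * s_mod + U
  logP_high <- matrix(bg$high[as.vector(states)], nrow = T) + d / 2 +
    stats::rnorm(T * n, sd = nz$seg_sd)
  logP_low <- matrix(bg$low[as.vector(states)], nrow = T) - d / 2 +
    stats::rnorm(T * n, sd = nz$seg_sd)
  list(logP_low = logP_low, logP_high = logP_high, d = d, shared = s_mod,
       u = U)
}

#' Simulate per-second band powers (generative layer)
#'
#' Produces each subject's `band_power_series` directly from the latent
#' per-second drivers, without synthesising raw voltage traces. This is the
#' layer at which all planted interbrain structure lives (the per-second
#' statistics downstream are blind to sub-second waveform detail), so it is
#' the efficient input for Monte-Carlo experiments; [simulate_lfp()] adds a
#' waveform consistent with these powers.
#'
#' Named bands are drawn around their composite: delta/theta/alpha jitter
#' around the low composite, gamma/high gamma around the high composite, and
#' beta loads half on the low composite with extra independent noise,
#' reproducing the observed band-correlation sign structure (low bands
#' mutually correlated, anti-correlated with high bands, beta intermediate).
#'
#' @param behavior output of [simulate_behavior()].
#' @param config the same [cohort_sim_config()].
#' @return list with `band_powers` (list of `band_power_series`, one per
#'   subject) and `drivers` (latent matrices incl. the planted log-HLR
#'   driver `d`).
#' @export
simulate_band_powers <- function(behavior, config) {
  T <- config$duration_s
  n <- config$n_subjects
  truth <- behavior$truth
  huddled <- !is.na(truth$huddle)
  drv <- .sim_drivers(truth$states, huddled, config)
  nz <- config$noise
  jsd <- nz$band_jitter_sd
  series <- vector("list", n)
  for (j in seq_len(n)) {
    lo <- drv$logP_low[, j]
    hi <- drv$logP_high[, j]
    df <- data.frame(
      subject_id = config$subject_ids[j],
      second = seq_len(T),
      delta = exp(lo + stats::rnorm(T, sd = jsd)),
      theta = exp(lo + stats::rnorm(T, sd = jsd)),
      alpha = exp(lo + stats::rnorm(T, sd = jsd)),
      beta = exp(0.5 * lo + stats::rnorm(T, sd = nz$beta_sd)),
      gamma = exp(hi + stats::rnorm(T, sd = jsd)),
      high_gamma = exp(hi + stats::rnorm(T, sd = jsd)),
      low = exp(lo),
      high = exp(hi),
      valid = TRUE)
    series[[j]] <- structure(df, cohort_id = config$cohort_id,
                             condition = config$condition,
                             class = c("band_power_series", "data.frame"))
  }
  names(series) <- config$subject_ids
  list(band_powers = series, drivers = drv)
}

## FIR band component: unit white noise filtered to [lo, hi] Hz and scaled
## so its one-sided in-band PSD density is 1.
.band_noise <- function(n, fs, lo, hi, taps = 256L) {
  w <- c(max(lo, 0.25), hi) / (fs / 2)
  h <- if (lo <= 0.25) signal::fir1(taps, w[2L], type = "low")
       else signal::fir1(taps, w, type = "pass")
  h <- as.numeric(h)
  x <- signal::fftfilt(h, stats::rnorm(n))
  f <- seq(0, fs / 2)
  H <- vapply(f, function(ff)
    Mod(sum(h * exp(-2i * pi * ff * seq_along(h) / fs))), 0)
  sel <- f >= lo & f <= hi & f > 0
  dens <- mean(2 * H[sel]^2 / fs)        # density of filtered unit noise
  x / sqrt(dens)
}

## per-sample amplitude envelope from per-second amplitudes with ~50 ms
## raised-cosine smoothing at segment boundaries (no clicks)
.envelope <- function(amps, fs) {
  env <- rep(amps, each = fs)
  L <- 2L * (round(0.025 * fs)) + 1L
  if (L >= 3L) {
    k <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    k <- k / sum(k)
    n <- length(env)
    padded <- c(rep(env[1L], (L - 1L) / 2L), env,
                rep(env[n], (L - 1L) / 2L))
    env <- as.numeric(stats::filter(padded, k, sides = 1L)[L:(n + L - 1L)])
  }
  env
}

## 1/f^alpha background via spectral shaping, scaled to `level` one-sided
## PSD density at 1 Hz
.pink_noise <- function(n, fs, level, alpha) {
  if (level <= 0) return(numeric(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                   # mirror for the conjugate half
  shape <- pmax(f, 1)^(-alpha / 2)       # flat below 1 Hz, 1/f^alpha above
  shape[1L] <- 0                         # no DC component
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * shape, inverse = TRUE)) / n
  # unit white noise has one-sided density 2/fs; shaping multiplies it by
  # shape(f)^2, so density at 1 Hz is (2/fs) * 1
  x * sqrt(level * fs / 2)
}

#' Synthesise raw LFP traces from planted band powers
#'
#' Each subject's trace is the sum of a low-band (0–12 Hz) and a high-band
#' (31–150 Hz) FIR-filtered noise carrier, amplitude-modulated per second so
#' the measured in-band PSD density of each 1-s segment matches the planted
#' band powers, plus a 1/f background and a white noise floor. Per-second
#' amplitude envelopes are smoothed with a ~50 ms raised-cosine kernel at
#' segment boundaries. Samples are scaled by `noise$adc_gain`, rounded and
#' clipped to the 16-bit ADC range so traces are hex-representable.
#'
#' @param bands output of [simulate_band_powers()] (or a list of
#'   `band_power_series` with `low`/`high` columns).
#' @param config the [cohort_sim_config()].
#' @return named list of [lfp_trace()] objects, one per subject.
#' @export
simulate_lfp <- function(bands, config) {
  series <- if (!is.null(bands$band_powers)) bands$band_powers else bands
  if (length(series) != config$n_subjects)
    stop("band powers and config disagree on the number of subjects")
  fs <- round(config$fs)
  T <- config$duration_s
  nz <- config$noise
  n <- T * fs
  half <- 2^15
  traces <- vector("list", length(series))
  for (j in seq_along(series)) {
    s <- series[[j]]
    if (nrow(s) != T) stop("band power series does not cover the session")
    a_low <- sqrt(s$low)                  # density = amplitude^2
    a_high <- sqrt(s$high)
    x <- .envelope(a_low, fs) * .band_noise(n, fs, 0, 12) +
      .envelope(a_high, fs) * .band_noise(n, fs, 31, 150) +
      .pink_noise(n, fs, nz$pink_level, nz$pink_exponent) +
      stats::rnorm(n, sd = sqrt(max(nz$white_floor, 0) * fs / 2))
    v <- round(x * nz$adc_gain)
    v <- pmin(pmax(v, -half), half - 1)
    traces[[j]] <- lfp_trace(v, fs = fs, subject_id = s$subject_id[1L],
                             cohort_id = config$cohort_id,
                             condition = config$condition)
  }
  names(traces) <- names(series)
  traces
}

#' Simulate a complete cohort session
#'
#' Composes [simulate_behavior()], [simulate_band_powers()] and (optionally)
#' [simulate_lfp()] into one seeded, reproducible session bundle directly
#' consumable by the analysis pipeline.
#'
#' @param config a [cohort_sim_config()]; `config$seed`, when non-`NULL`,
#'   makes the bundle deterministic.
#' @param signal `"band"` returns the per-second generative layer only
#'   (fast; all planted interbrain structure lives at this 1 Hz timescale);
#'   `"lfp"` additionally synthesises full-rate voltage traces.
#' @return list of class `cohort_bundle` with `manifest`, `annotations`,
#'   `band_powers`, `traces` (or `NULL`) and `truth` (planted states, huddle
#'   membership, latent drivers, shared modulator, edge list).
#' @export
simulate_cohort <- function(config = cohort_sim_config(),
                            signal = c("band", "lfp")) {
  signal <- match.arg(signal)
  if (!is.null(config$seed)) set.seed(config$seed)
  behav <- simulate_behavior(config)
  bp <- simulate_band_powers(behav, config)
  traces <- if (signal == "lfp") simulate_lfp(bp, config) else NULL
  manifest <- session_manifest(config$cohort_id, config$condition,
                               config$subject_ids,
                               duration_s = config$duration_s,
                               fs = config$fs)
  truth <- c(behav$truth,
             list(drivers = bp$drivers, planted_log_hlr = bp$drivers$d))
  structure(list(manifest = manifest, annotations = behav$annotations,
                 band_powers = bp$band_powers, traces = traces,
                 truth = truth, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> cohort %s (%s): %d subjects, %d s%s\n",
              x$config$cohort_id, x$config$condition, x$config$n_subjects,
              x$config$duration_s,
              if (is.null(x$traces)) " (band-power level)" else
                sprintf(", traces @ %g Hz", x$config$fs)))
  invisible(x)
}

#' Simulate a multi-cohort experiment (group day + single day)
#'
#' Emulates the full study design: each cohort of four mice is recorded once
#' in group condition and once, the next day, individually in single
#' condition. Session seeds are derived deterministically from `seed`.
#'
#' @param n_cohorts number of cohorts (default 3).
#' @param seed integer master seed.
#' @param config_fn function `(cohort_id, condition, seed)` returning a
#'   [cohort_sim_config()]; override to change the generative conditions of
#'   every session consistently.
#' @param signal passed to [simulate_cohort()].
#' @return list of `cohort_bundle`s named `<cohort>_group` /
#'   `<cohort>_single`.
#' @export
simulate_experiment <- function(n_cohorts = 3L, seed = 1L,
                                config_fn = NULL,
                                signal = c("band", "lfp")) {
  signal <- match.arg(signal)
  if (is.null(config_fn))
    config_fn <- function(cohort_id, condition, seed)
      cohort_sim_config(condition = condition, cohort_id = cohort_id,
                        seed = seed)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 2L * n_cohorts)
  out <- list()
  for (k in seq_len(n_cohorts)) {
    cid <- sprintf("c%02d", k)
    for (cond in c("group", "single")) {
      s <- seeds[2L * (k - 1L) + (cond == "single") + 1L]
      cfg <- config_fn(cid, cond, s)
      out[[paste(cid, cond, sep = "_")]] <- simulate_cohort(cfg, signal)
    }
  }
  out
}

#' Write a cohort bundle to disk
#'
#' Writes the manifest (YAML), annotation CSV, ground-truth JSON and, when
#' present, one hexadecimal trace file per subject.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- bundle$manifest
  if (!is.null(bundle$traces)) {
    files <- list()
    for (id in names(bundle$traces)) {
      f <- file.path(dir, paste0(id, ".hex"))
      write_cbrain_hex(bundle$traces[[id]], f)
      files[[id]] <- basename(f)
    }
    manifest$files <- files
  }
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  write_annotations(bundle$annotations, file.path(dir, "annotations.csv"))
  truth <- bundle$truth
  jsonlite::write_json(
    list(states = truth$states, huddle = truth$huddle,
         edges = truth$edges, coupling_strength = truth$coupling_strength),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null",
    na = "null")
  invisible(dir)
}
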