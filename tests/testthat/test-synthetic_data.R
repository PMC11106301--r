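test_that("configuration invariants are enforced", {
  bad <- matrix(c(0.5, 0.5, 0.2, 0.3, 0.6, 0.1, 0.1, 0.1, 0.8), 3, 3)
  expect_error(cohort_sim_config(state_transition = bad), "sum to 1")
  expect_error(cohort_sim_config(duration_s = 30), "at least 60")
  expect_error(cohort_sim_config(coupling_strength = 1.2), "\\[0, 1\\]")
  expect_error(cohort_sim_config(
    leader_map = data.frame(from = 1, to = 2, lag = 0, weight = 0.5)),
    "lag")
  expect_error(cohort_sim_config(
    leader_map = data.frame(from = 1, to = 1, lag = 1, weight = 0.5)),
    "self-edges")
})

test_that("the same seed reproduces a bundle bit for bit", {
  cfg <- quick_config(duration_s = 120, seed = 77)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$truth$states, b2$truth$states)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(b1$band_powers, b2$band_powers)

  t1 <- simulate_cohort(quick_config(n_subjects = 2, duration_s = 60,
                                     seed = 5), signal = "lfp")
  t2 <- simulate_cohort(quick_config(n_subjects = 2, duration_s = 60,
                                     seed = 5), signal = "lfp")
  expect_identical(t1$traces[[1]]$samples, t2$traces[[1]]$samples)
})

test_that("an absorbing inactive state with immediate huddling fills the session", {
  absorbing <- matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  cfg <- quick_config(duration_s = 300, seed = 2,
                      state_transition = absorbing,
                      huddle_params = list(formation_rate = 1,
                                           breakup_rate = 1e-9))
  b <- simulate_cohort(cfg)
  # from the second step on, every subject is absorbed into inactive
  expect_true(all(b$annotations$locomotive_state[
    b$annotations$second > 1] == "inactive"))
  eps <- huddle_episodes(b$annotations)
  expect_equal(nrow(eps$episodes), 1L)
  expect_gt(eps$episodes$duration, 290)
})

test_that("full-weight lag-1 adoption copies the leader's states", {
  cfg <- quick_config(
    duration_s = 400, seed = 3, n_subjects = 2,
    huddle_params = list(formation_rate = 0),   # no huddle gating
    leader_map = data.frame(from = 1, to = 2, lag = 1, weight = 1))
  b <- simulate_behavior(cfg)
  S <- b$truth$states
  expect_equal(S[2:400, 2], S[1:399, 1])
})

test_that("uncoupled single-condition subjects have uncorrelated state sequences", {
  rs <- vapply(1:20, function(s) {
    cfg <- cohort_sim_config(n_subjects = 2, duration_s = 10800,
                             condition = "single", seed = 100 + s)
    b <- simulate_behavior(cfg)
    cor(b$truth$states[, 1], b$truth$states[, 2])
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("generated huddle episodes obey persistence and size bounds", {
  for (s in 1:5) {
    b <- simulate_cohort(quick_config(duration_s = 2000, seed = 30 + s))
    eps <- huddle_episodes(b$annotations)
    # persistence: raw label runs in the generator output already exceed
    # 10 s, so the rule discards nothing
    lab <- b$annotations$huddle_group_id
    raw <- tapply(seq_along(lab), paste(b$annotations$subject_id, lab),
                  length)
    if (length(raw)) expect_true(all(raw > 10))
    if (nrow(eps$episodes)) {
      expect_true(all(eps$episodes$duration > 10))
      expect_true(all(eps$episodes$max_size <= 4))
      expect_true(all(eps$size_per_second <= 4))
    }
  }
})

test_that("state-dependent gains separate inactive and active HLR distributions", {
  b <- simulate_cohort(quick_config(duration_s = 1500, seed = 40))
  h <- hlr(b$band_powers[[1]])
  st <- b$annotations[b$annotations$subject_id ==
                        b$config$subject_ids[1], ]
  st <- st$locomotive_state[order(st$second)]
  ina <- h$hlr[st == "inactive"]
  act <- h$hlr[st == "active"]
  expect_gt(length(ina) + length(act), 1000)
  # probability a random inactive segment beats a random active one
  u <- wilcox.test(ina, act)$statistic / (length(ina) * length(act))
  expect_lt(u, 0.01)
  expect_lt(median(ina), median(act))
})

test_that("zero gains and zero noise produce an all-zero trace", {
  cfg <- cohort_sim_config(
    n_subjects = 1, duration_s = 60, fs = 512, seed = 6,
    coupling_strength = 0, leader_map = edge_df(),
    band_gains = list(low = c(inactive = -Inf, active_still = -Inf,
                              active = -Inf),
                      high = c(inactive = -Inf, active_still = -Inf,
                               active = -Inf),
                      context_offset = c(single = 0, group_huddled = 0,
                                         group_non_huddled = 0)),
    noise = list(pink_level = 0, white_floor = 0, seg_sd = 0,
                 driver_sd = 0))
  b <- simulate_cohort(cfg, signal = "lfp")
  expect_true(all(b$traces[[1]]$samples == 0))
})

test_that("full shared coupling with identical states synchronises HLR", {
  for (s in 1:5) {
    # fully shared modulation with every other source of between-animal
    # difference switched off: identical (absorbing) states, no huddle
    # episodes, no directed latents
    cfg <- cohort_sim_config(
      n_subjects = 2, duration_s = 10800, seed = 50 + s,
      coupling_strength = 1, leader_map = edge_df(),
      huddle_params = list(formation_rate = 0),
      noise = list(driver_sd = 0),
      state_transition = matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3,
                                byrow = TRUE))
    b <- simulate_cohort(cfg)
    h <- lapply(b$band_powers, hlr)
    expect_gt(pair_correlation(h[[1]], h[[2]])$r, 0.9)
  }
})

test_that("default band-level bundles have the full study shape", {
  cfg <- cohort_sim_config(seed = 60)
  b <- simulate_cohort(cfg)
  expect_equal(length(b$band_powers), 4L)
  expect_equal(nrow(b$band_powers[[1]]), 10800L)
  expect_equal(nrow(b$annotations), 4L * 10800L)
  expect_equal(dim(b$truth$states), c(10800L, 4L))
})

test_that("a written bundle is re-readable and consistent with memory", {
  dir <- withr::local_tempdir()
  cfg <- quick_config(n_subjects = 2, duration_s = 60, seed = 8)
  b <- simulate_cohort(cfg, signal = "lfp")
  write_cohort_bundle(b, dir)
  man <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(man$subjects, cfg$subject_ids)
  ann <- read_annotations(file.path(dir, "annotations.csv"), man)
  expect_equal(ann$locomotive_state, b$annotations$locomotive_state)
  tr <- read_cbrain_hex(file.path(dir, paste0(cfg$subject_ids[1], ".hex")),
                        fs = man$fs)
  expect_identical(tr$samples, b$traces[[1]]$samples)
})

test_that("simulated experiments pair each cohort's group and single day", {
  ex <- simulate_experiment(n_cohorts = 2, seed = 9, config_fn =
    function(cid, cond, seed)
      quick_config(duration_s = 120, cohort_id = cid, condition = cond,
                   seed = seed))
  expect_named(ex, c("c01_group", "c01_single", "c02_group", "c02_single"))
  expect_equal(attr(ex$c01_single$annotations, "condition"), "single")
  expect_true(all(is.na(ex$c01_single$annotations$huddle_group_id)))
})
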