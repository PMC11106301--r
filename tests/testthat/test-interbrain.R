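test_that("pair correlation identities, symmetry and undefined flagging", {
  withr::local_seed(1)
  v <- runif(200)
  a <- hlr_from_values(v, subject = "a")
  b <- hlr_from_values(2 * v + 1, subject = "b")
  expect_equal(pair_correlation(a, b)$r, 1)
  neg <- hlr_from_values(-v, subject = "c")
  expect_equal(pair_correlation(a, neg)$r, -1)

  w <- hlr_from_values(runif(200), subject = "d")
  expect_identical(pair_correlation(a, w)$r, pair_correlation(w, a)$r)

  const <- hlr_from_values(rep(1, 200), subject = "e")
  pc <- pair_correlation(a, const)
  expect_true(pc$undefined)
  expect_true(is.na(pc$r))
})

test_that("correlation uses only pairwise-valid overlapping seconds", {
  v <- c(1, 2, 3, 4, 100)
  a <- hlr_from_values(v, valid = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  b <- hlr_from_values(v, subject = "b")
  pc <- pair_correlation(a, b)
  expect_equal(pc$n, 4L)
  expect_equal(pc$r, 1)
})

test_that("combination classes partition pair provenance", {
  pool <- list()
  for (co in c("c1", "c2", "c3")) for (cond in c("group", "single"))
    for (m in 1:2)
      pool[[length(pool) + 1L]] <- hlr_from_values(
        runif(50), subject = paste0(co, "_m", m, "_", cond),
        cohort = co, condition = cond)
  grp <- build_combinations(pool, "group")
  expect_equal(nrow(grp), 3L)               # C(2,2) per cohort x 3
  expect_true(all(grp$cohort_i == grp$cohort_j))
  gs <- build_combinations(pool, "group_shuffled")
  expect_equal(nrow(gs), 12L)               # 2x2 pairs x C(3,2) cohorts
  expect_true(all(gs$cohort_i != gs$cohort_j))
  mix <- build_combinations(pool, "group_single_shuffled")
  expect_equal(nrow(mix), 12L)              # 2x2 per cohort + same-subject
  ss <- build_combinations(pool, "single_shuffled")
  expect_equal(nrow(ss), 3L)
  expect_true(all(ss$i != ss$j))            # never a series with itself
})

test_that("four-mouse cohorts yield the expected group pair count", {
  pool <- list()
  for (co in c("c1", "c2", "c3")) for (m in 1:4)
    pool[[length(pool) + 1L]] <- hlr_from_values(
      runif(20), subject = paste0(co, "_m", m), cohort = co,
      condition = "group")
  expect_equal(nrow(build_combinations(pool, "group")), 18L)  # 3 x C(4,2)
  expect_error(build_combinations(pool, "single_shuffled"), "no pair")
})

test_that("permutation null is seeded, summarised and exchangeable", {
  withr::local_seed(5)
  pool <- lapply(1:6, function(i) hlr_from_values(runif(400),
                                                  subject = paste0("s", i)))
  n1 <- permutation_null(pool, n_draws = 2000, seed = 99)
  n2 <- permutation_null(pool, n_draws = 2000, seed = 99)
  expect_identical(n1$draws, n2$draws)
  expect_equal(n1$band[["lower"]], n1$mean - 1.96 * n1$sd)
  expect_equal(unname(n1$quantile(0.5)), unname(median(n1$draws)))
  expect_equal(n1$percentile(max(n1$draws) + 1), 100)

  # pool order must not change the distribution summary
  n3 <- permutation_null(pool[sample(6)], n_draws = 2000, seed = 99)
  expect_lt(abs(n3$mean - n1$mean), 0.01)
  expect_lt(abs(n3$sd - n1$sd), 0.01)

  expect_warning(permutation_null(pool, n_draws = 500), "1000")
  expect_error(permutation_null(pool[1:3]), "at least 4")
})

test_that("lagged cross-correlation peaks at the planted lead", {
  withr::local_seed(6)
  z <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  a <- hlr_from_values(z[2:2000], subject = "lead")
  b <- hlr_from_values(z[1:1999], subject = "lag")
  cc <- cross_correlation(a, b, max_lag = 5)
  expect_equal(cc$lag[which.max(cc$r)], -1)   # b trails a by 1 s
})

test_that("pooled residual regression has zero-mean residuals and recovers shape", {
  # two band-level sessions (group + single) from one cohort
  ex <- simulate_experiment(n_cohorts = 1, seed = 31, config_fn =
    function(cid, cond, seed)
      cohort_sim_config(duration_s = 3600, cohort_id = cid,
                        condition = cond, seed = seed))
  sessions <- lapply(ex, function(b)
    list(hlr = bundle_hlr(b), annotations = b$annotations))
  res <- residual_correlation(sessions, segment_min = 15)
  expect_equal(mean(res$segments$residual), 0, tolerance = 1e-10)
  expect_true(all(c("r_locomotive", "r_hlr", "predicted", "residual")
                  %in% names(res$segments)))
  expect_equal(nrow(res$fit), 1L)

  # per-condition fits zero the residual mean within each condition
  res2 <- residual_correlation(sessions, segment_min = 15,
                               fit_scope = "condition")
  for (cond in unique(res2$segments$condition))
    expect_equal(mean(res2$segments$residual[res2$segments$condition ==
                                               cond]), 0,
                 tolerance = 1e-10)
})

test_that("granger_test detects a planted lag-1 influence and its direction", {
  withr::local_seed(7)
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * c(0, x[-n]) + rnorm(n)
  fwd <- granger_test(x, y, lag = 1)
  rev <- granger_test(y, x, lag = 1)
  expect_lt(fwd$p, 1e-6)
  expect_gt(rev$p, 0.001)

  # deterministic lead: y is x delayed by one second
  z <- rnorm(n)
  lead <- z[2:n]
  trail <- z[1:(n - 1)]
  det <- granger_test(lead, trail, lag = 1)
  expect_lt(det$p, 1e-12)
  expect_gt(granger_test(trail, lead, lag = 1)$p, 0.001)

  expect_error(granger_test(rnorm(15), rnorm(15)), "too short")
  expect_error(granger_test(rep(1, 100), rnorm(100)), "constant")
})

test_that("granger test keeps its nominal size on independent series", {
  withr::local_seed(8)
  reps <- 300
  p <- vapply(seq_len(reps), function(i) {
    x <- as.numeric(arima.sim(list(ar = 0.5), 1000))
    y <- as.numeric(arima.sim(list(ar = 0.5), 1000))
    granger_test(x, y, lag = 1)$p
  }, 0)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("granger power grows with planted coupling strength", {
  withr::local_seed(9)
  med_F <- vapply(c(0.2, 0.45, 0.7), function(w) {
    Fs <- vapply(1:20, function(i) {
      x <- rnorm(1500)
      y <- w * c(0, x[-1500]) + rnorm(1500)
      granger_test(x, y, lag = 1)$F
    }, 0)
    median(Fs)
  }, 0)
  expect_true(all(diff(med_F) > 0))
})

test_that("granger alignment bridges short gaps and falls back to runs", {
  withr::local_seed(10)
  v1 <- runif(500); v2 <- runif(500)
  ok <- rep(TRUE, 500); ok[100:101] <- FALSE     # 2-s gap: bridged
  a <- hlr_from_values(v1, subject = "a", valid = ok)
  b <- hlr_from_values(v2, subject = "b")
  gm <- granger_matrix(list(a, b))
  expect_equal(gm$n_used, 500L)

  ok2 <- rep(TRUE, 500); ok2[200:250] <- FALSE   # long gap: longest run
  a2 <- hlr_from_values(v1, subject = "a", valid = ok2)
  gm2 <- granger_matrix(list(a2, b))
  expect_equal(gm2$n_used, 250L)   # the 251..500 run wins
})

test_that("directionality classes follow the two p-values", {
  P <- matrix(c(NA, 0.01, 0.40, NA), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  g <- classify_directionality(P)
  expect_equal(g$pairs$class, "unidirectional")
  expect_equal(g$pairs$direction, "a->b")
  expect_equal(g$degrees$out_degree[g$degrees$subject_id == "a"], 1L)

  P[1, 2] <- 0.01; P[2, 1] <- 0.01
  expect_equal(classify_directionality(P)$pairs$class, "bidirectional")
  P[1, 2] <- 0.40; P[2, 1] <- 0.40
  expect_equal(classify_directionality(P)$pairs$class, "none")
  P[2, 1] <- NA
  expect_error(classify_directionality(P), "missing")
})

test_that("granger_test agrees with an established reference implementation", {
  skip_if_not_installed("lmtest")
  withr::local_seed(11)
  x <- rnorm(500)
  y <- 0.3 * c(0, x[-500]) + rnorm(500)
  ours <- granger_test(x, y, lag = 1)
  ref <- lmtest::grangertest(y ~ x, order = 1)
  expect_equal(ours$F, ref$F[2], tolerance = 1e-8)
  expect_equal(ours$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
})
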