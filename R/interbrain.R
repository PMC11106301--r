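## provenance of an hlr_series
.series_meta <- function(h) {
  list(subject_id = h$subject_id[1L],
       cohort_id = attr(h, "cohort_id"),
       condition = attr(h, "condition"))
}

#' Combination class of a pair of HLR series
#'
#' `group`: same cohort, both group condition (socially co-present);
#' `group_shuffled`: different cohorts, both group; `group_single_shuffled`:
#' same cohort, one group and one single session; `single_shuffled`: same
#' cohort, both single condition (simultaneously recorded but socially
#' separated). The last three are negative-control constructions.
#'
#' @param a,b `hlr_series` objects with provenance attributes.
#' @return character class, or `NA` for combinations outside the four
#'   classes (e.g. single sessions from different cohorts).
#' @export
pair_class <- function(a, b) {
  ma <- .series_meta(a); mb <- .series_meta(b)
  same <- identical(ma$cohort_id, mb$cohort_id)
  conds <- sort(c(ma$condition, mb$condition))
  if (same && all(conds == "group")) return("group")
  if (!same && all(conds == "group")) return("group_shuffled")
  if (same && identical(conds, c("group", "single")))
    return("group_single_shuffled")
  if (same && all(conds == "single")) return("single_shuffled")
  NA_character_
}

#' Lag-0 interbrain correlation of two HLR series
#'
#' Pearson correlation over the seconds where both series are valid.
#' "Cross-correlation" throughout the pipeline means the lag-0 coefficient;
#' [cross_correlation()] provides a lag scan when needed.
#'
#' @param a,b `hlr_series` objects.
#' @return object of class `pair_correlation`: list with `subjects`,
#'   `cohorts`, `conditions`, `class`, `r`, `n`. `r` is `NA` (flagged
#'   `undefined`) when either series is constant over the overlap.
#' @export
pair_correlation <- function(a, b) {
  m <- merge(a[a$valid, c("second", "hlr")], b[b$valid, c("second", "hlr")],
             by = "second", suffixes = c("_a", "_b"))
  if (nrow(m) < 2L) stop("fewer than 2 overlapping valid seconds")
  undefined <- stats::sd(m$hlr_a) == 0 || stats::sd(m$hlr_b) == 0
  r <- if (undefined) NA_real_ else stats::cor(m$hlr_a, m$hlr_b)
  ma <- .series_meta(a); mb <- .series_meta(b)
  structure(list(subjects = c(ma$subject_id, mb$subject_id),
                 cohorts = c(ma$cohort_id, mb$cohort_id),
                 conditions = c(ma$condition, mb$condition),
                 class = pair_class(a, b), r = r, n = nrow(m),
                 undefined = undefined),
            class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("<pair_correlation> %s ~ %s [%s]: r = %.4f (n = %d)\n",
              x$subjects[1L], x$subjects[2L], x$class, x$r, x$n))
  invisible(x)
}

#' Enumerate pair combinations of one class
#'
#' @param pool list of `hlr_series` with provenance attributes.
#' @param class one of the four combination classes of [pair_class()].
#' @return data.frame with indices `i`, `j` (`i < j`) into `pool` and the
#'   subject/cohort identifiers; no pair duplicated, no self-pairs.
#' @export
build_combinations <- function(pool,
                               class = c("group", "group_shuffled",
                                         "group_single_shuffled",
                                         "single_shuffled")) {
  class <- match.arg(class)
  m <- length(pool)
  if (m < 2L) stop("pool must contain at least 2 series")
  meta <- lapply(pool, .series_meta)
  rows <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (identical(pair_class(pool[[i]], pool[[j]]), class))
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j,
        subject_i = meta[[i]]$subject_id, subject_j = meta[[j]]$subject_id,
        cohort_i = meta[[i]]$cohort_id, cohort_j = meta[[j]]$cohort_id)
  }
  if (!length(rows))
    stop("no pair in the pool satisfies class '", class, "'")
  do.call(rbind, rows)
}

#' Mean correlation of a combination class
#'
#' @inheritParams build_combinations
#' @return data.frame of per-pair correlations with the class mean as
#'   attribute `mean_r`.
#' @export
class_correlations <- function(pool, class = "group") {
  combos <- build_combinations(pool, class)
  combos$r <- vapply(seq_len(nrow(combos)), function(k)
    pair_correlation(pool[[combos$i[k]]], pool[[combos$j[k]]])$r, 0)
  combos$class <- class
  attr(combos, "mean_r") <- mean(combos$r, na.rm = TRUE)
  combos
}

#' Shuffled-pair permutation null distribution
#'
#' Draws `n_draws` random pairs of distinct series from the pooled HLRs of
#' all cohorts and conditions (with replacement across draws), computes the
#' lag-0 Pearson coefficient of each, and summarises the resulting null
#' distribution with its mean, SD and the mean +/- 1.96 SD band against
#' which an observed in-class mean is judged.
#'
#' @param pool list of at least 4 `hlr_series`.
#' @param n_draws number of random pairs (default 10000; below 1000 a
#'   warning is issued).
#' @param seed optional integer seed for the draws.
#' @return object of class `null_distribution`: `draws`, `n_draws`, `mean`,
#'   `sd`, `band` (length-2), and helper closures `percentile(x)` (empirical
#'   percentile of `x` in the draws) and `quantile(p)`.
#' @export
permutation_null <- function(pool, n_draws = 10000L, seed = NULL) {
  m <- length(pool)
  if (m < 4L) stop("pool must contain at least 4 series")
  if (n_draws < 1000L)
    warning("fewer than 1000 draws gives an unstable null band")
  if (!is.null(seed)) set.seed(seed)
  len <- vapply(pool, nrow, 0L)
  L <- min(len)
  vals <- vapply(pool, function(h) h$hlr[seq_len(L)], numeric(L))
  ok <- vapply(pool, function(h) h$valid[seq_len(L)], logical(L))
  i <- sample.int(m, n_draws, replace = TRUE)
  j <- sample.int(m - 1L, n_draws, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)         # distinct series within a draw
  draws <- vapply(seq_len(n_draws), function(k) {
    sel <- ok[, i[k]] & ok[, j[k]]
    suppressWarnings(stats::cor(vals[sel, i[k]], vals[sel, j[k]]))
  }, 0)
  mu <- mean(draws, na.rm = TRUE)
  sdv <- stats::sd(draws, na.rm = TRUE)
  structure(list(draws = draws, n_draws = n_draws, mean = mu, sd = sdv,
                 band = c(lower = mu - 1.96 * sdv, upper = mu + 1.96 * sdv),
                 percentile = function(x) 100 * mean(draws <= x,
                                                     na.rm = TRUE),
                 quantile = function(p) stats::quantile(draws, p,
                                                        na.rm = TRUE,
                                                        names = FALSE)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(paste0("<null_distribution> %d draws: mean %.4f, SD %.4f, ",
                     "+/-1.96 SD band [%.4f, %.4f]\n"),
              x$n_draws, x$mean, x$sd, x$band[1L], x$band[2L]))
  invisible(x)
}

#' Lagged cross-correlation scan
#'
#' Pearson coefficient of `a` against `b` shifted by each lag in
#' `-max_lag:max_lag` seconds (positive lag: `a` leads).
#' @param a,b `hlr_series` objects.
#' @param max_lag maximum lag in seconds.
#' @return data.frame with `lag` and `r`.
#' @export
cross_correlation <- function(a, b, max_lag = 30L) {
  m <- merge(a[, c("second", "hlr", "valid")],
             b[, c("second", "hlr", "valid")],
             by = "second", suffixes = c("_a", "_b"))
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    n <- nrow(m)
    ia <- seq_len(n - abs(l))
    if (l >= 0) { xa <- ia + l; xb <- ia } else { xa <- ia; xb <- ia - l }
    sel <- m$valid_a[xa] & m$valid_b[xb]
    if (sum(sel) < 2L) return(NA_real_)
    suppressWarnings(stats::cor(m$hlr_a[xa][sel], m$hlr_b[xb][sel]))
  }, 0)
  data.frame(lag = lags, r = r)
}

.encode_states <- function(states)
  match(states, .locomotive_states) - 1L   # ordinal 0/1/2 mobility coding

#' Locomotion-residualised interbrain correlation
#'
#' Quantifies the interbrain HLR correlation left over once shared
#' locomotion is accounted for. Sessions are cut into `segment_min`-minute
#' segments; for every simultaneously recorded pair and segment the lag-0
#' correlation of the two HLR series (`r_hlr`) and of the two
#' ordinally-encoded locomotive state series (`r_locomotive`; inactive = 0,
#' active_still = 1, active = 2) are computed. A least-squares line of
#' `r_hlr` on `r_locomotive` is then fitted — pooled over conditions by
#' default so the group-vs-single contrast of the residuals remains
#' informative — and each segment's residual is the observed minus predicted
#' `r_hlr`.
#'
#' @param sessions list of sessions, each a list with `hlr` (list of
#'   `hlr_series`) and `annotations` (the session's [annotation_table()]).
#' @param segment_min segment length in minutes (default 15).
#' @param fit_scope `"pooled"` (one regression over all segments) or
#'   `"condition"` (one per condition; residual means are then zero within
#'   each condition by construction).
#' @return list with `segments` (per pair x segment table with `r_locomotive`,
#'   `r_hlr`, `predicted`, `residual`), `fit` (coefficients), and
#'   `pair_means` (per-pair mean residual with cohort/condition).
#' @export
residual_correlation <- function(sessions, segment_min = 15,
                                 fit_scope = c("pooled", "condition")) {
  fit_scope <- match.arg(fit_scope)
  seg_s <- round(segment_min * 60)
  rows <- list()
  for (sess in sessions) {
    hl <- sess$hlr
    ann <- sess$annotations
    condition <- attr(ann, "condition")
    cohort <- attr(hl[[1L]], "cohort_id")
    T <- attr(ann, "duration_s")
    n_seg <- T %/% seg_s
    if (n_seg < 1L) stop("session shorter than one segment")
    subjects <- vapply(hl, function(h) h$subject_id[1L], "")
    enc <- lapply(subjects, function(s) {
      a <- ann[ann$subject_id == s, ]
      .encode_states(a$locomotive_state[order(a$second)])
    })
    for (i in seq_along(hl)[-length(hl)]) for (j in (i + 1L):length(hl)) {
      for (k in seq_len(n_seg)) {
        secs <- ((k - 1L) * seg_s + 1L):(k * seg_s)
        ai <- hl[[i]][secs, ]; aj <- hl[[j]][secs, ]
        sel <- ai$valid & aj$valid
        li <- enc[[i]][secs]; lj <- enc[[j]][secs]
        if (stats::sd(li) == 0 || stats::sd(lj) == 0) next  # constant state
        if (sum(sel) < 2L || stats::sd(ai$hlr[sel]) == 0 ||
            stats::sd(aj$hlr[sel]) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          cohort_id = cohort, condition = condition,
          subject_i = subjects[i], subject_j = subjects[j], segment = k,
          r_locomotive = stats::cor(li, lj),
          r_hlr = stats::cor(ai$hlr[sel], aj$hlr[sel]))
      }
    }
  }
  if (!length(rows)) stop("no usable segments")
  seg <- do.call(rbind, rows)
  if (fit_scope == "pooled") {
    fit <- stats::lm(r_hlr ~ r_locomotive, data = seg)
    seg$predicted <- stats::predict(fit, seg)
    coefs <- data.frame(scope = "pooled",
                        intercept = stats::coef(fit)[1L],
                        slope = stats::coef(fit)[2L])
  } else {
    seg$predicted <- NA_real_
    coefs <- list()
    for (cond in unique(seg$condition)) {
      sel <- seg$condition == cond
      fit <- stats::lm(r_hlr ~ r_locomotive, data = seg[sel, ])
      seg$predicted[sel] <- stats::predict(fit, seg[sel, ])
      coefs[[cond]] <- data.frame(scope = cond,
                                  intercept = stats::coef(fit)[1L],
                                  slope = stats::coef(fit)[2L])
    }
    coefs <- do.call(rbind, coefs)
  }
  rownames(coefs) <- NULL
  seg$residual <- seg$r_hlr - seg$predicted
  pm <- stats::aggregate(
    residual ~ cohort_id + condition + subject_i + subject_j, data = seg,
    FUN = mean)
  names(pm)[names(pm) == "residual"] <- "mean_residual"
  list(segments = seg, fit = coefs, pair_means = pm)
}

## ---- Granger causality ----

#' Bivariate Granger causality test
#'
#' Tests whether `x` Granger-causes `y` at the given lag: an F-test on the
#' residual sums of squares of the restricted autoregression
#' `y_t ~ 1 + y_{t-1..lag}` against the full model that adds
#' `x_{t-1..lag}`.
#'
#' @param x,y numeric series of equal length (candidate cause `x`, effect
#'   `y`).
#' @param lag model order in samples (default 1).
#' @return list with `F`, `p`, `df1`, `df2`, `n`.
#' @export
granger_test <- function(x, y, lag = 1L) {
  stopifnot(length(x) == length(y), lag >= 1L)
  n <- length(y)
  if (n < 10L * lag + 10L)
    stop("series too short for a reliable Granger test at this lag")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: Granger test undefined")
  t_idx <- (lag + 1L):n
  ylags <- vapply(seq_len(lag), function(l) y[t_idx - l],
                  numeric(length(t_idx)))
  xlags <- vapply(seq_len(lag), function(l) x[t_idx - l],
                  numeric(length(t_idx)))
  Y <- y[t_idx]
  Xr <- cbind(1, ylags)
  Xf <- cbind(Xr, xlags)
  rss_r <- sum(stats::.lm.fit(Xr, Y)$residuals^2)
  rss_f <- sum(stats::.lm.fit(Xf, Y)$residuals^2)
  df2 <- length(Y) - ncol(Xf)
  Fst <- ((rss_r - rss_f) / lag) / (rss_f / df2)
  list(F = Fst, p = stats::pf(Fst, lag, df2, lower.tail = FALSE),
       df1 = lag, df2 = df2, n = length(Y))
}

## listwise-valid alignment of a cohort's HLR series: gaps of <= bridge_s
## invalid seconds are linearly interpolated, otherwise the longest
## contiguous valid run is used (the AR models need contiguity)
.align_contiguous <- function(hlrs, bridge_s = 2L) {
  L <- min(vapply(hlrs, nrow, 0L))
  vals <- vapply(hlrs, function(h) h$hlr[seq_len(L)], numeric(L))
  ok <- apply(vapply(hlrs, function(h) h$valid[seq_len(L)], logical(L)),
              1L, all) & apply(is.finite(vals), 1L, all)
  if (!any(ok)) stop("no overlapping valid seconds")
  r <- rle(ok)
  gap_ok <- !r$values & r$lengths <= bridge_s
  # bridge short gaps not at the edges
  if (any(gap_ok)) {
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(gap_ok)) {
      if (g == 1L || g == length(r$values)) next
      idx <- starts[g]:ends[g]
      for (cc in seq_len(ncol(vals)))
        vals[idx, cc] <- stats::approx(
          x = c(starts[g] - 1L, ends[g] + 1L),
          y = vals[c(starts[g] - 1L, ends[g] + 1L), cc], xout = idx)$y
      ok[idx] <- TRUE
    }
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  vals[starts[best]:ends[best], , drop = FALSE]
}

#' Pairwise Granger causality matrix of a cohort
#'
#' Runs [granger_test()] at the given lag for every ordered pair of the
#' cohort's HLR series (all permutations: 1->2, 1->3, ..., 4->3) and
#' assembles the p-values into a matrix whose `[i, j]` entry tests "subject
#' i Granger-causes subject j".
#'
#' @param hlrs list of `hlr_series` from one cohort's group session.
#' @param lag model order in seconds (default 1).
#' @param bridge_s invalid-gap length (s) bridged by linear interpolation
#'   before falling back to the longest contiguous valid run.
#' @return object of class `granger_matrix`: `p` and `F` matrices (`NA`
#'   diagonal), `n_used` seconds, `lag`, `subjects`.
#' @export
granger_matrix <- function(hlrs, lag = 1L, bridge_s = 2L) {
  if (length(hlrs) < 2L) stop("need at least 2 series")
  subjects <- vapply(hlrs, function(h) h$subject_id[1L], "")
  vals <- .align_contiguous(hlrs, bridge_s)
  n <- ncol(vals)
  P <- Fm <- matrix(NA_real_, n, n, dimnames = list(subjects, subjects))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gt <- granger_test(vals[, i], vals[, j], lag = lag)
    P[i, j] <- gt$p
    Fm[i, j] <- gt$F
  }
  structure(list(p = P, F = Fm, n_used = nrow(vals), lag = lag,
                 subjects = subjects),
            class = "granger_matrix")
}

#' @export
print.granger_matrix <- function(x, ...) {
  cat(sprintf("<granger_matrix> lag %d, %d seconds used; p[i,j]: i -> j\n",
              x$lag, x$n_used))
  print(round(x$p, 4))
  invisible(x)
}

#' Classify pair directionality from a Granger p-value matrix
#'
#' For every unordered pair, the pair is `unidirectional` iff exactly one
#' direction is significant at `alpha`, `bidirectional` iff both are, and
#' `none` iff neither. Raw p-values are used by default, matching the
#' analysis convention; `p_adjust` applies a multiplicity correction over
#' all ordered pairs first.
#'
#' @param gm a `granger_matrix` (or a plain p-value matrix).
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust method passed to [stats::p.adjust()] (default
#'   `"none"`).
#' @return object of class `granger_graph`: `pairs` (per unordered pair:
#'   class and the significant direction if unidirectional), `edges`
#'   (directed edge list), `degrees` (per-subject out/in degree), `alpha`.
#' @export
classify_directionality <- function(gm, alpha = 0.05, p_adjust = "none") {
  P <- if (inherits(gm, "granger_matrix")) gm$p else gm
  subjects <- rownames(P)
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(P)))
  off <- !is.na(P)
  if (any(is.na(P[upper.tri(P) | lower.tri(P)])))
    stop("missing p-value for an ordered pair")
  Padj <- P
  Padj[off] <- stats::p.adjust(P[off], method = p_adjust)
  n <- nrow(P)
  pairs <- list()
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sig_ij <- Padj[i, j] < alpha
    sig_ji <- Padj[j, i] < alpha
    cls <- if (sig_ij && sig_ji) "bidirectional"
           else if (sig_ij || sig_ji) "unidirectional" else "none"
    dir <- if (cls == "unidirectional") {
      if (sig_ij) sprintf("%s->%s", subjects[i], subjects[j])
      else sprintf("%s->%s", subjects[j], subjects[i])
    } else NA_character_
    pairs[[length(pairs) + 1L]] <- data.frame(
      subject_i = subjects[i], subject_j = subjects[j], class = cls,
      direction = dir, p_ij = Padj[i, j], p_ji = Padj[j, i])
    if (sig_ij) edges[[length(edges) + 1L]] <-
      data.frame(from = subjects[i], to = subjects[j], p = Padj[i, j])
    if (sig_ji) edges[[length(edges) + 1L]] <-
      data.frame(from = subjects[j], to = subjects[i], p = Padj[j, i])
  }
  pairs <- do.call(rbind, pairs)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), p = numeric())
  degrees <- data.frame(
    subject_id = subjects,
    out_degree = vapply(subjects, function(s) sum(edges$from == s), 0L),
    in_degree = vapply(subjects, function(s) sum(edges$to == s), 0L),
    row.names = NULL)
  structure(list(pairs = pairs, edges = edges, degrees = degrees,
                 alpha = alpha, p_adjust = p_adjust),
            class = "granger_graph")
}

#' @export
print.granger_graph <- function(x, ...) {
  cat(sprintf("<granger_graph> alpha = %g (%s): %d unidirectional, %d bidirectional, %d none\n",
              x$alpha, x$p_adjust,
              sum(x$pairs$class == "unidirectional"),
              sum(x$pairs$class == "bidirectional"),
              sum(x$pairs$class == "none")))
  if (nrow(x$edges)) {
    cat("edges:\n")
    print(x$edges, row.names = FALSE)
  }
  invisible(x)
}
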