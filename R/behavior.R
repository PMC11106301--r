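#' Extract huddle episodes from per-second contact labels
#'
#' A huddle is a stable trunk-to-trunk aggregation of at least two animals.
#' The annotation table carries raw per-second contact labels
#' (`huddle_group_id`); this function applies the persistence rule: a
#' contiguous run of the same label must persist for more than
#' `min_persist_s` seconds (default 10 s) to count as an episode. Any
#' interruption of contact splits the run before the rule is applied, and
#' seconds where a label has fewer than two members are treated as
#' non-contact. Runs at or below the threshold are discarded and their
#' seconds counted as non-huddled.
#'
#' @param table an [annotation_table()] from a group-condition session.
#' @param min_persist_s persistence threshold in seconds; episodes must be
#'   strictly longer.
#' @return list with `episodes` (data.frame: `episode_id`, `label`,
#'   `start`, `end`, `duration`, `max_size`), `membership` (data.frame:
#'   `episode_id`, `second`, `subject_id`), `size_per_second` (integer
#'   vector, 0 = no huddle) and `huddled` (logical matrix seconds x
#'   subjects).
#' @export
huddle_episodes <- function(table, min_persist_s = 10) {
  stopifnot(inherits(table, "annotation_table"))
  if (attr(table, "condition") == "single") {
    if (any(!is.na(table$huddle_group_id)))
      stop("huddle labels present in a single-condition table")
  }
  T <- attr(table, "duration_s")
  subjects <- sort(unique(table$subject_id))
  ## contact matrix of labels, seconds x subjects
  lab <- matrix(NA_character_, nrow = T, ncol = length(subjects),
                dimnames = list(NULL, subjects))
  lab[cbind(table$second, match(table$subject_id, subjects))] <-
    table$huddle_group_id
  ## per second, a label only counts as contact if >= 2 members share it
  for (t in seq_len(T)) {
    tt <- table(lab[t, ])
    solo <- names(tt)[tt < 2L]
    if (length(solo)) lab[t, lab[t, ] %in% solo] <- NA_character_
  }
  active_lab <- apply(lab, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) sort(unique(r)) else character()
  })
  episodes <- list()
  membership <- list()
  all_labels <- sort(unique(stats::na.omit(as.vector(lab))))
  ep_id <- 0L
  for (lb in all_labels) {
    present <- vapply(seq_len(T), function(t) any(lab[t, ] == lb,
                                                  na.rm = TRUE), TRUE)
    r <- rle(present)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      if (r$lengths[i] <= min_persist_s) next  # persistence rule
      ep_id <- ep_id + 1L
      secs <- starts[i]:ends[i]
      mem <- which(lab[secs, , drop = FALSE] == lb, arr.ind = TRUE)
      episodes[[ep_id]] <- data.frame(
        episode_id = ep_id, label = lb, start = starts[i], end = ends[i],
        duration = r$lengths[i],
        max_size = max(tabulate(mem[, 1L])))
      membership[[ep_id]] <- data.frame(
        episode_id = ep_id, second = secs[mem[, 1L]],
        subject_id = subjects[mem[, 2L]])
    }
  }
  episodes <- if (length(episodes)) do.call(rbind, episodes) else
    data.frame(episode_id = integer(), label = character(),
               start = integer(), end = integer(), duration = integer(),
               max_size = integer())
  membership <- if (length(membership)) do.call(rbind, membership) else
    data.frame(episode_id = integer(), second = integer(),
               subject_id = character())
  huddled <- matrix(FALSE, nrow = T, ncol = length(subjects),
                    dimnames = list(NULL, subjects))
  if (nrow(membership))
    huddled[cbind(membership$second,
                  match(membership$subject_id, subjects))] <- TRUE
  size_per_second <- tabulate(membership$second, nbins = T)
  list(episodes = episodes, membership = membership,
       size_per_second = as.integer(size_per_second), huddled = huddled)
}

#' Time budget per subject
#'
#' Fraction of session seconds each subject spends in each category:
#' locomotive states, huddled/non-huddled status, or huddle size. Fractions
#' sum to 1 per subject.
#'
#' @param table an [annotation_table()].
#' @param by `"locomotive_state"`, `"huddle_status"` or `"huddle_size"`.
#' @param episodes optional result of [huddle_episodes()] (computed on
#'   demand for the huddle groupings).
#' @param min_persist_s persistence threshold forwarded to
#'   [huddle_episodes()].
#' @return data.frame with columns `subject_id`, `category`, `fraction`,
#'   plus a `"group_mean"` row block averaging over subjects.
#' @export
time_budget <- function(table, by = c("locomotive_state", "huddle_status",
                                      "huddle_size"),
                        episodes = NULL, min_persist_s = 10) {
  by <- match.arg(by)
  stopifnot(inherits(table, "annotation_table"))
  T <- attr(table, "duration_s")
  subjects <- sort(unique(table$subject_id))
  if (by == "locomotive_state") {
    cats <- .locomotive_states
    val <- factor(table$locomotive_state, levels = cats)
    subj <- table$subject_id
  } else {
    if (is.null(episodes)) episodes <- huddle_episodes(table, min_persist_s)
    if (by == "huddle_status") {
      cats <- c("huddled", "non_huddled")
      val <- factor(ifelse(as.vector(episodes$huddled), "huddled",
                           "non_huddled"), levels = cats)
      subj <- rep(subjects, each = T)
    } else {
      ## huddle size experienced by each subject-second: the size of the
      ## episode it participates in, else 0 ("none")
      sz <- matrix(0L, nrow = T, ncol = length(subjects))
      if (nrow(episodes$membership)) {
        m <- episodes$membership
        per_sec_size <- stats::aggregate(
          subject_id ~ episode_id + second, data = m, FUN = length)
        names(per_sec_size)[3L] <- "size"
        m <- merge(m, per_sec_size, by = c("episode_id", "second"))
        sz[cbind(m$second, match(m$subject_id, subjects))] <- m$size
      }
      cats <- c("none", as.character(2:max(2L, max(sz))))
      val <- factor(ifelse(as.vector(sz) == 0L, "none",
                           as.character(as.vector(sz))), levels = cats)
      subj <- rep(subjects, each = T)
    }
  }
  tab <- table(subject_id = subj, category = val)
  frac <- prop.table(tab, margin = 1L)
  out <- as.data.frame(frac, responseName = "fraction",
                       stringsAsFactors = FALSE)
  gm <- stats::aggregate(fraction ~ category, data = out, FUN = mean)
  gm <- data.frame(subject_id = "group_mean", gm)
  rbind(out, gm[, names(out)])
}

#' Label immobility-defined sleep
#'
#' Flags every second belonging to a contiguous run of `inactive` seconds of
#' length at least `min_immobile_s` as sleep. Any interruption (a single
#' non-inactive second) resets the run. The default threshold of 40 s is the
#' common immobility-defined-sleep convention; polysomnography is not
#' emulated.
#'
#' @param table an [annotation_table()].
#' @param min_immobile_s minimum immobile run length in seconds (>= 1).
#' @return the table with a logical `sleep` column added/replaced.
#' @export
label_sleep <- function(table, min_immobile_s = 40) {
  stopifnot(inherits(table, "annotation_table"))
  if (min_immobile_s < 1) stop("'min_immobile_s' must be at least 1 s")
  attrs <- attributes(table)
  sleep <- logical(nrow(table))
  for (s in unique(table$subject_id)) {
    idx <- which(table$subject_id == s)
    idx <- idx[order(table$second[idx])]
    r <- rle(table$locomotive_state[idx] == "inactive")
    flag <- rep(r$values & r$lengths >= min_immobile_s, r$lengths)
    sleep[idx] <- flag
  }
  table$sleep <- sleep
  attributes(table) <- utils::modifyList(attrs,
                                         list(names = names(table)))
  table
}

#' Align HLR series with behavioural annotations
#'
#' Joins per-second HLR values with locomotive state, huddle status (after
#' the episode persistence rule) and optional sleep flags, producing the
#' long-format segment table that cell means and external ANOVA consume.
#' Social context is `single`, `group_huddled` or `group_non_huddled`.
#'
#' @param hlr_list list of `hlr_series` (one per subject) from one session.
#' @param table the session's [annotation_table()].
#' @param episodes optional [huddle_episodes()] result.
#' @param min_persist_s persistence threshold for the huddle rule.
#' @return data.frame with columns `subject_id`, `second`, `condition`,
#'   `locomotive_state`, `huddle_status`, `context`, `sleep` (if present),
#'   `hlr`, `valid`.
#' @export
align_segments <- function(hlr_list, table, episodes = NULL,
                           min_persist_s = 10) {
  if (inherits(hlr_list, "hlr_series")) hlr_list <- list(hlr_list)
  condition <- attr(table, "condition")
  if (condition == "group" && is.null(episodes))
    episodes <- huddle_episodes(table, min_persist_s)
  subjects <- colnames(episodes$huddled)
  out <- lapply(hlr_list, function(h) {
    sid <- h$subject_id[1L]
    ann <- table[table$subject_id == sid, , drop = FALSE]
    if (nrow(ann) == 0L)
      stop("no annotations for HLR subject ", sid)
    m <- merge(h, ann[, setdiff(names(ann), "huddle_group_id"),
                      drop = FALSE],
               by = c("subject_id", "second"))
    m$condition <- condition
    m$huddle_status <- if (condition == "group")
      ifelse(episodes$huddled[m$second, match(sid, subjects)], "huddled",
             "non_huddled")
    else "single"
    m$context <- ifelse(m$condition == "single", "single",
                        paste0("group_", m$huddle_status))
    m[order(m$second), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' State-conditioned HLR cell means
#'
#' Mean, SD and n of the per-second HLR in every cell of locomotive state x
#' social context (and optionally sleep), the summary behind the
#' state/context comparisons. Seconds with invalid HLR are excluded and
#' counted. Empty cells are reported with `n = 0` and undefined mean.
#'
#' @param segments long-format table from [align_segments()], or a list
#'   `list(hlr_list, table)` pair via the `table` argument.
#' @param table optional [annotation_table()]; when supplied, `segments` is
#'   interpreted as an HLR series list and aligned first.
#' @param by grouping columns (subset of `locomotive_state`, `context`,
#'   `condition`, `huddle_status`, `sleep`).
#' @return data.frame of cells with `mean`, `sd`, `n` and an
#'   `n_invalid` attribute counting excluded seconds.
#' @export
condition_means <- function(segments, table = NULL,
                            by = c("locomotive_state", "context")) {
  if (!is.null(table)) segments <- align_segments(segments, table)
  by <- intersect(by, names(segments))
  if (!length(by)) stop("no grouping columns found in the segment table")
  n_invalid <- sum(!segments$valid)
  ok <- segments[segments$valid & is.finite(segments$hlr), , drop = FALSE]
  lev <- lapply(by, function(cn) {
    if (cn == "locomotive_state") .locomotive_states else
      sort(unique(segments[[cn]]))
  })
  names(lev) <- by
  cells <- expand.grid(lev, stringsAsFactors = FALSE)
  key <- do.call(paste, c(ok[by], sep = "\r"))
  ckey <- do.call(paste, c(cells, sep = "\r"))
  cells$mean <- vapply(ckey, function(k) {
    v <- ok$hlr[key == k]
    if (length(v)) mean(v) else NA_real_
  }, 0, USE.NAMES = FALSE)
  cells$sd <- vapply(ckey, function(k) {
    v <- ok$hlr[key == k]
    if (length(v) > 1L) stats::sd(v) else NA_real_
  }, 0, USE.NAMES = FALSE)
  cells$n <- vapply(ckey, function(k) sum(key == k), 0L,
                    USE.NAMES = FALSE)
  attr(cells, "n_invalid") <- n_invalid
  cells
}
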