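#' Elo-rating configuration
#'
#' Conventions for the sequential Elo-rating engine: every submission event
#' carries equal weight `k = 100`, individuals present at the onset start at
#' 1000 points, and an individual entering the hierarchy later (maturing or
#' immigrating) is initialized at the lowest score held by the group's
#' females on its entrance day, computed before any of that day's updates.
#'
#' @param k update constant (> 0); equal for all submission events.
#' @param initial score assigned to individuals present at the study onset.
#' @param win_prob expected-win-probability curve: `"normal"` (probit,
#'   `pnorm(diff / (200 * sqrt(2)))`, the convention of the standard
#'   sequential Elo-rating routine for animal dominance data) or
#'   `"logistic"` (`1 / (1 + 10^(-diff / 400))`, the chess convention).
#' @param timing which daily state is attached to same-day aggression:
#'   `"end_of_day"` (after all of the day's submission updates; default) or
#'   `"start_of_day"`.
#' @return An object of class `"elo_config"`.
#' @export
elo_config <- function(k = 100, initial = 1000,
                       win_prob = c("normal", "logistic"),
                       timing = c("end_of_day", "start_of_day")) {
  win_prob <- match.arg(win_prob)
  timing <- match.arg(timing)
  if (!is.finite(k) || k <= 0) stop("k must be a positive finite number")
  if (!is.finite(initial)) stop("initial score must be finite")
  structure(list(k = k, initial = initial, win_prob = win_prob,
                 timing = timing), class = "elo_config")
}

#' Expected winning probability
#'
#' Probability that the first individual wins an encounter given the two
#' current ratings, under either the probit (`"normal"`) or the classical
#' logistic curve. Satisfies `p(a, b) + p(b, a) = 1` and is strictly
#' increasing in the rating difference.
#'
#' @param r_a,r_b current ratings (Elo points).
#' @param method `"normal"` or `"logistic"`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
expected_win_prob <- function(r_a, r_b, method = c("normal", "logistic")) {
  method <- match.arg(method)
  if (!all(is.finite(r_a)) || !all(is.finite(r_b)))
    stop("ratings must be finite")
  d <- r_a - r_b
  switch(method,
         normal = stats::pnorm(d / (200 * sqrt(2))),
         logistic = 1 / (1 + 10^(-d / 400)))
}

#' Update the ratings of a winner and loser
#'
#' Both scores move by `(1 - p_winner) * k`: winners with low prior winning
#' probability gain more, and the total number of Elo points is conserved.
#'
#' @param r_winner,r_loser current ratings.
#' @param cfg an [elo_config()].
#' @return named numeric vector `c(winner = , loser = )`.
#' @export
update_ratings <- function(r_winner, r_loser, cfg = elo_config()) {
  p <- unname(expected_win_prob(r_winner, r_loser, cfg$win_prob))
  delta <- (1 - p) * cfg$k
  c(winner = unname(r_winner) + delta, loser = unname(r_loser) - delta)
}

#' Run the sequential Elo-rating over a submission-event log
#'
#' Processes decided-avoidance/displacement events in (date, file-order)
#' sequence, one hierarchy per group, producing a daily raw score for every
#' adult female present in the group. The `actor` of a submission record is
#' the individual that was avoided or that displaced (the winner); the
#' `receiver` is the one that yielded (the loser). Scores carry forward
#' unchanged between interaction days; individuals entering after the onset
#' start at the minimum raw score among the group's females on the entrance
#' day (taken before that day's updates).
#'
#' @param subs an `"interactions"` table; only `channel == "submission"` rows
#'   are used.
#' @param dem a [demography()] defining presence and adulthood.
#' @param cfg an [elo_config()].
#' @param thresholds an [age_thresholds()]; the rated population on each day
#'   is the adult females present in the group.
#' @param from,to first and last day of the rating grid; default to the span
#'   of the submission events.
#' @param groups groups to rate; defaults to all groups with entry records.
#' @return A data frame of class `"elo_ratings"` with one row per
#'   (group, individual, day): columns `group`, `id`, `date`, `raw`,
#'   `interacted`. Use [standardize_daily()] to add the within group-day
#'   standardized score.
#' @export
run_elo_sequence <- function(subs, dem, cfg = elo_config(),
                             thresholds = age_thresholds(),
                             from = NULL, to = NULL, groups = NULL) {
  stopifnot(inherits(dem, "demography"))
  s <- as.data.frame(subs)
  s$date <- as.Date(s$date)
  # the default grid spans all supplied events (aggression included), so
  # that same-day aggression preceding the first submission is still rated
  if (is.null(from)) from <- if (nrow(s)) min(s$date) else min(dem$events$date)
  if (is.null(to)) to <- if (nrow(s)) max(s$date) else max(dem$events$date)
  if (!is.null(s$channel)) s <- s[s$channel == "submission", , drop = FALSE]
  s <- s[order(s$date, method = "radix"), , drop = FALSE]
  from <- as.Date(from); to <- as.Date(to)
  if (is.null(groups)) groups <- dem_groups(dem)
  days <- seq(from, to, by = "day")
  nd <- length(days)

  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pres <- presence_matrix(dem, g, days, thresholds = thresholds, sex = "F")
    ids <- rownames(pres)
    if (!length(ids)) next
    sg <- s[s$group == g, , drop = FALSE]
    bad <- setdiff(unique(c(sg$actor, sg$receiver)), ids)
    if (length(bad))
      stop("submission event in group ", g, " involves individual(s) not ",
           "rated there (absent, male, or under-age): ",
           paste(bad, collapse = ", "))
    day_idx <- as.integer(sg$date - from) + 1L
    cur <- stats::setNames(rep(NA_real_, length(ids)), ids)
    entered <- stats::setNames(rep(FALSE, length(ids)), ids)
    raw <- matrix(NA_real_, length(ids), nd, dimnames = list(ids, NULL))
    inter <- matrix(FALSE, length(ids), nd, dimnames = list(ids, NULL))
    ev_by_day <- split(seq_len(nrow(sg)), factor(day_idx, levels = seq_len(nd)))
    for (t in seq_len(nd)) {
      here <- pres[, t]
      newcomers <- ids[here & !entered]
      if (length(newcomers)) {
        # entrance-day minimum uses carried-forward scores before any of the
        # day's updates; at the onset (or an empty group) the initial score
        base <- cur[entered & here]
        init <- if (t == 1L || !length(base)) cfg$initial else min(base)
        cur[newcomers] <- init
        entered[newcomers] <- TRUE
      }
      evs <- ev_by_day[[t]]
      if (length(evs)) {
        for (e in evs) {
          w <- sg$actor[e]; l <- sg$receiver[e]
          if (!here[w] || !here[l])
            stop("submission on ", format(days[t]), " in group ", g,
                 " involves an individual not present that day: ",
                 paste(c(w, l)[!here[c(w, l)]], collapse = ", "))
          up <- update_ratings(cur[w], cur[l], cfg)
          cur[w] <- up[["winner"]]; cur[l] <- up[["loser"]]
          inter[w, t] <- TRUE; inter[l, t] <- TRUE
        }
      }
      raw[here, t] <- cur[here]
    }
    keep <- which(!is.na(raw))
    out[[gi]] <- data.frame(
      group = g,
      id = rep(ids, times = nd)[keep],
      date = rep(days, each = length(ids))[keep],
      raw = raw[keep],
      interacted = inter[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group = character(), id = character(),
                      date = as.Date(character()), raw = numeric(),
                      interacted = logical())
  rownames(res) <- NULL
  attr(res, "config") <- cfg
  class(res) <- c("elo_ratings", "data.frame")
  res
}

#' Study-level Elo standings
#'
#' The study-level hierarchy of each group: every individual's mean raw and
#' mean standardized score over a trailing window of the rated span,
#' ordered into ranks (1 = top). A single-day snapshot of an Elo trajectory
#' is jolted by update noise (one event moves a score by up to `k` points),
#' so the stable ordering that daily scores fluctuate around is estimated
#' by time-averaging; individuals absent from the common window (e.g.
#' departed females) are averaged over the trailing window of their own
#' rated days instead.
#'
#' @param series an `"elo_ratings"` table from [standardize_daily()].
#' @param window_frac trailing fraction of the rated span to average over.
#' @return data frame `group`, `id`, `mean_raw`, `mean_std`, `rank`.
#' @export
elo_ranking <- function(series, window_frac = 0.5) {
  x <- as.data.frame(series)
  if (is.null(x$std)) stop("run standardize_daily() first")
  out <- do.call(rbind, lapply(split(x, x$group), function(g) {
    cut <- max(g$date) - floor(as.numeric(max(g$date) - min(g$date)) * window_frac)
    res <- do.call(rbind, lapply(split(g, g$id), function(gi) {
      w <- gi[gi$date >= cut, , drop = FALSE]
      if (!nrow(w)) {
        cuti <- max(gi$date) -
          floor(as.numeric(max(gi$date) - min(gi$date)) * window_frac)
        w <- gi[gi$date >= cuti, , drop = FALSE]
      }
      data.frame(group = gi$group[1], id = gi$id[1],
                 mean_raw = mean(w$raw),
                 mean_std = mean(w$std, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    res$rank <- rank(-res$mean_raw, ties.method = "min")
    res
  }))
  rownames(out) <- NULL
  out
}

#' Standardize Elo-scores within group and day
#'
#' Per group-day, raw scores are mapped linearly so that the highest score is
#' 1 and the lowest 0 (`(s - min) / (max - min)`), over all adult females
#' present that day (interacted or not). Degenerate group-days are handled
#' explicitly: a single present female gets `NA` (no within-group rank is
#' defined), and a day on which all present females hold the identical raw
#' score gets 0.5 for everyone. Aggression falling on `NA` days is excluded
#' downstream, with a logged count.
#'
#' @param series an `"elo_ratings"` table from [run_elo_sequence()].
#' @return the same table with a `std` column added.
#' @export
standardize_daily <- function(series) {
  x <- as.data.frame(series)
  key <- paste(x$group, x$date)
  lo <- stats::ave(x$raw, key, FUN = min)
  hi <- stats::ave(x$raw, key, FUN = max)
  n <- stats::ave(x$raw, key, FUN = length)
  rng <- hi - lo
  std <- ifelse(n < 2, NA_real_, ifelse(rng == 0, 0.5, (x$raw - lo) / rng))
  x$std <- std
  attr(x, "config") <- attr(series, "config")
  class(x) <- c("elo_ratings", "data.frame")
  x
}
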