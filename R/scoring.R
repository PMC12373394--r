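#' Interaction score: recipient minus aggressor standardized Elo
#'
#' The score of an aggressive interaction is the recipient's standardized
#' Elo-score minus the aggressor's. It is +1 when the group's lowest-ranking
#' female attacks the highest-ranking one, -1 for the reverse, and in
#' general positive for aggression up and negative for aggression down the
#' hierarchy.
#'
#' @param aggressor_std,recipient_std standardized Elo-scores in `[0, 1]`.
#' @return numeric score in `[-1, 1]`.
#' @export
interaction_score <- function(aggressor_std, recipient_std) {
  if (anyNA(aggressor_std) || anyNA(recipient_std))
    stop("standardized Elo-score missing; events on degenerate group-days ",
         "must be excluded, never silently scored")
  if (any(aggressor_std < 0 | aggressor_std > 1 |
          recipient_std < 0 | recipient_std > 1))
    stop("standardized Elo-scores must lie in [0, 1]")
  recipient_std - aggressor_std
}

# join standardized scores onto events; returns events + actor_std,
# receiver_std, score, plus attr "dropped" with exclusion counts.
# reference picks the rating state: the event day's end-of-day scores
# (default), the standings carried into the day, or the time-averaged
# study-level standings from elo_ranking().
attach_scores <- function(events, ratings,
                          reference = c("event_day", "previous_day",
                                        "study", "rolling"),
                          window = 180L) {
  reference <- match.arg(reference)
  x <- as.data.frame(events)
  r <- as.data.frame(ratings)
  if (is.null(r$std)) stop("ratings lack standardized scores; run standardize_daily()")
  if (reference == "rolling") {
    # mean standardized score over [date - window, date + window]: the
    # stable standing around the event, immune to single-event jolts and
    # era-consistent for individuals with partial tenure
    r <- r[order(r$group, r$id, r$date, method = "radix"), , drop = FALSE]
    keys <- paste(r$group, r$id)
    idx <- split(seq_len(nrow(r)), keys)
    roll_std <- function(ids, groups, dates) {
      dates <- as.Date(dates)
      vapply(seq_along(ids), function(i) {
        ii <- idx[[paste(groups[i], ids[i])]]
        if (is.null(ii)) return(NA_real_)
        dd <- r$date[ii]
        j <- ii[dd >= dates[i] - window & dd <= dates[i] + window]
        if (!length(j)) return(NA_real_)
        mean(r$std[j], na.rm = TRUE)
      }, numeric(1))
    }
    x$actor_std <- roll_std(x$actor, x$group, x$date)
    x$receiver_std <- roll_std(x$receiver, x$group, x$date)
    not_rated <- is.na(x$actor_std) & is.na(x$receiver_std)  # never rated
    degenerate <- is.nan(x$actor_std) | is.nan(x$receiver_std)
    x$score <- ifelse(is.na(x$actor_std) | is.na(x$receiver_std), NA_real_,
                      x$receiver_std - x$actor_std)
    attr(x, "dropped") <- c(not_rated = sum(not_rated),
                            degenerate_day = sum(degenerate, na.rm = TRUE))
    return(x)
  }
  if (reference == "study") {
    rk0 <- elo_ranking(ratings)
    r <- data.frame(group = rk0$group, id = rk0$id, std = rk0$mean_std,
                    stringsAsFactors = FALSE)
    rk <- paste(r$group, r$id)
    key <- function(g, i, d) paste(g, i)
  } else {
    lag <- if (reference == "previous_day") 1L else 0L
    rk <- paste(r$group, r$id, format(as.Date(r$date)))
    key <- function(g, i, d) paste(g, i, format(as.Date(d) - lag))
  }
  ia <- match(key(x$group, x$actor, x$date), rk)
  ir <- match(key(x$group, x$receiver, x$date), rk)
  # an individual rated in a different group the same day signals a
  # cross-group event: a consistency error, not a silent exclusion
  if (reference == "study") {
    idk <- r$id
    ekey <- function(ids, dates) ids
  } else {
    idk <- paste(r$id, format(r$date))
    ekey <- function(ids, dates) paste(ids, format(as.Date(dates) - lag))
  }
  for (side in c("actor", "receiver")) {
    im <- if (side == "actor") ia else ir
    missn <- which(is.na(im))
    if (length(missn)) {
      other <- match(ekey(x[[side]][missn], x$date[missn]), idk)
      if (any(!is.na(other)))
        stop("event(s) involve individuals rated in a different group the ",
             "same day: ",
             paste(unique(x[[side]][missn][!is.na(other)]), collapse = ", "))
    }
  }
  x$actor_std <- r$std[ia]
  x$receiver_std <- r$std[ir]
  not_rated <- is.na(ia) | is.na(ir)
  degenerate <- !not_rated & (is.na(x$actor_std) | is.na(x$receiver_std))
  x$score <- ifelse(not_rated | degenerate, NA_real_,
                    x$receiver_std - x$actor_std)
  attr(x, "dropped") <- c(not_rated = sum(not_rated),
                          degenerate_day = sum(degenerate))
  x
}

#' Score submission or aggression events against daily ratings
#'
#' `score_events()` attaches the interaction score (receiver minus actor
#' standardized Elo) to any event table, dropping events whose participants
#' are unrated or whose group-day is degenerate; it is the summary route for
#' submission events. [score_interactions()] additionally attaches the model
#' covariates to aggression events.
#'
#' @param events an `"interactions"` table (or any data frame with `date`,
#'   `group`, `actor`, `receiver`).
#' @param ratings standardized ratings from [standardize_daily()].
#' @param reference rating state an event is scored against:
#'   `"event_day"` uses the end-of-day scores of the event's own day (the
#'   aggression convention); `"previous_day"` the standings carried into
#'   the day, before its own updates; `"study"` the time-averaged
#'   study-level standings from [elo_ranking()] — the appropriate
#'   reference when asking what fraction of submission events ran against
#'   the stable hierarchy they themselves establish, since day-level
#'   ratings are jolted by the very events being classified.
#' @return the retained events with a `score` column; exclusion counts in
#'   `attr(, "dropped")`.
#' @export
score_events <- function(events, ratings,
                         reference = c("event_day", "previous_day",
                                       "study", "rolling"), window = 180L) {
  x <- attach_scores(events, ratings, reference = reference, window = window)
  dropped <- attr(x, "dropped")
  out <- x[!is.na(x$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Score aggression events and attach model covariates
#'
#' One output row per retained adult-female aggression event: the
#' interaction score (recipient minus aggressor standardized Elo, using the
#' end-of-day scores of the event day by default), the aggressor's
#' reproductive state, the numbers of adult males and females in the group
#' that day, species, intensity, and the unordered dyad key shared by both
#' directions of a pair. Events are excluded — with reasons tallied in
#' `attr(, "exclusions")` and reported via a message — when a participant is
#' not a rated adult female of the group that day (`not_rated`), the
#' group-day is degenerate (`degenerate_day`: a single female, so no
#' standardized score exists), the aggressor's state is `unknown`
#' (`unknown_state`), or composition is unavailable
#' (`missing_composition`).
#'
#' @param aggr an `"interactions"` table; only `channel == "aggression"`
#'   rows are used.
#' @param ratings standardized ratings from [standardize_daily()].
#' @param states state table from [state_table()].
#' @param composition composition table from [composition_table()].
#' @return data frame of class `"scored_aggression"`: `date`, `group`,
#'   `aggressor`, `recipient`, `behaviour`, `intensity`, `score`, `state`,
#'   `n_males`, `n_females`, `species`, `dyad`.
#' @export
score_interactions <- function(aggr, ratings, states, composition) {
  x <- as.data.frame(aggr)
  if (!is.null(x$channel)) x <- x[x$channel == "aggression", , drop = FALSE]
  x$date <- as.Date(x$date)
  x <- attach_scores(x, ratings)
  dropped <- attr(x, "dropped")

  sk <- paste(states$id, format(as.Date(states$date)))
  x$state <- states$state[match(paste(x$actor, format(x$date)), sk)]
  ck <- paste(composition$group, format(as.Date(composition$date)))
  ic <- match(paste(x$group, format(x$date)), ck)
  x$n_males <- composition$n_males[ic]
  x$n_females <- composition$n_females[ic]
  x$species <- composition$species[ic]

  unknown_state <- !is.na(x$score) &
    (is.na(x$state) | x$state == "unknown")
  missing_comp <- !is.na(x$score) & !unknown_state & is.na(ic)
  keep <- !is.na(x$score) & !unknown_state & !missing_comp
  exclusions <- c(dropped, unknown_state = sum(unknown_state),
                  missing_composition = sum(missing_comp))
  if (sum(exclusions) > 0)
    message("score_interactions: excluded ", sum(exclusions), " event(s) [",
            paste(names(exclusions), exclusions, sep = "=", collapse = ", "),
            "]")
  out <- data.frame(
    date = x$date[keep], group = x$group[keep],
    aggressor = x$actor[keep], recipient = x$receiver[keep],
    behaviour = x$behaviour[keep],
    intensity = factor(as.character(x$intensity[keep]),
                       levels = intensity_levels),
    score = x$score[keep],
    state = factor(as.character(x$state[keep]),
                   levels = reproductive_states[reproductive_states != "unknown"]),
    n_males = x$n_males[keep], n_females = x$n_females[keep],
    species = factor(x$species[keep], levels = c("mountain", "western")),
    stringsAsFactors = FALSE)
  out$dyad <- paste(pmin(out$aggressor, out$recipient),
                    pmax(out$aggressor, out$recipient), sep = ":")
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  class(out) <- c("scored_aggression", "data.frame")
  out
}

#' Direction summary of scored events
#'
#' Per group: the percentage of events directed up the hierarchy
#' (`score > 0`), down (`score < 0`), and exactly tied (`score == 0`; ties
#' are possible only when two females share a raw score and are reported as
#' their own category rather than folded into either direction). The pooled
#' figure is the unweighted mean (and SD) of the group percentages, matching
#' the convention of reporting an across-group average rather than a
#' pooled-event percentage. When an `intensity` column is present, the
#' within-direction intensity composition is reported as well.
#'
#' @param x a `"scored_aggression"` table, or any data frame with `group`
#'   and `score` columns (e.g. scored submission events from
#'   [score_events()]).
#' @return An object of class `"direction_summary"`: list with `by_group`
#'   (per-group counts and percentages), `pooled` (`mean_pct_up`,
#'   `sd_pct_up`, `n_events`, `n_groups`), and optionally
#'   `intensity_by_direction`.
#' @export
direction_summary <- function(x) {
  x <- as.data.frame(x)
  stopifnot(all(c("group", "score") %in% names(x)))
  if (!nrow(x)) stop("no scored events to summarize")
  empty <- setdiff(unique(x$group), x$group[!is.na(x$score)])
  if (length(empty))
    warning("group(s) without scored events omitted from the across-group ",
            "mean: ", paste(empty, collapse = ", "))
  by_group <- do.call(rbind, lapply(split(x, x$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               pct_up = 100 * mean(g$score > 0),
               pct_down = 100 * mean(g$score < 0),
               pct_tied = 100 * mean(g$score == 0),
               stringsAsFactors = FALSE)
  }))
  rownames(by_group) <- NULL
  pooled <- list(mean_pct_up = mean(by_group$pct_up),
                 sd_pct_up = stats::sd(by_group$pct_up),
                 n_events = nrow(x), n_groups = nrow(by_group))
  res <- list(by_group = by_group, pooled = pooled)
  if (!is.null(x$intensity)) {
    dir <- ifelse(x$score > 0, "up", ifelse(x$score < 0, "down", "tied"))
    tab <- 100 * prop.table(table(direction = dir,
                                  intensity = x$intensity), margin = 1)
    res$intensity_by_direction <- tab
  }
  class(res) <- "direction_summary"
  res
}

#' @export
print.direction_summary <- function(x, digits = 1, ...) {
  cat("Aggression direction by group:\n")
  print(cbind(x$by_group[1:2],
              round(x$by_group[3:5], digits)), row.names = FALSE)
  cat(sprintf("Across-group mean up-hierarchy: %.1f%% (SD %.1f), %d events in %d group(s)\n",
              x$pooled$mean_pct_up, x$pooled$sd_pct_up,
              x$pooled$n_events, x$pooled$n_groups))
  if (!is.null(x$intensity_by_direction)) {
    cat("Intensity composition within direction (%):\n")
    print(round(x$intensity_by_direction, digits))
  }
  invisible(x)
}
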