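test_that("interaction score hits the +1/-1 anchors and subtracts exactly", {
  expect_identical(interaction_score(0, 1), 1)     # lowest attacks highest
  expect_identical(interaction_score(1, 0), -1)    # highest attacks lowest
  expect_equal(interaction_score(0.5625, 0), -0.5625)
  expect_error(interaction_score(NA, 0.5), "missing")
  expect_error(interaction_score(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the score is antisymmetric and bounded, attaining the bounds
           only for extreme pairs", {
  set.seed(2)
  a <- runif(200); b <- runif(200)
  expect_equal(interaction_score(a, b), -interaction_score(b, a))
  s <- interaction_score(a, b)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(all(abs(s) < 1 | (pmin(a, b) == 0 & pmax(a, b) == 1)))
})

scored_fixture <- function() {
  dem <- make_dem(n_females = 3)
  # make F01 > F02 > F03 in the hierarchy, then three aggression events
  ev <- interactions(data.frame(
    date = c("2020-01-02", "2020-01-03", "2020-01-05", "2020-01-05",
             "2020-01-06"),
    group = "G",
    actor = c("F01", "F02", "F03", "F01", "F02"),
    receiver = c("F02", "F03", "F01", "F03", "F01"),
    behaviour = c("displace", "avoid", "bite", "chest_beat", "scream")))
  r <- standardize_daily(run_elo_sequence(ev, dem, from = "2020-01-01",
                                          to = "2020-01-06"))
  st <- state_table(dem, from = "2020-01-01", to = "2020-01-06")
  st$state[] <- "cycling"
  comp <- composition_table(dem, from = "2020-01-01", to = "2020-01-06")
  list(dem = dem, ev = ev, r = r, st = st, comp = comp)
}

test_that("score_interactions scores retained events end-of-day and carries
           all covariates", {
  fx <- scored_fixture()
  sa <- suppressMessages(score_interactions(fx$ev, fx$r, fx$st, fx$comp))
  expect_s3_class(sa, "scored_aggression")
  expect_identical(nrow(sa), 3L)
  # lowest attacks highest on a settled day: score +1
  up <- sa[sa$aggressor == "F03" & sa$recipient == "F01", ]
  expect_equal(up$score, 1)
  expect_identical(as.character(up$intensity), "severe")
  expect_identical(up$dyad, "F01:F03")
  expect_true(all(sa$n_females == 3 & sa$n_males == 0))
  expect_true(all(as.character(sa$state) == "cycling"))
  expect_identical(as.character(unique(sa$species)), "mountain")
})

test_that("events with unknown aggressor state are excluded and tallied,
           never silently scored", {
  fx <- scored_fixture()
  st <- fx$st
  st$state[st$id == "F02"] <- "unknown"
  msgs <- capture_messages(
    sa <- score_interactions(fx$ev, fx$r, st, fx$comp))
  expect_match(paste(msgs, collapse = ""), "unknown_state=1")
  expect_identical(nrow(sa), 2L)
  expect_identical(attr(sa, "exclusions")[["unknown_state"]], 1L)
})

test_that("aggression on a single-female (degenerate) day is excluded with
           a counted reason", {
  extra <- data.frame(id = "X", event_type = c("birth", "entry"),
                      date = as.Date(c("2005-01-01", "2020-02-01")),
                      group = c(NA, "G"), sex = c("F", NA),
                      species = c("mountain", NA), detail = NA)
  dem <- make_dem(n_females = 1, extra = extra)
  ev <- interactions(data.frame(date = "2020-01-05", group = "G",
                                actor = "F01", receiver = "X",
                                behaviour = "bite"))
  r <- standardize_daily(run_elo_sequence(ev[0, ], dem,
                                          from = "2020-01-01", to = "2020-03-01"))
  st <- state_table(dem, from = "2020-01-01", to = "2020-03-01")
  st$state[] <- "cycling"
  comp <- composition_table(dem, from = "2020-01-01", to = "2020-03-01")
  sa <- suppressMessages(score_interactions(ev, r, st, comp))
  expect_identical(nrow(sa), 0L)
  expect_identical(sum(attr(sa, "exclusions")), 1L)
})

test_that("direction_summary computes per-group percentages, the unweighted
           across-group mean, and a tied category", {
  x <- data.frame(group = "A", score = c(0.3, -0.2, 0.1, -0.8))
  s <- direction_summary(x)
  expect_equal(s$by_group$pct_up, 50)
  x2 <- data.frame(group = rep(c("A", "B"), c(5, 5)),
                   score = c(rep(1, 2), rep(-1, 3), rep(1, 3), rep(-1, 2)))
  s2 <- direction_summary(x2)
  expect_equal(s2$pooled$mean_pct_up, 50)
  expect_equal(s2$pooled$sd_pct_up, sqrt(200))   # groups at 40% and 60%
  all_up <- direction_summary(data.frame(group = "A", score = rep(0.2, 7)))
  expect_equal(all_up$by_group$pct_up, 100)
  with_tie <- direction_summary(data.frame(group = "A", score = c(0, 0.5, -0.5)))
  expect_equal(with_tie$by_group$pct_up + with_tie$by_group$pct_down +
                 with_tie$by_group$pct_tied, 100)
  expect_equal(with_tie$by_group$pct_tied, 100 / 3)
})

test_that("direction_summary reports the intensity mix within direction", {
  x <- data.frame(group = "A", score = c(0.5, 0.5, -0.5, -0.5),
                  intensity = factor(c("mild", "severe", "mild", "mild"),
                                     levels = c("mild", "moderate", "severe")))
  s <- direction_summary(x)
  expect_equal(unname(s$intensity_by_direction["up", "mild"]), 50)
  expect_equal(unname(s$intensity_by_direction["down", "mild"]), 100)
})

test_that("score_events supports daily and study-level references and logs
           drops", {
  fx <- scored_fixture()
  subs <- fx$ev[fx$ev$channel == "submission", ]
  se_day <- score_events(subs, fx$r)
  expect_identical(nrow(se_day), 2L)
  se_study <- score_events(subs, fx$r, reference = "study")
  expect_identical(nrow(se_study), 2L)
  se_roll <- score_events(subs, fx$r, reference = "rolling", window = 30L)
  expect_identical(nrow(se_roll), 2L)
  # previous-day reference drops the first grid day's event
  first_day <- interactions(data.frame(date = "2020-01-01", group = "G",
                                       actor = "F01", receiver = "F02",
                                       behaviour = "avoid"))
  se_prev <- score_events(first_day, fx$r, reference = "previous_day")
  expect_identical(nrow(se_prev), 0L)
  expect_identical(attr(se_prev, "dropped")[["not_rated"]], 1L)
})
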