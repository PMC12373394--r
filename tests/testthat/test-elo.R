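test_that("expected winning probabilities match their closed forms and are
           symmetric and monotone", {
  expect_equal(expected_win_prob(1000, 1000, "normal"), 0.5)
  expect_equal(expected_win_prob(1000, 1000, "logistic"), 0.5)
  expect_equal(expected_win_prob(1200, 1000, "logistic"), 0.7597469,
               tolerance = 1e-6)
  expect_equal(expected_win_prob(1200, 1000, "normal"), 0.7602499,
               tolerance = 1e-6)
  d <- seq(-800, 800, by = 50)
  for (m in c("normal", "logistic")) {
    p <- expected_win_prob(1000 + d, 1000, m)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(diff(p) > 0))
    expect_equal(p + expected_win_prob(1000, 1000 + d, m), rep(1, length(d)))
  }
  expect_error(expected_win_prob(Inf, 1000), "finite")
})

test_that("rating updates conserve points, split the symmetric contest
           50/50 at k=100, and vanish for sure winners", {
  expect_equal(update_ratings(1000, 1000), c(winner = 1050, loser = 950))
  set.seed(1)
  for (i in 1:50) {
    ra <- runif(1, 500, 1500); rb <- runif(1, 500, 1500)
    up <- update_ratings(ra, rb, elo_config(k = 100))
    expect_equal(sum(up), ra + rb)
  }
  up <- update_ratings(3000, 1000)
  expect_lt(up[["winner"]] - 3000, 1e-6)
})

test_that("the worked micro-sequence reproduces carry-forward, the 1050/950
           update, and the entrant-at-minimum rule", {
  extra <- data.frame(id = "C", event_type = c("birth", "entry"),
                      date = as.Date(c("2008-01-01", "2020-01-03")),
                      group = c(NA, "G"), sex = c("F", NA),
                      species = c("mountain", NA), detail = NA)
  dem <- make_dem(n_females = 2, extra = extra)
  ev <- interactions(data.frame(date = "2020-01-02", group = "G",
                                actor = "F01", receiver = "F02",
                                behaviour = "displace"))
  r <- run_elo_sequence(ev, dem, from = "2020-01-01", to = "2020-01-04")
  g <- function(id, day) r$raw[r$id == id & r$date == as.Date(day)]
  expect_equal(g("F01", "2020-01-01"), 1000)    # onset score
  expect_equal(g("F01", "2020-01-02"), 1050)
  expect_equal(g("F02", "2020-01-02"), 950)
  expect_equal(g("F01", "2020-01-04"), 1050)    # carry-forward
  expect_equal(g("C", "2020-01-03"), 950)       # entrant at current minimum
  expect_true(all(r$interacted[r$date == as.Date("2020-01-02") &
                                 r$id %in% c("F01", "F02")]))
})

test_that("an empty submission log leaves every present female at the
           initial score on every day", {
  dem <- make_dem(n_females = 3)
  ev <- interactions(data.frame(date = character(), group = character(),
                                actor = character(), receiver = character(),
                                behaviour = character()))
  r <- run_elo_sequence(ev, dem, from = "2020-01-01", to = "2020-01-05")
  expect_identical(nrow(r), 15L)
  expect_true(all(r$raw == 1000))
})

test_that("events naming absent or unrated individuals are consistency
           errors", {
  dem <- make_dem(n_females = 2)
  ghost <- interactions(data.frame(date = "2020-01-02", group = "G",
                                   actor = "F01", receiver = "NOBODY",
                                   behaviour = "avoid"))
  expect_error(run_elo_sequence(ghost, dem, from = "2020-01-01",
                                to = "2020-01-03"), "NOBODY")
})

test_that("run_elo_sequence matches a naive event-by-event recomputation
           exactly on random sequences", {
  dem <- make_dem(n_females = 8)
  ids <- sprintf("F%02d", 1:8)
  set.seed(99)
  for (rep in 1:60) {
    n_ev <- sample(20:120, 1)
    ev <- random_submissions(n_ev, ids)
    r <- run_elo_sequence(ev, dem, from = "2020-01-01", to = "2020-03-01")
    last <- r[r$date == max(r$date), ]
    oracle <- naive_elo(as.data.frame(ev), ids)
    expect_equal(stats::setNames(last$raw, last$id)[ids], oracle)
  }
})

test_that("total Elo points are conserved across a closed-group sequence", {
  dem <- make_dem(n_females = 6)
  ids <- sprintf("F%02d", 1:6)
  set.seed(5)
  ev <- random_submissions(300, ids)
  r <- run_elo_sequence(ev, dem, from = "2020-01-01", to = "2020-03-01")
  daily_total <- tapply(r$raw, r$date, sum)
  expect_true(all(abs(daily_total - 6000) < 1e-8))
})

test_that("daily standardization maps the micro-example to 0.5625/1/0 and
           handles degenerate group-days explicitly", {
  r <- data.frame(group = "G", id = c("A", "B", "C"),
                  date = as.Date("2020-01-01"),
                  raw = c(986, 1014, 950), interacted = TRUE)
  class(r) <- c("elo_ratings", "data.frame")
  s <- standardize_daily(r)
  expect_equal(s$std, c(0.5625, 1, 0))
  # singleton: no within-group rank defined
  one <- r[1, ]
  expect_true(is.na(standardize_daily(one)$std))
  # zero range: everyone at 0.5
  tie <- r; tie$raw <- 1000
  expect_equal(standardize_daily(tie)$std, rep(0.5, 3))
})

test_that("standardized scores are invariant to affine maps of the raw
           scores within a group-day", {
  set.seed(11)
  r <- data.frame(group = "G", id = letters[1:5],
                  date = as.Date("2020-01-01"),
                  raw = rnorm(5, 1000, 120), interacted = FALSE)
  s1 <- standardize_daily(r)$std
  r2 <- r; r2$raw <- 3.7 * r$raw + 212
  expect_equal(standardize_daily(r2)$std, s1)
})

test_that("rank recovery: time-averaged study ordering tracks the latent
           hierarchy on noisy synthetic submissions", {
  dem <- make_dem(n_females = 6)
  ids <- sprintf("F%02d", 1:6)
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    latent <- sample(6)
    n_ev <- 500
    days <- as.Date("2020-01-01") + sort(sample.int(730, n_ev, replace = TRUE)) - 1
    pair <- t(vapply(seq_len(n_ev), function(i) sample(ids, 2), character(2)))
    dom <- ifelse(latent[match(pair[, 1], ids)] < latent[match(pair[, 2], ids)],
                  pair[, 1], pair[, 2])
    sub <- ifelse(dom == pair[, 1], pair[, 2], pair[, 1])
    rev <- runif(n_ev) < 0.15
    ev <- interactions(data.frame(
      date = days, group = "G",
      actor = ifelse(rev, sub, dom), receiver = ifelse(rev, dom, sub),
      behaviour = "displace", stringsAsFactors = FALSE))
    r <- standardize_daily(run_elo_sequence(ev, dem, from = "2020-01-01",
                                            to = "2021-12-31"))
    rk <- elo_ranking(r)
    cor(-latent, rk$mean_raw[match(ids, rk$id)], method = "spearman")
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.95)
})
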