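# shared fixtures, built in code

# a small single-group demography: n adult females present from `from`,
# plus optional adult males; mountain species unless stated
make_dem <- function(n_females = 3, n_males = 0, group = "G",
                     species = "mountain", from = as.Date("2020-01-01"),
                     extra = NULL) {
  rows <- list()
  add <- function(id, type, date, grp = NA, sex = NA, spp = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, event_type = type, date = as.Date(date), group = grp,
      sex = sex, species = spp, detail = NA_character_,
      stringsAsFactors = FALSE)
  for (i in seq_len(n_females)) {
    id <- sprintf("F%02d", i)
    add(id, "birth", from - round((12 + i) * 365.25), sex = "F", spp = species)
    add(id, "entry", from, grp = group)
  }
  for (i in seq_len(n_males)) {
    id <- sprintf("M%02d", i)
    add(id, "birth", from - round((15 + i) * 365.25), sex = "M", spp = species)
    add(id, "entry", from, grp = group)
  }
  ev <- do.call(rbind, rows)
  if (!is.null(extra)) ev <- rbind(ev, extra)
  demography(ev)
}

# deliberately naive sequential Elo recomputation: a flat loop over events
# with its own update arithmetic, independent of run_elo_sequence
naive_elo <- function(events, ids, k = 100, initial = 1000,
                      method = c("normal", "logistic")) {
  method <- match.arg(method)
  s <- stats::setNames(rep(initial, length(ids)), ids)
  for (i in seq_len(nrow(events))) {
    w <- events$actor[i]; l <- events$receiver[i]
    p <- if (method == "normal") pnorm((s[w] - s[l]) / (200 * sqrt(2)))
         else 1 / (1 + 10^(-(s[w] - s[l]) / 400))
    s[w] <- s[w] + (1 - p) * k
    s[l] <- s[l] - (1 - p) * k
  }
  s
}

# random submission sequence over one group, as an interactions table
random_submissions <- function(n_events, ids, from = as.Date("2020-01-01"),
                               n_days = 60, group = "G") {
  days <- from + sort(sample.int(n_days, n_events, replace = TRUE)) - 1L
  pairs <- t(vapply(seq_len(n_events), function(i) sample(ids, 2),
                    character(2)))
  interactions(data.frame(
    date = days, group = group, actor = pairs[, 1], receiver = pairs[, 2],
    behaviour = sample(c("avoid", "displace"), n_events, replace = TRUE),
    stringsAsFactors = FALSE))
}

# a small fitted model on model-simulated scores (shared by model tests)
small_fit <- local({
  fit <- NULL
  function(family = "linear") {
    if (!is.null(fit) && fit$family == family) return(fit)
    sc <- simulation_scenario(
      seed = 42,
      groups = data.frame(name = c("G1", "G2"),
                          species = c("mountain", "western"),
                          n_females = c(6L, 7L), stringsAsFactors = FALSE),
      span_days = 500L)
    b <- simulate_study(sc)
    d <- b$truth
    d$dyad <- paste(pmin(d$aggressor, d$recipient),
                    pmax(d$aggressor, d$recipient), sep = ":")
    d$score <- simulate_scores(d, beta = sc$beta, sigma = sc$sigma, seed = 43)
    fit <<- suppressWarnings(direction_model(d, family = family))
    fit
  }
})
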