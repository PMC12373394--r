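#' Simulation scenario for synthetic study bundles
#'
#' Describes a complete synthetic study: group sizes and species mirroring a
#' multi-group female gorilla study (one western, four mountain groups of
#' 6-9 females), a stable latent hierarchy per group, submission events
#' directed down the latent hierarchy except for a reversal fraction
#' `epsilon` (default 0.16, matching the observed share of
#' avoidance/displacement events running up-hierarchy), aggression events
#' whose interaction score is drawn around a linear predictor with the
#' published effect sizes as ground truth, and demography records
#' (parturitions, matings, nipple contacts) constructed so that
#' [classify_state()] reproduces the intended daily state sequence exactly.
#'
#' The default score model (`beta`, on the interaction-score scale) uses
#' the published fixed-effect estimates as generator truth (moderate -0.030,
#' severe -0.014, males +0.018, females -0.011, trimesters
#' +0.130/+0.093/+0.146, lactating +0.043, western +0.088); the intercept
#' and residual scale `sigma` are generator design constants, calibrated
#' once so that the pooled up-hierarchy fraction of the default scenario
#' sits near the observed 42%.
#'
#' @param groups data frame with columns `name`, `species`, `n_females`
#'   (total females ever in the group, entrants included).
#' @param start first study day (`Date`); `span_days` the study length.
#' @param submission_rate expected submission events per dyad-day.
#' @param aggression_rate expected aggression events per present-female-day.
#' @param epsilon probability that a submission event runs up the latent
#'   hierarchy; must lie in `[0, 0.5)`.
#' @param beta named vector of true score-model coefficients (see Details).
#' @param sigma residual SD of the target score draw.
#' @param re_sd named vector of random-intercept SDs used in generation
#'   (`aggressor`, `group`).
#' @param intensity_probs sampling probabilities of `mild`, `moderate`,
#'   `severe` aggression.
#' @param gestation_days gestation length (days; pregnancy window).
#' @param lactation_days,cycling_days min/max duration (days) of the
#'   lactation and cycling phases of the simulated reproductive cycle.
#' @param mating_interval,nipple_interval days between observed matings
#'   (while cycling) and nipple contacts (while lactating).
#' @param n_males_range range of the initial adult-male count per group.
#' @param male_changes range of the number of male arrivals/departures per
#'   group over the study.
#' @param entrants_per_group females per group that mature into the
#'   hierarchy during the study; `exits_per_group` resident females that
#'   leave; `transients_per_group` immigrant females present for only part
#'   of the study. Together these reproduce the within-group variability of
#'   daily female counts seen in multi-year field records.
#' @param seed root seed; every stochastic element derives from it.
#' @return validated list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(
    groups = data.frame(
      name = c("ATL", "BRA", "KIB", "MUH", "ORB"),
      species = c("western", "mountain", "mountain", "mountain", "mountain"),
      n_females = c(6L, 6L, 9L, 8L, 8L),
      stringsAsFactors = FALSE),
    start = as.Date("2015-01-01"), span_days = 1096L,
    submission_rate = 0.05, aggression_rate = 0.2557,
    epsilon = 0.16,
    beta = c(intercept = -0.168, moderate = -0.030, severe = -0.014,
             n_males = 0.018, n_females = -0.011,
             pregnant_1 = 0.130, pregnant_2 = 0.093, pregnant_3 = 0.146,
             lactating = 0.043, western = 0.088),
    sigma = 0.30,
    re_sd = c(aggressor = 0.03, group = 0.02),
    intensity_probs = c(mild = 0.824, moderate = 0.098, severe = 0.078),
    gestation_days = 255L,
    lactation_days = c(550L, 950L), cycling_days = c(60L, 300L),
    mating_interval = 15L, nipple_interval = 30L,
    n_males_range = c(1L, 4L), male_changes = c(2L, 5L),
    entrants_per_group = 2L, exits_per_group = 2L,
    transients_per_group = 1L,
    seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("name", "species", "n_females") %in% names(groups)))
  if (epsilon < 0 || epsilon >= 0.5) stop("epsilon must lie in [0, 0.5)")
  if (submission_rate <= 0 || aggression_rate <= 0)
    stop("event rates must be positive")
  if (any(groups$n_females < 2 + entrants_per_group + transients_per_group))
    stop("each group needs at least two founder females")
  need_b <- c("intercept", "moderate", "severe", "n_males", "n_females",
              "pregnant_1", "pregnant_2", "pregnant_3", "lactating", "western")
  if (!all(need_b %in% names(beta)))
    stop("beta must name: ", paste(need_b, collapse = ", "))
  # attainability: the linear predictor must stay inside the score range
  states_b <- c(0, beta[c("pregnant_1", "pregnant_2", "pregnant_3", "lactating")])
  ints_b <- c(0, beta[c("moderate", "severe")])
  mu_rng <- beta[["intercept"]] +
    range(outer(states_b, ints_b, "+")) +
    range(beta[["n_males"]] * n_males_range) +
    range(beta[["n_females"]] * range(groups$n_females)) +
    c(0, beta[["western"]])
  if (any(abs(mu_rng) > 1))
    stop("unattainable mean score (|mu| > 1) under this scenario; ",
         "shrink the coefficients or the covariate ranges")
  sc <- list(groups = groups, start = as.Date(start),
             span_days = as.integer(span_days),
             submission_rate = submission_rate,
             aggression_rate = aggression_rate, epsilon = epsilon,
             beta = beta, sigma = sigma, re_sd = re_sd,
             intensity_probs = intensity_probs,
             gestation_days = as.integer(gestation_days),
             lactation_days = lactation_days, cycling_days = cycling_days,
             mating_interval = as.integer(mating_interval),
             nipple_interval = as.integer(nipple_interval),
             n_males_range = n_males_range, male_changes = male_changes,
             entrants_per_group = as.integer(entrants_per_group),
             exits_per_group = as.integer(exits_per_group),
             transients_per_group = as.integer(transients_per_group),
             seed = as.integer(seed))
  class(sc) <- "simulation_scenario"
  sc
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat("Simulation scenario:", nrow(x$groups), "groups,",
      sum(x$groups$n_females), "females,", x$span_days, "days, seed",
      x$seed, "\n")
  invisible(x)
}

adult_onset <- function(birth, thr) birth + floor(thr * 365.25) + 1

# reproductive timeline of one female from adulthood onward: demography
# events plus ground-truth state intervals, built so classify_state()
# reproduces the intended states exactly (a mating opens every cycling
# phase; the last nipple contact falls on the final lactation day)
gen_timeline <- function(adult_from, until, sc) {
  ev_date <- list(); ev_type <- list()
  iv_from <- c(); iv_to <- c(); iv_state <- c()
  t <- as.integer(adult_from)
  while (t <= as.integer(until)) {
    dc <- sample(sc$cycling_days[1]:sc$cycling_days[2], 1L)
    mats <- seq(t, t + dc - 1L, by = sc$mating_interval)
    ev_date[[length(ev_date) + 1L]] <- mats
    ev_type[[length(ev_type) + 1L]] <- rep("mating", length(mats))
    iv_from <- c(iv_from, t); iv_to <- c(iv_to, t + dc - 1L)
    iv_state <- c(iv_state, "cycling")
    cpt <- t + dc                                    # conception day
    part <- cpt + sc$gestation_days                  # parturition
    ev_date[[length(ev_date) + 1L]] <- part
    ev_type[[length(ev_type) + 1L]] <- "parturition"
    iv_from <- c(iv_from, cpt, cpt + 85L, cpt + 170L)
    iv_to <- c(iv_to, cpt + 84L, cpt + 169L, part - 1L)
    iv_state <- c(iv_state, "pregnant_1", "pregnant_2", "pregnant_3")
    dl <- sample(sc$lactation_days[1]:sc$lactation_days[2], 1L)
    nips <- unique(c(seq(part, part + dl, by = sc$nipple_interval), part + dl))
    ev_date[[length(ev_date) + 1L]] <- nips
    ev_type[[length(ev_type) + 1L]] <- rep("nipple_contact", length(nips))
    iv_from <- c(iv_from, part); iv_to <- c(iv_to, part + dl)
    iv_state <- c(iv_state, "lactating")
    t <- part + dl + 1L
  }
  list(events = data.frame(date = as.Date(unlist(ev_date), origin = "1970-01-01"),
                           event_type = unlist(ev_type),
                           stringsAsFactors = FALSE),
       intervals = data.frame(from = iv_from, to = iv_to, state = iv_state,
                              stringsAsFactors = FALSE))
}

truth_state <- function(intervals, days) {
  d <- as.integer(days)
  i <- findInterval(d, intervals$from)
  ok <- i > 0 & d <= intervals$to[pmax(i, 1L)]
  out <- rep("unknown", length(d))
  out[ok] <- intervals$state[i[ok]]
  factor(out, levels = reproductive_states)
}

#' Simulate one study group
#'
#' Generates the group's demography (founder and maturing females with full
#' reproductive timelines, adult males arriving and departing), its
#' submission-event log directed down a fixed latent hierarchy with
#' reversal probability `epsilon`, its daily Elo-scores (via the package's
#' own rating engine, end-of-day convention), and its aggression events:
#' for each event a target score is drawn from the linear score model and
#' the recipient is the present female whose realized rank difference is
#' nearest the target (ties broken by a seed-controlled shuffle), so
#' ground-truth scores are attainable in small groups by construction.
#'
#' @param sc a [simulation_scenario()].
#' @param g group index into `sc$groups`.
#' @param thresholds an [age_thresholds()].
#' @return list with `interactions` (raw event rows), `demography_events`,
#'   `states` (ground-truth female-day states), and `truth` (aggression
#'   events with realized scores and covariates).
#' @export
simulate_group <- function(sc, g, thresholds = age_thresholds()) {
  stopifnot(inherits(sc, "simulation_scenario"))
  gi <- sc$groups[g, ]
  seed_g <- (sc$seed * 1009L + 97L * g) %% 2147483647L
  with_seed(seed_g, simulate_group_impl(sc, gi, thresholds))
}

simulate_group_impl <- function(sc, gi, thresholds) {
  start <- sc$start
  end <- start + sc$span_days - 1L
  gname <- gi$name; species <- gi$species
  thr_f <- thresholds$female[[species]]
  thr_m <- thresholds$male[[species]]
  eth <- default_ethogram()

  n_total <- gi$n_females
  n_entr <- sc$entrants_per_group
  n_exit <- sc$exits_per_group
  n_trans <- sc$transients_per_group
  fids <- sprintf("%s_F%02d", gname, seq_len(n_total))
  founders <- fids[seq_len(n_total - n_entr - n_trans)]
  entrants <- fids[seq_len(n_entr) + length(founders)]
  transients <- setdiff(fids, c(founders, entrants))

  ev <- list()
  add_ev <- function(id, type, date, group = NA, sex = NA, species_ = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      id = id, event_type = type, date = as.Date(date, origin = "1970-01-01"),
      group = group, sex = sex, species = species_, detail = NA_character_,
      stringsAsFactors = FALSE)
  }

  pres_from <- stats::setNames(rep(start, n_total), fids)
  pres_to <- stats::setNames(rep(end, n_total), fids)
  birth <- stats::setNames(rep(start, n_total), fids)
  for (id in founders) {
    age <- stats::runif(1, thr_f + 3, thr_f + 18)
    birth[id] <- start - round(age * 365.25)
  }
  for (id in entrants) {
    e <- start + sample(floor(0.1 * sc$span_days):floor(0.8 * sc$span_days), 1L)
    birth[id] <- e - (floor(thr_f * 365.25) + 1L)   # matures exactly on entry
    pres_from[id] <- e
  }
  for (id in transients) {                          # immigrant, partial tenure
    e <- start + sample(floor(0.1 * sc$span_days):floor(0.6 * sc$span_days), 1L)
    birth[id] <- e - round(stats::runif(1, thr_f + 2, thr_f + 10) * 365.25)
    pres_from[id] <- e
    pres_to[id] <- min(end - 1L, e +
      sample(floor(0.2 * sc$span_days):floor(0.4 * sc$span_days), 1L))
  }
  if (n_exit > 0) {
    leavers <- sample(founders, n_exit)
    for (id in leavers)
      pres_to[id] <- start +
        sample(floor(0.2 * sc$span_days):floor(0.9 * sc$span_days), 1L)
  }
  ivs <- list()
  for (id in fids) {
    add_ev(id, "birth", birth[id], sex = "F", species_ = species)
    add_ev(id, "entry", pres_from[id], group = gname)
    if (pres_to[id] < end) add_ev(id, "exit", pres_to[id], group = gname)
    tl <- gen_timeline(adult_onset(birth[id], thr_f), pres_to[id], sc)
    for (ty in unique(tl$events$event_type))
      add_ev(id, ty, tl$events$date[tl$events$event_type == ty])
    ivs[[id]] <- tl$intervals
  }

  # adult males: a piecewise-constant head count realized via entries/exits
  n0 <- sample(sc$n_males_range[1]:sc$n_males_range[2], 1L)
  nch <- sample(sc$male_changes[1]:sc$male_changes[2], 1L)
  chg_days <- sort(start + sample(30:(sc$span_days - 30L), nch))
  mk <- 0L
  new_male <- function(day) {
    mk <<- mk + 1L
    id <- sprintf("%s_M%02d", gname, mk)
    add_ev(id, "birth", day - round(stats::runif(1, thr_m + 2, thr_m + 15) * 365.25),
           sex = "M", species_ = species)
    add_ev(id, "entry", day, group = gname)
    id
  }
  males <- vapply(seq_len(n0), function(i) new_male(start), character(1))
  cur_n <- n0
  for (d in chg_days) {
    up <- if (cur_n <= sc$n_males_range[1]) TRUE else
      if (cur_n >= sc$n_males_range[2] + 1L) FALSE else stats::runif(1) < 0.5
    if (up) {
      males <- c(males, new_male(d))
      cur_n <- cur_n + 1L
    } else {
      out <- sample(males, 1L)
      add_ev(out, "exit", d, group = gname)
      males <- setdiff(males, out)
      cur_n <- cur_n - 1L
    }
  }

  events <- do.call(rbind, ev)
  dem <- demography(events)
  days <- seq(start, end, by = "day")
  presF <- presence_matrix(dem, gname, days, thresholds = thresholds, sex = "F")
  presM <- presence_matrix(dem, gname, days, thresholds = thresholds, sex = "M")
  nf_day <- colSums(presF)
  nm_day <- colSums(presM)

  # ground-truth states over present female-days
  states <- do.call(rbind, lapply(rownames(presF), function(id) {
    dd <- days[presF[id, ]]
    if (!length(dd)) return(NULL)
    data.frame(group = gname, id = id, date = dd,
               state = truth_state(ivs[[id]], dd), stringsAsFactors = FALSE)
  }))

  # submission events down a fixed latent hierarchy (rank 1 = top);
  # females maturing into or immigrating into the group hold the lowest
  # ranks, as newcomers do in female gorilla hierarchies
  n_found <- length(founders)
  latent <- stats::setNames(
    c(sample(seq_len(n_found)),
      n_found + sample(seq_len(n_total - n_found))),
    c(founders, entrants, transients))
  latent <- latent[fids]
  dyads_day <- choose(nf_day, 2)
  n_sub <- stats::rpois(1, sc$submission_rate * sum(dyads_day))
  sub_day <- sort(sample.int(length(days), n_sub, replace = TRUE,
                             prob = dyads_day))
  sub_w <- sub_l <- character(n_sub)
  rev <- stats::runif(n_sub) < sc$epsilon
  for (i in seq_len(n_sub)) {
    t <- sub_day[i]
    pair <- sample(rownames(presF)[presF[, t]], 2L)
    dominant <- pair[which.min(latent[pair])]
    subordinate <- setdiff(pair, dominant)
    sub_w[i] <- if (rev[i]) subordinate else dominant
    sub_l[i] <- if (rev[i]) dominant else subordinate
  }
  subs <- data.frame(date = days[sub_day], group = rep(gname, n_sub),
                     actor = sub_w, receiver = sub_l,
                     behaviour = sample(eth$submission, n_sub, replace = TRUE),
                     stringsAsFactors = FALSE)

  # daily standardized scores via the package's own engine (end-of-day)
  ratings <- standardize_daily(run_elo_sequence(
    interactions(subs, eth), dem, elo_config(), thresholds,
    from = start, to = end, groups = gname))
  std <- matrix(NA_real_, nrow(presF), length(days),
                dimnames = list(rownames(presF), NULL))
  std[cbind(match(ratings$id, rownames(presF)),
            as.integer(ratings$date - start) + 1L)] <- ratings$std

  # aggression events: target score from the linear model, recipient the
  # nearest attainable rank difference
  re_aggr <- stats::setNames(stats::rnorm(n_total, 0, sc$re_sd[["aggressor"]]),
                             fids)
  re_group <- stats::rnorm(1, 0, sc$re_sd[["group"]])
  b <- sc$beta
  elig_idx <- which(nf_day >= 2)
  n_agg <- stats::rpois(1, sc$aggression_rate * sum(nf_day[elig_idx]))
  agg_day <- sort(elig_idx[sample.int(length(elig_idx), n_agg, replace = TRUE,
                                      prob = nf_day[elig_idx])])
  ints <- sample(intensity_levels, n_agg, replace = TRUE,
                 prob = sc$intensity_probs)
  skey <- paste(states$id, states$date)
  state_of <- stats::setNames(as.character(states$state), skey)
  int_off <- c(mild = 0, moderate = b[["moderate"]], severe = b[["severe"]])
  st_off <- c(cycling = 0, b[c("pregnant_1", "pregnant_2", "pregnant_3",
                               "lactating")])
  aggr_v <- rec_v <- code_v <- st_v <- character(n_agg)
  score_v <- numeric(n_agg)
  noise <- stats::rnorm(n_agg, 0, sc$sigma)
  for (i in seq_len(n_agg)) {
    t <- agg_day[i]
    here <- rownames(presF)[presF[, t]]
    aggr <- sample(here, 1L)
    others <- sample(setdiff(here, aggr))           # shuffled: seed-set ties
    st <- state_of[[paste(aggr, days[t])]]
    mu <- b[["intercept"]] + int_off[[ints[i]]] + st_off[[st]] +
      b[["n_males"]] * nm_day[t] + b[["n_females"]] * nf_day[t] +
      (if (species == "western") b[["western"]] else 0) +
      re_aggr[[aggr]] + re_group
    diffs <- std[others, t] - std[aggr, t]
    pick <- which.min(abs(diffs - (mu + noise[i])))
    aggr_v[i] <- aggr; rec_v[i] <- others[pick]
    st_v[i] <- st; score_v[i] <- unname(diffs[pick])
    code_v[i] <- sample(eth[[ints[i]]], 1L)
  }
  aggs <- data.frame(date = days[agg_day], group = rep(gname, n_agg),
                     actor = aggr_v, receiver = rec_v, behaviour = code_v,
                     stringsAsFactors = FALSE)
  truth <- data.frame(date = days[agg_day], group = rep(gname, n_agg),
                      aggressor = aggr_v, recipient = rec_v,
                      intensity = ints, score = score_v, state = st_v,
                      n_males = as.integer(unname(nm_day[agg_day])),
                      n_females = as.integer(unname(nf_day[agg_day])),
                      species = rep(species, n_agg), stringsAsFactors = FALSE)

  list(interactions = rbind(subs, aggs), demography_events = events,
       states = states, truth = truth,
       hierarchy = data.frame(group = gname, id = fids,
                              latent_rank = unname(latent),
                              stringsAsFactors = FALSE))
}

#' Simulate a complete multi-group study bundle
#'
#' Runs [simulate_group()] over every group of the scenario and assembles a
#' validated bundle: the combined interaction log (stably date-ordered,
#' within-day generation order preserved), the validated demography, the
#' ground-truth daily states, and the ground-truth aggression scores with
#' covariates. Given the same scenario (including its seed) the bundle is
#' identical across runs.
#'
#' @param sc a [simulation_scenario()].
#' @param thresholds an [age_thresholds()].
#' @return An object of class `"synthetic_bundle"`: list with
#'   `interactions`, `demography`, `states`, `truth`, `hierarchy` (the
#'   latent rank order per group, 1 = top), and `scenario`.
#' @export
simulate_study <- function(sc, thresholds = age_thresholds()) {
  stopifnot(inherits(sc, "simulation_scenario"))
  frags <- lapply(seq_len(nrow(sc$groups)), simulate_group, sc = sc,
                  thresholds = thresholds)
  inter <- interactions(do.call(rbind, lapply(frags, `[[`, "interactions")))
  dem <- demography(do.call(rbind, lapply(frags, `[[`, "demography_events")))
  states <- do.call(rbind, lapply(frags, `[[`, "states"))
  truth <- do.call(rbind, lapply(frags, `[[`, "truth"))
  hier <- do.call(rbind, lapply(frags, `[[`, "hierarchy"))
  rownames(states) <- rownames(truth) <- rownames(hier) <- NULL
  structure(list(interactions = inter, demography = dem, states = states,
                 truth = truth, hierarchy = hier, scenario = sc),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic study bundle: ",
      sum(x$interactions$channel == "submission"), " submission and ",
      sum(x$interactions$channel == "aggression"), " aggression events, ",
      nrow(x$demography$individuals), " individuals, seed ",
      x$scenario$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate interaction scores from the direction model's own process
#'
#' Draws a response vector for an existing covariate table from the
#' generative process the direction model assumes: a linear predictor on
#' the score scale with the supplied coefficients, plus independent random
#' intercepts for aggressor, recipient, dyad and group, plus Gaussian
#' noise, clamped to the attainable score range `[-1, 1]`. This is the
#' canonical parameter-recovery design for validating the estimator
#' itself: responses generated from the model being fitted, on the
#' realistic covariate structure of a synthetic bundle.
#'
#' It deliberately differs from the behavioural score mechanism of
#' [simulate_group()], where covariates shift which recipient is attacked
#' and the realized score is the chosen recipient's rank difference. Under
#' that selection mechanism the covariate effects live entirely between
#' dyads, and a model with identity random intercepts absorbs them — an
#' identification limit of rank-difference responses under stable
#' hierarchies, discussed in the package vignette.
#'
#' @param covars data frame with columns `intensity`, `n_males`,
#'   `n_females`, `state`, `species`, `aggressor`, `recipient`, `dyad`,
#'   `group` (e.g. the `truth` table of a bundle, or a
#'   `"scored_aggression"` table).
#' @param beta named coefficient vector as in [simulation_scenario()]
#'   (`intercept`, `moderate`, `severe`, `n_males`, `n_females`,
#'   `pregnant_1`, `pregnant_2`, `pregnant_3`, `lactating`, `western`).
#' @param sigma residual SD on the score scale.
#' @param re_sd named vector of random-intercept SDs (`aggressor`,
#'   `recipient`, `dyad`, `group`); missing names default to 0.
#' @param seed RNG seed.
#' @return numeric score vector in `[-1, 1]`, one per row of `covars`.
#' @export
simulate_scores <- function(covars, beta, sigma = 0.3,
                            re_sd = c(aggressor = 0.05, recipient = 0.05,
                                      dyad = 0.02, group = 0.02),
                            seed = 1) {
  x <- as.data.frame(covars)
  if (is.null(x$dyad))
    x$dyad <- paste(pmin(x$aggressor, x$recipient),
                    pmax(x$aggressor, x$recipient), sep = ":")
  sdv <- function(nm) if (nm %in% names(re_sd)) re_sd[[nm]] else 0
  int_off <- c(mild = 0, moderate = beta[["moderate"]],
               severe = beta[["severe"]])
  st_off <- c(cycling = 0, beta[c("pregnant_1", "pregnant_2", "pregnant_3",
                                  "lactating")])
  names(st_off) <- c("cycling", "pregnant_1", "pregnant_2", "pregnant_3",
                     "lactating")
  with_seed(seed, {
    draw <- function(ids, nm) {
      u <- stats::setNames(stats::rnorm(length(unique(ids)), 0, sdv(nm)),
                           unique(ids))
      u[ids]
    }
    mu <- beta[["intercept"]] +
      int_off[as.character(x$intensity)] +
      beta[["n_males"]] * x$n_males + beta[["n_females"]] * x$n_females +
      st_off[as.character(x$state)] +
      ifelse(as.character(x$species) == "western", beta[["western"]], 0) +
      draw(x$aggressor, "aggressor") + draw(x$recipient, "recipient") +
      draw(x$dyad, "dyad") + draw(x$group, "group")
    pmin(1, pmax(-1, unname(mu) + stats::rnorm(nrow(x), 0, sigma)))
  })
}

#' Write a synthetic bundle to a directory
#'
#' Writes `interactions.csv` and `demography.csv` in the formats that
#' [read_interactions()] and [read_demography()] accept, plus the ground
#' truth (`states.csv`, `truth.csv`) for validation.
#'
#' @param bundle a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(bundle$interactions, file.path(dir, "interactions.csv"))
  write_demography(bundle$demography, file.path(dir, "demography.csv"))
  utils::write.csv(bundle$states, file.path(dir, "states.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
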