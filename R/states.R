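#' Species-specific adult-age thresholds
#'
#' Adulthood is strict: an individual counts as adult only when its age in
#' years strictly exceeds the species threshold. Defaults: females > 10
#' (western) and > 8 (mountain) years; males > 14 (western) and > 12
#' (mountain) years.
#'
#' @param female,male named numeric vectors with elements `western` and
#'   `mountain` (years).
#' @return An object of class `"age_thresholds"`.
#' @export
age_thresholds <- function(female = c(western = 10, mountain = 8),
                           male = c(western = 14, mountain = 12)) {
  for (v in list(female, male))
    if (!all(c("western", "mountain") %in% names(v)) || any(v <= 0))
      stop("thresholds must be positive and keyed by species")
  structure(list(female = female, male = male), class = "age_thresholds")
}

threshold_for <- function(thresholds, species, sex) {
  tab <- ifelse(sex == "F", "female", "male")
  vapply(seq_along(species), function(i)
    thresholds[[tab[i]]][[species[i]]], numeric(1))
}

reproductive_states <- c("cycling", "pregnant_1", "pregnant_2", "pregnant_3",
                         "lactating", "unknown")

#' Classify a female's daily reproductive state
#'
#' A female is *pregnant* on a given day when a parturition falls 1 to 255
#' days after that day; the pregnancy day `p = 256 - (days until birth)` is
#' binned into trimesters of 85 days each (`[1, 85]`, `[86, 170]`,
#' `[171, 255]`), so the day before birth is pregnancy day 255 and the
#' parturition day itself is the first lactation day. Otherwise she is
#' *cycling* when a mating has been observed on or before the day and after
#' her last parturition (for nulliparous females: after she reached adult
#' age); otherwise *lactating* when she has a dependent infant, i.e. the day
#' is not after the last nipple-contact record of her most recent offspring;
#' otherwise *unknown* (no residual category is defined, and unknown
#' female-days are excluded from modelling with a logged count).
#'
#' @param dem a [demography()].
#' @param id female identifier.
#' @param days vector of days (`Date`).
#' @param thresholds an [age_thresholds()] (used for the nulliparous-cycling
#'   rule).
#' @return factor over `days` with levels `cycling`, `pregnant_1`,
#'   `pregnant_2`, `pregnant_3`, `lactating`, `unknown`.
#' @export
classify_state <- function(dem, id, days, thresholds = age_thresholds()) {
  stopifnot(inherits(dem, "demography"))
  days <- as.Date(days)
  birth <- dem_birth(dem, id)
  if (is.na(birth)) stop("unknown individual: ", id)
  if (any(days < birth)) stop("day before birth of ", id)
  if (!identical(dem_sex(dem, id), "F"))
    stop("reproductive state is defined for females only: ", id)
  parts <- sort(dem_dates(dem, id, "parturition"))
  mats <- sort(dem_dates(dem, id, "mating"))
  nips <- sort(dem_dates(dem, id, "nipple_contact"))
  thr <- threshold_for(thresholds, dem_species(dem, id), "F")
  adult_from <- birth + floor(thr * 365.25) + 1  # first day with age > thr

  d <- as.integer(days)
  if (length(parts)) {
    pi <- findInterval(d, as.integer(parts))        # parturitions <= day
    last_part <- ifelse(pi > 0L, as.integer(parts)[pmax(pi, 1L)], NA_integer_)
    next_part <- ifelse(pi < length(parts),
                        as.integer(parts)[pmin(pi + 1L, length(parts))],
                        NA_integer_)
  } else {
    last_part <- next_part <- rep(NA_integer_, length(d))
  }
  until <- next_part - d
  p_day <- 256L - until                              # pregnancy day in [1, 255]
  pregnant <- !is.na(until) & until >= 1L & until <= 255L
  trimester <- 1L + (p_day > 85L) + (p_day > 170L)

  # cycling: a mating after the last parturition (or after adulthood when
  # nulliparous), observed on or before the day
  mi <- as.integer(mats)
  cyc <- vapply(seq_along(d), function(i) {
    lb <- if (is.na(last_part[i])) as.integer(adult_from) - 1L else last_part[i]
    any(mi > lb & mi <= d[i])
  }, logical(1))

  # lactating: dependent infant from the most recent parturition, day not
  # past its last nipple-contact record
  ni <- as.integer(nips)
  lac <- vapply(seq_along(d), function(i) {
    if (is.na(last_part[i])) return(FALSE)
    dep <- ni[ni >= last_part[i]]
    length(dep) > 0L && d[i] <= max(dep)
  }, logical(1))

  state <- rep("unknown", length(d))
  state[lac] <- "lactating"
  state[cyc] <- "cycling"
  state[pregnant] <- paste0("pregnant_", trimester[pregnant])
  factor(state, levels = reproductive_states)
}

#' Daily reproductive-state table for all adult females
#'
#' Applies [classify_state()] to every adult female present in each group on
#' each day of the window.
#'
#' @param dem a [demography()].
#' @param from,to window (`Date`); default to the demography event span.
#' @param groups group labels; default all.
#' @param thresholds an [age_thresholds()].
#' @return data frame `group`, `id`, `date`, `state`.
#' @export
state_table <- function(dem, from = NULL, to = NULL, groups = NULL,
                        thresholds = age_thresholds()) {
  stopifnot(inherits(dem, "demography"))
  if (is.null(from)) from <- min(dem$events$date)
  if (is.null(to)) to <- max(dem$events$date)
  from <- as.Date(from); to <- as.Date(to)
  if (is.null(groups)) groups <- dem_groups(dem)
  days <- seq(from, to, by = "day")
  out <- list()
  for (g in groups) {
    pres <- presence_matrix(dem, g, days, thresholds = thresholds, sex = "F")
    for (id in rownames(pres)) {
      dd <- days[pres[id, ]]
      if (!length(dd)) next
      out[[length(out) + 1L]] <- data.frame(
        group = g, id = id, date = dd,
        state = classify_state(dem, id, dd, thresholds),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(), id = character(),
               date = as.Date(character()),
               state = factor(character(), levels = reproductive_states))
  rownames(res) <- NULL
  res
}

#' Daily adult group composition
#'
#' Counts the adult males and adult females present in a group on each day,
#' using strict species-specific age thresholds. Individuals without a birth
#' date cannot occur in a validated [demography()]; the age rule is strict,
#' so an individual exactly at the threshold age is not counted.
#'
#' @param dem a [demography()].
#' @param group group label (scalar) for `group_composition()`; `groups` a
#'   vector for `composition_table()`.
#' @param days vector of days (`Date`).
#' @param thresholds an [age_thresholds()].
#' @return data frame `group`, `date`, `n_males`, `n_females`, `species`.
#' @export
group_composition <- function(dem, group, days, thresholds = age_thresholds()) {
  days <- as.Date(days)
  pf <- presence_matrix(dem, group, days, thresholds = thresholds, sex = "F")
  pm <- presence_matrix(dem, group, days, thresholds = thresholds, sex = "M")
  sp <- unique(dem_species(dem, rownames(pf)))
  if (!length(sp)) sp <- unique(dem_species(dem, rownames(pm)))
  data.frame(group = group, date = days,
             n_males = as.integer(colSums(pm)),
             n_females = as.integer(colSums(pf)),
             species = if (length(sp)) sp[1] else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname group_composition
#' @param from,to window (`Date`); default to the demography event span.
#' @export
composition_table <- function(dem, groups = NULL, from = NULL, to = NULL,
                              thresholds = age_thresholds()) {
  stopifnot(inherits(dem, "demography"))
  if (is.null(from)) from <- min(dem$events$date)
  if (is.null(to)) to <- max(dem$events$date)
  if (is.null(groups)) groups <- dem_groups(dem)
  days <- seq(as.Date(from), as.Date(to), by = "day")
  res <- do.call(rbind, lapply(groups, function(g)
    group_composition(dem, g, days, thresholds)))
  rownames(res) <- NULL
  res
}
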