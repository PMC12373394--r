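#' Construct and validate an interaction table
#'
#' An interaction table holds dated agonistic events between identified
#' individuals. Submission events (decided avoidance, displacement) feed the
#' Elo-rating engine; aggression events are scored against the inferred
#' hierarchy. Records are kept in (date, file-order) sequence: no
#' within-day timestamps are assumed, so sequence-dependent Elo results
#' depend on the within-day row order of the source file. This convention is
#' deliberate and documented; reorder the rows upstream if a different
#' within-day ordering is wanted.
#'
#' @param x a data frame with columns `date`, `group`, `actor`, `receiver`,
#'   `behaviour` and optionally `provenance` (focal/ad libitum; carried
#'   through, ignored by all computation).
#' @param eth an [ethogram()] used to validate codes and assign the channel.
#' @return A data frame of class `"interactions"` with the input columns plus
#'   `channel` (`"submission"` or `"aggression"`) and `intensity` (factor,
#'   `NA` for submissions), sorted stably by date.
#' @export
interactions <- function(x, eth = default_ethogram()) {
  x <- as.data.frame(x)
  need <- c("date", "group", "actor", "receiver", "behaviour")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x$date <- parse_iso_date(x$date)
  if (anyNA(x$date))
    stop("unparseable date in row(s): ",
         paste(utils::head(which(is.na(x$date)), 5L), collapse = ", "))
  for (cc in c("group", "actor", "receiver", "behaviour"))
    x[[cc]] <- as.character(x[[cc]])
  self <- which(x$actor == x$receiver)
  if (length(self))
    stop("actor equals receiver in row(s): ",
         paste(utils::head(self, 5L), collapse = ", "))
  lk <- ethogram_lookup(eth)
  known <- c(names(lk), eth$submission)
  bad <- which(!x$behaviour %in% known)
  if (length(bad))
    stop("unknown behaviour code(s): ",
         paste(unique(x$behaviour[bad]), collapse = ", "),
         " (row ", paste(utils::head(bad, 5L), collapse = ", "), ")")
  x$channel <- ifelse(x$behaviour %in% eth$submission, "submission", "aggression")
  x$intensity <- factor(rep(NA_character_, nrow(x)), levels = intensity_levels)
  agg <- x$channel == "aggression"
  x$intensity[agg] <- classify_intensity(x$behaviour[agg], eth)
  # stable sort: within-day file order is preserved
  x <- x[order(x$date, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("interactions", "data.frame")
  x
}

#' Read or write an interaction event log
#'
#' Flat delimited text (comma by default, UTF-8, ISO-8601 dates) with header
#' `date,group,actor,receiver,behaviour[,provenance]`.
#'
#' @param path file path.
#' @param eth an [ethogram()].
#' @param sep field delimiter.
#' @param x an `"interactions"` table.
#' @return `read_interactions()` returns a validated `"interactions"` table;
#'   `write_interactions()` returns `path` invisibly.
#' @export
read_interactions <- function(path, eth = default_ethogram(), sep = ",") {
  if (!file.exists(path)) stop("interactions file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  interactions(x, eth)
}

#' @rdname read_interactions
#' @export
write_interactions <- function(x, path, sep = ",") {
  keep <- intersect(c("date", "group", "actor", "receiver", "behaviour",
                      "provenance"), names(x))
  utils::write.table(as.data.frame(x)[keep], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# strict ISO-8601 parsing: malformed strings become NA instead of an
# opaque base-R error
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(as.character(x), format = "%Y-%m-%d")
}

demography_event_types <-
  c("birth", "entry", "exit", "parturition", "mating", "nipple_contact")

#' Construct and validate a demography table
#'
#' Long-format demographic event records, one row per individual-event:
#' `event_type` is one of `birth`, `entry`, `exit`, `parturition`, `mating`,
#' `nipple_contact`. The `birth` row carries `sex` (`"F"`/`"M"`) and
#' `species` (`"western"`/`"mountain"`); `entry`/`exit` rows carry `group`;
#' `nipple_contact` rows may carry an infant identifier in `detail`.
#' Presence in a group runs from an `entry` date through the matching `exit`
#' date inclusive (or the end of observation when no exit is recorded).
#'
#' Validation enforces: one birth per individual; exits after their entries
#' and non-overlapping presence intervals per individual-group; strictly
#' increasing parturition dates, none before `birth + min_parturition_age`
#' years; no event before birth. Inter-birth intervals shorter than
#' `ibi_warn_days` raise a warning (biologically implausible but tolerated).
#'
#' @param x data frame with columns `id`, `event_type`, `date` and optionally
#'   `group`, `sex`, `species`, `detail`.
#' @param min_parturition_age minimum plausible age (years) at parturition.
#' @param ibi_warn_days warn when two parturitions are closer than this.
#' @return An object of class `"demography"`: list with `events` (validated
#'   long table) and `individuals` (`id`, `sex`, `species`, `birth`).
#' @export
demography <- function(x, min_parturition_age = 6, ibi_warn_days = 300) {
  x <- as.data.frame(x)
  need <- c("id", "event_type", "date")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("group", "sex", "species", "detail"))
    if (is.null(x[[cc]])) x[[cc]] <- NA_character_ else x[[cc]] <- as.character(x[[cc]])
  x$id <- as.character(x$id)
  x$event_type <- as.character(x$event_type)
  x$date <- parse_iso_date(x$date)
  if (anyNA(x$date))
    stop("unparseable date in row(s): ",
         paste(utils::head(which(is.na(x$date)), 5L), collapse = ", "))
  bad <- which(!x$event_type %in% demography_event_types)
  if (length(bad))
    stop("unknown event_type(s): ",
         paste(unique(x$event_type[bad]), collapse = ", "),
         " (row ", paste(utils::head(bad, 5L), collapse = ", "), ")")
  x <- x[order(x$id, x$date, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL

  births <- x[x$event_type == "birth", , drop = FALSE]
  nb <- table(factor(x$id[x$event_type == "birth"], levels = unique(x$id)))
  if (any(nb != 1L))
    stop("each individual needs exactly one birth event; offending id(s): ",
         paste(names(nb)[nb != 1L], collapse = ", "))
  ind <- data.frame(id = births$id, sex = births$sex, species = births$species,
                    birth = births$date, stringsAsFactors = FALSE)
  if (anyNA(ind$sex) || anyNA(ind$species))
    stop("birth rows must carry sex and species; offending id(s): ",
         paste(ind$id[is.na(ind$sex) | is.na(ind$species)], collapse = ", "))
  if (any(!ind$species %in% c("western", "mountain")))
    stop("species must be 'western' or 'mountain'")

  birth_of <- stats::setNames(ind$birth, ind$id)
  pre <- which(x$date < birth_of[x$id])
  if (length(pre))
    stop("event before birth for id(s): ",
         paste(unique(x$id[pre]), collapse = ", "),
         " (row ", paste(utils::head(pre, 5L), collapse = ", "), ")")

  for (id in ind$id) {
    ev <- x[x$id == id, , drop = FALSE]
    # presence intervals per group: alternating entry/exit, exit >= entry,
    # non-overlapping
    for (g in unique(ev$group[ev$event_type %in% c("entry", "exit")])) {
      eg <- ev[ev$group %in% g & ev$event_type %in% c("entry", "exit"), , drop = FALSE]
      ty <- eg$event_type
      ok <- all(ty[seq(1L, length(ty), by = 2L)] == "entry") &&
        (length(ty) < 2L || all(ty[seq(2L, length(ty), by = 2L)] == "exit"))
      if (!ok || is.unsorted(eg$date, strictly = FALSE))
        stop("invalid or overlapping presence intervals for ", id,
             " in group ", g)
      if (length(ty) >= 2L) {
        en <- eg$date[ty == "entry"]; ex <- eg$date[ty == "exit"]
        if (any(ex < en[seq_along(ex)]))
          stop("exit before entry for ", id, " in group ", g)
        if (length(en) > 1L && any(en[-1L] <= ex[seq_len(length(en) - 1L)]))
          stop("invalid or overlapping presence intervals for ", id,
               " in group ", g)
      }
    }
    pp <- ev$date[ev$event_type == "parturition"]
    if (length(pp)) {
      if (is.unsorted(pp, strictly = TRUE))
        stop("parturitions not strictly ordered for ", id)
      min_age <- birth_of[id] + floor(min_parturition_age * 365.25)
      if (any(pp < min_age))
        stop("parturition before age ", min_parturition_age, " years for ", id)
      if (length(pp) > 1L && any(diff(as.integer(pp)) < ibi_warn_days))
        warning("inter-birth interval under ", ibi_warn_days,
                " days for ", id, " (biologically implausible)")
    }
  }
  structure(list(events = x, individuals = ind), class = "demography")
}

#' Read or write a demography table
#'
#' @param path file path to a delimited file with header
#'   `id,event_type,date,group,sex,species,detail` (trailing columns
#'   optional).
#' @param sep field delimiter.
#' @param ... passed to [demography()].
#' @param d a `"demography"` object.
#' @return `read_demography()` returns a validated `"demography"`;
#'   `write_demography()` returns `path` invisibly.
#' @export
read_demography <- function(path, sep = ",", ...) {
  if (!file.exists(path)) stop("demography file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, colClasses = "character")
  demography(x, ...)
}

#' @rdname read_demography
#' @export
write_demography <- function(d, path, sep = ",") {
  stopifnot(inherits(d, "demography"))
  utils::write.table(d$events, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.demography <- function(x, ...) {
  cat("Demography: ", nrow(x$individuals), " individuals, ",
      nrow(x$events), " events (",
      format(min(x$events$date)), " to ", format(max(x$events$date)), ")\n",
      sep = "")
  invisible(x)
}

# ---- internal demography accessors ------------------------------------------

dem_groups <- function(d) {
  sort(unique(d$events$group[d$events$event_type == "entry"]))
}

# presence intervals of one individual in one group:
# data.frame(from, to) with to = NA meaning open-ended
dem_presence <- function(d, id, group) {
  ev <- d$events
  eg <- ev[ev$id == id & ev$group %in% group &
             ev$event_type %in% c("entry", "exit"), , drop = FALSE]
  if (!nrow(eg)) return(data.frame(from = as.Date(character()), to = as.Date(character())))
  en <- eg$date[eg$event_type == "entry"]
  ex <- eg$date[eg$event_type == "exit"]
  length(ex) <- length(en)
  data.frame(from = en, to = as.Date(ex))
}

# logical matrix [ids x days]: individual present in group on day, optionally
# restricted to adult females (age strictly above the species threshold)
presence_matrix <- function(d, group, days, thresholds = NULL, sex = NULL) {
  ev <- d$events
  ids <- unique(ev$id[ev$group %in% group & ev$event_type == "entry"])
  if (!is.null(sex))
    ids <- ids[dem_sex(d, ids) %in% sex]
  m <- matrix(FALSE, length(ids), length(days),
              dimnames = list(ids, format(days)))
  for (id in ids) {
    pr <- dem_presence(d, id, group)
    for (k in seq_len(nrow(pr))) {
      hi <- if (is.na(pr$to[k])) max(days) else pr$to[k]
      m[id, ] <- m[id, ] | (days >= pr$from[k] & days <= hi)
    }
  }
  if (!is.null(thresholds)) {
    for (id in ids) {
      thr <- threshold_for(thresholds, dem_species(d, id), dem_sex(d, id))
      age <- as.numeric(days - dem_birth(d, id)) / 365.25
      m[id, ] <- m[id, ] & (age > thr)
    }
  }
  m
}

dem_birth <- function(d, id) {
  d$individuals$birth[match(id, d$individuals$id)]
}
dem_sex <- function(d, id) {
  d$individuals$sex[match(id, d$individuals$id)]
}
dem_species <- function(d, id) {
  d$individuals$species[match(id, d$individuals$id)]
}
dem_dates <- function(d, id, type) {
  ev <- d$events
  ev$date[ev$id == id & ev$event_type == type]
}
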