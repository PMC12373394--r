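#' Behavioural ethogram
#'
#' An ethogram maps behaviour codes onto the three aggression intensity
#' levels (`mild`, `moderate`, `severe`) and names the ritualized submission
#' behaviours (`avoid`, `displace`) used to infer dominance relationships.
#' Codes are snake_case slugs of the field terms (e.g. `"pull_vegetation"`,
#' `"strut_stand_run"`); the default instance holds the standard gorilla
#' female-female ethogram, and site-specific variants can be supplied via
#' [read_ethogram()] or by calling `ethogram()` with modified code lists.
#'
#' @param mild,moderate,severe character vectors of aggression codes, one per
#'   intensity level.
#' @param submission character vector of submission codes.
#' @return An object of class `"ethogram"`: a list with elements `mild`,
#'   `moderate`, `severe`, `submission`.
#' @examples
#' eth <- default_ethogram()
#' classify_intensity("chest_beat", eth)
#' @export
ethogram <- function(mild, moderate, severe, submission = c("avoid", "displace")) {
  levels <- list(mild = as.character(mild), moderate = as.character(moderate),
                 severe = as.character(severe))
  all_codes <- c(unlist(levels, use.names = FALSE), as.character(submission))
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup))
    stop("behaviour code(s) assigned to more than one category: ",
         paste(dup, collapse = ", "))
  if (any(!nzchar(all_codes)) || anyNA(all_codes))
    stop("empty or missing behaviour codes are not allowed")
  structure(c(levels, list(submission = as.character(submission))),
            class = "ethogram")
}

#' @rdname ethogram
#' @export
default_ethogram <- function() {
  ethogram(
    mild = c("cough_grunt", "soft_bark", "bark", "scream", "pull_vegetation"),
    moderate = c("chest_beat", "strut_stand_run", "lunge", "direct_charge",
                 "indirect_charge", "run_at_over", "push"),
    severe = c("hit", "attack", "drag", "fight", "bite", "chase", "kick"),
    submission = c("avoid", "displace")
  )
}

intensity_levels <- c("mild", "moderate", "severe")

# code -> level lookup (named character vector over aggression codes only)
ethogram_lookup <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  codes <- unlist(eth[intensity_levels], use.names = FALSE)
  stats::setNames(rep(intensity_levels, lengths(eth[intensity_levels])), codes)
}

#' Classify a behaviour code into an aggression intensity level
#'
#' @param behaviour character vector of behaviour codes.
#' @param eth an [ethogram()].
#' @return factor with levels `mild`, `moderate`, `severe`.
#' @export
classify_intensity <- function(behaviour, eth = default_ethogram()) {
  lk <- ethogram_lookup(eth)
  out <- lk[as.character(behaviour)]
  if (anyNA(out)) {
    bad <- unique(as.character(behaviour)[is.na(out)])
    stop("unknown behaviour code(s): ", paste(bad, collapse = ", "))
  }
  factor(unname(out), levels = intensity_levels)
}

#' Read or write an ethogram as YAML
#'
#' The YAML layout maps each category to its code list:
#' `mild: [...]`, `moderate: [...]`, `severe: [...]`, `submission: [...]`.
#'
#' @param path file path.
#' @param eth an [ethogram()].
#' @return `read_ethogram()` returns an `"ethogram"`; `write_ethogram()`
#'   returns `path` invisibly.
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop("ethogram file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("mild", "moderate", "severe")
  if (!all(need %in% names(y)))
    stop("ethogram YAML must define categories: ", paste(need, collapse = ", "))
  ethogram(mild = y$mild, moderate = y$moderate, severe = y$severe,
           submission = if (is.null(y$submission)) c("avoid", "displace")
                        else y$submission)
}

#' @rdname read_ethogram
#' @export
write_ethogram <- function(eth, path) {
  stopifnot(inherits(eth, "ethogram"))
  yaml::write_yaml(unclass(eth), path)
  invisible(path)
}

#' @export
print.ethogram <- function(x, ...) {
  cat("Ethogram:\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
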