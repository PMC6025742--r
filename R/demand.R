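# Phase I: census -> required daily care hours + minimum nurse percentage.

#' Illness-severity categories
#'
#' The four inpatient illness-severity categories of the COFEN 293/2004
#' care standard, ordered by increasing acuity.
#'
#' @return Character vector `c("minimal", "intermediary", "semi_intensive",
#'   "intensive")`.
#' @export
severity_categories <- function() {
  c("minimal", "intermediary", "semi_intensive", "intensive")
}

# coerce a length-4 vector to the canonical category order
.named4 <- function(x, what) {
  cats <- severity_categories()
  if (length(x) != 4L) {
    stop(sprintf("`%s` must have one value per severity category (4), got %d",
                 what, length(x)), call. = FALSE)
  }
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), cats)) {
      stop(sprintf("`%s` names must be {%s}", what, paste(cats, collapse = ", ")),
           call. = FALSE)
    }
    x <- x[cats]
  } else {
    names(x) <- cats
  }
  if (any(!is.finite(x))) stop(sprintf("`%s` must be finite", what), call. = FALSE)
  x
}

.check_count <- function(value, field) {
  if (length(value) != 1L || !is.finite(value)) {
    stop(sprintf("count `%s` must be a single finite number", field), call. = FALSE)
  }
  if (value < 0) {
    stop(sprintf("negative count for `%s` (%s)", field, format(value)), call. = FALSE)
  }
  if (abs(value - round(value)) > 1e-9) {
    stop(sprintf("count `%s` must be a whole number, got %s", field, format(value)),
         call. = FALSE)
  }
  as.integer(round(value))
}

#' Care standard (COFEN 293/2004 defaults)
#'
#' Bundles the per-category minimum daily care hours per patient, the
#' per-category minimum nurse percentage of the nursing workforce, and the
#' Technical Safety Index (TSI) that buffers all types of staff absence.
#'
#' @param hours_per_patient Named or positional numeric vector of daily care
#'   hours per patient for the four severity categories. Defaults are the
#'   COFEN values 3.8, 5.6, 9.4 and 17.9 hours. Must be strictly increasing
#'   with acuity.
#' @param nurse_pct Minimum percentage of nurses among all nursing workers
#'   per category; defaults 33, 33, 42, 52.
#' @param tsi Technical Safety Index as a fraction (default 0.15, i.e. 15%).
#' @return An object of class `care_standard`.
#' @examples
#' std <- care_standard()
#' std$hours_per_patient
#' @export
care_standard <- function(hours_per_patient = c(minimal = 3.8, intermediary = 5.6,
                                                semi_intensive = 9.4, intensive = 17.9),
                          nurse_pct = c(minimal = 33, intermediary = 33,
                                        semi_intensive = 42, intensive = 52),
                          tsi = 0.15) {
  hours_per_patient <- .named4(as.numeric(hours_per_patient), "hours_per_patient")
  nurse_pct <- .named4(as.numeric(nurse_pct), "nurse_pct")
  if (any(diff(hours_per_patient) <= 0)) {
    stop("`hours_per_patient` must be strictly increasing across acuity",
         call. = FALSE)
  }
  if (any(nurse_pct <= 0 | nurse_pct > 100)) {
    stop("`nurse_pct` values must lie in (0, 100]", call. = FALSE)
  }
  if (length(tsi) != 1L || !is.finite(tsi) || tsi < 0) {
    stop("`tsi` must be a single non-negative fraction", call. = FALSE)
  }
  structure(list(hours_per_patient = hours_per_patient,
                 nurse_pct = nurse_pct, tsi = tsi),
            class = "care_standard")
}

#' Patient census for one unit-day
#'
#' Per-day inpatient counts by illness-severity category, plus patients not
#' yet classified. Unclassified patients are folded into the intermediary
#' category by [normalize_census()] before any computation.
#'
#' @param minimal,intermediary,semi_intensive,intensive Non-negative integer
#'   patient counts per severity category.
#' @param unclassified Non-negative integer count of unclassified inpatients.
#' @param unit Optional unit label.
#' @param date Optional ISO-8601 date string.
#' @return An object of class `patient_census`.
#' @examples
#' patient_census(minimal = 21, intermediary = 10, semi_intensive = 3)
#' @export
patient_census <- function(minimal = 0, intermediary = 0, semi_intensive = 0,
                           intensive = 0, unclassified = 0,
                           unit = NA_character_, date = NA_character_) {
  counts <- c(minimal = .check_count(minimal, "minimal"),
              intermediary = .check_count(intermediary, "intermediary"),
              semi_intensive = .check_count(semi_intensive, "semi_intensive"),
              intensive = .check_count(intensive, "intensive"))
  structure(list(counts = counts,
                 unclassified = .check_count(unclassified, "unclassified"),
                 unit = as.character(unit), date = as.character(date)),
            class = "patient_census")
}

#' Fold unclassified patients into the intermediary category
#'
#' Unclassified inpatients are counted as needing intermediary care. The
#' total number of patients is conserved and the operation is idempotent.
#'
#' @param census A [patient_census()].
#' @return A `patient_census` with `unclassified = 0`.
#' @export
normalize_census <- function(census) {
  stopifnot(inherits(census, "patient_census"))
  census$counts[["intermediary"]] <-
    census$counts[["intermediary"]] + census$unclassified
  census$unclassified <- 0L
  census
}

#' Required daily nursing care hours
#'
#' Sum over severity categories of patient count times the category's care
#' hours per patient per day. Linear in the census.
#'
#' @param census A [patient_census()]; normalized internally.
#' @param standard A [care_standard()].
#' @return Required care hours per day (numeric scalar).
#' @examples
#' care_hours(patient_census(21, 10, 3, 0)) # 164
#' @export
care_hours <- function(census, standard = care_standard()) {
  stopifnot(inherits(standard, "care_standard"))
  census <- normalize_census(census)
  sum(census$counts * standard$hours_per_patient)
}

#' Minimum nurse percentage, dominant-category rule
#'
#' The COFEN text rule: the minimum nurse-to-workforce percentage of the
#' severity category holding the largest number of inpatients. Ties are
#' broken toward the higher-acuity category.
#'
#' @inheritParams care_hours
#' @return Integer percentage.
#' @export
nurse_ratio_dominant <- function(census, standard = care_standard()) {
  stopifnot(inherits(standard, "care_standard"))
  census <- normalize_census(census)
  if (sum(census$counts) == 0L) stop("no patients", call. = FALSE)
  idx <- max(which(census$counts == max(census$counts)))
  unname(standard$nurse_pct[[idx]])
}

# round half away from zero (arguments here are always non-negative)
.round_half_up <- function(x) floor(x + 0.5)

#' Minimum nurse percentage, demand-weighted rule
#'
#' Averages the per-category nurse percentages weighted by each category's
#' share of the total care hours, rounded to the nearest integer percent
#' (half away from zero). This rule reproduces every published HSJ unit-day
#' value (34/35), which the dominant-category rule does not; it is the
#' package default in [phase1()].
#'
#' @inheritParams care_hours
#' @return Integer percentage.
#' @export
nurse_ratio_weighted <- function(census, standard = care_standard()) {
  stopifnot(inherits(standard, "care_standard"))
  census <- normalize_census(census)
  h <- census$counts * standard$hours_per_patient
  if (sum(h) <= 0) stop("census has zero care hours", call. = FALSE)
  .round_half_up(sum(h * standard$nurse_pct) / sum(h))
}

#' Demand profile (Phase I output)
#'
#' @param care_hours Required nursing care hours per day.
#' @param nurse_ratio Minimum nurse percentage of the nursing workforce.
#' @param census Optional originating [patient_census()].
#' @param ratio_rule Label of the rule that produced `nurse_ratio`.
#' @return An object of class `demand_profile`.
#' @export
demand_profile <- function(care_hours, nurse_ratio, census = NULL,
                           ratio_rule = NA_character_) {
  if (care_hours < 0) stop("`care_hours` must be non-negative", call. = FALSE)
  if (nurse_ratio < 0 || nurse_ratio >= 100) {
    stop("`nurse_ratio` must be a percentage in [0, 100)", call. = FALSE)
  }
  structure(list(care_hours = care_hours, nurse_ratio = nurse_ratio,
                 census = census, ratio_rule = ratio_rule),
            class = "demand_profile")
}

#' Phase I: demand computation
#'
#' Converts a census into the required daily care hours and the minimum
#' nurse percentage, the two quantities the staffing model consumes.
#'
#' @inheritParams care_hours
#' @param ratio_rule `"weighted"` (default) or `"dominant"`; see
#'   [nurse_ratio_weighted()] and [nurse_ratio_dominant()].
#' @return A [demand_profile()].
#' @examples
#' phase1(patient_census(21, 10, 3, 0))
#' @export
phase1 <- function(census, standard = care_standard(),
                   ratio_rule = c("weighted", "dominant")) {
  ratio_rule <- match.arg(ratio_rule)
  census <- normalize_census(census)
  ratio <- switch(ratio_rule,
                  weighted = nurse_ratio_weighted(census, standard),
                  dominant = nurse_ratio_dominant(census, standard))
  demand_profile(care_hours(census, standard), ratio, census, ratio_rule)
}

#' @export
print.demand_profile <- function(x, ...) {
  cat("Demand profile:", format(x$care_hours), "care hours/day,",
      paste0(x$nurse_ratio, "%"), "minimum nurses",
      if (!is.na(x$ratio_rule)) sprintf("(%s rule)", x$ratio_rule), "\n")
  invisible(x)
}

#' @export
print.patient_census <- function(x, ...) {
  cat("Patient census", if (!is.na(x$unit)) paste0("[", x$unit, "]"),
      if (!is.na(x$date)) x$date, "\n")
  print(c(x$counts, unclassified = x$unclassified))
  invisible(x)
}
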