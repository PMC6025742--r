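# Packaged case-study data and a seeded synthetic census generator.

#' Eight-day HSJ case study
#'
#' The published eight-consecutive-day census of the Hospital São José
#' "In. U 4th floor PRT/CNV" inpatient unit (from Wednesday 2016-09-07),
#' together with the published per-day reference staffing vectors, the
#' published care hours and nurse ratios, and the unit's actual roster
#' (4 nurses and 22 technicians, constant across days).
#'
#' @return A list with elements `census` (data frame in the census CSV
#'   layout), `reference` (data frame of published per-day demand values
#'   and staffing vectors), and `actual` (named vector with the real
#'   roster's nurse and technician counts).
#' @examples
#' hsj <- hsj_eight_days()
#' nrow(hsj$census)
#' @export
hsj_eight_days <- function() {
  census <- read_census_csv(system.file("extdata", "hsj_table2.csv",
                                        package = "nursedim", mustWork = TRUE))
  reference <- utils::read.csv(
    system.file("extdata", "hsj_reference_solutions.csv",
                package = "nursedim", mustWork = TRUE),
    stringsAsFactors = FALSE)
  reference$nurses_total <- reference$nurse_morning + reference$nurse_afternoon +
    reference$nurse_night1 + reference$nurse_night2
  reference$technicians_total <- reference$technician_morning +
    reference$technician_afternoon + reference$technician_night1 +
    reference$technician_night2
  list(census = census, reference = reference,
       actual = c(nurses = 4L, technicians = 22L))
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random synthetic census table
#'
#' Draws per-category patient counts uniformly from configured inclusive
#' ranges, one row per day. The same seed always yields the same table;
#' the caller's RNG state is left untouched. The default ranges emulate a
#' medium general inpatient unit like the HSJ case study: mostly minimal
#' and intermediary patients, few semi-intensive, rare intensive, and a
#' handful of not-yet-classified admissions.
#'
#' @param seed Integer seed.
#' @param n_days Number of days (rows).
#' @param count_ranges Named list of `c(min, max)` integer ranges for
#'   `minimal`, `intermediary`, `semi_intensive`, `intensive`,
#'   `unclassified`.
#' @param unit Unit label for the generated rows.
#' @param start_date First day (ISO-8601); subsequent rows are consecutive.
#' @return A data frame in the census CSV layout.
#' @export
random_census <- function(seed, n_days = 8L,
                          count_ranges = list(minimal = c(10, 25),
                                              intermediary = c(4, 12),
                                              semi_intensive = c(0, 4),
                                              intensive = c(0, 2),
                                              unclassified = c(0, 3)),
                          unit = "synthetic unit",
                          start_date = "2016-09-07") {
  fields <- c("minimal", "intermediary", "semi_intensive", "intensive",
              "unclassified")
  if (!setequal(names(count_ranges), fields)) {
    stop("`count_ranges` must name exactly: ", paste(fields, collapse = ", "),
         call. = FALSE)
  }
  for (f in fields) {
    r <- count_ranges[[f]]
    if (length(r) != 2L || any(r < 0) || r[2L] < r[1L]) {
      stop(sprintf("invalid range for `%s`: must be c(min, max) with 0 <= min <= max", f),
           call. = FALSE)
    }
  }
  if (n_days < 1L) stop("`n_days` must be at least 1", call. = FALSE)
  draws <- .with_seed(seed, {
    vapply(fields, function(f) {
      r <- count_ranges[[f]]
      sample(seq.int(r[1L], r[2L]), n_days, replace = TRUE)
    }, integer(n_days))
  })
  draws <- matrix(draws, nrow = n_days,
                  dimnames = list(NULL, fields))
  data.frame(unit = unit,
             date = format(as.Date(start_date) + seq_len(n_days) - 1L),
             draws, stringsAsFactors = FALSE)
}

#' Random small staffing instance
#'
#' Seeded generator of small Phase II instances for property tests:
#' demand, TSI, skill mix, balance, minimum cover and the model-variant
#' flags are all drawn at random, sized so the enumeration oracle's
#' default cap admits every generated instance.
#'
#' @param seed Integer seed.
#' @param max_hours Upper end of the uniform demand range (default 15).
#' @param vary_variant Whether to sample the model-variant flags (default
#'   `TRUE`); otherwise the default variant is used.
#' @return A [build_instance()] result.
#' @export
random_instance <- function(seed, max_hours = 15, vary_variant = TRUE) {
  .with_seed(seed, {
    H <- stats::runif(1L, 0, max_hours)
    tsi <- sample(c(0, 0.1, 0.15, 0.2), 1L)
    prop <- stats::runif(1L, 0, 0.4)
    alpha <- sample(0:2, 2L, replace = TRUE)
    ms <- matrix(sample(0:1, 8L, replace = TRUE), 2L, 4L)
    variant <- if (vary_variant) {
      model_variant(
        tsi_scope = sample(c("per_cell", "per_skill", "global"), 1L),
        aux_integrality = sample(c("continuous", "integer"), 1L),
        night_demand_hours = sample(c("both_cohorts", "single_cohort"), 1L),
        prop_counting = sample(c("all_employees", "per_day_staff"), 1L))
    } else {
      model_variant()
    }
    build_instance(demand_profile(H, 0), # prop injected via params below
                   model_parameters(tsi = tsi, prop = prop, alpha = alpha,
                                    min_staff = ms),
                   variant = variant)
  })
}
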