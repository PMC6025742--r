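# Census CSV ingestion and configuration loading.

.CENSUS_COLUMNS <- c("unit", "date", "minimal", "intermediary",
                     "semi_intensive", "intensive", "unclassified")

#' Read a census CSV
#'
#' Reads and validates a per-unit, per-day census table. The file must be
#' UTF-8, comma-separated, with exactly the header
#' `unit,date,minimal,intermediary,semi_intensive,intensive,unclassified`
#' and ISO-8601 dates. Unknown or missing columns, negative counts and
#' malformed dates are rejected with a message naming the offending
#' row/column.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame with the census columns; integer counts.
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) stop("census file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  extra <- setdiff(names(df), .CENSUS_COLUMNS)
  missing <- setdiff(.CENSUS_COLUMNS, names(df))
  if (length(extra) > 0L) {
    stop("unknown census column(s): ", paste(extra, collapse = ", "),
         "; expected exactly: ", paste(.CENSUS_COLUMNS, collapse = ","),
         call. = FALSE)
  }
  if (length(missing) > 0L) {
    stop("missing census column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .CENSUS_COLUMNS]
  count_cols <- setdiff(.CENSUS_COLUMNS, c("unit", "date"))
  for (col in count_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) | vals < 0 | abs(vals - round(vals)) > 1e-9)
    if (length(bad) > 0L) {
      stop(sprintf("invalid count in column `%s`, row %d: %s",
                   col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- as.integer(round(vals))
  }
  if (nrow(df) > 0L) {
    parsed <- as.Date(df$date, format = "%Y-%m-%d")
    # strptime tolerates trailing text; require an exact ISO round-trip
    bad <- which(is.na(parsed) | format(parsed) != df$date)
    if (length(bad) > 0L) {
      stop(sprintf("malformed date in row %d: `%s` (expected ISO-8601)",
                   bad[1L], df$date[bad[1L]]), call. = FALSE)
    }
    df$date <- format(parsed)
  }
  df
}

# recursively overlay user config onto defaults; unknown keys are errors
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s)%s: %s",
                 if (nzchar(path)) paste0(" under `", path, "`") else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    defaults[[k]] <- .merge_config(defaults[[k]],
                                   user[[k]],
                                   if (nzchar(path)) paste(path, k, sep = ".") else k)
  }
  defaults
}

.config_defaults <- function() {
  list(
    care_standard = list(
      hours_per_patient = list(minimal = 3.8, intermediary = 5.6,
                               semi_intensive = 9.4, intensive = 17.9),
      nurse_pct = list(minimal = 33, intermediary = 33,
                       semi_intensive = 42, intensive = 52),
      tsi = 0.15),
    shift_structure = list(morning = 6, afternoon = 6, night = 12),
    cost_schedule = list(nurse_rate = 1.0, technician_rate = 0.6,
                         night_premium = 0.375),
    model_parameters = list(prop = NULL,
                            alpha = list(nurse = 1, technician = 1),
                            min_staff = 1),
    variant = list(tsi_scope = "per_cell", aux_integrality = "continuous",
                   night_demand_hours = "both_cohorts",
                   prop_counting = "all_employees"),
    solver = list(oracle_cap = 8))
}

.config_objects <- function(cfg) {
  cs <- cfg$care_standard
  std <- care_standard(unlist(cs$hours_per_patient), unlist(cs$nurse_pct),
                       cs$tsi)
  ss <- shift_structure(cfg$shift_structure$morning,
                        cfg$shift_structure$afternoon,
                        cfg$shift_structure$night)
  co <- cost_schedule(cfg$cost_schedule$nurse_rate,
                      cfg$cost_schedule$technician_rate,
                      cfg$cost_schedule$night_premium)
  mp <- cfg$model_parameters
  ms <- mp$min_staff
  if (is.list(ms)) {
    ms <- rbind(unlist(ms$nurse), unlist(ms$technician))
  }
  pars <- model_parameters(tsi = cs$tsi, prop = mp$prop,
                           alpha = unlist(mp$alpha), min_staff = ms)
  var <- do.call(model_variant, cfg$variant)
  list(care_standard = std, shift_structure = ss, cost_schedule = co,
       model_parameters = pars, variant = var,
       oracle_cap = cfg$solver$oracle_cap)
}

#' Default configuration
#'
#' The shipped parameter bundle: COFEN care standards (hours 3.8/5.6/9.4/
#' 17.9, nurse percentages 33/33/42/52, TSI 15%), shift lengths 6/6/12 h,
#' rates 1.0/0.6 m.u. with a 37.5% night premium, minimum staff 1 per
#' skill and shift, balance bound 1, and the default model variant.
#'
#' @return A list with elements `care_standard`, `shift_structure`,
#'   `cost_schedule`, `model_parameters`, `variant`, `oracle_cap`.
#' @export
default_config <- function() .config_objects(.config_defaults())

#' Load a configuration file
#'
#' Reads a YAML configuration and overlays it onto the shipped defaults;
#' omitted keys keep their default values, unknown keys and invalid values
#' are rejected. See the packaged `extdata/default_config.yaml` for the
#' full documented schema.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Same structure as [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  .config_objects(cfg)
}
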