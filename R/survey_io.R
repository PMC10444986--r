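#' Read and validate the species metadata table
#'
#' The species table declares, for every flowering species in a survey, its
#' origin (alien or native), whether it bears nectaries, and the floral unit
#' used when counting open flowers (an individual `flower`, or a flower
#' `head` for composite and clover species).
#'
#' @param path Path to a UTF-8 CSV file with columns
#'   `species_id,origin,has_nectaries,floral_unit_type`.
#' @return A tibble with one validated row per species.
#' @export
read_species_table <- function(path) {
  df <- read_survey_csv(path, c("species_id", "origin", "has_nectaries",
                                "floral_unit_type"))
  df$has_nectaries <- as.logical(df$has_nectaries)
  validate_species_table(df)
}

#' @rdname read_species_table
#' @param species A data frame to validate in place of reading from disk.
#' @export
validate_species_table <- function(species) {
  species <- tibble::as_tibble(species)
  if (anyDuplicated(species$species_id)) {
    stop_florivis("duplicated species_id in species table",
                  "florivis_validation_error")
  }
  if (!all(species$origin %in% c("alien", "native"))) {
    stop_florivis("column 'origin' must be 'alien' or 'native'",
                  "florivis_validation_error")
  }
  if (anyNA(species$has_nectaries)) {
    stop_florivis("column 'has_nectaries' must be TRUE/FALSE",
                  "florivis_validation_error")
  }
  if (!all(species$floral_unit_type %in% c("flower", "head"))) {
    stop_florivis("column 'floral_unit_type' must be 'flower' or 'head'",
                  "florivis_validation_error")
  }
  species
}

#' Read per-plot open floral-unit counts
#'
#' One row is one species' count of open floral units in one 1 m^2 plot on
#' one survey occasion.  Missing survey occasions are represented by absent
#' rows, never by zero-filled rows.
#'
#' @param path CSV with columns `site,date,plot_id,species_id,floral_units`
#'   (ISO-8601 dates).
#' @param species Species table the counts must reference.
#' @return A validated tibble of count records.
#' @export
read_floral_counts <- function(path, species) {
  df <- read_survey_csv(path, c("site", "date", "plot_id", "species_id",
                                "floral_units"))
  df$date <- as.Date(df$date)
  df$floral_units <- as_count(df$floral_units, "floral_units")
  validate_floral_counts(df, species)
}

#' @rdname read_floral_counts
#' @param counts A data frame of count records to validate.
#' @export
validate_floral_counts <- function(counts, species) {
  counts <- tibble::as_tibble(counts)
  check_nonneg_int(counts$floral_units, "floral_units")
  check_known_species(counts$species_id, species)
  key <- paste(counts$site, counts$date, counts$plot_id, counts$species_id)
  if (anyDuplicated(key)) {
    stop_florivis(
      sprintf("duplicate (site, date, plot_id, species_id) at row %d",
              which(duplicated(key))[1]),
      "florivis_validation_error")
  }
  inform(sprintf("floral counts: %d records, %d species, %d survey dates",
                 nrow(counts), dplyr::n_distinct(counts$species_id),
                 dplyr::n_distinct(counts$date)))
  counts
}

#' Read per-plot insect visit counts
#'
#' Visit counts are stored pre-summed over the two 10-min observation rounds
#' of each plot and occasion (20 min of observation per plot in total).
#'
#' @param path CSV with columns
#'   `site,date,plot_id,species_id,insect_group,count`.
#' @param species Species table the records must reference.
#' @return A validated tibble of visit records.
#' @export
read_visit_records <- function(path, species) {
  df <- read_survey_csv(path, c("site", "date", "plot_id", "species_id",
                                "insect_group", "count"))
  df$date <- as.Date(df$date)
  df$count <- as_count(df$count, "count")
  validate_visit_records(df, species)
}

#' @rdname read_visit_records
#' @param visits A data frame of visit records to validate.
#' @export
validate_visit_records <- function(visits, species) {
  visits <- tibble::as_tibble(visits)
  check_nonneg_int(visits$count, "count")
  bad <- setdiff(unique(visits$insect_group), ALL_GROUPS)
  if (length(bad)) {
    stop_florivis(sprintf("unknown insect_group: %s",
                          paste(bad, collapse = ", ")),
                  "florivis_validation_error")
  }
  check_known_species(visits$species_id, species)
  visits
}

#' Retain only wild pollinator groups
#'
#' Drops records of European honeybees (an artificially managed species whose
#' visit timing can reflect migratory beekeeping rather than wild foraging)
#' and of Coleoptera and Hemiptera (recorded in too small numbers for
#' analysis).  The numbers removed per group are reported and attached as the
#' `"removed"` attribute.
#'
#' @param visits Validated visit records.
#' @return The records whose `insect_group` is one of `bee_wasp`,
#'   `hoverfly`, `butterfly`.
#' @export
filter_visits <- function(visits) {
  visits <- tibble::as_tibble(visits)
  dropped <- visits[!visits$insect_group %in% WILD_GROUPS, , drop = FALSE]
  kept <- visits[visits$insect_group %in% WILD_GROUPS, , drop = FALSE]
  removed <- tapply(dropped$count, factor(dropped$insect_group,
                                          setdiff(ALL_GROUPS, WILD_GROUPS)),
                    sum, default = 0L)
  if (nrow(dropped)) {
    inform(sprintf("filter_visits: removed %d records (%s)", nrow(dropped),
                   paste(names(removed), removed, sep = "=", collapse = ", ")))
  }
  attr(kept, "removed") <- removed
  kept
}

#' Study-year boundaries
#'
#' The two study years are half-open, contiguous date intervals.  Defaults
#' follow the original survey design: the first year ran from 21 April 2018
#' up to (but excluding) 14 April 2019, the second from 14 April 2019 to
#' 4 April 2020 inclusive.
#'
#' @param year1_start,year2_start,end Dates (coerced with [as.Date()]).
#' @return A named list of class `study_year_boundaries`.
#' @export
study_year_boundaries <- function(year1_start = "2018-04-21",
                                  year2_start = "2019-04-14",
                                  end = "2020-04-04") {
  b <- list(year1_start = as.Date(year1_start),
            year2_start = as.Date(year2_start),
            end = as.Date(end))
  if (!(b$year1_start < b$year2_start && b$year2_start <= b$end)) {
    stop_florivis("year boundaries must satisfy year1_start < year2_start <= end",
                  "florivis_validation_error")
  }
  structure(b, class = "study_year_boundaries")
}

#' Map survey dates to study year and calendar month
#'
#' Every date is assigned to exactly one study year (1 or 2) and one
#' year-month label; dates outside the study window are an error.
#'
#' @param dates A vector coercible to `Date`.
#' @param boundaries A [study_year_boundaries()] object.
#' @return A tibble with columns `date`, `study_year`, `month_label`.
#' @export
assign_periods <- function(dates, boundaries = study_year_boundaries()) {
  dates <- as.Date(dates)
  out_of_range <- dates < boundaries$year1_start | dates > boundaries$end
  if (any(out_of_range)) {
    stop_florivis(
      sprintf("date %s outside the study window [%s, %s]",
              dates[which(out_of_range)[1]], boundaries$year1_start,
              boundaries$end),
      "florivis_range_error")
  }
  tibble::tibble(
    date = dates,
    study_year = ifelse(dates < boundaries$year2_start, 1L, 2L),
    month_label = format(dates, "%Y-%m")
  )
}

#' Write survey tables as CSV
#'
#' @param tables Named list of data frames (e.g. `floral_counts`, `visits`,
#'   `species`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_survey_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

# ---- internal helpers -------------------------------------------------------

read_survey_csv <- function(path, expected_cols) {
  if (!file.exists(path)) {
    stop_florivis(sprintf("file not found: %s", path), "florivis_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing)) {
    stop_florivis(
      sprintf("%s: missing column(s) %s", basename(path),
              paste(missing, collapse = ", ")),
      "florivis_format_error")
  }
  df[expected_cols]
}

as_count <- function(x, name) {
  out <- suppressWarnings(as.integer(x))
  if (anyNA(out) && !anyNA(x)) {
    stop_florivis(sprintf("column '%s' is not integer-valued", name),
                  "florivis_format_error")
  }
  out
}

check_nonneg_int <- function(x, name) {
  if (anyNA(x)) {
    stop_florivis(sprintf("column '%s' contains missing values at row %d",
                          name, which(is.na(x))[1]),
                  "florivis_validation_error")
  }
  if (any(x < 0)) {
    stop_florivis(sprintf("column '%s' negative at row %d", name,
                          which(x < 0)[1]),
                  "florivis_validation_error")
  }
  invisible(x)
}

check_known_species <- function(ids, species) {
  unknown <- setdiff(unique(ids), species$species_id)
  if (length(unknown)) {
    stop_florivis(
      sprintf("species_id not in species table: %s",
              paste(head(unknown, 5), collapse = ", ")),
      "florivis_referential_error")
  }
  invisible(ids)
}
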