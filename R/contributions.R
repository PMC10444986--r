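#' Species contributions to resources and visits
#'
#' Because single 1 m^2 plots capture only part of a site's flowering
#' community, species shares are computed at the site (river) scale by
#' pooling raw totals over all plots and occasions of a period, then
#' dividing each species' total by the pooled grand total.  Monthly shares
#' pool within calendar months; annual shares pool within study years (raw
#' year totals, never averages of monthly proportions).  Resource measures
#' (`sugar`, `pollen`) cover only species with a measured profile for that
#' resource; visit measures cover every visited species, measured or not.
#'
#' @param availability A [plot_availability()] object (or its `per_species`
#'   tibble); `NULL` to skip resource measures.
#' @param visits Validated, wild-group-filtered visit records; `NULL` to
#'   skip visit measures.  Records of non-wild groups are dropped with a
#'   message if still present.
#' @param period `"month"` or `"year"`.
#' @param boundaries Study-year boundaries, see [study_year_boundaries()].
#' @return A tibble `site, period, measure, species_id, proportion` where
#'   `measure` is one of `sugar`, `pollen`, `visits_all`, `visits_bee_wasp`,
#'   `visits_hoverfly`, `visits_butterfly`.  Periods whose grand total is
#'   zero are absent and listed in the `"empty_periods"` attribute.
#' @export
species_contributions <- function(availability = NULL, visits = NULL,
                                  period = c("month", "year"),
                                  boundaries = study_year_boundaries()) {
  period <- match.arg(period)
  pieces <- list()

  if (!is.null(availability)) {
    per <- if (inherits(availability, "plot_availability")) {
      availability$per_species
    } else {
      tibble::as_tibble(availability)
    }
    pieces$sugar <- tibble::tibble(site = per$site, date = per$date,
                                   measure = "sugar", species_id = per$species_id,
                                   value = per$sugar_ug_m2)
    pieces$pollen <- tibble::tibble(site = per$site, date = per$date,
                                    measure = "pollen", species_id = per$species_id,
                                    value = per$pollen_ul_m2)
  }

  if (!is.null(visits)) {
    visits <- tibble::as_tibble(visits)
    if (any(!visits$insect_group %in% WILD_GROUPS)) {
      visits <- filter_visits(visits)
    }
    pieces$visits_all <- tibble::tibble(site = visits$site, date = visits$date,
                                        measure = "visits_all",
                                        species_id = visits$species_id,
                                        value = as.numeric(visits$count))
    for (g in WILD_GROUPS) {
      sub <- visits[visits$insect_group == g, , drop = FALSE]
      pieces[[paste0("visits_", g)]] <- tibble::tibble(
        site = sub$site, date = sub$date,
        measure = paste0("visits_", g), species_id = sub$species_id,
        value = as.numeric(sub$count))
    }
  }

  if (!length(pieces)) {
    stop_florivis("supply at least one of availability or visits",
                  "florivis_validation_error")
  }

  long <- dplyr::bind_rows(pieces)
  long <- long[!is.na(long$value), , drop = FALSE]  # unmeasured species excluded
  idx <- assign_periods(long$date, boundaries)
  long$period <- if (period == "month") idx$month_label else idx$study_year

  tot <- dplyr::summarise(
    dplyr::group_by(long, .data$site, .data$period, .data$measure,
                    .data$species_id),
    total = sum(.data$value), .groups = "drop_last")
  tot <- dplyr::mutate(tot, grand = sum(.data$total))
  tot <- dplyr::ungroup(tot)

  empty <- unique(tot[tot$grand == 0, c("site", "period", "measure")])
  tot <- tot[tot$grand > 0, , drop = FALSE]
  tot$proportion <- tot$total / tot$grand
  out <- tot[, c("site", "period", "measure", "species_id", "proportion")]
  attr(out, "empty_periods") <- empty
  out
}

#' @rdname species_contributions
#' @export
monthly_contributions <- function(availability = NULL, visits = NULL,
                                  boundaries = study_year_boundaries()) {
  species_contributions(availability, visits, period = "month",
                        boundaries = boundaries)
}

#' @rdname species_contributions
#' @export
annual_contributions <- function(availability = NULL, visits = NULL,
                                 boundaries = study_year_boundaries()) {
  species_contributions(availability, visits, period = "year",
                        boundaries = boundaries)
}
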