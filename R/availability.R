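#' Per-plot, per-occasion floral resource availability
#'
#' Converts open floral-unit counts into nectar-sugar (ug/m^2) and pollen
#' (uL/m^2) availability by multiplying each species' count by its mean
#' per-flower resource value.  Species whose profile lacks a measurement for
#' a resource are excluded from that resource's totals (and listed), never
#' treated as zero; a species can therefore contribute to pollen totals but
#' not to sugar totals.
#'
#' @param counts Validated floral count records.
#' @param profiles Species resource profiles from
#'   [build_species_profiles()].
#' @return A list of class `plot_availability` with elements
#'   \describe{
#'     \item{per_species}{long tibble: `site`, `date`, `plot_id`,
#'       `species_id`, `floral_units`, `sugar_ug_m2`, `pollen_ul_m2` (`NA`
#'       where the species is unmeasured for that resource)}
#'     \item{totals}{one row per plot x occasion with summed `sugar_ug_m2`
#'       and `pollen_ul_m2` (unmeasured species excluded)}
#'     \item{unmeasured}{species excluded from each resource's totals}
#'   }
#' @export
plot_availability <- function(counts, profiles) {
  counts <- tibble::as_tibble(counts)
  unknown <- setdiff(unique(counts$species_id), profiles$species_id)
  if (length(unknown)) {
    stop_florivis(sprintf("no profile row for species: %s",
                          paste(head(unknown, 5), collapse = ", ")),
                  "florivis_referential_error")
  }

  per <- dplyr::left_join(counts,
                          profiles[c("species_id", "mean_sugar_ug",
                                     "mean_pollen_ul")],
                          by = "species_id")
  per$sugar_ug_m2 <- per$floral_units * per$mean_sugar_ug
  per$pollen_ul_m2 <- per$floral_units * per$mean_pollen_ul
  per <- per[, c("site", "date", "plot_id", "species_id", "floral_units",
                 "sugar_ug_m2", "pollen_ul_m2")]

  totals <- dplyr::summarise(
    dplyr::group_by(per, .data$site, .data$date, .data$plot_id),
    sugar_ug_m2 = sum(.data$sugar_ug_m2, na.rm = TRUE),
    pollen_ul_m2 = sum(.data$pollen_ul_m2, na.rm = TRUE),
    .groups = "drop")

  seen <- unique(per$species_id)
  unmeasured <- tibble::tibble(
    species_id = c(seen[seen %in% profiles$species_id[is.na(profiles$mean_sugar_ug)]],
                   seen[seen %in% profiles$species_id[is.na(profiles$mean_pollen_ul)]]),
    resource = c(rep("sugar", sum(seen %in% profiles$species_id[is.na(profiles$mean_sugar_ug)])),
                 rep("pollen", sum(seen %in% profiles$species_id[is.na(profiles$mean_pollen_ul)])))
  )

  structure(list(per_species = per, totals = totals, unmeasured = unmeasured),
            class = "plot_availability")
}

#' @export
print.plot_availability <- function(x, ...) {
  cat("<plot_availability>\n")
  cat(sprintf("  %d plot x occasion totals, %d per-species rows\n",
              nrow(x$totals), nrow(x$per_species)))
  if (nrow(x$unmeasured)) {
    cat(sprintf("  %d species x resource exclusions (unmeasured)\n",
                nrow(x$unmeasured)))
  }
  invisible(x)
}
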