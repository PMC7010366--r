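#' Indicator species profiles
#'
#' Habitat associations, mean natal dispersal distance and minimum patch area
#' for the ten indicator species used throughout the package: eight birds
#' (three generalists, three farmland specialists, two woodland specialists)
#' and two amphibians. Habitat classes follow the UK Land Cover Map broad
#' habitat codes (1 broadleaved woodland, 2 coniferous woodland, 3 arable,
#' 4 improved grassland, 5 rough grassland, 6 neutral grassland,
#' 7 calcareous grassland, 8 acid grassland, 9 fen/marsh/swamp, 10 heather,
#' 11 heather grassland, 16 freshwater).
#'
#' @return A tibble with columns `species`, `common_name`, `group`,
#'   `dispersal_km`, `suitable_classes` (list of integer class codes) and
#'   `min_area_ha`.
#' @export
#' @examples
#' species_profiles()
species_profiles <- function() {
  path <- system.file("extdata", "species_profiles.csv", package = "landsust")
  read_species_profiles(path)
}

#' Read a species-profile table
#'
#' Reads a delimited table with columns `species`, `dispersal_km`, `classes`
#' (semicolon-separated habitat class codes) and `min_area_ha`; extra columns
#' are carried through.
#'
#' @param path Path to a CSV file.
#' @return A tibble; `classes` is parsed into a `suitable_classes`
#'   list-column of integer vectors.
#' @export
read_species_profiles <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "dispersal_km", "classes", "min_area_ha")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(paste0("species profile table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  df <- tibble::as_tibble(df)
  df$suitable_classes <- lapply(strsplit(as.character(df$classes), ";"),
                                function(v) as.integer(trimws(v)))
  bad <- df$dispersal_km <= 0 | df$min_area_ha <= 0 |
    vapply(df$suitable_classes, length, integer(1)) == 0
  if (any(bad))
    abort(paste0("invalid species profile row(s): ",
                 paste(df$species[bad], collapse = ", ")))
  df$classes <- NULL
  df
}

#' Habitat class table with synthetic national coverage
#'
#' The broad habitat classes used by the package, each with a national
#' coverage figure used only to rank classes from most to least common for
#' the national-rarity removal scenario. The coverage values bundled here are
#' synthetic placeholders that preserve a plausible commonness ranking for
#' Great Britain; they are not survey figures. Freshwater is flagged
#' non-removable: its patches are mostly permanent water bodies whose loss to
#' development is not realistic, so scenario generators neither remove nor
#' count them in the habitat-area total.
#'
#' @return A tibble with columns `class_id`, `name`, `national_cover_ha`
#'   (synthetic) and `removable`.
#' @export
habitat_classes <- function() {
  path <- system.file("extdata", "habitat_classes_synthetic.csv",
                      package = "landsust")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Reference habitat-loss thresholds from a UK urban case study
#'
#' A reference table of detected habitat-loss thresholds for the ten
#' indicator species across six loss scenarios, as reported for a UK urban
#' case study (Nottingham). Each row is a species-scenario combination that
#' displayed a threshold: the 10-percentage-point loss interval in which mean
#' occupancy first fell by more than 30% of present-day occupancy, and the
#' size of that fall as a percentage of present-day occupancy.
#'
#' @return A tibble with columns `species`, `scenario`, `loss_lower_pct`,
#'   `loss_upper_pct`, `occupancy_decrease_pct`.
#' @seealso [tally_thresholds()]
#' @export
reported_thresholds <- function() {
  path <- system.file("extdata", "reported_thresholds.csv", package = "landsust")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Tally threshold intervals by loss level
#'
#' Counts how often each habitat-loss level (the upper bound of the interval
#' in which the threshold fell) occurs in a threshold table, and reports the
#' modal level.
#'
#' @param thresholds A data frame with a `loss_upper_pct` column, e.g.
#'   [reported_thresholds()] or the `thresholds` element of
#'   [run_experiment()] output (rows with a detected threshold).
#' @return A tibble with columns `loss_upper_pct`, `n` and `modal` (logical),
#'   sorted by decreasing count.
#' @export
#' @examples
#' tally_thresholds(reported_thresholds())
tally_thresholds <- function(thresholds) {
  stopifnot("loss_upper_pct" %in% names(thresholds))
  tab <- dplyr::count(tibble::as_tibble(thresholds), .data$loss_upper_pct,
                      name = "n")
  tab <- dplyr::arrange(tab, dplyr::desc(.data$n), .data$loss_upper_pct)
  tab$modal <- tab$n == max(tab$n)
  tab
}
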