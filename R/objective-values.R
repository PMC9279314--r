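#' Conservation value of a unit for boreal caribou habitat
#'
#' Under the protected-area-expansion scenario the value is the unprotected
#' area > 500 m from human disturbance (`undist_human_area`); under the
#' critical-habitat scenario it is the full undisturbed-habitat definition,
#' additionally unburned > 40 years (`undist_full_area`). Both arrive as
#' precomputed columns on the unit table; no buffering or fire-history
#' overlay is done here.
#'
#' @param unit a one-row unit data.frame (or list) with both undisturbed-area
#'   fields.
#' @param scenario `"expand"` or `"protect"`.
#' @return habitat value in km².
#' @export
caribou_habitat_value <- function(unit, scenario = c("expand", "protect")) {
  scenario <- match.arg(scenario)
  if (scenario == "expand") unit$undist_human_area else unit$undist_full_area
}

#' Species richness of a planning unit
#'
#' Number of at-risk species whose extent of occurrence overlaps the
#' unprotected portion of the unit, i.e. the row sum of the incidence
#' matrix.
#'
#' @param presence unit x species logical (or 0/1) matrix with unit ids as
#'   row names.
#' @param unit_id unit to score.
#' @return integer count.
#' @export
richness_value <- function(presence, unit_id) {
  row <- presence_row(presence, unit_id)
  sum(row)
}

presence_row <- function(presence, unit_id) {
  if (!(unit_id %in% rownames(presence))) {
    stop("unit not in presence matrix: ", unit_id, call. = FALSE)
  }
  as.logical(presence[unit_id, ])
}

#' Taxonomic representation of a planning unit
#'
#' Modified inverse Berger-Parker dominance index: the number of species
#' present in the unit divided by the number of present species in the
#' unit's most-represented taxonomic group. Rewards taxonomic spread: 1 when
#' all present species share one group, approaching the number of groups
#' when evenly spread. Defined as 0 for a unit with no species (an empty
#' unit contributes nothing to the objective). The denominator is computed
#' per unit by default (dominance among the unit's own species, so the
#' index is 0 or at least 1); `denominator = "global"` divides instead by
#' the size of the most speciose group in the whole species pool, the
#' distribution-wide reading of the index (which can fall below 1).
#'
#' @param presence unit x species logical matrix (species ids as colnames).
#' @param meta species metadata data.frame (`species_id`, `taxon_group`, ...).
#' @param unit_id unit to score.
#' @param denominator `"per_unit"` (default) or `"global"`.
#' @return dimensionless index in {0} U [1, n_groups].
#' @export
taxonomic_representation_value <- function(presence, meta, unit_id,
                                           denominator = c("per_unit", "global")) {
  denominator <- match.arg(denominator)
  row <- presence_row(presence, unit_id)
  present <- colnames(presence)[row]
  if (length(present) == 0) return(0)
  grp <- meta$taxon_group[match(present, meta$species_id)]
  if (anyNA(grp)) {
    stop("species without taxon metadata: ",
         paste(present[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  n <- length(present)
  n_max <- if (denominator == "per_unit") {
    max(table(grp))
  } else {
    # distribution-wide reading: size of the most speciose group in the pool
    max(table(meta$taxon_group))
  }
  n / n_max
}

#' Species passing the range-restriction uniqueness filter
#'
#' "Unique" species are those whose extent of occurrence covers at most 20%
#' of the caribou distribution and whose Canadian extent lies more than 50%
#' inside it — range-restricted species for which the study region is the
#' conservation stronghold. Boundaries follow the filter as printed:
#' inclusive at 0.20, strict at 0.50.
#'
#' @param meta species metadata with `frac_distribution` and
#'   `frac_canadian_inside` in `[0, 1]`.
#' @return character vector of species ids.
#' @export
unique_species_set <- function(meta) {
  keep <- meta$frac_distribution <= 0.20 & meta$frac_canadian_inside > 0.50
  meta$species_id[keep]
}

#' Assemble the unit x objective conservation-value matrix
#'
#' Builds the objective matrix for either planning scenario from unit-level
#' ingredients: caribou habitat area (expand scenario only — under the
#' habitat-target scenario that objective is carried by the sub-population
#' constraints instead and is omitted from the objective set), species
#' richness, taxonomic representation, unique-species count, refugia-potential
#' sum, and soil-carbon tonnes.
#'
#' @param landscape a `landscape`.
#' @param presence unit x species logical matrix (rownames = unit ids).
#' @param meta species metadata (`species_id`, `taxon_group`,
#'   `frac_distribution`, `frac_canadian_inside`).
#' @param refugia_by_unit,carbon_by_unit named numeric vectors (unit_id ->
#'   nonnegative value).
#' @param scenario `"expand"` (six columns) or `"protect"` (five columns).
#' @param taxonomic_denominator passed to [taxonomic_representation_value()].
#' @return numeric matrix with unit ids as row names and objective names
#'   `caribou_habitat` (expand only), `richness`, `taxonomic`,
#'   `unique_species`, `refugia`, `carbon` as column names.
#' @export
assemble_objective_matrix <- function(landscape, presence, meta,
                                      refugia_by_unit, carbon_by_unit,
                                      scenario = c("expand", "protect"),
                                      taxonomic_denominator = "per_unit") {
  scenario <- match.arg(scenario)
  ids <- landscape$units$unit_id
  check_unit_keys(ids, rownames(presence), "presence")
  check_unit_keys(ids, names(refugia_by_unit), "refugia_by_unit")
  check_unit_keys(ids, names(carbon_by_unit), "carbon_by_unit")
  stopifnot(all(refugia_by_unit >= 0), all(carbon_by_unit >= 0))

  uniq <- unique_species_set(meta)
  rich <- vapply(ids, function(i) richness_value(presence, i), numeric(1))
  taxo <- vapply(ids, function(i)
    taxonomic_representation_value(presence, meta, i,
                                   denominator = taxonomic_denominator),
    numeric(1))
  nuni <- vapply(ids, function(i) {
    row <- presence_row(presence, i)
    sum(colnames(presence)[row] %in% uniq)
  }, numeric(1))

  m <- cbind(richness = rich, taxonomic = taxo, unique_species = nuni,
             refugia = unname(refugia_by_unit[ids]),
             carbon = unname(carbon_by_unit[ids]))
  if (scenario == "expand") {
    hab <- landscape$units$undist_human_area
    m <- cbind(caribou_habitat = hab, m)
  }
  rownames(m) <- ids
  structure(m, scenario = scenario)
}

check_unit_keys <- function(ids, keys, what) {
  if (is.null(keys)) stop(what, " has no unit names", call. = FALSE)
  d1 <- setdiff(ids, keys)
  d2 <- setdiff(keys, ids)
  if (length(d1) || length(d2)) {
    stop("unit sets differ for ", what,
         if (length(d1)) paste0("; missing: ", paste(d1, collapse = ", ")),
         if (length(d2)) paste0("; extra: ", paste(d2, collapse = ", ")),
         call. = FALSE)
  }
}
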