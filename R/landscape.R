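#' Construct a planning-unit landscape
#'
#' A landscape is the decision space for reserve selection: a table of
#' planning units (hexagonal grid cells clipped to a species distribution,
#' each either selected for protection or not) plus an adjacency graph.
#' All areas are in km². Units carry the already-protected area and two
#' undisturbed-area variants: `undist_human_area` (unprotected land/inland
#' water > 500 m from human disturbance) and `undist_full_area` (additionally
#' unburned for > 40 years), the two habitat-value definitions used by the
#' Expand Protection and Protect Habitat scenarios respectively.
#'
#' @param units data.frame with columns `unit_id`, `total_area`,
#'   `protected_area`, `undist_human_area`, `undist_full_area`. Extra columns
#'   are preserved and ignored. `unprotected_area` and `is_partial` are
#'   derived if absent.
#' @param adjacency data.frame with columns `unit_a`, `unit_b`; undirected,
#'   one row per edge (symmetric duplicates are collapsed).
#' @param unit_area_nominal nominal (unclipped) unit area in km²; default 5000.
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return An object of class `landscape`: list with elements `units`
#'   (data.frame ordered by unit_id), `adjacency` (data.frame of canonical
#'   edges), `unit_area_nominal`, and derived totals `total_area`,
#'   `total_protected`, `protected_fraction`.
#' @export
landscape <- function(units, adjacency = NULL, unit_area_nominal = 5000,
                      validate = TRUE) {
  required <- c("unit_id", "total_area", "protected_area",
                "undist_human_area", "undist_full_area")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    stop("units table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) {
    stop("duplicate unit_id values: ",
         paste(unique(units$unit_id[duplicated(units$unit_id)]), collapse = ", "),
         call. = FALSE)
  }
  units <- units[order(units$unit_id), , drop = FALSE]
  rownames(units) <- NULL
  if (is.null(units$unprotected_area)) {
    units$unprotected_area <- units$total_area - units$protected_area
  }
  units$is_partial <- units$total_area < unit_area_nominal - 1e-6

  if (is.null(adjacency)) {
    adjacency <- data.frame(unit_a = character(0), unit_b = character(0),
                            stringsAsFactors = FALSE)
  }
  adjacency <- canonical_edges(adjacency)

  x <- structure(
    list(units = units, adjacency = adjacency,
         unit_area_nominal = unit_area_nominal),
    class = "landscape")
  x$total_area <- sum(units$total_area)
  x$total_protected <- sum(units$protected_area)
  x$protected_fraction <- x$total_protected / x$total_area

  if (validate) {
    diag <- validate_landscape(x)
    if (length(diag) > 0) {
      stop("invalid landscape:\n  ", paste(diag, collapse = "\n  "),
           call. = FALSE)
    }
  }
  x
}

# canonical undirected edge table: unit_a < unit_b, unique, sorted
canonical_edges <- function(adjacency) {
  required <- c("unit_a", "unit_b")
  missing_cols <- setdiff(required, names(adjacency))
  if (length(missing_cols) > 0) {
    stop("adjacency table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  a <- as.character(adjacency$unit_a)
  b <- as.character(adjacency$unit_b)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  e <- unique(data.frame(unit_a = lo, unit_b = hi, stringsAsFactors = FALSE))
  e <- e[order(e$unit_a, e$unit_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d units (%d partial), %d edges\n",
              nrow(x$units), sum(x$units$is_partial), nrow(x$adjacency)))
  cat(sprintf("  total area %.1f km2, protected %.1f km2 (%.1f%%)\n",
              x$total_area, x$total_protected, 100 * x$protected_fraction))
  invisible(x)
}

#' Validate a landscape against its type invariants
#'
#' Checks every planning-unit and adjacency invariant and returns a
#' character vector of diagnostics, one per violation, naming the offending
#' units or edges. An empty vector means the landscape is valid. Never
#' throws and never mutates its input.
#'
#' @param x a `landscape` (or a list with `units`/`adjacency` in the same
#'   shape, so partially-constructed objects can be checked).
#' @param tol numeric tolerance for area identities (km²).
#' @return character vector of diagnostics (length 0 when valid).
#' @export
validate_landscape <- function(x, tol = 1e-6) {
  u <- x$units
  out <- character(0)
  bad <- function(cond) u$unit_id[which(cond)]

  ids <- bad(!(u$total_area > 0 & u$total_area <= x$unit_area_nominal + tol))
  if (length(ids)) out <- c(out, paste0(
    "total_area outside (0, unit_area_nominal]: ", paste(ids, collapse = ", ")))

  ids <- bad(abs(u$protected_area + u$unprotected_area - u$total_area) > tol)
  if (length(ids)) out <- c(out, paste0(
    "protected_area + unprotected_area != total_area: ",
    paste(ids, collapse = ", ")))

  ids <- bad(u$protected_area < -tol | u$unprotected_area < -tol)
  if (length(ids)) out <- c(out, paste0(
    "negative protected/unprotected area: ", paste(ids, collapse = ", ")))

  ids <- bad(u$undist_full_area < -tol |
               u$undist_full_area > u$undist_human_area + tol |
               u$undist_human_area > u$unprotected_area + tol)
  if (length(ids)) out <- c(out, paste0(
    "undisturbed-area ordering 0 <= undist_full <= undist_human <= unprotected violated: ",
    paste(ids, collapse = ", ")))

  e <- x$adjacency
  if (nrow(e) > 0) {
    self <- e$unit_a == e$unit_b
    if (any(self)) out <- c(out, paste0(
      "self-loop edge(s): ", paste(e$unit_a[self], collapse = ", ")))
    unknown <- setdiff(unique(c(e$unit_a, e$unit_b)), u$unit_id)
    if (length(unknown)) out <- c(out, paste0(
      "edge endpoint(s) not in unit table: ", paste(unknown, collapse = ", ")))
    key <- paste(pmin(e$unit_a, e$unit_b), pmax(e$unit_a, e$unit_b))
    if (anyDuplicated(key)) out <- c(out, paste0(
      "duplicate/asymmetric edge(s): ",
      paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  out
}

#' Read a landscape from delimited tables
#'
#' @param units_path CSV of planning units (header: unit_id, total_area,
#'   protected_area, undist_human_area, undist_full_area; extra columns kept).
#' @param adjacency_path CSV with columns unit_a, unit_b (optional).
#' @param config optional list, or path to a YAML/JSON file, with entry
#'   `unit_area_nominal` (km²).
#' @return a validated `landscape`.
#' @export
read_landscape <- function(units_path, adjacency_path = NULL, config = NULL) {
  if (!file.exists(units_path)) stop("units file not found: ", units_path)
  units <- utils::read.csv(units_path, stringsAsFactors = FALSE)
  adjacency <- NULL
  if (!is.null(adjacency_path)) {
    if (!file.exists(adjacency_path))
      stop("adjacency file not found: ", adjacency_path)
    adjacency <- utils::read.csv(adjacency_path, stringsAsFactors = FALSE,
                                 colClasses = "character")
  }
  cfg <- read_config(config)
  nominal <- cfg$unit_area_nominal %||% 5000
  landscape(units, adjacency, unit_area_nominal = nominal)
}

read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      return(jsonlite::read_json(config, simplifyVector = TRUE))
    }
    return(yaml::read_yaml(config))
  }
  as.list(config)
}

#' Write a landscape to delimited tables
#'
#' Inverse of [read_landscape()]; numeric fields round-trip to full double
#' precision.
#'
#' @param x a `landscape`.
#' @param units_path,adjacency_path output CSV paths.
#' @export
write_landscape <- function(x, units_path, adjacency_path) {
  utils::write.csv(x$units, units_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$adjacency, adjacency_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Neighbor index list for a landscape
#'
#' @param x a `landscape`.
#' @return list of integer vectors, one per unit (in unit-table order),
#'   giving the row indices of that unit's hex neighbors.
#' @export
neighbor_index <- function(x) {
  ids <- x$units$unit_id
  idx <- stats::setNames(seq_along(ids), ids)
  nb <- vector("list", length(ids))
  for (k in seq_len(nrow(x$adjacency))) {
    i <- idx[[x$adjacency$unit_a[k]]]
    j <- idx[[x$adjacency$unit_b[k]]]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

#' Write a selection of priority units
#'
#' One row per landscape unit, ordered by unit_id, with columns `unit_id`,
#' `selected` (0/1) and `minarea_slack` (the minimum-area shortfall fraction,
#' empty for unselected units).
#'
#' @param path output CSV path.
#' @param selection a `selection` (see [solve_milp()]) or a character vector
#'   of selected unit ids.
#' @param landscape the landscape the selection refers to.
#' @export
write_selection <- function(path, selection, landscape) {
  sel_ids <- selected_ids(selection)
  unknown <- setdiff(sel_ids, landscape$units$unit_id)
  if (length(unknown)) {
    stop("selection contains unknown unit id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  slack <- if (is.list(selection)) selection$slack_by_unit else NULL
  ids <- landscape$units$unit_id
  sel <- as.integer(ids %in% sel_ids)
  sl <- rep(NA_real_, length(ids))
  if (!is.null(slack) && length(slack)) {
    sl[match(names(slack), ids)] <- unname(slack)
  }
  sl[sel == 1 & is.na(sl)] <- 0
  out <- data.frame(unit_id = ids, selected = sel, minarea_slack = sl,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}

#' Read a selection written by [write_selection()]
#'
#' @param path CSV path.
#' @return character vector of selected unit ids, with the slack table
#'   attached as attribute `table`.
#' @export
read_selection <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(unit_id = "character"))
  ids <- tab$unit_id[tab$selected == 1]
  attr(ids, "table") <- tab
  ids
}

selected_ids <- function(selection) {
  if (is.list(selection)) as.character(selection$selected)
  else as.character(selection)
}

#' Construct a caribou sub-population record
#'
#' A sub-population has a range area, a nominal critical-habitat target
#' (fraction of range required undisturbed: 0.40 for the Boreal Shield
#' sub-population, 0.65 otherwise), the unprotected undisturbed habitat each
#' planning unit contributes inside the range (`habitat_by_unit`, km²), and
#' the already-protected undisturbed habitat in the range (`protected_undisturbed`).
#'
#' @param subpop_id character id.
#' @param range_area range extent in km².
#' @param nominal_target_pct fraction of range (0.40 or 0.65 in the standard
#'   recovery-strategy setting; any value in (0,1] accepted).
#' @param habitat_by_unit named numeric vector, unit_id -> km².
#' @param protected_undisturbed km² of protected undisturbed habitat in range.
#' @return object of class `subpopulation`.
#' @export
subpopulation <- function(subpop_id, range_area, nominal_target_pct,
                          habitat_by_unit, protected_undisturbed = 0) {
  stopifnot(range_area > 0, nominal_target_pct > 0, nominal_target_pct <= 1,
            all(habitat_by_unit >= 0), protected_undisturbed >= 0)
  if (sum(habitat_by_unit) + protected_undisturbed > range_area + 1e-6) {
    stop("habitat + protected_undisturbed exceeds range_area for ",
         subpop_id, call. = FALSE)
  }
  structure(list(subpop_id = as.character(subpop_id),
                 range_area = range_area,
                 nominal_target_pct = nominal_target_pct,
                 habitat_by_unit = habitat_by_unit,
                 protected_undisturbed = protected_undisturbed),
            class = "subpopulation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
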