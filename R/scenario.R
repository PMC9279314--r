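#' Best single-objective outcome for every objective
#'
#' Solves one area-budgeted selection problem per objective column and
#' records, for each objective k: the optimum `V*_k` (the normalizer and
#' "best possible outcome" for the multi-objective analyses), the selected
#' unit set, and the coverage of the maximum
#' (`V*_k / sum_i v_ik`, the fraction of the value attainable if everything
#' unprotected were protected).
#'
#' @param landscape a `landscape`.
#' @param objective_matrix unit x objective matrix.
#' @param budget_fraction fraction of total distribution area.
#' @param settings a [solver_settings()].
#' @return list with `vstar`, `selections` (named list), `coverage`,
#'   `statuses`.
#' @export
run_single_objective_suite <- function(landscape, objective_matrix,
                                       budget_fraction,
                                       settings = solver_settings()) {
  objs <- colnames(objective_matrix)
  selections <- vector("list", length(objs))
  names(selections) <- objs
  vstar <- coverage <- stats::setNames(numeric(length(objs)), objs)
  statuses <- stats::setNames(character(length(objs)), objs)
  for (k in objs) {
    prob <- build_single_objective(landscape, objective_matrix[, k],
                                   budget_fraction)
    sel <- solve_milp(prob, settings)
    selections[[k]] <- sel
    vstar[k] <- sel$objective_value
    total_k <- sum(objective_matrix[, k])
    coverage[k] <- if (total_k > 0) sel$objective_value / total_k else 0
    statuses[k] <- sel$status
  }
  list(vstar = vstar, selections = selections, coverage = coverage,
       statuses = statuses)
}

#' Trade-off matrix across objectives
#'
#' Entry (l, k) is the value achieved for objective k by the selection
#' optimized for objective l, as a fraction of objective k's own optimum
#' `V*_k` — the "what do you give up by planning for something else"
#' matrix. A final `multi` row evaluates the multi-objective selection the
#' same way. Diagonal entries are 1 up to the solver gap.
#'
#' @param selections_by_objective named list of single-objective selections.
#' @param multi_selection the multi-objective selection (or NULL).
#' @param objective_matrix unit x objective matrix.
#' @param vstar named vector of single-objective optima.
#' @return numeric matrix, rows = optimized-for (plus `multi`),
#'   columns = evaluated objectives.
#' @export
trade_off_matrix <- function(selections_by_objective, multi_selection,
                             objective_matrix, vstar) {
  objs <- colnames(objective_matrix)
  vstar <- vstar[objs]
  rows <- selections_by_objective
  if (!is.null(multi_selection)) rows <- c(rows, list(multi = multi_selection))
  m <- vapply(rows, function(sel) {
    vals <- evaluate_selection(sel, objective_matrix)
    ifelse(vstar > 0, vals / vstar, 0)
  }, numeric(length(objs)))
  t(matrix(m, nrow = length(objs), dimnames = list(objs, names(rows))))
}

# count objective pairs (k evaluated, l != k optimized-for) where the
# single-objective cross outcome beats the multi-objective outcome
count_tradeoff_exceptions <- function(tom) {
  objs <- colnames(tom)
  single_rows <- setdiff(rownames(tom), "multi")
  exceptions <- data.frame(objective = character(0), better_under = character(0))
  for (k in objs) for (l in single_rows) {
    if (l == k) next
    if (tom[l, k] > tom["multi", k] + 1e-9) {
      exceptions <- rbind(exceptions,
                          data.frame(objective = k, better_under = l))
    }
  }
  exceptions
}

#' Run the protected-area-expansion scenario
#'
#' The network-expansion analysis: at an area budget (default 0.195 of the
#' distribution — the gap between 10.5% already protected and a 30%
#' protection target), solve the six single-objective problems, then the
#' maximin multi-objective problem normalized by those optima, and report
#' each objective's fraction of its best single-objective outcome, the
#' trade-off matrix, and budget/slack audits.
#'
#' @param landscape a `landscape`.
#' @param objective_matrix six-column unit x objective matrix.
#' @param budget_fraction area budget as a fraction of the distribution.
#' @param minarea_penalty elastic minimum-area penalty (default 0, the
#'   reported configuration; the sensitivity grid spans 0-1000).
#' @param settings a [solver_settings()].
#' @return list of class `scenario_report`.
#' @export
run_expand_protection <- function(landscape, objective_matrix,
                                  budget_fraction = 0.195,
                                  minarea_penalty = 0,
                                  settings = solver_settings()) {
  suite <- run_single_objective_suite(landscape, objective_matrix,
                                      budget_fraction, settings)
  prob <- build_expand_multiobjective(landscape, objective_matrix,
                                      budget_fraction, minarea_penalty,
                                      normalizers = suite$vstar)
  multi <- solve_milp(prob, settings)
  finish_report("expand_protection", landscape, objective_matrix, suite,
                multi,
                config = list(budget_fraction = budget_fraction,
                              minarea_penalty = minarea_penalty,
                              relative_gap = settings$relative_gap,
                              time_limit = settings$time_limit),
                budget = prob$budget)
}

finish_report <- function(scenario, landscape, objective_matrix, suite,
                          multi, config, budget = NULL, extra = list()) {
  fractions <- ifelse(suite$vstar > 0,
                      evaluate_selection(multi, objective_matrix) / suite$vstar,
                      0)
  tom <- trade_off_matrix(suite$selections, multi, objective_matrix,
                          suite$vstar)
  report <- c(list(
    scenario = scenario,
    vstar = suite$vstar,
    coverage_of_maximum = suite$coverage,
    selections = lapply(suite$selections, `[[`, "selected"),
    multi_selection = multi$selected,
    multi_cost = multi$cost,
    multi_status = multi$status,
    single_statuses = suite$statuses,
    fractions_of_best = fractions,
    min_fraction = min(fractions),
    trade_off = tom,
    tradeoff_exceptions = count_tradeoff_exceptions(tom),
    slack_total = sum(multi$slack_by_unit),
    budget = budget,
    budget_ok = if (!is.null(budget)) multi$cost <= budget + 1e-6 else NA,
    config = config), extra)
  class(report) <- "scenario_report"
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("%s report: %d units selected, min fraction-of-best %.3f\n",
              x$scenario, length(x$multi_selection), x$min_fraction))
  print(round(x$fractions_of_best, 3))
  invisible(x)
}

#' Run the critical-habitat-protection scenario
#'
#' The habitat-target analysis: compute the effective (capped)
#' sub-population targets at the requested scaling, find the minimum total
#' area satisfying them, compute each objective's best possible outcome at
#' a budget equal to that minimum area, then solve the maximin problem over
#' the five non-caribou objectives subject to the habitat-target
#' constraints, with an area-expansion penalty `q` instead of a budget.
#'
#' @param landscape a `landscape`.
#' @param objective_matrix five-column matrix (no caribou-habitat column).
#' @param subpops list of `subpopulation` objects.
#' @param target_scaling fraction of the nominal targets (0.25, 0.5, 0.75
#'   or 1 in the standard design).
#' @param area_penalty `q` (default 10, the reported configuration).
#' @param minarea_penalty elastic minimum-area penalty (default 0).
#' @param settings a [solver_settings()].
#' @return list of class `scenario_report`, with additional elements
#'   `targets`, `minimum_area`, `minimum_area_proportion` (of the
#'   landscape's unprotected area), `prioritized_area_proportion`,
#'   `n_capped_targets`, `targets_ok`.
#' @export
run_protect_habitat <- function(landscape, objective_matrix, subpops,
                                target_scaling = 1, area_penalty = 10,
                                minarea_penalty = 0,
                                settings = solver_settings()) {
  targets <- compute_effective_targets(subpops, target_scaling)
  minarea_prob <- build_minimum_area_problem(landscape, subpops, targets)
  minarea_sel <- solve_milp(minarea_prob, settings)
  a_min <- minarea_sel$objective_value
  c_total <- sum(landscape$units$unprotected_area)

  suite <- run_single_objective_suite(landscape, objective_matrix,
                                      a_min / landscape$total_area, settings)
  # degenerate scalings (all-zero targets) leave V* = 0; any positive
  # normalizer yields the same (empty) optimum there
  normalizers <- ifelse(suite$vstar > 0, suite$vstar, 1)
  prob <- build_protect_habitat(landscape, objective_matrix, subpops,
                                targets, area_penalty, minarea_penalty,
                                normalizers = normalizers)
  multi <- solve_milp(prob, settings)

  x <- as.numeric(landscape$units$unit_id %in% multi$selected)
  lhs <- as.numeric(crossprod(prob$subpop$h, x))
  targets_ok <- all(lhs + prob$subpop$P >= prob$subpop$effective - 1e-6)

  finish_report("protect_habitat", landscape, objective_matrix, suite, multi,
                config = list(target_scaling = target_scaling,
                              area_penalty = area_penalty,
                              minarea_penalty = minarea_penalty,
                              relative_gap = settings$relative_gap,
                              time_limit = settings$time_limit),
                extra = list(
                  targets = targets,
                  minimum_area = a_min,
                  minimum_area_selection = minarea_sel$selected,
                  minimum_area_proportion = a_min / c_total,
                  prioritized_area_proportion = multi$cost / c_total,
                  n_capped_targets = sum(targets$capped),
                  targets_ok = targets_ok))
}

#' Penalty sensitivity grid
#'
#' Re-runs a scenario across a grid of penalties and reports per-cell
#' summaries and the pairwise Jaccard overlap of the resulting priority
#' sets. The expansion scenario varies the minimum-area penalty (8 cells at
#' the full design); the habitat scenario crosses minimum-area penalties,
#' area penalties and target scalings (8 x 8 x 4 = 256 cells at the full
#' design). Single-objective normalizers are computed once per budget or
#' scaling and reused across penalty cells. If `cell_dir` is given, each
#' cell's result is written to (and, when re-run, restored from) a JSON
#' file, so interrupted grids resume.
#'
#' @param scenario `"expand"` or `"protect"`.
#' @param landscape a `landscape`.
#' @param objective_matrix objective matrix for the scenario (6 or 5
#'   columns).
#' @param subpops sub-populations (protect scenario only).
#' @param minarea_penalties,area_penalties penalty axes (defaults: the full
#'   design grid 0, 0.001, 0.01, 0.1, 1, 10, 100, 1000).
#' @param target_scalings scaling axis (protect scenario; default
#'   0.25, 0.5, 0.75, 1).
#' @param budget_fraction expansion-scenario budget.
#' @param settings a [solver_settings()].
#' @param cell_dir optional directory for per-cell result files.
#' @return list of class `sensitivity_grid`: `cells` (data.frame of axis
#'   values, min fraction, prioritized-area proportion, status), `jaccard`
#'   (symmetric matrix with unit diagonal), `selections`.
#' @export
sensitivity_grid <- function(scenario = c("expand", "protect"), landscape,
                             objective_matrix, subpops = NULL,
                             minarea_penalties = default_penalty_grid(),
                             area_penalties = default_penalty_grid(),
                             target_scalings = c(0.25, 0.5, 0.75, 1),
                             budget_fraction = 0.195,
                             settings = solver_settings(),
                             cell_dir = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(length(minarea_penalties) > 0)
  if (!is.null(cell_dir)) dir.create(cell_dir, showWarnings = FALSE,
                                     recursive = TRUE)
  cells <- list(); selections <- list()
  c_total <- sum(landscape$units$unprotected_area)

  run_cell <- function(label, fn) {
    res <- if (!is.null(cell_dir)) {
      f <- file.path(cell_dir, paste0(label, ".json"))
      if (file.exists(f)) {
        jsonlite::read_json(f, simplifyVector = TRUE)
      } else {
        r <- fn()
        jsonlite::write_json(r, f, auto_unbox = TRUE, digits = NA)
        r
      }
    } else {
      fn()
    }
    res$selected <- as.character(unlist(res$selected))
    res
  }

  if (scenario == "expand") {
    suite <- run_single_objective_suite(landscape, objective_matrix,
                                        budget_fraction, settings)
    for (p in minarea_penalties) {
      label <- sprintf("expand_p%g", p)
      res <- run_cell(label, function() {
        prob <- build_expand_multiobjective(landscape, objective_matrix,
                                            budget_fraction, p,
                                            normalizers = suite$vstar)
        sel <- solve_milp(prob, settings)
        fr <- ifelse(suite$vstar > 0,
                     evaluate_selection(sel, objective_matrix) / suite$vstar, 0)
        list(selected = sel$selected, min_fraction = min(fr),
             area_proportion = sel$cost / c_total, status = sel$status)
      })
      cells[[label]] <- data.frame(minarea_penalty = p,
                                   min_fraction = res$min_fraction,
                                   area_proportion = res$area_proportion,
                                   status = res$status)
      selections[[label]] <- res$selected
    }
  } else {
    stopifnot(!is.null(subpops), length(area_penalties) > 0,
              length(target_scalings) > 0)
    for (sc in target_scalings) {
      targets <- compute_effective_targets(subpops, sc)
      minarea_sel <- solve_milp(
        build_minimum_area_problem(landscape, subpops, targets), settings)
      suite <- run_single_objective_suite(
        landscape, objective_matrix,
        minarea_sel$objective_value / landscape$total_area, settings)
      normalizers <- ifelse(suite$vstar > 0, suite$vstar, 1)
      for (q in area_penalties) for (p in minarea_penalties) {
        label <- sprintf("protect_s%g_q%g_p%g", sc, q, p)
        res <- run_cell(label, function() {
          prob <- build_protect_habitat(landscape, objective_matrix, subpops,
                                        targets, q, p,
                                        normalizers = normalizers)
          sel <- solve_milp(prob, settings)
          fr <- ifelse(suite$vstar > 0,
                       evaluate_selection(sel, objective_matrix) /
                         suite$vstar, 0)
          list(selected = sel$selected, min_fraction = min(fr),
               area_proportion = sel$cost / c_total, status = sel$status)
        })
        cells[[label]] <- data.frame(target_scaling = sc, area_penalty = q,
                                     minarea_penalty = p,
                                     min_fraction = res$min_fraction,
                                     area_proportion = res$area_proportion,
                                     status = res$status)
        selections[[label]] <- res$selected
      }
    }
  }
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  cells$cell <- names(selections)
  structure(list(cells = cells, jaccard = jaccard_matrix(selections),
                 selections = selections),
            class = "sensitivity_grid")
}

#' The standard penalty grid
#'
#' @return `c(0, 0.001, 0.01, 0.1, 1, 10, 100, 1000)`, the eight penalty
#'   levels used by both sensitivity designs.
#' @export
default_penalty_grid <- function() c(0, 0.001, 0.01, 0.1, 1, 10, 100, 1000)

#' Write a scenario report to JSON
#'
#' Reports are pure functions of (inputs, settings), so re-running a
#' scenario and re-writing yields identical files.
#'
#' @param report a `scenario_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$trade_off <- as.data.frame(out$trade_off)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
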