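#' @name milp-builders
#' @title Integer programs for reserve prioritization
#'
#' @description
#' Four problem builders cover the planning analyses:
#' \itemize{
#'   \item [build_single_objective()] — maximize one conservation value under
#'     an area budget (binary knapsack); used both directly and to obtain the
#'     single-objective optima that normalize the maximin problems.
#'   \item [build_expand_multiobjective()] — maximin prioritization: maximize
#'     the worst normalized objective across all conservation objectives at a
#'     fixed area budget, with elastic minimum-area constraints.
#'   \item [build_minimum_area_problem()] — minimum total area satisfying all
#'     sub-population habitat targets.
#'   \item [build_protect_habitat()] — maximin prioritization constrained by
#'     the habitat targets, with a penalty on total area added instead of a
#'     hard budget.
#' }
#' Every builder returns a `milp_problem`, a structured description solved by
#' [solve_milp()] (HiGHS branch-and-cut) or, exactly, by
#' [brute_force_solve()] on small instances.
#'
#' The unit selection cost is always the unprotected area of the unit (the
#' area that would be added to the network). The elastic minimum-area
#' constraint for unit i reads
#' `A_i + sum_{j in N(i)} (prot_j + c_j x_j) + M s_i >= M x_i`,
#' where `A_i` is the unit's total area, `N(i)` its hex neighbors, `prot_j`
#' a neighbor's existing protected area, `c_j x_j` a neighbor's co-selected
#' unprotected area, `M` the nominal unit area (5000 km²) and
#' `s_i in [0, 1]` the shortfall fraction, penalized linearly in the
#' objective. A unit can thus qualify through its own size, through
#' protected neighbors, or through co-selected neighbors.
NULL

new_milp_problem <- function(type, sense, landscape, v, budget = NULL,
                             normalizers = NULL, minarea = NULL,
                             subpop = NULL, area_penalty = 0) {
  structure(list(
    type = type, sense = sense,
    unit_ids = landscape$units$unit_id,
    cost = landscape$units$unprotected_area,
    total_area = landscape$total_area,
    v = v, budget = budget, normalizers = normalizers,
    minarea = minarea, subpop = subpop,
    area_penalty = area_penalty,
    C_total = sum(landscape$units$unprotected_area)
  ), class = "milp_problem")
}

#' @export
print.milp_problem <- function(x, ...) {
  cat(sprintf("milp_problem [%s]: %d units", x$type, length(x$unit_ids)))
  if (!is.null(x$budget)) cat(sprintf(", budget %.1f km2", x$budget))
  if (!is.null(x$subpop)) cat(sprintf(", %d habitat targets", length(x$subpop$rhs)))
  if (!is.null(x$minarea)) cat(sprintf(", elastic min-area (p=%g)", x$minarea$penalty))
  cat("\n")
  invisible(x)
}

minarea_terms <- function(landscape, penalty, elastic = TRUE) {
  nb <- neighbor_index(landscape)
  u <- landscape$units
  const <- u$total_area +
    vapply(nb, function(j) sum(u$protected_area[j]), numeric(1))
  list(M = landscape$unit_area_nominal, const = const, nb = nb,
       penalty = penalty, elastic = elastic)
}

subpop_terms <- function(landscape, subpops, targets) {
  ids <- landscape$units$unit_id
  S <- length(subpops)
  h <- matrix(0, nrow = length(ids), ncol = S,
              dimnames = list(ids, vapply(subpops, `[[`, "", "subpop_id")))
  P <- numeric(S)
  for (s in seq_len(S)) {
    sp <- subpops[[s]]
    unknown <- setdiff(names(sp$habitat_by_unit), ids)
    if (length(unknown)) {
      stop("sub-population ", sp$subpop_id, " references unknown unit(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    h[names(sp$habitat_by_unit), s] <- sp$habitat_by_unit
    P[s] <- sp$protected_undisturbed
  }
  eff <- targets$effective[match(colnames(h), targets$subpop_id)]
  list(h = h, rhs = pmax(0, eff - P), P = P,
       effective = eff, subpop_ids = colnames(h))
}

#' Single-objective reserve selection under an area budget
#'
#' Maximize the summed conservation value of selected units subject to the
#' total unprotected area added not exceeding `budget_fraction` of the
#' landscape's total distribution area.
#'
#' @param landscape a `landscape`.
#' @param values nonnegative per-unit value vector (landscape unit order, or
#'   named by unit_id).
#' @param budget_fraction fraction of total distribution area, in `[0, 1]`.
#' @return a `milp_problem`.
#' @export
build_single_objective <- function(landscape, values, budget_fraction) {
  values <- align_values(landscape, values)
  if (any(values < 0)) stop("objective values must be nonnegative", call. = FALSE)
  stopifnot(budget_fraction >= 0, budget_fraction <= 1)
  new_milp_problem("single", "max", landscape,
                   v = matrix(values, ncol = 1,
                              dimnames = list(landscape$units$unit_id, "objective")),
                   budget = budget_fraction * landscape$total_area)
}

align_values <- function(landscape, values) {
  ids <- landscape$units$unit_id
  if (!is.null(names(values))) {
    check_unit_keys(ids, names(values), "values")
    values <- values[ids]
  } else if (length(values) != length(ids)) {
    stop("values length does not match unit count", call. = FALSE)
  }
  as.numeric(values)
}

align_matrix <- function(landscape, m) {
  ids <- landscape$units$unit_id
  check_unit_keys(ids, rownames(m), "objective matrix")
  m <- m[ids, , drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("objective matrix must be finite and nonnegative", call. = FALSE)
  }
  m
}

check_normalizers <- function(normalizers, m) {
  if (is.null(names(normalizers))) names(normalizers) <- colnames(m)
  missing_n <- setdiff(colnames(m), names(normalizers))
  if (length(missing_n)) {
    stop("missing normalizer(s): ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  }
  normalizers <- normalizers[colnames(m)]
  if (any(normalizers <= 0)) {
    stop("zero/negative normalizer for objective(s): ",
         paste(colnames(m)[normalizers <= 0], collapse = ", "),
         " (objective unattainable at this budget)", call. = FALSE)
  }
  normalizers
}

#' Maximin multi-objective prioritization at an area budget
#'
#' Maximize `t - p * sum(s_i)` where `t` is the minimum across objectives of
#' the selected summed value divided by that objective's single-objective
#' optimum at the same budget (so `t` reads directly as "fraction of the
#' best single-objective outcome"), and `s_i` are the elastic minimum-area
#' shortfalls described in [milp-builders].
#'
#' @param landscape a `landscape`.
#' @param objective_matrix unit x objective nonnegative matrix.
#' @param budget_fraction fraction of total distribution area.
#' @param minarea_penalty slack penalty `p >= 0` (the sensitivity design uses
#'   0, 0.001, 0.01, 0.1, 1, 10, 100, 1000).
#' @param normalizers named positive vector of single-objective optima
#'   `V*_k` at the same budget (from [run_single_objective_suite()]).
#' @return a `milp_problem`.
#' @export
build_expand_multiobjective <- function(landscape, objective_matrix,
                                        budget_fraction, minarea_penalty = 0,
                                        normalizers) {
  m <- align_matrix(landscape, objective_matrix)
  normalizers <- check_normalizers(normalizers, m)
  stopifnot(budget_fraction >= 0, budget_fraction <= 1, minarea_penalty >= 0)
  new_milp_problem("expand", "max", landscape, v = m,
                   budget = budget_fraction * landscape$total_area,
                   normalizers = normalizers,
                   minarea = minarea_terms(landscape, minarea_penalty))
}

#' Effective habitat-protection targets per sub-population
#'
#' The nominal target is `scaling * nominal_target_pct * range_area`. Where
#' disturbance has left less undisturbed habitat than the nominal target,
#' the target is capped at what is available
#' (`sum_i h_{i,s} + protected_undisturbed`), guaranteeing feasibility; the
#' `capped` flag records this.
#'
#' @param subpops list of `subpopulation` objects.
#' @param scaling fraction of the nominal critical-habitat target
#'   (the planning analyses use 0.25, 0.5, 0.75 and 1).
#' @return data.frame of class `effective_targets` with columns `subpop_id`,
#'   `range_area`, `nominal_target_pct`, `nominal`, `available`, `effective`,
#'   `capped`.
#' @export
compute_effective_targets <- function(subpops, scaling = 1) {
  stopifnot(scaling >= 0, scaling <= 1)
  rows <- lapply(subpops, function(sp) {
    nominal <- scaling * sp$nominal_target_pct * sp$range_area
    available <- sum(sp$habitat_by_unit) + sp$protected_undisturbed
    data.frame(subpop_id = sp$subpop_id, range_area = sp$range_area,
               nominal_target_pct = sp$nominal_target_pct,
               nominal = nominal, available = available,
               effective = min(nominal, available),
               capped = available < nominal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effective_targets", "data.frame")
  out
}

#' Minimum area needed to satisfy all habitat targets
#'
#' Minimize the total unprotected area selected subject to, for each
#' sub-population s, `sum_i h_{i,s} x_i + P_s >= effective_s`. Already
#' protected undisturbed habitat `P_s` is credited toward the target.
#' Minimum-area constraints are off by default; `include_minarea = TRUE`
#' adds them as hard constraints.
#'
#' @param landscape a `landscape`.
#' @param subpops list of `subpopulation` objects.
#' @param targets an `effective_targets` table from
#'   [compute_effective_targets()].
#' @param include_minarea add hard minimum-area constraints (default FALSE).
#' @return a `milp_problem` (minimization).
#' @export
build_minimum_area_problem <- function(landscape, subpops, targets,
                                       include_minarea = FALSE) {
  sp <- subpop_terms(landscape, subpops, targets)
  minarea <- if (include_minarea) {
    minarea_terms(landscape, penalty = 0, elastic = FALSE)
  }
  new_milp_problem("minarea", "min", landscape,
                   v = NULL, subpop = sp, minarea = minarea)
}

#' Maximin prioritization under critical-habitat targets
#'
#' Maximize `t - p * sum(s_i) - q * sum(c_i x_i) / C_total`: the maximin
#' level over the five non-caribou objectives, an elastic minimum-area
#' penalty, and a penalty `q` on the fraction of the landscape's unprotected
#' area `C_total` that is added to the network (caribou habitat enters
#' through the sub-population target constraints rather than as an
#' objective). There is no budget constraint; `q` governs the trade-off
#' between conservation outcome and area protected.
#'
#' @param landscape a `landscape`.
#' @param objective_matrix unit x objective matrix of the five non-caribou
#'   objectives.
#' @param subpops list of `subpopulation` objects.
#' @param targets `effective_targets` table.
#' @param area_penalty `q >= 0` (dimensionless; the sensitivity design spans
#'   0 to 1000).
#' @param minarea_penalty slack penalty `p >= 0`.
#' @param normalizers named positive vector of per-objective best-possible
#'   values at the matching minimum-area budget.
#' @return a `milp_problem`.
#' @export
build_protect_habitat <- function(landscape, objective_matrix, subpops,
                                  targets, area_penalty = 10,
                                  minarea_penalty = 0, normalizers) {
  m <- align_matrix(landscape, objective_matrix)
  normalizers <- check_normalizers(normalizers, m)
  stopifnot(area_penalty >= 0, minarea_penalty >= 0)
  new_milp_problem("protect", "max", landscape, v = m,
                   normalizers = normalizers,
                   minarea = minarea_terms(landscape, minarea_penalty),
                   subpop = subpop_terms(landscape, subpops, targets),
                   area_penalty = area_penalty)
}

#' Per-objective value of a selection
#'
#' @param selection a `selection` or character vector of unit ids.
#' @param objective_matrix unit x objective matrix.
#' @return named numeric vector of summed values, one per objective.
#' @export
evaluate_selection <- function(selection, objective_matrix) {
  ids <- selected_ids(selection)
  unknown <- setdiff(ids, rownames(objective_matrix))
  if (length(unknown)) {
    stop("selection contains unknown unit(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  colSums(objective_matrix[rownames(objective_matrix) %in% ids, , drop = FALSE])
}

# Minimal feasible min-area shortfall fractions for a 0/1 selection vector.
# s_i = max(0, (M - A_i - sum_{j in N(i)} (prot_j + c_j x_j)) / M) for
# selected i, 0 otherwise; never exceeds 1 because the numerator is at most M.
minarea_slack <- function(problem, x) {
  ma <- problem$minarea
  if (is.null(ma)) return(numeric(length(x)))
  neigh_sel <- vapply(seq_along(x), function(i)
    sum(problem$cost[ma$nb[[i]]] * x[ma$nb[[i]]]), numeric(1))
  pmax(0, (ma$M * x - ma$const - neigh_sel) / ma$M)
}

# Objective of a 0/1 selection with analytically optimal slack and t.
selection_objective <- function(problem, x) {
  obj <- switch(problem$type,
    single = sum(problem$v[, 1] * x),
    minarea = sum(problem$cost * x),
    expand = ,
    protect = {
      sums <- as.numeric(crossprod(problem$v, x))
      t_val <- min(sums / problem$normalizers)
      pen <- problem$minarea$penalty * sum(minarea_slack(problem, x))
      area_pen <- if (problem$type == "protect")
        problem$area_penalty * sum(problem$cost * x) / problem$C_total else 0
      t_val - pen - area_pen
    })
  obj
}

selection_feasible <- function(problem, x, tol = 1e-9) {
  if (!is.null(problem$budget) &&
      sum(problem$cost * x) > problem$budget + tol * (1 + problem$budget)) {
    return(FALSE)
  }
  if (!is.null(problem$subpop)) {
    lhs <- as.numeric(crossprod(problem$subpop$h, x))
    if (any(lhs < problem$subpop$rhs - tol * (1 + problem$subpop$rhs))) {
      return(FALSE)
    }
  }
  if (!is.null(problem$minarea) && !problem$minarea$elastic) {
    if (any(minarea_slack(problem, x) > tol)) return(FALSE)
  }
  TRUE
}

#' Exact optimum by exhaustive enumeration
#'
#' Test oracle for small instances: enumerates all 2^n unit subsets,
#' computes the optimal slack and maximin level analytically for each, and
#' returns the exact optimum. Ties are broken by the lexicographically
#' smallest selected id-set. Limited to 20 units.
#'
#' @param problem a `milp_problem` with at most 20 units.
#' @return a `selection` (same shape as [solve_milp()]).
#' @export
brute_force_solve <- function(problem) {
  n <- length(problem$unit_ids)
  if (n > 20) stop("brute_force_solve limited to 20 units", call. = FALSE)
  best_obj <- if (problem$sense == "max") -Inf else Inf
  best_key <- NULL
  best_x <- NULL
  better <- function(a, b) if (problem$sense == "max") a > b + 1e-9 else a < b - 1e-9
  for (mask in 0:(2^n - 1)) {
    x <- as.numeric(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L)
    if (!selection_feasible(problem, x)) next
    obj <- selection_objective(problem, x)
    key <- paste(problem$unit_ids[x == 1], collapse = ",")
    if (is.null(best_x) || better(obj, best_obj) ||
        (abs(obj - best_obj) <= 1e-9 && key < best_key)) {
      best_obj <- obj
      best_key <- key
      best_x <- x
    }
  }
  if (is.null(best_x)) {
    return(structure(list(selected = character(0),
                          slack_by_unit = numeric(0),
                          status = "infeasible",
                          objective_value = NA_real_, best_bound = NA_real_,
                          sense = problem$sense),
                     class = "selection"))
  }
  make_selection(problem, best_x, best_obj, best_obj, "optimal_within_gap")
}

make_selection <- function(problem, x, objective_value, best_bound, status) {
  sel <- problem$unit_ids[x == 1]
  slack <- if (!is.null(problem$minarea)) {
    s <- minarea_slack(problem, x)
    stats::setNames(s[x == 1], sel)
  } else {
    stats::setNames(rep(0, length(sel)), sel)
  }
  t_val <- if (problem$type %in% c("expand", "protect")) {
    sums <- as.numeric(crossprod(problem$v, x))
    min(sums / problem$normalizers)
  } else NA_real_
  structure(list(selected = sel, slack_by_unit = slack, status = status,
                 objective_value = objective_value, best_bound = best_bound,
                 t = t_val, cost = sum(problem$cost * x),
                 sense = problem$sense),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("selection: %d units, status %s, objective %.6g (bound %.6g)\n",
              length(x$selected), x$status, x$objective_value, x$best_bound))
  invisible(x)
}
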