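#' Solver settings
#'
#' @param relative_gap relative MIP gap tolerance; 0.005 (0.5%) is the
#'   standard planning setting, 0 forces a proven optimum.
#' @param time_limit wall-clock limit in seconds; if hit, the best feasible
#'   incumbent is returned with status `feasible_timeout`.
#' @param backend solver backend id; `"scipy-highs"` (the HiGHS
#'   branch-and-cut solver driven through a Python subprocess) is the only
#'   built-in backend.
#' @return list of class `solver_settings`.
#' @export
solver_settings <- function(relative_gap = 0.005, time_limit = 300,
                            backend = "scipy-highs") {
  stopifnot(relative_gap >= 0, time_limit > 0)
  structure(list(relative_gap = relative_gap, time_limit = time_limit,
                 backend = backend),
            class = "solver_settings")
}

# Generic matrix form of a structured problem.
# Variable layout: x_1..x_n (binary), then s_1..s_n (continuous in [0,1])
# when elastic min-area constraints are present, then t (continuous >= 0)
# for maximin problems. Constraint rows are tagged for audits.
milp_matrix_form <- function(problem) {
  n <- length(problem$unit_ids)
  has_slack <- !is.null(problem$minarea) && problem$minarea$elastic
  has_t <- problem$type %in% c("expand", "protect")
  n_vars <- n + if (has_slack) n else 0
  t_idx <- if (has_t) n_vars + 1L else NULL
  if (has_t) n_vars <- n_vars + 1L
  s_idx <- if (has_slack) n + seq_len(n) else integer(0)

  obj <- numeric(n_vars)
  if (problem$type == "single") obj[seq_len(n)] <- problem$v[, 1]
  if (problem$type == "minarea") obj[seq_len(n)] <- problem$cost
  if (has_t) obj[t_idx] <- 1
  if (has_slack) obj[s_idx] <- -problem$minarea$penalty
  if (problem$type == "protect") {
    obj[seq_len(n)] <- obj[seq_len(n)] -
      problem$area_penalty * problem$cost / problem$C_total
  }

  lb <- numeric(n_vars)
  ub <- c(rep(1, n), rep(1, length(s_idx)), if (has_t) Inf)
  integrality <- c(rep(1L, n), rep(0L, n_vars - n))

  ai <- list(); aj <- list(); ax <- list()
  row_lb <- numeric(0); row_ub <- numeric(0); tags <- character(0)
  r <- 0L
  add_row <- function(cols, vals, lo, hi, tag) {
    r <<- r + 1L
    ai[[r]] <<- rep(r, length(cols)); aj[[r]] <<- cols; ax[[r]] <<- vals
    row_lb[r] <<- lo; row_ub[r] <<- hi; tags[r] <<- tag
  }

  if (!is.null(problem$budget)) {
    add_row(seq_len(n), problem$cost, -Inf, problem$budget, "budget")
  }
  if (has_t) {
    for (k in seq_len(ncol(problem$v))) {
      add_row(c(seq_len(n), t_idx),
              c(problem$v[, k], -problem$normalizers[k]),
              0, Inf, paste0("maximin_", colnames(problem$v)[k]))
    }
  }
  if (!is.null(problem$subpop)) {
    for (s in seq_len(length(problem$subpop$rhs))) {
      nz <- which(problem$subpop$h[, s] != 0)
      if (length(nz) == 0 && problem$subpop$rhs[s] <= 0) next
      add_row(nz, problem$subpop$h[nz, s], problem$subpop$rhs[s], Inf,
              paste0("subpop_", problem$subpop$subpop_ids[s]))
    }
  }
  if (!is.null(problem$minarea)) {
    ma <- problem$minarea
    for (i in seq_len(n)) {
      cols <- c(ma$nb[[i]], i)
      vals <- c(problem$cost[ma$nb[[i]]], -ma$M)
      if (ma$elastic) { cols <- c(cols, s_idx[i]); vals <- c(vals, ma$M) }
      add_row(cols, vals, -ma$const[i], Inf,
              paste0("minarea_", problem$unit_ids[i]))
    }
  }

  list(n = n, n_vars = n_vars, obj = obj, lb = lb, ub = ub,
       integrality = integrality,
       A_row = unlist(ai), A_col = unlist(aj), A_val = unlist(ax),
       row_lb = row_lb, row_ub = row_ub, n_rows = r, tags = tags,
       s_idx = s_idx, t_idx = t_idx)
}

find_python <- function() {
  py <- getOption("reservemax.python", Sys.getenv("RESERVEMAX_PYTHON", ""))
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no python interpreter found for the scipy-highs backend; ",
         "set options(reservemax.python=...)", call. = FALSE)
  }
  py
}

#' Solve a prioritization problem
#'
#' Solves the mixed-integer program through the HiGHS branch-and-cut solver
#' (via scipy in a Python subprocess, exchanged as JSON). The returned
#' `selection` reports the selected unit set, the minimal feasible
#' minimum-area shortfall per selected unit (recomputed analytically from
#' the selection, so it is deterministic even when the shortfall penalty is
#' zero and the solver leaves slack values arbitrary), the achieved
#' objective, the solver's best bound, and a status:
#' `optimal_within_gap`, `feasible_timeout`, or `infeasible`.
#'
#' @param problem a `milp_problem` from one of the builders.
#' @param settings a [solver_settings()].
#' @return object of class `selection`.
#' @export
solve_milp <- function(problem, settings = solver_settings()) {
  mf <- milp_matrix_form(problem)
  sense_mult <- if (problem$sense == "max") -1 else 1
  big <- 1e30  # HiGHS treats |bound| >= 1e30 as infinite
  clip <- function(v) pmin(pmax(v, -big), big)
  payload <- list(
    n_vars = mf$n_vars, n_rows = mf$n_rows,
    obj = sense_mult * mf$obj,
    lb = clip(mf$lb), ub = clip(mf$ub), integrality = mf$integrality,
    A_row = mf$A_row - 1L, A_col = mf$A_col - 1L, A_val = mf$A_val,
    row_lb = clip(mf$row_lb), row_ub = clip(mf$row_ub),
    mip_rel_gap = settings$relative_gap, time_limit = settings$time_limit)

  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "milp_backend.py", package = "reservemax",
                        mustWork = TRUE)
  status <- system2(find_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("MILP backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)

  if (res$status == 2) {
    return(structure(list(selected = character(0),
                          slack_by_unit = numeric(0), status = "infeasible",
                          objective_value = NA_real_, best_bound = NA_real_,
                          sense = problem$sense),
                     class = "selection"))
  }
  if (is.null(res$x) || all(is.na(res$x))) {
    stop("solver returned no solution (status ", res$status, "): ",
         res$message, call. = FALSE)
  }
  x <- round(res$x[seq_len(mf$n)])
  status_str <- if (res$status == 0) "optimal_within_gap" else "feasible_timeout"
  objective_value <- sense_mult * res$fun
  best_bound <- if (!is.null(res$mip_dual_bound) && is.finite(res$mip_dual_bound)) {
    sense_mult * res$mip_dual_bound
  } else {
    objective_value
  }
  # guard against the bound crossing the incumbent by roundoff
  if (problem$sense == "max") best_bound <- max(best_bound, objective_value)
  else best_bound <- min(best_bound, objective_value)
  make_selection(problem, x, objective_value, best_bound, status_str)
}

#' Export a problem in LP text format
#'
#' Writes a human-readable LP-format file of the generic matrix form, for
#' debugging or for feeding an external solver.
#'
#' @param problem a `milp_problem`.
#' @param path output path.
#' @export
write_lp <- function(problem, path) {
  mf <- milp_matrix_form(problem)
  vn <- c(paste0("x_", problem$unit_ids),
          if (length(mf$s_idx)) paste0("s_", problem$unit_ids),
          if (!is.null(mf$t_idx)) "t")
  term <- function(cols, vals) {
    paste(sprintf("%+.12g %s", vals, vn[cols]), collapse = " ")
  }
  lines <- c(if (problem$sense == "max") "Maximize" else "Minimize",
             paste(" obj:", term(which(mf$obj != 0), mf$obj[mf$obj != 0])),
             "Subject To")
  for (r in seq_len(mf$n_rows)) {
    sel <- mf$A_row == r
    expr <- term(mf$A_col[sel], mf$A_val[sel])
    tag <- mf$tags[r]
    if (is.finite(mf$row_lb[r]))
      lines <- c(lines, sprintf(" %s_lo: %s >= %.12g", tag, expr, mf$row_lb[r]))
    if (is.finite(mf$row_ub[r]))
      lines <- c(lines, sprintf(" %s_up: %s <= %.12g", tag, expr, mf$row_ub[r]))
  }
  lines <- c(lines, "Bounds")
  for (j in seq_len(mf$n_vars)) {
    lines <- c(lines, sprintf(" %.12g <= %s <= %s", mf$lb[j], vn[j],
                              if (is.finite(mf$ub[j]))
                                sprintf("%.12g", mf$ub[j]) else "+inf"))
  }
  lines <- c(lines, "Binaries",
             paste("", paste(vn[mf$integrality == 1], collapse = " ")),
             "End")
  writeLines(lines, path)
  invisible(path)
}
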