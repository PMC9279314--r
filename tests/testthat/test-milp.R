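test_that("single-objective knapsack matches exhaustive enumeration", {
  land <- mk_land(c(5, 3, 3, 1))
  prob <- build_single_objective(land, c(10, 6, 5, 2), 6 / land$total_area)
  bf <- brute_force_solve(prob)
  expect_equal(bf$objective_value, 12)
  expect_setequal(bf$selected, c("u1", "u4"))
  sel <- solve_milp(prob, exact())
  expect_equal(sel$objective_value, 12)
  expect_equal(sel$status, "optimal_within_gap")
  expect_setequal(sel$selected, c("u1", "u4"))

  # degenerate budgets
  expect_length(brute_force_solve(
    build_single_objective(land, c(10, 6, 5, 2), 0))$selected, 0)
  all_in <- brute_force_solve(build_single_objective(land, c(10, 6, 5, 2), 1))
  expect_equal(all_in$objective_value, 23)
  expect_length(all_in$selected, 4)

  expect_error(build_single_objective(land, c(-1, 1, 1, 1), 0.5), "nonnegative")
})

test_that("maximin problem reproduces the two-objective toy", {
  toy <- toy_maximin()
  suite_vstar <- vapply(colnames(toy$m), function(k)
    brute_force_solve(build_single_objective(toy$land, toy$m[, k],
                                             toy$budget_fraction))$objective_value,
    numeric(1))
  expect_equal(unname(suite_vstar), c(16, 16))
  prob <- build_expand_multiobjective(toy$land, toy$m, toy$budget_fraction,
                                      0, normalizers = suite_vstar)
  bf <- brute_force_solve(prob)
  expect_equal(bf$t, 0.625)
  expect_setequal(bf$selected, c("u1", "u2"))
  sel <- solve_milp(prob, exact())
  expect_equal(sel$t, 0.625, tolerance = 1e-9)
  expect_setequal(sel$selected, c("u1", "u2"))

  expect_error(build_expand_multiobjective(toy$land, toy$m, 0.5, 0,
                                           normalizers = c(A = 16, B = 0)),
               "normalizer")
})

test_that("minimum-area slack is the shortfall fraction of the nominal area", {
  # a full 5000 km2 unit alone needs no slack
  land_full <- mk_land(5000)
  p_full <- build_expand_multiobjective(
    land_full, matrix(1, 1, 1, dimnames = list("u1", "A")), 1, 1,
    normalizers = c(A = 1))
  s_full <- brute_force_solve(p_full)
  expect_equal(unname(s_full$slack_by_unit["u1"]), 0)

  # partial 3000 km2 unit with an unselected neighbor holding 500 km2
  # protected: shortfall (5000 - 3500)/5000 = 0.3
  land <- mk_land(c(3000, 2000), prot = c(0, 500),
                  edges = data.frame(unit_a = "u1", unit_b = "u2"))
  m <- matrix(c(10, 0.001), 2, 1, dimnames = list(c("u1", "u2"), "A"))
  prob <- build_expand_multiobjective(land, m, 3000 / land$total_area, 0.01,
                                      normalizers = c(A = 10))
  sel <- brute_force_solve(prob)
  expect_identical(sel$selected, "u1")
  expect_equal(unname(sel$slack_by_unit["u1"]), 0.3)
  expect_equal(unname(solve_milp(prob, exact())$slack_by_unit["u1"]), 0.3)

  # a co-selected neighbor's unprotected area counts toward the threshold
  land2 <- mk_land(c(3000, 2500), edges = data.frame(unit_a = "u1", unit_b = "u2"))
  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("u1", "u2"), "A"))
  prob2 <- build_expand_multiobjective(land2, m2, 1, 10, normalizers = c(A = 20))
  sel2 <- brute_force_solve(prob2)
  expect_setequal(sel2$selected, c("u1", "u2"))
  expect_equal(unname(sel2$slack_by_unit), c(0, 0))
})

test_that("effective targets scale and cap at available habitat", {
  sp <- subpopulation("s1", 10000, 0.65,
                      c(u1 = 3000, u2 = 1500), protected_undisturbed = 500)
  t1 <- compute_effective_targets(list(sp), 1)
  expect_equal(t1$nominal, 6500)
  expect_equal(t1$available, 5000)
  expect_equal(t1$effective, 5000)
  expect_true(t1$capped)

  t25 <- compute_effective_targets(list(sp), 0.25)
  expect_equal(t25$effective, 1625)
  expect_false(t25$capped)

  sp0 <- subpopulation("s2", 1000, 0.65, c(u1 = 0), protected_undisturbed = 0)
  expect_equal(compute_effective_targets(list(sp0), 1)$effective, 0)
})

test_that("minimum-area problem matches enumeration and separates over disjoint ranges", {
  toy <- toy_minarea()
  prob <- build_minimum_area_problem(toy$land, toy$subpops, toy$targets)
  bf <- brute_force_solve(prob)
  expect_equal(bf$objective_value, 5)
  expect_setequal(bf$selected, c("u2", "u3"))
  expect_equal(solve_milp(prob, exact())$objective_value, 5)

  # zero target -> empty selection
  t0 <- toy$targets; t0$effective <- 0
  expect_length(brute_force_solve(
    build_minimum_area_problem(toy$land, toy$subpops, t0))$selected, 0)

  # disjoint sub-populations solve independently
  set.seed(44)
  land <- random_landscape(8, p_edge = 0)
  h1 <- setNames(land$units$undist_full_area[1:4] * 0.8,
                 land$units$unit_id[1:4])
  h2 <- setNames(land$units$undist_full_area[5:8] * 0.8,
                 land$units$unit_id[5:8])
  spA <- subpopulation("A", sum(h1) * 1.2, 0.65, h1)
  spB <- subpopulation("B", sum(h2) * 1.2, 0.65, h2)
  both <- compute_effective_targets(list(spA, spB), 0.75)
  joint <- brute_force_solve(build_minimum_area_problem(land, list(spA, spB), both))
  solo_a <- brute_force_solve(build_minimum_area_problem(
    land, list(spA), compute_effective_targets(list(spA), 0.75)))
  solo_b <- brute_force_solve(build_minimum_area_problem(
    land, list(spB), compute_effective_targets(list(spB), 0.75)))
  expect_equal(joint$objective_value,
               solo_a$objective_value + solo_b$objective_value)
  expect_setequal(joint$selected, c(solo_a$selected, solo_b$selected))
})

test_that("habitat-target maximin behaves at the penalty extremes", {
  toy <- toy_minarea()
  m <- matrix(c(1, 5, 3), 3, 1, dimnames = list(toy$land$units$unit_id, "A"))

  # enormous area penalty: cost approaches the minimum-area optimum
  prob_hi <- build_protect_habitat(toy$land, m, toy$subpops, toy$targets,
                                   area_penalty = 1e4, minarea_penalty = 0,
                                   normalizers = c(A = 9))
  sel_hi <- brute_force_solve(prob_hi)
  expect_setequal(sel_hi$selected, c("u2", "u3"))
  expect_equal(sel_hi$cost, 5)

  # no penalties, no targets: more value never hurts, everything selected
  t0 <- toy$targets; t0$effective <- 0
  prob_free <- build_protect_habitat(toy$land, m, toy$subpops, t0,
                                     area_penalty = 0, minarea_penalty = 0,
                                     normalizers = c(A = 9))
  expect_length(brute_force_solve(prob_free)$selected, 3)
})

test_that("solver reports infeasibility when targets exceed available habitat", {
  toy <- toy_minarea()
  t_bad <- toy$targets
  t_bad$effective <- 100  # more than sum(h) = 9
  prob <- build_minimum_area_problem(toy$land, toy$subpops, t_bad)
  expect_equal(brute_force_solve(prob)$status, "infeasible")
  expect_equal(solve_milp(prob, exact())$status, "infeasible")
})

test_that("evaluate_selection sums the selected rows per objective", {
  m <- matrix(1:15, 5, 3, dimnames = list(paste0("u", 1:5), c("a", "b", "c")))
  expect_equal(unname(evaluate_selection(character(0), m)), c(0, 0, 0))
  expect_equal(unname(evaluate_selection(paste0("u", 1:5), m)),
               unname(colSums(m)))
  expect_equal(unname(evaluate_selection(c("u2", "u4"), m)),
               unname(m["u2", ] + m["u4", ]))
  expect_error(evaluate_selection("zz", m), "zz")
})

test_that("gapped solves stay within the advertised bound of the optimum", {
  set.seed(77)
  for (rep in 1:10) {
    prob <- random_problem("single", n = 12)
    opt <- brute_force_solve(prob)$objective_value
    sel <- solve_milp(prob, solver_settings(relative_gap = 0.005))
    expect_gte(sel$objective_value, 0.995 * opt - 1e-9)
    expect_lte(sel$objective_value, opt + 1e-6 * (1 + abs(opt)))
    expect_gte(sel$best_bound, sel$objective_value - 1e-9)
  }
})

test_that("LP export contains the tagged constraint sections", {
  toy <- toy_maximin()
  prob <- build_expand_multiobjective(toy$land, toy$m, 0.5, 0.1,
                                      normalizers = c(A = 16, B = 16))
  f <- tempfile(fileext = ".lp")
  write_lp(prob, f)
  txt <- readLines(f)
  expect_true(any(grepl("^Maximize", txt)))
  expect_true(any(grepl("budget", txt)))
  expect_true(any(grepl("maximin_A", txt)))
  expect_true(any(grepl("minarea_u1", txt)))
  expect_true(any(grepl("^Binaries", txt)))
})
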