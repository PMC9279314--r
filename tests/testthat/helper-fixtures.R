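# fixtures are built in code; no data files

exact <- function() solver_settings(relative_gap = 0, time_limit = 120)

# minimal landscape: unprotected == total - prot, fully undisturbed
mk_land <- function(total, prot = rep(0, length(total)), edges = NULL,
                    undist_human = NULL, undist_full = NULL, nominal = 5000) {
  undist_human <- undist_human %||% (total - prot)
  undist_full <- undist_full %||% undist_human
  u <- data.frame(unit_id = paste0("u", seq_along(total)), total_area = total,
                  protected_area = prot, undist_human_area = undist_human,
                  undist_full_area = undist_full, stringsAsFactors = FALSE)
  landscape(u, edges, unit_area_nominal = nominal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the two-objective maximin toy: 4 units of area 1, budget 2 units,
# objective A = (10,0,6,0), B = (0,10,6,0); V* = (16,16), optimum {u1,u2}
toy_maximin <- function() {
  land <- mk_land(c(1, 1, 1, 1))
  m <- cbind(A = c(10, 0, 6, 0), B = c(0, 10, 6, 0))
  rownames(m) <- land$units$unit_id
  list(land = land, m = m, budget_fraction = 0.5)
}

# the minimum-area toy: h = (4,3,2), costs (5,3,2), target 5 -> {u2,u3}
toy_minarea <- function() {
  land <- mk_land(c(5, 3, 2))
  sp <- subpopulation("s1", 100, 0.65,
                      c(u1 = 4, u2 = 3, u3 = 2), protected_undisturbed = 0)
  targets <- compute_effective_targets(list(sp), 1)
  targets$effective <- 5
  list(land = land, subpops = list(sp), targets = targets)
}

random_landscape <- function(n, p_edge = 0.3, nominal = 5000) {
  total <- stats::runif(n, 500, nominal)
  prot <- total * stats::runif(n, 0, 0.3)
  unprot <- total - prot
  uh <- unprot * stats::runif(n, 0.4, 1)
  uf <- uh * stats::runif(n, 0.4, 1)
  ids <- sprintf("u%02d", seq_len(n))
  edges <- NULL
  if (n > 1) {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p_edge
    edges <- data.frame(unit_a = ids[pairs[keep, 1]],
                        unit_b = ids[pairs[keep, 2]],
                        stringsAsFactors = FALSE)
  }
  u <- data.frame(unit_id = ids, total_area = total, protected_area = prot,
                  undist_human_area = uh, undist_full_area = uf,
                  stringsAsFactors = FALSE)
  landscape(u, edges, unit_area_nominal = nominal)
}

random_subpops <- function(land, n_sub) {
  n <- nrow(land$units)
  lapply(seq_len(n_sub), function(s) {
    members <- sort(sample.int(n, sample(2:max(2, n - 1), 1)))
    h <- land$units$undist_full_area[members] *
      stats::runif(length(members), 0.2, 1)
    names(h) <- land$units$unit_id[members]
    P <- stats::runif(1, 0, 0.3 * sum(h))
    subpopulation(paste0("s", s), (sum(h) + P) * stats::runif(1, 1.05, 1.5),
                  sample(c(0.4, 0.65), 1), h, P)
  })
}

# single-objective companion problem at the same landscape and budget,
# for dominance comparisons against a maximin problem
build_single_objective_from <- function(prob, k) {
  p <- prob
  p$type <- "single"
  p$sense <- "max"
  p$v <- prob$v[, k, drop = FALSE]
  p$minarea <- NULL
  p$normalizers <- NULL
  p
}

# draws one random structured problem; relies on the caller's RNG state
random_problem <- function(type, n = sample(4:12, 1), minarea_penalty = NULL) {
  land <- random_landscape(n)
  if (type == "single") {
    return(build_single_objective(land, stats::runif(n, 0.1, 10),
                                  stats::runif(1, 0.15, 0.6)))
  }
  if (type == "expand") {
    repeat {
      m <- matrix(stats::runif(n * 3, 0.1, 10), n, 3,
                  dimnames = list(land$units$unit_id, c("A", "B", "C")))
      bf <- stats::runif(1, 0.25, 0.6)
      vstar <- vapply(colnames(m), function(k)
        brute_force_solve(build_single_objective(land, m[, k], bf))$objective_value,
        numeric(1))
      if (all(vstar > 0)) {
        p <- minarea_penalty %||% sample(c(0, 0.01, 1), 1)
        return(build_expand_multiobjective(land, m, bf, p,
                                           normalizers = vstar))
      }
    }
  }
  subpops <- random_subpops(land, sample(1:3, 1))
  targets <- compute_effective_targets(subpops, sample(c(0.25, 0.5, 0.75, 1), 1))
  if (type == "minarea") {
    return(build_minimum_area_problem(land, subpops, targets))
  }
  m <- matrix(stats::runif(n * 3, 0.1, 10), n, 3,
              dimnames = list(land$units$unit_id, c("A", "B", "C")))
  build_protect_habitat(land, m, subpops, targets,
                        area_penalty = sample(c(0, 0.01, 1, 100), 1),
                        minarea_penalty = sample(c(0, 0.01, 1), 1),
                        normalizers = colSums(m) * stats::runif(3, 0.3, 0.8))
}

# shared small synthetic dataset, generated once per test run
test_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_config(
        n_rows = 6, n_cols = 7, n_subpops = 4, n_species = 40, seed = 7))
    }
    cache
  }
})

expect_same_value <- function(a, b, tol = 1e-6) {
  expect_lt(abs(a - b), tol * (1 + abs(b)))
}
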