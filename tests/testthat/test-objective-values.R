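toy_meta <- function() {
  data.frame(species_id = c("bird1", "bird2", "fish1"),
             taxon_group = c("bird", "bird", "fish"),
             frac_distribution = c(0.5, 0.5, 0.1),
             frac_canadian_inside = c(0.2, 0.2, 0.6),
             stringsAsFactors = FALSE)
}

test_that("caribou habitat value picks the scenario's undisturbed field", {
  unit <- list(undist_human_area = 50, undist_full_area = 30)
  expect_equal(caribou_habitat_value(unit, "expand"), 50)
  expect_equal(caribou_habitat_value(unit, "protect"), 30)
  zero <- list(undist_human_area = 0, undist_full_area = 0)
  expect_equal(caribou_habitat_value(zero, "expand"), 0)
  expect_equal(caribou_habitat_value(zero, "protect"), 0)
  expect_error(caribou_habitat_value(unit, "bogus"))
})

test_that("richness counts overlapping species, matching a brute recount", {
  p <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), nrow = 2,
              dimnames = list(c("u1", "u2"), c("s1", "s2", "s3")))
  p["u1", ] <- c(TRUE, TRUE, FALSE)
  p["u2", ] <- FALSE
  expect_equal(richness_value(p, "u1"), 2)
  expect_equal(richness_value(p, "u2"), 0)
  expect_error(richness_value(p, "u9"), "u9")

  set.seed(5)
  big <- matrix(runif(20 * 15) < 0.4, 20, 15,
                dimnames = list(sprintf("u%02d", 1:20), sprintf("s%02d", 1:15)))
  for (i in rownames(big)) {
    recount <- sum(vapply(colnames(big), function(s) big[i, s], logical(1)))
    expect_equal(richness_value(big, i), recount)
  }
})

test_that("taxonomic index is species count over dominant-group count", {
  meta <- toy_meta()
  p <- matrix(TRUE, 1, 3, dimnames = list("u1", meta$species_id))
  expect_equal(taxonomic_representation_value(p, meta, "u1"), 1.5)
  p2 <- matrix(c(TRUE, TRUE, FALSE), 1, 3,
               dimnames = list("u1", meta$species_id))
  expect_equal(taxonomic_representation_value(p2, meta, "u1"), 1.0)
  p3 <- matrix(FALSE, 1, 3, dimnames = list("u1", meta$species_id))
  expect_equal(taxonomic_representation_value(p3, meta, "u1"), 0)

  bad_meta <- meta[1:2, ]
  expect_error(taxonomic_representation_value(p, bad_meta, "u1"), "fish1")
})

test_that("taxonomic index stays in {0} U [1, n_groups] over all patterns", {
  # exhaustive: 3 species in 2 groups, all 2^3 presence patterns
  meta <- data.frame(species_id = c("a", "b", "c"),
                     taxon_group = c("g1", "g1", "g2"),
                     frac_distribution = 0.1, frac_canadian_inside = 0.1)
  for (mask in 0:7) {
    row <- as.logical(bitwAnd(bitwShiftL(1L, 0:2), mask))
    p <- matrix(row, 1, 3, dimnames = list("u1", meta$species_id))
    v <- taxonomic_representation_value(p, meta, "u1")
    n <- sum(row)
    nmax <- if (n == 0) NA else max(table(meta$taxon_group[row]))
    expect_equal(v, if (n == 0) 0 else n / nmax)
    expect_true(v == 0 || (v >= 1 && v <= 2))
  }
})

test_that("richness and taxonomic index ignore species column order", {
  set.seed(21)
  meta <- data.frame(species_id = sprintf("s%02d", 1:12),
                     taxon_group = sample(c("bird", "fish", "moss"), 12, TRUE),
                     frac_distribution = runif(12), frac_canadian_inside = runif(12))
  p <- matrix(runif(5 * 12) < 0.5, 5, 12,
              dimnames = list(sprintf("u%d", 1:5), meta$species_id))
  base_r <- vapply(rownames(p), function(i) richness_value(p, i), numeric(1))
  base_t <- vapply(rownames(p), function(i)
    taxonomic_representation_value(p, meta, i), numeric(1))
  for (rep in 1:50) {
    perm <- sample(ncol(p))
    ps <- p[, perm]
    expect_equal(vapply(rownames(ps), function(i) richness_value(ps, i),
                        numeric(1)), base_r)
    expect_equal(vapply(rownames(ps), function(i)
      taxonomic_representation_value(ps, meta, i), numeric(1)), base_t)
  }
})

test_that("uniqueness filter applies the printed boundaries", {
  meta <- data.frame(species_id = c("in", "wide", "edge"),
                     taxon_group = "bird",
                     frac_distribution = c(0.10, 0.25, 0.10),
                     frac_canadian_inside = c(0.60, 0.60, 0.50))
  expect_identical(unique_species_set(meta), "in")
  # boundary inclusivity: exactly 0.20 coverage passes, exactly 0.50 inside fails
  meta$frac_distribution[3] <- 0.20
  expect_identical(unique_species_set(meta), "in")
  meta$frac_canadian_inside[3] <- 0.500001
  expect_setequal(unique_species_set(meta), c("in", "edge"))
})

test_that("uniqueness filter is monotone in the metadata fractions", {
  set.seed(31)
  meta <- data.frame(species_id = sprintf("s%02d", 1:30),
                     taxon_group = "bird",
                     frac_distribution = runif(30),
                     frac_canadian_inside = runif(30))
  base <- unique_species_set(meta)
  for (rep in 1:20) {
    relaxed <- meta
    k <- sample(30, 5)
    relaxed$frac_distribution[k] <- relaxed$frac_distribution[k] * runif(5)
    relaxed$frac_canadian_inside[k] <-
      1 - (1 - relaxed$frac_canadian_inside[k]) * runif(5)
    expect_true(all(base %in% unique_species_set(relaxed)))
  }
})

test_that("objective matrix assembly composes the per-unit formulas", {
  land <- mk_land(100, undist_human = 40, undist_full = 25)
  meta <- toy_meta()
  p <- matrix(c(TRUE, FALSE, TRUE), 1, 3,
              dimnames = list("u1", meta$species_id))
  # per-unit dominance: {bird1, fish1} -> 2 species / largest present group 1
  m <- assemble_objective_matrix(land, p, meta, c(u1 = 2.5), c(u1 = 100),
                                 scenario = "expand")
  expect_equal(unname(m["u1", ]), c(40, 2, 2.0, 1, 2.5, 100))
  expect_equal(colnames(m), c("caribou_habitat", "richness", "taxonomic",
                              "unique_species", "refugia", "carbon"))
  # distribution-wide denominator: the pool's largest group (2 birds) -> 1.0
  mg <- assemble_objective_matrix(land, p, meta, c(u1 = 2.5), c(u1 = 100),
                                  scenario = "expand",
                                  taxonomic_denominator = "global")
  expect_equal(unname(mg["u1", ]), c(40, 2, 1.0, 1, 2.5, 100))

  m5 <- assemble_objective_matrix(land, p, meta, c(u1 = 2.5), c(u1 = 100),
                                  scenario = "protect")
  expect_equal(unname(m5["u1", ]), c(2, 2.0, 1, 2.5, 100))
  expect_false("caribou_habitat" %in% colnames(m5))

  p0 <- matrix(FALSE, 1, 3, dimnames = list("u1", meta$species_id))
  land0 <- mk_land(100, undist_human = 0, undist_full = 0)
  m0 <- assemble_objective_matrix(land0, p0, meta, c(u1 = 0), c(u1 = 0),
                                  scenario = "expand")
  expect_equal(unname(m0["u1", ]), rep(0, 6))

  expect_error(assemble_objective_matrix(land, p, meta, c(u9 = 1), c(u1 = 1)),
               "refugia")
})
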