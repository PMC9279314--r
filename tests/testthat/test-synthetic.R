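test_that("hex grid has lattice structure and is deterministic", {
  cfg <- generator_config(n_rows = 3, n_cols = 3, clip_fraction = 0, seed = 2)
  g <- generate_hex_grid(cfg)
  expect_equal(nrow(g$units), 9)
  expect_true(all(g$units$total_area == cfg$unit_area_nominal))
  deg <- lengths(neighbor_index(g))
  expect_lte(max(deg), 6)
  expect_gte(min(deg), 2)
  # hex lattice: 3x3 odd-r offset grid has 16 edges
  expect_equal(nrow(g$adjacency), 16)

  g1 <- generate_hex_grid(generator_config(n_rows = 1, n_cols = 1, seed = 2))
  expect_equal(nrow(g1$units), 1)
  expect_equal(nrow(g1$adjacency), 0)

  cfg2 <- generator_config(n_rows = 5, n_cols = 4, clip_fraction = 0.7, seed = 9)
  a <- generate_hex_grid(cfg2)
  b <- generate_hex_grid(cfg2)
  expect_identical(a$units, b$units)
  expect_identical(a$adjacency, b$adjacency)
  expect_gt(sum(a$units$is_partial), 0)
})

test_that("value layers are nonnegative, deterministic, and carry the target correlations", {
  cfg <- generator_config(n_rows = 8, n_cols = 8, clip_fraction = 0, seed = 4)
  sk <- generate_hex_grid(cfg)
  v <- generate_value_layers(sk, cfg)
  expect_true(all(is.finite(v)) && all(v >= 0))
  expect_identical(v, generate_value_layers(sk, cfg))
  # latent-scale correlations are induced exactly
  expect_equal(cor(log(v)), cfg$objective_correlation, tolerance = 1e-8,
               ignore_attr = TRUE)

  strong <- diag(3)
  strong[1, 2] <- strong[2, 1] <- 0.9
  cfg_s <- generator_config(n_rows = 8, n_cols = 8, clip_fraction = 0, seed = 4,
                            objective_correlation = strong,
                            layer_scales = rep(1, 3))
  vs <- generate_value_layers(sk, cfg_s)
  expect_gte(cor(vs[, 1], vs[, 2]), 0.6)

  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(generator_config(objective_correlation = bad),
               "positive semi-definite")
})

test_that("protection and disturbance hit their targets and keep invariants", {
  cfg <- generator_config(n_rows = 6, n_cols = 6, seed = 5)
  land <- generate_protection_and_disturbance(generate_hex_grid(cfg), cfg)
  expect_length(validate_landscape(land), 0)
  expect_lt(abs(land$protected_fraction - 0.105), 0.02)

  cfg0 <- generator_config(n_rows = 6, n_cols = 6, seed = 5,
                           disturbance_fraction_target = 0)
  land0 <- generate_protection_and_disturbance(generate_hex_grid(cfg0), cfg0)
  expect_equal(land0$units$undist_human_area, land0$units$unprotected_area)
})

test_that("sub-population ranges cover the landscape with valid habitat shares", {
  cfg <- generator_config(n_rows = 6, n_cols = 6, n_subpops = 5, seed = 6)
  land <- generate_protection_and_disturbance(generate_hex_grid(cfg), cfg)
  sps <- generate_subpopulations(land, cfg)
  expect_length(sps, 5)
  expect_equal(sum(vapply(sps, `[[`, 0, "nominal_target_pct") == 0.40), 1)
  for (sp in sps) {
    expect_lte(sum(sp$habitat_by_unit) + sp$protected_undisturbed,
               sp$range_area + 1e-6)
    full <- land$units$undist_full_area[match(names(sp$habitat_by_unit),
                                              land$units$unit_id)]
    expect_true(all(sp$habitat_by_unit <= full + 1e-9))
  }
  # determinism and n_subpops = 1 coverage
  sps2 <- generate_subpopulations(land, cfg)
  expect_identical(lapply(sps, `[[`, "habitat_by_unit"),
                   lapply(sps2, `[[`, "habitat_by_unit"))
  cfg1 <- generator_config(n_rows = 4, n_cols = 4, n_subpops = 1, seed = 6)
  land1 <- generate_protection_and_disturbance(generate_hex_grid(cfg1), cfg1)
  sp1 <- generate_subpopulations(land1, cfg1)[[1]]
  expect_setequal(names(sp1$habitat_by_unit), land1$units$unit_id)

  expect_error(generate_subpopulations(
    land1, generator_config(n_rows = 4, n_cols = 4, n_subpops = 99, seed = 1)),
    "n_subpops")
})

test_that("species metadata is recomputed from the generated ranges", {
  cfg <- generator_config(n_rows = 6, n_cols = 8, n_species = 30, seed = 8)
  land <- generate_protection_and_disturbance(generate_hex_grid(cfg), cfg)
  sp <- generate_species(land, cfg)
  expect_equal(dim(sp$presence), c(nrow(land$units), 30))
  for (k in seq_len(30)) {
    ratio <- sum(land$units$total_area[sp$presence[, k]]) / land$total_area
    expect_equal(sp$meta$frac_distribution[k], ratio)
  }
  expect_true(all(sp$meta$taxon_group %in%
                    c("amphibian", "arthropod", "bird", "lichen", "mollusc",
                      "mammal", "reptile", "vascular plant", "fish")))
  expect_identical(sp$presence, generate_species(land, cfg)$presence)
})

test_that("the default species mixture yields a plausible unique-species count", {
  counts <- vapply(1:20, function(s) {
    cfg <- generator_config(n_rows = 6, n_cols = 10, seed = s)
    land <- generate_protection_and_disturbance(generate_hex_grid(cfg), cfg)
    sp <- generate_species(land, cfg)
    length(unique_species_set(sp$meta))
  }, numeric(1))
  expect_true(all(counts >= 1 & counts <= 15))
})

test_that("a generated dataset is internally consistent and serializable", {
  d <- test_dataset()
  expect_length(validate_landscape(d$landscape), 0)
  expect_equal(colnames(d$objective_protect),
               setdiff(colnames(d$objective_expand), "caribou_habitat"))
  expect_equal(d$objective_expand[, "caribou_habitat"],
               setNames(d$landscape$units$undist_human_area,
                        d$landscape$units$unit_id))
  dir <- tempfile()
  write_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "units.csv", "adjacency.csv", "species_presence.csv", "species_meta.csv",
    "subpopulations.csv", "subpop_habitat.csv", "value_layers.csv",
    "provenance.json")))))
  back <- read_landscape(file.path(dir, "units.csv"),
                         file.path(dir, "adjacency.csv"))
  expect_equal(back$units$total_area, d$landscape$units$total_area,
               tolerance = 1e-9)
})
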