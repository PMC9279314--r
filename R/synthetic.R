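#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the statistical structure of the boreal caribou
#' study system at desk scale: a clipped hexagonal grid of planning units of
#' at most 5000 km² (a mix of full interior units and partial boundary
#' units), roughly 10.5% of the area already protected in spatially
#' clustered blocks, a spatially clustered human-disturbance footprint with
#' additional fire-only disturbance, spatially autocorrelated and weakly
#' cross-correlated conservation-value layers with localized hotspots,
#' overlapping sub-population ranges, and heavy-tailed species ranges. The
#' default profile (14 x 15 = 210 units, 12 sub-populations, 80 species) is
#' a scaled-down stand-in for the 665-unit / 51-sub-population / 80-species
#' study system.
#'
#' @param n_rows,n_cols hex-grid dimensions.
#' @param unit_area_nominal nominal unit area (km²).
#' @param clip_fraction fraction of boundary units given a reduced
#'   ("clipped") area.
#' @param protected_fraction_target target landscape protected fraction
#'   (study system: 0.105).
#' @param disturbance_fraction_target target fraction of unprotected area
#'   within 500 m of human disturbance.
#' @param fire_fraction_target additional fire-only disturbed fraction
#'   (creates the gap between the two undisturbed-area definitions).
#' @param n_species,n_taxa species pool size and number of taxonomic groups
#'   (study system: 80 species in 9 groups).
#' @param n_subpops number of sub-population ranges (study system: 51;
#'   desk-scale default 12).
#' @param subpop_overlap_prob probability a range absorbs an adjacent
#'   foreign unit, creating range overlap.
#' @param objective_correlation symmetric positive-semidefinite matrix of
#'   target cross-layer correlations for the latent value fields; the
#'   default uses weak correlations with one strong pair
#'   (richness-taxonomic).
#' @param layer_scales named positive vector of per-layer magnitudes.
#' @param layer_sigma lognormal shape of the value layers (hotspot
#'   intensity).
#' @param smoothing_passes rounds of neighbor-averaging applied to latent
#'   fields (spatial autocorrelation).
#' @param unique_species_prob probability a species draws a high
#'   "fraction of Canadian extent inside the distribution", calibrated so a
#'   handful of the 80 species pass the uniqueness filter.
#' @param seed integer root seed; every generator stage derives its own
#'   substream from it, so outputs are pure functions of (config, seed) and
#'   adding a stage never perturbs earlier ones.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_rows = 10, n_cols = 20,
                             unit_area_nominal = 5000,
                             clip_fraction = 0.8,
                             protected_fraction_target = 0.105,
                             disturbance_fraction_target = 0.35,
                             fire_fraction_target = 0.15,
                             n_species = 80, n_taxa = 9,
                             n_subpops = 10,
                             subpop_overlap_prob = 0.3,
                             objective_correlation = default_objective_correlation(),
                             layer_scales = default_layer_scales(),
                             layer_sigma = 0.75,
                             smoothing_passes = 2,
                             unique_species_prob = 0.09,
                             seed = 1L) {
  cfg <- list(n_rows = n_rows, n_cols = n_cols,
              unit_area_nominal = unit_area_nominal,
              clip_fraction = clip_fraction,
              protected_fraction_target = protected_fraction_target,
              disturbance_fraction_target = disturbance_fraction_target,
              fire_fraction_target = fire_fraction_target,
              n_species = n_species, n_taxa = n_taxa,
              n_subpops = n_subpops,
              subpop_overlap_prob = subpop_overlap_prob,
              objective_correlation = objective_correlation,
              layer_scales = layer_scales,
              layer_sigma = layer_sigma,
              smoothing_passes = smoothing_passes,
              unique_species_prob = unique_species_prob,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

default_objective_correlation <- function() {
  nm <- c("caribou_habitat", "richness", "taxonomic", "unique_species",
          "refugia", "carbon")
  R <- diag(6)
  dimnames(R) <- list(nm, nm)
  R["richness", "taxonomic"] <- R["taxonomic", "richness"] <- 0.8
  R["richness", "unique_species"] <- R["unique_species", "richness"] <- 0.2
  R["caribou_habitat", "refugia"] <- R["refugia", "caribou_habitat"] <- 0.15
  R["refugia", "carbon"] <- R["carbon", "refugia"] <- -0.1
  R
}

default_layer_scales <- function() {
  # order-of-magnitude stand-ins: km2 of habitat, species counts, index,
  # refugia sum, tonnes of soil carbon
  c(caribou_habitat = 2000, richness = 10, taxonomic = 1.5,
    unique_species = 1, refugia = 1000, carbon = 5e8)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_rows >= 1, cfg$n_cols >= 1, cfg$unit_area_nominal > 0,
            cfg$smoothing_passes >= 0, cfg$n_species >= 1, cfg$n_taxa >= 1,
            cfg$n_subpops >= 1)
  for (f in c("clip_fraction", "protected_fraction_target",
              "disturbance_fraction_target", "fire_fraction_target")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]", call. = FALSE)
  }
  R <- cfg$objective_correlation
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8)) {
    stop("objective_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-9) {
    stop("objective_correlation is not positive semi-definite", call. = FALSE)
  }
  invisible(cfg)
}

# deterministic per-stage substreams of the root seed
stage_seed <- function(seed, stage) {
  offset <- match(stage, c("grid", "layers", "protection", "disturbance",
                           "subpops", "species"))
  set.seed((abs(as.integer(seed)) %% 1000000L) * 1009L + offset * 101L)
}

#' Generate a hexagonal-grid landscape skeleton
#'
#' Lays out `n_rows x n_cols` planning units on an odd-row offset hex
#' lattice with 6-neighbor adjacency (interior degree 6) and clips a seeded
#' subset of boundary units to a uniformly drawn partial area, emulating a
#' grid intersected with a species distribution. The skeleton is pristine:
#' no protection, no disturbance.
#'
#' @param config a [generator_config()].
#' @return a `landscape` with extra columns `row`, `col`.
#' @export
generate_hex_grid <- function(config) {
  stage_seed(config$seed, "grid")
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  width <- max(3, nchar(as.character(n)))
  idx <- seq_len(n) - 1L
  row <- idx %/% nc + 1L
  col <- idx %% nc + 1L
  ids <- sprintf(paste0("u%0", width, "d"), seq_len(n))

  # odd-r offset hex neighbors
  off_even <- cbind(c(-1, -1, 0, 0, 1, 1), c(-1, 0, -1, 1, -1, 0))
  off_odd  <- cbind(c(-1, -1, 0, 0, 1, 1), c(0, 1, -1, 1, 0, 1))
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n)) {
    off <- if (row[i] %% 2 == 0) off_even else off_odd
    rr <- row[i] + off[, 1]; cc <- col[i] + off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    j <- (rr[ok] - 1L) * nc + cc[ok]
    keep <- j > i
    if (any(keep)) { ea <- c(ea, rep(ids[i], sum(keep))); eb <- c(eb, ids[j[keep]]) }
  }

  boundary <- row == 1 | row == nr | col == 1 | col == nc
  total <- rep(config$unit_area_nominal, n)
  n_clip <- round(config$clip_fraction * sum(boundary))
  if (n_clip > 0) {
    clip_idx <- sample(which(boundary), n_clip)
    total[clip_idx] <- stats::runif(n_clip, 0.001, 0.999) * config$unit_area_nominal
  }
  units <- data.frame(unit_id = ids, total_area = total, protected_area = 0,
                      undist_human_area = total, undist_full_area = total,
                      row = row, col = col, stringsAsFactors = FALSE)
  landscape(units, data.frame(unit_a = ea, unit_b = eb),
            unit_area_nominal = config$unit_area_nominal)
}

# one smoothed, restandardized standard-normal latent field per column
latent_fields <- function(n, k, nb, smoothing_passes) {
  Z <- matrix(stats::rnorm(n * k), n, k)
  for (p in seq_len(smoothing_passes)) {
    Znew <- Z
    for (i in seq_len(n)) {
      j <- nb[[i]]
      if (length(j)) Znew[i, ] <- (Z[i, ] + colSums(Z[j, , drop = FALSE])) /
          (1 + length(j))
    }
    Z <- Znew
  }
  scale(Z)
}

#' Generate cross-correlated per-unit conservation-value layers
#'
#' Draws one spatially autocorrelated standard-normal latent field per
#' layer (neighbor-averaged `smoothing_passes` times, then restandardized),
#' whitens the fields against their empirical cross-correlation, mixes them
#' by the symmetric square root of `objective_correlation` — so the latent
#' fields carry the configured correlations exactly in-sample, independent
#' of the autocorrelation-reduced effective sample size — and maps to
#' nonnegative values with localized hotspots by exponentiation:
#' `value = scale * exp(sigma * field)`. Exponentiation attenuates
#' value-scale Pearson correlations slightly (about 0.05 at the default
#' `layer_sigma` of 0.75).
#'
#' @param skeleton a `landscape`.
#' @param config a [generator_config()].
#' @return unit x layer numeric matrix (row names = unit ids).
#' @export
generate_value_layers <- function(skeleton, config) {
  validate_generator_config(config)
  stage_seed(config$seed, "layers")
  R <- config$objective_correlation
  k <- ncol(R)
  nb <- neighbor_index(skeleton)
  n <- nrow(skeleton$units)
  if (n <= k) stop("need more units than value layers", call. = FALSE)
  Z <- latent_fields(n, k, nb, config$smoothing_passes)
  Z <- scale(Z %*% solve(chol(stats::cov(Z))))  # exact identity sample cor
  ev <- eigen(R, symmetric = TRUE)
  U <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  mixed <- Z %*% U
  layer_names <- colnames(R) %||% sprintf("layer%02d", seq_len(k))
  scales <- config$layer_scales
  if (!is.null(names(scales))) scales <- scales[layer_names]
  if (length(scales) != k) scales <- rep(1, k)
  scales[is.na(scales)] <- 1
  vals <- sweep(exp(config$layer_sigma * mixed), 2, scales, `*`)
  dimnames(vals) <- list(skeleton$units$unit_id, layer_names)
  vals
}

#' Add protected areas and a disturbance footprint to a skeleton
#'
#' Protection grows as seeded clustered blocks (breadth-first expansion
#' from a few random seed units, with the final unit protected only
#' partially) until the landscape protected fraction equals the target.
#' Human disturbance and fire-only disturbance are assigned per unit from
#' two independent smoothed lognormal fields scaled to their respective
#' aggregate targets; they reduce `undist_human_area` and
#' `undist_full_area` so the unit ordering invariant holds by construction.
#' The per-unit disturbed fractions are kept as extra columns
#' `human_dist_frac` and `fire_frac`.
#'
#' @param skeleton a `landscape` from [generate_hex_grid()].
#' @param config a [generator_config()].
#' @return a completed `landscape` (passes [validate_landscape()]).
#' @export
generate_protection_and_disturbance <- function(skeleton, config) {
  validate_generator_config(config)
  u <- skeleton$units
  n <- nrow(u)
  nb <- neighbor_index(skeleton)

  stage_seed(config$seed, "protection")
  target <- config$protected_fraction_target * sum(u$total_area)
  prot <- numeric(n)
  if (target > 0) {
    n_seeds <- max(1L, round(n / 60))
    frontier <- sample.int(n, n_seeds)
    visited <- rep(FALSE, n)
    acc <- 0
    while (acc < target && length(frontier) > 0) {
      i <- frontier[[1]]
      frontier <- frontier[-1]
      if (visited[i]) next
      visited[i] <- TRUE
      add <- min(u$total_area[i], target - acc)
      prot[i] <- add
      acc <- acc + add
      nxt <- nb[[i]][!visited[nb[[i]]]]
      frontier <- c(frontier, sample(nxt))
      if (length(frontier) == 0 && acc < target) {
        frontier <- sample(which(!visited), 1)
      }
    }
  }
  u$protected_area <- prot
  u$unprotected_area <- u$total_area - prot

  stage_seed(config$seed, "disturbance")
  scaled_field <- function(target_frac) {
    if (target_frac == 0) return(numeric(n))
    f <- as.numeric(latent_fields(n, 1, nb, config$smoothing_passes))
    w <- exp(0.75 * f)
    wm <- stats::weighted.mean(w, u$unprotected_area)
    pmin(0.98, target_frac * w / wm)
  }
  d <- scaled_field(config$disturbance_fraction_target)
  fr <- scaled_field(config$fire_fraction_target)
  u$human_dist_frac <- d
  u$fire_frac <- fr
  u$undist_human_area <- u$unprotected_area * (1 - d)
  u$undist_full_area <- u$undist_human_area * (1 - fr)
  landscape(u, skeleton$adjacency,
            unit_area_nominal = skeleton$unit_area_nominal)
}

# multi-source randomized BFS region growing; returns list of unit-index sets
grow_regions <- function(n, nb, n_regions) {
  seeds <- sample.int(n, n_regions)
  owner <- rep(NA_integer_, n)
  owner[seeds] <- seq_len(n_regions)
  frontier <- lapply(seeds, function(s) sample(nb[[s]]))
  repeat {
    assigned_any <- FALSE
    for (r in sample.int(n_regions)) {
      f <- frontier[[r]]
      f <- f[is.na(owner[f])]
      if (length(f) == 0) { frontier[[r]] <- integer(0); next }
      i <- f[[1]]
      owner[i] <- r
      frontier[[r]] <- c(f[-1], sample(nb[[i]]))
      assigned_any <- TRUE
    }
    if (all(!is.na(owner))) break
    if (!assigned_any) {
      # disconnected leftovers: attach each to a random region
      left <- which(is.na(owner))
      owner[left] <- sample.int(n_regions, length(left), replace = TRUE)
      break
    }
  }
  split(seq_len(n), owner)
}

#' Generate overlapping sub-population ranges
#'
#' Grows `n_subpops` contiguous ranges by seeded multi-source region
#' growing over the hex adjacency, then lets each range absorb adjacent
#' foreign units with probability `subpop_overlap_prob` so ranges overlap
#' at their edges. Each unit's unprotected undisturbed habitat
#' (`undist_full_area`) and protected undisturbed habitat are apportioned
#' equally among the ranges covering it, so the sub-population invariants
#' hold by construction. The first sub-population receives the 0.40
#' critical-habitat target (the Boreal Shield setting); all others 0.65.
#'
#' @param landscape a completed `landscape` (with `human_dist_frac` and
#'   `fire_frac` columns; absent columns are treated as zero disturbance).
#' @param config a [generator_config()].
#' @return list of `subpopulation` objects.
#' @export
generate_subpopulations <- function(landscape, config) {
  n <- nrow(landscape$units)
  if (config$n_subpops > n) {
    stop("n_subpops exceeds the number of units", call. = FALSE)
  }
  stage_seed(config$seed, "subpops")
  nb <- neighbor_index(landscape)
  regions <- grow_regions(n, nb, config$n_subpops)
  # overlap: absorb adjacent foreign units with configured probability
  regions <- lapply(regions, function(members) {
    adj <- setdiff(unique(unlist(nb[members])), members)
    extra <- adj[stats::runif(length(adj)) < config$subpop_overlap_prob]
    sort(c(members, extra))
  })
  u <- landscape$units
  d <- u$human_dist_frac %||% rep(0, n)
  fr <- u$fire_frac %||% rep(0, n)
  prot_undist <- u$protected_area * (1 - d) * (1 - fr)
  n_cov <- tabulate(unlist(regions), nbins = n)
  width <- max(2, nchar(as.character(config$n_subpops)))
  lapply(seq_along(regions), function(s) {
    members <- regions[[s]]
    share <- 1 / n_cov[members]
    subpopulation(
      subpop_id = sprintf(paste0("sp%0", width, "d"), s),
      range_area = sum(u$total_area[members] * share),
      nominal_target_pct = if (s == 1) 0.40 else 0.65,
      habitat_by_unit = stats::setNames(u$undist_full_area[members] * share,
                                        u$unit_id[members]),
      protected_undisturbed = sum(prot_undist[members] * share))
  })
}

#' Generate a species pool with contiguous ranges and metadata
#'
#' Each species receives a contiguous range grown from a random seed unit,
#' with range size drawn from a heavy-tailed lognormal so that most species
#' are range-restricted while a few are widespread. `frac_distribution` is
#' recomputed from the generated range (range area over landscape area);
#' `frac_canadian_inside` is drawn from a mixture (high with probability
#' `unique_species_prob`) calibrated so a handful of species pass the
#' uniqueness filter, mirroring the study system where 7 of 80 did.
#'
#' @param landscape a `landscape`.
#' @param config a [generator_config()].
#' @return list with `presence` (unit x species logical matrix) and `meta`
#'   (data.frame: species_id, taxon_group, frac_distribution,
#'   frac_canadian_inside).
#' @export
generate_species <- function(landscape, config) {
  stage_seed(config$seed, "species")
  n <- nrow(landscape$units)
  nb <- neighbor_index(landscape)
  taxa <- c("amphibian", "arthropod", "bird", "lichen", "mollusc", "mammal",
            "reptile", "vascular plant", "fish")[seq_len(min(config$n_taxa, 9))]
  if (config$n_taxa > 9) taxa <- c(taxa, paste0("group", 10:config$n_taxa))
  presence <- matrix(FALSE, n, config$n_species,
                     dimnames = list(landscape$units$unit_id,
                                     sprintf("sp%03d", seq_len(config$n_species))))
  sizes <- pmin(n, pmax(1, round(n * stats::rlnorm(config$n_species,
                                                   log(0.06), 1))))
  for (k in seq_len(config$n_species)) {
    members <- integer(0)
    frontier <- sample.int(n, 1)
    while (length(members) < sizes[k] && length(frontier) > 0) {
      i <- frontier[[1]]
      frontier <- frontier[-1]
      if (i %in% members) next
      members <- c(members, i)
      frontier <- c(frontier, sample(setdiff(nb[[i]], members)))
    }
    presence[members, k] <- TRUE
  }
  frac_dist <- as.numeric(crossprod(presence, landscape$units$total_area)) /
    landscape$total_area
  high <- stats::runif(config$n_species) < config$unique_species_prob
  inside <- ifelse(high, stats::runif(config$n_species, 0.55, 0.95),
                   stats::runif(config$n_species, 0, 0.5))
  meta <- data.frame(
    species_id = colnames(presence),
    taxon_group = sample(taxa, config$n_species, replace = TRUE),
    frac_distribution = frac_dist,
    frac_canadian_inside = inside,
    stringsAsFactors = FALSE)
  list(presence = presence, meta = meta)
}

#' Generate a complete synthetic planning dataset
#'
#' Runs every generator stage on its own seed substream and assembles the
#' scenario inputs: the landscape, species presence/metadata,
#' sub-populations, refugia and carbon layers (from
#' [generate_value_layers()]), and the objective matrices for both
#' scenarios (richness, taxonomic and unique-species columns computed from
#' the generated species tables via [assemble_objective_matrix()]).
#'
#' @param config a [generator_config()].
#' @return list with elements `landscape`, `presence`, `meta`, `subpops`,
#'   `layers`, `objective_expand` (6 columns), `objective_protect`
#'   (5 columns), `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  skeleton <- generate_hex_grid(config)
  land <- generate_protection_and_disturbance(skeleton, config)
  layers <- generate_value_layers(land, config)
  subpops <- generate_subpopulations(land, config)
  sp <- generate_species(land, config)
  refugia <- stats::setNames(layers[, "refugia"], rownames(layers))
  carbon <- stats::setNames(layers[, "carbon"], rownames(layers))
  obj6 <- assemble_objective_matrix(land, sp$presence, sp$meta,
                                    refugia, carbon, scenario = "expand")
  obj5 <- assemble_objective_matrix(land, sp$presence, sp$meta,
                                    refugia, carbon, scenario = "protect")
  list(landscape = land, presence = sp$presence, meta = sp$meta,
       subpops = subpops, layers = layers,
       objective_expand = obj6, objective_protect = obj5,
       config = config)
}

#' Write a generated dataset to a directory of delimited tables
#'
#' Emits the landscape CSV schemas plus species and sub-population tables
#' and a provenance JSON echoing the scalar configuration.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_landscape(dataset$landscape, p("units.csv"), p("adjacency.csv"))
  long <- which(dataset$presence, arr.ind = TRUE)
  utils::write.csv(data.frame(
    unit_id = rownames(dataset$presence)[long[, 1]],
    species_id = colnames(dataset$presence)[long[, 2]]),
    p("species_presence.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$meta, p("species_meta.csv"),
                   row.names = FALSE, quote = FALSE)
  sp_meta <- do.call(rbind, lapply(dataset$subpops, function(s) data.frame(
    subpop_id = s$subpop_id, range_area = s$range_area,
    nominal_target_pct = s$nominal_target_pct,
    protected_undisturbed = s$protected_undisturbed)))
  utils::write.csv(sp_meta, p("subpopulations.csv"),
                   row.names = FALSE, quote = FALSE)
  sp_hab <- do.call(rbind, lapply(dataset$subpops, function(s) data.frame(
    subpop_id = s$subpop_id, unit_id = names(s$habitat_by_unit),
    habitat = unname(s$habitat_by_unit))))
  utils::write.csv(sp_hab, p("subpop_habitat.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(unit_id = rownames(dataset$layers),
                              dataset$layers, check.names = FALSE),
                   p("value_layers.csv"), row.names = FALSE, quote = FALSE)
  cfg <- unclass(dataset$config)
  cfg$objective_correlation <- NULL
  jsonlite::write_json(cfg, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
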