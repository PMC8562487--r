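#' Define a synthetic gradient-community scenario
#'
#' A scenario bundles every knob of the synthetic generator: the regional
#' taxon pool, the sampling design (sites x plots along an elevation
#' gradient), and the strengths of the three assembly mechanisms the
#' generator can mix — Gaussian environmental filtering of a phylogenetically
#' conserved niche trait, exponential distance-decay of immigration from
#' site-specific source pools, and demographic drift (lognormal abundance
#' noise plus a finite-depth multinomial draw).
#'
#' The defaults emulate a montane study design: 12 sites x 8 plots = 96
#' samples spanning 1800-4100 m, a temperature lapse of 0.67 degC / 100 m,
#' a precipitation rise of 67.5 mm / 100 m, soil pH spanning 3.53-7.23,
#' and a sequencing depth of 1500 reads per sample.
#'
#' @param n_taxa number of taxa in the regional pool.
#' @param n_sites number of elevation sites.
#' @param plots_per_site number of plots (samples) per site.
#' @param elevation_range length-2 numeric, min and max elevation in metres.
#' @param selection_strength non-negative Gaussian filter strength
#'   (inverse squared niche width, in units of the filtered variable^-2);
#'   `Inf` switches to a hard cutoff of width `hard_cutoff`.
#' @param dispersal_decay non-negative exponential decay rate of immigration
#'   per kilometre of distance from a taxon's home site; 0 = well mixed.
#' @param drift_intensity non-negative lognormal sd of per-taxon,
#'   per-sample abundance noise (demographic drift proxy).
#' @param trait_sigma Brownian-motion rate of niche-trait evolution
#'   (trait units per square-root unit of tree depth).
#' @param pool_sdlog lognormal sd of the regional species-abundance
#'   distribution (fixed per-taxon base abundances); > 0 gives the uneven,
#'   sparse tables real amplicon surveys show, 0 a perfectly even pool.
#' @param root_trait niche-trait value at the root of the phylogeny.
#' @param filtered_variable metadata column the niche trait is matched
#'   against ("pH" by default; "plant_richness" gives a plant-driven guild).
#' @param depth multinomial sequencing depth per sample.
#' @param plot_noise_sd multiplier (>= 0) on all within-site plot-level
#'   environmental noise scales; 0 gives noise-free metadata.
#' @param hard_cutoff tolerance of the hard niche filter used when
#'   `selection_strength = Inf`, in trait units.
#' @param seed integer seed from which all of the scenario's randomness is
#'   derived via a fixed splitting rule.
#'
#' @return An object of class `"synthetic_scenario"` (a named list).
#' @seealso [scenario_preset()], [simulate_dataset()]
#' @export
synthetic_scenario <- function(n_taxa = 150L,
                               n_sites = 12L,
                               plots_per_site = 8L,
                               elevation_range = c(1800, 4100),
                               selection_strength = 6,
                               dispersal_decay = 0,
                               drift_intensity = 0.25,
                               trait_sigma = 1,
                               pool_sdlog = 1.5,
                               root_trait = 5.4,
                               filtered_variable = "pH",
                               depth = 1500L,
                               plot_noise_sd = 1,
                               hard_cutoff = 0.5,
                               seed = 1L) {
  if (n_taxa < 1L) stop("n_taxa must be >= 1", call. = FALSE)
  if (n_sites < 1L || plots_per_site < 1L)
    stop("n_sites and plots_per_site must be >= 1", call. = FALSE)
  if (length(elevation_range) != 2L || elevation_range[1] >= elevation_range[2])
    stop("elevation_range must be c(min, max) with min < max", call. = FALSE)
  if (selection_strength < 0 || dispersal_decay < 0 || drift_intensity < 0 ||
      trait_sigma < 0 || plot_noise_sd < 0 || pool_sdlog < 0)
    stop("strengths and rates must be non-negative", call. = FALSE)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  structure(list(
    n_taxa = as.integer(n_taxa),
    n_sites = as.integer(n_sites),
    plots_per_site = as.integer(plots_per_site),
    elevation_range = as.numeric(elevation_range),
    selection_strength = selection_strength,
    dispersal_decay = dispersal_decay,
    drift_intensity = drift_intensity,
    trait_sigma = trait_sigma,
    pool_sdlog = pool_sdlog,
    root_trait = root_trait,
    filtered_variable = filtered_variable,
    depth = as.integer(depth),
    plot_noise_sd = plot_noise_sd,
    hard_cutoff = hard_cutoff,
    seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Named scenario presets for the three canonical assembly regimes
#'
#' * `"selection"` — strong Gaussian filtering of a conserved trait across
#'   a heterogeneous gradient, well-mixed dispersal, moderate drift: the
#'   regime in which deterministic (selection) processes dominate turnover.
#' * `"dispersal_limited"` — no selection, strong distance-decay of
#'   immigration from site-specific source pools, stronger drift: divergence
#'   by dispersal limitation.
#' * `"well_mixed"` — no selection and no distance-decay: drift around a
#'   common expected profile, i.e. the homogenizing end of the stochastic
#'   spectrum.
#'
#' @param regime one of `"selection"`, `"dispersal_limited"`, `"well_mixed"`.
#' @param ... overrides passed on to [synthetic_scenario()].
#' @return A `"synthetic_scenario"`.
#' @export
scenario_preset <- function(regime = c("selection", "dispersal_limited",
                                       "well_mixed"), ...) {
  regime <- match.arg(regime)
  args <- switch(regime,
    selection = list(selection_strength = 6, dispersal_decay = 0,
                     drift_intensity = 0.25),
    dispersal_limited = list(selection_strength = 0, dispersal_decay = 1.5,
                             drift_intensity = 0.5),
    well_mixed = list(selection_strength = 0, dispersal_decay = 0,
                      drift_intensity = 0.5)
  )
  do.call(synthetic_scenario, utils::modifyList(args, list(...)))
}

#' Simulate a rooted ultrametric phylogeny for the regional pool
#'
#' Pure-birth (Yule) tree with constant speciation rate, rescaled to unit
#' root-to-tip depth so that trait rates and cophenetic distances are on a
#' fixed scale regardless of pool size.
#'
#' @param n_taxa number of leaves (>= 1).
#' @param seed integer RNG seed.
#' @return An [ape::phylo] object with `n_taxa` uniquely labelled leaves,
#'   strictly positive branch lengths and unit depth.
#' @export
simulate_phylogeny <- function(n_taxa, seed = 1L) {
  if (length(n_taxa) != 1L || is.na(n_taxa) || n_taxa < 1)
    stop("n_taxa must be a single integer >= 1", call. = FALSE)
  n_taxa <- as.integer(n_taxa)
  labels <- sprintf("OTU%03d", seq_len(n_taxa))
  if (n_taxa == 1L) {
    tree <- ape::read.tree(text = paste0("(", labels, ":1);"))
    return(tree)
  }
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- labels
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Evolve niche optima along a phylogeny by Brownian motion
#'
#' Each branch contributes an independent Gaussian increment with variance
#' `trait_sigma^2 * branch length`, producing the phylogenetic niche
#' conservatism that nearest-taxon statistics assume: close relatives get
#' similar environmental optima.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait_sigma Brownian rate (>= 0).
#' @param root_value trait value at the root.
#' @param seed integer RNG seed.
#' @return Named numeric vector of niche optima, one per leaf.
#' @export
evolve_niche_traits <- function(tree, trait_sigma, root_value = 0, seed = 1L) {
  if (trait_sigma < 0) stop("trait_sigma must be >= 0", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 1L) stop("tree must have at least one leaf", call. = FALSE)
  if (n == 1L) {
    bl <- sum(tree$edge.length)
    tr <- with_seed(seed, root_value + stats::rnorm(1, 0, trait_sigma * sqrt(bl)))
    names(tr) <- tree$tip.label
    return(tr)
  }
  tr <- with_seed(seed,
                  ape::rTraitCont(tree, model = "BM", sigma = trait_sigma,
                                  root.value = root_value))
  tr[tree$tip.label]
}

#' Simulate plot-level environmental metadata along the elevation gradient
#'
#' One row per plot. Climate follows fixed lapse rates (MAT falls by
#' 0.67 degC and MAP rises by 67.5 mm per 100 m of elevation); soil
#' chemistry, conductivity, vegetation structure (percent DBH of deciduous
#' broadleaf, evergreen broadleaf and dark conifer trees), plant richness
#' (a decrease-then-increase pattern), and nirK/nirS gene copy numbers all
#' follow smooth elevation trends with seeded plot-level noise whose scale
#' is multiplied by `plot_noise_sd`. pH declines from circumneutral to
#' strongly acidic and is clamped to [3.53, 7.23].
#'
#' @param scenario a [synthetic_scenario()].
#' @return A data.frame with one row per plot and a mandatory `sample_id`
#'   column; sites are labelled `E01..`, plots `E01P1..`.
#' @export
simulate_gradient_metadata <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  ns <- scenario$n_sites
  np <- scenario$plots_per_site
  n <- ns * np
  k <- scenario$plot_noise_sd
  elev_site <- seq(scenario$elevation_range[1], scenario$elevation_range[2],
                   length.out = ns)
  site <- rep(seq_len(ns), each = np)
  elevation <- elev_site[site]
  frac <- (elevation - scenario$elevation_range[1]) /
    diff(scenario$elevation_range)

  md <- with_seed(split_seed(scenario$seed, 11L), {
    noise <- function(sd) stats::rnorm(n, 0, sd * k)
    lat <- 29.55 + (site - 1) * 0.018 + noise(3e-4)
    lon <- 101.95 - (site - 1) * 0.009 + noise(3e-4)
    MAT <- 13.0 - 0.67 * (elevation - scenario$elevation_range[1]) / 100 +
      noise(0.1)
    MAP <- 950 + 67.5 * (elevation - scenario$elevation_range[1]) / 100 +
      noise(15)
    pH <- pmin(7.23, pmax(3.53, 7.0 - 3.2 * frac + noise(0.2)))
    TC <- pmax(1, 62 - 35 * frac + noise(5))
    TN <- pmax(0.1, 4.2 - 2.2 * frac + noise(0.35))
    NH4 <- pmin(62.78, pmax(1.81, 6 + 45 * frac + noise(5)))
    NO3 <- pmax(0.05, 28 - 22 * frac + noise(3))
    cond <- pmax(5, 160 - 100 * frac + noise(12))
    pr <- pmax(3, round(28 - 40 * frac + 34 * frac^2 + noise(2)))
    # vegetation-structure scores -> percentages of total DBH; the
    # non-woody (shrub/meadow) component absorbs the remainder at the top
    s_eb <- pmax(0, 1 - 3 * frac) + pmax(0, noise(0.02))
    s_db <- exp(-((frac - 0.25) / 0.25)^2) + pmax(0, noise(0.02))
    s_dc <- exp(-((frac - 0.65) / 0.30)^2) + pmax(0, noise(0.02))
    s_open <- 3 * pmax(0, frac - 0.7)
    tot <- s_eb + s_db + s_dc + s_open
    nirK <- exp(log(8.89e8) - 1.85 * frac + noise(0.4))
    nirS <- exp(log(3.20e7) - 1.10 * frac + noise(0.4))
    data.frame(
      sample_id = sprintf("E%02dP%d", site, rep(seq_len(np), times = ns)),
      site = sprintf("E%02d", site),
      elevation = elevation,
      latitude = lat, longitude = lon,
      MAT = MAT, MAP = MAP, pH = pH,
      TC = TC, TN = TN, TC_TN = TC / TN,
      NH4_N = NH4, NO3_N = NO3,
      conductivity = cond,
      plant_richness = pr,
      DBH_DB = 100 * s_db / tot,
      DBH_EB = 100 * s_eb / tot,
      DBH_DC = 100 * s_dc / tot,
      nirK_copies = nirK, nirS_copies = nirS,
      stringsAsFactors = FALSE
    )
  })
  rownames(md) <- md$sample_id
  md
}

# Pairwise great-circle distances (km) between site centroids.
site_distances_km <- function(metadata) {
  sites <- unique(metadata$site)
  cent <- t(vapply(sites, function(s) {
    sel <- metadata$site == s
    c(lon = mean(metadata$longitude[sel]), lat = mean(metadata$latitude[sel]))
  }, numeric(2)))
  d <- geosphere::distm(cent, fun = geosphere::distHaversine) / 1000
  dimnames(d) <- list(sites, sites)
  d
}

#' Assemble community count tables under a known mixture of processes
#'
#' Expected abundance of taxon i in plot j is
#' `exp(-selection_strength * (trait_i - env_j)^2)` (Gaussian niche filter
#' on the scenario's filtered variable) times an exponential
#' distance-decay immigration kernel from the taxon's home site, times
#' lognormal drift noise; counts are then a multinomial draw of `depth`
#' reads per plot. With `selection_strength = Inf` the Gaussian filter
#' becomes a hard cutoff of half-width `hard_cutoff`.
#'
#' @param tree phylogeny over the pool (leaf set = taxa).
#' @param traits named niche-optimum vector covering all leaves.
#' @param metadata output of [simulate_gradient_metadata()] (must contain
#'   the filtered variable plus `site`, `latitude`, `longitude`).
#' @param scenario the [synthetic_scenario()].
#' @return Integer samples x taxa matrix; every row sums to `depth`.
#' @export
assemble_communities <- function(tree, traits, metadata, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  taxa <- tree$tip.label
  if (!all(taxa %in% names(traits)))
    stop("trait map does not cover all tree leaves", call. = FALSE)
  env_var <- scenario$filtered_variable
  if (!env_var %in% names(metadata))
    stop("metadata lacks the filtered variable '", env_var, "'", call. = FALSE)
  traits <- traits[taxa]
  env <- metadata[[env_var]]
  n_taxa <- length(taxa)
  n_samp <- nrow(metadata)

  # Gaussian (or hard-cutoff) niche filter: taxa x samples
  dev <- outer(traits, env, "-")
  if (is.infinite(scenario$selection_strength)) {
    w_sel <- (abs(dev) <= scenario$hard_cutoff) * 1
  } else {
    w_sel <- exp(-scenario$selection_strength * dev^2)
  }

  with_seed(split_seed(scenario$seed, 23L), {
    # fixed regional species-abundance distribution (lognormal base
    # abundances), shared by all samples
    base <- exp(stats::rnorm(n_taxa, 0, scenario$pool_sdlog))
    # immigration: each taxon has a home site; weight decays with distance
    sites <- unique(metadata$site)
    home <- sample.int(length(sites), n_taxa, replace = TRUE)
    if (scenario$dispersal_decay > 0) {
      dkm <- site_distances_km(metadata)
      site_of <- match(metadata$site, sites)
      w_disp <- exp(-scenario$dispersal_decay * dkm[home, site_of, drop = FALSE])
    } else {
      w_disp <- matrix(1, n_taxa, n_samp)
    }
    w_noise <- matrix(
      exp(stats::rnorm(n_taxa * n_samp, 0, scenario$drift_intensity)),
      n_taxa, n_samp)
    w <- base * w_sel * w_disp * w_noise
    empty <- colSums(w) == 0
    if (any(empty))
      stop("no taxa pass the niche filter in sample(s): ",
           paste(metadata$sample_id[empty], collapse = ", "), call. = FALSE)
    counts <- vapply(seq_len(n_samp), function(j) {
      stats::rmultinom(1, scenario$depth, prob = w[, j])[, 1]
    }, integer(n_taxa))
    otu <- t(counts)
    dimnames(otu) <- list(metadata$sample_id, taxa)
    otu
  })
}

#' Simulate a potential denitrification rate driven by community composition
#'
#' PDR is a fixed linear function of a weighted community-composition score
#' (`score_j = sum_i w_i p_ij` with fixed taxon loadings `w` drawn once from
#' the seed and `p` relative abundances) plus Gaussian noise. Turnover in
#' composition — not total abundance — therefore predicts PDR by
#' construction, which is the ground truth the distance-based regressions
#' are checked against. With `noise_sd = 0` identical community profiles
#' map to identical PDR.
#'
#' @param otu samples x taxa count matrix.
#' @param metadata sample metadata; row order must match `otu`.
#' @param noise_sd Gaussian noise sd on the rate scale.
#' @param seed integer RNG seed (loadings and noise use separate sub-seeds).
#' @param base,gain intercept and slope of the rate on the composition score
#'   (defaults span roughly 1-300 ug N2O-N g^-1 h^-1 across regimes).
#' @return `metadata` with a `PDR` column appended.
#' @export
simulate_pdr <- function(otu, metadata, noise_sd = 5, seed = 1L,
                         base = 15, gain = 280) {
  otu <- check_otu_table(otu)
  if (nrow(otu) != nrow(metadata) ||
      !all(rownames(otu) == metadata$sample_id))
    stop("sample sets of OTU table and metadata do not match", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  p <- otu / rowSums(otu)
  w <- with_seed(split_seed(seed, 31L), stats::runif(ncol(otu)))
  score <- as.numeric(p %*% w)
  eps <- if (noise_sd > 0)
    with_seed(split_seed(seed, 37L), stats::rnorm(nrow(otu), 0, noise_sd))
  else 0
  pdr <- base + gain * score + eps
  if (any(pdr < 0))
    warning(sum(pdr < 0), " negative PDR value(s) generated", call. = FALSE)
  metadata$PDR <- pdr
  metadata
}

#' Generate a complete synthetic dataset for one scenario
#'
#' Runs the whole generator: phylogeny, Brownian niche traits, gradient
#' metadata, community assembly, and the composition-driven PDR.
#'
#' @param scenario a [synthetic_scenario()].
#' @param pdr_noise_sd noise sd forwarded to [simulate_pdr()].
#' @return A list of class `"synthetic_dataset"` with elements `tree`,
#'   `traits`, `metadata` (including `PDR`), `otu`, and `scenario`.
#' @export
simulate_dataset <- function(scenario = synthetic_scenario(),
                             pdr_noise_sd = 5) {
  tree <- simulate_phylogeny(scenario$n_taxa, split_seed(scenario$seed, 1L))
  traits <- evolve_niche_traits(tree, scenario$trait_sigma,
                                root_value = scenario$root_trait,
                                seed = split_seed(scenario$seed, 2L))
  metadata <- simulate_gradient_metadata(scenario)
  otu <- assemble_communities(tree, traits, metadata, scenario)
  metadata <- simulate_pdr(otu, metadata, noise_sd = pdr_noise_sd,
                           seed = split_seed(scenario$seed, 3L))
  structure(list(tree = tree, traits = traits, metadata = metadata,
                 otu = otu, scenario = scenario),
            class = "synthetic_dataset")
}
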