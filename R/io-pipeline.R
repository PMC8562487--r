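#' Read / write an OTU table in QIIME-classic TSV layout
#'
#' Taxa as rows, samples as columns, first column `#OTU_ID`, tab-separated,
#' UTF-8. In memory the table is the transpose: a samples x taxa matrix.
#'
#' @param path file path.
#' @return `read_otu_table`: samples x taxa numeric matrix.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "#OTU_ID")
    stop("OTU table must have '#OTU_ID' as its first column", call. = FALSE)
  taxa <- tab[[1]]
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- taxa
  check_otu_table(m)
}

#' @param otu samples x taxa matrix.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(otu, path) {
  otu <- check_otu_table(otu)
  df <- data.frame(`#OTU_ID` = colnames(otu), t(otu),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Tab-separated with a mandatory `sample_id` column; duplicate sample ids
#' are a hard error.
#'
#' @param path file path.
#' @return data.frame with rownames set to `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md))
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", "), call. = FALSE)
  rownames(md) <- md$sample_id
  md
}

#' @param metadata data.frame with `sample_id`.
#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a Newick tree
#'
#' Reading first checks parenthesis balance and reports the byte offset of
#' the first imbalance before handing over to [ape::read.tree()].
#'
#' @param path file path.
#' @return An [ape::phylo] object.
#' @export
read_phylo_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unbalanced ')' at offset ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at offset ",
         length(chars), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e)
                     stop("Newick parse failure: ", conditionMessage(e),
                          call. = FALSE))
  if (is.null(tree)) stop("Newick parse failure", call. = FALSE)
  tree
}

#' @param tree an [ape::phylo] object.
#' @rdname read_phylo_tree
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write a scenario configuration (key: value text format)
#'
#' @param path file path.
#' @return `read_scenario_config`: a [synthetic_scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  args <- stats::setNames(as.list(vals), keys)
  numeric_keys <- c("n_taxa", "n_sites", "plots_per_site",
                    "selection_strength", "dispersal_decay",
                    "drift_intensity", "trait_sigma", "root_trait", "depth",
                    "plot_noise_sd", "hard_cutoff", "seed")
  for (k in intersect(names(args), numeric_keys))
    args[[k]] <- as.numeric(args[[k]])
  if ("elevation_min" %in% names(args) || "elevation_max" %in% names(args)) {
    args$elevation_range <- c(as.numeric(args$elevation_min),
                              as.numeric(args$elevation_max))
    args$elevation_min <- args$elevation_max <- NULL
  }
  do.call(synthetic_scenario, args)
}

#' @param scenario a [synthetic_scenario()].
#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- unclass(scenario)
  sc$elevation_min <- sc$elevation_range[1]
  sc$elevation_max <- sc$elevation_range[2]
  sc$elevation_range <- NULL
  writeLines(sprintf("%s: %s", names(sc),
                     vapply(sc, function(v) paste(format(v), collapse = " "),
                            "")), path)
  invisible(path)
}

#' Load and reconcile an OTU table, tree and metadata from disk
#'
#' Taxa present in the table but absent from the tree are a hard error
#' (listing the names); extra tree leaves are pruned with a warning.
#' Samples are reconciled to those present in both table and metadata
#' (warning if any are dropped) and returned in metadata order, so the
#' ordering is deterministic.
#'
#' @param otu_path,tree_path,metadata_path file paths.
#' @return List with elements `otu`, `tree`, `metadata`.
#' @export
load_dataset <- function(otu_path, tree_path, metadata_path) {
  otu <- read_otu_table(otu_path)
  tree <- read_phylo_tree(tree_path)
  metadata <- read_sample_metadata(metadata_path)
  missing <- setdiff(colnames(otu), tree$tip.label)
  if (length(missing))
    stop("taxa in table absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(tree$tip.label, colnames(otu))
  if (length(extra)) {
    warning("pruning ", length(extra), " tree leaf/leaves absent from table",
            call. = FALSE)
    tree <- ape::keep.tip(tree, colnames(otu))
  }
  common <- intersect(metadata$sample_id, rownames(otu))
  if (length(common) < nrow(otu) || length(common) < nrow(metadata))
    warning("dropping samples not shared by table and metadata",
            call. = FALSE)
  if (!length(common)) stop("no shared samples", call. = FALSE)
  metadata <- metadata[metadata$sample_id %in% common, , drop = FALSE]
  otu <- otu[metadata$sample_id, , drop = FALSE]
  list(otu = otu, tree = tree, metadata = metadata)
}

#' Pipeline configuration
#'
#' Either a scenario (simulate mode) or a triplet of input paths (run
#' mode), plus the analysis parameters shared by all stages.
#'
#' @param scenario a [synthetic_scenario()] (simulate mode), or NULL.
#' @param otu_path,tree_path,metadata_path input files (run mode).
#' @param outdir output directory (created if needed).
#' @param depth rarefaction depth.
#' @param n_null null-model randomizations for the assembly stage.
#' @param n_perm permutations for NPMANOVA / Mantel / MRM.
#' @param group_col metadata column defining the NPMANOVA groups.
#' @param env_vars metadata columns used as environmental drivers.
#' @param seed top-level seed; all stages derive sub-seeds from it.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scenario = NULL, otu_path = NULL,
                            tree_path = NULL, metadata_path = NULL,
                            outdir, depth = 1500L, n_null = 999L,
                            n_perm = 999L, group_col = "site",
                            env_vars = c("pH", "MAT", "MAP", "TC", "TN",
                                         "NH4_N", "NO3_N", "conductivity",
                                         "plant_richness"),
                            seed = 1L) {
  if (is.null(scenario) &&
      (is.null(otu_path) || is.null(tree_path) || is.null(metadata_path)))
    stop("provide either a scenario or all three input paths", call. = FALSE)
  if (!is.null(otu_path)) {
    for (p in c(otu_path, tree_path, metadata_path))
      if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  structure(list(scenario = scenario, otu_path = otu_path,
                 tree_path = tree_path, metadata_path = metadata_path,
                 outdir = outdir, depth = as.integer(depth),
                 n_null = as.integer(n_null), n_perm = as.integer(n_perm),
                 group_col = group_col, env_vars = env_vars,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

pipeline_log <- function(stage, seed, t0) {
  message(sprintf("[%s] seed=%s elapsed=%.2fs", stage,
                  if (is.null(seed)) "-" else seed,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> rarefy -> alpha/beta diversity ->
#' NPMANOVA -> assembly-process partition -> driver attribution (partial
#' Mantel table over environmental drivers, MRM of community turnover on
#' drivers and of PDR on community turnover, stepwise regression of
#' alpha-diversity, PCNM + PLS-PM), writing one TSV per result plus a JSON
#' manifest of every seed and parameter. Identical config and seed give
#' byte-identical outputs; no stage mutates its inputs on disk.
#'
#' @param cfg a [pipeline_config()].
#' @return The output directory path, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  out <- function(f) file.path(cfg$outdir, f)
  stage <- "load"
  withCallingHandlers({
    if (!is.null(cfg$scenario)) {
      stage <- "simulate"
      ds <- simulate_dataset(cfg$scenario)
      otu <- ds$otu; tree <- ds$tree; metadata <- ds$metadata
      write_otu_table(otu, out("otu.tsv"))
      write_phylo_tree(tree, out("tree.nwk"))
      write_sample_metadata(metadata, out("metadata.tsv"))
      write_scenario_config(cfg$scenario, out("scenario.cfg"))
      pipeline_log(stage, cfg$scenario$seed, t0)
    } else {
      ds <- load_dataset(cfg$otu_path, cfg$tree_path, cfg$metadata_path)
      otu <- ds$otu; tree <- ds$tree; metadata <- ds$metadata
      pipeline_log(stage, NULL, t0)
    }
    for (col in unique(c(cfg$group_col, cfg$env_vars,
                         "latitude", "longitude")))
      if (!col %in% names(metadata))
        stop("metadata lacks required column '", col, "'", call. = FALSE)

    stage <- "rarefy"
    otu_r <- rarefy(otu, depth = cfg$depth, seed = split_seed(cfg$seed, 201L))
    metadata <- metadata[rownames(otu_r), , drop = FALSE]
    write_otu_table(otu_r, out("otu_rarefied.tsv"))
    pipeline_log(stage, cfg$seed, t0)

    stage <- "alpha_diversity"
    write_tsv(alpha_diversity(otu_r), out("alpha_diversity.tsv"))

    stage <- "beta_diversity"
    bc <- bray_curtis(otu_r)
    write_matrix_tsv(bc, out("bray_curtis.tsv"))
    ord <- pcoa(bc, k = 2)
    write_matrix_tsv(ord$points, out("pcoa_coordinates.tsv"))
    pipeline_log(stage, NULL, t0)

    stage <- "npmanova"
    pm <- permanova(bc, metadata[[cfg$group_col]], n_perm = cfg$n_perm,
                    seed = split_seed(cfg$seed, 202L))
    write_tsv(data.frame(pseudo_F = pm$f, R2 = pm$r2, p = pm$p,
                         n_perm = pm$n_perm), out("npmanova.tsv"))
    write_tsv(pm$pairwise, out("npmanova_pairwise.tsv"))
    pipeline_log(stage, cfg$seed, t0)

    stage <- "assembly"
    cfg_null <- null_model_config(n_null = cfg$n_null,
                                  seed = split_seed(cfg$seed, 203L))
    asm <- assembly_analysis(otu_r, tree, cfg_null)
    write_tsv(asm$nti, out("nti.tsv"))
    write_tsv(asm$partition$pairs, out("assembly_pairs.tsv"))
    write_tsv(data.frame(process = names(asm$partition$fractions),
                         fraction = asm$partition$fractions,
                         row.names = NULL),
              out("assembly_fractions.tsv"))
    pipeline_log(stage, cfg$seed, t0)

    stage <- "drivers"
    geo <- env_distance(metadata, c("latitude", "longitude"),
                        standardize = FALSE)
    mantel_rows <- lapply(cfg$env_vars, function(v) {
      mt <- mantel_test(env_distance(metadata, v), bc, dz = geo,
                        n_perm = cfg$n_perm,
                        seed = split_seed(cfg$seed, 204L))
      data.frame(factor = v, pmantel_r = mt$r, p = mt$p,
                 stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, mantel_rows), out("partial_mantel.tsv"))

    env_d <- lapply(cfg$env_vars, function(v) env_distance(metadata, v))
    names(env_d) <- cfg$env_vars
    mrm_comm <- mrm(bc, env_d, n_perm = cfg$n_perm,
                    seed = split_seed(cfg$seed, 205L))
    write_tsv(cbind(mrm_comm$coefficients,
                    model_r2 = mrm_comm$r2, model_p = mrm_comm$p),
              out("mrm_community.tsv"))
    if ("PDR" %in% names(metadata)) {
      pdr_d <- env_distance(metadata, "PDR", standardize = FALSE)
      mrm_pdr <- mrm(pdr_d, list(community = bc), n_perm = cfg$n_perm,
                     seed = split_seed(cfg$seed, 206L))
      write_tsv(cbind(mrm_pdr$coefficients,
                      model_r2 = mrm_pdr$r2, model_p = mrm_pdr$p),
                out("mrm_pdr.tsv"))
    }

    alpha <- alpha_diversity(otu_r)
    sw <- stepwise_regression(alpha$chao1,
                              metadata[, cfg$env_vars, drop = FALSE])
    write_tsv(if (length(sw$selected)) data.frame(
      predictor = sw$selected,
      contribution_pct = sw$contribution_pct,
      p = unname(sw$p_values), adj_r2 = sw$adj_r2) else
        data.frame(predictor = character(0), contribution_pct = numeric(0),
                   p = numeric(0), adj_r2 = numeric(0)),
      out("stepwise_alpha.tsv"))

    stage <- "plspm"
    pcnm <- pcnm_axes(metadata$latitude, metadata$longitude)
    pls_data <- data.frame(PCNM1 = pcnm$PCNM1, MAT = metadata$MAT,
                           plant_richness = metadata$plant_richness,
                           pH = metadata$pH, TN = metadata$TN,
                           Axis1 = ord$points[, 1],
                           Axis2 = ord$points[, 2])
    blocks <- list(geography = "PCNM1", climate = "MAT",
                   plant = "plant_richness", soil = c("pH", "TN"),
                   community = c("Axis1", "Axis2"))
    path <- matrix(0, 5, 5)
    path[2, 1] <- 1                # geography -> climate
    path[3, 1:2] <- 1              # -> plant
    path[4, 1:3] <- 1              # -> soil
    path[5, 1:4] <- 1              # -> community
    pls <- plspm_fit(pls_data, blocks, path)
    write_tsv(pls$paths, out("plspm_paths.tsv"))
    write_tsv(data.frame(latent = names(pls$r2), r2 = pls$r2,
                         gof = pls$gof, row.names = NULL),
              out("plspm_fit.tsv"))
    pipeline_log(stage, NULL, t0)

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("gradientAssembly")),
      seed = cfg$seed, depth = cfg$depth, n_null = cfg$n_null,
      n_perm = cfg$n_perm, group_col = cfg$group_col,
      env_vars = cfg$env_vars,
      scenario = if (!is.null(cfg$scenario))
        unclass(cfg$scenario) else NULL,
      inputs = list(otu = cfg$otu_path, tree = cfg$tree_path,
                    metadata = cfg$metadata_path),
      outputs = sort(setdiff(list.files(cfg$outdir), "manifest.json"))
    )
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               out("manifest.json"))
  }, error = function(e) {
    message("pipeline failed in stage '", stage, "'")
  })
  invisible(cfg$outdir)
}
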