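#' Null-model configuration for the assembly analysis
#'
#' @param n_null number of null randomizations (>= 99; default 999).
#' @param abundance_weighted weight nearest-taxon distances by relative
#'   abundance (default TRUE; FALSE = presence/absence).
#' @param seed integer RNG seed.
#' @param scope randomization scope for the phylogenetic nulls:
#'   `"regional"` shuffles taxon labels across the full cophenetic matrix of
#'   all taxa in the table; `"pairwise"` restricts the shuffle to the taxa
#'   occurring in the two samples being compared.
#' @return List of class `"null_model_config"`.
#' @export
null_model_config <- function(n_null = 999L, abundance_weighted = TRUE,
                              seed = 1L, scope = c("regional", "pairwise")) {
  if (n_null < 99L) stop("n_null must be >= 99", call. = FALSE)
  structure(list(n_null = as.integer(n_null),
                 abundance_weighted = isTRUE(abundance_weighted),
                 seed = as.integer(seed), scope = match.arg(scope)),
            class = "null_model_config")
}

#' Patristic (cophenetic) distances between tree leaves
#'
#' Entry (i, j) is the sum of branch lengths on the path between leaves i
#' and j. If `taxa` is given, all of them must be leaves of the tree and
#' the matrix is returned in that order.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param taxa optional character vector of required taxa.
#' @return Symmetric matrix with zero diagonal, leaf labels as dimnames.
#' @export
cophenetic_distances <- function(tree, taxa = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(d))
    if (length(missing))
      stop("taxa absent from tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    d <- d[taxa, taxa, drop = FALSE]
  }
  d
}

# Relative-abundance (or uniform-presence) matrix, taxa x samples.
rel_abund_matrix <- function(otu, weighted) {
  f <- t(otu)
  if (!weighted) f <- (f > 0) * 1
  sweep(f, 2, colSums(f), "/")
}

# n_taxa x n_samples matrix of min distance from every pool taxon to the
# taxa present in each sample (0 for a taxon present in the sample itself).
nearest_in_sample <- function(d, presence) {
  vapply(presence, function(idx) row_mins_subset(d, idx), numeric(nrow(d)))
}

# All-pairs beta-MNTD from a taxa x samples relative-abundance matrix and a
# cophenetic matrix: B = (t(F) M + (t(F) M)^T) / 2 with M the
# nearest-in-sample matrix.
bmntd_matrix <- function(f, d, presence) {
  m <- nearest_in_sample(d, presence)
  p <- crossprod(f, m)
  (p + t(p)) / 2
}

#' Between-sample mean nearest taxon distance (beta-MNTD) for one pair
#'
#' `0.5 * [sum_i f_i min_j d(i, j) + sum_j f_j min_i d(j, i)]` where the
#' minima run over the other sample's resident taxa (a shared taxon's
#' nearest neighbour is itself, distance 0) and `f` are relative abundances
#' (uniform over residents when `weighted = FALSE`).
#'
#' @param x,y abundance vectors aligned with the rows of `coph` (or named
#'   by taxon).
#' @param coph cophenetic distance matrix over the pool.
#' @param weighted abundance weighting (default TRUE).
#' @return Single numeric beta-MNTD in branch-length units.
#' @export
beta_mntd <- function(x, y, coph, weighted = TRUE) {
  if (!is.null(names(x))) x <- x[rownames(coph)]
  if (!is.null(names(y))) y <- y[rownames(coph)]
  if (length(x) != nrow(coph) || length(y) != nrow(coph))
    stop("abundance vectors must align with the cophenetic matrix",
         call. = FALSE)
  if (sum(x) == 0 || sum(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  otu <- rbind(a = x, b = y)
  f <- rel_abund_matrix(otu, weighted)
  presence <- list(which(x > 0), which(y > 0))
  unname(bmntd_matrix(f, coph, presence)[1, 2])
}

# Within-sample abundance-weighted MNTD for every sample (self excluded).
mntd_samples <- function(otu, d, weighted) {
  f <- rel_abund_matrix(otu, weighted)
  vapply(seq_len(nrow(otu)), function(s) {
    idx <- which(otu[s, ] > 0)
    sub <- d[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mn <- row_mins_subset(sub, seq_along(idx))
    sum(f[idx, s] * mn)
  }, numeric(1))
}

#' Nearest taxon index (NTI) per sample
#'
#' NTI is the negated z-score of the observed within-sample mean
#' nearest-taxon distance against a null built by shuffling taxon labels
#' across the cophenetic matrix: `NTI = -(MNTD_obs - mean_null) / sd_null`,
#' so phylogenetic clustering gives positive values. Samples for which the
#' null has zero spread (e.g. a star tree) are flagged undefined (`NA` with
#' `undefined = TRUE`), never returned as a silent number.
#'
#' @param otu samples x taxa count matrix (>= 2 taxa present per sample).
#' @param coph cophenetic matrix covering all table taxa.
#' @param cfg a [null_model_config()].
#' @param exact replace Monte-Carlo shuffles by exhaustive enumeration of
#'   all taxon-label permutations (small pools only).
#' @return data.frame: `sample_id`, `mntd_obs`, `null_mean`, `null_sd`,
#'   `nti`, `undefined`.
#' @export
nti <- function(otu, coph, cfg = null_model_config(), exact = FALSE) {
  otu <- check_otu_table(otu)
  coph <- coph[colnames(otu), colnames(otu)]
  if (any(rowSums(otu > 0) < 2L))
    stop("every sample needs at least two resident taxa", call. = FALSE)
  obs <- mntd_samples(otu, coph, cfg$abundance_weighted)
  n <- ncol(otu)
  perms <- if (exact) all_permutations(n) else NULL
  n_null <- if (exact) length(perms) else cfg$n_null
  nulls <- with_seed(split_seed(cfg$seed, 51L), {
    vapply(seq_len(n_null), function(b) {
      p <- if (exact) perms[[b]] else sample.int(n)
      mntd_samples(otu, coph[p, p], cfg$abundance_weighted)
    }, numeric(nrow(otu)))
  })
  if (nrow(otu) == 1L) nulls <- matrix(nulls, nrow = 1L)
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1, stats::sd)
  undef <- sdv < 1e-12
  z <- ifelse(undef, NA_real_, -(obs - mu) / sdv)
  data.frame(sample_id = rownames(otu), mntd_obs = obs, null_mean = mu,
             null_sd = sdv, nti = z, undefined = undef,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise beta nearest taxon index (beta-NTI)
#'
#' For every sample pair, `betaNTI = (betaMNTD_obs - mean_null) / sd_null`,
#' with nulls generated by shuffling taxon labels across the cophenetic
#' matrix (regional pool by default, pairwise pool via `cfg$scope`).
#' Pairs whose null has zero spread are flagged `NA`.
#'
#' @inheritParams nti
#' @return List of class `"beta_nti_result"`: `bnti` and `bmntd_obs`
#'   (sample x sample matrices), `n_null`, `n_undefined`.
#' @export
beta_nti <- function(otu, coph, cfg = null_model_config(), exact = FALSE) {
  otu <- check_otu_table(otu)
  coph <- coph[colnames(otu), colnames(otu)]
  if (any(rowSums(otu) == 0)) stop("empty sample(s) in table", call. = FALSE)
  n_samp <- nrow(otu)
  if (n_samp < 2L) stop("need at least two samples", call. = FALSE)
  f <- rel_abund_matrix(otu, cfg$abundance_weighted)
  presence <- lapply(seq_len(n_samp), function(s) which(otu[s, ] > 0))
  obs <- bmntd_matrix(f, coph, presence)
  n <- ncol(otu)
  if (cfg$scope == "pairwise" && !exact) {
    res <- beta_nti_pairwise_scope(otu, coph, cfg)
  } else {
    perms <- if (exact) all_permutations(n) else NULL
    n_null <- if (exact) length(perms) else cfg$n_null
    sum1 <- matrix(0, n_samp, n_samp)
    sum2 <- matrix(0, n_samp, n_samp)
    with_seed(split_seed(cfg$seed, 53L), {
      for (b in seq_len(n_null)) {
        p <- if (exact) perms[[b]] else sample.int(n)
        bnull <- bmntd_matrix(f, coph[p, p], presence)
        sum1 <- sum1 + bnull
        sum2 <- sum2 + bnull^2
      }
    })
    mu <- sum1 / n_null
    v <- (sum2 - n_null * mu^2) / (n_null - 1)
    v[v < 0] <- 0                     # numerical cancellation guard
    res <- list(mu = mu, sdv = sqrt(v), n_null = n_null)
  }
  undef <- res$sdv < 1e-12
  z <- (obs - res$mu) / res$sdv
  z[undef] <- NA_real_
  diag(z) <- NA_real_
  dimnames(z) <- dimnames(obs) <- list(rownames(otu), rownames(otu))
  structure(list(bnti = z, bmntd_obs = obs, n_null = res$n_null,
                 n_undefined = sum(undef[lower.tri(undef)])),
            class = "beta_nti_result")
}

# Pairwise-pool scope: nulls shuffle only the union of the two samples'
# taxa on the corresponding cophenetic submatrix.
beta_nti_pairwise_scope <- function(otu, coph, cfg) {
  n_samp <- nrow(otu)
  mu <- matrix(0, n_samp, n_samp)
  sdv <- matrix(0, n_samp, n_samp)
  with_seed(split_seed(cfg$seed, 53L), {
    for (i in seq_len(n_samp - 1L)) for (j in seq(i + 1L, n_samp)) {
      u <- which(otu[i, ] > 0 | otu[j, ] > 0)
      sub_otu <- otu[c(i, j), u, drop = FALSE]
      f <- rel_abund_matrix(sub_otu, cfg$abundance_weighted)
      presence <- list(which(sub_otu[1, ] > 0), which(sub_otu[2, ] > 0))
      dsub <- coph[u, u, drop = FALSE]
      vals <- vapply(seq_len(cfg$n_null), function(b) {
        p <- sample.int(length(u))
        bmntd_matrix(f, dsub[p, p], presence)[1, 2]
      }, numeric(1))
      mu[i, j] <- mu[j, i] <- mean(vals)
      sdv[i, j] <- sdv[j, i] <- stats::sd(vals)
    }
  })
  list(mu = mu, sdv = sdv, n_null = cfg$n_null)
}

# Probability that sequential weighted sampling without replacement from
# the pool returns exactly this (unordered) subset.
subset_probability <- function(w_subset, w_total) {
  rec <- function(remaining, removed) {
    if (!length(remaining)) return(1)
    s <- 0
    for (k in seq_along(remaining)) {
      s <- s + remaining[k] / (w_total - removed) *
        rec(remaining[-k], removed + remaining[k])
    }
    s
  }
  rec(w_subset, 0)
}

# Integer compositions of n into k non-negative parts.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# Exhaustive distribution over null assemblies for one sample: all
# richness-preserving subsets (occupancy-weighted, without replacement) x
# all multinomial allocations of the remaining individuals.
null_assembly_distribution <- function(richness, total, occupancy, relabund) {
  pool <- which(occupancy > 0)
  subsets <- if (length(pool) == 1L) matrix(pool, 1L, 1L) else
    utils::combn(pool, richness)
  communities <- list()
  probs <- numeric(0)
  for (s in seq_len(ncol(subsets))) {
    chosen <- subsets[, s]
    p_sub <- subset_probability(occupancy[chosen], sum(occupancy[pool]))
    extra <- total - richness
    alloc <- compositions(extra, richness)
    pr <- relabund[chosen] / sum(relabund[chosen])
    for (a in seq_len(nrow(alloc))) {
      counts <- numeric(length(occupancy))
      counts[chosen] <- 1 + alloc[a, ]
      p_alloc <- stats::dmultinom(alloc[a, ], prob = pr)
      communities[[length(communities) + 1L]] <- counts
      probs <- c(probs, p_sub * p_alloc)
    }
  }
  list(communities = do.call(rbind, communities), probs = probs)
}

bray_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Abundance-based Raup-Crick dissimilarity (RC_bray)
#'
#' For each sample pair, null community pairs are assembled preserving each
#' sample's observed richness and total abundance: species identities are
#' drawn without replacement with probability proportional to regional
#' occupancy, then the remaining individuals are allocated multinomially
#' with probability proportional to regional relative abundance. The
#' observed Bray-Curtis dissimilarity is located in the null distribution:
#' `RC = 2 * [(# null < obs) + 0.5 (# null = obs)] / n_null - 1`, clamped
#' to [-1, 1]; ties count at half weight. `exact = TRUE` replaces the
#' Monte-Carlo draw by exhaustive enumeration of every
#' richness/abundance-preserving assembly (tiny pools only) and returns the
#' exact probability-weighted statistic.
#'
#' @param otu samples x taxa integer count matrix (post-rarefaction).
#' @param cfg a [null_model_config()] (`n_null` and `seed` are used).
#' @param exact exhaustive enumeration instead of Monte Carlo.
#' @return Symmetric sample x sample matrix of RC_bray in [-1, 1].
#' @export
raup_crick_bray <- function(otu, cfg = null_model_config(), exact = FALSE) {
  otu <- check_otu_table(otu, integer_counts = TRUE)
  n_samp <- nrow(otu)
  if (n_samp < 2L) stop("need at least two samples", call. = FALSE)
  if (any(rowSums(otu) == 0)) stop("empty sample(s) in table", call. = FALSE)
  occupancy <- colSums(otu > 0)
  relabund <- colSums(otu) / sum(otu)
  richness <- rowSums(otu > 0)
  totals <- rowSums(otu)
  tol <- 1e-10
  rc <- matrix(0, n_samp, n_samp,
               dimnames = list(rownames(otu), rownames(otu)))
  if (exact) {
    dists <- lapply(seq_len(n_samp), function(s)
      null_assembly_distribution(richness[s], totals[s], occupancy, relabund))
    for (i in seq_len(n_samp - 1L)) for (j in seq(i + 1L, n_samp)) {
      obs <- bray_pair(otu[i, ], otu[j, ])
      ci <- dists[[i]]; cj <- dists[[j]]
      p_less <- 0; p_tie <- 0
      for (a in seq_along(ci$probs)) for (b in seq_along(cj$probs)) {
        bc <- bray_pair(ci$communities[a, ], cj$communities[b, ])
        pr <- ci$probs[a] * cj$probs[b]
        if (bc < obs - tol) p_less <- p_less + pr
        else if (abs(bc - obs) <= tol) p_tie <- p_tie + pr
      }
      rc[i, j] <- rc[j, i] <- max(-1, min(1, 2 * (p_less + 0.5 * p_tie) - 1))
    }
    return(rc)
  }
  # Monte Carlo: a bank of n_null seeded null communities per sample; the
  # k-th null pair for (x, y) combines the k-th draws of the two banks.
  pool <- which(occupancy > 0)
  bank <- with_seed(split_seed(cfg$seed, 61L), {
    lapply(seq_len(n_samp), function(s) {
      b <- matrix(0, cfg$n_null, ncol(otu))
      for (k in seq_len(cfg$n_null)) {
        chosen <- if (length(pool) == 1L) pool else
          sample(pool, richness[s], prob = occupancy[pool])
        cnt <- rep(1, length(chosen))
        if (totals[s] > richness[s]) {
          cnt <- cnt + stats::rmultinom(1, totals[s] - richness[s],
                                        prob = relabund[chosen])[, 1]
        }
        b[k, chosen] <- cnt
      }
      b
    })
  })
  for (i in seq_len(n_samp - 1L)) for (j in seq(i + 1L, n_samp)) {
    obs <- bray_pair(otu[i, ], otu[j, ])
    bi <- bank[[i]]; bj <- bank[[j]]
    bc_null <- rowSums(abs(bi - bj)) / rowSums(bi + bj)
    less <- sum(bc_null < obs - tol)
    ties <- sum(abs(bc_null - obs) <= tol)
    rc[i, j] <- rc[j, i] <-
      max(-1, min(1, 2 * ((less + 0.5 * ties) / cfg$n_null) - 1))
  }
  rc
}

#' Partition community turnover into five assembly processes
#'
#' Classifies every sample pair from its (betaNTI, RC_bray) values:
#' betaNTI > 2 -> heterogeneous selection; betaNTI < -2 -> homogeneous
#' selection; |betaNTI| < 2 with RC > 0.95 -> dispersal limitation, with
#' RC < -0.95 -> homogenizing dispersal, otherwise undominated. Boundary
#' values (betaNTI exactly +/-2, |RC| exactly 0.95) follow the strict
#' inequalities, falling to the stochastic / undominated side. Pairs with
#' undefined betaNTI are excluded from the fractions with a message.
#'
#' @param bnti pairwise betaNTI matrix (or `"beta_nti_result"`).
#' @param rc pairwise RC_bray matrix aligned on the same samples.
#' @return List of class `"assembly_partition"`: `pairs` (long-format
#'   data.frame with per-pair values and class) and `fractions` (named
#'   vector over the five classes, summing to 1).
#' @export
partition_processes <- function(bnti, rc) {
  if (inherits(bnti, "beta_nti_result")) bnti <- bnti$bnti
  if (!all(dim(bnti) == dim(rc)) ||
      !identical(rownames(bnti), rownames(rc)))
    stop("betaNTI and RC matrices must be aligned on the same samples",
         call. = FALSE)
  n <- nrow(bnti)
  ii <- which(lower.tri(bnti), arr.ind = TRUE)
  b <- bnti[lower.tri(bnti)]
  r <- rc[lower.tri(rc)]
  cls <- rep(NA_character_, length(b))
  cls[!is.na(b) & b > 2] <- "heterogeneous_selection"
  cls[!is.na(b) & b < -2] <- "homogeneous_selection"
  sto <- !is.na(b) & abs(b) <= 2
  cls[sto & r > 0.95] <- "dispersal_limitation"
  cls[sto & r < -0.95] <- "homogenizing_dispersal"
  cls[sto & abs(r) <= 0.95] <- "undominated"
  pairs <- data.frame(
    sample_1 = rownames(bnti)[ii[, 2]],
    sample_2 = rownames(bnti)[ii[, 1]],
    bnti = b, rc_bray = r, process = cls,
    stringsAsFactors = FALSE
  )
  n_undef <- sum(is.na(b))
  if (n_undef > 0)
    message(n_undef, " pair(s) with undefined betaNTI excluded from fractions")
  classified <- pairs$process[!is.na(pairs$process)]
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "undominated")
  fractions <- as.numeric(table(factor(classified, levels = lev))) /
    length(classified)
  names(fractions) <- lev
  structure(list(pairs = pairs, fractions = fractions,
                 n_undefined = n_undef),
            class = "assembly_partition")
}

#' @export
print.assembly_partition <- function(x, ...) {
  cat("Assembly-process partition over", nrow(x$pairs), "sample pairs:\n")
  print(round(100 * x$fractions, 1))
  if (x$n_undefined > 0)
    cat("(", x$n_undefined, "pair(s) undefined, excluded )\n")
  invisible(x)
}

#' Full assembly analysis for one OTU table and tree
#'
#' Convenience wrapper running [cophenetic_distances()], [nti()],
#' [beta_nti()], [raup_crick_bray()], and [partition_processes()]. The
#' significance of the mean NTI is evaluated by a two-sided one-sample
#' t-test of the per-sample NTI values against zero.
#'
#' @param otu samples x taxa integer count matrix.
#' @param tree phylogeny covering all table taxa.
#' @param cfg a [null_model_config()].
#' @return List of class `"assembly_result"` with elements `nti`,
#'   `mean_nti`, `mean_nti_p`, `beta_nti`, `rc_bray`, `partition`.
#' @export
assembly_analysis <- function(otu, tree, cfg = null_model_config()) {
  otu <- check_otu_table(otu, integer_counts = TRUE)
  coph <- cophenetic_distances(tree, colnames(otu))
  nti_df <- nti(otu, coph, cfg)
  bn <- beta_nti(otu, coph, cfg)
  rc <- raup_crick_bray(otu, cfg)
  part <- partition_processes(bn, rc)
  nti_vals <- nti_df$nti[!nti_df$undefined]
  tt <- if (length(nti_vals) > 1L && stats::sd(nti_vals) > 0)
    stats::t.test(nti_vals, mu = 0)$p.value else NA_real_
  structure(list(nti = nti_df, mean_nti = mean(nti_vals),
                 mean_nti_p = tt, beta_nti = bn, rc_bray = rc,
                 partition = part),
            class = "assembly_result")
}
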