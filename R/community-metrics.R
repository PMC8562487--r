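#' Rarefy an OTU table to equal depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (a single seeded draw, not an average over draws). Samples whose
#' total is below `depth` are dropped with a warning; a sample whose total
#' equals `depth` is returned unchanged.
#'
#' @param otu samples x taxa non-negative integer matrix.
#' @param depth target depth (default 1500 reads).
#' @param seed integer RNG seed; each sample draws from its own sub-seed so
#'   the result does not depend on sample order.
#' @return Rarefied integer matrix; every row sums to `depth`.
#' @export
rarefy <- function(otu, depth = 1500L, seed = 1L) {
  otu <- check_otu_table(otu, integer_counts = TRUE)
  if (length(depth) != 1L || depth <= 0)
    stop("depth must be a single positive integer", call. = FALSE)
  depth <- as.integer(depth)
  totals <- rowSums(otu)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(otu)[drop], collapse = ", "), call. = FALSE)
    otu <- otu[!drop, , drop = FALSE]
    totals <- totals[!drop]
  }
  if (nrow(otu) == 0L) stop("no samples at or above depth", call. = FALSE)
  out <- otu
  for (i in seq_len(nrow(otu))) {
    if (totals[i] == depth) next
    x <- otu[i, ]
    cum <- cumsum(x)
    picked <- with_seed(split_seed(seed, i), sample.int(totals[i], depth))
    out[i, ] <- tabulate(findInterval(picked, cum + 0.5) + 1L,
                         nbins = ncol(otu))
  }
  storage.mode(out) <- "integer"
  out
}

#' Observed richness and bias-corrected Chao1 per sample
#'
#' Observed richness counts taxa with nonzero counts; Chao1 uses the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1/F2 the
#' singleton and doubleton counts, so it is defined (and equals `S_obs`)
#' when there are no singletons. `classic = TRUE` switches to the classical
#' `S_obs + F1^2 / (2 F2)` form (falling back to the bias-corrected form
#' when F2 = 0). An all-zero sample yields (0, 0).
#'
#' @param otu samples x taxa integer count matrix (post-rarefaction).
#' @param classic use the classical Chao1 variant.
#' @return data.frame with `sample_id`, `observed`, `chao1`.
#' @export
alpha_diversity <- function(otu, classic = FALSE) {
  otu <- check_otu_table(otu, integer_counts = TRUE)
  obs <- rowSums(otu > 0)
  f1 <- rowSums(otu == 1)
  f2 <- rowSums(otu == 2)
  chao1 <- if (classic) {
    ifelse(f2 > 0, obs + f1^2 / (2 * f2), obs + f1 * (f1 - 1) / 2)
  } else {
    obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  chao1[obs == 0] <- 0
  data.frame(sample_id = rownames(otu), observed = as.integer(obs),
             chao1 = chao1, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`; symmetric, zero diagonal,
#' entries in [0, 1]. A pair of all-zero samples has undefined
#' dissimilarity and raises an error.
#'
#' @param otu samples x taxa abundance matrix (>= 2 samples).
#' @return Square symmetric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(otu) {
  otu <- check_otu_table(otu)
  if (nrow(otu) < 2L) stop("need at least two samples", call. = FALSE)
  zero <- rowSums(otu) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined for all-zero sample pair(s): ",
         paste(rownames(otu)[zero], collapse = ", "), call. = FALSE)
  d <- as.matrix(vegan::vegdist(otu, method = "bray"))
  dimnames(d) <- list(rownames(otu), rownames(otu))
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centred `-D^2 / 2` matrix. All
#' eigenvalues are reported (negative ones included, flagged); the
#' variance-explained denominator uses positive eigenvalues only and no
#' negative-eigenvalue correction is applied. If fewer than `k` positive
#' eigenvalues exist the coordinates are truncated with a warning.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param k number of axes to return (default 2).
#' @return List of class `"pcoa_result"`: `points` (n x k'), `eigenvalues`
#'   (all, descending), `variance_explained` (per returned axis),
#'   `negative_eigenvalues` flag.
#' @export
pcoa <- function(d, k = 2L) {
  d <- check_dist_matrix(d)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * 1e-10
  n_pos <- sum(pos)
  if (n_pos == 0L) stop("no positive eigenvalues", call. = FALSE)
  k_use <- min(k, n_pos)
  if (k_use < k)
    warning("only ", n_pos, " positive eigenvalue(s); returning ", k_use,
            " axes", call. = FALSE)
  pts <- e$vectors[, seq_len(k_use), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k_use)]), k_use)
  dimnames(pts) <- list(rownames(d), paste0("Axis", seq_len(k_use)))
  structure(list(
    points = pts,
    eigenvalues = e$values,
    variance_explained = e$values[seq_len(k_use)] / sum(e$values[pos]),
    negative_eigenvalues = any(e$values < -max(e$values[1], 0) * 1e-10)
  ), class = "pcoa_result")
}

# Pseudo-F and R^2 for one grouping of a distance matrix, from squared
# distances: SST = sum_{i<j} d^2 / N; SSW = sum_g within-group sum / n_g.
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  a <- length(lev)
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][lower.tri(d2[idx, idx, drop = FALSE])]) /
      length(idx)
  }
  ssa <- sst - ssw
  f <- (ssa / (a - 1)) / (ssw / (n - a))
  c(f = f, r2 = ssa / sst)
}

#' Permutation NPMANOVA on a dissimilarity matrix
#'
#' Single-factor nonparametric MANOVA: pseudo-F from among/within sums of
#' squared dissimilarities, with significance by free permutation of sample
#' labels (no strata). Monte-Carlo p-values follow the
#' `(exceedances + 1) / (n_perm + 1)` convention; `permutations =
#' "exhaustive"` enumerates all label permutations (small n only) and
#' returns the exact proportion with F >= observed. All pairwise two-group
#' tests are reported with raw and Bonferroni-adjusted p-values.
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param groups group labels, one per sample (>= 2 groups of >= 2).
#' @param n_perm number of Monte-Carlo permutations (>= 99).
#' @param seed integer RNG seed.
#' @param permutations `"montecarlo"` or `"exhaustive"`.
#' @param pairwise also run all pairwise two-group comparisons.
#' @return List of class `"permanova_result"`: `f`, `r2`, `p`, `n_perm`,
#'   and a `pairwise` data.frame with raw and Bonferroni-adjusted p-values.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L,
                      permutations = c("montecarlo", "exhaustive"),
                      pairwise = TRUE) {
  d <- check_dist_matrix(d)
  permutations <- match.arg(permutations)
  groups <- as.character(groups)
  if (length(groups) != nrow(d))
    stop("groups must have one label per sample", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L))
    stop("every group needs at least two members (singleton: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")", call. = FALSE)
  if (permutations == "montecarlo" && n_perm < 99L)
    stop("n_perm must be >= 99", call. = FALSE)
  d2 <- d^2
  obs <- permanova_stat(d2, groups)
  n <- nrow(d)
  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    fs <- vapply(perms, function(p) permanova_stat(d2, groups[p])[["f"]],
                 numeric(1))
    p_val <- mean(fs >= obs[["f"]] - 1e-12)
    n_used <- length(perms)
  } else {
    fs <- with_seed(split_seed(seed, 41L),
      vapply(seq_len(n_perm), function(i) {
        permanova_stat(d2, groups[sample.int(n)])[["f"]]
      }, numeric(1)))
    p_val <- (sum(fs >= obs[["f"]] - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  pw <- NULL
  if (pairwise) {
    lev <- names(tab)
    combs <- utils::combn(lev, 2)
    n_comp <- ncol(combs)
    pw <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
      idx <- groups %in% combs[, i]
      sub <- permanova(d[idx, idx], groups[idx], n_perm = n_perm,
                       seed = split_seed(seed, 100L + i),
                       permutations = permutations, pairwise = FALSE)
      data.frame(group1 = combs[1, i], group2 = combs[2, i],
                 f = sub$f, r2 = sub$r2, p = sub$p,
                 p_bonferroni = min(1, sub$p * n_comp),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(f = obs[["f"]], r2 = obs[["r2"]], p = p_val,
                 n_perm = n_used, pairwise = pw),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("NPMANOVA: pseudo-F =", format(x$f, digits = 4),
      " R2 =", format(x$r2, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$n_perm, "permutations )\n")
  if (!is.null(x$pairwise)) {
    cat("Pairwise comparisons (Bonferroni-adjusted):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}
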