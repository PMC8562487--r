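#' Spearman correlations with Benjamini-Hochberg adjustment
#'
#' Correlates every (variable, response) combination by Spearman's rank
#' correlation and adjusts the raw p-values across the whole declared test
#' family by the Benjamini-Hochberg step-up procedure. Constant variables
#' or responses give an undefined rho, flagged rather than silently NA.
#'
#' @param metadata data.frame of environmental variables.
#' @param responses data.frame (or named vector list) of response variables,
#'   same row order as `metadata`.
#' @param variables which metadata columns to test (default: all numeric).
#' @return data.frame: `variable`, `response`, `rho`, `p`, `p_adj`,
#'   `undefined`.
#' @export
spearman_with_fdr <- function(metadata, responses, variables = NULL) {
  if (is.null(variables))
    variables <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  responses <- as.data.frame(responses)
  if (nrow(responses) != nrow(metadata))
    stop("metadata and responses must have the same rows", call. = FALSE)
  grid <- expand.grid(variable = variables, response = names(responses),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- metadata[[grid$variable[i]]]
    y <- responses[[grid$response[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4L)
      stop("fewer than 4 paired observations for ", grid$variable[i],
           " vs ", grid$response[i], call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, rho = res[, "rho"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$undefined <- is.na(out$rho)
  out
}

#' Forward stepwise multivariate regression
#'
#' Forward selection: at each step the candidate giving the largest
#' sum-of-squares increment enters if its partial F-test is significant at
#' `alpha_enter`; selection stops when no candidate qualifies. A candidate
#' perfectly collinear with entered predictors contributes a zero increment
#' and never enters. Per-predictor contributions are sequential
#' (entry-order) shares of the total sum of squares, so they add up to the
#' full model's R-squared. `direction = "aic"` instead delegates to
#' both-direction AIC search via [stats::step()].
#'
#' @param y numeric response vector.
#' @param candidates data.frame of candidate predictors.
#' @param alpha_enter entry threshold for the partial F-test.
#' @param direction `"forward"` (default) or `"aic"`.
#' @return List of class `"stepwise_model"`: `selected` (entry order),
#'   `contribution_pct` (sequential % of total SS), `p_values`,
#'   `adj_r2`, `model` (the final `lm`).
#' @export
stepwise_regression <- function(y, candidates, alpha_enter = 0.05,
                                direction = c("forward", "aic")) {
  direction <- match.arg(direction)
  candidates <- as.data.frame(candidates)
  if (length(y) != nrow(candidates))
    stop("y and candidates must have the same length", call. = FALSE)
  dat <- data.frame(.y = y, candidates, check.names = FALSE)
  if (direction == "aic") {
    full <- stats::lm(.y ~ ., data = dat)
    null <- stats::lm(.y ~ 1, data = dat)
    fit <- stats::step(null, scope = list(lower = null, upper = full),
                       direction = "both", trace = 0)
    selected <- attr(stats::terms(fit), "term.labels")
  } else {
    selected <- character(0)
    pool <- names(candidates)
    repeat {
      if (!length(pool)) break
      base_fml <- stats::reformulate(
        if (length(selected)) sprintf("`%s`", selected) else "1",
        response = ".y")
      base_fit <- stats::lm(base_fml, data = dat)
      rss0 <- sum(stats::residuals(base_fit)^2)
      df0 <- stats::df.residual(base_fit)
      best <- NULL
      best_rss <- rss0
      for (cand in pool) {
        fml <- stats::reformulate(sprintf("`%s`", c(selected, cand)),
                                  response = ".y")
        fit <- stats::lm(fml, data = dat)
        rss <- sum(stats::residuals(fit)^2)
        if (rss < best_rss - 1e-12) {
          best <- cand
          best_rss <- rss
          best_fit <- fit
        }
      }
      if (is.null(best)) break
      df1 <- stats::df.residual(best_fit)
      if (df1 < 1L) break
      f_stat <- ((rss0 - best_rss) / (df0 - df1)) / (best_rss / df1)
      p_enter <- stats::pf(f_stat, df0 - df1, df1, lower.tail = FALSE)
      if (p_enter > alpha_enter) break
      selected <- c(selected, best)
      pool <- setdiff(pool, best)
    }
  }
  if (!length(selected)) {
    return(structure(list(selected = character(0),
                          contribution_pct = numeric(0),
                          p_values = numeric(0), adj_r2 = 0,
                          model = stats::lm(.y ~ 1, data = dat)),
                     class = "stepwise_model"))
  }
  fml <- stats::reformulate(sprintf("`%s`", selected), response = ".y")
  fit <- stats::lm(fml, data = dat)
  an <- stats::anova(fit)
  sst <- sum((y - mean(y))^2)
  seq_ss <- an[selected, "Sum Sq"]
  pvals <- an[selected, "Pr(>F)"]
  structure(list(selected = selected,
                 contribution_pct = 100 * seq_ss / sst,
                 p_values = stats::setNames(pvals, selected),
                 adj_r2 = summary(fit)$adj.r.squared,
                 model = fit),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (!length(x$selected)) {
    cat("Stepwise model: no predictor entered\n")
    return(invisible(x))
  }
  cat("Stepwise model (entry order):\n")
  print(data.frame(predictor = x$selected,
                   contribution_pct = round(x$contribution_pct, 2),
                   p = signif(x$p_values, 3), row.names = NULL))
  cat("Adjusted R2 =", round(x$adj_r2, 4), "\n")
  invisible(x)
}

#' Spatial eigenvectors from principal coordinates of neighbour matrices
#'
#' Builds the pairwise geographic distance matrix (great-circle by default,
#' planar Euclidean for synthetic grids), truncates it at the largest
#' minimum-spanning-tree edge (distances beyond the threshold are replaced
#' by four times the threshold), and returns the positive-eigenvalue axes
#' of its principal coordinates, PCNM1 first.
#'
#' @param latitude,longitude per-sample coordinates (decimal degrees, or
#'   arbitrary planar units with `planar = TRUE`).
#' @param planar use planar Euclidean distances instead of great-circle.
#' @return data.frame of PCNM axes (columns `PCNM1`, `PCNM2`, ...), with
#'   attributes `eigenvalues` and `threshold`.
#' @export
pcnm_axes <- function(latitude, longitude, planar = FALSE) {
  if (length(latitude) != length(longitude))
    stop("latitude and longitude must have the same length", call. = FALSE)
  xy <- cbind(longitude, latitude)
  if (nrow(unique(xy)) < 3L)
    stop("need at least three distinct locations", call. = FALSE)
  d <- if (planar) stats::dist(xy) else
    stats::as.dist(geosphere::distm(xy, fun = geosphere::distHaversine) / 1000)
  res <- vegan::pcnm(d)
  out <- as.data.frame(res$vectors)
  names(out) <- paste0("PCNM", seq_len(ncol(out)))
  attr(out, "eigenvalues") <- res$values[res$values > 0]
  attr(out, "threshold") <- res$threshold
  out
}

#' Euclidean distance matrix over selected metadata variables
#'
#' Standardizes each variable to zero mean and unit variance by default
#' before computing Euclidean distances, so variables on different scales
#' contribute comparably to the distance-matrix regressions.
#'
#' @param metadata data.frame with a `sample_id` column (used as ids) or
#'   rownames.
#' @param vars character vector of metadata columns.
#' @param standardize z-score each variable first (default TRUE).
#' @return Square symmetric matrix with sample ids as dimnames.
#' @export
env_distance <- function(metadata, vars, standardize = TRUE) {
  missing <- setdiff(vars, names(metadata))
  if (length(missing))
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(metadata[, vars, drop = FALSE])
  if (standardize) x <- scale(x)
  d <- as.matrix(stats::dist(x))
  ids <- if ("sample_id" %in% names(metadata)) metadata$sample_id
         else rownames(metadata)
  dimnames(d) <- list(ids, ids)
  d
}

mantel_r <- function(vx, vy, method) {
  if (method == "spearman") stats::cor(vx, vy, method = "spearman")
  else stats::cor(vx, vy)
}

#' Mantel and partial Mantel tests
#'
#' Correlates the unfolded off-diagonal vectors of two distance matrices
#' (Spearman rank correlation by default, Pearson via `method`). The
#' partial variant, given a conditioning matrix `dz`, correlates the
#' residuals of `dx | dz` with those of `dy | dz` (on ranks for the
#' Spearman form). Significance is one-sided (upper tail) by simultaneous
#' row/column permutation of one matrix, with the
#' `(exceedances + 1) / (n_perm + 1)` convention; `permutations =
#' "exhaustive"` enumerates all permutations (small n) and returns the
#' exact proportion.
#'
#' @param dx,dy distance matrices aligned on the same samples.
#' @param dz optional conditioning distance matrix (partial Mantel).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @param permutations `"montecarlo"` or `"exhaustive"`.
#' @return List of class `"mantel_result"`: `r`, `p`, `n_perm`, `partial`.
#' @export
mantel_test <- function(dx, dy, dz = NULL, method = c("spearman", "pearson"),
                        n_perm = 999L, seed = 1L,
                        permutations = c("montecarlo", "exhaustive")) {
  method <- match.arg(method)
  permutations <- match.arg(permutations)
  dx <- check_dist_matrix(dx)
  dy <- check_dist_matrix(dy)
  if (!all(dim(dx) == dim(dy)))
    stop("distance matrices must be aligned", call. = FALSE)
  if (!is.null(dz)) {
    dz <- check_dist_matrix(dz)
    if (!all(dim(dz) == dim(dx)))
      stop("conditioning matrix must be aligned", call. = FALSE)
  }
  n <- nrow(dx)
  vy <- offdiag(dy)
  if (stats::sd(offdiag(dx)) == 0 || stats::sd(vy) == 0)
    stop("constant off-diagonal: Mantel r undefined", call. = FALSE)
  # Partial r is the correlation of the residuals of x|z and y|z; for a
  # single conditioning matrix that equals the first-order partial
  # correlation formula, which avoids refitting per permutation.
  vz <- if (!is.null(dz)) offdiag(dz)
  stat <- function(mx) {
    vx <- offdiag(mx)
    if (is.null(dz)) return(mantel_r(vx, vy, method))
    if (method == "spearman") {
      vx <- rank(vx); vyr <- rank(vy); vzr <- rank(vz)
    } else {
      vyr <- vy; vzr <- vz
    }
    rxy <- stats::cor(vx, vyr)
    rxz <- stats::cor(vx, vzr)
    ryz <- stats::cor(vyr, vzr)
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (!is.finite(den) || den < 1e-12) return(0)
    (rxy - rxz * ryz) / den
  }
  r_obs <- stat(dx)
  if (permutations == "exhaustive") {
    perms <- all_permutations(n)
    rs <- vapply(perms, function(p) stat(dx[p, p]), numeric(1))
    p_val <- mean(rs >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
    rs <- with_seed(split_seed(seed, 71L),
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        stat(dx[p, p])
      }, numeric(1)))
    p_val <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p_val, n_perm = n_used,
                 partial = !is.null(dz), method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (x$partial) "Partial Mantel" else "Mantel",
      "(", x$method, "): r =", format(x$r, digits = 4),
      " p =", format(x$p, digits = 4),
      " (", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Multiple regression on distance matrices (MRM)
#'
#' Ordinary least squares of the unfolded off-diagonal response distances
#' on the unfolded predictor distances. Coefficient and R-squared p-values
#' come from simultaneously permuting the rows and columns of the response
#' matrix and refitting: coefficients are tested two-sided on |b|, the
#' model R-squared upper-tail, both with the
#' `(exceedances + 1) / (n_perm + 1)` convention. Collinear predictor
#' distances are flagged with a warning and their coefficients reported
#' as fitted by the pseudoinverse-free `lm` (NA for aliased terms).
#'
#' @param dy response distance matrix.
#' @param predictors named list of predictor distance matrices.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed.
#' @return List of class `"mrm_result"`: `coefficients` (data.frame with
#'   estimate and permutation p per predictor), `r2`, `p` (overall), `f`.
#' @export
mrm <- function(dy, predictors, n_perm = 999L, seed = 1L) {
  dy <- check_dist_matrix(dy)
  if (!is.list(predictors)) predictors <- list(X1 = predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    names(predictors) <- paste0("X", seq_along(predictors))
  predictors <- lapply(predictors, check_dist_matrix)
  if (any(vapply(predictors, function(m) !all(dim(m) == dim(dy)),
                 logical(1))))
    stop("all matrices must be aligned", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  n <- nrow(dy)
  x <- cbind(`(Intercept)` = 1,
             do.call(cbind, lapply(predictors, offdiag)))
  qx <- qr(x)
  if (qx$rank < ncol(x))
    warning("collinear predictor distances; coefficients not unique",
            call. = FALSE)
  fit_one <- function(yv) {
    cf <- qr.coef(qx, yv)
    res <- yv - x %*% ifelse(is.na(cf), 0, cf)
    r2 <- 1 - sum(res^2) / sum((yv - mean(yv))^2)
    list(coef = cf, r2 = r2)
  }
  y_obs <- offdiag(dy)
  obs <- fit_one(y_obs)
  k <- length(predictors)
  b_obs <- obs$coef[-1]
  exceed_b <- numeric(k)
  exceed_r2 <- 0
  with_seed(split_seed(seed, 73L), {
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      prm <- fit_one(offdiag(dy[p, p]))
      exceed_b <- exceed_b +
        (abs(prm$coef[-1]) >= abs(b_obs) - 1e-12)
      exceed_r2 <- exceed_r2 + (prm$r2 >= obs$r2 - 1e-12)
    }
  })
  coef_df <- data.frame(
    predictor = names(predictors),
    estimate = unname(b_obs),
    p = unname((exceed_b + 1) / (n_perm + 1)),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coef_df, r2 = obs$r2,
                 p = (exceed_r2 + 1) / (n_perm + 1),
                 intercept = unname(obs$coef[1]), n_perm = n_perm),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat("MRM: R2 =", format(x$r2, digits = 4),
      " p =", format(x$p, digits = 4), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Partial least squares path modeling (PLS-PM)
#'
#' Latent variables are estimated iteratively (centroid inner scheme,
#' mode A outer estimation) until the outer weights change by less than
#' `tol` (default 1e-6) or `max_iter` (default 300) iterations are reached;
#' non-convergence is an error reporting the iteration trace. Latent scores
#' are standardized to unit variance, path coefficients are OLS
#' coefficients of each endogenous latent on its predecessors (hence
#' standardized), and the goodness of fit is
#' `GoF = sqrt(mean communality x mean R2)`. Indirect effects along a path
#' are products of path coefficients.
#'
#' @param data data.frame holding every indicator (complete cases required).
#' @param blocks named list: latent variable -> character vector of
#'   indicator columns (each indicator in exactly one block).
#' @param path square lower-triangular 0/1 matrix (rows/cols = latent
#'   variables, in `names(blocks)` order); `path[i, j] = 1` means latent j
#'   predicts latent i. Must be acyclic (lower-triangular).
#' @param max_iter,tol iteration cap and convergence tolerance.
#' @return List of class `"plspm_model"`: `scores`, `outer_weights`,
#'   `loadings`, `paths` (data.frame from, to, coefficient, p),
#'   `r2`, `communality`, `gof`, `effects` (direct/indirect/total),
#'   `iterations`.
#' @export
plspm_fit <- function(data, blocks, path, max_iter = 300L, tol = 1e-6) {
  lv <- names(blocks)
  if (is.null(lv) || anyDuplicated(lv))
    stop("blocks must be a uniquely named list", call. = FALSE)
  inds <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(inds))
    stop("each indicator must belong to exactly one block", call. = FALSE)
  missing <- setdiff(inds, names(data))
  if (length(missing))
    stop("data lacks indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.matrix(path) || nrow(path) != length(lv) ||
      ncol(path) != length(lv))
    stop("path must be a square matrix over the blocks", call. = FALSE)
  if (any(path[upper.tri(path, diag = TRUE)] != 0))
    stop("path matrix must be lower-triangular (acyclic, diagonal zero)",
         call. = FALSE)
  dimnames(path) <- list(lv, lv)
  x <- as.matrix(data[, inds, drop = FALSE])
  if (any(!stats::complete.cases(x)))
    stop("complete cases required for all indicators", call. = FALSE)
  n <- nrow(x)
  xs <- scale(x)
  if (any(!is.finite(xs)))
    stop("constant indicator(s): cannot standardize", call. = FALSE)
  xb <- lapply(blocks, function(cols) xs[, cols, drop = FALSE])
  adj <- (path + t(path)) > 0

  w <- lapply(blocks, function(cols) rep(1, length(cols)))
  scores <- vapply(lv, function(b) {
    as.numeric(scale(xb[[b]] %*% w[[b]]))
  }, numeric(n))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cmat <- stats::cor(scores)
    # centroid inner scheme: inner proxy = sign-weighted sum of adjacent
    z <- vapply(lv, function(b) {
      nb <- which(adj[b, ])
      as.numeric(scores[, nb, drop = FALSE] %*% sign(cmat[b, nb]))
    }, numeric(n))
    # mode A outer estimation: weights = indicator-proxy correlations
    w_new <- lapply(lv, function(b) {
      wb <- as.numeric(stats::cor(xb[[b]], z[, b]))
      wb / sqrt(sum(wb^2))
    })
    names(w_new) <- lv
    w_norm <- lapply(lv, function(b) w[[b]] / sqrt(sum(w[[b]]^2)))
    delta <- max(unlist(Map(function(a, b) max(abs(abs(a) - abs(b))),
                            w_new, w_norm)))
    trace <- c(trace, delta)
    w <- w_new
    scores <- vapply(lv, function(b) {
      as.numeric(scale(xb[[b]] %*% w[[b]]))
    }, numeric(n))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("PLS-PM did not converge in ", max_iter,
         " iterations; last weight changes: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
         call. = FALSE)
  # orient each latent with its first indicator
  for (b in lv) {
    s <- stats::cor(scores[, b], xb[[b]][, 1])
    if (is.finite(s) && s < 0) {
      scores[, b] <- -scores[, b]
      w[[b]] <- -w[[b]]
    }
  }
  loadings <- lapply(lv, function(b) {
    stats::setNames(as.numeric(stats::cor(xb[[b]], scores[, b])),
                    blocks[[b]])
  })
  names(loadings) <- lv
  communality <- unlist(lapply(loadings, function(l) l^2))

  endo <- lv[rowSums(path) > 0]
  b_mat <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  paths_df <- NULL
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (b in endo) {
    preds <- lv[path[b, ] > 0]
    df <- data.frame(.y = scores[, b], scores[, preds, drop = FALSE])
    names(df) <- c(".y", preds)
    fit <- stats::lm(.y ~ ., data = df)
    sm <- summary(fit)
    cf <- stats::coef(fit)[preds]
    b_mat[b, preds] <- cf
    r2[b] <- sm$r.squared
    paths_df <- rbind(paths_df, data.frame(
      from = preds, to = b, coefficient = unname(cf),
      p = unname(sm$coefficients[preds, "Pr(>|t|)"]),
      stringsAsFactors = FALSE))
  }
  # total effects: sum over all directed paths = sum of powers of B
  total <- b_mat
  pw <- b_mat
  for (i in seq_len(length(lv) - 1L)) {
    pw <- pw %*% b_mat
    total <- total + pw
  }
  eff <- NULL
  for (b in endo) for (a in lv[total[b, ] != 0 | b_mat[b, ] != 0]) {
    eff <- rbind(eff, data.frame(
      from = a, to = b, direct = b_mat[b, a],
      indirect = total[b, a] - b_mat[b, a], total = total[b, a],
      stringsAsFactors = FALSE))
  }
  gof <- sqrt(mean(communality) * mean(r2))
  structure(list(scores = scores, outer_weights = w, loadings = loadings,
                 paths = paths_df, r2 = r2, communality = communality,
                 gof = gof, effects = eff, iterations = it,
                 blocks = blocks, path = path),
            class = "plspm_model")
}

#' @export
print.plspm_model <- function(x, ...) {
  cat("PLS-PM (centroid scheme, mode A), converged in", x$iterations,
      "iterations\n")
  print(x$paths, digits = 3)
  cat("R2:", paste(names(x$r2), round(x$r2, 3), sep = " = ",
                   collapse = ", "), "\n")
  cat("GoF =", round(x$gof, 4), "\n")
  invisible(x)
}

#' Potential denitrification rate from two-point N2O accumulation
#'
#' `rate = (N2O at 4 h - N2O at 2 h) / (2 h x dry soil mass)`, in
#' ug N2O-N per g dry soil per hour. Negative rates are allowed but
#' flagged with a warning.
#'
#' @param n2o_at_2h,n2o_at_4h accumulated N2O-N mass (ug) at 2 h and 4 h.
#' @param dry_soil dry-soil mass in the incubation (g, > 0).
#' @return Numeric rate(s), ug N2O-N g^-1 h^-1.
#' @export
pdr_rate <- function(n2o_at_2h, n2o_at_4h, dry_soil) {
  if (any(dry_soil <= 0)) stop("dry_soil must be > 0", call. = FALSE)
  rate <- (n2o_at_4h - n2o_at_2h) / (2 * dry_soil)
  if (any(rate < 0))
    warning(sum(rate < 0), " negative rate(s): N2O decreased between ",
            "measurements", call. = FALSE)
  rate
}
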