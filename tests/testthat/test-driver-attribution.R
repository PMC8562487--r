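test_that("Spearman correlations and BH adjustment follow the closed forms", {
  md <- data.frame(x = 1:8, const = rep(1, 8))
  resp <- data.frame(y = (1:8)^2)
  out <- spearman_with_fdr(md, resp, variables = c("x", "const"))
  expect_equal(out$rho[out$variable == "x"], 1)
  expect_true(out$undefined[out$variable == "const"])

  # BH step-up on (0.01, 0.02, 0.03, 0.04), family of 4 -> all 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))

  expect_error(spearman_with_fdr(md[1:3, ], resp[1:3, , drop = FALSE],
                                 variables = "x"), "4 paired")
})

test_that("spearman raw p-values are calibrated under independence", {
  rej <- 0
  n_rep <- 200
  set.seed(17)
  for (i in seq_len(n_rep)) {
    md <- data.frame(x = stats::rnorm(30))
    resp <- data.frame(y = stats::rnorm(30))
    out <- spearman_with_fdr(md, resp, variables = "x")
    if (out$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.01)
  expect_lte(rej / n_rep, 0.10)
})

test_that("forward stepwise selection recovers planted predictors", {
  set.seed(5)
  x1 <- stats::rnorm(96)
  x2 <- stats::rnorm(96)
  x3 <- stats::rnorm(96)

  # exact dependence on x1 only
  m <- stepwise_regression(3 * x1 + 1, data.frame(x1, x2, x3))
  expect_equal(m$selected, "x1")
  expect_equal(m$adj_r2, 1, tolerance = 1e-10)

  # duplicated candidate: only one of the pair enters
  m2 <- stepwise_regression(3 * x1 + 1, data.frame(x1, x1b = x1, x2))
  expect_length(intersect(m2$selected, c("x1", "x1b")), 1)

  # two planted effects: x1 enters first, contributions ordered, and the
  # sequential contributions sum to the model R^2
  y <- x1 + 0.5 * x2 + stats::rnorm(96, 0, 0.4)
  m3 <- stepwise_regression(y, data.frame(x1, x2, x3))
  expect_setequal(m3$selected, c("x1", "x2"))
  expect_equal(m3$selected[1], "x1")
  expect_gt(m3$contribution_pct[1], m3$contribution_pct[2])
  r2 <- summary(m3$model)$r.squared
  expect_equal(sum(m3$contribution_pct) / 100, r2, tolerance = 1e-10)
})

test_that("PCNM axes match an independent eigendecomposition", {
  # 10 equally spaced collinear points, planar distances
  lat <- rep(0, 10)
  lon <- seq(0, 9)
  ax <- pcnm_axes(lat, lon, planar = TRUE)
  # oracle: hand-built truncated matrix, double-centred eigendecomposition
  d <- as.matrix(stats::dist(cbind(lon, lat)))
  thr <- 1                      # largest MST edge of a unit-spaced line
  dt <- d
  dt[dt > thr] <- 4 * thr
  n <- nrow(dt)
  g <- -0.5 * dt^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  ev <- eigen(ctr %*% g %*% ctr, symmetric = TRUE)$values
  n_pos <- sum(ev > max(ev) * 1e-8)
  expect_equal(ncol(ax), n_pos)
  expect_equal(sum(ax$PCNM1), 0, tolerance = 1e-10)

  # doubling the spacing leaves eigenvector directions unchanged
  ax2 <- pcnm_axes(lat, 2 * lon, planar = TRUE)
  expect_equal(abs(stats::cor(ax$PCNM1, ax2$PCNM1)), 1, tolerance = 1e-8)

  expect_error(pcnm_axes(rep(1, 5), rep(2, 5)), "distinct")
})

test_that("Mantel statistics match identity, enumeration, and vegan", {
  otu <- random_otu(6, 12, seed = 21, depth = 80)
  d <- bray_curtis(otu)
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)

  # pearson r agrees with vegan's mantel statistic
  otu2 <- random_otu(6, 12, seed = 22, depth = 80)
  d2 <- bray_curtis(otu2)
  mt2 <- mantel_test(d, d2, method = "pearson", n_perm = 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(d), stats::as.dist(d2),
                       permutations = 99)
  expect_equal(mt2$r, ref$statistic, ignore_attr = TRUE, tolerance = 1e-10)

  # exhaustive 4x4 p equals direct enumeration over all 4! relabelings
  d4 <- bray_curtis(random_otu(4, 10, seed = 3, depth = 50))
  e4 <- bray_curtis(random_otu(4, 10, seed = 4, depth = 50))
  mt4 <- mantel_test(d4, e4, method = "pearson",
                     permutations = "exhaustive")
  perms <- combinat_perms(4)
  rs <- vapply(perms, function(p) {
    stats::cor(as.vector(stats::as.dist(d4[p, p])),
               as.vector(stats::as.dist(e4)))
  }, numeric(1))
  expect_equal(mt4$p, mean(rs >= mt4$r - 1e-12), tolerance = 1e-12)

  # partialling a matrix out of itself removes all signal
  mtp <- mantel_test(d, d2, dz = d, n_perm = 99, seed = 1)
  expect_lt(abs(mtp$r), 1e-10)
  mtself <- mantel_test(d, d2, dz = d2, n_perm = 99, seed = 1)
  expect_lt(abs(mtself$r), 1e-10)

  # empty conditioning set equals the plain test
  expect_equal(mantel_test(d, d2, n_perm = 99, seed = 1)$r,
               mantel_test(d, d2, dz = NULL, n_perm = 99, seed = 1)$r)

  cst <- matrix(0.3, 6, 6) - diag(0.3, 6)
  expect_error(mantel_test(cst, d), "constant")
})

test_that("MRM equals direct OLS on unfolded distances", {
  set.seed(8)
  x <- matrix(stats::rnorm(24), 12, 2)
  dx1 <- as.matrix(stats::dist(x[, 1]))
  dx2 <- as.matrix(stats::dist(x[, 2]))
  dy <- 2 * dx1 + 3 * dx2
  m <- mrm(dy, list(a = dx1, b = dx2), n_perm = 99, seed = 2)
  expect_equal(m$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)

  # coefficients equal lm on the unfolded vectors
  otu <- random_otu(10, 15, seed = 30, depth = 100)
  dyy <- bray_curtis(otu)
  fit <- stats::lm(as.vector(stats::as.dist(dyy)) ~
                     as.vector(stats::as.dist(dx1[1:10, 1:10])) +
                     as.vector(stats::as.dist(dx2[1:10, 1:10])))
  m2 <- mrm(dyy, list(a = dx1[1:10, 1:10], b = dx2[1:10, 1:10]),
            n_perm = 99, seed = 2)
  expect_equal(m2$coefficients$estimate, unname(stats::coef(fit)[-1]),
               tolerance = 1e-10)

  # duplicate predictor spans the same space: R^2 unchanged
  expect_warning(
    m3 <- mrm(dyy, list(a = dx1[1:10, 1:10], a2 = dx1[1:10, 1:10]),
              n_perm = 99, seed = 2), "collinear")
  m4 <- mrm(dyy, list(a = dx1[1:10, 1:10]), n_perm = 99, seed = 2)
  expect_equal(m3$r2, m4$r2, tolerance = 1e-10)
})

test_that("PLS-PM collapses to Pearson paths for single-indicator blocks", {
  set.seed(12)
  x <- stats::rnorm(200)
  y <- 0.6 * x + stats::rnorm(200, 0, 0.8)
  dat <- data.frame(x = x, y = y)
  path <- matrix(c(0, 1, 0, 0), 2, 2)
  fit <- plspm_fit(dat, list(X = "x", Y = "y"), path)
  expect_equal(fit$paths$coefficient, stats::cor(x, y), tolerance = 1e-8)
  expect_equal(unname(fit$communality), c(1, 1), tolerance = 1e-10)
  expect_equal(fit$gof, sqrt(mean(fit$r2)), tolerance = 1e-10)
  # latent scores standardized to unit variance
  expect_equal(unname(apply(fit$scores, 2, stats::var)), c(1, 1),
               tolerance = 1e-8)
})

test_that("PLS-PM recovers planted path coefficients in a latent chain", {
  set.seed(77)
  n <- 500
  geo <- stats::rnorm(n)
  mat <- 0.7 * geo + stats::rnorm(n, 0, sqrt(1 - 0.49))
  plant <- 0.6 * mat + stats::rnorm(n, 0, sqrt(1 - 0.36))
  soil <- 0.65 * plant + stats::rnorm(n, 0, sqrt(1 - 0.4225))
  comm <- 0.6 * soil + stats::rnorm(n, 0, sqrt(1 - 0.36))
  mk <- function(lv) data.frame(a = lv + stats::rnorm(n, 0, 0.3),
                                b = lv + stats::rnorm(n, 0, 0.3))
  dat <- cbind(stats::setNames(mk(geo), c("g1", "g2")),
               stats::setNames(mk(mat), c("m1", "m2")),
               stats::setNames(mk(plant), c("p1", "p2")),
               stats::setNames(mk(soil), c("s1", "s2")),
               stats::setNames(mk(comm), c("c1", "c2")))
  blocks <- list(geo = c("g1", "g2"), climate = c("m1", "m2"),
                 plant = c("p1", "p2"), soil = c("s1", "s2"),
                 community = c("c1", "c2"))
  path <- matrix(0, 5, 5)
  path[2, 1] <- path[3, 2] <- path[4, 3] <- path[5, 4] <- 1
  fit <- plspm_fit(dat, blocks, path)
  truth <- c(0.7, 0.6, 0.65, 0.6)
  expect_equal(fit$paths$coefficient, truth, tolerance = 0.1)
  expect_true(fit$gof > 0 && fit$gof < 1)
  # indirect effect of geo on community = product along the chain
  eff <- fit$effects
  ind <- eff$indirect[eff$from == "geo" & eff$to == "community"]
  expect_equal(ind, prod(fit$paths$coefficient), tolerance = 1e-10)
})

test_that("PDR rates follow the two-point incubation arithmetic", {
  expect_equal(pdr_rate(40, 40, 20), 0)
  expect_equal(pdr_rate(40, 80, 20), 1.0)
  expect_equal(pdr_rate(2 * 40, 2 * 80, 20), 2 * pdr_rate(40, 80, 20))
  expect_warning(r <- pdr_rate(80, 40, 20), "negative")
  expect_equal(r, -1.0)
  expect_error(pdr_rate(40, 80, 0), "dry_soil")
})
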