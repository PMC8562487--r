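test_that("cophenetic distances are path lengths on the tree", {
  d <- cophenetic_distances(balanced_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["C", "D"], 2)
  expect_true(all(diag(d) == 0))
  ds <- cophenetic_distances(star_tree(5))
  expect_true(all(ds[upper.tri(ds)] == 2))
  expect_error(cophenetic_distances(balanced_tree(), taxa = c("A", "Z")), "Z")
})

test_that("beta-MNTD matches hand values and the brute-force oracle", {
  d <- cophenetic_distances(balanced_tree())
  x <- c(A = 1, B = 1, C = 0, D = 0)
  y <- c(A = 0, B = 0, C = 1, D = 1)
  expect_equal(beta_mntd(x, y, d), 4)          # every cross-distance is 4
  expect_equal(beta_mntd(x, x, d), 0)          # self-match
  expect_equal(beta_mntd(2 * x, 2 * y, d), beta_mntd(x, y, d))
  expect_error(beta_mntd(x, c(A = 0, B = 0, C = 0, D = 0), d), "non-empty")

  # oracle equivalence on random tables, weighted and unweighted
  for (s in 1:8) {
    set.seed(s)
    n_taxa <- sample(3:6, 1)
    tree <- simulate_phylogeny(n_taxa, seed = s)
    dmat <- cophenetic_distances(tree)
    otu <- random_otu(sample(2:4, 1), n_taxa, seed = s + 50, depth = 20)
    colnames(otu) <- rownames(dmat)
    for (w in c(TRUE, FALSE)) {
      for (i in seq_len(nrow(otu) - 1)) for (j in seq(i + 1, nrow(otu))) {
        expect_equal(beta_mntd(otu[i, ], otu[j, ], dmat, weighted = w),
                     oracle_bmntd(otu[i, ], otu[j, ], dmat, weighted = w),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("exact beta-NTI equals the exhaustive permutation z-score", {
  for (s in 1:4) {
    tree <- simulate_phylogeny(5, seed = s)
    dmat <- cophenetic_distances(tree)
    otu <- random_otu(3, 5, seed = s + 10, depth = 15)
    colnames(otu) <- rownames(dmat)
    bn <- beta_nti(otu, dmat, null_model_config(seed = 1), exact = TRUE)
    for (i in 1:2) for (j in seq(i + 1, 3)) {
      expect_equal(bn$bnti[i, j],
                   oracle_exact_bnti(otu[i, ], otu[j, ], dmat),
                   tolerance = 1e-12)
    }
    # invariant to taxon ordering under the exhaustive null
    prm <- sample(5)
    bn2 <- beta_nti(otu[, prm], dmat, null_model_config(seed = 1),
                    exact = TRUE)
    expect_equal(bn$bnti, bn2$bnti, tolerance = 1e-10)
  }
})

test_that("phylogenetically clustered disjoint communities give negative beta-NTI", {
  # two samples drawing disjoint taxon sets from one shallow clade of a
  # 30-taxon pool: observed beta-MNTD is far below the label-shuffling null
  nwk <- paste0("((a1:0.05,a2:0.05,a3:0.05,a4:0.05,a5:0.05,a6:0.05):0.95,(",
                paste0("b", 1:24, ":0.5", collapse = ","), "):0.5);")
  tree <- ape::read.tree(text = nwk)
  dmat <- cophenetic_distances(tree)
  x <- stats::setNames(numeric(30), rownames(dmat))
  y <- x
  x[c("a1", "a2", "a3")] <- 10
  y[c("a4", "a5", "a6")] <- 10
  otu <- rbind(S1 = x, S2 = y)
  bn <- beta_nti(otu, dmat, null_model_config(n_null = 999, seed = 3))
  expect_equal(bn$bmntd_obs[1, 2], 0.1)
  expect_lt(bn$bnti[1, 2], -2)

  # identical communities are invariant under the coupled label shuffle:
  # every null equals the observed zero, so the pair is flagged undefined
  otu2 <- rbind(S1 = x, S2 = x)
  bn2 <- beta_nti(otu2, dmat, null_model_config(n_null = 999, seed = 3))
  expect_equal(bn2$bmntd_obs[1, 2], 0)
  expect_true(is.na(bn2$bnti[1, 2]))
  expect_equal(bn2$n_undefined, 1)
})

test_that("communities shuffled off the phylogeny calibrate within |betaNTI| < 2", {
  tree <- simulate_phylogeny(60, seed = 11)
  dmat <- cophenetic_distances(tree)
  set.seed(99)
  otu <- random_otu(10, 60, seed = 99, depth = 300)
  otu[otu < 3] <- 0                      # sparsify, identity random wrt tree
  colnames(otu) <- sample(rownames(dmat))
  otu <- otu[, rownames(dmat)]
  bn <- beta_nti(otu, dmat, null_model_config(n_null = 199, seed = 4))
  vals <- bn$bnti[lower.tri(bn$bnti)]
  expect_gte(mean(abs(vals[!is.na(vals)]) < 2), 0.8)
})

test_that("observed MNTD and beta-MNTD agree with picante", {
  skip_if_not_installed("picante")
  tree <- simulate_phylogeny(15, seed = 8)
  dmat <- cophenetic_distances(tree)
  otu <- random_otu(6, 15, seed = 4, depth = 60)
  colnames(otu) <- rownames(dmat)
  cfg <- null_model_config(n_null = 99, seed = 1)
  ours <- beta_nti(otu, dmat, cfg)$bmntd_obs
  ref <- as.matrix(picante::comdistnt(otu, dmat, abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
  obs_mntd <- nti(otu, dmat, cfg)$mntd_obs
  ref_mntd <- picante::mntd(otu, dmat, abundance.weighted = TRUE)
  expect_equal(obs_mntd, ref_mntd, tolerance = 1e-10)
})

test_that("NTI flags degenerate nulls and detects clustering", {
  dstar <- cophenetic_distances(star_tree(6))
  otu <- matrix(5L, 2, 6,
                dimnames = list(c("S1", "S2"), rownames(dstar)))
  res <- nti(otu, dstar, null_model_config(n_null = 99, seed = 1))
  expect_true(all(res$undefined))
  expect_true(all(is.na(res$nti)))

  # two sister taxa on the balanced tree are clustered under the
  # exhaustive 4!-permutation null
  d4 <- cophenetic_distances(balanced_tree())
  sample_ab <- matrix(c(3L, 3L, 0L, 0L, 3L, 0L, 3L, 0L), 2, 4, byrow = TRUE,
                      dimnames = list(c("SisterPair", "Spread"),
                                      rownames(d4)))
  res4 <- nti(sample_ab, d4, null_model_config(seed = 1), exact = TRUE)
  expect_gt(res4$nti[1], 0)
  expect_error(nti(matrix(c(5L, 0L, 0L, 0L), 1, 4,
                          dimnames = list("S1", rownames(d4))), d4),
               "two resident taxa")
})

test_that("exact Raup-Crick matches the exhaustive enumeration oracle", {
  # 4-taxon pool, 2 individuals per sample
  otu <- rbind(S1 = c(1L, 1L, 0L, 0L), S2 = c(0L, 1L, 1L, 0L),
               S3 = c(0L, 0L, 2L, 0L), S4 = c(1L, 0L, 0L, 1L))
  colnames(otu) <- paste0("t", 1:4)
  rc <- raup_crick_bray(otu, exact = TRUE)
  for (i in 1:3) for (j in seq(i + 1, 4)) {
    expect_equal(rc[i, j], oracle_rc_pair(otu, i, j), tolerance = 1e-12)
  }
  expect_equal(rc, t(rc))
  # invariant under taxon reordering (exact mode)
  prm <- c(3, 1, 4, 2)
  rc2 <- raup_crick_bray(otu[, prm], exact = TRUE)
  expect_equal(unname(rc), unname(rc2), tolerance = 1e-12)
})

test_that("Raup-Crick hits its boundary cases", {
  # identical samples in a diverse pool: observed BC = 0 below all nulls
  pool <- random_otu(6, 20, seed = 12, depth = 100)
  pool[1, ] <- pool[2, ]
  rc <- raup_crick_bray(pool, null_model_config(n_null = 199, seed = 5))
  expect_lt(rc[1, 2], -0.95)
  expect_true(all(rc >= -1 & rc <= 1))

  # a single-taxon pool: every null equals the observed zero -> RC = 0
  mono <- rbind(S1 = c(4L), S2 = c(7L))
  colnames(mono) <- "t1"
  rc1 <- raup_crick_bray(mono, exact = TRUE)
  expect_equal(rc1[1, 2], 0)

  expect_error(raup_crick_bray(pool[1, , drop = FALSE]), "two samples")
})

test_that("the five-process partition follows the threshold rules exactly", {
  b <- c(2.5, -2.5, 1.0, 1.0, 1.0, 2.0, -2.0, 0.5, 0.5)
  r <- c(0.1, 0.1, 0.97, -0.97, 0.5, 0.99, -0.99, 0.95, -0.95)
  expected <- c("heterogeneous_selection", "homogeneous_selection",
                "dispersal_limitation", "homogenizing_dispersal",
                "undominated",
                # boundary conventions: |betaNTI| = 2 and |RC| = 0.95 are
                # not strict exceedances
                "dispersal_limitation", "homogenizing_dispersal",
                "undominated", "undominated")
  n <- length(b) + 1
  bm <- matrix(0, n, n, dimnames = list(paste0("S", 1:n), paste0("S", 1:n)))
  rm_ <- bm
  bm[2:n, 1] <- b; bm[1, 2:n] <- b
  rm_[2:n, 1] <- r; rm_[1, 2:n] <- r
  part <- partition_processes(bm, rm_)
  got <- part$pairs$process[part$pairs$sample_1 == "S1"]
  expect_equal(got, expected)
  expect_equal(sum(part$fractions), 1, tolerance = 1e-15)

  # fractions sum to one on arbitrary matrices
  set.seed(31)
  for (rep in 1:5) {
    nn <- 8
    bmat <- matrix(0, nn, nn); rmat <- matrix(0, nn, nn)
    bv <- stats::rnorm(nn * (nn - 1) / 2, 0, 2)
    rv <- stats::runif(nn * (nn - 1) / 2, -1, 1)
    bmat[lower.tri(bmat)] <- bv; bmat <- bmat + t(bmat)
    rmat[lower.tri(rmat)] <- rv; rmat <- rmat + t(rmat)
    dimnames(bmat) <- dimnames(rmat) <-
      list(paste0("S", 1:nn), paste0("S", 1:nn))
    pp <- partition_processes(bmat, rmat)
    expect_equal(sum(pp$fractions), 1, tolerance = 1e-15)
  }

  expect_error(partition_processes(bm[1:5, 1:5], rm_), "aligned")
})
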