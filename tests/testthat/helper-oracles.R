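# Shared fixtures and independent brute-force oracles for the null-model
# machinery. Oracles deliberately use naive double loops and exhaustive
# ordered enumeration so they share no code path with the implementation.

balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0(
    "(", paste0(letters[seq_len(n)], ":1", collapse = ","), ");"))
}

random_otu <- function(n_samples, n_taxa, seed, depth = 50L) {
  set.seed(seed)
  m <- t(stats::rmultinom(n_samples, depth,
                          prob = stats::runif(n_taxa, 0.2, 1)))
  dimnames(m) <- list(paste0("S", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  m
}

# Double-loop beta-MNTD: mean over each sample's residents of the distance
# to the nearest resident of the other sample, averaged over both
# directions.
oracle_bmntd <- function(x, y, d, weighted = TRUE) {
  ix <- which(x > 0)
  iy <- which(y > 0)
  fx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  fy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  t1 <- 0
  for (k in seq_along(ix)) t1 <- t1 + fx[k] * min(d[ix[k], iy])
  t2 <- 0
  for (k in seq_along(iy)) t2 <- t2 + fy[k] * min(d[iy[k], ix])
  unname((t1 + t2) / 2)
}

# Exact beta-NTI z-score over all taxon-label permutations, built on the
# double-loop oracle.
oracle_exact_bnti <- function(x, y, d) {
  n <- nrow(d)
  perms <- combinat_perms(n)
  obs <- oracle_bmntd(x, y, d)
  nulls <- vapply(perms, function(p) oracle_bmntd(x, y, d[p, p]), numeric(1))
  unname((obs - mean(nulls)) / stats::sd(nulls))
}

# Recursive permutation generator kept separate from the package internals.
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

# Exhaustive Raup-Crick oracle: enumerates ordered species draws (weighted
# without replacement by occupancy) and per-individual allocations
# (weighted by regional relative abundance), so every richness- and
# abundance-preserving assembly appears with its exact probability.
oracle_rc_pair <- function(otu, i, j) {
  occ <- colSums(otu > 0)
  ra <- colSums(otu) / sum(otu)
  pool <- which(occ > 0)
  enum_nulls <- function(S, N) {
    seqs <- if (S == 1) matrix(pool, ncol = 1) else {
      g <- as.matrix(expand.grid(rep(list(pool), S)))
      g[apply(g, 1, function(r) length(unique(r)) == S), , drop = FALSE]
    }
    out_c <- list()
    out_p <- numeric(0)
    for (r in seq_len(nrow(seqs))) {
      sp <- seqs[r, ]
      pr <- 1
      rem <- sum(occ[pool])
      for (s in sp) {
        pr <- pr * occ[s] / rem
        rem <- rem - occ[s]
      }
      extra <- N - S
      if (extra == 0) {
        cnt <- numeric(ncol(otu))
        cnt[sp] <- 1
        out_c[[length(out_c) + 1L]] <- cnt
        out_p <- c(out_p, pr)
      } else {
        assign <- as.matrix(expand.grid(rep(list(seq_along(sp)), extra)))
        w <- ra[sp] / sum(ra[sp])
        for (a in seq_len(nrow(assign))) {
          cnt <- numeric(ncol(otu))
          cnt[sp] <- 1
          pa <- 1
          for (e in seq_len(ncol(assign))) {
            k <- assign[a, e]
            cnt[sp[k]] <- cnt[sp[k]] + 1
            pa <- pa * w[k]
          }
          out_c[[length(out_c) + 1L]] <- cnt
          out_p <- c(out_p, pr * pa)
        }
      }
    }
    list(c = do.call(rbind, out_c), p = out_p)
  }
  bc <- function(a, b) sum(abs(a - b)) / sum(a + b)
  obs <- bc(otu[i, ], otu[j, ])
  ni <- enum_nulls(sum(otu[i, ] > 0), sum(otu[i, ]))
  nj <- enum_nulls(sum(otu[j, ] > 0), sum(otu[j, ]))
  p_less <- 0
  p_tie <- 0
  for (a in seq_along(ni$p)) for (b in seq_along(nj$p)) {
    v <- bc(ni$c[a, ], nj$c[b, ])
    pr <- ni$p[a] * nj$p[b]
    if (v < obs - 1e-10) p_less <- p_less + pr
    else if (abs(v - obs) <= 1e-10) p_tie <- p_tie + pr
  }
  unname(2 * (p_less + 0.5 * p_tie) - 1)
}
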