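# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Deterministic seed-splitting rule: every stochastic stage draws its own
# sub-seed from the single top-level seed, so stages are reproducible in
# isolation and insensitive to the order in which other stages consume
# random numbers. Kept below 2^31 - 1.
split_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 1000003L) * 2039L + 7919L * offset) %% 2147483562L
}

# Lower-triangle unfolding of a square symmetric matrix (column-major,
# matching as.vector(as.dist(m))).
offdiag <- function(m) m[lower.tri(m)]

# Validate a square symmetric dissimilarity matrix with zero diagonal.
check_dist_matrix <- function(d, name = deparse(substitute(d))) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(name, " must be a square matrix or 'dist' object", call. = FALSE)
  if (any(!is.finite(d)))
    stop(name, " contains non-finite entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop(name, " is not symmetric", call. = FALSE)
  if (max(abs(diag(d))) > 1e-8)
    stop(name, " has a nonzero diagonal", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
  }
  d
}

# Validate a samples x taxa count/abundance matrix.
check_otu_table <- function(otu, integer_counts = FALSE) {
  if (is.data.frame(otu)) otu <- as.matrix(otu)
  if (!is.matrix(otu) || !is.numeric(otu))
    stop("OTU table must be a numeric samples x taxa matrix", call. = FALSE)
  if (any(!is.finite(otu)) || any(otu < 0))
    stop("OTU table entries must be finite and non-negative", call. = FALSE)
  if (is.null(rownames(otu))) rownames(otu) <- paste0("S", seq_len(nrow(otu)))
  if (is.null(colnames(otu))) colnames(otu) <- paste0("OTU", seq_len(ncol(otu)))
  if (anyDuplicated(rownames(otu)))
    stop("duplicate sample ids in OTU table", call. = FALSE)
  if (anyDuplicated(colnames(otu)))
    stop("duplicate taxon ids in OTU table", call. = FALSE)
  if (integer_counts && any(abs(otu - round(otu)) > 1e-8))
    stop("OTU table must hold integer counts (rarefy first)", call. = FALSE)
  otu
}

# All permutations of seq_len(n), as a list; used by the exhaustive null
# options. Guarded: n! grows fast.
all_permutations <- function(n, max_n = 8L) {
  if (n > max_n)
    stop("exhaustive enumeration limited to n <= ", max_n, call. = FALSE)
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  rec <- function(prefix, remaining) {
    if (!length(remaining)) {
      k <<- k + 1L
      out[[k]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(remaining))
      rec(c(prefix, remaining[i]), remaining[-i])
  }
  rec(integer(0), seq_len(n))
  out
}

# Column-wise minima of d[, idx] as a vector over rows; pmin chain keeps
# this at C speed without extra dependencies.
row_mins_subset <- function(d, idx) {
  if (length(idx) == 1L) return(d[, idx])
  do.call(pmin.int, lapply(idx, function(j) d[, j]))
}
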